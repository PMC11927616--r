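CATEGORIES <- c("face", "house", "flower", "hand")

#' Generate a category-structured stimulus feature set
#'
#' Emulates deep-network embeddings of natural images from four stimulus
#' categories (face, house, flower, hand). Each category is assigned a mean
#' vector in feature space; pairwise distances between category means are
#' governed by `separation`, and individual stimuli scatter isotropically
#' (unit variance per dimension) around their category mean. With the
#' default separation the leading principal component of the features
#' separates animate from inanimate categories, mirroring the structure of
#' real network embeddings.
#'
#' @param n_per_category Stimuli per category (default 40).
#' @param D Feature dimension (default 512).
#' @param separation Half the pairwise distance between category means, in
#'   within-category SD units (near-orthogonal means of norm
#'   `sqrt(2) * separation`); 0 plants no category signal.
#' @param seed Integer seed; output is a pure function of the arguments.
#' @return A `stimulus_set`: list with `stimulus_id` (integer),
#'   `category` (factor over the four categories) and `features`
#'   (`[n_stimuli x D]` matrix, rows named by stimulus id).
#' @export
#' @examples
#' ss <- generate_stimulus_features(10, D = 16, separation = 4, seed = 1)
#' table(ss$category)
generate_stimulus_features <- function(n_per_category = 40, D = 512,
                                       separation = 4, seed = 1) {
  if (n_per_category < 1 || D < 2) {
    stop("invalid argument: counts must be positive and D >= 2",
         call. = FALSE)
  }
  if (separation < 0) stop("separation must be >= 0", call. = FALSE)
  n <- n_per_category * length(CATEGORIES)
  withr::with_seed(seed, {
    # Random near-orthogonal category directions of norm sqrt(2) *
    # separation; two orthogonal means then sit at pairwise distance
    # 2 * separation, i.e. `separation` noise-SDs on each side of the
    # midpoint.
    mu <- matrix(stats::rnorm(length(CATEGORIES) * D), ncol = D)
    mu <- mu / sqrt(rowSums(mu^2)) * sqrt(2) * separation
    category <- factor(rep(CATEGORIES, each = n_per_category),
                       levels = CATEGORIES)
    features <- mu[as.integer(category), , drop = FALSE] +
      matrix(stats::rnorm(n * D), nrow = n)
  })
  rownames(features) <- as.character(seq_len(n))
  structure(
    list(stimulus_id = seq_len(n), category = category,
         features = features),
    class = "stimulus_set"
  )
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("<stimulus_set> ", length(x$stimulus_id), " stimuli x ",
      ncol(x$features), " features; categories: ",
      paste(levels(x$category), collapse = ", "), "\n", sep = "")
  invisible(x)
}
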