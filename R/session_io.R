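#' Write a session to a directory layout
#'
#' Serialises a session as plain files: `events.csv`, `units.csv`,
#' `spikes/unit_<id>.csv` (one spike time in ms per line),
#' `lfp/channel_<id>.f32` (little-endian 32-bit float raw array) with
#' `lfp_meta.csv`, and optionally `features.csv` (stimulus_id, category,
#' f0..f{D-1}) and `ground_truth.csv`. All CSVs carry a header row.
#'
#' @param session A `session`.
#' @param path Directory to create/write into.
#' @param stimuli Optional `stimulus_set` to write as `features.csv`.
#' @param truth Optional `ground_truth`; its unit table is written as
#'   `ground_truth.csv`.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, stimuli = NULL, truth = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "spikes"), showWarnings = FALSE)
  dir.create(file.path(path, "lfp"), showWarnings = FALSE)
  utils::write.csv(session$events, file.path(path, "events.csv"),
                   row.names = FALSE)
  units_df <- do.call(rbind, lapply(session$units, function(u) {
    data.frame(unit_id = u$unit_id, area = u$area,
               electrode_id = u$electrode_id)
  }))
  utils::write.csv(units_df, file.path(path, "units.csv"),
                   row.names = FALSE)
  for (u in session$units) {
    f <- file.path(path, "spikes", sprintf("unit_%d.csv", u$unit_id))
    utils::write.csv(data.frame(spike_time_ms = u$spike_times), f,
                     row.names = FALSE)
  }
  meta <- do.call(rbind, lapply(session$lfp, function(ch) {
    data.frame(channel_id = ch$channel_id, area = ch$area,
               electrode_id = ch$electrode_id, fs_hz = ch$fs,
               n_samples = length(ch$samples))
  }))
  utils::write.csv(meta, file.path(path, "lfp_meta.csv"), row.names = FALSE)
  for (ch in session$lfp) {
    f <- file.path(path, "lfp", sprintf("channel_%d.f32", ch$channel_id))
    con <- file(f, "wb")
    writeBin(as.numeric(ch$samples), con, size = 4L, endian = "little")
    close(con)
  }
  if (!is.null(stimuli)) {
    feat <- as.data.frame(stimuli$features)
    names(feat) <- sprintf("f%d", seq_len(ncol(feat)) - 1L)
    feat <- cbind(data.frame(stimulus_id = stimuli$stimulus_id,
                             category = as.character(stimuli$category)),
                  feat)
    utils::write.csv(feat, file.path(path, "features.csv"),
                     row.names = FALSE)
  }
  if (!is.null(truth)) {
    utils::write.csv(truth$units, file.path(path, "ground_truth.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a session from a directory layout
#'
#' Inverse of [write_session()]: `read_session(write_session(s, p))` equals
#' `s` up to 32-bit float representation of the LFP samples. Errors name
#' the first missing component file.
#'
#' @param path Session directory.
#' @return A `session` (plus `stimuli` attribute when `features.csv` is
#'   present).
#' @export
read_session <- function(path) {
  need <- function(f) {
    p <- file.path(path, f)
    if (!file.exists(p)) stop(f, " not found in ", path, call. = FALSE)
    p
  }
  events <- utils::read.csv(need("events.csv"))
  units_df <- utils::read.csv(need("units.csv"))
  meta <- utils::read.csv(need("lfp_meta.csv"))
  units <- lapply(seq_len(nrow(units_df)), function(i) {
    f <- need(sprintf("spikes/unit_%d.csv", units_df$unit_id[i]))
    st <- utils::read.csv(f)$spike_time_ms
    list(unit_id = units_df$unit_id[i], area = units_df$area[i],
         electrode_id = units_df$electrode_id[i],
         spike_times = as.numeric(st))
  })
  lfp <- lapply(seq_len(nrow(meta)), function(i) {
    f <- need(sprintf("lfp/channel_%d.f32", meta$channel_id[i]))
    con <- file(f, "rb")
    on.exit(close(con))
    x <- readBin(con, "numeric", n = meta$n_samples[i], size = 4L,
                 endian = "little")
    if (length(x) != meta$n_samples[i]) {
      stop(sprintf("lfp/channel_%d.f32 is truncated", meta$channel_id[i]),
           call. = FALSE)
    }
    list(channel_id = meta$channel_id[i], area = meta$area[i],
         electrode_id = meta$electrode_id[i], samples = x,
         fs = meta$fs_hz[i])
  })
  fs <- if (nrow(meta) > 0L) meta$fs_hz[1] else 1000
  dur <- max(events$t_off_ms,
             vapply(units, function(u) {
               if (length(u$spike_times)) max(u$spike_times) else 0
             }, numeric(1)))
  s <- structure(
    list(events = events, arrays = NULL, units = units, lfp = lfp,
         fs = fs, duration_ms = ceiling(dur)),
    class = "session"
  )
  fpath <- file.path(path, "features.csv")
  if (file.exists(fpath)) {
    feat <- utils::read.csv(fpath)
    fcols <- grep("^f\\d+$", names(feat))
    fm <- as.matrix(feat[, fcols])
    rownames(fm) <- as.character(feat$stimulus_id)
    attr(s, "stimuli") <- structure(
      list(stimulus_id = feat$stimulus_id,
           category = factor(feat$category, levels = CATEGORIES),
           features = fm),
      class = "stimulus_set"
    )
  }
  s
}
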