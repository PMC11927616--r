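test_that("visual responsiveness uses a greater-than rank-sum screen", {
  withr::with_seed(1, {
    base <- rnorm(50, 10, 2)
    same <- rnorm(50, 10, 2)
    up <- base + 10
  })
  expect_false(assess_visual_responsiveness(same, same, base)$flag)
  res <- assess_visual_responsiveness(up, same, base)
  expect_true(res$flag)
  # matches the rank-sum oracle applied directly
  expect_equal(res$p_cue,
               wilcox.test(up, base, alternative = "greater",
                           exact = FALSE)$p.value)
  expect_error(assess_visual_responsiveness(1:2, 1:2, 1:2),
               "insufficient")
})

test_that("receptive-field classification follows the cue/array rule", {
  expect_equal(classify_rf(0.01, 0.5), "focal_foveal")
  expect_equal(classify_rf(0.01, 0.01), "broad_foveal")
  expect_equal(classify_rf(0.5, 0.01), "peripheral")
  expect_equal(classify_rf(0.5, 0.5), "unclassified")
})

test_that("selectivity index formula, threshold and clamps", {
  expect_equal(category_selectivity_index(1.3, 1.0), 0.3 / 2.3)
  expect_gte(category_selectivity_index(1.3, 1.0), 0.13)
  expect_identical(category_selectivity_index(2, -1), 1)
  expect_identical(category_selectivity_index(-1, 2), -1)
  expect_equal(category_selectivity_index(1, 1), 0)
  expect_error(category_selectivity_index(0, 0), "undefined")
  # antisymmetric up to the clamps
  withr::with_seed(2, {
    for (i in 1:20) {
      a <- runif(1, 0.1, 5); b <- runif(1, 0.1, 5)
      expect_equal(category_selectivity_index(a, b),
                   -category_selectivity_index(b, a))
    }
  })
})

test_that("category classification combines rank-sum and SI criteria", {
  withr::with_seed(3, {
    house <- rnorm(60, 10, 1)
    face_strong <- house * 3
    face_weak <- house + 0.5       # significant but SI well under 0.13
  })
  expect_equal(classify_category(house, house + rnorm(60, 0, 1e-6))$class,
               "nonselective")
  strong <- classify_category(face_strong, house)
  expect_equal(strong$class, "face")
  expect_gt(strong$SI, 0.13)
  weak <- classify_category(face_weak, house)
  expect_lt(weak$p, 0.05)
  expect_equal(weak$class, "undefined")
  expect_equal(classify_category(house, face_strong)$class, "house")
  expect_error(classify_category(1:3, 1:3), "insufficient")
})

test_that("attention selectivity pairs stimuli and computes the index", {
  withr::with_seed(4, {
    d <- runif(40, 5, 15)
  })
  same <- detect_attention_selectivity(d, d)
  expect_false(same$flag)
  expect_equal(same$attention_index, 0)

  up <- detect_attention_selectivity(1.5 * d, d)
  expect_true(up$flag)
  expect_equal(up$attention_index, 0.5 / 2.5)  # (1.5-1)/(1.5+1)
  expect_equal(up$p,
               wilcox.test(1.5 * d, d, paired = TRUE, exact = FALSE)$p.value)

  expect_error(detect_attention_selectivity(1:3, 2:4), "insufficient")
})

test_that("attention screen false-positive rate is near its alpha", {
  withr::with_seed(5, {
    flags <- replicate(400, {
      detect_attention_selectivity(rnorm(30, 10), rnorm(30, 10))$flag
    })
  })
  expect_gt(mean(flags), 0.02)
  expect_lt(mean(flags), 0.09)
})

test_that("session-level screen produces coherent unit records", {
  w <- small_world()
  scr <- screen_units(w$session, w$stimuli)
  expect_equal(nrow(scr), length(w$session$units))
  expect_true(all(scr$SI >= -1 & scr$SI <= 1))
  expect_true(all(scr$rf_class %in%
                    c("focal_foveal", "broad_foveal", "peripheral",
                      "unclassified")))
  expect_true(all(scr$category_class %in%
                    c("face", "house", "nonselective", "undefined")))
  ok <- !is.na(scr$attention_index)
  expect_true(all(abs(scr$attention_index[ok]) <= 1))
  # the simulator drives every unit from foveated stimuli, so most units
  # should be visually responsive
  expect_gt(mean(scr$visually_responsive), 0.7)
})
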