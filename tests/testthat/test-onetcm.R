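test_that("1TCM recovers noiseless generating parameters", {
  ors <- oracle_subject()
  x <- generate_tissue_tac(ors$input, 0.13, 0.037, ors$schedule, "cs")
  f <- fit_1tcm(x, ors$aif)
  expect_lt(abs(f$K1 / 0.13 - 1), 1e-3)
  expect_lt(abs(f$k2 / 0.037 - 1), 1e-3)
  expect_equal(f$V_T, 3.514, tolerance = 1e-3)
  expect_equal(f$V_T, f$K1 / f$k2)
  # zero-residual limit: negligible parameter uncertainty
  expect_lt(f$rse_K1, 0.01)
  expect_lt(f$rse_k2, 0.01)
  # optimum is at least as good as every multi-start initial point
  expect_true(all(f$wrss <= f$start_wrss + 1e-12))
})

test_that("1TCM is scale-equivariant in the TAC", {
  ors <- oracle_subject()
  x <- tac(ors$schedule, ors$target[, 5], "roi05")
  f1 <- fit_1tcm(x, ors$aif)
  x2 <- tac(ors$schedule, 2 * ors$target[, 5], "roi05")
  f2 <- fit_1tcm(x2, ors$aif, weights = compute_frame_weights(x))
  expect_equal(f2$K1 / f1$K1, 2, tolerance = 1e-6)
  expect_equal(f2$V_T / f1$V_T, 2, tolerance = 1e-6)
  expect_equal(f2$k2, f1$k2, tolerance = 1e-6)
})

test_that("1TCM V_T is nearly unbiased under count noise", {
  ors <- oracle_subject()
  cs <- generate_tissue_tac(ors$input, 0.13, 0.037, ors$schedule, "cs")
  vts <- vapply(1:200, function(i) {
    noisy <- add_noise(cs, noise_model(0.05, seed = i))
    fit_1tcm(noisy, ors$aif)$V_T
  }, 0)
  expect_lt(abs(stats::median(vts) / (0.13 / 0.037) - 1), 0.02)
})

test_that("rSE scales with the noise level", {
  ors <- oracle_subject()
  cs <- generate_tissue_tac(ors$input, 0.13, 0.037, ors$schedule, "cs")
  rse <- function(scale) vapply(1:60, function(i)
    fit_1tcm(add_noise(cs, noise_model(scale, seed = i)), ors$aif)$rse_V_T, 0)
  r1 <- stats::median(rse(0.05))
  r2 <- stats::median(rse(0.10))
  expect_gt(r2 / r1, 1.5)
  expect_lt(r2 / r1, 2.6)
})

test_that("BP_ND from V_T ratio", {
  expect_equal(bpnd_from_vt(3.5, 3.5), 0)
  expect_equal(bpnd_from_vt(10.5, 3.5), 2)
  low <- bpnd_from_vt(2, 3.5)
  expect_lt(low, 0)
  expect_gt(low, -1)
  expect_error(bpnd_from_vt(3, 0), "positive")
})
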