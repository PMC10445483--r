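test_that("SRTM is exact for one-tissue target/reference pairs", {
  ors <- oracle_subject()
  ref <- ors$ref_tac

  # identity: target equals reference
  f0 <- fit_srtm(ref, ref)
  expect_equal(f0$R1, 1, tolerance = 1e-6)
  expect_equal(f0$BP_ND, 0, tolerance = 1e-6)

  # V_T-ratio oracle: ref (0.13, 0.037), target (0.13, 0.0185) => BP = 1
  tar <- generate_tissue_tac(ors$input, 0.13, 0.0185, ors$schedule, "t")
  refb <- generate_tissue_tac(ors$input, 0.13, 0.037, ors$schedule, "ref")
  f1 <- fit_srtm(tar, refb)
  expect_equal(f1$BP_ND, 1, tolerance = 5e-3)
  expect_equal(f1$R1, 1, tolerance = 5e-3)

  # generate-and-refit at BP = 3, R1 = 1.2
  K1 <- 1.2 * 0.13
  k2 <- K1 / ((0.13 / 0.037) * 4)   # V_T = 4 x ref V_T => BP = 3
  tar2 <- generate_tissue_tac(ors$input, K1, k2, ors$schedule, "t2")
  f2 <- fit_srtm(tar2, refb)
  expect_equal(f2$BP_ND, 3, tolerance = 5e-3 * 3)
  expect_equal(f2$R1, 1.2, tolerance = 5e-3 * 1.2)
  expect_true(all(f2$wrss <= f2$start_wrss + 1e-12))
})

test_that("SRTM2 recovers BP_ND when k2' is true, and shifts when mis-set", {
  ors <- oracle_subject()
  refb <- generate_tissue_tac(ors$input, 0.13, 0.037, ors$schedule, "ref")
  f0 <- fit_srtm2(refb, refb, 0.037)
  expect_equal(f0$R1, 1, tolerance = 1e-6)
  expect_equal(f0$BP_ND, 0, tolerance = 1e-6)

  tar <- generate_tissue_tac(ors$input, 0.13, 0.0185, ors$schedule, "t")
  f1 <- fit_srtm2(tar, refb, 0.037)
  expect_equal(f1$BP_ND, 1, tolerance = 5e-3)
  expect_equal(f1$k2, f1$R1 * 0.037)

  # deliberately mis-set k2' reproduces the brute-force profile optimum
  f2 <- fit_srtm2(tar, refb, 0.032)
  w <- compute_frame_weights(tar)
  ctx <- refkin:::srtm_context(refb)
  prof <- function(k2a) {
    b <- refb$values + (0.032 - k2a) * refkin:::srtm_conv_term(ctx, k2a)
    R1 <- sum(w * tar$values * b) / sum(w * b^2)
    sum(w * (tar$values - R1 * b)^2)
  }
  k2a_opt <- stats::optimize(prof, c(0.005, 0.1), tol = 1e-10)$minimum
  b <- refb$values + (0.032 - k2a_opt) * refkin:::srtm_conv_term(ctx, k2a_opt)
  R1_opt <- sum(w * tar$values * b) / sum(w * b^2)
  bp_oracle <- R1_opt * 0.032 / k2a_opt - 1
  expect_equal(f2$BP_ND, bp_oracle, tolerance = 1e-4)
  expect_false(abs(f2$BP_ND - 1) < 1e-3)           # bias is nonzero
  expect_equal(sign(f2$BP_ND - 1), sign(bp_oracle - 1))
})

test_that("coupled fit recovers the shared reference efflux constant", {
  ors <- oracle_subject()
  tacs <- oracle_target_tacs()[c(1, 8, 14, 20, 24, 28)]
  cp <- fit_srtm_coupled(tacs, ors$ref_tac)
  expect_lt(abs(cp$k2_prime / 0.037 - 1), 0.01)

  # permutation symmetry of the shared estimate
  cp2 <- fit_srtm_coupled(rev(tacs), ors$ref_tac)
  expect_equal(cp2$k2_prime, cp$k2_prime, tolerance = 1e-8)

  # single region: warning and fall back to free SRTM
  expect_warning(cp1 <- fit_srtm_coupled(tacs[1], ors$ref_tac), "single region")
  f <- fit_srtm(tacs[[1]], ors$ref_tac)
  expect_equal(cp1$fits[[1]]$BP_ND, f$BP_ND, tolerance = 1e-8)
})

test_that("noiseless SRTM-family rSE is negligible and noisy rSE is finite", {
  ors <- oracle_subject()
  tar <- tac(ors$schedule, ors$target[, 14], "roi14")
  f <- fit_srtm2(tar, ors$ref_tac, 0.037)
  expect_lt(f$rse_BP, 0.1)
  noisy <- add_noise(tar, noise_model(0.05, seed = 3))
  fn <- fit_srtm2(noisy, ors$ref_tac, 0.037,
                  weights = compute_frame_weights(noisy))
  expect_true(is.finite(fn$rse_BP) && fn$rse_BP > 0)
})
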