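test_that("tissue forward model matches closed forms and a brute-force oracle", {
  sched <- default_frame_schedule()
  grid <- fine_time_grid(120)
  ors <- oracle_subject()

  # K1 = 0 gives the zero TAC
  z <- generate_tissue_tac(ors$input, 0, 0.05, sched)
  expect_equal(z$values, numeric(sched$n))

  # step response: constant input c has frame averages matching the analytic
  # average of K1 c / k2 (1 - exp(-k2 t)) over each frame
  cst <- list(times = grid, values = rep(3, length(grid)))
  K1 <- 0.2; k2 <- 0.05
  got <- generate_tissue_tac(cst, K1, k2, sched)$values
  t0 <- sched$start; t1 <- sched$end
  want <- K1 * 3 / k2 * (1 + (exp(-k2 * t1) - exp(-k2 * t0)) / (k2 * sched$dur))
  expect_equal(got, want, tolerance = 1e-9)

  # brute-force Riemann convolution at 0.1 s resolution
  fine <- fine_time_grid(120, 0.1 / 60)
  u <- stats::approx(ors$input$times, ors$input$values, xout = fine)$y
  dt <- fine[2] - fine[1]
  K1 <- 0.13; k2 <- 0.037
  ct <- K1 * dt * (stats::convolve(u, rev(exp(-k2 * fine)), type = "open")[seq_along(fine)])
  brute <- frame_average(fine, ct, sched)
  got <- generate_tissue_tac(ors$input, K1, k2, sched)$values
  expect_lt(max(abs(got - brute)) / max(brute), 2e-3)

  expect_error(generate_tissue_tac(ors$input, -0.1, 0.05, sched), "K1")
  expect_error(generate_tissue_tac(ors$input, 0.1, 0, sched), "k2")
})

test_that("count noise model is seeded, scaled, and zero-scale exact", {
  ors <- oracle_subject()
  x <- tac(ors$schedule, ors$target[, 14], "roi14")

  expect_identical(add_noise(x, noise_model(0))$values, x$values)
  n1 <- add_noise(x, noise_model(0.05, seed = 9))
  n2 <- add_noise(x, noise_model(0.05, seed = 9))
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values, add_noise(x, noise_model(0.05, seed = 10))$values))

  # Monte-Carlo check of the per-frame standard deviation formula
  reps <- vapply(seq_len(1000), function(i)
    add_noise(x, noise_model(0.05, seed = i))$values, numeric(x$schedule$n))
  d <- exp(-log(2) * x$schedule$mid / 109.77)
  want_sd <- 0.05 * sqrt(x$values / (x$schedule$dur * d))
  got_sd <- apply(reps, 1, stats::sd)
  late <- x$schedule$mid > 5  # early low-count frames are clipped at zero
  expect_lt(max(abs(got_sd[late] / want_sd[late] - 1)), 0.1)
})

test_that("generated subjects store self-consistent ground truth", {
  for (seed in 1:5) {
    s <- generate_subject(paste0("s", seed), if (seed %% 2) "hc" else "pd",
                          seed = seed)
    implied <- (s$region_K1 / s$region_k2) / (s$ref_K1 / s$ref_k2) - 1
    expect_equal(unname(implied), unname(s$true_bpnd), tolerance = 1e-12)
    expect_true(all(s$region_K1 > 0) && all(s$region_k2 > 0) && s$ref_k2 > 0)
    expect_true(all(s$true_bpnd > -1))
  }
})
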