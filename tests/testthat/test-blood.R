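test_that("dispersion forward model and correction are numerical inverses", {
  s <- generate_subject("s1", "hc", seed = 3)
  grid <- fine_time_grid(22)
  dt <- grid[2] - grid[1]
  wb <- refkin:::true_wholeblood(s, grid)

  # identity kernel
  expect_equal(apply_dispersion(wb, dt, 0, 0), wb)
  expect_equal(correct_dispersion_delay(wb, dt, 0, 0), wb)

  # dispersed curve peaks later and lower
  disp <- apply_dispersion(wb, dt, 5, 0)
  expect_gt(which.max(disp), which.max(wb))
  expect_lt(max(disp), max(wb))

  # the kernel preserves the area under the curve
  expect_lt(abs(sum(disp) / sum(wb) - 1), 5e-3)

  # pure delay: correction restores the peak time
  del <- apply_dispersion(wb, dt, 0, 10)
  rec <- correct_dispersion_delay(del, dt, 0, 10)
  expect_equal(which.max(rec), which.max(wb))

  # full round trip within 1% RMS of peak
  meas <- apply_dispersion(wb, dt, 5, 10)
  rec <- correct_dispersion_delay(meas, dt, 5, 10)
  expect_lt(sqrt(mean((rec - wb)^2)) / max(wb), 0.01)

  expect_error(apply_dispersion(wb, dt, -1, 0), "tau")
  expect_error(correct_dispersion_delay(wb, dt, -1, 0), "tau")
})

test_that("plasma-to-whole-blood ratio models fit their generating data", {
  s <- generate_subject("s1", "hc", seed = 4)
  sched <- default_frame_schedule()
  ds <- generate_blood_dataset(s, sched, pf_noise_sd = 0)

  # constant data
  rfun <- compute_plasma_wb_ratio(ds)
  expect_equal(unname(rfun(c(0, 50, 110))), rep(s$plasma_wb_ratio, 3),
               tolerance = 1e-12)

  # arithmetic mean of a small set
  ds2 <- ds
  ds2$manual_times <- c(10, 20, 30)
  ds2$manual_wholeblood <- c(1, 1, 1)
  ds2$manual_plasma <- c(1.0, 1.1, 1.2)
  expect_equal(unname(compute_plasma_wb_ratio(ds2)(5)), 1.1)

  # linear drift recovered
  ds3 <- ds2
  ds3$manual_plasma <- (1.2 + 0.002 * ds3$manual_times) * ds3$manual_wholeblood
  rlin <- compute_plasma_wb_ratio(ds3, "linear")
  cf <- attr(rlin, "coef")
  expect_equal(unname(cf[["intercept"]]), 1.2, tolerance = 1e-6)
  expect_equal(unname(cf[["slope"]]), 0.002, tolerance = 1e-6)

  ds4 <- ds2
  ds4$manual_times <- 10; ds4$manual_wholeblood <- 1; ds4$manual_plasma <- 1.2
  expect_error(compute_plasma_wb_ratio(ds4), "at least 2")
})

test_that("curve merging uses the automatic window then manual samples", {
  # manual samples lying exactly on the auto curve: no discontinuity
  at <- fine_time_grid(22)
  av <- 100 * exp(-0.05 * at)
  mt <- c(30, 45, 60)
  mv <- 100 * exp(-0.05 * mt)
  m <- merge_curves(at, av, mt, mv, t_end = 60)
  expect_equal(m$values[m$times <= 22],
               100 * exp(-0.05 * m$times[m$times <= 22]), tolerance = 1e-9)
  expect_lt(max(abs(diff(m$values))), 0.2)  # no jump at the junction

  # single manual point: linear interpolation from auto end to it
  m2 <- merge_curves(at, av, 30, 50, t_end = 30)
  a22 <- 100 * exp(-0.05 * 22)
  mid <- which.min(abs(m2$times - 26))
  expect_equal(m2$values[mid],
               a22 + (50 - a22) * (m2$times[mid] - 22) / 8, tolerance = 1e-9)
})

test_that("Hill fitting recovers generating parameters", {
  h <- hill_params(0.2, 20, 2)
  t <- c(2.5, 7, 12, 15, 20, 30, 45, 60, 90, 110)
  fit <- fit_hill_parent_fraction(t, generate_parent_fraction(h, t))
  expect_equal(fit$pf_inf, 0.2, tolerance = 1e-3)
  expect_equal(fit$t50, 20, tolerance = 1e-3)
  expect_equal(fit$h, 2, tolerance = 1e-3)

  # recovered curve is monotone nonincreasing over the scan
  tt <- seq(0, 120, by = 0.5)
  expect_true(all(diff(generate_parent_fraction(fit, tt)) <= 0))

  # degenerate flat data
  flat <- fit_hill_parent_fraction(t, rep(1, length(t)))
  expect_lt(max(abs(generate_parent_fraction(flat, tt) - 1)), 1e-6)

  expect_error(fit_hill_parent_fraction(c(1, 2, 3), c(1, 0.9, 0.8)),
               "at least 4")
})

test_that("AIF is the pointwise product of plasma and parent fraction", {
  plasma <- list(times = fine_time_grid(120), values = NULL)
  plasma$values <- 50 * exp(-0.02 * plasma$times)
  # pf identically 1
  a1 <- build_input_function(plasma, hill_params(1, 20, 2))
  expect_equal(a1$activity, plasma$values)
  # general Hill curve: exact product
  h <- hill_params(0.3, 15, 1.2)
  a2 <- build_input_function(plasma, h)
  expect_equal(a2$activity,
               plasma$values * generate_parent_fraction(h, plasma$times))
})

test_that("full blood chain reconstructs the generating AIF", {
  s <- generate_subject("s1", "hc", seed = 6)
  sched <- default_frame_schedule()
  ds <- generate_blood_dataset(s, sched, pf_noise_sd = 0)
  aif <- process_blood(ds, tau = s$input_params$dispersion_tau,
                       delay = s$input_params$delay)
  truth <- true_aif(s)
  rms <- sqrt(mean((aif$activity - truth$activity)^2)) / max(truth$activity)
  expect_lt(rms, 0.01)

  # provenance records the corrections
  expect_equal(aif$provenance$dispersion_tau_s, 5)
  expect_equal(aif$provenance$delay_s, 10)

  # merged plasma matches true plasma within 2% RMS over [1, 110] min
  grid <- truth$times
  plasma_true <- generate_input_function(s$input_params, grid)
  corrected <- correct_dispersion_delay(ds$auto_wholeblood, 1 / 60, 5, 10)
  merged <- merge_curves(ds$auto_times, corrected * s$plasma_wb_ratio,
                         ds$manual_times, ds$manual_plasma)
  win <- grid >= 1 & grid <= 110
  expect_lt(sqrt(mean((merged$values[win] - plasma_true[win])^2)) /
              max(plasma_true), 0.02)
})

test_that("AIF is invariant to merge/convert order for a constant ratio", {
  s <- generate_subject("s1", "hc", seed = 8)
  sched <- default_frame_schedule()
  ds <- generate_blood_dataset(s, sched, pf_noise_sd = 0)
  dt <- 1 / 60
  corrected <- correct_dispersion_delay(ds$auto_wholeblood, dt, 5, 10)
  r <- s$plasma_wb_ratio
  # convert then merge
  m1 <- merge_curves(ds$auto_times, corrected * r, ds$manual_times,
                     ds$manual_plasma)
  # merge in whole-blood space then convert
  m2 <- merge_curves(ds$auto_times, corrected, ds$manual_times,
                     ds$manual_plasma / r)
  expect_equal(m1$values, m2$values * r, tolerance = 1e-12)
})

test_that("blood dataset construction validates and matches ground truth", {
  s <- generate_subject("s1", "hc", seed = 5)
  sched <- default_frame_schedule()
  # manual plasma / whole blood equals the subject ratio by construction
  ds <- generate_blood_dataset(s, sched, pf_noise_sd = 0)
  expect_equal(ds$manual_plasma / ds$manual_wholeblood,
               rep(s$plasma_wb_ratio, length(ds$manual_times)))
  # dispersion/delay off: auto curve equals the true whole-blood curve
  s0 <- s
  s0$input_params$dispersion_tau <- 0
  s0$input_params$delay <- 0
  ds0 <- generate_blood_dataset(s0, sched, pf_noise_sd = 0)
  expect_equal(ds0$auto_wholeblood,
               refkin:::true_wholeblood(s0, ds0$auto_times))
  expect_error(blood_dataset(c(1, 0), c(1, 1), 1, 1, 1, 1, 0.5), "ascending")
  expect_error(blood_dataset(c(0, 1), c(1, 1), 1, 1, 1, 1, 1.5), "\\[0, 1\\]")
})
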