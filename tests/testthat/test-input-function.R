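test_that("parametric input curve follows its piecewise closed form", {
  grid <- fine_time_grid(120)

  # zero amplitudes give the zero curve
  p0 <- input_function_params(amplitudes = c(0, 0, 0))
  expect_equal(generate_input_function(p0, grid), numeric(length(grid)))

  # single-exponential tail matches A exp(-lambda (t - t_peak)) pointwise
  p1 <- input_function_params(amplitudes = c(80, 0, 0),
                              decay_rates = c(0.3, 0.25, 0.015))
  v <- generate_input_function(p1, grid)
  post <- grid > p1$t_peak
  expect_equal(v[post], 80 * exp(-0.3 * (grid[post] - p1$t_peak)),
               tolerance = 1e-12)
  expect_true(all(v >= 0))

  # numeric integral of the default curve agrees with analytic integration
  p <- input_function_params()
  v <- generate_input_function(p, grid)
  num <- sum((v[-1] + v[-length(v)]) / 2) * (grid[2] - grid[1])
  ana <- refkin:::input_function_integral(p, 120)
  expect_lt(abs(num / ana - 1), 1e-3)
})

test_that("input parameter validation", {
  expect_error(input_function_params(decay_rates = c(-1, 0.2, 0.01)),
               "positive")
  expect_error(input_function_params(decay_rates = c(0.2, 0.2, 0.01)),
               "distinct")
  expect_error(input_function_params(amplitudes = c(1, 2)), "3 elements")
})

test_that("Hill parent fraction obeys its boundary and formula identities", {
  expect_equal(generate_parent_fraction(hill_params(0.3, 25, 2), 0), 1)
  # half-saturation with zero asymptote
  expect_equal(generate_parent_fraction(hill_params(0, 20, 1.7), 20), 0.5)
  # direct formula evaluation
  h <- hill_params(0.2, 20, 2)
  expect_equal(generate_parent_fraction(h, 60),
               1 - 0.8 * 60^2 / (20^2 + 60^2), tolerance = 1e-15)
  # monotone nonincreasing with asymptote pf_inf
  t <- seq(0, 500, by = 0.5)
  pf <- generate_parent_fraction(h, t)
  expect_true(all(diff(pf) <= 0))
  expect_equal(pf[length(pf)], 0.2, tolerance = 1e-2)
  expect_error(generate_parent_fraction(h, c(-1, 2)), "nonnegative")
  expect_error(hill_params(1.2, 20, 2), "pf_inf")
  expect_error(hill_params(0.2, -1, 2), "t50")
})
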