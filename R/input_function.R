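#' Parameters of the parametric arterial input model
#'
#' A Feng-type bolus shape: the plasma curve is zero until the rise onset,
#' climbs linearly (at `slope` kBq/mL/min) to its peak at `t_peak`, and then
#' decays as the sum of three exponentials. Defaults place the plasma peak
#' about one minute post injection with a 90-min tail near 2% of peak,
#' typical of a bolus [18F]SynVesT-1 injection of ~185 MBq.
#'
#' @param t_peak Peak time (minutes).
#' @param slope Rise slope (kBq/mL/min).
#' @param amplitudes Three exponential amplitudes at the peak (kBq/mL).
#' @param decay_rates Three decay constants (1/min), positive and distinct.
#' @param delay Tubing delay of the automatic sampler (seconds).
#' @param dispersion_tau Dispersion time constant of the sampler (seconds).
#' @return An object of class `input_function_params`.
#' @export
input_function_params <- function(t_peak = 1.0,
                                  slope = 300,
                                  amplitudes = c(100, 20, 12),
                                  decay_rates = c(4.0, 0.25, 0.015),
                                  delay = 10,
                                  dispersion_tau = 5) {
  if (length(amplitudes) != 3 || length(decay_rates) != 3)
    stop("amplitudes and decay_rates must each have 3 elements")
  if (any(!is.finite(decay_rates)) || any(decay_rates <= 0))
    stop("decay rates must be strictly positive")
  if (anyDuplicated(decay_rates))
    stop("decay rates must be distinct")
  if (sum(amplitudes) < 0)
    stop("amplitudes must produce a nonnegative peak")
  if (dispersion_tau < 0) stop("dispersion_tau must be >= 0")
  if (t_peak <= 0 || slope <= 0) stop("t_peak and slope must be positive")
  structure(list(t_peak = t_peak, slope = slope, amplitudes = amplitudes,
                 decay_rates = decay_rates, delay = delay,
                 dispersion_tau = dispersion_tau),
            class = "input_function_params")
}

#' Evaluate the parametric plasma input curve on a time grid
#'
#' @param params An [input_function_params()].
#' @param grid Uniform time grid (minutes) covering the scan.
#' @return Plasma activity (kBq/mL) on `grid`; nonnegative everywhere.
#' @export
generate_input_function <- function(params, grid) {
  stopifnot(inherits(params, "input_function_params"))
  peak <- sum(params$amplitudes)
  rise <- peak / params$slope
  t0 <- params$t_peak - rise
  v <- numeric(length(grid))
  up <- grid > t0 & grid <= params$t_peak
  v[up] <- params$slope * (grid[up] - t0)
  post <- grid > params$t_peak
  if (any(post)) {
    tt <- grid[post] - params$t_peak
    v[post] <- drop(exp(-outer(tt, params$decay_rates)) %*% params$amplitudes)
  }
  pmax(v, 0)
}

# Closed-form integral of the piecewise input model over [0, t_end]; used
# as an analytic cross-check of the sampled curve.
input_function_integral <- function(params, t_end) {
  peak <- sum(params$amplitudes)
  rise <- peak / params$slope
  t0 <- max(params$t_peak - rise, 0)
  tri <- params$slope * (min(t_end, params$t_peak) - t0)^2 / 2
  if (t_end <= params$t_peak) return(if (t_end <= t0) 0 else tri)
  tt <- t_end - params$t_peak
  tail <- sum(params$amplitudes / params$decay_rates *
                (1 - exp(-params$decay_rates * tt)))
  tri + tail
}

#' Hill model of the plasma parent fraction
#'
#' `pf(t) = 1 - (1 - pf_inf) * t^h / (t50^h + t^h)`: unity at injection,
#' monotone nonincreasing, approaching the asymptote `pf_inf`.
#'
#' @param pf_inf Asymptotic parent fraction, in `[0, 1]`.
#' @param t50 Half-transition time (minutes), > 0.
#' @param h Hill exponent, > 0.
#' @return An object of class `hill_params`.
#' @export
hill_params <- function(pf_inf = 0.2, t50 = 20, h = 1.5) {
  if (pf_inf < 0 || pf_inf > 1) stop("pf_inf must lie in [0, 1]")
  if (t50 <= 0) stop("t50 must be positive")
  if (h <= 0) stop("h must be positive")
  structure(list(pf_inf = pf_inf, t50 = t50, h = h), class = "hill_params")
}

#' Evaluate the Hill parent-fraction curve
#'
#' @param hill A [hill_params()].
#' @param times Times (minutes), all >= 0.
#' @return Parent fraction at each time.
#' @export
generate_parent_fraction <- function(hill, times) {
  stopifnot(inherits(hill, "hill_params"))
  if (any(times < 0)) stop("times must be nonnegative")
  th <- times^hill$h
  1 - (1 - hill$pf_inf) * th / (hill$t50^hill$h + th)
}

#' Forward one-tissue model: tissue TAC from an input curve
#'
#' Computes the continuous tissue response
#' `C_T(t) = K1 * (input (x) exp(-k2 t))` on the input grid and returns its
#' frame averages as a [tac()].
#'
#' @param input List with `times` (uniform grid, minutes) and `values`
#'   (kBq/mL), e.g. the output of [generate_input_function()] paired with
#'   its grid.
#' @param K1 Influx rate (mL/cm3/min), >= 0.
#' @param k2 Efflux rate (1/min), > 0.
#' @param schedule A [frame_schedule()] covered by the grid.
#' @param roi_id Region label for the returned TAC.
#' @return A [tac()] of frame-averaged tissue activity.
#' @export
generate_tissue_tac <- function(input, K1, k2, schedule, roi_id = "roi") {
  if (!is.finite(K1) || K1 < 0) stop("K1 must be >= 0")
  if (!is.finite(k2) || k2 <= 0) stop("k2 must be > 0")
  dt <- input$times[2] - input$times[1]
  if (dt > min(schedule$dur) + 1e-12)
    stop("input grid must be finer than the shortest frame")
  cc <- conv_context(input$times, input$values, schedule)
  tac(schedule, K1 * conv_frame_average(cc, k2), roi_id)
}

#' Count-based noise model for frame activities
#'
#' Per-frame Gaussian noise with standard deviation
#' `scale * sqrt(C_i / (dt_i * d_i))`, where `d_i` is the isotope decay
#' factor at the frame mid-time. Variance grows for short, late, hot frames,
#' mimicking count statistics after decay correction.
#'
#' @param scale Unitless noise scale, >= 0.
#' @param halflife Isotope half-life (minutes); default 109.77 (F-18).
#' @param seed Integer seed used by [add_noise()].
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(scale = 0.05, halflife = 109.77, seed = 1L) {
  if (scale < 0) stop("scale must be >= 0")
  if (halflife <= 0) stop("halflife must be > 0")
  structure(list(scale = scale, halflife = halflife, seed = as.integer(seed)),
            class = "noise_model")
}

# Decay factor at frame mid-times.
decay_factor <- function(schedule, halflife) {
  exp(-log(2) * schedule$mid / halflife)
}

#' Add seeded count-like noise to a TAC
#'
#' @param x A [tac()] with nonnegative values.
#' @param model A [noise_model()]. `scale = 0` returns the input unchanged.
#' @return A noisy [tac()], clipped at zero.
#' @export
add_noise <- function(x, model) {
  stopifnot(inherits(x, "tac"), inherits(model, "noise_model"))
  if (model$scale == 0) return(x)
  sched <- x$schedule
  d <- decay_factor(sched, model$halflife)
  sdv <- model$scale * sqrt(pmax(x$values, 0) / (sched$dur * d))
  vals <- with_seed(model$seed, x$values + stats::rnorm(sched$n, 0, sdv))
  tac(sched, pmax(vals, 0), x$roi_id)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; restores the
# caller's stream afterwards so generators do not perturb user code.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
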