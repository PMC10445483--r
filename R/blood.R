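#' Arterial blood dataset
#'
#' Container for the raw blood measurements of one scan: the
#' automatic-sampler whole-blood curve (uniform ~1 s grid, typically
#' 0-22 min), manual whole-blood and plasma samples, and parent-fraction
#' measurements.
#'
#' @param auto_times,auto_wholeblood Automatic sampler times (minutes) and
#'   whole-blood activity (kBq/mL).
#' @param manual_times,manual_wholeblood,manual_plasma Manual sample times
#'   (minutes) and activities (kBq/mL).
#' @param pf_times,pf_values Parent-fraction measurement times and values
#'   (fractions in `[0, 1]`).
#' @return An object of class `blood_dataset`.
#' @export
blood_dataset <- function(auto_times, auto_wholeblood,
                          manual_times, manual_wholeblood, manual_plasma,
                          pf_times, pf_values) {
  chk <- function(t, v, nm) {
    if (length(t) != length(v)) stop(nm, ": times and values differ in length")
    if (is.unsorted(t, strictly = TRUE)) stop(nm, ": times must be ascending")
    if (any(v < 0)) stop(nm, ": activities must be >= 0")
  }
  chk(auto_times, auto_wholeblood, "auto")
  chk(manual_times, manual_wholeblood, "manual whole blood")
  chk(manual_times, manual_plasma, "manual plasma")
  chk(pf_times, pf_values, "parent fraction")
  if (any(pf_values > 1)) stop("parent fractions must lie in [0, 1]")
  structure(list(auto_times = auto_times, auto_wholeblood = auto_wholeblood,
                 manual_times = manual_times,
                 manual_wholeblood = manual_wholeblood,
                 manual_plasma = manual_plasma,
                 pf_times = pf_times, pf_values = pf_values),
            class = "blood_dataset")
}

#' Apply sampler dispersion and delay to a curve (forward model)
#'
#' Convolves with the monoexponential dispersion kernel
#' `(1/tau) exp(-t/tau)` and shifts by the tubing delay — what the automatic
#' sampler measures downstream of the artery.
#'
#' @param values Curve samples on a uniform grid.
#' @param dt Grid step (minutes).
#' @param tau Dispersion time constant (seconds); 0 disables dispersion.
#' @param delay Delay (seconds); rounded to the nearest grid step.
#' @return Dispersed, delayed curve on the same grid.
#' @export
apply_dispersion <- function(values, dt, tau, delay = 0) {
  if (tau < 0) stop("tau must be >= 0")
  tau_min <- tau / 60
  out <- if (tau_min > 0) conv_exp(values, dt, 1 / tau_min) / tau_min else values
  m <- round(delay / 60 / dt)
  if (m > 0) out <- c(numeric(m), out[seq_len(length(out) - m)])
  if (m < 0) out <- c(out[(-m + 1):length(out)], rep(out[length(out)], -m))
  out
}

#' Remove sampler dispersion and delay from a measured curve
#'
#' Inverts [apply_dispersion()]: the delay is removed by time-shifting and
#' the monoexponential dispersion by the identity
#' `c_true(t) = c_meas(t) + tau * dc_meas/dt`, with the derivative taken on a
#' 3-point centered stencil after a 5-sample moving-average smooth (the
#' standard bias/noise compromise for 1 s sampling).
#'
#' @param values Measured curve on a uniform grid.
#' @param dt Grid step (minutes).
#' @param tau Dispersion time constant (seconds); must be >= 0.
#' @param delay Delay (seconds).
#' @return Corrected curve, clipped at zero.
#' @export
correct_dispersion_delay <- function(values, dt, tau, delay = 0) {
  if (tau < 0) stop("tau must be >= 0")
  n <- length(values)
  out <- values
  m <- round(delay / 60 / dt)
  if (m != 0) out <- apply_dispersion(out, dt, 0, -delay)
  if (tau > 0) {
    sm <- as.numeric(stats::filter(out, rep(1 / 5, 5), sides = 2))
    sm[is.na(sm)] <- out[is.na(sm)]
    dcdt <- c(sm[2] - sm[1],
              (sm[-(1:2)] - sm[-((n - 1):n)]) / 2,
              sm[n] - sm[n - 1]) / dt
    out <- out + (tau / 60) * dcdt
  }
  pmax(out, 0)
}

#' Plasma-to-whole-blood ratio model from manual samples
#'
#' @param ds A [blood_dataset()] with at least two paired manual samples.
#' @param model `"constant"` (mean ratio) or `"linear"` (least-squares drift
#'   in time).
#' @return A function of time returning the ratio (clipped above zero), with
#'   attributes `model` and `coef`.
#' @export
compute_plasma_wb_ratio <- function(ds, model = c("constant", "linear")) {
  model <- match.arg(model)
  ok <- ds$manual_wholeblood > 0 & ds$manual_plasma >= 0
  if (sum(ok) < 2)
    stop("need at least 2 paired manual plasma/whole-blood samples")
  t <- ds$manual_times[ok]
  r <- ds$manual_plasma[ok] / ds$manual_wholeblood[ok]
  if (model == "constant") {
    cf <- c(intercept = mean(r), slope = 0)
  } else {
    fit <- stats::lm.fit(cbind(1, t), r)
    cf <- c(intercept = fit$coefficients[[1]], slope = fit$coefficients[[2]])
  }
  f <- function(time) pmax(cf[["intercept"]] + cf[["slope"]] * time, 1e-6)
  attr(f, "model") <- model
  attr(f, "coef") <- cf
  f
}

#' Merge the corrected automatic plasma curve with manual plasma samples
#'
#' Uses the (ratio-converted, dispersion/delay-corrected) automatic curve
#' where it exists, then linear interpolation through the manual plasma
#' samples beyond it, with log-linear extrapolation past the last sample.
#'
#' @param auto_times,auto_plasma Corrected automatic curve, already in
#'   plasma units.
#' @param manual_times,manual_plasma Manual plasma samples (only those after
#'   the automatic window are used).
#' @param t_end End of the merged grid (minutes).
#' @param dt Output grid step (minutes).
#' @return List with `times` (uniform grid over `[0, t_end]`) and `values`.
#' @export
merge_curves <- function(auto_times, auto_plasma, manual_times, manual_plasma,
                         t_end = 120, dt = 1 / 60) {
  grid <- fine_time_grid(t_end, dt)
  a_end <- auto_times[length(auto_times)]
  late_t <- manual_times[manual_times > a_end]
  late_v <- manual_plasma[manual_times > a_end]
  if (length(late_t) && late_t[1] - a_end > 15)
    warning("gap of ", round(late_t[1] - a_end, 1),
            " min between automatic and manual series; merging anyway")
  knots_t <- c(a_end, late_t)
  knots_v <- c(stats::approx(auto_times, auto_plasma, xout = a_end)$y, late_v)
  v <- numeric(length(grid))
  early <- grid <= a_end
  v[early] <- stats::approx(auto_times, auto_plasma, xout = grid[early],
                            rule = 2)$y
  if (length(late_t)) {
    mid <- grid > a_end & grid <= late_t[length(late_t)]
    v[mid] <- stats::approx(knots_t, knots_v, xout = grid[mid])$y
    beyond <- grid > late_t[length(late_t)]
    if (any(beyond)) {
      nk <- length(knots_t)
      v1 <- knots_v[nk - 1]; v2 <- knots_v[nk]
      if (v1 > 0 && v2 > 0 && v2 < v1) {
        lam <- log(v1 / v2) / (knots_t[nk] - knots_t[nk - 1])
        v[beyond] <- v2 * exp(-lam * (grid[beyond] - knots_t[nk]))
      } else {
        v[beyond] <- v2
      }
    }
  } else {
    v[!early] <- v[sum(early)]
  }
  list(times = grid, values = pmax(v, 0))
}

#' Fit a Hill function to parent-fraction measurements
#'
#' Least squares over `(pf_inf, t50, h)` of
#' `pf(t) = 1 - (1 - pf_inf) t^h / (t50^h + t^h)`, with bounds
#' `pf_inf` in `[0, 1]`, `t50` in `(0, 500]`, `h` in `(0, 10]`, started from
#' eight fixed initializations.
#'
#' @param pf_times,pf_values Measurement times (minutes) and fractions.
#' @return A [hill_params()] with attributes `fitted` (function of time) and
#'   `rss`.
#' @export
fit_hill_parent_fraction <- function(pf_times, pf_values) {
  if (length(pf_times) < 4) stop("need at least 4 parent-fraction points")
  resid_fn <- function(p) {
    pf <- 1 - (1 - p[1]) * pf_times^p[3] / (p[2]^p[3] + pf_times^p[3])
    pf - pf_values
  }
  starts <- expand.grid(pf_inf = c(0.05, 0.4), t50 = c(10, 60),
                        h = c(1, 2.5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = as.numeric(starts[i, ]), fn = resid_fn,
                         lower = c(0, 1e-3, 1e-3), upper = c(1, 500, 10),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best))
    stop("Hill fit failed to converge from all starts (",
         length(pf_values), " points, range ",
         paste(signif(range(pf_values), 3), collapse = "-"), ")")
  p <- best$par
  hp <- hill_params(p[1], p[2], p[3])
  attr(hp, "fitted") <- function(t) generate_parent_fraction(hp, t)
  attr(hp, "rss") <- best$deviance
  hp
}

# Internal AIF constructor.
new_aif <- function(times, activity, provenance = list()) {
  structure(list(times = times, activity = pmax(activity, 0),
                 provenance = provenance), class = "aif")
}

#' @export
print.aif <- function(x, ...) {
  cat("<aif> ", length(x$times), " samples over [0, ",
      x$times[length(x$times)], "] min, peak ",
      signif(max(x$activity), 4), " kBq/mL\n", sep = "")
  invisible(x)
}

#' Metabolite-corrected arterial input function
#'
#' Pointwise product of the merged plasma curve with the fitted
#' parent-fraction curve.
#'
#' @param merged_plasma List with `times` and `values` ([merge_curves()]).
#' @param hill A [hill_params()] (fitted or known).
#' @param provenance Optional list recording upstream corrections.
#' @return An object of class `aif` with `times`, `activity`, `provenance`.
#' @export
build_input_function <- function(merged_plasma, hill, provenance = list()) {
  pf <- generate_parent_fraction(hill, merged_plasma$times)
  new_aif(merged_plasma$times, merged_plasma$values * pf,
          c(provenance, list(hill = unclass(hill))))
}

#' Truncate an AIF at a maximum scan time
#'
#' @param aif An `aif`.
#' @param t_max Maximum retained time (minutes).
#' @return The trimmed `aif`.
#' @export
truncate_aif <- function(aif, t_max) {
  keep <- aif$times <= t_max + 1e-9
  new_aif(aif$times[keep], aif$activity[keep], aif$provenance)
}

#' Run the full blood chain for one dataset
#'
#' Dispersion/delay correction of the automatic whole-blood curve,
#' conversion to plasma via the fitted plasma/whole-blood ratio, merging
#' with the manual plasma samples, Hill parent-fraction fit, and the final
#' product AIF.
#'
#' @param ds A [blood_dataset()].
#' @param tau,delay Sampler dispersion (seconds) and delay (seconds); known
#'   in simulation, user-supplied for real data.
#' @param t_end Scan end (minutes).
#' @param ratio_model Passed to [compute_plasma_wb_ratio()].
#' @return An `aif` whose provenance records every correction.
#' @export
process_blood <- function(ds, tau = 5, delay = 10, t_end = 120,
                          ratio_model = "constant") {
  dt <- ds$auto_times[2] - ds$auto_times[1]
  corrected <- correct_dispersion_delay(ds$auto_wholeblood, dt, tau, delay)
  ratio <- compute_plasma_wb_ratio(ds, ratio_model)
  auto_plasma <- corrected * ratio(ds$auto_times)
  merged <- merge_curves(ds$auto_times, auto_plasma,
                         ds$manual_times, ds$manual_plasma, t_end = t_end,
                         dt = dt)
  hill <- fit_hill_parent_fraction(ds$pf_times, ds$pf_values)
  build_input_function(merged, hill, provenance = list(
    dispersion_tau_s = tau, delay_s = delay,
    ratio = attr(ratio, "coef"), ratio_model = attr(ratio, "model")))
}
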