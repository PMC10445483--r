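#' Fit the one-tissue compartment model to a TAC
#'
#' Weighted nonlinear least squares of the frame-averaged model
#' `K1 * (AIF (x) exp(-k2 t))` to the measured TAC. `K1` is profiled (it
#' enters linearly) over a log grid of `k2` values to seed a bounded
#' Levenberg-Marquardt polish from multiple starts; bounds are
#' `K1 in (1e-4, 2]` mL/cm3/min and `k2 in (1e-4, 1]` 1/min.
#'
#' @param x A [tac()].
#' @param aif An `aif` covering the TAC's time span.
#' @param weights Frame weights; default [compute_frame_weights()] of `x`.
#' @return An object of class `onetcm_fit`: `K1`, `k2`, `V_T` (= K1/k2),
#'   `rse_K1`, `rse_k2`, `rse_V_T` (percent), `wrss`, `at_boundary`,
#'   `start_wrss`.
#' @export
fit_1tcm <- function(x, aif, weights = compute_frame_weights(x)) {
  stopifnot(inherits(x, "tac"), inherits(aif, "aif"))
  sched <- x$schedule
  if (aif$times[length(aif$times)] < sched$end[sched$n] - 1e-9)
    stop("AIF does not cover the TAC time span")
  cc <- conv_context(aif$times, aif$activity, sched)
  y <- x$values
  sw <- sqrt(weights)
  model_k2 <- function(k2) conv_frame_average(cc, k2)

  # profile K1 on a coarse log grid of k2 to locate the basin
  k2_grid <- exp(seq(log(2e-3), log(0.5), length.out = 25))
  prof <- vapply(k2_grid, function(k2) {
    m <- model_k2(k2)
    K1 <- sum(weights * y * m) / max(sum(weights * m^2), 1e-12)
    K1 <- min(max(K1, 1e-4), 2)
    sum(weights * (y - K1 * m)^2)
  }, 0)
  k2_best <- k2_grid[which.min(prof)]
  m <- model_k2(k2_best)
  K1_best <- min(max(sum(weights * y * m) / max(sum(weights * m^2), 1e-12),
                     1e-4), 2)

  resid_fn <- function(p) sw * (y - p[1] * model_k2(p[2]))
  starts <- list(c(K1_best, k2_best), c(0.1, 0.05))
  fit <- ms_nlls(resid_fn, starts, lower = c(1e-4, 1e-4), upper = c(2, 1))
  K1 <- fit$par[1]; k2 <- fit$par[2]
  cov <- gn_covariance(resid_fn, fit$par, fit$wrss, fit$n_resid)
  var_vt <- if (is.null(cov)) NULL else {
    g <- c(1 / k2, -K1 / k2^2)
    drop(t(g) %*% cov %*% g)
  }
  structure(list(
    K1 = K1, k2 = k2, V_T = K1 / k2,
    rse_K1 = rse_pct(if (is.null(cov)) NULL else cov[1, 1], K1),
    rse_k2 = rse_pct(if (is.null(cov)) NULL else cov[2, 2], k2),
    rse_V_T = rse_pct(var_vt, K1 / k2),
    wrss = fit$wrss, at_boundary = fit$at_boundary,
    start_wrss = fit$start_wrss, roi_id = x$roi_id
  ), class = "onetcm_fit")
}

#' @export
print.onetcm_fit <- function(x, ...) {
  cat("<onetcm_fit> ", x$roi_id, ": K1 = ", signif(x$K1, 4),
      " mL/cm3/min, k2 = ", signif(x$k2, 4), " 1/min, V_T = ",
      signif(x$V_T, 4), " mL/cm3\n", sep = "")
  invisible(x)
}

#' Binding potential from volumes of distribution
#'
#' `BP_ND = V_T^ROI / V_T^ref - 1`, using a low-binding reference region's
#' V_T as the estimate of nondisplaceable uptake.
#'
#' @param vt_roi Target-region V_T (mL/cm3).
#' @param vt_ref Reference-region V_T (mL/cm3), > 0.
#' @return BP_ND (unitless).
#' @export
bpnd_from_vt <- function(vt_roi, vt_ref) {
  if (any(vt_ref <= 0)) stop("reference V_T must be positive")
  vt_roi / vt_ref - 1
}
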