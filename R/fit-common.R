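# Shared weighted nonlinear least-squares machinery. All model fits go
# through ms_nlls(): deterministic Levenberg-Marquardt from a fixed list of
# starts, bounds enforced, best weighted RSS wins (ties broken by start
# order). Uncertainty comes from the Gauss-Newton covariance at the optimum.

# Multi-start bounded LM minimization of sum(resid_fn(par)^2).
# Returns par, deviance (WRSS), hessian-based covariance, flags.
ms_nlls <- function(resid_fn, starts, lower, upper, maxiter = 200) {
  best <- NULL
  start_dev <- vapply(starts, function(s) sum(resid_fn(s)^2), 0)
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(fit$par)) &&
        (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best))
    stop("nonlinear fit failed to converge from all ", length(starts),
         " starts")
  at_bound <- any(abs(best$par - lower) < 1e-8 | abs(best$par - upper) < 1e-8)
  list(par = best$par, wrss = best$deviance, start_wrss = start_dev,
       at_boundary = at_bound, n_resid = length(resid_fn(best$par)))
}

# Finite-difference Jacobian of the (already weight-scaled) residual vector.
fd_jacobian <- function(resid_fn, par, rel = 1e-6) {
  r0 <- resid_fn(par)
  J <- matrix(0, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- max(abs(par[j]) * rel, 1e-10)
    pp <- par; pp[j] <- pp[j] + h
    J[, j] <- (resid_fn(pp) - r0) / h
  }
  J
}

# Covariance of the parameters from the Gauss-Newton approximation,
# sigma^2 (J'J)^-1 with sigma^2 = WRSS / (n - p). Returns NULL when the
# curvature is singular.
gn_covariance <- function(resid_fn, par, wrss, n_resid) {
  J <- fd_jacobian(resid_fn, par)
  p <- length(par)
  dof <- max(n_resid - p, 1)
  JtJ <- crossprod(J)
  cov <- tryCatch(solve(JtJ) * wrss / dof, error = function(e) NULL)
  if (!is.null(cov) && any(!is.finite(cov))) cov <- NULL
  cov
}

#' Relative standard error of fitted parameters
#'
#' `100 * SE / |estimate|` per parameter, from the Gauss-Newton covariance
#' scaled by the weighted residual variance. Model fits in this package
#' attach these as `rse_*` fields; this helper extracts them.
#'
#' @param fit A fit object (`onetcm_fit`, `srtm_fit`, `logan_fit`).
#' @return Named numeric vector of rSE values in percent (NA where the
#'   curvature was singular).
#' @export
relative_standard_error <- function(fit) {
  rse <- unlist(fit[grep("^rse_", names(fit))])
  names(rse) <- sub("^rse_", "", names(rse))
  rse
}

# rSE (%) from a variance: NA_real_ if var is NULL/negative.
rse_pct <- function(variance, estimate) {
  if (is.null(variance) || !is.finite(variance) || variance < 0) return(NA_real_)
  100 * sqrt(variance) / abs(estimate)
}
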