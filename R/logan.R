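#' Logan reference-region graphical analysis
#'
#' Ordinary least squares of
#' `Y(t) = int_0^t C_T / C_T(t)` on
#' `X(t) = [int_0^t C_R + C_R(t)/k2'] / C_T(t)` over frames with mid-time
#' `>= t_star`; the slope is the distribution volume ratio (DVR) and
#' `BP_ND = DVR - 1`. Integrals are trapezoids over frame mid-points with a
#' zero anchor at injection.
#'
#' @param target,reference [tac()]s sharing one schedule.
#' @param k2_prime Reference efflux constant (1/min), > 0.
#' @param t_star Start of the linear segment (minutes); default 30.
#' @return An object of class `logan_fit`: `DVR`, `BP_ND`, `intercept`
#'   (minutes), `t_star`, `n_points`, `r_squared`.
#' @export
logan_reference <- function(target, reference, k2_prime, t_star = 30) {
  stopifnot(inherits(target, "tac"), inherits(reference, "tac"))
  if (!is.finite(k2_prime) || k2_prime <= 0) stop("k2_prime must be > 0")
  sched <- target$schedule
  if (!isTRUE(all.equal(sched$end, reference$schedule$end)))
    stop("target and reference must share a schedule")
  mid <- sched$mid
  trap <- function(v) {
    x <- c(0, mid); y <- c(0, v)
    (cumsum(c(0, (y[-1] + y[-length(y)]) / 2 * diff(x))))[-1]
  }
  int_t <- trap(target$values)
  int_r <- trap(reference$values)
  use <- mid >= t_star & target$values > 0
  if (sum(use) < 3)
    stop("need at least 3 frames with mid-time >= t_star = ", t_star, " min")
  Y <- int_t[use] / target$values[use]
  X <- (int_r[use] + reference$values[use] / k2_prime) / target$values[use]
  fit <- stats::lm.fit(cbind(1, X), Y)
  dvr <- fit$coefficients[[2]]
  r2 <- 1 - sum(fit$residuals^2) / sum((Y - mean(Y))^2)
  structure(list(DVR = dvr, BP_ND = dvr - 1,
                 intercept = fit$coefficients[[1]], t_star = t_star,
                 n_points = sum(use), r_squared = r2,
                 roi_id = target$roi_id),
            class = "logan_fit")
}

#' @export
print.logan_fit <- function(x, ...) {
  cat("<logan_fit> ", x$roi_id, ": DVR = ", signif(x$DVR, 4), ", BP_ND = ",
      signif(x$BP_ND, 4), " (", x$n_points, " points, R2 = ",
      signif(x$r_squared, 4), ")\n", sep = "")
  invisible(x)
}
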