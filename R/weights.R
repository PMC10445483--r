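#' Count-based frame weights for kinetic fitting
#'
#' Weights proportional to the inverse variance implied by count statistics:
#' `w_i = (dt_i d_i)^2 / max(C_i dt_i d_i, eps)` with `d_i` the isotope decay
#' factor at the frame mid-time and `eps = 1e-6 * max(C_i dt_i d_i)`.
#' Weights are normalized to mean 1.
#'
#' @param x A [tac()] (nonnegative values).
#' @param halflife Isotope half-life (minutes); default F-18.
#' @return Numeric weight per frame.
#' @export
compute_frame_weights <- function(x, halflife = 109.77) {
  stopifnot(inherits(x, "tac"))
  sched <- x$schedule
  d <- decay_factor(sched, halflife)
  prod <- pmax(x$values, 0) * sched$dur * d
  if (max(prod) == 0) {
    warning("all-zero TAC: using uniform weights")
    return(rep(1, sched$n))
  }
  eps <- 1e-6 * max(prod)
  w <- (sched$dur * d)^2 / pmax(prod, eps)
  w / mean(w)
}
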