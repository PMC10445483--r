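# Shared numerical kernels: exponential convolution on a uniform grid and
# frame averaging. All kinetic models reduce to convolutions of an input
# curve with exp(-k t); these run on a fine uniform grid (default 1 s) and
# are exact for piecewise-linear inputs, which avoids FFT edge effects on
# short scans.

#' Fine uniform time grid
#'
#' @param t_end End of the grid (minutes).
#' @param dt Grid step (minutes); default 1/60 (one second).
#' @return Numeric vector `seq(0, t_end, by = dt)`.
#' @export
fine_time_grid <- function(t_end, dt = 1 / 60) {
  if (t_end <= 0 || dt <= 0) stop("t_end and dt must be positive")
  seq(0, t_end, by = dt)
}

#' Convolution with a decaying exponential on a uniform grid
#'
#' Computes `C(t_i) = integral_0^{t_i} u(s) exp(-k (t_i - s)) ds` for `u`
#' piecewise linear on the grid, using the exact per-step analytic update
#' implemented as a first-order recursive filter.
#'
#' @param u Input samples on a uniform grid.
#' @param dt Grid step (minutes).
#' @param k Decay constant (1/min), must be > 0.
#' @return Vector of the same length as `u`.
#' @export
conv_exp <- function(u, dt, k) {
  if (!is.finite(k) || k <= 0) stop("decay constant k must be positive")
  n <- length(u)
  if (n < 2) return(numeric(n))
  E <- exp(-k * dt)
  g1 <- (1 - E) / k
  # g2 = int_0^dt (s/dt) exp(-k (dt - s)) ds
  g2 <- g1 - (1 - E * (1 + k * dt)) / (k * k * dt)
  b <- u[-n] * (g1 - g2) + u[-1] * g2
  c(0, as.numeric(stats::filter(b, E, method = "recursive")))
}

# Cumulative trapezoid integral on a uniform grid.
cumtrap_uniform <- function(v, dt) {
  n <- length(v)
  c(0, cumsum((v[-1] + v[-n]) / 2) * dt)
}

# Precompute the mapping from a uniform grid to frame boundaries so frame
# averages reduce to differences of a cumulative integral. Frame edges that
# fall off the grid are linearly interpolated.
frame_map <- function(times, schedule) {
  dt <- times[2] - times[1]
  idx_exact <- function(t) {
    i <- (t - times[1]) / dt
    list(lo = pmin(floor(i), length(times) - 1L) + 1L, frac = i - floor(i))
  }
  if (schedule$end[schedule$n] > times[length(times)] + 1e-9)
    stop("grid (ends at ", times[length(times)],
         " min) does not cover the schedule (ends at ",
         schedule$end[schedule$n], " min)")
  list(dt = dt, s = idx_exact(schedule$start), e = idx_exact(schedule$end),
       dur = schedule$dur)
}

# Frame-average a continuous curve sampled on the uniform grid, given a
# precomputed frame_map.
frame_average_map <- function(v, fm) {
  Z <- cumtrap_uniform(v, fm$dt)
  at <- function(ix) {
    z <- Z[ix$lo] + ix$frac * (Z[pmin(ix$lo + 1L, length(Z))] - Z[ix$lo])
    z
  }
  (at(fm$e) - at(fm$s)) / fm$dur
}

# Context for repeated frame-averaged convolutions of one input curve
# against many decay constants. Precomputes the frame integrals of the input
# and the boundary indices; conv_frame_average() then exploits the identity
# d/dt conv = u - k conv, so the frame integral of the convolution is
# (int_frame u - delta conv)/k — exact for piecewise-linear u, and needing
# the convolution only at frame boundaries.
conv_context <- function(times, u, schedule) {
  fm <- frame_map(times, schedule)
  Z <- cumtrap_uniform(u, fm$dt)
  bval <- function(v, ix) v[ix$lo] + ix$frac * (v[pmin(ix$lo + 1L, length(v))] - v[ix$lo])
  list(u = u, dt = fm$dt, s = fm$s, e = fm$e, dur = fm$dur,
       Uf = bval(Z, fm$e) - bval(Z, fm$s))
}

conv_frame_average <- function(cc, k) {
  cv <- conv_exp(cc$u, cc$dt, k)
  bval <- function(ix) cv[ix$lo] + ix$frac * (cv[pmin(ix$lo + 1L, length(cv))] - cv[ix$lo])
  (cc$Uf - (bval(cc$e) - bval(cc$s))) / (k * cc$dur)
}

#' Average a continuous curve over the frames of a schedule
#'
#' @param times Uniform time grid (minutes).
#' @param values Curve samples on `times`.
#' @param schedule A [frame_schedule()] covered by the grid.
#' @return One average per frame (trapezoid integral over the frame divided
#'   by its duration).
#' @export
frame_average <- function(times, values, schedule) {
  frame_average_map(values, frame_map(times, schedule))
}

# Piecewise-linear interpolation of frame values onto a fine grid, anchored
# at (0, 0) and held constant beyond the last frame mid-time. Used to put a
# measured reference TAC on the convolution grid.
interp_tac_fine <- function(tac_values, schedule, times) {
  x <- c(0, schedule$mid)
  y <- c(0, tac_values)
  stats::approx(x, y, xout = times, rule = 2)$y
}
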