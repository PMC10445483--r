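#' Frame schedule for a dynamic PET acquisition
#'
#' A frame schedule holds the start and end time of every reconstructed frame,
#' in minutes post injection. Frames must be contiguous (each frame starts
#' where the previous one ends) and strictly increasing; intervals are
#' half-open `[start, end)`.
#'
#' @param start Numeric vector of frame start times (minutes).
#' @param end Numeric vector of frame end times (minutes), same length.
#' @return An object of class `frame_schedule` with elements `start`, `end`,
#'   `mid` (frame mid-times), `dur` (frame durations) and `n`.
#' @examples
#' sched <- frame_schedule(c(0, 0.5, 1), c(0.5, 1, 2))
#' sched$mid
#' @export
frame_schedule <- function(start, end) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != length(end) || length(start) == 0)
    stop("start and end must be nonempty vectors of equal length")
  if (any(!is.finite(start)) || any(!is.finite(end)))
    stop("frame times must be finite")
  if (start[1] < 0)
    stop("first frame start must be >= 0")
  if (any(diff(start) <= 0))
    stop("frame starts must be strictly increasing (offending row ",
         which(diff(start) <= 0)[1] + 1L, ")")
  if (any(end <= start))
    stop("frame_end must exceed frame_start (offending row ",
         which(end <= start)[1], ")")
  gap <- which(abs(start[-1] - end[-length(end)]) > 1e-9)
  if (length(gap))
    stop("frames must be contiguous: start[", gap[1] + 1L,
         "] != end[", gap[1], "]")
  structure(
    list(start = start, end = end, mid = (start + end) / 2,
         dur = end - start, n = length(start)),
    class = "frame_schedule"
  )
}

#' Default 120-min acquisition schedule
#'
#' The standard [18F]SynVesT-1 binning: 6 x 30 s, 3 x 60 s, 2 x 120 s and
#' 22 x 300 s frames — 33 frames, 120 minutes in total.
#'
#' @return A [frame_schedule()].
#' @export
default_frame_schedule <- function() {
  dur <- c(rep(0.5, 6), rep(1, 3), rep(2, 2), rep(5, 22))
  end <- cumsum(dur)
  frame_schedule(c(0, end[-length(end)]), end)
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat("<frame_schedule> ", x$n, " frames, ",
      x$start[1], "-", x$end[x$n], " min\n", sep = "")
  invisible(x)
}

#' Truncate a frame schedule at a maximum scan time
#'
#' Retains frames whose end time does not exceed `t_max`.
#'
#' @param schedule A [frame_schedule()].
#' @param t_max Maximum retained time (minutes).
#' @return A shorter `frame_schedule`.
#' @export
truncate_schedule <- function(schedule, t_max) {
  keep <- schedule$end <= t_max + 1e-9
  if (!any(keep))
    stop("t_max = ", t_max, " min is below the end of the first frame")
  frame_schedule(schedule$start[keep], schedule$end[keep])
}

#' Time-activity curve for one region or voxel
#'
#' @param schedule A [frame_schedule()].
#' @param values Frame activity concentrations (kBq/mL), one per frame.
#' @param roi_id Region label.
#' @return An object of class `tac`.
#' @export
tac <- function(schedule, values, roi_id = "roi") {
  stopifnot(inherits(schedule, "frame_schedule"))
  values <- as.numeric(values)
  if (length(values) != schedule$n)
    stop("values length (", length(values), ") must match schedule (",
         schedule$n, " frames)")
  if (any(!is.finite(values)))
    stop("TAC values must be finite")
  structure(list(schedule = schedule, values = values, roi_id = roi_id),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat("<tac> ", x$roi_id, ": ", x$schedule$n, " frames, peak ",
      signif(max(x$values), 4), " kBq/mL\n", sep = "")
  invisible(x)
}

#' Truncate a TAC at a maximum scan time
#'
#' @param x A [tac()].
#' @param t_max Maximum retained time (minutes).
#' @return A `tac` on the truncated schedule.
#' @export
truncate_tac <- function(x, t_max) {
  stopifnot(inherits(x, "tac"))
  sched <- truncate_schedule(x$schedule, t_max)
  tac(sched, x$values[seq_len(sched$n)], x$roi_id)
}
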