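#' Quantification settings
#'
#' @param methods Subset of `c("1TCM", "SRTM2-pop", "SRTM2-coupled", "SRTM",
#'   "Logan")`.
#' @param k2_prime Fixed reference efflux constant (1/min) used by
#'   `SRTM2-pop` and `Logan` (a population value in practice).
#' @param t_star Logan linear-segment start (minutes).
#' @param halflife Isotope half-life for frame weights (minutes).
#' @param dt Fine-grid step for convolutions (minutes).
#' @return A list of class `run_config`.
#' @export
run_config <- function(methods = c("1TCM", "SRTM2-pop", "SRTM2-coupled",
                                   "SRTM", "Logan"),
                       k2_prime = 0.037, t_star = 30, halflife = 109.77,
                       dt = 1 / 60) {
  allowed <- c("1TCM", "SRTM2-pop", "SRTM2-coupled", "SRTM", "Logan")
  bad <- setdiff(methods, allowed)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  if (k2_prime <= 0) stop("k2_prime must be > 0")
  structure(list(methods = methods, k2_prime = k2_prime, t_star = t_star,
                 halflife = halflife, dt = dt), class = "run_config")
}

#' Per-subject data bundle for quantification
#'
#' @param subject_id,group Labels.
#' @param schedule A [frame_schedule()].
#' @param target Matrix of target-region TAC values (frames x regions, named
#'   columns).
#' @param reference Reference-region TAC values (one per frame).
#' @param aif An `aif`, or `NULL` when no arterial data exist.
#' @return An object of class `subject_data` (with `scan_end`).
#' @export
subject_data <- function(subject_id, group, schedule, target, reference,
                         aif = NULL) {
  stopifnot(inherits(schedule, "frame_schedule"), is.matrix(target))
  if (nrow(target) != schedule$n || length(reference) != schedule$n)
    stop("TACs must match the schedule's frame count")
  if (is.null(colnames(target)))
    colnames(target) <- sprintf("roi%02d", seq_len(ncol(target)))
  structure(list(subject_id = subject_id, group = group, schedule = schedule,
                 target = target, reference = as.numeric(reference),
                 aif = aif, scan_end = schedule$end[schedule$n]),
            class = "subject_data")
}

#' Assemble subject_data bundles from a synthetic cohort
#'
#' @param cohort A [generate_cohort()] result.
#' @param aif `"blood"` to run the full blood chain ([process_blood()] with
#'   the subject's true dispersion/delay), `"true"` for the generating AIF,
#'   or `"none"`.
#' @return Named list of [subject_data()].
#' @export
cohort_to_subject_data <- function(cohort, aif = c("blood", "true", "none")) {
  aif <- match.arg(aif)
  scan_end <- cohort$schedule$end[cohort$schedule$n]
  out <- lapply(names(cohort$subjects), function(id) {
    s <- cohort$subjects[[id]]
    a <- switch(aif,
                blood = process_blood(cohort$blood[[id]],
                                      tau = s$input_params$dispersion_tau,
                                      delay = s$input_params$delay,
                                      t_end = scan_end),
                true = true_aif(s, scan_end),
                none = NULL)
    m <- cohort$tacs[[id]]
    subject_data(id, s$group, cohort$schedule,
                 m[, colnames(m) != "ref", drop = FALSE], m[, "ref"], a)
  })
  stats::setNames(out, names(cohort$subjects))
}

#' Truncate a subject's scan at a maximum time
#'
#' Retains frames ending at or before `t_max` and trims the AIF to match.
#'
#' @param subject A [subject_data()].
#' @param t_max Maximum retained time (minutes).
#' @return A truncated [subject_data()].
#' @export
truncate_scan <- function(subject, t_max) {
  stopifnot(inherits(subject, "subject_data"))
  sched <- truncate_schedule(subject$schedule, t_max)
  keep <- seq_len(sched$n)
  subject_data(subject$subject_id, subject$group, sched,
               subject$target[keep, , drop = FALSE],
               subject$reference[keep],
               if (is.null(subject$aif)) NULL else truncate_aif(subject$aif, t_max))
}

#' Run every configured quantification method on one subject
#'
#' Produces per-method BP_ND for all target regions. The 1TCM method fits
#' every target and the reference region against the AIF and converts
#' V_T ratios to BP_ND ([bpnd_from_vt()]); reference-region methods use the
#' reference TAC directly. If the 1TCM is requested without an AIF it is
#' skipped with a flag.
#'
#' @param subject A [subject_data()].
#' @param config A [run_config()].
#' @return Named list of `method_results`, each with `method`, `bpnd`
#'   (named per region), `auxiliary` (fits, V_T table, k2' used) and
#'   `flags`.
#' @export
run_subject <- function(subject, config = run_config()) {
  stopifnot(inherits(subject, "subject_data"))
  sched <- subject$schedule
  rois <- colnames(subject$target)
  tacs <- lapply(rois, function(r) tac(sched, subject$target[, r], r))
  names(tacs) <- rois
  ref <- tac(sched, subject$reference, "ref")
  w <- lapply(tacs, compute_frame_weights, halflife = config$halflife)
  out <- list()

  if ("1TCM" %in% config$methods) {
    if (is.null(subject$aif)) {
      out[["1TCM"]] <- list(method = "1TCM", bpnd = NULL, auxiliary = NULL,
                            flags = "skipped: no AIF")
    } else {
      fits <- lapply(tacs, fit_1tcm, aif = subject$aif)
      ref_fit <- fit_1tcm(ref, subject$aif,
                          compute_frame_weights(ref, config$halflife))
      vt <- vapply(fits, `[[`, 0, "V_T")
      out[["1TCM"]] <- list(
        method = "1TCM",
        bpnd = bpnd_from_vt(vt, ref_fit$V_T),
        auxiliary = list(fits = fits, ref_fit = ref_fit, V_T = vt,
                         ref_V_T = ref_fit$V_T, ref_k2 = ref_fit$k2),
        flags = character())
    }
  }
  ctx <- srtm_context(ref, config$dt)
  if ("SRTM2-pop" %in% config$methods) {
    fits <- lapply(rois, function(r)
      fit_srtm2(tacs[[r]], ref, config$k2_prime, w[[r]], config$dt, ctx))
    names(fits) <- rois
    out[["SRTM2-pop"]] <- list(
      method = "SRTM2-pop", bpnd = vapply(fits, `[[`, 0, "BP_ND"),
      auxiliary = list(fits = fits, k2_prime = config$k2_prime),
      flags = character())
  }
  if ("SRTM2-coupled" %in% config$methods) {
    cp <- fit_srtm_coupled(tacs, ref, w, config$dt)
    out[["SRTM2-coupled"]] <- list(
      method = "SRTM2-coupled", bpnd = vapply(cp$fits, `[[`, 0, "BP_ND"),
      auxiliary = list(fits = cp$fits, k2_prime = cp$k2_prime),
      flags = character())
  }
  if ("SRTM" %in% config$methods) {
    fits <- lapply(rois, function(r) fit_srtm(tacs[[r]], ref, w[[r]], config$dt))
    names(fits) <- rois
    out[["SRTM"]] <- list(
      method = "SRTM", bpnd = vapply(fits, `[[`, 0, "BP_ND"),
      auxiliary = list(fits = fits),
      flags = character())
  }
  if ("Logan" %in% config$methods) {
    fits <- lapply(rois, function(r)
      logan_reference(tacs[[r]], ref, config$k2_prime, config$t_star))
    names(fits) <- rois
    out[["Logan"]] <- list(
      method = "Logan", bpnd = vapply(fits, `[[`, 0, "BP_ND"),
      auxiliary = list(fits = fits, k2_prime = config$k2_prime,
                       t_star = config$t_star),
      flags = character())
  }
  out
}

#' Population reference efflux constant from 1TCM fits
#'
#' Arithmetic mean of per-subject reference-region k2 values from 1TCM,
#' optionally excluding subjects (the convention for short scans).
#'
#' @param cs_k2 Named numeric vector of per-subject reference-region k2
#'   (1/min).
#' @param include Optional character vector of subject ids to keep.
#' @return List of class `pop_k2prime`: `value`, `contributing_subjects`,
#'   `per_subject_cs_k2`.
#' @export
estimate_pop_k2prime <- function(cs_k2, include = names(cs_k2)) {
  keep <- intersect(names(cs_k2), include)
  if (!length(keep)) stop("no contributing subjects")
  structure(list(value = mean(cs_k2[keep]), contributing_subjects = keep,
                 per_subject_cs_k2 = cs_k2[keep]),
            class = "pop_k2prime")
}

#' @export
print.pop_k2prime <- function(x, ...) {
  cat("<pop_k2prime> ", signif(x$value, 4), " 1/min from ",
      length(x$contributing_subjects), " subjects\n", sep = "")
  invisible(x)
}
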