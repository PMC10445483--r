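# Cohort-level study drivers mirroring the clinical analysis: estimate the
# population reference efflux constant from 1TCM fits of the reference
# region, quantify every subject with each method, and assemble the
# method-agreement and time-stability reports.

#' Method-agreement study on a cohort
#'
#' Runs the full quantification chain on every subject: blood processing to
#' an AIF, 1TCM fits of all regions and the reference region, population
#' k2' as the mean reference k2 across (non-excluded) subjects, then the
#' requested reference-region methods with that value, and per-method
#' agreement against 1TCM BP_ND.
#'
#' @param cohort A [generate_cohort()] result (or a named list of
#'   [subject_data()] with AIFs, plus `groups`).
#' @param methods Reference-region methods to evaluate (subset of
#'   `c("SRTM2-pop", "SRTM2-coupled", "SRTM", "Logan")`).
#' @param aif How to obtain AIFs from a cohort; see
#'   [cohort_to_subject_data()].
#' @param t_star Logan start time (minutes).
#' @param exclude_from_popk2 Subject ids excluded from the population k2'
#'   (the convention for short scans).
#' @return List of class `agreement_study`: `pop_k2prime`, `results`
#'   (per-subject method results incl. 1TCM), `agreement` (one
#'   [method_agreement()] report per method), `groups`.
#' @export
agreement_study <- function(cohort, methods = "SRTM2-pop", aif = "blood",
                            t_star = 30, exclude_from_popk2 = character()) {
  if (inherits(cohort, "synthetic_cohort")) {
    sds <- cohort_to_subject_data(cohort, aif = aif)
    groups <- vapply(cohort$subjects, `[[`, "", "group")
  } else {
    sds <- cohort$subjects
    groups <- cohort$groups
  }
  res_1tcm <- lapply(sds, run_subject, config = run_config(methods = "1TCM"))
  cs_k2 <- vapply(res_1tcm, function(r) r[["1TCM"]]$auxiliary$ref_k2, 0)
  pop <- estimate_pop_k2prime(cs_k2,
                              include = setdiff(names(cs_k2),
                                                exclude_from_popk2))
  cfg <- run_config(methods = methods, k2_prime = pop$value, t_star = t_star)
  res_ref <- lapply(sds, run_subject, config = cfg)
  bp_1tcm <- lapply(res_1tcm, function(r) r[["1TCM"]]$bpnd)
  agreement <- lapply(methods, function(m) {
    bp_m <- lapply(res_ref, function(r) r[[m]]$bpnd)
    method_agreement(bp_m, bp_1tcm, groups, method = m)
  })
  names(agreement) <- methods
  results <- lapply(names(sds), function(id)
    c(res_1tcm[[id]], res_ref[[id]]))
  names(results) <- names(sds)
  structure(list(pop_k2prime = pop, results = results,
                 agreement = agreement, groups = groups),
            class = "agreement_study")
}

#' @export
print.agreement_study <- function(x, ...) {
  cat("<agreement_study> pop-k2' = ", signif(x$pop_k2prime$value, 3),
      " 1/min (", length(x$pop_k2prime$contributing_subjects),
      " subjects)\n", sep = "")
  for (m in names(x$agreement)) print(x$agreement[[m]])
  invisible(x)
}

#' Time-stability study on a cohort
#'
#' Estimates the population k2' from full-length 1TCM reference fits, then
#' runs [time_stability()] for every subject with the requested methods and
#' truncation grid, and summarizes percent bias by method, t_max, and group.
#'
#' @param cohort A [generate_cohort()] result.
#' @param methods Methods to evaluate (any of the [run_config()] set; the
#'   1TCM requires AIFs).
#' @param t_max_grid Truncation times (minutes).
#' @param aif See [cohort_to_subject_data()].
#' @return List of class `time_stability_study`: `pop_k2prime`, `reports`
#'   (per subject), `summary` ([summarize_time_stability()]).
#' @export
time_stability_study <- function(cohort, methods = "SRTM2-pop",
                                 t_max_grid = c(40, 60, 80, 90, 100),
                                 aif = "blood") {
  need_aif <- "1TCM" %in% methods
  sds <- cohort_to_subject_data(cohort, aif = if (need_aif || aif == "blood")
    aif else "none")
  if (aif == "none" && !need_aif) {
    # pop-k2' still needs 1TCM of the reference region; use blood AIFs
    sds_b <- cohort_to_subject_data(cohort, aif = "blood")
  } else sds_b <- sds
  ref_fits <- lapply(sds_b, function(sd) {
    fit_1tcm(tac(sd$schedule, sd$reference, "ref"), sd$aif)
  })
  pop <- estimate_pop_k2prime(vapply(ref_fits, `[[`, 0, "k2"))
  cfg <- run_config(methods = methods, k2_prime = pop$value)
  reports <- lapply(sds, time_stability, config = cfg,
                    t_max_grid = t_max_grid)
  structure(list(pop_k2prime = pop, reports = reports,
                 summary = summarize_time_stability(reports)),
            class = "time_stability_study")
}

#' @export
print.time_stability_study <- function(x, ...) {
  cat("<time_stability_study> pop-k2' = ", signif(x$pop_k2prime$value, 3),
      " 1/min\n", sep = "")
  print(x$summary[x$summary$group == "all",
                  c("method", "t_max", "bias_mean", "bias_sd",
                    "abs_bias_mean")])
  invisible(x)
}
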