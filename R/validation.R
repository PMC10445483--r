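#' Percent bias of an estimate against a reference value
#'
#' `100 * (est - ref) / ref`; negative values indicate underestimation.
#'
#' @param est Estimated value(s).
#' @param ref Reference value(s) (e.g. 1TCM BP_ND); zeros yield `NA` with a
#'   warning.
#' @return Percent bias, same length as the inputs.
#' @export
percent_bias <- function(est, ref) {
  out <- 100 * (est - ref) / ref
  if (any(ref == 0)) {
    warning("reference value of 0: percent bias undefined")
    out[ref == 0] <- NA_real_
  }
  out
}

#' Welch two-sample comparison of two groups
#'
#' Unequal-variance (Welch) t-test, two-sided. When both groups are constant
#' and identical the difference is degenerate and `p = 1` by convention.
#'
#' @param values_hc,values_pd Numeric vectors (>= 2 values each).
#' @param variable Label for the compared quantity.
#' @return List of class `group_comparison`: `variable`, `mean_sd_by_group`,
#'   `t`, `df`, `p_value`.
#' @export
group_ttest <- function(values_hc, values_pd, variable = "value") {
  if (length(values_hc) < 2 || length(values_pd) < 2)
    stop("need at least 2 values per group")
  msd <- rbind(hc = c(mean = mean(values_hc), sd = stats::sd(values_hc)),
               pd = c(mean = mean(values_pd), sd = stats::sd(values_pd)))
  res <- tryCatch({
    tt <- stats::t.test(values_hc, values_pd, var.equal = FALSE)
    list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
  }, error = function(e) {
    # degenerate (essentially constant) data: identical groups get p = 1,
    # a certain difference gets p = 0
    d <- abs(mean(values_hc) - mean(values_pd))
    if (d <= 1e-10 * max(1, abs(mean(values_hc))))
      list(t = 0, df = NA_real_, p = 1)
    else list(t = Inf, df = NA_real_, p = 0)
  })
  structure(list(variable = variable, mean_sd_by_group = msd, t = res$t,
                 df = res$df, p_value = res$p),
            class = "group_comparison")
}

# OLS of y on x returning slope, intercept, R^2.
ols_line <- function(x, y) {
  fit <- stats::lm.fit(cbind(1, x), y)
  ssr <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  c(intercept = fit$coefficients[[1]], slope = fit$coefficients[[2]],
    r_squared = if (sst > 0) 1 - ssr / sst else 1)
}

#' Agreement of a quantification method with the 1TCM standard
#'
#' Per-subject ordinary least-squares regression of the method's BP_ND on
#' 1TCM BP_ND across regions, pooled regression across all points, and
#' percent-bias summaries (mean +/- SD across regions within subject, then
#' by group), with a Welch test for a group difference in mean bias.
#'
#' @param bpnd_method Named list (by subject) of named BP_ND vectors from
#'   the evaluated method.
#' @param bpnd_1tcm Same structure from the 1TCM.
#' @param groups Named character vector of group labels (`"hc"`/`"pd"`) per
#'   subject.
#' @param method Label of the evaluated method.
#' @return List of class `agreement_report`: `per_subject` (data frame with
#'   slope, intercept, r_squared, bias_mean, bias_sd), `pooled`, `by_group`,
#'   `group_p`, `skipped`.
#' @export
method_agreement <- function(bpnd_method, bpnd_1tcm, groups,
                             method = "method") {
  subjects <- intersect(names(bpnd_method), names(bpnd_1tcm))
  rows <- list()
  skipped <- character()
  all_x <- numeric(); all_y <- numeric()
  for (id in subjects) {
    common <- intersect(names(bpnd_method[[id]]), names(bpnd_1tcm[[id]]))
    if (length(common) < 3) {
      skipped <- c(skipped, id)
      next
    }
    x <- bpnd_1tcm[[id]][common]
    y <- bpnd_method[[id]][common]
    ln <- ols_line(x, y)
    bias <- percent_bias(y, x)
    rows[[id]] <- data.frame(
      subject_id = id, group = groups[[id]],
      slope = ln[["slope"]], intercept = ln[["intercept"]],
      r_squared = ln[["r_squared"]],
      bias_mean = mean(bias), bias_sd = stats::sd(bias))
    all_x <- c(all_x, x); all_y <- c(all_y, y)
  }
  if (!length(rows)) stop("no subject had >= 3 common regions")
  per_subject <- do.call(rbind, rows)
  rownames(per_subject) <- NULL
  pooled_ln <- ols_line(all_x, all_y)
  pooled <- c(pooled_ln, bias_mean = mean(percent_bias(all_y, all_x)),
              bias_sd = stats::sd(percent_bias(all_y, all_x)))
  by_group <- do.call(rbind, lapply(split(per_subject, per_subject$group),
                                    function(d) data.frame(
                                      group = d$group[1], n = nrow(d),
                                      bias_mean = mean(d$bias_mean),
                                      bias_sd = stats::sd(d$bias_mean))))
  rownames(by_group) <- NULL
  hc <- per_subject$bias_mean[per_subject$group == "hc"]
  pd <- per_subject$bias_mean[per_subject$group == "pd"]
  group_p <- if (length(hc) >= 2 && length(pd) >= 2)
    group_ttest(hc, pd, "bias")$p_value else NA_real_
  structure(list(method = method, per_subject = per_subject, pooled = pooled,
                 by_group = by_group, group_p = group_p, skipped = skipped),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report> ", x$method, " vs 1TCM: pooled slope ",
      signif(x$pooled[["slope"]], 3), ", R2 ",
      signif(x$pooled[["r_squared"]], 4), ", bias ",
      signif(x$pooled[["bias_mean"]], 3), "% (group p = ",
      signif(x$group_p, 3), ")\n", sep = "")
  invisible(x)
}

#' Scan-truncation (time-stability) analysis of one subject
#'
#' For each `t_max`, truncates the scan, refits the requested methods, and
#' expresses BP_ND (and, for 1TCM, V_T) as percent bias against the
#' full-length estimate from the same method. rSE values of BP_ND are
#' collected where available.
#'
#' @param subject A full-length [subject_data()].
#' @param config A [run_config()] naming the methods to evaluate.
#' @param t_max_grid Truncation times (minutes); values beyond the scan end
#'   are skipped with a flag.
#' @return List of class `time_stability_report`: `bias` (data frame with
#'   subject, method, t_max, roi, bpnd, bias_pct, rse_bp), `full` (the
#'   full-length results), `skipped_t_max`.
#' @export
time_stability <- function(subject, config = run_config(methods = "SRTM2-pop"),
                           t_max_grid = c(40, 60, 80, 90, 100)) {
  stopifnot(inherits(subject, "subject_data"))
  full <- run_subject(subject, config)
  skipped <- t_max_grid[t_max_grid > subject$scan_end + 1e-9]
  grid <- t_max_grid[t_max_grid <= subject$scan_end + 1e-9]
  rows <- list()
  extract_rse <- function(res) {
    if (is.null(res$auxiliary$fits)) return(NULL)
    vapply(res$auxiliary$fits, function(f)
      if (!is.null(f$rse_BP)) f$rse_BP else NA_real_, 0)
  }
  for (tm in c(grid, subject$scan_end)) {
    res <- run_subject(truncate_scan(subject, tm), config)
    for (m in names(res)) {
      if (is.null(res[[m]]$bpnd)) next
      rois <- names(res[[m]]$bpnd)
      rse <- extract_rse(res[[m]])
      rows[[paste(m, tm)]] <- data.frame(
        subject_id = subject$subject_id, group = subject$group,
        method = m, t_max = tm, roi = rois,
        bpnd = unname(res[[m]]$bpnd),
        bias_pct = percent_bias(unname(res[[m]]$bpnd),
                                unname(full[[m]]$bpnd[rois])),
        rse_bp = if (is.null(rse)) NA_real_ else unname(rse[rois]))
    }
  }
  bias <- do.call(rbind, rows)
  rownames(bias) <- NULL
  structure(list(bias = bias, full = full, t_max_grid = grid,
                 skipped_t_max = skipped),
            class = "time_stability_report")
}

#' Summarize time-stability bias across subjects
#'
#' @param reports List of [time_stability()] reports (one per subject).
#' @return Data frame of mean +/- SD percent bias and mean absolute bias per
#'   method, `t_max`, and group, plus the pooled (`"all"`) rows.
#' @export
summarize_time_stability <- function(reports) {
  bias <- do.call(rbind, lapply(reports, `[[`, "bias"))
  agg <- function(d, g) data.frame(
    method = d$method[1], t_max = d$t_max[1], group = g, n = nrow(d),
    bias_mean = mean(d$bias_pct), bias_sd = stats::sd(d$bias_pct),
    abs_bias_mean = mean(abs(d$bias_pct)),
    rse_mean = mean(d$rse_bp, na.rm = TRUE))
  parts <- split(bias, list(bias$method, bias$t_max), drop = TRUE)
  out <- do.call(rbind, c(
    lapply(parts, agg, g = "all"),
    unlist(lapply(parts, function(d)
      lapply(split(d, d$group), function(dd) agg(dd, dd$group[1]))),
      recursive = FALSE)))
  rownames(out) <- NULL
  out[order(out$method, out$t_max, out$group), ]
}
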