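#!/usr/bin/env Rscript
# Method-agreement analysis: per-subject linear regression of each
# reference-region method's BP_ND on the 1TCM standard, percent-bias
# summaries by group, and Welch tests for group differences in bias.
# Writes per-method agreement CSV/JSON and a scatter figure.

suppressPackageStartupMessages(library(refkin))

fit_table <- utils::read.csv("results/fits.csv")
out <- "results"
dir.create(file.path(out, "figures"), recursive = TRUE, showWarnings = FALSE)

split_bp <- function(m) {
  d <- fit_table[fit_table$method == m, ]
  lapply(split(d, d$subject_id), function(x)
    stats::setNames(x$bpnd, x$roi))
}
groups <- vapply(split(fit_table, fit_table$subject_id),
                 function(d) d$group[1], "")
bp_1tcm <- split_bp("1TCM")

methods <- c("SRTM2-pop", "SRTM2-coupled", "SRTM", "Logan")
for (m in methods) {
  ag <- method_agreement(split_bp(m), bp_1tcm, groups, method = m)
  print(ag)
  write_agreement_report(ag,
                         csv_path = file.path(out, paste0("agreement_", m, ".csv")),
                         json_path = file.path(out, paste0("agreement_", m, ".json")))
}

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  wide <- merge(fit_table[fit_table$method == "1TCM",
                          c("subject_id", "group", "roi", "bpnd")],
                fit_table[fit_table$method != "1TCM",
                          c("subject_id", "method", "roi", "bpnd")],
                by = c("subject_id", "roi"), suffixes = c("_1tcm", ""))
  p <- ggplot(wide, aes(bpnd_1tcm, bpnd, color = group)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey50") +
    geom_point(size = 0.8, alpha = 0.7) +
    facet_wrap(~method) +
    labs(x = expression(BP[ND] ~ "(1TCM)"),
         y = expression(BP[ND] ~ "(reference method)"),
         title = "Reference-region methods vs 1TCM") +
    theme_bw()
  ggsave(file.path(out, "figures", "agreement_scatter.png"), p,
         width = 7, height = 6, dpi = 150)
  message("wrote figures/agreement_scatter.png")
}
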