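# Plain-text readers and writers: TAC tables as TSV, blood data as CSV, AIFs
# as TSV, reports and provenance as JSON, images as NIfTI. Column names carry
# units so the files are self-describing and diffable.

#' Write regional TACs to a TSV table
#'
#' Columns `frame_start_min`, `frame_end_min`, then one column of kBq/mL
#' values per region.
#'
#' @param schedule A [frame_schedule()].
#' @param values Matrix (frames x regions) with column names, or a single
#'   numeric vector.
#' @param path Output file.
#' @export
write_tac_table <- function(schedule, values, path) {
  if (!is.matrix(values)) values <- matrix(values, ncol = 1,
                                           dimnames = list(NULL, "roi"))
  stopifnot(nrow(values) == schedule$n)
  df <- data.frame(frame_start_min = schedule$start,
                   frame_end_min = schedule$end, values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a TAC table written by [write_tac_table()]
#'
#' @param path TSV file with `frame_start_min`, `frame_end_min` and at least
#'   one region column.
#' @return List with `schedule` (validated [frame_schedule()]) and `values`
#'   (frames x regions matrix).
#' @export
read_tac_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("frame_start_min", "frame_end_min")
  if (!all(need %in% names(df)))
    stop("TAC table must contain columns ", paste(need, collapse = ", "))
  if (ncol(df) < 3) stop("TAC table must contain at least one region column")
  sched <- frame_schedule(df$frame_start_min, df$frame_end_min)
  vals <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
  if (any(!is.finite(vals))) stop("TAC table contains non-finite values")
  list(schedule = sched, values = vals)
}

#' Write a blood dataset to CSV
#'
#' Long format with columns `series` (auto/manual), `time_min`,
#' `whole_blood`, `plasma`, `parent_fraction`; cells are empty where a
#' quantity was not measured in that series.
#'
#' @param ds A [blood_dataset()].
#' @param path Output file.
#' @export
write_blood_csv <- function(ds, path) {
  df <- rbind(
    data.frame(series = "auto", time_min = ds$auto_times,
               whole_blood = ds$auto_wholeblood, plasma = NA_real_,
               parent_fraction = NA_real_),
    data.frame(series = "manual", time_min = ds$manual_times,
               whole_blood = ds$manual_wholeblood, plasma = ds$manual_plasma,
               parent_fraction = ds$pf_values[match(ds$manual_times,
                                                    ds$pf_times)]))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a blood CSV written by [write_blood_csv()]
#'
#' @param path CSV file.
#' @return A [blood_dataset()].
#' @export
read_blood_csv <- function(path) {
  df <- utils::read.csv(path)
  a <- df[df$series == "auto", ]
  m <- df[df$series == "manual", ]
  pf_ok <- !is.na(m$parent_fraction)
  blood_dataset(auto_times = a$time_min, auto_wholeblood = a$whole_blood,
                manual_times = m$time_min, manual_wholeblood = m$whole_blood,
                manual_plasma = m$plasma,
                pf_times = m$time_min[pf_ok], pf_values = m$parent_fraction[pf_ok])
}

#' Write an arterial input function to TSV (with JSON provenance sidecar)
#'
#' @param aif An `aif`.
#' @param path Output TSV (`time_min`, `activity_kBq_per_mL`); provenance is
#'   written to `paste0(path, ".json")`.
#' @export
write_aif_tsv <- function(aif, path) {
  utils::write.table(data.frame(time_min = aif$times,
                                activity_kBq_per_mL = aif$activity),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(aif$provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an AIF TSV written by [write_aif_tsv()]
#'
#' @param path TSV file.
#' @return An `aif` (provenance restored from the sidecar if present).
#' @export
read_aif_tsv <- function(path) {
  df <- utils::read.delim(path)
  side <- paste0(path, ".json")
  prov <- if (file.exists(side)) jsonlite::read_json(side) else list()
  new_aif(df$time_min, df$activity_kBq_per_mL, prov)
}

#' Write a 4D dynamic image (or 3D label map) as NIfTI
#'
#' @param img Numeric 3D/4D array.
#' @param path Output `.nii` or `.nii.gz` file.
#' @param voxel_size Voxel edge length (mm).
#' @export
write_nifti_image <- function(img, path, voxel_size = 2) {
  RNifti::writeNifti(RNifti::asNifti(img, pixdim = rep(voxel_size,
                                                       min(length(dim(img)), 3))),
                     path)
  invisible(path)
}

#' Read a NIfTI image as a plain array
#'
#' @param path `.nii`/`.nii.gz` file.
#' @return Numeric array.
#' @export
read_nifti_image <- function(path) {
  as.array(RNifti::readNifti(path))
}

#' Read and validate a run configuration (JSON or YAML)
#'
#' Recognized keys: `methods`, `k2_prime`, `t_star`, `halflife`, `dt`,
#' `truncation_grid`, `seed`, `n_hc`, `n_pd`, `noise_scale`. Unknown keys
#' are rejected.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return List with a validated [run_config()] under `$run` plus the
#'   simulation keys (`truncation_grid`, `seed`, `n_hc`, `n_pd`,
#'   `noise_scale`) at the top level.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  known <- c("methods", "k2_prime", "t_star", "halflife", "dt",
             "truncation_grid", "seed", "n_hc", "n_pd", "noise_scale")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  rc_args <- raw[intersect(names(raw), c("methods", "k2_prime", "t_star",
                                         "halflife", "dt"))]
  out <- raw[intersect(names(raw), c("truncation_grid", "seed", "n_hc",
                                     "n_pd", "noise_scale"))]
  out$run <- do.call(run_config, rc_args)
  out
}

#' Write an agreement report to CSV and JSON
#'
#' @param report An [method_agreement()] result.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @export
write_agreement_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report$per_subject, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(method = report$method, pooled = as.list(report$pooled),
           by_group = report$by_group, group_p = report$group_p,
           per_subject = report$per_subject),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(report)
}
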