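#' Configuration of the synthetic cohort generator
#'
#' Population distributions are anchored to centrum semiovale (CS) 1TCM
#' values reported for [18F]SynVesT-1: reference efflux k2 ~ N(0.036, 0.006)
#' in controls and N(0.037, 0.005) in patients (truncated above 0.01 1/min),
#' reference V_T ~ N(3.6, 0.9) and N(3.5, 0.4) mL/cm3. Target grey-matter
#' regions get true BP_ND values spanning `bp_range`, reduced multiplicatively
#' by `pd_reduction` in `pd_rois` for the patient group.
#'
#' @param n_rois Number of target grey-matter regions (default 28).
#' @param ref_k2_mean,ref_k2_sd Group means/SDs of reference k2 (1/min),
#'   named `hc` and `pd`.
#' @param ref_vt_mean,ref_vt_sd Group means/SDs of reference V_T (mL/cm3).
#' @param bp_range Range of true target BP_ND values (span across regions).
#' @param bp_subject_cv Log-scale SD of per-subject, per-region BP_ND jitter.
#' @param pd_reduction Multiplicative BP_ND factor applied to `pd_rois` in
#'   the patient group (1 = no group difference).
#' @param pd_rois Indices of regions affected by `pd_reduction`.
#' @param region_r1_mean,region_r1_sd Distribution of the target/reference
#'   influx ratio R1 = K1/K1' (truncated to `[0.5, 2.8]`); region K1 is
#'   `R1 * ref_K1` and region k2 follows from K1 and the region's V_T, so
#'   grey-matter influx stays near-constant across binding levels.
#' @param plasma_wb_ratio Plasma-to-whole-blood ratio (constant in time).
#' @param pf_noise_sd SD of additive noise on parent-fraction measurements.
#' @param blood_noise_cv Multiplicative CV of noise on automatic-sampler and
#'   manual blood samples (0 = noiseless blood).
#' @param noise_scale TAC noise scale passed to [noise_model()].
#' @param grid_dt Fine-grid step for curve generation (minutes).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_rois = 28L,
                          ref_k2_mean = c(hc = 0.036, pd = 0.037),
                          ref_k2_sd = c(hc = 0.006, pd = 0.005),
                          ref_vt_mean = c(hc = 3.6, pd = 3.5),
                          ref_vt_sd = c(hc = 0.9, pd = 0.4),
                          bp_range = c(0.5, 4.5),
                          bp_subject_cv = 0.05,
                          pd_reduction = 0.85,
                          pd_rois = seq_len(n_rois),
                          region_r1_mean = 2.0,
                          region_r1_sd = 0.2,
                          plasma_wb_ratio = 1.25,
                          pf_noise_sd = 0.02,
                          blood_noise_cv = 0,
                          noise_scale = 0.05,
                          grid_dt = 1 / 60) {
  stopifnot(n_rois >= 1, bp_range[1] > -1, diff(bp_range) >= 0,
            pd_reduction > 0, noise_scale >= 0)
  structure(as.list(environment()), class = "cohort_config")
}

# Truncated-normal draw (resampling; distributions here are far from the
# bound so this terminates immediately in practice).
rnorm_trunc <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x <= lower
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x <= lower
  }
  x
}

#' Draw one ground-truth subject
#'
#' @param subject_id Label.
#' @param group `"hc"` or `"pd"`.
#' @param config A [cohort_config()].
#' @param seed Integer seed for this subject's parameter draws.
#' @return An object of class `ground_truth_subject` holding the reference
#'   kinetics (`ref_K1`, `ref_k2`), per-region `region_K1`/`region_k2`, the
#'   implied `true_bpnd` per region, blood-model parameters, and the fine
#'   grid step.
#' @export
generate_subject <- function(subject_id, group = c("hc", "pd"),
                             config = cohort_config(), seed = 1L) {
  group <- match.arg(group)
  with_seed(seed, {
    ref_k2 <- rnorm_trunc(1, config$ref_k2_mean[[group]],
                          config$ref_k2_sd[[group]], 0.01)
    ref_vt <- rnorm_trunc(1, config$ref_vt_mean[[group]],
                          config$ref_vt_sd[[group]], 0.5)
    n <- config$n_rois
    bp <- seq(config$bp_range[1], config$bp_range[2], length.out = n)
    if (group == "pd") bp[config$pd_rois] <- bp[config$pd_rois] * config$pd_reduction
    bp <- bp * exp(stats::rnorm(n, 0, config$bp_subject_cv))
    r1 <- pmin(rnorm_trunc(n, config$region_r1_mean, config$region_r1_sd, 0.5),
               2.8)
    region_K1 <- r1 * ref_vt * ref_k2
    region_k2 <- region_K1 / (ref_vt * (1 + bp))
    subj <- structure(list(
      subject_id = subject_id, group = group,
      ref_K1 = ref_vt * ref_k2, ref_k2 = ref_k2,
      region_K1 = stats::setNames(region_K1, sprintf("roi%02d", seq_len(n))),
      region_k2 = stats::setNames(region_k2, sprintf("roi%02d", seq_len(n))),
      true_bpnd = stats::setNames(bp, sprintf("roi%02d", seq_len(n))),
      plasma_wb_ratio = config$plasma_wb_ratio,
      hill = hill_params(),
      input_params = input_function_params(),
      grid_dt = config$grid_dt
    ), class = "ground_truth_subject")
    subj
  })
}

#' @export
print.ground_truth_subject <- function(x, ...) {
  cat("<ground_truth_subject> ", x$subject_id, " (", toupper(x$group), "): ",
      length(x$region_K1), " target regions, ref V_T = ",
      signif(x$ref_K1 / x$ref_k2, 4), " mL/cm3, ref k2 = ",
      signif(x$ref_k2, 3), " 1/min\n", sep = "")
  invisible(x)
}

#' True metabolite-corrected arterial input function of a subject
#'
#' Evaluates the subject's generating plasma model times its Hill
#' parent-fraction curve on a fine grid — the ground-truth AIF against which
#' blood processing and 1TCM fits are validated.
#'
#' @param subject A [generate_subject()] result.
#' @param t_end Grid end (minutes).
#' @return An object of class `aif` (see [build_input_function()]).
#' @export
true_aif <- function(subject, t_end = 120) {
  grid <- fine_time_grid(t_end, subject$grid_dt)
  plasma <- generate_input_function(subject$input_params, grid)
  pf <- generate_parent_fraction(subject$hill, grid)
  new_aif(grid, plasma * pf, list(source = "ground truth"))
}

# True whole-blood curve: plasma divided by the plasma/WB ratio.
true_wholeblood <- function(subject, grid) {
  generate_input_function(subject$input_params, grid) / subject$plasma_wb_ratio
}

#' Simulate the blood data acquired for one subject
#'
#' Produces what the blood chain sees: (a) an automatic-sampler whole-blood
#' curve at 1 s resolution over 0-22 min with the subject's dispersion and
#' delay applied, (b) manual whole-blood and plasma samples at the standard
#' draw times, and (c) parent-fraction measurements at those times from the
#' subject's Hill curve plus optional noise.
#'
#' @param subject A [generate_subject()] result.
#' @param schedule A [frame_schedule()] (sets the scan end).
#' @param seed Integer seed for measurement noise.
#' @param manual_times Manual draw times (minutes).
#' @param auto_end End of the automatic sampling window (minutes).
#' @param pf_noise_sd,blood_noise_cv Noise settings (see [cohort_config()]).
#' @return An object of class `blood_dataset` (see [blood_dataset()]).
#' @export
generate_blood_dataset <- function(subject, schedule, seed = 1L,
                                   manual_times = c(2.5, 7, 12, 15, 20, 30,
                                                    45, 60, 90, 110),
                                   auto_end = 22,
                                   pf_noise_sd = 0.02,
                                   blood_noise_cv = 0) {
  scan_end <- schedule$end[schedule$n]
  manual_times <- manual_times[manual_times <= scan_end]
  grid <- fine_time_grid(auto_end, subject$grid_dt)
  wb <- true_wholeblood(subject, grid)
  meas <- apply_dispersion(wb, subject$grid_dt,
                           tau = subject$input_params$dispersion_tau,
                           delay = subject$input_params$delay)
  grid_all <- fine_time_grid(scan_end, subject$grid_dt)
  wb_manual <- stats::approx(grid_all, true_wholeblood(subject, grid_all),
                             xout = manual_times)$y
  plasma_manual <- wb_manual * subject$plasma_wb_ratio
  pf <- generate_parent_fraction(subject$hill, manual_times)
  with_seed(seed, {
    if (blood_noise_cv > 0) {
      meas <- pmax(meas * (1 + stats::rnorm(length(meas), 0, blood_noise_cv)), 0)
      wb_manual <- pmax(wb_manual * (1 + stats::rnorm(length(wb_manual), 0, blood_noise_cv)), 0)
      plasma_manual <- pmax(plasma_manual * (1 + stats::rnorm(length(plasma_manual), 0, blood_noise_cv)), 0)
    }
    if (pf_noise_sd > 0)
      pf <- pmin(pmax(pf + stats::rnorm(length(pf), 0, pf_noise_sd), 0), 1)
  })
  blood_dataset(auto_times = grid, auto_wholeblood = meas,
                manual_times = manual_times, manual_wholeblood = wb_manual,
                manual_plasma = plasma_manual,
                pf_times = manual_times, pf_values = pf)
}

#' Generate a synthetic cohort
#'
#' Draws `n_hc` control and `n_pd` patient subjects, generates every
#' subject's regional and reference TACs (noisy at the configured scale) and
#' blood dataset. Per-subject seeds are derived from the master seed, so the
#' cohort is reproducible bitwise.
#'
#' @param n_hc,n_pd Group sizes, both >= 1.
#' @param schedule A [frame_schedule()]; default [default_frame_schedule()].
#' @param config A [cohort_config()].
#' @param seed Master integer seed.
#' @return An object of class `synthetic_cohort`: `subjects` (list of
#'   [generate_subject()] results), `schedule`, `tacs` (per subject: matrix
#'   frames x regions plus a `ref` column), and `blood` (per subject).
#' @export
generate_cohort <- function(n_hc, n_pd, schedule = default_frame_schedule(),
                            config = cohort_config(), seed = 1L) {
  if (n_hc < 1 || n_pd < 1) stop("n_hc and n_pd must be >= 1")
  n <- n_hc + n_pd
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 3L * n))
  groups <- c(rep("hc", n_hc), rep("pd", n_pd))
  ids <- sprintf("%s%02d", groups, c(seq_len(n_hc), seq_len(n_pd)))
  subjects <- vector("list", n)
  tacs <- vector("list", n)
  blood <- vector("list", n)
  for (i in seq_len(n)) {
    s <- generate_subject(ids[i], groups[i], config, seed = sub_seeds[i])
    grid <- fine_time_grid(schedule$end[schedule$n], config$grid_dt)
    input <- list(times = grid,
                  values = generate_input_function(s$input_params, grid) *
                    generate_parent_fraction(s$hill, grid))
    nm <- config$n_rois
    mat <- matrix(0, schedule$n, nm + 1L,
                  dimnames = list(NULL, c(names(s$region_K1), "ref")))
    noise_seeds <- with_seed(sub_seeds[n + i],
                             sample.int(.Machine$integer.max - 1L, nm + 1L))
    for (j in seq_len(nm)) {
      tj <- generate_tissue_tac(input, s$region_K1[j], s$region_k2[j],
                                schedule, names(s$region_K1)[j])
      mat[, j] <- add_noise(tj, noise_model(config$noise_scale,
                                            seed = noise_seeds[j]))$values
    }
    tref <- generate_tissue_tac(input, s$ref_K1, s$ref_k2, schedule, "ref")
    mat[, nm + 1L] <- add_noise(tref, noise_model(config$noise_scale,
                                                  seed = noise_seeds[nm + 1L]))$values
    subjects[[i]] <- s
    tacs[[i]] <- mat
    blood[[i]] <- generate_blood_dataset(s, schedule, seed = sub_seeds[2L * n + i],
                                         pf_noise_sd = config$pf_noise_sd,
                                         blood_noise_cv = config$blood_noise_cv)
  }
  names(subjects) <- names(tacs) <- names(blood) <- ids
  structure(list(subjects = subjects, schedule = schedule, tacs = tacs,
                 blood = blood, config = config, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  gr <- vapply(x$subjects, `[[`, "", "group")
  cat("<synthetic_cohort> ", sum(gr == "hc"), " HC + ", sum(gr == "pd"),
      " PD subjects, ", x$schedule$n, " frames, ",
      ncol(x$tacs[[1]]) - 1L, " target regions + reference\n", sep = "")
  invisible(x)
}

#' Generate a small 4D dynamic image for a subject
#'
#' Every voxel's TAC equals its region's noiseless TAC (from the subject's
#' generating kinetics) plus optional voxel-level count noise; background
#' voxels are zero.
#'
#' @param subject A [generate_subject()] result.
#' @param schedule A [frame_schedule()].
#' @param label_map Integer 3D array; 0 = background, `r` = index into the
#'   subject's regions, `length(subject$region_K1) + 1` = reference region.
#' @param noise_scale Voxel-level noise scale (0 = noiseless).
#' @param seed Integer seed for voxel noise.
#' @return List with `img` (4D array x,y,z,frame), `label_map`, `schedule`.
#' @export
generate_dynamic_image <- function(subject, schedule, label_map,
                                   noise_scale = 0, seed = 1L) {
  if (!is.array(label_map) || length(dim(label_map)) != 3)
    stop("label_map must be a 3D integer array")
  nroi <- length(subject$region_K1)
  labs <- sort(unique(as.integer(label_map)))
  if (any(labs < 0 | labs > nroi + 1L))
    stop("label_map contains ids outside 0..", nroi + 1L)
  grid <- fine_time_grid(schedule$end[schedule$n], subject$grid_dt)
  input <- list(times = grid,
                values = generate_input_function(subject$input_params, grid) *
                  generate_parent_fraction(subject$hill, grid))
  curves <- matrix(0, schedule$n, nroi + 2L)  # col 1 = background
  for (r in seq_len(nroi))
    curves[, r + 1L] <- generate_tissue_tac(input, subject$region_K1[r],
                                            subject$region_k2[r], schedule)$values
  curves[, nroi + 2L] <- generate_tissue_tac(input, subject$ref_K1,
                                             subject$ref_k2, schedule)$values
  dm <- dim(label_map)
  nv <- prod(dm)
  img <- t(curves[, as.integer(label_map) + 1L, drop = FALSE])  # nv x frames
  if (noise_scale > 0) {
    d <- decay_factor(schedule, 109.77)
    sdm <- noise_scale * sqrt(pmax(img, 0) /
                                matrix(schedule$dur * d, nv, schedule$n, byrow = TRUE))
    img <- with_seed(seed, pmax(img + stats::rnorm(length(img), 0, as.numeric(sdm)), 0))
    img[as.integer(label_map) == 0L, ] <- 0
  }
  list(img = array(img, c(dm, schedule$n)), label_map = label_map,
       schedule = schedule)
}
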