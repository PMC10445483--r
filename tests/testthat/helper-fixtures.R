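# Shared fixtures, built once per test run and cached. The "oracle subject"
# is a fully deterministic noiseless subject with reference kinetics
# k2 = 0.037 1/min and V_T = 3.5 mL/cm3 and 28 target regions whose true
# BP_ND spans 0.5-4.5 at a fixed influx ratio R1 = 2; every model fit can be
# checked against these generating values.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = fixture_cache)) assign(key, build(), fixture_cache)
  get(key, envir = fixture_cache)
}

oracle_subject <- function(n_rois = 28) {
  cached(paste0("oracle", n_rois), function() {
    sched <- default_frame_schedule()
    params <- input_function_params()
    hill <- hill_params()
    grid <- fine_time_grid(120)
    aif_vals <- generate_input_function(params, grid) *
      generate_parent_fraction(hill, grid)
    aif <- build_input_function(list(times = grid, values = aif_vals),
                                hill_params(1, 1, 1))  # pf = 1: pass-through
    aif$activity <- aif_vals
    input <- list(times = grid, values = aif_vals)
    ref_k2 <- 0.037; ref_vt <- 3.5
    ref_K1 <- ref_vt * ref_k2
    bp <- seq(0.5, 4.5, length.out = n_rois)
    K1 <- rep(2 * ref_K1, n_rois)
    k2 <- K1 / (ref_vt * (1 + bp))
    names(bp) <- names(K1) <- names(k2) <- sprintf("roi%02d", seq_len(n_rois))
    ref_tac <- generate_tissue_tac(input, ref_K1, ref_k2, sched, "ref")
    target <- vapply(seq_len(n_rois), function(j)
      generate_tissue_tac(input, K1[j], k2[j], sched, names(bp)[j])$values,
      numeric(sched$n))
    colnames(target) <- names(bp)
    list(schedule = sched, input = input, aif = aif, ref_tac = ref_tac,
         target = target, true_bp = bp, K1 = K1, k2 = k2,
         ref_K1 = ref_K1, ref_k2 = ref_k2, ref_vt = ref_vt)
  })
}

oracle_target_tacs <- function(n_rois = 28) {
  ors <- oracle_subject(n_rois)
  lapply(colnames(ors$target), function(r)
    tac(ors$schedule, ors$target[, r], r))
}

oracle_subject_data <- function(n_rois = 28) {
  ors <- oracle_subject(n_rois)
  subject_data("oracle", "hc", ors$schedule, ors$target,
               ors$ref_tac$values, ors$aif)
}

# Small cohort reused across pipeline-level tests.
small_cohort <- function() {
  cached("small_cohort", function() generate_cohort(2, 2, seed = 42))
}
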