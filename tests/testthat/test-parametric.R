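test_that("basis set construction matches the SRTM2 convolution term", {
  ors <- oracle_subject(6)
  basis <- build_basis(ors$ref_tac, 0.037, n_basis = 30)
  expect_equal(basis$k2a_grid[1], 0.006)
  expect_equal(basis$k2a_grid[30], 0.6)
  # each basis column equals the frame-averaged convolution of the
  # (interpolated) reference with exp(-k2a t), i.e. a unit-K1 tissue TAC
  ctxgrid <- fine_time_grid(120)
  ref_fine <- refkin:::interp_tac_fine(ors$ref_tac$values, ors$schedule,
                                       ctxgrid)
  for (j in c(1, 15, 30)) {
    want <- generate_tissue_tac(list(times = ctxgrid, values = ref_fine),
                                1, basis$k2a_grid[j], ors$schedule)$values
    expect_equal(basis$conv[, j], want, tolerance = 1e-10)
  }
  expect_error(build_basis(ors$ref_tac, 0.037, k2a_bounds = c(0.1, 0.1)),
               "bounds")
  expect_error(build_basis(ors$ref_tac, 0.037, n_basis = 5), "n_basis")
})

test_that("voxelwise SRTM2 equals the ROI fit on a homogeneous phantom", {
  ors <- oracle_subject(6)
  sched <- ors$schedule
  tar <- tac(sched, ors$target[, 4], "roi04")
  img <- array(rep(tar$values, each = 8 * 8 * 4), c(8, 8, 4, sched$n))
  basis <- build_basis(ors$ref_tac, 0.037)
  w <- compute_frame_weights(tar)
  map <- fit_srtm2_voxelwise(img, basis, weights = w)
  roi_fit <- fit_srtm2(tar, ors$ref_tac, 0.037, weights = w)
  expect_lt(max(abs(map$bpnd_map / roi_fit$BP_ND - 1), na.rm = TRUE), 0.01)
  expect_equal(sum(map$mask), 8 * 8 * 4)

  # voxel equal to the reference: BP ~ 0, R1 ~ 1
  img_ref <- array(rep(ors$ref_tac$values, each = 4), c(2, 2, 1, sched$n))
  map_ref <- fit_srtm2_voxelwise(img_ref, basis)
  expect_lt(max(abs(map_ref$bpnd_map)), 0.01)
  expect_lt(max(abs(map_ref$r1_map - 1)), 0.01)

  expect_error(fit_srtm2_voxelwise(img, basis,
                                   mask = array(FALSE, c(8, 8, 4))),
               "empty mask")
})

test_that("grid quantization error shrinks as the basis densifies", {
  ors <- oracle_subject(6)
  sched <- ors$schedule
  tar <- tac(sched, ors$target[, 6], "roi06")
  img <- array(tar$values, c(1, 1, 1, sched$n))
  w <- compute_frame_weights(tar)
  roi_fit <- fit_srtm2(tar, ors$ref_tac, 0.037, weights = w)
  err <- vapply(c(25, 200), function(nb) {
    basis <- build_basis(ors$ref_tac, 0.037, n_basis = nb)
    map <- fit_srtm2_voxelwise(img, basis, weights = w, refine = FALSE)
    abs(map$bpnd_map[1, 1, 1] - roi_fit$BP_ND)
  }, 0)
  # an 8x denser grid should cut the quantization error several-fold
  expect_lt(err[2], err[1] / 2)
  # and the parabolic refinement reaches the ROI fit within 1%
  basis <- build_basis(ors$ref_tac, 0.037)
  mapr <- fit_srtm2_voxelwise(img, basis, weights = w, refine = TRUE)
  expect_lt(abs(mapr$bpnd_map[1, 1, 1] / roi_fit$BP_ND - 1), 0.01)
})

test_that("parametric ROI means aggregate voxels correctly", {
  ors <- oracle_subject(6)
  sched <- ors$schedule
  lab <- array(0L, c(4, 4, 1))
  lab[1, 1, 1] <- 1L          # single-voxel region
  lab[2:3, , 1] <- 2L         # 8-voxel region
  img <- array(0, c(4, 4, 1, sched$n))
  for (i in 1:4) for (j in 1:4)
    img[i, j, 1, ] <- if (lab[i, j, 1] > 0) ors$target[, lab[i, j, 1]] else 0
  basis <- build_basis(ors$ref_tac, 0.037)
  map <- fit_srtm2_voxelwise(img, basis, mask = lab > 0)
  means <- extract_parametric_roi_means(map, lab)
  expect_equal(unname(means["1"]), map$bpnd_map[1, 1, 1])
  expect_equal(unname(means["2"]), mean(map$bpnd_map[2:3, , 1]))

  # checkerboard of two values averages by voxel count
  map2 <- map
  map2$bpnd_map[2:3, , 1] <- rep(c(1, 3), 4)
  expect_equal(unname(extract_parametric_roi_means(map2, lab)["2"]), 2)

  lab2 <- lab
  lab2[4, 4, 1] <- 9L  # region entirely outside the mask
  expect_warning(m3 <- extract_parametric_roi_means(map, lab2), "no in-mask")
  expect_true(is.na(m3["9"]))
})

test_that("dynamic image generator puts region TACs in voxels", {
  s <- generate_subject("s1", "hc", seed = 12)
  sched <- default_frame_schedule()
  lab <- array(0L, c(6, 6, 2))
  lab[2:5, 2:5, ] <- 3L
  out <- generate_dynamic_image(s, sched, lab)
  grid <- fine_time_grid(120)
  input <- list(times = grid,
                values = generate_input_function(s$input_params, grid) *
                  generate_parent_fraction(s$hill, grid))
  want <- generate_tissue_tac(input, s$region_K1[3], s$region_k2[3], sched)$values
  expect_equal(out$img[3, 3, 1, ], want)
  expect_equal(out$img[1, 1, 1, ], numeric(sched$n))

  # law of large numbers: ROI mean of noisy voxels approaches the clean TAC
  lab2 <- array(1L, c(10, 10, 6))   # 600 voxels
  noisy <- generate_dynamic_image(s, sched, lab2, noise_scale = 0.05, seed = 4)
  want1 <- generate_tissue_tac(input, s$region_K1[1], s$region_k2[1], sched)$values
  got <- apply(matrix(noisy$img, 600, sched$n), 2, mean)
  late <- sched$mid > 5
  expect_lt(max(abs(got[late] / want1[late] - 1)), 0.01)

  expect_error(generate_dynamic_image(s, sched, array(99L, c(2, 2, 1))),
               "outside")
})
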