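# Voxelwise SRTM2 by basis functions: the model R1 [C_R + (k2' - k2a) B(k2a)]
# is linear in R1 once k2a is on a grid, so each voxel reduces to a weighted
# linear solve per basis curve plus a discrete minimum over the grid, with an
# optional 3-point parabolic refinement in log(k2a).

#' Precompute an SRTM2 basis set from a reference TAC
#'
#' For each of `n_basis` log-spaced `k2a` values in `k2a_bounds`,
#' precomputes the frame-averaged convolution `C_R (x) exp(-k2a t)`.
#'
#' @param reference Reference [tac()].
#' @param k2_prime Fixed reference efflux constant (1/min).
#' @param k2a_bounds Grid bounds (1/min), both positive, low < high; the
#'   default covers BP_ND in about (-0.5, 20) at k2' = 0.037.
#' @param n_basis Number of grid points (>= 20).
#' @param dt Fine-grid step (minutes).
#' @return List of class `basis_set`: `k2a_grid`, `conv` (frames x n_basis
#'   matrix of convolution terms), `ref_frames`, `k2_prime`, `schedule`.
#' @export
build_basis <- function(reference, k2_prime, k2a_bounds = c(0.006, 0.6),
                        n_basis = 100, dt = 1 / 60) {
  stopifnot(inherits(reference, "tac"))
  if (any(k2a_bounds <= 0) || k2a_bounds[1] >= k2a_bounds[2])
    stop("k2a_bounds must be positive with low < high")
  if (n_basis < 20) stop("n_basis must be >= 20")
  if (k2_prime <= 0) stop("k2_prime must be > 0")
  ctx <- srtm_context(reference, dt)
  grid <- exp(seq(log(k2a_bounds[1]), log(k2a_bounds[2]),
                  length.out = n_basis))
  conv <- vapply(grid, function(k2a) srtm_conv_term(ctx, k2a),
                 numeric(reference$schedule$n))
  structure(list(k2a_grid = grid, conv = conv,
                 ref_frames = reference$values, k2_prime = k2_prime,
                 schedule = reference$schedule),
            class = "basis_set")
}

#' Voxelwise SRTM2 fit of a dynamic image
#'
#' For every in-mask voxel and every basis `k2a`, solves the weighted
#' two-parameter linear problem for `(R1 direct term, convolution
#' coefficient)` and keeps the grid `k2a` minimizing the weighted RSS;
#' `BP_ND = R1 k2'/k2a - 1`. With `refine = TRUE` (default) the discrete
#' minimum is polished by one parabolic interpolation of the WRSS profile in
#' `log(k2a)`, removing the grid-quantization error.
#'
#' @param img 4D activity array (x, y, z, frame) or a list with `img` as
#'   produced by [generate_dynamic_image()].
#' @param basis A [build_basis()] result matching the image's schedule.
#' @param weights Frame weights shared by all voxels (e.g. from the
#'   whole-brain mean TAC); default uniform.
#' @param mask Logical 3D array; default: voxels with any nonzero activity.
#' @param refine Parabolic refinement of `k2a` (default `TRUE`).
#' @return List of class `parametric_map`: `bpnd_map`, `r1_map`, `k2a_map`
#'   (3D arrays, `NA` outside the mask), `mask`, `k2_prime`, `n_clamped`
#'   (voxels whose BP_ND hit the sanity bounds (-0.9, 30]).
#' @export
fit_srtm2_voxelwise <- function(img, basis, weights = NULL, mask = NULL,
                                refine = TRUE) {
  if (is.list(img)) img <- img$img
  stopifnot(is.array(img), length(dim(img)) == 4)
  dm <- dim(img)
  nf <- dm[4]
  if (nf != basis$schedule$n)
    stop("image frame count does not match the basis schedule")
  if (is.null(weights)) weights <- rep(1, nf)
  Y <- matrix(img, prod(dm[1:3]), nf)  # voxels x frames
  if (is.null(mask)) mask <- array(rowSums(Y) > 0, dm[1:3])
  vox <- which(as.logical(mask))
  if (!length(vox)) stop("empty mask")
  Yv <- t(Y[vox, , drop = FALSE])      # frames x voxels
  w <- weights
  nb <- length(basis$k2a_grid)
  nv <- length(vox)
  wrss <- matrix(Inf, nb, nv)
  th1 <- matrix(0, nb, nv)  # R1 (direct-term coefficient)
  th2 <- matrix(0, nb, nv)  # convolution coefficient R1 (k2' - k2a)
  wY <- Yv * w
  swy2 <- colSums(Yv^2 * w)
  for (j in seq_len(nb)) {
    A <- cbind(basis$ref_frames, basis$conv[, j])
    AtWA <- crossprod(A * w, A)
    det <- AtWA[1, 1] * AtWA[2, 2] - AtWA[1, 2]^2
    if (det <= 0) next
    AtWY <- crossprod(A, wY)           # 2 x nv
    th1[j, ] <- (AtWA[2, 2] * AtWY[1, ] - AtWA[1, 2] * AtWY[2, ]) / det
    th2[j, ] <- (AtWA[1, 1] * AtWY[2, ] - AtWA[1, 2] * AtWY[1, ]) / det
    wrss[j, ] <- swy2 - (th1[j, ] * AtWY[1, ] + th2[j, ] * AtWY[2, ])
  }
  jbest <- max.col(-t(wrss), ties.method = "first")
  pick <- cbind(jbest, seq_len(nv))
  k2a <- basis$k2a_grid[jbest]
  R1 <- th1[pick]
  cf2 <- th2[pick]
  if (refine) {
    lg <- log(basis$k2a_grid)
    inner <- jbest > 1 & jbest < nb
    if (any(inner)) {
      ref_ctx <- srtm_context(tac(basis$schedule, basis$ref_frames, "ref"))
      i <- jbest[inner]; v <- which(inner)
      f0 <- wrss[cbind(i, v)]
      fm <- wrss[cbind(i - 1L, v)]
      fp <- wrss[cbind(i + 1L, v)]
      denom <- fm - 2 * f0 + fp
      ok <- is.finite(denom) & denom > 0
      step <- ifelse(ok, 0.5 * (fm - fp) / denom, 0)
      step <- pmax(pmin(step, 1), -1)
      h <- (lg[pmin(i + 1L, nb)] - lg[pmax(i - 1L, 1L)]) / 2
      k2a[v] <- exp(lg[i] + step * h)
      # re-solve R1 at the refined k2a; one convolution per unique value
      refv <- v[ok & abs(step) > 1e-12]
      for (u in unique(k2a[refv])) {
        vv <- refv[k2a[refv] == u]
        ctxA <- cbind(basis$ref_frames, srtm_conv_term(ref_ctx, u))
        AtWA <- crossprod(ctxA * w, ctxA)
        det <- AtWA[1, 1] * AtWA[2, 2] - AtWA[1, 2]^2
        if (det <= 0) next
        AtWY <- crossprod(ctxA, Yv[, vv, drop = FALSE] * w)
        R1[vv] <- (AtWA[2, 2] * AtWY[1, ] - AtWA[1, 2] * AtWY[2, ]) / det
        cf2[vv] <- (AtWA[1, 1] * AtWY[2, ] - AtWA[1, 2] * AtWY[1, ]) / det
      }
    }
  }
  # derive the apparent efflux from the fitted coefficients: the model is
  # R1 C_R + R1 (k2' - k2a) B, so k2a = k2' - cf2/R1; this stays exact at
  # the optimum and remains well-defined for voxels indistinguishable from
  # the reference (cf2 = 0), where the grid k2a is arbitrary
  k2a <- ifelse(abs(R1) > 1e-6,
                pmin(pmax(basis$k2_prime - cf2 / R1, 1e-4), 2), k2a)
  bp <- R1 * basis$k2_prime / k2a - 1
  clamped <- bp < -0.9 | bp > 30
  bp[bp < -0.9] <- -0.9
  bp[bp > 30] <- 30
  tomap <- function(v) {
    m <- array(NA_real_, dm[1:3])
    m[vox] <- v
    m
  }
  structure(list(bpnd_map = tomap(bp), r1_map = tomap(R1),
                 k2a_map = tomap(k2a), mask = array(as.logical(mask), dm[1:3]),
                 k2_prime = basis$k2_prime, n_clamped = sum(clamped)),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  cat("<parametric_map> ", sum(x$mask), " voxels in mask, k2' = ",
      signif(x$k2_prime, 3), " 1/min, ", x$n_clamped, " clamped\n", sep = "")
  invisible(x)
}

#' Mean parametric BP_ND per region
#'
#' @param map A [fit_srtm2_voxelwise()] result.
#' @param label_map Integer 3D array of region ids (0 = background).
#' @return Named numeric vector of mean in-mask BP_ND per region id; regions
#'   with no in-mask voxels are `NA` with a warning.
#' @export
extract_parametric_roi_means <- function(map, label_map) {
  stopifnot(inherits(map, "parametric_map"))
  if (!identical(dim(label_map), dim(map$mask)))
    stop("label map does not match the parametric map dimensions")
  labs <- sort(setdiff(unique(as.integer(label_map)), 0L))
  out <- vapply(labs, function(l) {
    sel <- label_map == l & map$mask
    if (!any(sel)) return(NA_real_)
    mean(map$bpnd_map[sel])
  }, 0)
  names(out) <- as.character(labs)
  if (any(is.na(out)))
    warning("regions with no in-mask voxels: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  out
}
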