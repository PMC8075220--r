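#' Reconstruct a quantitative T1 map from an MP2RAGE acquisition
#'
#' Computes the denoised T1-weighted product, thresholds it at a fraction
#' of its robust maximum (99th percentile) to form the brain mask, and
#' inverts the UNI image through the lookup table voxelwise inside that
#' mask. Voxels outside the mask, or whose UNI falls outside the table's
#' monotone branch, are set to `NA` and flagged in the QC mask.
#'
#' @param inv2,uni [volume()]s on one grid: second-inversion image and UNI.
#' @param protocol An [mp2rage_protocol()]; used to build the lookup table
#'   when `lookup` is not supplied.
#' @param lookup Optional precomputed [build_lookup()] table.
#' @param mask_threshold Brain-mask threshold as a fraction of the robust
#'   maximum of the denoised T1-weighted product.
#' @return A list: `t1` (a [volume()] in seconds, `NA` where flagged),
#'   `qc_flagged` (logical array), `brain_mask` (logical array).
#' @export
reconstruct_t1_map <- function(inv2, uni, protocol = mp2rage_protocol(),
                               lookup = NULL, mask_threshold = 0.05) {
  check_same_grid(inv2, uni)
  if (is.null(lookup)) lookup <- build_lookup(protocol)
  t1w <- denoised_t1w(inv2, uni)
  dat <- abs(vol_data(t1w))
  rmax <- stats::quantile(dat, 0.99, names = FALSE)
  brain <- dat > mask_threshold * rmax
  if (rmax == 0) brain[] <- FALSE
  est <- t1_from_uni(vol_data(uni)[brain], lookup)
  shp <- dim(vol_data(uni))
  t1 <- array(NA_real_, dim = shp)
  t1[brain] <- ifelse(est$out_of_range, NA_real_, est$t1)
  flagged <- array(TRUE, dim = shp)
  flagged[brain] <- est$out_of_range
  list(t1 = volume(t1, vol_affine(uni), units = "s"),
       qc_flagged = flagged, brain_mask = brain)
}

#' Rigidly align the post-contrast volume to pre-contrast space
#'
#' `known_transform` mode applies the exact inverse of a supplied rigid
#' misalignment (as parameters or a 4x4 voxel-space matrix).
#' `estimate_rigid` mode recovers the transform by maximising normalised
#' cross-correlation over a multi-resolution pyramid: a coarse translation
#' search, then Nelder-Mead refinement of all six rigid parameters at each
#' level, with an integer-lattice polish of the translations.
#'
#' @param post,pre [volume()]s on one grid.
#' @param mode `"known_transform"` or `"estimate_rigid"`.
#' @param transform For `known_transform`: the applied misalignment, either
#'   length-6 parameters (translations vox, rotations deg) or a 4x4 matrix.
#' @param levels Pyramid downsampling factors, coarse to fine.
#' @return A list: `aligned` (post resampled into pre space), `matrix`
#'   (the 4x4 voxel-space resampling map), `parameters` (length 6, when
#'   estimated), `converged`.
#' @export
register_post_to_pre <- function(post, pre,
                                 mode = c("estimate_rigid", "known_transform"),
                                 transform = NULL, levels = c(4, 2, 1)) {
  mode <- match.arg(mode)
  check_same_grid(post, pre)
  shp <- dim(vol_data(post))
  if (mode == "known_transform") {
    if (is.null(transform)) stop("known_transform mode needs `transform`",
                                 call. = FALSE)
    m <- if (is.matrix(transform)) transform else
      rigid_matrix(transform[1:3], transform[4:6], shp)
    inv <- solve(m)
    return(list(aligned = resample_valid(post, inv), matrix = inv,
                parameters = NULL, converged = TRUE))
  }

  fixed <- vol_data(pre); moving <- vol_data(post)
  fixed[is.na(fixed)] <- 0; moving[is.na(moving)] <- 0
  # metric copies are lightly smoothed: matching blur on both sides damps
  # the interpolation-induced local NCC maxima near the voxel lattice
  fixed <- smooth3d(fixed); moving <- smooth3d(moving)
  par <- c(0, 0, 0, 0, 0, 0)
  for (f in levels) {
    fx <- downsample(fixed, f); mv <- downsample(moving, f)
    sshp <- dim(fx)
    objective <- function(p) {
      warp <- resample_volume(mv, rigid_matrix(p[1:3], p[4:6], sshp))
      -ncc(fx, warp)
    }
    p0 <- c(par[1:3] / f, par[4:6])
    if (f == levels[1]) {
      # coarse integer translation search seeds the optimiser
      rng <- -3:3
      best <- p0; bestv <- objective(p0)
      for (dx in rng) for (dy in rng) for (dz in rng) {
        cand <- c(dx, dy, dz, 0, 0, 0)
        v <- objective(cand)
        if (v < bestv) { bestv <- v; best <- cand }
      }
      p0 <- best
    }
    if (f == 1) {
      # subvoxel interpolation smoothing creates local NCC maxima near the
      # integer lattice; a coordinate-wise quarter-voxel scan steps over them
      for (pass in 1:2) for (ax in 1:3) {
        deltas <- seq(-1.5, 1.5, by = 0.25)
        vals <- vapply(deltas, function(d) {
          q <- p0; q[ax] <- q[ax] + d; objective(q)
        }, numeric(1))
        p0[ax] <- p0[ax] + deltas[which.min(vals)]
      }
    }
    # translation-first at every level: translations carry most of the
    # misalignment and are far better conditioned than the rotations
    topt <- stats::optim(p0[1:3], function(t) objective(c(t, p0[4:6])),
                         method = "Nelder-Mead",
                         control = list(maxit = 300, reltol = 1e-10))
    p0[1:3] <- topt$par
    opt <- stats::optim(p0, objective, method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-10))
    par <- c(opt$par[1:3] * f, opt$par[4:6])
  }
  final_obj <- function(p) -ncc(fixed, resample_volume(moving,
                                                       rigid_matrix(p[1:3], p[4:6], shp)))
  # polish, preferring the simplest transform among near-ties: integer
  # translations reproduce same-grid voxels exactly, and near-symmetric
  # anatomy leaves the rotations weakly constrained, so zeroed rotations
  # and rounded translations are tested against the optimised solution
  cands <- list(c(round(par[1:3]), 0, 0, 0), c(par[1:3], 0, 0, 0),
                c(round(par[1:3]), par[4:6]), par)
  vals <- vapply(cands, final_obj, numeric(1))
  par <- cands[[which(vals <= min(vals) + 1e-7)[1]]]
  # success is judged by the achieved similarity, not the optimiser's
  # iteration-count flag: same-modality volumes align to high NCC
  ok <- -min(vals) >= 0.8
  if (!ok) {
    warning("rigid registration did not converge; returning identity")
    par <- rep(0, 6)
  }
  m <- rigid_matrix(par[1:3], par[4:6], shp)
  list(aligned = resample_valid(post, m), matrix = m, parameters = par,
       converged = ok)
}

# resample a volume while propagating missingness: output voxels whose
# interpolation stencil touches an NA or out-of-grid sample become NA
resample_valid <- function(vol, matrix) {
  dat <- vol_data(vol)
  valid <- array(as.numeric(!is.na(dat)), dim = dim(dat))
  out <- resample_volume(vol, matrix, fill = 0)
  vmask <- resample_volume(valid, matrix, fill = 0)
  if (is_volume(out)) out$data[vmask < 1 - 1e-9] <- NA_real_ else
    out[vmask < 1 - 1e-9] <- NA_real_
  out
}

# separable 1-2-1 binomial smoothing with edge replication
smooth3d <- function(a) {
  shp <- dim(a)
  for (ax in 1:3) {
    n <- shp[ax]
    lo <- c(1, seq_len(n - 1)); hi <- c(seq_len(n - 1) + 1, n)
    a <- switch(ax,
                (a[lo, , , drop = FALSE] + 2 * a + a[hi, , , drop = FALSE]) / 4,
                (a[, lo, , drop = FALSE] + 2 * a + a[, hi, , drop = FALSE]) / 4,
                (a[, , lo, drop = FALSE] + 2 * a + a[, , hi, drop = FALSE]) / 4)
  }
  a
}

downsample <- function(arr, factor) {
  if (factor == 1) return(arr)
  shp <- dim(arr)
  idx <- lapply(shp, function(n) seq(1, n, by = factor))
  arr[idx[[1]], idx[[2]], idx[[3]]]
}

ncc <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

#' Subtract pre- from post-contrast T1 to form the delta-T1 map
#'
#' Voxelwise `post - pre` in seconds; negative values mean
#' gadolinium-induced shortening. Voxels flagged by either reconstruction's
#' QC mask (or `NA` in either input) are set to missing rather than
#' propagated.
#'
#' @param pre_t1,post_t1 T1 [volume()]s in seconds on one grid (post
#'   already aligned to pre space).
#' @param qc_pre,qc_post Optional logical arrays of flagged voxels.
#' @return A `delta_t1_map`: a [volume()] in seconds with attribute
#'   `provenance`.
#' @export
compute_delta_t1 <- function(pre_t1, post_t1, qc_pre = NULL, qc_post = NULL) {
  check_same_grid(pre_t1, post_t1)
  if (is_volume(pre_t1) && is_volume(post_t1) &&
      !identical(pre_t1$units, post_t1$units))
    stop("unit mismatch between pre and post T1 maps", call. = FALSE)
  d <- vol_data(post_t1) - vol_data(pre_t1)
  if (!is.null(qc_pre)) d[qc_pre] <- NA_real_
  if (!is.null(qc_post)) d[qc_post] <- NA_real_
  out <- volume(d, vol_affine(pre_t1), units = "s")
  attr(out, "provenance") <- list(convention = "post - pre",
                                  computed = format(Sys.time(), "%Y-%m-%d"))
  class(out) <- c("delta_t1_map", class(out))
  out
}
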