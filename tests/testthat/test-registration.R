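# smooth synthetic volume for transform-recovery checks: random Gaussian
# blobs give the NCC metric texture without tissue-boundary staircases
smooth_blob_volume <- function(shape = c(48, 48, 48), n_blobs = 12, seed = 9) {
  set.seed(seed)
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  dat <- numeric(nrow(g))
  for (i in seq_len(n_blobs)) {
    c0 <- runif(3, shape * 0.25, shape * 0.75)
    w <- runif(1, 3, 7)
    dat <- dat + runif(1, 0.5, 2) *
      exp(-((g$x - c0[1])^2 + (g$y - c0[2])^2 + (g$z - c0[3])^2) / (2 * w^2))
  }
  volume(array(dat, shape))
}

test_that("known_transform mode applies the exact inverse", {
  v <- smooth_blob_volume()
  mis <- c(2, -1, 3, 0, 0, 0)
  moved <- resample_volume(v, rigid_matrix(mis[1:3], mis[4:6], dim(v$data)))
  reg <- register_post_to_pre(moved, v, mode = "known_transform",
                              transform = mis)
  inner <- array(FALSE, dim(v$data)); inner[9:40, 9:40, 9:40] <- TRUE
  keep <- inner & !is.na(reg$aligned$data)
  expect_gt(sum(keep), 1e4)
  expect_lt(max(abs(reg$aligned$data[keep] - v$data[keep])), 1e-10)
})

test_that("identity misalignment estimates to the identity transform", {
  v <- smooth_blob_volume()
  reg <- register_post_to_pre(v, v, mode = "estimate_rigid")
  expect_true(reg$converged)
  expect_equal(reg$parameters, rep(0, 6), tolerance = 1e-8)
  expect_equal(reg$aligned$data, v$data)
})

test_that("integer and subvoxel shifts are recovered on a smooth phantom", {
  v <- smooth_blob_volume()
  shp <- dim(v$data)
  # 2-voxel integer shift: recovered translation within 0.25 vox per axis
  mis <- c(2, 0, -1, 0, 0, 0)
  moved <- resample_volume(v, rigid_matrix(mis[1:3], mis[4:6], shp))
  reg <- register_post_to_pre(moved, v, mode = "estimate_rigid")
  expect_true(reg$converged)
  expect_lt(max(abs(reg$parameters[1:3] - c(-2, 0, 1))), 0.25)
  # subvoxel 0.5-voxel shift: within 0.2 vox
  mis2 <- c(0.5, 0, 0, 0, 0, 0)
  moved2 <- resample_volume(v, rigid_matrix(mis2[1:3], mis2[4:6], shp))
  reg2 <- register_post_to_pre(moved2, v, mode = "estimate_rigid")
  expect_lt(max(abs(reg2$parameters[1:3] - c(-0.5, 0, 0))), 0.2)
})

test_that("registered 2-voxel misalignment matches the aligned pipeline", {
  tol_factor <- 3
  aligned <- run_noiseless_pipeline(shape = c(48, 48, 48), seed = 3,
                                    el_fraction = 0)
  err_aligned <- abs(mask_median(aligned$delta, aligned$gt$masks$nel) + 0.134)

  mis <- c(2, 0, -1, 0, 0, 0)
  run <- run_noiseless_pipeline(shape = c(48, 48, 48), seed = 3,
                                el_fraction = 0, misalignment = mis)
  reg <- register_post_to_pre(run$rec_post$t1, run$rec_pre$t1,
                              mode = "estimate_rigid")
  expect_true(reg$converged)
  d <- compute_delta_t1(run$rec_pre$t1, reg$aligned,
                        qc_pre = run$rec_pre$qc_flagged,
                        qc_post = is.na(reg$aligned$data))
  err_reg <- abs(mask_median(d, run$gt$masks$nel) + 0.134)
  expect_lte(err_reg, max(tol_factor * err_aligned, 1e-12))
})
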