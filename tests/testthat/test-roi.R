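test_that("roi_metrics uses the stated conventions on a hand case", {
  m <- roi_metrics(c(1, 2, 3, 4, 5))
  expect_equal(m$mean, 3)
  expect_equal(m$median, 3)
  expect_equal(m$variance, 2.5)     # n-1 denominator
  expect_equal(m$iqr, 2)            # linear-interpolation quartiles
  expect_identical(m$n_voxels, 5L)
})

test_that("kurtosis follows the Pearson convention (normal = 3)", {
  set.seed(31)
  m <- roi_metrics(rnorm(1e5))
  expect_equal(m$kurtosis, 3.0, tolerance = 0.1 / 3)
  ex <- roi_metrics(rnorm(1e4), kurtosis_convention = "excess")
  expect_lt(abs(ex$kurtosis), 0.25)
  const <- roi_metrics(rep(2, 50))
  expect_equal(const$variance, 0)
  expect_true(is.na(const$kurtosis))
})

test_that("roi_metrics masks, drops missing voxels, is order-invariant", {
  shp <- c(10, 10, 10)
  dat <- array(rnorm(1000), shp)
  mask <- array(FALSE, shp); mask[1:5, , ] <- TRUE
  dat[1, 1, 1] <- NA
  m <- roi_metrics(volume(dat, units = "s"), mask, subject_id = "S1",
                   tissue = "NEL")
  expect_identical(m$n_voxels, 499L)
  set.seed(8)
  v <- rnorm(200)
  expect_equal(roi_metrics(v)[, -(1:2)], roi_metrics(sample(v))[, -(1:2)])
  expect_error(roi_metrics(array(NA_real_, shp), mask), "empty")
})

test_that("uniform zero-spread ROI gives exact median and zero IQR", {
  run <- run_noiseless_pipeline(shape = c(32, 32, 32), lesion_count = 2,
                                el_fraction = 0, seed = 6)
  m <- roi_metrics(run$gt$true_t1_post$data - run$gt$true_t1_pre$data,
                   run$gt$masks$nel)
  expect_equal(m$median, -0.134)
  expect_identical(m$iqr, 0)
})

test_that("pooled voxel values conserve counts and subject order", {
  mk <- function(n, id) {
    shp <- c(6, 6, 6)
    mask <- array(FALSE, shp); mask[seq_len(n)] <- TRUE
    list(subject_id = id, pre_t1 = array(rnorm(216, 1.9, 0.1), shp),
         delta_t1 = array(rnorm(216, -0.1, 0.05), shp),
         masks = list(nel = mask))
  }
  set.seed(12)
  pooled <- pooled_voxel_values(list(mk(10, "A"), mk(15, "B")), "nel")
  expect_identical(nrow(pooled), 25L)
  expect_identical(unique(pooled$subject), c("A", "B"))
  one <- pooled_voxel_values(list(mk(10, "A")), "nel")
  expect_identical(nrow(one), 10L)
  expect_error(pooled_voxel_values(list(), "nel"), "no subjects")
})

test_that("independently generated delta-T1 shows no pooled correlation", {
  set.seed(77)
  shp <- c(22, 22, 22)
  subj <- lapply(1:2, function(i) {
    mask <- array(TRUE, shp)
    list(pre_t1 = array(rnorm(prod(shp), 1.9, 0.15), shp),
         delta_t1 = array(rnorm(prod(shp), -0.13, 0.05), shp),
         masks = list(nel = mask))
  })
  pooled <- pooled_voxel_values(subj, "nel")
  expect_gt(nrow(pooled), 1e4)
  rho <- stats::cor(pooled$pre_t1, pooled$delta_t1, method = "spearman")
  expect_lt(abs(rho), 0.05)
})

test_that("KDE summary integrates to one and matches the normal density", {
  set.seed(5)
  k <- kde_summary(rnorm(1e4))
  dx <- diff(k$grid[1:2])
  expect_equal(sum(k$density) * dx, 1, tolerance = 1e-3)
  at0 <- k$density[which.min(abs(k$grid))]
  expect_equal(at0, 1 / sqrt(2 * pi), tolerance = 0.1)
  # two-point sample: symmetric about 0
  k2 <- kde_summary(c(-1, 1))
  expect_equal(k2$density[which.min(abs(k2$grid + 1))],
               k2$density[which.min(abs(k2$grid - 1))], tolerance = 1e-6)
  expect_error(kde_summary(rep(1, 10)), "distinct")
})
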