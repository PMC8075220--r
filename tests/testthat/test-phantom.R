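test_that("phantom lesions form the requested number of components", {
  cfg <- phantom_config(shape = c(64, 64, 64), lesion_count = 5,
                        lesion_radius_range = c(3, 3), seed = 1)
  gt <- build_phantom(cfg)
  expect_identical(count_components(gt$masks$wml), 5L)
})

test_that("phantom is deterministic and degenerate cases behave", {
  cfg <- phantom_config(shape = c(32, 32, 32), lesion_count = 3,
                        lesion_radius_range = c(2, 3), seed = 7)
  a <- build_phantom(cfg); b <- build_phantom(cfg)
  expect_identical(a$label, b$label)
  expect_identical(a$true_t1_pre$data, b$true_t1_pre$data)
  none <- build_phantom(phantom_config(shape = c(32, 32, 32), lesion_count = 0))
  expect_identical(sum(none$masks$wml), 0L)
  expect_identical(none$masks$nawm, none$masks$cerebral_wm)
})

test_that("mask invariants hold across seeded phantoms", {
  for (seed in 1:5) {
    gt <- build_phantom(phantom_config(shape = c(32, 32, 32), lesion_count = 3,
                                       lesion_radius_range = c(2, 3),
                                       el_fraction = 0.34, seed = seed))
    m <- gt$masks
    expect_true(all(m$wml[m$el]))               # EL subset of WML
    expect_identical(sum(m$nel) + sum(m$el), sum(m$wml))
    expect_false(any(m$nawm & m$wml))
    expect_false(any(m$wml & gt$label == 0L))   # masks disjoint from background
  }
})

test_that("gadolinium modes: direct arithmetic, relaxivity, and null dose", {
  gt <- build_phantom(phantom_config(shape = c(32, 32, 32), lesion_count = 2,
                                     lesion_radius_range = c(2, 3), seed = 2))
  gtd <- apply_gadolinium(gt, mode = "direct")
  dt <- gtd$true_t1_post$data - gtd$true_t1_pre$data
  expect_equal(unique(dt[gtd$masks$nel]), -0.134)
  expect_equal(stats::median(gtd$true_t1_post$data[gtd$masks$nel]), 1.778)

  tis <- tissue_spec()
  tis$r1 <- 2; tis$conc <- ifelse(tis$label %in% c("WML", "EL"), 0.05, 0)
  gtr <- apply_gadolinium(gt, tis, mode = "relaxivity")
  pre <- gtr$true_t1_pre$data[gtr$masks$nel][1]
  expect_equal(gtr$true_t1_post$data[gtr$masks$nel][1],
               1 / (1 / pre + 0.1))
  # zero concentration leaves T1 untouched
  tis0 <- tis; tis0$conc <- 0
  gt0 <- apply_gadolinium(gt, tis0, mode = "relaxivity")
  expect_equal(gt0$true_t1_post$data, gt0$true_t1_pre$data)
  # driving T1 below zero errors
  bad <- tissue_spec(nel_dt1 = -5)
  expect_error(apply_gadolinium(gt, bad, mode = "direct"), "t1_post")
})

test_that("noiseless acquisition equals the voxelwise forward model", {
  gt <- apply_gadolinium(build_phantom(phantom_config(
    shape = c(32, 32, 32), lesion_count = 2, lesion_radius_range = c(2, 3),
    seed = 3)))
  p <- study_protocol()
  acq <- simulate_acquisition(gt, p, phase = "pre")
  idx <- which(gt$label > 0)[seq(1, 8000, by = 397)]
  ref <- simulate_signals(p, gt$true_t1_pre$data[idx])
  expect_equal(acq$inv2$data[idx], ref$s2)
  expect_equal(acq$uni$data[idx], uni_from_signals(ref))
  # a constant-1 B1 field is the same as none
  cfgb <- gt$config; cfgb$b1_field <- c(1, 1)
  acqb <- simulate_acquisition(gt, p, config = cfgb, phase = "pre")
  expect_identical(acqb$uni$data, acq$uni$data)
})

test_that("background magnitude noise has the Rayleigh mean", {
  cfg <- phantom_config(shape = c(48, 48, 48), lesion_count = 0, seed = 5,
                        noise_sigma = 0.02)
  gt <- build_phantom(cfg)
  acq <- simulate_acquisition(gt, study_protocol(), phase = "pre")
  bg <- acq$inv2$data[gt$label == 0L]
  expect_gt(length(bg), 1e4)
  expect_equal(mean(bg), 0.02 * sqrt(pi / 2), tolerance = 0.02)
})

test_that("a B1 gradient biases T1 estimates away from the nominal-field case", {
  cfg <- phantom_config(shape = c(32, 32, 32), lesion_count = 0, seed = 5,
                        b1_field = c(0.8, 1.2))
  gt <- build_phantom(cfg)
  p <- study_protocol()
  acq <- simulate_acquisition(gt, p, phase = "pre")
  rec <- reconstruct_t1_map(acq$inv2, acq$uni, p)
  vals <- rec$t1$data[gt$masks$nawm]
  expect_gt(stats::sd(vals, na.rm = TRUE), 0.005)  # spatial bias, not constant
})

test_that("cohort composition, orderings and determinism", {
  coh <- simulate_cohort(cohort_spec(n_subjects = 47, seed = 11))
  expect_identical(unname(table(coh$phenotype)["RRMS"]), 34L)
  expect_identical(unname(table(coh$phenotype)["PMS"]), 13L)
  coh2 <- simulate_cohort(cohort_spec(n_subjects = 47, seed = 11))
  expect_identical(coh, coh2)

  big <- simulate_cohort(cohort_spec(n_subjects = 200, seed = 7))
  med <- function(g) stats::median(big$nel_delta_t1[g])
  expect_lt(med(big$phenotype == "PMS"), med(big$phenotype == "RRMS"))
  expect_lt(med(!big$treated), med(big$treated))
  expect_lt(med(big$edss_group == ">median"), med(big$edss_group == "<=median"))
})
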