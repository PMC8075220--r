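#' Tissue specification table
#'
#' One row per tissue compartment with pre-contrast T1 and the
#' gadolinium-induced T1 change. Defaults are the cohort-median values of
#' the 7T study: NAWM 1.300 s, cortical GM 1.898 s, non-enhancing lesions
#' 1.912 s, enhancing lesions 2.430 s (CSF set to 4.3 s, a typical 7T
#' value), with median delta-T1 of -0.004, -0.096, -0.134 and -1.100 s
#' respectively and no change in CSF. `spread` columns are per-voxel
#' standard deviations (seconds); the study-condition defaults are zero so
#' that ground truth is exactly the configured medians.
#'
#' Alternatively a relaxivity model can be used per tissue: `r1` (1/s/mM)
#' and `conc` (mM) define `1/t1_post = 1/t1_pre + r1 * conc`.
#'
#' @param nawm_t1,cgm_t1,csf_t1,nel_t1,el_t1 Pre-contrast T1 centres, s.
#' @param nawm_dt1,cgm_dt1,csf_dt1,nel_dt1,el_dt1 Delta-T1 centres, s.
#' @param t1_spread,dt1_spread Per-voxel SDs applied to every tissue, s.
#' @return A tibble with class `tissue_spec`, one row per tissue label.
#' @export
tissue_spec <- function(nawm_t1 = 1.300, cgm_t1 = 1.898, csf_t1 = 4.3,
                        nel_t1 = 1.912, el_t1 = 2.430,
                        nawm_dt1 = -0.004, cgm_dt1 = -0.096, csf_dt1 = 0,
                        nel_dt1 = -0.134, el_dt1 = -1.100,
                        t1_spread = 0, dt1_spread = 0) {
  tb <- tibble::tibble(
    label = c("NAWM", "cGM", "CSF", "WML", "EL"),
    t1_pre_center = c(nawm_t1, cgm_t1, csf_t1, nel_t1, el_t1),
    t1_pre_spread = t1_spread,
    delta_t1_center = c(nawm_dt1, cgm_dt1, csf_dt1, nel_dt1, el_dt1),
    delta_t1_spread = dt1_spread,
    r1 = NA_real_, conc = NA_real_)
  if (any(tb$t1_pre_center <= 0)) stop("t1_pre_center must be > 0", call. = FALSE)
  class(tb) <- c("tissue_spec", class(tb))
  tb
}

#' Phantom configuration
#'
#' Geometry, lesion load, noise and acquisition-degradation settings for
#' the digital brain phantom: a concentric-shell head (CSF rim, cortical-GM
#' ribbon, WM core) carrying non-overlapping spherical lesions, a subset of
#' which enhance.
#'
#' @param shape Grid size, length-3 (voxels).
#' @param voxel_size Isotropic-equivalent voxel edge lengths, mm.
#' @param lesion_count Number of lesions placed in the WM core.
#' @param lesion_radius_range Min/max lesion radius, voxels.
#' @param el_fraction Fraction of lesions that enhance, in \[0, 1\].
#' @param seed Integer seed; the phantom is deterministic given it.
#' @param noise_sigma Rician noise scale on the GRE magnitudes, as a
#'   fraction of `m0` (0 = noiseless).
#' @param b1_field `NULL` for a uniform transmit field, or `c(min, max)`
#'   for a linear left-right gradient of flip-angle scaling.
#' @param misalignment `NULL`, or length-6 rigid parameters
#'   (3 translations in voxels, 3 rotations in degrees) applied to the
#'   post-contrast acquisition.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(64, 64, 64), voxel_size = c(0.7, 0.688, 0.688),
                           lesion_count = 6, lesion_radius_range = c(3, 5),
                           el_fraction = 0, seed = 1L, noise_sigma = 0,
                           b1_field = NULL, misalignment = NULL) {
  stopifnot(length(shape) == 3, all(shape >= 16))
  if (el_fraction < 0 || el_fraction > 1) stop("el_fraction must be in [0,1]",
                                               call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (!is.null(misalignment) && length(misalignment) != 6)
    stop("misalignment must be NULL or length 6", call. = FALSE)
  structure(list(shape = as.integer(shape), voxel_size = voxel_size,
                 lesion_count = as.integer(lesion_count),
                 lesion_radius_range = lesion_radius_range,
                 el_fraction = el_fraction, seed = as.integer(seed),
                 noise_sigma = noise_sigma, b1_field = b1_field,
                 misalignment = misalignment),
            class = "phantom_config")
}

# run code under a local RNG stream without disturbing the global state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Build the digital brain phantom
#'
#' Deterministic (given `config$seed`) concentric-shell head with spherical
#' white-matter lesions. Returns ground truth for every downstream stage:
#' the label volume, true pre-contrast T1 field, tissue masks and the m0
#' field (1 inside the head, 0 background).
#'
#' Label codes: 0 background, 1 NAWM (WM core outside lesions), 2 cGM,
#' 3 CSF, 4 non-enhancing lesion, 5 enhancing lesion.
#'
#' @param config A [phantom_config()].
#' @param tissues A [tissue_spec()] table.
#' @return A `ground_truth` list: `label`, `true_t1_pre` ([volume()]),
#'   `m0`, `masks` (a `mask_set`), `config`, `tissues`.
#' @examples
#' gt <- build_phantom(phantom_config(shape = c(32, 32, 32), lesion_count = 2))
#' sum(gt$masks$wml) > 0
#' @export
build_phantom <- function(config = phantom_config(), tissues = tissue_spec()) {
  stopifnot(inherits(config, "phantom_config"))
  shp <- config$shape
  g <- expand.grid(x = seq_len(shp[1]), y = seq_len(shp[2]), z = seq_len(shp[3]))
  ctr <- (shp + 1) / 2
  # normalised ellipsoidal radius so the head fills the grid regardless of shape
  rn <- sqrt(((g$x - ctr[1]) / (shp[1] / 2))^2 +
             ((g$y - ctr[2]) / (shp[2] / 2))^2 +
             ((g$z - ctr[3]) / (shp[3] / 2))^2)
  label <- integer(nrow(g))
  label[rn <= 0.92] <- 3L  # CSF rim
  label[rn <= 0.78] <- 2L  # cortical GM ribbon
  label[rn <= 0.60] <- 1L  # WM core
  label <- array(label, dim = shp)

  lesions <- list()
  if (config$lesion_count > 0) {
    wm_idx <- which(label == 1L, arr.ind = TRUE)
    rmin <- config$lesion_radius_range[1]; rmax <- config$lesion_radius_range[2]
    with_local_seed(config$seed, {
      placed <- 0L; tries <- 0L
      centres <- matrix(0, 0, 3); radii <- numeric(0)
      while (placed < config$lesion_count) {
        tries <- tries + 1L
        if (tries > 200L * config$lesion_count)
          stop("could not place non-overlapping lesions; reduce count/radius",
               call. = FALSE)
        r <- stats::runif(1, rmin, rmax)
        cand <- wm_idx[sample.int(nrow(wm_idx), 1L), ]
        # lesion must sit wholly inside the WM core with a 1-voxel margin
        rr <- sqrt(((cand[1] - ctr[1]) / (shp[1] / 2))^2 +
                   ((cand[2] - ctr[2]) / (shp[2] / 2))^2 +
                   ((cand[3] - ctr[3]) / (shp[3] / 2))^2)
        if (rr + (r + 1) / (min(shp) / 2) > 0.60) next
        if (nrow(centres) &&
            any(sqrt(rowSums((centres - matrix(cand, nrow(centres), 3,
                                               byrow = TRUE))^2)) <
                radii + r + 1)) next
        centres <- rbind(centres, cand); radii <- c(radii, r)
        placed <- placed + 1L
      }
      n_el <- round(config$el_fraction * config$lesion_count)
      el_ids <- if (n_el > 0) sample.int(config$lesion_count, n_el) else integer(0)
      lesions <- list(centres = centres, radii = radii, el_ids = el_ids)
    })
    for (i in seq_len(config$lesion_count)) {
      cc <- lesions$centres[i, ]; r <- lesions$radii[i]
      d2 <- (g$x - cc[1])^2 + (g$y - cc[2])^2 + (g$z - cc[3])^2
      inside <- array(d2 <= r^2, dim = shp)
      label[inside] <- if (i %in% lesions$el_ids) 5L else 4L
    }
  }

  tiss_row <- function(lab) tissues[tissues$label == lab, ]
  code_map <- c("1" = "NAWM", "2" = "cGM", "3" = "CSF", "4" = "WML", "5" = "EL")
  t1 <- array(NA_real_, dim = shp)
  with_local_seed(config$seed + 104729L, {  # independent stream for voxel draws
    for (code in names(code_map)) {
      row <- tiss_row(code_map[[code]])
      if (!nrow(row)) next
      idx <- which(label == as.integer(code))
      if (!length(idx)) next
      vals <- rep(row$t1_pre_center, length(idx))
      if (row$t1_pre_spread > 0)
        vals <- vals + stats::rnorm(length(idx), 0, row$t1_pre_spread)
      t1[idx] <- pmax(vals, 0.05)
    }
  })

  m0 <- array(as.numeric(label > 0L), dim = shp)
  aff <- default_affine(shp, config$voxel_size)
  masks <- derive_masks(wml = label >= 4L, el = label == 5L,
                        cerebral_wm = label == 1L | label >= 4L,
                        cgm = label == 2L)
  structure(list(label = label,
                 true_t1_pre = volume(t1, aff, units = "s"),
                 true_t1_post = NULL,
                 m0 = volume(m0, aff, units = "signal"),
                 masks = masks, lesions = lesions,
                 config = config, tissues = tissues,
                 applied_misalignment = config$misalignment),
            class = "ground_truth")
}

#' Apply the gadolinium effect to phantom ground truth
#'
#' Populates the true post-contrast T1 field. In `direct` mode each
#' tissue's configured delta-T1 (centre, with optional per-voxel spread) is
#' added to the pre-contrast field; in `relaxivity` mode
#' `1/t1_post = 1/t1_pre + r1 * conc` using the tissue's `r1` and `conc`
#' columns (missing values mean no agent reaches that tissue).
#'
#' @param gt A `ground_truth` from [build_phantom()].
#' @param tissues A [tissue_spec()]; defaults to the one baked into `gt`.
#' @param mode `"direct"` or `"relaxivity"`.
#' @return `gt` with `true_t1_post` filled in.
#' @export
apply_gadolinium <- function(gt, tissues = gt$tissues, mode = c("direct", "relaxivity")) {
  mode <- match.arg(mode)
  stopifnot(inherits(gt, "ground_truth"))
  t1_pre <- gt$true_t1_pre$data
  t1_post <- t1_pre
  code_map <- c("1" = "NAWM", "2" = "cGM", "3" = "CSF", "4" = "WML", "5" = "EL")
  with_local_seed(gt$config$seed + 224737L, {
    for (code in names(code_map)) {
      row <- tissues[tissues$label == code_map[[code]], ]
      if (!nrow(row)) next
      idx <- which(gt$label == as.integer(code))
      if (!length(idx)) next
      if (mode == "direct") {
        dt <- rep(row$delta_t1_center, length(idx))
        if (row$delta_t1_spread > 0)
          dt <- dt + stats::rnorm(length(idx), 0, row$delta_t1_spread)
        t1_post[idx] <- t1_pre[idx] + dt
      } else {
        r1c <- if (is.na(row$r1) || is.na(row$conc)) 0 else row$r1 * row$conc
        t1_post[idx] <- 1 / (1 / t1_pre[idx] + r1c)
      }
    }
  })
  if (any(t1_post[gt$label > 0] <= 0, na.rm = TRUE))
    stop("gadolinium model drove t1_post <= 0; check delta_t1/relaxivity",
         call. = FALSE)
  gt$true_t1_post <- volume(t1_post, gt$true_t1_pre$affine, units = "s")
  gt$tissues <- tissues
  gt
}

#' Forward-simulate an MP2RAGE acquisition of the phantom
#'
#' Voxelwise steady-state simulation of both readouts from the phase's true
#' T1 field, with optional linear B1+ gradient scaling the flip angles,
#' noise, and, for the post phase, rigid misalignment of the acquired
#' volumes. Noise is circular complex Gaussian of scale `noise_sigma` per
#' channel added to each GRE readout — so the stored second-inversion image
#' is Rician-distributed (Rayleigh in the background, mean
#' `sigma * sqrt(pi/2)`) and the UNI image is formed from the complex
#' combination `Re(S1 * Conj(S2)) / (|S1|^2 + |S2|^2)`, as in the scanner
#' reconstruction.
#'
#' @param gt A `ground_truth` (post phase requires [apply_gadolinium()]).
#' @param protocol An [mp2rage_protocol()].
#' @param config A [phantom_config()]; defaults to the phantom's own.
#' @param phase `"pre"` or `"post"`.
#' @return A list of [volume()]s `inv2` and `uni`.
#' @export
simulate_acquisition <- function(gt, protocol = mp2rage_protocol(),
                                 config = gt$config, phase = c("pre", "post")) {
  phase <- match.arg(phase)
  t1v <- if (phase == "pre") gt$true_t1_pre else gt$true_t1_post
  if (is.null(t1v)) stop("no ground-truth T1 for phase '", phase,
                         "'; run apply_gadolinium() first", call. = FALSE)
  shp <- dim(t1v$data)
  b1 <- b1_field_array(config$b1_field, shp)
  m0 <- gt$m0$data
  t1 <- t1v$data
  inside <- which(m0 > 0)
  s1 <- numeric(length(m0)); s2 <- numeric(length(m0))
  sig <- simulate_signals(protocol, t1[inside], b1_scale = b1[inside],
                          m0 = m0[inside])
  s1[inside] <- sig$s1; s2[inside] <- sig$s2
  if (config$noise_sigma > 0) {
    seed_off <- if (phase == "pre") 15485863L else 32452843L
    with_local_seed(config$seed + seed_off, {
      sg <- config$noise_sigma
      nv <- length(s1)
      s1r <- s1 + stats::rnorm(nv, 0, sg); s1i <- stats::rnorm(nv, 0, sg)
      s2r <- s2 + stats::rnorm(nv, 0, sg); s2i <- stats::rnorm(nv, 0, sg)
    })
    denom <- s1r^2 + s1i^2 + s2r^2 + s2i^2
    uni <- ifelse(denom > 0, (s1r * s2r + s1i * s2i) / denom, 0)
    s2 <- sqrt(s2r^2 + s2i^2)  # stored INV2 is the Rician magnitude
  } else {
    uni <- uni_from_signals(list(s1 = s1, s2 = s2), zero_undefined = TRUE)
  }
  aff <- t1v$affine
  inv2 <- volume(array(s2, shp), aff, units = "signal")
  univ <- volume(array(uni, shp), aff, units = "dimensionless")
  if (phase == "post" && !is.null(config$misalignment)) {
    m <- rigid_matrix(config$misalignment[1:3], config$misalignment[4:6], shp)
    inv2 <- resample_volume(inv2, m)
    univ <- resample_volume(univ, m)
  }
  list(inv2 = inv2, uni = univ)
}

b1_field_array <- function(b1_field, shp) {
  if (is.null(b1_field)) return(array(1, dim = shp))
  stopifnot(length(b1_field) == 2)
  sc <- seq(b1_field[1], b1_field[2], length.out = shp[1])
  array(rep(sc, times = shp[2] * shp[3]), dim = shp)
}

#' Noise scale for a target tissue SNR
#'
#' Converts a signal-to-noise ratio, defined on the noiseless
#' second-inversion (INV2) signal of a reference tissue, into the Rician
#' `noise_sigma` used by [phantom_config()].
#'
#' @param protocol An [mp2rage_protocol()].
#' @param snr Target SNR (e.g. 30).
#' @param t1_ref Reference-tissue T1, s (default: white matter 1.3 s).
#' @return Noise sigma as a fraction of `m0`.
#' @export
snr_to_sigma <- function(protocol = mp2rage_protocol(), snr, t1_ref = 1.3) {
  s <- simulate_signals(protocol, t1_ref)
  abs(s$s2) / snr
}
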