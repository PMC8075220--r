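#' Cohort specification
#'
#' Parameters of the simulated clinical cohort. Defaults mirror the study
#' population: 47 subjects, 13/47 progressive (PMS), 34/47 on treatment
#' (79% of RRMS, 54% of PMS), EDSS median 3 with range 1-6.5 (higher in
#' PMS), and subject-level non-enhancing-lesion (NEL) median delta-T1
#' centred on the group medians reported for the cohort: more negative in
#' PMS than RRMS, in untreated than treated, and at higher disability.
#'
#' The generative model for a subject's NEL median delta-T1 (seconds) is
#' `base + pms_effect * PMS + untreated_effect * untreated +
#'  edss_slope * (EDSS - 3) + Normal(0, subject_sd)`.
#'
#' @param n_subjects Number of subjects.
#' @param pms_fraction Fraction with progressive phenotype.
#' @param treated_fraction Overall fraction on treatment.
#' @param base Treated-RRMS NEL median delta-T1 centre at EDSS 3, s.
#' @param pms_effect,untreated_effect Additive shifts, s (negative = more
#'   gadolinium-induced shortening).
#' @param edss_slope Delta-T1 change per EDSS point, s.
#' @param subject_sd Between-subject SD of NEL median delta-T1, s.
#' @param seed Integer seed; one global seed fans out to per-subject seeds.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 47, pms_fraction = 13 / 47,
                        treated_fraction = 34 / 47,
                        base = -0.110, pms_effect = -0.055,
                        untreated_effect = -0.040, edss_slope = -0.012,
                        subject_sd = 0.045, seed = 1L) {
  stopifnot(n_subjects >= 2, pms_fraction >= 0, pms_fraction <= 1,
            treated_fraction >= 0, treated_fraction <= 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 pms_fraction = pms_fraction,
                 treated_fraction = treated_fraction, base = base,
                 pms_effect = pms_effect, untreated_effect = untreated_effect,
                 edss_slope = edss_slope, subject_sd = subject_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate the clinical cohort
#'
#' Draws per-subject demographics, clinical scores and the subject-level
#' NEL median delta-T1 from the generative model in [cohort_spec()].
#' Deterministic given the spec's seed. The returned `phantom_seed` column
#' fans the global seed out to per-subject phantom seeds by fixed
#' arithmetic, so imaging runs are reproducible subject by subject.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per subject: `subject_id`, `age`, `sex`,
#'   `phenotype` ("RRMS"/"PMS"), `treated`, `edss`, `edss_group`
#'   (dichotomised at the sample median), clinical scores (`sdmt`, `pasat`,
#'   `mfis`, `hpt_dom`, `hpt_nondom`, `walk25`, `symptom_duration`),
#'   `nel_delta_t1` (the subject's generative NEL median delta-T1, s) and
#'   `phantom_seed`.
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_subjects = 47))
#' table(coh$phenotype)
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  n_pms <- round(spec$pms_fraction * n)
  if (n - n_pms < 2 || (n_pms > 0 && n_pms < 2))
    warning("fewer than 2 subjects in a phenotype group; group analyses degenerate")
  with_local_seed(spec$seed, {
    phenotype <- c(rep("PMS", n_pms), rep("RRMS", n - n_pms))
    # treatment probability differs by phenotype (progressive patients are
    # less often treated), rescaled to hit the overall treated fraction
    p_rel <- ifelse(phenotype == "PMS", 0.54, 0.79)
    p_treat <- pmin(1, p_rel * spec$treated_fraction /
                      (sum(p_rel) / n))
    treated <- stats::runif(n) < p_treat
    # EDSS on the 0-10 half-point ladder, higher in PMS
    edss <- ifelse(phenotype == "PMS",
                   pmin(6.5, pmax(4, round(stats::rnorm(n, 5.5, 0.9) * 2) / 2)),
                   pmin(6.0, pmax(1, round(stats::rnorm(n, 3.0, 1.2) * 2) / 2)))
    age <- pmin(65, pmax(18, stats::rnorm(n, ifelse(phenotype == "PMS", 51.2, 44.3),
                                          ifelse(phenotype == "PMS", 9.4, 11.4))))
    sex <- ifelse(stats::runif(n) < ifelse(phenotype == "PMS", 0.539, 0.677),
                  "F", "M")
    symptom_duration <- pmax(0.5, stats::rnorm(n, 11.5, 8.3))
    sdmt <- stats::rnorm(n, ifelse(phenotype == "PMS", 46.5, 55.7),
                         ifelse(phenotype == "PMS", 7.9, 12.8))
    pasat <- stats::rnorm(n, ifelse(phenotype == "PMS", 42.1, 45.9), 12)
    mfis <- pmax(0, stats::rnorm(n, ifelse(phenotype == "PMS", 49.9, 35.5), 18))
    hpt_dom <- pmax(12, stats::rnorm(n, ifelse(phenotype == "PMS", 40.9, 25.3), 12))
    hpt_nondom <- pmax(12, stats::rnorm(n, ifelse(phenotype == "PMS", 46.1, 27.1), 14))
    walk25 <- pmax(3, stats::rnorm(n, ifelse(phenotype == "PMS", 17.0, 5.5),
                                   ifelse(phenotype == "PMS", 8, 2.5)))
    nel_delta_t1 <- spec$base +
      spec$pms_effect * (phenotype == "PMS") +
      spec$untreated_effect * (!treated) +
      spec$edss_slope * (edss - 3) +
      stats::rnorm(n, 0, spec$subject_sd)
    ord <- sample.int(n)  # shuffle so id order carries no group structure
    out <- tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      age = age[ord], sex = sex[ord], phenotype = phenotype[ord],
      treated = treated[ord], edss = edss[ord],
      sdmt = sdmt[ord], pasat = pasat[ord], mfis = mfis[ord],
      hpt_dom = hpt_dom[ord], hpt_nondom = hpt_nondom[ord],
      walk25 = walk25[ord], symptom_duration = symptom_duration[ord],
      nel_delta_t1 = nel_delta_t1[ord],
      phantom_seed = (spec$seed + 9973L * seq_len(n)) %% .Machine$integer.max)
  })
  out$edss_group <- edss_dichotomize(out$edss)
  out
}

#' Dichotomise EDSS at the sample median
#'
#' Splits subjects into mild (score at or below the cohort median) and
#' moderate (above the median) disability groups, the convention used for
#' the study's group comparisons.
#'
#' @param edss Numeric EDSS scores.
#' @return Factor with levels `"<=median"`, `">median"`.
#' @export
edss_dichotomize <- function(edss) {
  med <- stats::median(edss, na.rm = TRUE)
  factor(ifelse(edss > med, ">median", "<=median"),
         levels = c("<=median", ">median"))
}

#' Per-subject phantom configuration for a cohort row
#'
#' Builds the phantom config and tissue table realising one simulated
#' subject: the subject's generative NEL median delta-T1 becomes the NEL
#' (WML) delta-T1 centre.
#'
#' @param subject One row of the [simulate_cohort()] tibble.
#' @param shape Phantom grid (small by default: cohort-scale runs).
#' @param lesion_count,noise_sigma Passed through to [phantom_config()].
#' @return A list with `config` and `tissues`.
#' @export
subject_phantom <- function(subject, shape = c(32, 32, 32), lesion_count = 3,
                            noise_sigma = 0) {
  stopifnot(nrow(subject) == 1)
  list(config = phantom_config(shape = shape, lesion_count = lesion_count,
                               lesion_radius_range = c(2, 3),
                               seed = as.integer(subject$phantom_seed),
                               noise_sigma = noise_sigma),
       tissues = tissue_spec(nel_dt1 = subject$nel_delta_t1))
}
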