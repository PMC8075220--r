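# deltaT1

Quantify gadolinium-induced T1 shortening (ΔT1) in non-enhancing multiple
sclerosis lesions from 7T MP2RAGE, as a surrogate for low-grade
blood-brain-barrier leakage.

Most MS lesions do not enhance visibly after contrast, yet their
blood-brain barrier may still leak. Subtracting a pre-contrast quantitative
T1 map from a post-contrast one,

    ΔT1 = T1_post − T1_pre   (seconds; negative = gadolinium shortening),

turns that leak into a measurable quantity inside non-enhancing lesion
(NEL) masks, while normal-appearing white matter (NAWM) stays near zero.
The package is aimed at quantitative-MRI researchers who want a tested,
fully synthetic-validatable implementation of this analysis: the MP2RAGE
periodic steady-state signal model (closed form plus a Bloch-stepping
reference), UNI combination and lookup-table T1 estimation, the denoised
T1-weighted product, rigid pre/post registration, ΔT1 subtraction with
lesion/tissue mask algebra (NEL = WML ∖ EL, NAWM = cerebral WM ∖ WML),
per-subject ROI distribution metrics (median, variance, IQR, Pearson
kurtosis), and the cohort statistics layer (paired t / Wilcoxon,
Mann-Whitney, partial correlations, logistic treatment models, FDR). A
digital brain phantom and simulated clinical cohort provide exact ground
truth for every stage.

## Worked example

Simulate one subject's phantom at the study's tissue values, acquire and
reconstruct both phases, and summarise the lesion ROI:

```r
library(deltaT1)

protocol <- mp2rage_protocol()           # 7T study protocol defaults
gt <- phantom_config(shape = c(48, 48, 48), lesion_count = 4, seed = 1) |>
  build_phantom() |>
  apply_gadolinium(mode = "direct")      # NEL delta-T1 ground truth: -0.134 s

pre  <- simulate_acquisition(gt, protocol, phase = "pre")
post <- simulate_acquisition(gt, protocol, phase = "post")
rec_pre  <- reconstruct_t1_map(pre$inv2,  pre$uni,  protocol)
rec_post <- reconstruct_t1_map(post$inv2, post$uni, protocol)
dt1 <- compute_delta_t1(rec_pre$t1, rec_post$t1,
                        rec_pre$qc_flagged, rec_post$qc_flagged)

roi_metrics(dt1, gt$masks$nel, subject_id = "S001", tissue = "NEL")
#> # A tibble: 1 x 8
#>   subject_id tissue n_voxels   mean median variance   iqr kurtosis
#>   <chr>      <chr>     <int>  <dbl>  <dbl>    <dbl> <dbl>    <dbl>
#> 1 S001       NEL        1014 -0.134 -0.134        0     0       NA
```

The reconstructed NEL median ΔT1 recovers the configured −0.134 s to the
lookup grid step (noiseless, zero per-voxel spread, so the spread metrics
vanish to rounding and kurtosis is undefined). `autoplot(dt1, mask = gt$masks$wml)` shows the lesion
heat-map slice.

A cohort-scale run — simulate subjects, image each one, collect metrics and
group statistics into tidy tables:

```r
res <- run_end_to_end(cohort_spec(n_subjects = 8, seed = 3),
                      shape = c(32, 32, 32), out_dir = "out")
res$report       # tissue x map medians with ranges
res$group_stats  # Mann-Whitney comparisons of NEL median delta-T1
```

A thin CLI over the same functions lives at `inst/cli/delta_t1.R`
(`simulate`, `reconstruct`, `register`, `delta`, `roi`, `run-all`).

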