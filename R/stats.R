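#' Paired pre/post comparison (paired t and matched-pairs Wilcoxon)
#'
#' Two-sided paired t-test and matched-pairs Wilcoxon signed-rank test on
#' the same pairs, the combination used for the pre- versus post-contrast
#' T1 comparisons. The Wilcoxon test uses exact enumeration up to
#' `exact_max` pairs (ties and zero differences permitting) and the normal
#' approximation with continuity correction above. Degenerate inputs
#' (all-zero or zero-variance differences) are flagged rather than
#' reported.
#'
#' @param pre,post Equal-length numeric vectors; pairs with missing values
#'   are dropped.
#' @param exact_max Largest n for exact Wilcoxon enumeration.
#' @return A tibble with one row per test: `method`, `estimate`,
#'   `statistic`, `p_value`, `n`, `flagged`, `note`.
#' @examples
#' compare_paired(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))
#' @export
compare_paired <- function(pre, post, exact_max = 12) {
  if (length(pre) != length(post)) stop("pre and post differ in length",
                                        call. = FALSE)
  keep <- !is.na(pre) & !is.na(post)
  pre <- pre[keep]; post <- post[keep]
  n <- length(pre)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  d <- post - pre

  if (stats::sd(d) == 0) {
    t_row <- tibble::tibble(method = "paired t", estimate = mean(d),
                            statistic = NA_real_, p_value = NA_real_, n = n,
                            flagged = TRUE, note = "zero-variance differences")
  } else {
    tt <- stats::t.test(post, pre, paired = TRUE)
    t_row <- tibble::tibble(method = "paired t", estimate = unname(tt$estimate),
                            statistic = unname(tt$statistic),
                            p_value = tt$p.value, n = n, flagged = FALSE,
                            note = NA_character_)
  }

  if (all(d == 0)) {
    w_row <- tibble::tibble(method = "wilcoxon signed-rank", estimate = 0,
                            statistic = NA_real_, p_value = NA_real_, n = n,
                            flagged = TRUE, note = "all differences zero")
  } else {
    nz <- d[d != 0]
    use_exact <- length(nz) <= exact_max && !any(duplicated(abs(nz)))
    wt <- suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE,
                                              exact = use_exact, correct = TRUE))
    w_row <- tibble::tibble(method = "wilcoxon signed-rank",
                            estimate = stats::median(d),
                            statistic = unname(wt$statistic),
                            p_value = wt$p.value, n = n, flagged = FALSE,
                            note = if (use_exact) "exact" else "normal approximation")
  }
  dplyr::bind_rows(t_row, w_row)
}

#' Two-group comparison by Mann-Whitney U
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test, the study's test for
#' group differences in delta-T1 metrics by disability group, phenotype and
#' treatment. Exact enumeration is used when `n_a + n_b <= exact_max` and
#' there are no ties; otherwise the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param a,b Numeric vectors (each with at least 2 non-missing values).
#' @param exact_max Largest combined n for exact enumeration.
#' @return A one-row tibble: `method`, `estimate` (the U statistic for the
#'   first group), `statistic`, `p_value`, `n`, `flagged`, `note`.
#' @export
compare_groups <- function(a, b, exact_max = 12) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 observations per group", call. = FALSE)
  ties <- any(duplicated(c(a, b)))
  use_exact <- (length(a) + length(b)) <= exact_max && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = use_exact,
                                            correct = TRUE))
  tibble::tibble(method = "mann-whitney U",
                 estimate = unname(wt$statistic),
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 n = length(a) + length(b), flagged = FALSE,
                 note = if (use_exact) "exact" else "normal approximation")
}

#' Bivariate and partial correlation
#'
#' Spearman or Pearson correlation with a two-sided p-value. With
#' covariates, a partial correlation is computed on the residuals of `x`
#' and `y` after linear regression on the covariates (for Spearman, ranks
#' are taken first), with the p-value on `n - 2 - k` degrees of freedom.
#' This is the machinery behind the correlations of delta-T1 metrics with
#' disability scores, adjusted for age, sex and symptom duration.
#'
#' @param x,y Equal-length numeric vectors.
#' @param method `"spearman"` or `"pearson"`.
#' @param covariates Optional numeric matrix / data frame of adjustment
#'   variables (one row per observation).
#' @return A one-row tibble: `method`, `estimate` (rho or r), `p_value`,
#'   `n`, `flagged`, `note`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson"),
                      covariates = NULL) {
  method <- match.arg(method)
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    keep <- keep & !apply(is.na(covariates), 1, any)
    covariates <- covariates[keep, , drop = FALSE]
  }
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n < 4 + k) stop("need n >= 4 + number of covariates", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(tibble::tibble(method = method, estimate = NA_real_,
                          p_value = NA_real_, n = n, flagged = TRUE,
                          note = "constant input"))
  lab <- if (k) paste0("partial ", method) else method
  if (k == 0) {
    ct <- suppressWarnings(stats::cor.test(x, y, method = method))
    return(tibble::tibble(method = lab, estimate = unname(ct$estimate),
                          p_value = ct$p.value, n = n, flagged = FALSE,
                          note = NA_character_))
  }
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  rx <- stats::resid(stats::lm(x ~ covariates))
  ry <- stats::resid(stats::lm(y ~ covariates))
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df)
  tibble::tibble(method = lab, estimate = r, p_value = p, n = n,
                 flagged = FALSE, note = sprintf("%d covariates", k))
}

#' Logistic model of treatment status on delta-T1
#'
#' Maximum-likelihood logistic regression of treatment status on the
#' subject-level NEL median delta-T1, optionally adjusted for MS phenotype
#' (`Tx = b0 + b1 * deltaT1 [+ b2 * PMS]`), with Wald p-values. Perfect
#' separation and non-convergence are detected and flagged; coefficients
#' are only reported for converged, non-separated fits.
#'
#' @param delta_t1 Subject-level delta-T1 values, seconds.
#' @param treated Logical (or 0/1) treatment status.
#' @param phenotype Optional phenotype vector; `"PMS"` is coded 1,
#'   `"RRMS"` 0 (numeric input is used as given).
#' @return An object of class `treatment_logistic` wrapping the `glm` fit,
#'   with `converged` and `separated` flags. Use [tidy()] / [glance()].
#' @export
fit_treatment_logistic <- function(delta_t1, treated, phenotype = NULL) {
  treated <- as.logical(treated)
  keep <- !is.na(delta_t1) & !is.na(treated)
  if (!is.null(phenotype)) keep <- keep & !is.na(phenotype)
  delta_t1 <- delta_t1[keep]; treated <- treated[keep]
  if (length(unique(treated)) < 2)
    stop("both treatment classes must be present", call. = FALSE)
  df <- data.frame(tx = as.integer(treated), delta_t1 = delta_t1)
  form <- tx ~ delta_t1
  if (!is.null(phenotype)) {
    ph <- phenotype[keep]
    df$pms <- if (is.numeric(ph)) ph else as.integer(ph == "PMS")
    form <- tx ~ delta_t1 + pms
  }
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = df),
    warning = function(w) invokeRestart("muffleWarning"))
  probs <- stats::fitted(fit)
  # perfect separation: every fitted probability sits at its class's extreme
  separated <- all(probs[df$tx == 1] > 1 - 1e-4) &&
    all(probs[df$tx == 0] < 1e-4)
  structure(list(fit = fit, converged = fit$converged && !separated,
                 separated = separated, n = nrow(df)),
            class = "treatment_logistic")
}

#' @export
print.treatment_logistic <- function(x, ...) {
  cat("logistic treatment model (n =", x$n, ")\n")
  if (!x$converged) {
    cat("  NOT reported:", if (x$separated) "perfect separation" else
      "did not converge", "\n")
  } else {
    print(glance(x))
    print(tidy(x))
  }
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; never decreases a
#' p-value, preserves order statistics, and is idempotent on already
#' monotone adjusted values.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.04))
#' @export
fdr_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}
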