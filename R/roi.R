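#' Distribution metrics of a map inside an ROI
#'
#' Per-subject, per-tissue summary of T1 or delta-T1 values: mean, median,
#' sample variance (n-1 denominator), interquartile range (linear
#' interpolation, Q3 - Q1) and Pearson kurtosis (fourth standardised
#' moment; normal = 3). Missing voxels (reconstruction QC exclusions) are
#' dropped, not imputed; a constant ROI has zero variance and missing
#' kurtosis.
#'
#' @param map A [volume()] / `delta_t1_map`, or a numeric array or vector.
#' @param mask Logical array selecting the ROI (ignored when `map` is
#'   already a vector of values).
#' @param subject_id,tissue Optional labels carried into the output row.
#' @param kurtosis_convention `"pearson"` (normal = 3) or `"excess"`
#'   (normal = 0).
#' @param quartile_type Quantile algorithm passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return A one-row tibble: `subject_id`, `tissue`, `n_voxels`, `mean`,
#'   `median`, `variance`, `iqr`, `kurtosis`.
#' @examples
#' roi_metrics(c(1, 2, 3, 4, 5))
#' @export
roi_metrics <- function(map, mask = NULL, subject_id = NA_character_,
                        tissue = NA_character_,
                        kurtosis_convention = c("pearson", "excess"),
                        quartile_type = 7) {
  kurtosis_convention <- match.arg(kurtosis_convention)
  vals <- vol_data(map)
  if (!is.null(mask)) {
    m <- vol_data(mask)
    if (!identical(dim(vals), dim(m)))
      stop("map and mask are on different grids", call. = FALSE)
    vals <- vals[m != 0]
  }
  vals <- as.numeric(vals[!is.na(vals)])
  if (!length(vals)) stop("ROI is empty after missing-value exclusion",
                          call. = FALSE)
  n <- length(vals)
  mu <- mean(vals)
  v <- if (n > 1) stats::var(vals) else 0
  q <- stats::quantile(vals, c(0.25, 0.75), type = quartile_type, names = FALSE)
  m2 <- mean((vals - mu)^2)
  kurt <- if (m2 == 0) NA_real_ else mean((vals - mu)^4) / m2^2
  if (!is.na(kurt) && kurtosis_convention == "excess") kurt <- kurt - 3
  tibble::tibble(subject_id = subject_id, tissue = tissue, n_voxels = n,
                 mean = mu, median = stats::median(vals), variance = v,
                 iqr = q[2] - q[1], kurtosis = kurt)
}

#' Pool voxelwise pre-contrast T1 and delta-T1 across subjects
#'
#' Concatenates, in subject order, the paired (pre-contrast T1, delta-T1)
#' voxel values inside one tissue mask across a list of subjects — the
#' input for the cohort-level per-voxel correlation analyses.
#'
#' @param subjects A list; each element has `pre_t1` (volume or array),
#'   `delta_t1` (volume or array) and `masks` (a `mask_set` or a list of
#'   logical arrays).
#' @param tissue Mask name to pool over (e.g. `"nel"`, `"nawm"`, `"cgm"`).
#' @return A tibble with columns `subject`, `pre_t1`, `delta_t1`, one row
#'   per voxel.
#' @export
pooled_voxel_values <- function(subjects, tissue) {
  if (!length(subjects)) stop("no subjects to pool", call. = FALSE)
  purrr::imap_dfr(subjects, function(s, i) {
    m <- s$masks[[tolower(tissue)]]
    if (is.null(m)) stop("no mask '", tissue, "' for subject ", i, call. = FALSE)
    m <- vol_data(m) != 0
    pre <- vol_data(s$pre_t1)[m]
    dt <- vol_data(s$delta_t1)[m]
    keep <- !is.na(pre) & !is.na(dt)
    tibble::tibble(subject = if (!is.null(s$subject_id)) s$subject_id else
      as.character(i), pre_t1 = pre[keep], delta_t1 = dt[keep])
  })
}

#' Kernel density summary of a value distribution
#'
#' Gaussian-kernel density estimate with Silverman's rule-of-thumb
#' bandwidth by default, as used for the per-subject delta-T1 distribution
#' overlays. The returned curve integrates to 1 on its evaluation grid.
#'
#' @param values Numeric vector with at least two distinct values.
#' @param bw Bandwidth rule or numeric bandwidth (see [stats::density()]).
#' @param n Number of grid points.
#' @return A tibble with class `kde_summary`: columns `grid`, `density`;
#'   attributes `bw` and `n_values`.
#' @export
kde_summary <- function(values, bw = "nrd0", n = 512) {
  values <- values[!is.na(values)]
  if (length(unique(values)) < 2)
    stop("need at least 2 distinct values for a density estimate", call. = FALSE)
  d <- stats::density(values, bw = bw, kernel = "gaussian", n = n)
  out <- tibble::tibble(grid = d$x, density = d$y)
  attr(out, "bw") <- d$bw
  attr(out, "n_values") <- length(values)
  class(out) <- c("kde_summary", class(out))
  out
}

#' Per-subject, per-tissue metric table for a reconstructed subject
#'
#' Convenience wrapper running [roi_metrics()] over the standard tissue
#' masks for the pre-contrast T1 map and the delta-T1 map of one subject.
#'
#' @param pre_t1 Pre-contrast T1 [volume()].
#' @param delta_t1 [compute_delta_t1()] output.
#' @param masks A `mask_set`.
#' @param subject_id Subject label.
#' @param tissues Mask names to summarise.
#' @return A tibble, one row per tissue x map, with a `map` column
#'   (`"pre_t1"` or `"delta_t1"`).
#' @export
subject_metrics <- function(pre_t1, delta_t1, masks, subject_id = "S001",
                            tissues = c("wml", "nel", "el", "nawm", "cgm")) {
  labels <- c(wml = "WML", nel = "NEL", el = "EL", nawm = "NAWM", cgm = "cGM")
  purrr::map_dfr(tissues, function(tis) {
    m <- masks[[tis]]
    lab <- if (tis %in% names(labels)) labels[[tis]] else toupper(tis)
    if (is.null(m) || !any(m)) return(NULL)
    dplyr::bind_rows(
      dplyr::mutate(roi_metrics(pre_t1, m, subject_id, lab),
                    map = "pre_t1", .after = "tissue"),
      dplyr::mutate(roi_metrics(delta_t1, m, subject_id, lab),
                    map = "delta_t1", .after = "tissue"))
  })
}
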