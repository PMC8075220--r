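#' 3D scalar volume with affine and unit tag
#'
#' Minimal container for an image volume: a 3D numeric array, a 4x4
#' voxel-to-world affine (mm) and a unit tag (`"s"` for T1/delta-T1 maps,
#' `"dimensionless"` for UNI, `"signal"` for raw readouts, `"mask"` for
#' boolean volumes).
#'
#' @param data 3D numeric or logical array.
#' @param affine 4x4 voxel-to-world matrix; default near-isotropic
#'   0.7 x 0.688 x 0.688 mm, the acquisition resolution.
#' @param units Unit tag string.
#' @return An object of class `d1_volume`.
#' @export
volume <- function(data, affine = default_affine(dim(data)), units = "dimensionless") {
  if (length(dim(data)) != 3) stop("volume data must be a 3D array", call. = FALSE)
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4x4 matrix", call. = FALSE)
  structure(list(data = data, affine = affine, units = units),
            class = "d1_volume")
}

#' @rdname volume
#' @param x Object to test.
#' @export
is_volume <- function(x) inherits(x, "d1_volume")

default_affine <- function(shape, voxel_size = c(0.7, 0.688, 0.688)) {
  a <- diag(c(voxel_size, 1))
  a[1:3, 4] <- -voxel_size * (shape / 2)  # centre the volume near the origin
  a
}

vol_data <- function(x) if (is_volume(x)) x$data else x
vol_affine <- function(x) if (is_volume(x)) x$affine else default_affine(dim(x))

check_same_grid <- function(a, b, tol = 1e-6) {
  if (!identical(dim(vol_data(a)), dim(vol_data(b))))
    stop("volumes are on different grids (shape mismatch)", call. = FALSE)
  if (max(abs(vol_affine(a) - vol_affine(b))) > tol)
    stop("volumes are on different grids (affine mismatch)", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.d1_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume %dx%dx%d [%s], voxel %.3gx%.3gx%.3g mm\n",
              d[1], d[2], d[3], x$units,
              sqrt(sum(x$affine[1:3, 1]^2)), sqrt(sum(x$affine[1:3, 2]^2)),
              sqrt(sum(x$affine[1:3, 3]^2))))
  invisible(x)
}

#' Read / write volumes as NIfTI-1
#'
#' `write_volume()` stores the array (float64 for scalar maps, uint8 for
#' masks) with the affine in the sform; the unit tag travels in the NIfTI
#' `intent_name` field and is recovered by `read_volume()` (absent tags are
#' assumed dimensionless, with a warning).
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param vol A [volume()].
#' @return `read_volume()` returns a [volume()]; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  units <- RNifti::niftiHeader(img)$intent_name
  if (!nzchar(units)) {
    warning("no unit tag in ", basename(path), "; assuming dimensionless")
    units <- "dimensionless"
  }
  dat <- array(as.numeric(img), dim = dim(img))
  if (identical(units, "mask")) dat <- array(dat != 0, dim = dim(dat))
  volume(dat, affine = RNifti::xform(img), units = units)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume(vol))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir, call. = FALSE)
  mask <- identical(vol$units, "mask") || is.logical(vol$data)
  dat <- if (mask) array(as.integer(vol$data != 0), dim = dim(vol$data)) else vol$data
  img <- RNifti::asNifti(dat)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  hdr <- list(intent_name = if (mask) "mask" else vol$units,
              datatype = if (mask) 2L else 64L)  # uint8 / float64
  img <- RNifti::asNifti(img, hdr)
  RNifti::writeNifti(img, path, datatype = if (mask) "uint8" else "double")
  invisible(path)
}

#' Boolean mask set derived from lesion and tissue masks
#'
#' Encodes the study's mask algebra: the non-enhancing lesion mask is the
#' white-matter-lesion mask minus the enhancing-lesion mask, and
#' normal-appearing white matter is cerebral white matter minus all lesions.
#' An enhancing-lesion mask that is not a subset of the lesion mask is
#' intersected with it (with a warning).
#'
#' @param wml,el,cerebral_wm,cgm Logical arrays or mask [volume()]s on one
#'   grid: white matter lesions, enhancing lesions, cerebral white matter,
#'   cortical grey matter.
#' @return A `mask_set` list of logical arrays `wml`, `el`, `nel`, `nawm`,
#'   `cgm`, `cerebral_wm`.
#' @examples
#' wm <- array(TRUE, c(4, 4, 4)); wml <- el <- array(FALSE, c(4, 4, 4))
#' wml[1:2, 1, 1] <- TRUE; el[1, 1, 1] <- TRUE
#' m <- derive_masks(wml, el, wm, array(FALSE, c(4, 4, 4)))
#' sum(m$nel)
#' @export
derive_masks <- function(wml, el, cerebral_wm, cgm) {
  vols <- lapply(list(wml = wml, el = el, cerebral_wm = cerebral_wm, cgm = cgm),
                 function(v) {
                   d <- vol_data(v)
                   array(d != 0 & !is.na(d), dim = dim(d))
                 })
  shp <- dim(vols$wml)
  if (!all(vapply(vols, function(v) identical(dim(v), shp), logical(1))))
    stop("masks are on different grids", call. = FALSE)
  if (!any(vols$cerebral_wm)) stop("cerebral WM mask is empty", call. = FALSE)
  if (any(vols$el & !vols$wml)) {
    warning("EL mask extends outside the WML mask; intersecting")
    vols$el <- vols$el & vols$wml
  }
  out <- list(wml = vols$wml, el = vols$el,
              nel = vols$wml & !vols$el,
              nawm = vols$cerebral_wm & !vols$wml,
              cgm = vols$cgm, cerebral_wm = vols$cerebral_wm)
  class(out) <- "mask_set"
  out
}

#' @export
print.mask_set <- function(x, ...) {
  n <- vapply(unclass(x), sum, numeric(1))
  cat("mask set (voxels):", paste(names(n), n, sep = "=", collapse = " "), "\n")
  invisible(x)
}
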