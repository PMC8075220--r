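#' Rigid transforms in voxel space
#'
#' A rigid transform is parameterised by three translations (voxels) and
#' three rotations (degrees, applied about the volume centre in the order
#' x, y, z). `rigid_matrix()` returns the 4x4 voxel-space matrix mapping
#' output voxel coordinates to input voxel coordinates when used with
#' [resample_volume()].
#'
#' @param translation Numeric length-3, voxels.
#' @param rotation Numeric length-3, degrees.
#' @param shape Volume shape (for the centre of rotation).
#' @return 4x4 numeric matrix.
#' @export
rigid_matrix <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                         shape) {
  stopifnot(length(translation) == 3, length(rotation) == 3)
  r <- rotation * pi / 180
  rx <- matrix(c(1, 0, 0, 0, cos(r[1]), -sin(r[1]), 0, sin(r[1]), cos(r[1])),
               3, 3, byrow = TRUE)
  ry <- matrix(c(cos(r[2]), 0, sin(r[2]), 0, 1, 0, -sin(r[2]), 0, cos(r[2])),
               3, 3, byrow = TRUE)
  rz <- matrix(c(cos(r[3]), -sin(r[3]), 0, sin(r[3]), cos(r[3]), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  rot <- rz %*% ry %*% rx
  centre <- (shape + 1) / 2
  m <- diag(4)
  m[1:3, 1:3] <- rot
  m[1:3, 4] <- centre - rot %*% centre + translation
  m
}

#' Resample a volume through a voxel-space transform (trilinear)
#'
#' For every output voxel, the transform maps its coordinate into the input
#' volume and the value is interpolated trilinearly. Coordinates falling
#' outside the input grid take `fill`.
#'
#' @param vol A [volume()] or 3D array.
#' @param matrix 4x4 voxel-space transform (output coordinate to input
#'   coordinate), e.g. from [rigid_matrix()].
#' @param fill Value for out-of-grid samples.
#' @return Same container type as `vol`.
#' @export
resample_volume <- function(vol, matrix, fill = 0) {
  dat <- vol_data(vol)
  dat[is.na(dat)] <- fill
  shp <- dim(dat)
  g <- as.matrix(expand.grid(x = seq_len(shp[1]), y = seq_len(shp[2]),
                             z = seq_len(shp[3])))
  src <- g %*% t(matrix[1:3, 1:3]) +
    matrix(matrix[1:3, 4], nrow(g), 3, byrow = TRUE)
  out <- trilinear_sample(dat, src, fill)
  res <- array(out, dim = shp)
  if (is_volume(vol)) volume(res, affine = vol$affine, units = vol$units) else res
}

# vectorised trilinear interpolation at fractional voxel coordinates (nx3)
trilinear_sample <- function(dat, coords, fill = 0) {
  shp <- dim(dat)
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  # points exactly on the far face belong to the last cell (weight 1)
  sel <- x0 == shp[1] & fx == 0; x0[sel] <- shp[1] - 1; fx[sel] <- 1
  sel <- y0 == shp[2] & fy == 0; y0[sel] <- shp[2] - 1; fy[sel] <- 1
  sel <- z0 == shp[3] & fz == 0; z0[sel] <- shp[3] - 1; fz[sel] <- 1
  inside <- x0 >= 1 & y0 >= 1 & z0 >= 1 &
    x0 + 1 <= shp[1] & y0 + 1 <= shp[2] & z0 + 1 <= shp[3]
  out <- rep(fill, length(x))
  if (!any(inside)) return(out)
  x0 <- x0[inside]; y0 <- y0[inside]; z0 <- z0[inside]
  fx <- fx[inside]; fy <- fy[inside]; fz <- fz[inside]
  idx <- function(i, j, k) (k - 1) * shp[1] * shp[2] + (j - 1) * shp[1] + i
  v000 <- dat[idx(x0,     y0,     z0)]
  v100 <- dat[idx(x0 + 1, y0,     z0)]
  v010 <- dat[idx(x0,     y0 + 1, z0)]
  v110 <- dat[idx(x0 + 1, y0 + 1, z0)]
  v001 <- dat[idx(x0,     y0,     z0 + 1)]
  v101 <- dat[idx(x0 + 1, y0,     z0 + 1)]
  v011 <- dat[idx(x0,     y0 + 1, z0 + 1)]
  v111 <- dat[idx(x0 + 1, y0 + 1, z0 + 1)]
  out[inside] <-
    (1 - fz) * ((1 - fy) * ((1 - fx) * v000 + fx * v100) +
                fy        * ((1 - fx) * v010 + fx * v110)) +
    fz       * ((1 - fy) * ((1 - fx) * v001 + fx * v101) +
                fy        * ((1 - fx) * v011 + fx * v111))
  out
}

read_transform <- function(path) {
  m <- as.matrix(utils::read.table(path, comment.char = "#"))
  dimnames(m) <- NULL
  if (!identical(dim(m), c(4L, 4L))) stop("transform file must hold a 4x4 matrix",
                                          call. = FALSE)
  m
}

write_transform <- function(matrix, path, seed = NULL) {
  hdr <- c("# rigid transform, voxel space, output -> input",
           if (!is.null(seed)) paste0("# seed: ", seed))
  writeLines(c(hdr, apply(matrix, 1, paste, collapse = " ")), path)
  invisible(path)
}
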