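#' Build a UNI-to-T1 lookup table
#'
#' Forward-simulates the UNI value on a regular T1 grid under `protocol`
#' and retains the largest strictly monotone branch of the UNI(T1) curve,
#' which is the invertible part used for T1 estimation. For the study
#' protocol the whole 0.3-5.0 s range is one strictly decreasing branch.
#'
#' @param protocol An [mp2rage_protocol()].
#' @param t1_min,t1_max T1 grid bounds, seconds.
#' @param step Grid spacing, seconds (default 1 ms, finer than any
#'   reported delta-T1 effect).
#' @param b1_scale Optional transmit scale baked into the table.
#' @return An object of class `uni_lookup` with fields `t1_grid`,
#'   `uni_values` (the retained branch) and `valid_range`.
#' @examples
#' lut <- build_lookup(mp2rage_protocol())
#' t1_from_uni(0.1, lut)
#' @export
build_lookup <- function(protocol, t1_min = 0.3, t1_max = 5.0, step = 0.001,
                         b1_scale = 1) {
  if (!(t1_min > 0 && t1_max > t1_min)) stop("need 0 < t1_min < t1_max", call. = FALSE)
  if (!(step > 0 && step <= t1_max - t1_min))
    stop("step must be positive and no larger than the grid range", call. = FALSE)
  t1 <- seq(t1_min, t1_max, by = step)
  uni <- uni_from_signals(simulate_signals(protocol, t1, b1_scale = b1_scale))
  d <- diff(uni)
  if (all(d == 0)) stop("degenerate protocol: UNI is constant in T1", call. = FALSE)
  # longest run of strictly same-signed successive differences
  s <- sign(d)
  runs <- rle(s)
  keep <- which(runs$values != 0)
  if (!length(keep)) stop("degenerate protocol: UNI nowhere monotone", call. = FALSE)
  best <- keep[which.max(runs$lengths[keep])]
  endc <- cumsum(runs$lengths)
  i1 <- if (best == 1) 1L else endc[best - 1L] + 1L  # first diff of the run
  i2 <- endc[best]                                   # last diff of the run
  idx <- i1:(i2 + 1L)
  out <- list(t1_grid = t1[idx], uni_values = uni[idx],
              valid_range = range(uni[idx]), protocol = protocol,
              direction = runs$values[best])
  class(out) <- "uni_lookup"
  out
}

#' Estimate T1 from UNI values through a lookup table
#'
#' Linear interpolation on the monotone branch of the table. UNI values
#' outside the branch's range are clamped to the nearest bound and flagged
#' out-of-range rather than erroring, so that noisy or background voxels
#' can be excluded downstream.
#'
#' @param uni Numeric vector of UNI values.
#' @param table A `uni_lookup` from [build_lookup()].
#' @return A list with `t1` (seconds) and logical `out_of_range`.
#' @export
t1_from_uni <- function(uni, table) {
  stopifnot(inherits(table, "uni_lookup"))
  flag <- uni < table$valid_range[1] | uni > table$valid_range[2] | !is.finite(uni)
  xo <- ifelse(is.finite(uni), uni, table$valid_range[1])
  ord <- if (table$direction < 0) rev(seq_along(table$uni_values)) else
    seq_along(table$uni_values)
  t1 <- stats::approx(table$uni_values[ord], table$t1_grid[ord], xout = xo,
                      rule = 2, ties = "ordered")$y
  list(t1 = t1, out_of_range = flag)
}

#' @export
print.uni_lookup <- function(x, ...) {
  cat(sprintf("UNI-T1 lookup: %d nodes, T1 %.3g-%.3g s, UNI %.4g..%.4g (%s)\n",
              length(x$t1_grid), min(x$t1_grid), max(x$t1_grid),
              x$uni_values[1], x$uni_values[length(x$uni_values)],
              if (x$direction < 0) "decreasing" else "increasing"))
  invisible(x)
}
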