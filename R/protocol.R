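#' MP2RAGE sequence protocol
#'
#' Container for the timing and flip-angle parameters that determine the
#' MP2RAGE steady-state signal. The default values reproduce the 7T study
#' protocol: cycle repetition time 8.5 s, inversion times 1.0/3.0 s, flip
#' angles 5/5 degrees, turbo factor 252 excitations per GRE block, echo
#' spacing 6.9 ms.
#'
#' Both gradient-echo readout blocks are centred on their inversion times:
#' the first excitation of a block fires at `ti - (n_exc/2) * tr_gre` and the
#' centre of k-space is acquired at `ti`. The constructor enforces that both
#' blocks fit inside the cycle.
#'
#' @param tr_mp2rage Cycle repetition time (inversion to inversion), seconds.
#' @param ti1,ti2 Inversion times of the two readouts, seconds.
#' @param alpha1,alpha2 Excitation flip angles of the two readouts, degrees.
#' @param n_exc Turbo factor: excitations per GRE block.
#' @param tr_gre Echo spacing between excitations, seconds.
#' @param inv_eff Inversion efficiency in (0, 1]; 1 is a perfect inversion.
#'
#' @return An object of class `mp2rage_protocol`.
#' @examples
#' p <- mp2rage_protocol()
#' p$ti1
#' @export
mp2rage_protocol <- function(tr_mp2rage = 8.5, ti1 = 1.0, ti2 = 3.0,
                             alpha1 = 5, alpha2 = 5, n_exc = 252,
                             tr_gre = 0.0069, inv_eff = 1.0) {
  p <- list(tr_mp2rage = as.numeric(tr_mp2rage), ti1 = as.numeric(ti1),
            ti2 = as.numeric(ti2), alpha1 = as.numeric(alpha1),
            alpha2 = as.numeric(alpha2), n_exc = as.integer(n_exc),
            tr_gre = as.numeric(tr_gre), inv_eff = as.numeric(inv_eff))
  class(p) <- "mp2rage_protocol"
  validate_protocol(p)
  p
}

validate_protocol <- function(p) {
  stopifnot(inherits(p, "mp2rage_protocol"))
  with(p, {
    if (!(tr_mp2rage > 0 && ti1 > 0 && tr_gre > 0 && n_exc > 0))
      stop("protocol timings must be positive", call. = FALSE)
    if (!(ti1 < ti2 && ti2 < tr_mp2rage))
      stop("protocol requires 0 < ti1 < ti2 < tr_mp2rage", call. = FALSE)
    half <- n_exc / 2 * tr_gre
    if (ti1 - half < 0 || ti2 + half > tr_mp2rage)
      stop("GRE blocks do not fit inside the MP2RAGE cycle", call. = FALSE)
    if (ti2 - ti1 < n_exc * tr_gre)
      stop("GRE blocks overlap: ti2 - ti1 < n_exc * tr_gre", call. = FALSE)
    if (!(inv_eff > 0 && inv_eff <= 1))
      stop("inv_eff must lie in (0, 1]", call. = FALSE)
  })
  invisible(p)
}

#' @export
print.mp2rage_protocol <- function(x, ...) {
  cat("MP2RAGE protocol\n")
  cat(sprintf("  TR(cycle) %.4g s | TI %.4g/%.4g s | flips %.3g/%.3g deg\n",
              x$tr_mp2rage, x$ti1, x$ti2, x$alpha1, x$alpha2))
  cat(sprintf("  turbo factor %d | TR(GRE) %.4g s | inversion efficiency %.3g\n",
              x$n_exc, x$tr_gre, x$inv_eff))
  invisible(x)
}

#' Read an MP2RAGE protocol from a key = value text file
#'
#' The file holds one `key = value` pair per line (SI units: seconds and
#' degrees), `#` starts a comment. Unknown keys error; missing keys fall back
#' to the study-protocol defaults.
#'
#' @param path Path to the protocol file.
#' @return An `mp2rage_protocol`.
#' @export
read_protocol <- function(path) {
  kv <- read_keyval(path)
  allowed <- names(formals(mp2rage_protocol))
  bad <- setdiff(names(kv), allowed)
  if (length(bad))
    stop("unknown protocol keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(mp2rage_protocol, lapply(kv, as.numeric))
}

# shared key=value parser for protocol and phantom configs
read_keyval <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!all(grepl("=", lines, fixed = TRUE)))
    stop("malformed config line (expected key = value): ",
         lines[!grepl("=", lines, fixed = TRUE)][1], call. = FALSE)
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  stats::setNames(as.list(vals), keys)
}
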