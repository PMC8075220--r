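#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the logistic treatment model
#'
#' One row per coefficient with the log-odds estimate, standard error,
#' Wald statistic and two-sided p-value. Coefficients are withheld (zero
#' rows) for non-converged or separated fits.
#'
#' @param x A [fit_treatment_logistic()] object.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @method tidy treatment_logistic
#' @export
tidy.treatment_logistic <- function(x, ...) {
  if (!x$converged)
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std_error = numeric(), statistic = numeric(),
                          p_value = numeric()))
  cf <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, 1], std_error = cf[, 2],
                 statistic = cf[, 3], p_value = cf[, 4])
}

#' @rdname tidy.treatment_logistic
#' @return `glance()` returns a one-row tibble: `n`, `converged`,
#'   `separated`, `null_deviance`, `deviance`, `aic`.
#' @method glance treatment_logistic
#' @export
glance.treatment_logistic <- function(x, ...) {
  tibble::tibble(n = x$n, converged = x$converged, separated = x$separated,
                 null_deviance = x$fit$null.deviance, deviance = x$fit$deviance,
                 aic = x$fit$aic)
}
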