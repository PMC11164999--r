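#' Deviation statistics between measured and calculated solubilities
#'
#' Computes the four reporting statistics used throughout the package, all on
#' mole fractions: the average absolute relative deviation
#' AARD% = (100/N) sum |y_exp - y_calc| / y_exp, the (signed, unscaled)
#' average deviation ARD% = (100/N) sum (y_exp - y_calc), the mean squared
#' error and the coefficient of determination
#' R^2 = 1 - sum (y_exp - y_calc)^2 / sum (y_exp - mean(y_exp))^2.
#'
#' @param y_exp experimental mole fractions (all > 0).
#' @param y_calc calculated mole fractions, same length.
#' @return an object of class `fit_stats`: a list with `aard_pct`,
#'   `ard_pct`, `mse`, `r2` and `n`.
#' @examples
#' fit_statistics(c(1e-4, 2e-4), c(1.1e-4, 1.8e-4))
#' @export
fit_statistics <- function(y_exp, y_calc) {
  if (length(y_exp) != length(y_calc))
    stop("y_exp and y_calc must have the same length", call. = FALSE)
  if (length(y_exp) == 0) stop("empty input", call. = FALSE)
  if (any(y_exp == 0)) stop("y_exp must be nonzero", call. = FALSE)
  n <- length(y_exp)
  d <- y_exp - y_calc
  sst <- sum((y_exp - mean(y_exp))^2)
  structure(list(
    aard_pct = 100 * mean(abs(d) / y_exp),
    ard_pct  = 100 * mean(d),
    mse      = mean(d^2),
    r2       = if (sst > 0) 1 - sum(d^2) / sst else NA_real_,
    n        = n
  ), class = "fit_stats")
}

#' @export
print.fit_stats <- function(x, ...) {
  cat(sprintf("AARD%% = %.3f  ARD%% = %.3g  MSE = %.3g  R2 = %.4f  (n = %d)\n",
              x$aard_pct, x$ard_pct, x$mse, x$r2, x$n))
  invisible(x)
}
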