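# Derived analyses: crossover pressure, MST self-consistency, model ranking.

#' Crossover pressure from the temperature trend of tabulated isobars
#'
#' Below the crossover pressure the loss of solvent density with temperature
#' dominates and solubility falls as T rises; above it the growing
#' sublimation pressure dominates and solubility rises with T. For every
#' pressure shared by at least two isotherms the y-versus-T trend is
#' classified as strictly decreasing (-1), strictly increasing (+1) or
#' non-monotone (0, excluded); the crossover is reported as the highest
#' decreasing tabulated pressure provided some higher shared pressure is
#' increasing. No interpolation between grid pressures is attempted: the
#' data grid is coarse and an interpolated intersection would manufacture
#' precision.
#'
#' @param table a [solubility_table()] with at least two isotherms sharing
#'   at least two pressures.
#' @return an object of class `crossover_result`: list with `pressure`
#'   (bar, `NA` when no sign change exists) and `trend` (named vector of
#'   -1/0/+1 per shared pressure).
#' @examples
#' \donttest{crossover_pressure(lumiracoxib_data())}
#' @export
crossover_pressure <- function(table) {
  stopifnot(inherits(table, "solubility_table"))
  if (length(unique(table$T_K)) < 2)
    stop("need at least 2 isotherms", call. = FALSE)
  shared <- sort(unique(table$P_bar[duplicated(table$P_bar)]))
  if (length(shared) < 2)
    stop("need at least 2 pressures shared across isotherms", call. = FALSE)
  trend <- vapply(shared, function(P) {
    rows <- table[table$P_bar == P, ]
    y <- rows$y2[order(rows$T_K)]
    d <- diff(y)
    if (all(d < 0)) -1L else if (all(d > 0)) 1L else 0L
  }, integer(1))
  names(trend) <- shared
  dec <- shared[trend == -1L]
  inc <- shared[trend == 1L]
  pressure <- NA_real_
  if (length(dec) && length(inc) && max(inc) > min(dec)) {
    cand <- dec[vapply(dec, function(p) any(inc > p), logical(1))]
    if (length(cand)) pressure <- max(cand)
  }
  structure(list(pressure = pressure, trend = trend), class = "crossover_result")
}

#' @export
print.crossover_result <- function(x, ...) {
  if (is.na(x$pressure)) cat("No crossover pressure detected\n")
  else cat(sprintf("Crossover pressure: %g bar\n", x$pressure))
  cat("Trend of y2 with T per shared pressure (-1 falling, +1 rising):\n")
  print(x$trend)
  invisible(x)
}

#' Self-consistency test of a fitted MST correlation
#'
#' Removes the fitted linear temperature term from the MST left-hand side
#' and checks that all isotherms collapse onto one straight line in density:
#' `T ln(y P / P_ref) - b T` is regressed against `rho` pooled over every
#' record. A collapse close to linear (`R^2` near 1) supports the
#' correlation's functional form and its use for moderate extrapolation.
#'
#' @param fit a `solufit` with model `"mst"`.
#' @param table,states the data (and optional CO2 states) to score;
#'   defaults to the data the model was fitted on.
#' @param extrapolation_states optional data frame with columns `T_K`,
#'   `P_bar`, `y2` (plus optional precomputed `rho_mass`) scored against the
#'   same collapsed line.
#' @return an object of class `mst_consistency`: list with `r2_collapsed`,
#'   `line` (intercept and slope of the collapsed line),
#'   `per_isotherm_residual_spread` (sd of line residuals within each
#'   isotherm) and, when requested, `extrapolation_residuals`.
#' @export
self_consistency_mst <- function(fit, table = fit$table, states = NULL,
                                 extrapolation_states = NULL) {
  stopifnot(inherits(fit, "solufit"))
  if (fit$model != "mst") stop("fit must be an MST fit", call. = FALSE)
  if (is.null(states)) {
    states <- if (identical(table, fit$table)) fit$states
              else co2_state(table$T_K, table$P_bar)
  }
  b <- fit$coefficients[["b"]]
  z <- table$T_K * log(table$y2 * table$P_bar / .P_REF) - b * table$T_K
  line <- stats::lm(z ~ states$rho_mass)
  # a perfect collapse (noise-free surfaces) triggers lm's perfect-fit warning
  r2 <- suppressWarnings(summary(line)$r.squared)
  res <- stats::residuals(line)
  spread <- vapply(split(res, table$T_K), stats::sd, numeric(1))
  out <- list(r2_collapsed = r2,
              line = c(intercept = unname(stats::coef(line)[1]),
                       slope = unname(stats::coef(line)[2])),
              per_isotherm_residual_spread = spread)
  if (!is.null(extrapolation_states)) {
    ex <- extrapolation_states
    rho <- ex$rho_mass %||% co2_state(ex$T_K, ex$P_bar)$rho_mass
    zx <- ex$T_K * log(ex$y2 * ex$P_bar / .P_REF) - b * ex$T_K
    out$extrapolation_residuals <- zx - (out$line["intercept"] + out$line["slope"] * rho)
  }
  structure(out, class = "mst_consistency")
}

#' @export
print.mst_consistency <- function(x, ...) {
  cat(sprintf("MST self-consistency: collapsed-line R2 = %.4f\n", x$r2_collapsed))
  cat("Per-isotherm residual spread:\n")
  print(signif(x$per_isotherm_residual_spread, 4))
  invisible(x)
}

#' Fit and rank all five density-based correlations
#'
#' Fits every model in [fit_solubility()] to the same table, ranks them by
#' AARD%, and annotates the report with the dissolution enthalpies (from the
#' Chrastil and Bartle fits) and the crossover pressure.
#'
#' @inheritParams fit_solubility
#' @param seed seed forwarded to the modified-Chrastil GA fit.
#' @return an object of class `model_comparison`: a data frame (one row per
#'   model, sorted by AARD%) with attributes `fits`, `enthalpies` and
#'   `crossover`.
#' @examples
#' \donttest{compare_models(lumiracoxib_data())}
#' @export
compare_models <- function(table, states = NULL, seed = 1L) {
  if (is.null(states)) states <- co2_state(table$T_K, table$P_bar)
  models <- .SOLUFIT_MODELS
  fits <- lapply(models, function(m)
    fit_solubility(table, m, states, control = list(seed = seed)))
  names(fits) <- models
  df <- do.call(rbind, lapply(fits, function(f)
    data.frame(model = f$model, a = f$coefficients[["a"]],
               b = f$coefficients[["b"]], c = f$coefficients[["c"]],
               aard_pct = f$stats$aard_pct, ard_pct = f$stats$ard_pct,
               mse = f$stats$mse, r2 = f$stats$r2, n = f$stats$n)))
  df <- df[order(df$aard_pct), ]
  rownames(df) <- NULL
  structure(df,
            fits = fits,
            enthalpies = enthalpies(fits$chrastil, fits$bartle),
            crossover = crossover_pressure(table),
            seed = seed,
            class = c("model_comparison", "data.frame"))
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison (%d records), ranked by AARD%%:\n",
              x$n[1]))
  print.data.frame(cbind(rank = seq_len(nrow(x)),
                         x[c("model", "a", "b", "c", "aard_pct", "r2")]),
                   digits = 5)
  print(attr(x, "enthalpies"))
  print(attr(x, "crossover"))
  invisible(x)
}
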