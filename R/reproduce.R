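#' Run the full solubility-modelling pipeline on the packaged data
#'
#' Fits the five density-based correlations to the packaged lumiracoxib
#' table, extracts dissolution enthalpies, locates the crossover pressure,
#' runs the MST self-consistency test, and recomputes the per-point
#' deviations of the nimesulide validation measurements against the
#' literature values. Optionally fits per-isotherm ER-EoS binary
#' interaction parameters (slow; off by default).
#'
#' @param seed seed for the stochastic (GA/DE) fits.
#' @param eos also fit `(kij, lij)` per isotherm with [fit_binary_params()];
#'   requires `eos_props`.
#' @param eos_props a [solute_props()] for the EoS stage. The sublimation
#'   pressure of lumiracoxib has never been measured, so no default is
#'   provided: any EoS run is conditional on a user-supplied model.
#' @return a list of class `scsolub_report` with components `comparison`
#'   (a [compare_models()] report), `enthalpies`, `crossover`,
#'   `self_consistency`, `nimesulide` (per-point deviation table) and
#'   optionally `eos_isotherms`; plus `seed`.
#' @examples
#' \donttest{reproduce_study(seed = 1)}
#' @export
reproduce_study <- function(seed = 1L, eos = FALSE, eos_props = NULL) {
  tab <- lumiracoxib_data()
  states <- co2_state(tab$T_K, tab$P_bar)
  comparison <- compare_models(tab, states, seed = seed)
  fits <- attr(comparison, "fits")
  sc <- self_consistency_mst(fits$mst)

  nim <- nimesulide_data("this_work")
  nim_ref <- nimesulide_data("macnaughton")
  stopifnot(all(nim$T_K == nim_ref$T_K), all(nim$P_bar == nim_ref$P_bar))
  nim_dev <- data.frame(T_K = nim$T_K, P_bar = nim$P_bar,
                        y_this_work = nim$y2, y_literature = nim_ref$y2,
                        dev_pct = 100 * abs(nim$y2 - nim_ref$y2) / nim$y2)

  out <- list(comparison = comparison,
              enthalpies = attr(comparison, "enthalpies"),
              crossover = attr(comparison, "crossover"),
              self_consistency = sc,
              nimesulide = nim_dev,
              seed = seed)
  if (eos) {
    if (is.null(eos_props))
      stop("eos = TRUE needs eos_props (no measured sublimation pressure exists)",
           call. = FALSE)
    iso <- split(seq_len(nrow(tab)), tab$T_K)
    out$eos_isotherms <- lapply(iso, function(i) {
      sub <- solubility_table(as.data.frame(tab)[i, ],
                              attr(tab, "solute_name"), attr(tab, "M_solute"))
      fit_binary_params(sub, eos_props, control = de_control(seed = seed))
    })
  }
  class(out) <- "scsolub_report"
  out
}

#' @export
print.scsolub_report <- function(x, ...) {
  print(x$comparison)
  print(x$self_consistency)
  cat("Nimesulide validation vs literature:\n")
  print(x$nimesulide, digits = 4)
  if (!is.null(x$eos_isotherms)) {
    cat("ER-EoS per-isotherm fits:\n")
    for (f in x$eos_isotherms) print(f)
  }
  invisible(x)
}
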