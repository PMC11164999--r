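# Synthetic solubility surfaces with known ground truth, so every fitting
# and analysis stage can be exercised against an exact answer.

#' Generate a synthetic solubility table from a known model surface
#'
#' Evaluates one of the package's forward models on a (T, P) grid and
#' applies multiplicative lognormal measurement noise with coefficient of
#' variation `noise_cv` (mean-one corrected: the noise factor is
#' `exp(sigma Z - sigma^2/2)` with `sigma^2 = log(1 + cv^2)`, so noisy
#' replicates average to the noiseless surface). Uncertainty is attached as
#' `u_y = noise_cv * y2`. The default grid mirrors the structure of the
#' measured lumiracoxib table: four isotherms 308.15-338.15 K, eight
#' pressures 120-400 bar, with the (338.15 K, 120 bar) cell dropped.
#'
#' @param model one of `"chrastil"`, `"modified_chrastil"`, `"mst"`,
#'   `"bartle"`, `"kj"`, `"eos"`.
#' @param params named parameters of the generating model: `a`, `b`, `c`
#'   for the correlations; for `"eos"` a list with `props` (a
#'   [solute_props()]), `kij`, `lij`.
#' @param temperatures,pressures grid axes (K, bar).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed (only the noise consumes randomness).
#' @param dropout optional data frame of grid cells to omit, columns `T_K`
#'   and `P_bar`.
#' @param solute_name,M_solute solute metadata for the generated table.
#' @param states optional precomputed CO2 states for the full grid (in grid
#'   order: temperatures varying slowest).
#' @return list with `table` (a [solubility_table()]) and `truth` (the
#'   generating model, parameters, noise level and seed).
#' @examples
#' \donttest{
#' g <- generate_table("chrastil", c(a = 7, b = -3165, c = 5.3),
#'                     noise_cv = 0.05, seed = 42)
#' fit_solubility(g$table, "chrastil")
#' }
#' @export
generate_table <- function(model = c("chrastil", "modified_chrastil", "mst",
                                     "bartle", "kj", "eos"),
                           params,
                           temperatures = c(308.15, 318.15, 328.15, 338.15),
                           pressures = seq(120, 400, by = 40),
                           noise_cv = 0, seed = 1L,
                           dropout = data.frame(T_K = 338.15, P_bar = 120),
                           solute_name = "synthetic", M_solute = 293.72,
                           states = NULL) {
  model <- match.arg(model)
  stopifnot(noise_cv >= 0, length(temperatures) > 0, length(pressures) > 0)
  grid <- expand.grid(P_bar = pressures, T_K = temperatures)[c("T_K", "P_bar")]
  if (!is.null(dropout) && nrow(dropout)) {
    drop_key <- paste(dropout$T_K, dropout$P_bar)
    grid <- grid[!(paste(grid$T_K, grid$P_bar) %in% drop_key), , drop = FALSE]
  }
  if (is.null(states)) states <- co2_state(grid$T_K, grid$P_bar)
  y0 <- .forward_model(model, params, grid$T_K, grid$P_bar, states, M_solute)
  bad <- which(!is.finite(y0) | y0 <= 0 | y0 >= 1)
  if (length(bad))
    stop(sprintf("generated y2 = %g outside (0, 1) at T = %g K, P = %g bar",
                 y0[bad[1]], grid$T_K[bad[1]], grid$P_bar[bad[1]]), call. = FALSE)
  y <- y0
  if (noise_cv > 0) {
    sigma <- sqrt(log(1 + noise_cv^2))
    y <- .with_seed(seed, function()
      y0 * exp(sigma * stats::rnorm(length(y0)) - sigma^2 / 2))
  }
  tab <- solubility_table(
    data.frame(T_K = grid$T_K, P_bar = grid$P_bar, y2 = y,
               u_y = if (noise_cv > 0) noise_cv * y else NA_real_),
    solute_name = solute_name, M_solute = M_solute)
  list(table = tab,
       truth = list(model = model, params = params, noise_cv = noise_cv,
                    seed = seed, y_noiseless = y0))
}

.forward_model <- function(model, params, T, P, states, M) {
  if (model == "eos") {
    stopifnot(is.list(params), inherits(params$props, "solute_props"))
    return(vapply(seq_along(T), function(i)
      as.numeric(solid_solubility_eos(T[i], P[i], params$props,
                                      params$kij %||% 0, params$lij %||% 0)),
      numeric(1)))
  }
  cf <- c(a = unname(params[["a"]]), b = unname(params[["b"]]),
          c = unname(params[["c"]]))
  .predict_model(model, cf, T, P, states, M)
}

#' Generate a synthetic surface with a prescribed crossover pressure
#'
#' Builds isotherms whose solubility falls with temperature over the
#' low-pressure band (density loss dominating) and rises with temperature
#' above it (sublimation pressure dominating), so that
#' [crossover_pressure()] must recover the band boundary, i.e. the highest
#' pressure of `low_band`. Log-solubility is linear in T within each band
#' with slopes of -2.5%/K and +2.5%/K: steep enough that the trend stays
#' unambiguous under a few percent of measurement noise.
#'
#' @param low_band,high_band pressure grid values (bar) where solubility
#'   decreases / increases with temperature; together they partition the
#'   pressure grid.
#' @param temperatures isotherm temperatures (K).
#' @param noise_cv,seed multiplicative noise level and seed, as in
#'   [generate_table()].
#' @param y_ref solubility scale at the grid centre.
#' @return list with `table` and `truth` (containing `boundary`, the
#'   expected crossover pressure, `NA` when `low_band` is empty).
#' @examples
#' \donttest{
#' g <- generate_crossover_surface(c(120, 160), seq(200, 400, 40))
#' crossover_pressure(g$table)$pressure
#' }
#' @export
generate_crossover_surface <- function(low_band, high_band,
                                       temperatures = c(308.15, 318.15, 328.15, 338.15),
                                       noise_cv = 0, seed = 1L, y_ref = 1.5e-4) {
  pressures <- sort(c(low_band, high_band))
  if (length(pressures) < 2)
    stop("need at least 2 grid pressures", call. = FALSE)
  if (length(intersect(low_band, high_band)))
    stop("low_band and high_band must partition the pressure grid", call. = FALSE)
  grid <- expand.grid(P_bar = pressures, T_K = temperatures)[c("T_K", "P_bar")]
  Tmid <- mean(range(temperatures))
  slope <- ifelse(grid$P_bar %in% low_band, -0.025, 0.025)
  # gentle pressure dependence keeps y inside the measured decade
  y0 <- y_ref * exp(0.8 * log(grid$P_bar / mean(pressures)) +
                      slope * (grid$T_K - Tmid))
  y <- y0
  if (noise_cv > 0) {
    sigma <- sqrt(log(1 + noise_cv^2))
    y <- .with_seed(seed, function()
      y0 * exp(sigma * stats::rnorm(length(y0)) - sigma^2 / 2))
  }
  tab <- solubility_table(
    data.frame(T_K = grid$T_K, P_bar = grid$P_bar, y2 = y,
               u_y = if (noise_cv > 0) noise_cv * y else NA_real_),
    solute_name = "synthetic-crossover", M_solute = 293.72)
  boundary <- if (length(low_band) && length(high_band) &&
                  max(high_band) > max(low_band)) max(low_band) else NA_real_
  list(table = tab,
       truth = list(boundary = boundary, noise_cv = noise_cv, seed = seed))
}
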