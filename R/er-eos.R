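# Esmaeilzadeh-Roshanfekr three-parameter cubic equation of state,
# vdW2 mixing rules, fugacity coefficients and the solid-SCF solubility
# closure. SI units internally (Pa, m3/mol); pressures cross the API in bar.

.er_cache <- new.env(parent = emptyenv())

# Dimensionless Omega coefficients from the critical conditions
# P(vc) = Pc, dP/dv = 0, d2P/dv2 = 0 imposed at a prescribed critical
# compressibility zeta_c; solved once per zeta_c by Newton iteration.
.er_omegas <- function(zeta_c = 0.29) {
  key <- sprintf("%.15g", zeta_c)
  if (!is.null(.er_cache[[key]])) return(.er_cache[[key]])
  v <- zeta_c
  f <- function(x) {
    A <- x[1]; B <- x[2]; C <- x[3]
    Q <- v^2 + 2 * C * v - C^2
    Qp <- 2 * v + 2 * C
    c(1 / (v - B) - A / Q - 1,
      -1 / (v - B)^2 + A * Qp / Q^2,
      2 / (v - B)^3 + A * (2 / Q^2 - 2 * Qp^2 / Q^3))
  }
  x <- c(0.45, 0.07, 0.06)
  for (it in seq_len(200)) {
    fx <- f(x)
    J <- matrix(0, 3, 3)
    h <- 1e-7
    for (j in 1:3) {
      xp <- x
      xp[j] <- xp[j] + h
      J[, j] <- (f(xp) - fx) / h
    }
    dx <- solve(J, -fx)
    x <- x + dx
    if (max(abs(dx)) < 1e-14) break
  }
  if (max(abs(f(x))) > 1e-10 || x[2] <= 0)
    stop("critical-condition solve failed for zeta_c = ", zeta_c, call. = FALSE)
  out <- c(omega_a = x[1], omega_b = x[2], omega_c = x[3])
  .er_cache[[key]] <- out
  out
}

#' Pure-component parameters of the ER cubic equation of state
#'
#' The equation of state is `P = RT/(v - b) - a(T) / (v(v + c) + c(v - c))`.
#' The dimensionless coefficients multiplying `R^2 Tc^2 / Pc` (for `a`) and
#' `R Tc / Pc` (for `b`, `c`) are obtained by imposing the critical
#' conditions numerically at a prescribed critical compressibility
#' `zeta_c` (default 0.29), so the returned parameter set reproduces the
#' input critical point by construction. The temperature dependence is a
#' Soave-type `alpha(T) = (1 + m (1 - sqrt(T/Tc)))^2` with
#' `m = 0.48 + 1.574 w - 0.176 w^2`.
#'
#' @param Tc,Pc critical temperature (K) and pressure (bar).
#' @param omega acentric factor.
#' @param T temperature (K) at which `a(T)` is evaluated.
#' @param zeta_c critical compressibility imposed on the cubic.
#' @return an object of class `er_params`: list with `a` (Pa m^6 mol^-2),
#'   `b`, `cc` (m^3 mol^-1), plus `ac`, `alpha`, `m`, `Tc`, `Pc`, `omega`,
#'   `T` and the dimensionless `omegas`.
#' @examples
#' p <- er_pure_params(304.1282, 73.773, 0.22394, 308.15)
#' er_volume_roots(308.15, 120, p)
#' @export
er_pure_params <- function(Tc, Pc, omega, T, zeta_c = 0.29) {
  stopifnot(Tc > 0, Pc > 0, T > 0)
  om <- .er_omegas(zeta_c)
  Pc_pa <- Pc * 1e5
  R <- .R_GAS
  m <- 0.48 + 1.574 * omega - 0.176 * omega^2
  alpha <- (1 + m * (1 - sqrt(T / Tc)))^2
  ac <- om[["omega_a"]] * R^2 * Tc^2 / Pc_pa
  structure(list(a = ac * alpha, b = om[["omega_b"]] * R * Tc / Pc_pa,
                 cc = om[["omega_c"]] * R * Tc / Pc_pa,
                 ac = ac, alpha = alpha, m = m,
                 Tc = Tc, Pc = Pc, omega = omega, T = T,
                 zeta_c = zeta_c, omegas = om),
            class = "er_params")
}

#' Pressure from the ER equation of state
#'
#' @param T temperature (K).
#' @param v molar volume (m^3 mol^-1), vectorised.
#' @param params an `er_params` (pure or mixture).
#' @return pressure in bar.
#' @export
er_pressure <- function(T, v, params) {
  (.R_GAS * T / (v - params$b) -
     params$a / (v^2 + 2 * params$cc * v - params$cc^2)) / 1e5
}

#' Real molar-volume roots of the ER equation of state
#'
#' Solves the pressure-explicit cubic for molar volume at (T, P) and returns
#' the real roots larger than the co-volume, in ascending order, each
#' polished to a relative pressure residual below 1e-10.
#'
#' @inheritParams er_pressure
#' @param P pressure (bar).
#' @return numeric vector of one to three molar volumes (m^3 mol^-1).
#' @export
er_volume_roots <- function(T, P, params) {
  stopifnot(P > 0)
  R <- .R_GAS
  Ppa <- P * 1e5
  a <- params$a; b <- params$b; cc <- params$cc
  RTP <- R * T / Ppa
  co <- c(b * cc^2 + cc^2 * RTP - a * b / Ppa,          # v^0
          -cc^2 - 2 * b * cc - 2 * cc * RTP + a / Ppa,  # v^1
          2 * cc - b - RTP,                             # v^2
          1)                                            # v^3
  z <- polyroot(co)
  v <- Re(z[abs(Im(z)) < 1e-8 * pmax(abs(z), 1)])
  v <- sort(unique(v[v > b]))
  if (!length(v))
    stop("no physical volume root (v > b) at this state", call. = FALSE)
  # Newton polish on P(v) - P
  for (k in seq_along(v)) {
    for (it in 1:50) {
      fv <- er_pressure(T, v[k], params) * 1e5 - Ppa
      if (abs(fv) / Ppa < 1e-12) break
      h <- 1e-8 * v[k]
      dfv <- (er_pressure(T, v[k] + h, params) - er_pressure(T, v[k] - h, params)) * 1e5 / (2 * h)
      step <- fv / dfv
      if (!is.finite(step)) break
      v[k] <- v[k] - step
    }
  }
  v <- v[abs(er_pressure(T, v, params) * 1e5 - Ppa) / Ppa < 1e-10]
  if (!length(v))
    stop("volume-root polishing failed at this state", call. = FALSE)
  v
}

#' Mixture parameters under the two-parameter van der Waals mixing rule
#'
#' `a_m = sum_ij y_i y_j (1 - k_ij) sqrt(a_i a_j)`,
#' `b_m = sum_ij y_i y_j (1 - l_ij) (b_i + b_j)/2`, and the third
#' (non-attractive) parameter mixes linearly, `c_m = sum_i y_i c_i`.
#'
#' @param y mole fractions (must sum to 1 within 1e-10).
#' @param pures list of `er_params`, one per component, at a common T.
#' @param kij,lij binary interaction corrections: scalars (two components)
#'   or symmetric zero-diagonal matrices.
#' @return an `er_params` for the mixture (with `$pure` detail attached).
#' @export
er_mixture_params <- function(y, pures, kij = 0, lij = 0) {
  n <- length(y)
  stopifnot(length(pures) == n)
  if (abs(sum(y) - 1) > 1e-10)
    stop("composition must sum to 1 (tolerance 1e-10)", call. = FALSE)
  K <- .as_bip_matrix(kij, n)
  L <- .as_bip_matrix(lij, n)
  ai <- vapply(pures, `[[`, numeric(1), "a")
  bi <- vapply(pures, `[[`, numeric(1), "b")
  ci <- vapply(pures, `[[`, numeric(1), "cc")
  Aij <- (1 - K) * sqrt(outer(ai, ai))
  Bij <- (1 - L) * outer(bi, bi, `+`) / 2
  structure(list(a = drop(y %*% Aij %*% y), b = drop(y %*% Bij %*% y),
                 cc = sum(y * ci), T = pures[[1]]$T,
                 y = y, Aij = Aij, Bij = Bij, ci = ci),
            class = "er_params")
}

.as_bip_matrix <- function(x, n) {
  if (is.matrix(x)) return(x)
  if (length(x) == 1 && n == 2) {
    m <- matrix(c(0, x, x, 0), 2, 2)
    return(m)
  }
  if (length(x) == 1 && x == 0) return(matrix(0, n, n))
  stop("kij/lij must be a scalar (binary) or an n x n matrix", call. = FALSE)
}

# ln(phi_i) for every component at a given molar volume root; closed form
# from standard thermodynamics for the ER cubic with vdW2 mixing.
.er_lnphi_at <- function(v, T, mix, P_bar) {
  R <- .R_GAS
  A <- mix$a; B <- mix$b; C <- mix$cc
  y <- mix$y
  Z <- (P_bar * 1e5) * v / (R * T)
  abar <- 2 * drop(mix$Aij %*% y)          # d(n^2 a_m)/dn_i / n
  bbar <- 2 * drop(mix$Bij %*% y) - B      # d(n b_m)/dn_i
  q1 <- (1 + sqrt(2)) * C
  q2 <- (1 - sqrt(2)) * C
  Lg <- log((v + q1) / (v + q2))
  D <- v^2 + 2 * C * v - C^2
  I2 <- (1 / (8 * C^2)) * (1 / (v + q2) + 1 / (v + q1) - Lg / (sqrt(2) * C))
  -log(Z * (v - B) / v) +
    bbar / (v - B) -
    abar * Lg / (2 * sqrt(2) * C * R * T) +
    (2 * A * mix$ci / (R * T)) * (1 / (2 * D) - 2 * C * I2)
}

#' Fugacity coefficients in an ER-EoS mixture
#'
#' Analytic `ln(phi_i)` for the ER equation of state with vdW2 mixing rules,
#' evaluated at the molar-volume root with the lowest total residual Gibbs
#' energy (the stable root; the supercritical states of interest are almost
#' always single-rooted).
#'
#' @param i component index, or `NULL` for the full vector.
#' @param y mole fractions.
#' @param T temperature (K).
#' @param P pressure (bar).
#' @param pures list of per-component `er_params` at `T`.
#' @inheritParams er_mixture_params
#' @return `ln(phi_i)` (scalar, or vector over components when `i` is
#'   `NULL`), with the volume root used attached as attribute `"volume"`.
#' @export
fugacity_coeff <- function(i = NULL, y, T, P, pures, kij = 0, lij = 0) {
  mix <- er_mixture_params(y, pures, kij, lij)
  roots <- er_volume_roots(T, P, mix)
  lnphi <- .er_lnphi_at(roots[1], T, mix, P)
  if (length(roots) > 1) {
    g <- vapply(roots, function(v) sum(y * .er_lnphi_at(v, T, mix, P)), numeric(1))
    lnphi <- .er_lnphi_at(roots[which.min(g)], T, mix, P)
    vused <- roots[which.min(g)]
  } else vused <- roots[1]
  out <- if (is.null(i)) lnphi else lnphi[i]
  attr(out, "volume") <- vused
  out
}

#' Solute physical-property bundle for the EoS solubility route
#'
#' @param M molar mass (g/mol).
#' @param Tc,Pc critical temperature (K) and pressure (bar).
#' @param omega acentric factor.
#' @param Vs solid molar volume (cm^3/mol).
#' @param psub_A,psub_B Clausius-Clapeyron sublimation-pressure parameters:
#'   `ln(Psub / Pa) = A - B / T`.
#' @return an object of class `solute_props`.
#' @examples
#' lumi <- solute_props(293.72, 768.76, 18.18, 0.9875, 215,
#'                      psub_A = 10.70, psub_B = 5426.5)
#' @export
solute_props <- function(M, Tc, Pc, omega, Vs, psub_A, psub_B) {
  stopifnot(M > 0, Tc > 0, Pc > 0, Vs > 0, psub_B > 0)
  structure(list(M = M, Tc = Tc, Pc = Pc, omega = omega, Vs = Vs,
                 psub_A = psub_A, psub_B = psub_B),
            class = "solute_props")
}

#' @rdname solute_props
#' @param props a `solute_props`.
#' @param T temperature (K).
#' @return `sublimation_pressure()`: Psub in Pa (increasing in T).
#' @export
sublimation_pressure <- function(props, T) exp(props$psub_A - props$psub_B / T)

.co2_er_props <- list(Tc = 304.1282, Pc = 73.773, omega = 0.22394)

#' Solid solubility in supercritical CO2 from the ER equation of state
#'
#' Solves the standard solid-supercritical fluid equilibrium closure
#' `y2 = (Psub/P) exp(Vs (P - Psub) / (R T)) / phi2(y2, T, P)`
#' by fixed-point iteration started from the ideal value `Psub/P`, with the
#' solute fugacity coefficient from [fugacity_coeff()] under vdW2 mixing.
#'
#' @param T temperature (K).
#' @param P pressure (bar).
#' @param props a [solute_props()].
#' @param kij,lij binary interaction parameters for the CO2(1)-solute(2) pair.
#' @param tol relative convergence tolerance.
#' @param max_iter iteration cap.
#' @param zeta_c critical compressibility used for both components.
#' @param y_start optional starting value for the iteration (defaults to the
#'   ideal-solubility value; the converged fixed point does not depend on it).
#' @return mole-fraction solubility `y2`, with the iteration count as
#'   attribute `"iterations"`.
#' @export
solid_solubility_eos <- function(T, P, props, kij = 0, lij = 0,
                                 tol = 1e-10, max_iter = 200, zeta_c = 0.29,
                                 y_start = NULL) {
  Ppa <- P * 1e5
  psub <- sublimation_pressure(props, T)
  poynting <- exp(props$Vs * 1e-6 * (Ppa - psub) / (.R_GAS * T))
  y_ideal <- psub / Ppa * poynting
  pures <- list(
    er_pure_params(.co2_er_props$Tc, .co2_er_props$Pc, .co2_er_props$omega, T, zeta_c),
    er_pure_params(props$Tc, props$Pc, props$omega, T, zeta_c))
  y2 <- if (is.null(y_start)) min(y_ideal, 0.1) else y_start
  hist <- numeric(0)
  for (it in seq_len(max_iter)) {
    lnphi2 <- fugacity_coeff(2, c(1 - y2, y2), T, P, pures, kij, lij)
    y_new <- y_ideal / exp(lnphi2)
    if (!is.finite(y_new) || y_new >= 0.5) {
      cond <- simpleError(sprintf(
        "solid-solubility closure leaves the dilute regime (y2 -> %.3g) at T = %g K, P = %g bar",
        y_new, T, P))
      cond$trace <- hist
      stop(cond)
    }
    hist[it] <- y_new
    if (abs(y_new - y2) <= tol * max(y_new, 1e-300)) {
      out <- y_new
      attr(out, "iterations") <- it
      return(out)
    }
    y2 <- y_new
  }
  cond <- simpleError(sprintf(
    "solid_solubility_eos did not converge in %d iterations at T = %g K, P = %g bar",
    max_iter, T, P))
  cond$trace <- hist
  stop(cond)
}

#' Fit per-isotherm binary interaction parameters by differential evolution
#'
#' Minimises the AARD% between [solid_solubility_eos()] predictions and the
#' measured isotherm over `(kij, lij)` in the given box, using
#' [de_minimize()]. States where the closure fails are penalised.
#'
#' @param table a [solubility_table()] whose records share one temperature
#'   (at least 4 of them).
#' @param props a [solute_props()].
#' @param control a [de_control()].
#' @param bounds length-2 interval searched for both parameters.
#' @return an object of class `er_isotherm_fit`: list with `T`, `kij`,
#'   `lij`, `aard_pct`, `stats`, `predicted` and the optimizer trace.
#' @export
fit_binary_params <- function(table, props, control = de_control(),
                              bounds = c(-1, 1)) {
  stopifnot(inherits(table, "solubility_table"))
  Tiso <- unique(table$T_K)
  if (length(Tiso) != 1)
    stop("records must form a single isotherm", call. = FALSE)
  if (nrow(table) < 4) stop("need at least 4 records", call. = FALSE)
  predict_iso <- function(k, l) {
    vapply(table$P_bar, function(P) {
      tryCatch(as.numeric(solid_solubility_eos(Tiso, P, props, k, l)),
               error = function(e) NA_real_)
    }, numeric(1))
  }
  obj <- function(p) {
    yc <- predict_iso(p[1], p[2])
    if (any(!is.finite(yc)) || any(yc <= 0)) return(1e6)
    100 * mean(abs(table$y2 - yc) / table$y2)
  }
  de <- de_minimize(obj, lower = rep(bounds[1], 2), upper = rep(bounds[2], 2),
                    control = control)
  yc <- predict_iso(de$par[1], de$par[2])
  structure(list(T = Tiso, kij = de$par[1], lij = de$par[2],
                 aard_pct = de$value,
                 stats = fit_statistics(table$y2, yc),
                 predicted = yc, trace = de$trace),
            class = "er_isotherm_fit")
}

#' @export
print.er_isotherm_fit <- function(x, ...) {
  cat(sprintf("ER-EoS isotherm fit at %g K: kij = %.4f, lij = %.4f, AARD%% = %.2f (n = %d)\n",
              x$T, x$kij, x$lij, x$aard_pct, x$stats$n))
  invisible(x)
}
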