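# Span-Wagner (1996) multiparameter Helmholtz equation of state for CO2,
# residual part only (density is the only property the package needs).
# Coefficients transcribed from the publication; the critical-point and
# saturation fingerprints in the test suite pin the transcription down.

.co2 <- list(
  Tc      = 304.1282,   # K
  Pc      = 7.3773e6,   # Pa
  rhoc    = 467.6,      # kg m-3
  Rs      = 188.9241,   # specific gas constant J kg-1 K-1 (R/M as used by the EoS)
  M       = 44.01       # g mol-1, used for molar conversions package-wide
)

# polynomial terms (1-7)
.sw_np <- c(0.388568232032e0, 0.293854759427e1, -0.558671885349e1, -0.767531995925e0,
            0.317290055804e0, 0.548033158978e0, 0.122794112203e0)
.sw_dp <- c(1, 1, 1, 1, 2, 2, 3)
.sw_tp <- c(0, 0.75, 1, 2, 0.75, 2, 0.75)

# exponential terms (8-34)
.sw_ne <- c( 0.216589615432e1,  0.158417351097e1, -0.231327054055e0,  0.581169164314e-1,
            -0.553691372054e0,  0.489466159094e0, -0.242757398435e-1, 0.624947905017e-1,
            -0.121758602252e0, -0.370556852701e0, -0.167758797004e-1, -0.119607366380e0,
            -0.456193625088e-1, 0.356127892703e-1, -0.744277271321e-2, -0.173957049024e-2,
            -0.218101212895e-1, 0.243321665592e-1, -0.374401334235e-1, 0.143387157569e0,
            -0.134919690833e0, -0.231512250535e-1, 0.123631254929e-1, 0.210583219729e-2,
            -0.339585190264e-3, 0.559936517716e-2, -0.303351180556e-3)
.sw_de <- c(1, 2, 4, 5, 5, 5, 6, 6, 6, 1, 1, 4, 4, 4, 7, 8, 2, 3, 3, 5, 5, 6, 7, 8, 10, 4, 8)
.sw_te <- c(1.5, 1.5, 2.5, 0, 1.5, 2, 0, 1, 2, 3, 6, 3, 6, 8, 6, 0, 7, 12, 16, 22, 24, 16,
            24, 8, 2, 28, 14)
.sw_ce <- c(1, 1, 1, 1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 2, 2, 2, 3, 3, 3, 4, 4, 4, 4, 4, 4, 5, 6)

# Gaussian bell-shaped terms (35-39)
.sw_ng <- c(-0.213654886883e3, 0.266415691493e5, -0.240272122046e5, -0.283416034240e3,
             0.212472844002e3)
.sw_dg <- c(2, 2, 2, 3, 3)
.sw_tg <- c(1, 0, 1, 3, 3)
.sw_ag <- c(25, 25, 25, 15, 20)
.sw_bg <- c(325, 300, 300, 275, 275)
.sw_gg <- c(1.16, 1.19, 1.19, 1.25, 1.22)

# non-analytic critical-region terms (40-42)
.sw_nn <- c(-0.666422765408e0, 0.726086323499e0, 0.550686686128e-1)
.sw_an <- c(3.5, 3.5, 3)
.sw_bn <- c(0.875, 0.925, 0.875)
.sw_betan <- c(0.3, 0.3, 0.3)
.sw_An <- c(0.7, 0.7, 0.7)
.sw_Bn <- c(0.3, 0.3, 1)
.sw_Cn <- c(10, 10, 12.5)
.sw_Dn <- c(275, 275, 275)

# the three non-analytic terms and a numerical delta-derivative; they vanish
# rapidly away from the critical point (psi ~ exp(-10 (delta-1)^2 - 275 (tau-1)^2))
.sw_alphar_na <- function(delta, tau) {
  s <- 0
  dm1 <- delta - 1
  for (i in 1:3) {
    theta <- (1 - tau) + .sw_An[i] * (dm1^2)^(1 / (2 * .sw_betan[i]))
    Delta <- theta^2 + .sw_Bn[i] * (dm1^2)^.sw_an[i]
    psi <- exp(-.sw_Cn[i] * dm1^2 - .sw_Dn[i] * (tau - 1)^2)
    s <- s + .sw_nn[i] * Delta^.sw_bn[i] * delta * psi
  }
  s
}

.sw_alphar <- function(delta, tau) {
  sum(.sw_np * delta^.sw_dp * tau^.sw_tp) +
    sum(.sw_ne * delta^.sw_de * tau^.sw_te * exp(-delta^.sw_ce)) +
    sum(.sw_ng * delta^.sw_dg * tau^.sw_tg *
          exp(-.sw_ag * (delta - 1)^2 - .sw_bg * (tau - .sw_gg)^2)) +
    .sw_alphar_na(delta, tau)
}

# d alpha^r / d delta (analytic for terms 1-39, central difference for 40-42)
.sw_alphar_d <- function(delta, tau) {
  s <- sum(.sw_np * .sw_dp * delta^(.sw_dp - 1) * tau^.sw_tp) +
    sum(.sw_ne * tau^.sw_te * exp(-delta^.sw_ce) *
          (.sw_de * delta^(.sw_de - 1) - .sw_ce * delta^(.sw_ce + .sw_de - 1))) +
    sum(.sw_ng * delta^.sw_dg * tau^.sw_tg *
          exp(-.sw_ag * (delta - 1)^2 - .sw_bg * (tau - .sw_gg)^2) *
          (.sw_dg / delta - 2 * .sw_ag * (delta - 1)))
  h <- 1e-6
  s + (.sw_alphar_na(delta + h, tau) - .sw_alphar_na(delta - h, tau)) / (2 * h)
}

# pressure in Pa from mass density (kg m-3) and temperature (K)
.sw_pressure <- function(rho, T) {
  delta <- rho / .co2$rhoc
  tau <- .co2$Tc / T
  rho * .co2$Rs * T * (1 + delta * .sw_alphar_d(delta, tau))
}

# ancillary vapour-pressure and saturated-density equations (used only to pick
# the physical branch at subcritical temperatures)
.sw_psat <- function(T) {
  th <- 1 - T / .co2$Tc
  a <- c(-7.0602087, 1.9391218, -1.6463597, -3.2995634)
  .co2$Pc * exp((.co2$Tc / T) * (a[1] * th + a[2] * th^1.5 + a[3] * th^2 + a[4] * th^4))
}
.sw_rholiq <- function(T) {
  th <- 1 - T / .co2$Tc
  a <- c(1.9245108, -0.62385555, -0.32731127, 0.39245142)
  t <- c(0.34, 0.5, 10 / 6, 11 / 6)
  .co2$rhoc * exp(sum(a * th^t))
}
.sw_rhovap <- function(T) {
  th <- 1 - T / .co2$Tc
  a <- c(-1.7074879, -0.82274670, -4.6008549, -10.111178, -29.742252)
  t <- c(0.34, 0.5, 1, 7 / 3, 14 / 3)
  .co2$rhoc * exp(sum(a * th^t))
}

.co2_envelope <- c(T_min = 290, T_max = 350, P_min = 60, P_max = 600)

.co2_check_envelope <- function(T, P) {
  bad <- T < .co2_envelope["T_min"] | T > .co2_envelope["T_max"] |
    P < .co2_envelope["P_min"] | P > .co2_envelope["P_max"]
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(paste0("(T = %g K, P = %g bar) is outside the supported CO2 envelope ",
                        "290-350 K, 60-600 bar"), T[i], P[i]), call. = FALSE)
  }
}

.co2_density_one <- function(T, P) {
  Ppa <- P * 1e5
  if (T >= .co2$Tc) {
    lo <- 1e-4
    hi <- 1500
  } else if (Ppa >= .sw_psat(T)) {
    lo <- 0.999 * .sw_rholiq(T)   # liquid branch
    hi <- 1500
  } else {
    lo <- 1e-4                    # vapour branch
    hi <- 1.001 * .sw_rhovap(T)
  }
  uniroot(function(r) .sw_pressure(r, T) - Ppa, c(lo, hi),
          tol = 1e-11, maxiter = 1000)$root
}

#' CO2 mass density from a reference-quality equation of state
#'
#' Evaluates the Span-Wagner multiparameter Helmholtz equation of state for
#' pure carbon dioxide and solves it for mass density at the requested state
#' points. The supported envelope, 290-350 K and 60-600 bar, covers the
#' supercritical working region of drug-solubility measurements with margin.
#'
#' @param T temperature in kelvin (vectorised).
#' @param P pressure in bar (vectorised, recycled against `T`).
#' @return mass density in kg m^-3.
#' @examples
#' co2_density(308.15, 120)
#' co2_density(c(308.15, 318.15), 200)
#' @seealso [co2_state()] for the bundled mass/molar state.
#' @export
co2_density <- function(T, P) {
  n <- max(length(T), length(P))
  T <- rep_len(as.numeric(T), n)
  P <- rep_len(as.numeric(P), n)
  if (any(!is.finite(T)) || any(!is.finite(P)))
    stop("T and P must be finite numbers", call. = FALSE)
  .co2_check_envelope(T, P)
  vapply(seq_len(n), function(i) .co2_density_one(T[i], P[i]), numeric(1))
}

#' CO2 state bundle at given temperature and pressure
#'
#' @inheritParams co2_density
#' @return a data frame with one row per state: `T` (K), `P` (bar),
#'   `rho_mass` (kg m^-3) and `rho_molar` (kmol m^-3, equal to
#'   `rho_mass / 44.01` by construction).
#' @examples
#' co2_state(308.15, c(120, 200, 400))
#' @export
co2_state <- function(T, P) {
  n <- max(length(T), length(P))
  T <- rep_len(as.numeric(T), n)
  P <- rep_len(as.numeric(P), n)
  rho <- co2_density(T, P)
  data.frame(T = T, P = P, rho_mass = rho, rho_molar = rho / .co2$M)
}
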