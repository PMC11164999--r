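# Shared fixtures: CO2 states are the expensive ingredient, so the packaged
# table and the standard synthetic grid are resolved once per session.

.fixture_env <- new.env(parent = emptyenv())

.memo <- function(name, make) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- make()
  .fixture_env[[name]]
}

lumi_table <- function() .memo("lumi", lumiracoxib_data)
lumi_states <- function() .memo("lumi_states", function() {
  tab <- lumi_table()
  co2_state(tab$T_K, tab$P_bar)
})

# full 4 x 8 grid (no dropout), used by the synthetic-data studies
grid_df <- function() expand.grid(P_bar = seq(120, 400, 40),
                                  T_K = c(308.15, 318.15, 328.15, 338.15))[c(2, 1)]
grid_states <- function() .memo("grid_states", function() {
  g <- grid_df()
  co2_state(g$T_K, g$P_bar)
})

# generating parameters of the same magnitude as the measured surface
true_params <- list(
  chrastil = c(a = -24.3, b = -3155, c = 5.09),
  mst      = c(a = -7892, b = 13.68, c = 3.03),
  kj       = c(a = -2.98, b = -3198, c = 0.2323),
  bartle   = c(a = 12.55, b = -5399, c = 0.009431),
  modified_chrastil = c(a = -63.97, b = -1603, c = 5.13))

toy_table <- function() {
  # two isotherms x three pressures, smooth but not on any model surface
  solubility_table(data.frame(
    T_K = rep(c(308.15, 328.15), each = 3),
    P_bar = rep(c(160, 240, 320), 2),
    y2 = c(1.1e-4, 1.7e-4, 2.2e-4, 0.9e-4, 1.9e-4, 2.6e-4)),
    solute_name = "toy", M_solute = 293.72)
}

synthetic_drug_props <- function()
  solute_props(293.72, 768.76, 18.18, 0.9875, 215,
               psub_A = 10.70, psub_B = 5426.5)

er_co2_pures <- function(T)
  list(er_pure_params(304.1282, 73.773, 0.22394, T),
       er_pure_params(768.76, 18.18, 0.9875, T))

# independent fugacity oracle: ln phi_i = int_V^inf [dP/dn_i/(RT) - 1/V] dV
# - ln Z, with dP/dn_i by finite differences of the mixture pressure and the
# integral by trapezoid under the substitution V = v/t
quad_lnphi <- function(i, y, T, P, pures, kij, lij, npts = 8000) {
  R <- 8.314
  mix <- er_mixture_params(y, pures, kij, lij)
  v <- er_volume_roots(T, P, mix)[1]
  Pmix <- function(n, V) {
    ntot <- sum(n)
    m <- er_mixture_params(n / ntot, pures, kij, lij)
    er_pressure(T, V / ntot, m) * 1e5
  }
  Z <- P * 1e5 * v / (R * T)
  hh <- 1e-6
  dPdni <- function(V) {
    n1 <- y; n1[i] <- n1[i] + hh
    n2 <- y; n2[i] <- n2[i] - hh
    (Pmix(n1, V) - Pmix(n2, V)) / (2 * hh)
  }
  t <- seq(1e-9, 1, length.out = npts)
  f <- vapply(t, function(tt) {
    V <- v / tt
    (dPdni(V) / (R * T) - 1 / V) * v / tt^2
  }, numeric(1))
  sum((f[-1] + f[-npts]) / 2 * diff(t)) - log(Z)
}
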