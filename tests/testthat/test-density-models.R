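# The shared regression engine behind the four log-linear correlations, the
# GA-fitted modified Chrastil form, prediction and enthalpy extraction.

test_that("refits of the measured lumiracoxib table are stable (regression)", {
  tab <- lumi_table()
  st <- lumi_states()
  frozen <- c(chrastil = 7.875624, mst = 9.474853, kj = 6.786164,
              bartle = 10.851935)
  for (m in names(frozen)) {
    f <- fit_solubility(tab, m, st)
    expect_equal(f$stats$aard_pct, frozen[[m]], tolerance = 1e-6)
    # self-consistency of the reported statistics with predict()
    expect_equal(fit_statistics(tab$y2, predict(f))$aard_pct, f$stats$aard_pct)
  }
  # byte-identical across runs: the least-squares path is deterministic
  f1 <- fit_solubility(tab, "chrastil", st)
  f2 <- fit_solubility(tab, "chrastil", st)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$stats, f2$stats)
})

test_that("pooled fits equal an explicit normal-equations oracle", {
  tab <- toy_table()
  st <- co2_state(tab$T_K, tab$P_bar)
  # oracle: solve X'X beta = X'z directly, no lm
  ne <- function(z, x1, x2) {
    X <- cbind(1, x1, x2)
    unname(drop(solve(crossprod(X), crossprod(X, z))))
  }
  f <- fit_solubility(tab, "kj", st, method = "pooled")
  expect_equal(unname(coef(f)),
               ne(log(tab$y2), 1 / tab$T_K, st$rho_molar), tolerance = 1e-10)
  f <- fit_solubility(tab, "mst", st, method = "pooled")
  expect_equal(unname(coef(f)),
               ne(tab$T_K * log(tab$y2 * tab$P_bar), tab$T_K, st$rho_mass),
               tolerance = 1e-10)
  f <- fit_solubility(tab, "chrastil", st, method = "pooled")
  s <- mass_concentration(tab$y2, st$rho_mass, 293.72)
  expect_equal(unname(coef(f)),
               ne(log(s), 1 / tab$T_K, log(st$rho_mass)), tolerance = 1e-10)
})

test_that("the two-stage fit equals a spreadsheet-style oracle", {
  tab <- toy_table()
  st <- co2_state(tab$T_K, tab$P_bar)
  z <- log(tab$y2 * tab$P_bar)
  x <- st$rho_mass - 700
  # hand-computed per-isotherm slope = cov/var, then intercepts at the mean
  # slope regressed on 1/T via the closed two-point formulas
  i1 <- tab$T_K == 308.15; i2 <- tab$T_K == 328.15
  sl <- function(i) sum((x[i] - mean(x[i])) * (z[i] - mean(z[i]))) /
    sum((x[i] - mean(x[i]))^2)
  cb <- (sl(i1) + sl(i2)) / 2
  int1 <- mean(z[i1] - cb * x[i1]); int2 <- mean(z[i2] - cb * x[i2])
  t1 <- 1 / 308.15; t2 <- 1 / 328.15
  b <- (int1 - int2) / (t1 - t2)
  a <- int1 - b * t1
  f <- fit_solubility(tab, "bartle", st)
  expect_equal(unname(coef(f)), c(a, b, cb), tolerance = 1e-10)
  expect_equal(f$meta$isotherm_slopes, c(sl(i1), sl(i2)), tolerance = 1e-10)
})

test_that("noise-free synthetic surfaces regenerate their true parameters", {
  st <- grid_states()
  for (m in names(true_params)) {
    g <- generate_table(m, true_params[[m]], noise_cv = 0, dropout = NULL,
                        states = st)
    f <- suppressWarnings(
      fit_solubility(g$table, m, states = st, control = list(seed = 3)))
    expect_lt(max(abs(coef(f) - true_params[[m]]) / abs(true_params[[m]])), 1e-6)
    expect_lt(f$stats$aard_pct, 1e-8)
    # pooled and average-slope agree exactly on-model
    if (m != "modified_chrastil") {
      fp <- suppressWarnings(fit_solubility(g$table, m, states = st,
                                            method = "pooled"))
      expect_equal(coef(fp), coef(f), tolerance = 1e-8)
    }
  }
})

test_that("a common true slope across isotherms is recovered exactly", {
  st <- grid_states()
  g <- generate_table("bartle", true_params$bartle, noise_cv = 0,
                      dropout = NULL, states = st)
  f <- fit_solubility(g$table, "bartle", states = st)
  expect_equal(unname(f$meta$isotherm_slopes),
               rep(true_params$bartle[["c"]], 4), tolerance = 1e-10)
})

test_that("the GA fit of the association-equilibrium form is seed-reproducible", {
  st <- grid_states()
  g <- generate_table("modified_chrastil", true_params$modified_chrastil,
                      noise_cv = 0.05, seed = 11, dropout = NULL, states = st)
  f1 <- fit_solubility(g$table, "modified_chrastil", states = st,
                       control = list(seed = 4))
  f2 <- fit_solubility(g$table, "modified_chrastil", states = st,
                       control = list(seed = 4))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$meta$seed, 4)
})

test_that("rescaling the density units shifts only the fitted a", {
  tab <- lumi_table()
  st <- lumi_states()
  f <- fit_solubility(tab, "modified_chrastil", st, control = list(seed = 1))
  cf <- coef(f)
  # same surface with D in g/cm3: a compensates by (c - 1) ln(1000)
  st2 <- st
  st2$rho_mass <- st$rho_mass / 1000
  cf2 <- cf
  cf2[["a"]] <- cf[["a"]] + (cf[["c"]] - 1) * log(1000)
  y1 <- scsolub:::.predict_model("modified_chrastil", cf, tab$T_K, tab$P_bar,
                                 st, 293.72)
  y2 <- scsolub:::.predict_model("modified_chrastil", cf2, tab$T_K, tab$P_bar,
                                 st2, 293.72)
  expect_equal(y2, y1, tolerance = 1e-12)
})

test_that("predictions behave physically", {
  tab <- lumi_table()
  st <- lumi_states()
  # published Bartle parameters at (308.15 K, 120 bar) land near the datum
  y <- exp(12.59 - 5426.5 / 308.15 + 0.009525 * (st$rho_mass[1] - 700)) / 120
  expect_lt(abs(log(y / 8.81e-5)), log(1.3))
  # Chrastil with c > 0: solubility rises with density along an isotherm
  f <- fit_solubility(tab, "chrastil", st)
  iso <- tab$T_K == 308.15
  expect_true(all(diff(predict(f)[iso][order(st$rho_mass[iso])]) > 0))
  expect_true(all(predict(f) > 0))
})

test_that("enthalpies follow from the reciprocal-temperature coefficients", {
  mk <- function(model, b) {
    structure(list(model = model, coefficients = c(a = 1, b = b, c = 1)),
              class = "solufit")
  }
  e <- enthalpies(mk("chrastil", -3165), mk("bartle", -5426.5))
  expect_equal(e$dH_total, 8.314 * 3165 / 1000, tolerance = 1e-10)   # 26.31
  expect_equal(e$dH_vaporization, 45.116, tolerance = 1e-3)
  expect_identical(e$dH_solvation, e$dH_total - e$dH_vaporization)
  expect_identical(enthalpies(mk("chrastil", 0), mk("bartle", 0))$dH_total, 0)
})

test_that("degenerate designs raise fitting errors", {
  one_t <- solubility_table(data.frame(
    T_K = 308.15, P_bar = c(120, 200, 280, 360),
    y2 = c(1e-4, 1.5e-4, 2e-4, 2.5e-4)), "toy", 293.72)
  expect_error(fit_solubility(one_t, "chrastil"), "2 temperatures")
  two_pt <- solubility_table(data.frame(
    T_K = rep(c(308.15, 328.15), c(2, 3)),
    P_bar = c(120, 200, 120, 200, 280),
    y2 = c(1e-4, 1.5e-4, 0.8e-4, 1.6e-4, 2.1e-4)), "toy", 293.72)
  expect_error(fit_solubility(two_pt, "bartle"), "308.15 K.*fewer than 3")
})
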