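test_that("the staged GA reaches benchmark floors", {
  sphere <- function(X) rowSums(X^2)
  g <- ga_staged(sphere, rep(-5, 3), rep(5, 3),
                 control = ga_control(seed = 7), vectorized = TRUE)
  expect_lt(g$value, 1e-6)
  # multimodal floor across seeds
  rastrigin <- function(X) rowSums(X^2 - 10 * cos(2 * pi * X) + 10)
  vals <- vapply(1:10, function(s)
    ga_staged(rastrigin, rep(-5.12, 3), rep(5.12, 3),
              control = ga_control(seed = s), vectorized = TRUE)$value,
    numeric(1))
  expect_lt(max(vals), 1.0)
})

test_that("staged narrowing never expands past the original bounds", {
  g <- ga_staged(function(X) rowSums(X^2), c(-5, -5), c(5, 5),
                 control = ga_control(seed = 2), vectorized = TRUE)
  for (bh in g$bounds_history) {
    expect_true(all(bh[, "lower"] >= -5 - 1e-12))
    expect_true(all(bh[, "upper"] <= 5 + 1e-12))
  }
  # later stages are nested in the first
  expect_true(all(g$bounds_history[[2]][, "lower"] >=
                    g$bounds_history[[1]][, "lower"]))
  expect_true(all(g$bounds_history[[2]][, "upper"] <=
                    g$bounds_history[[1]][, "upper"]))
  expect_equal(nrow(g$trace), 3 * 5)   # stages x restarts
})

test_that("every evaluated candidate respects its bounds", {
  seen <- new.env(); seen$bad <- 0L
  lo <- c(-2, 0.5); up <- c(1, 3)
  fn <- function(X) {
    if (any(X < rep(lo, each = nrow(X)) - 1e-12) ||
        any(X > rep(up, each = nrow(X)) + 1e-12))
      seen$bad <- seen$bad + 1L
    rowSums((X - 0.7)^2)
  }
  ga_staged(fn, lo, up, control = ga_control(seed = 5, n_stages = 2,
                                             restarts_per_stage = 2,
                                             gen_range = c(100, 150)),
            vectorized = TRUE)
  fn2 <- function(p) {
    if (any(p < lo - 1e-12) || any(p > up + 1e-12)) seen$bad <- seen$bad + 1L
    sum((p - 0.7)^2)
  }
  de_minimize(fn2, lo, up, control = de_control(seed = 5, max_generations = 50))
  expect_identical(seen$bad, 0L)
})

test_that("identical seeds give identical runs, and traces are monotone", {
  fn <- function(X) rowSums(X^2)
  g1 <- ga_staged(fn, rep(-1, 2), rep(1, 2), ga_control(seed = 9), vectorized = TRUE)
  g2 <- ga_staged(fn, rep(-1, 2), rep(1, 2), ga_control(seed = 9), vectorized = TRUE)
  expect_identical(g1$trace, g2$trace)
  expect_identical(g1$par, g2$par)
  d1 <- de_minimize(function(p) sum(p^2), rep(-1, 2), rep(1, 2), de_control(seed = 9))
  d2 <- de_minimize(function(p) sum(p^2), rep(-1, 2), rep(1, 2), de_control(seed = 9))
  expect_identical(d1$trace, d2$trace)
  expect_true(all(diff(d1$trace) <= 0))
  # the caller's RNG stream is untouched
  set.seed(123); r1 <- runif(1)
  set.seed(123); invisible(de_minimize(function(p) sum(p^2), -1, 1, de_control(seed = 1)))
  expect_identical(runif(1), r1)
})

test_that("differential evolution reaches benchmark floors", {
  d <- de_minimize(function(p) sum(p^2), rep(-5, 3), rep(5, 3),
                   control = de_control(seed = 2))
  expect_lt(d$value, 1e-8)
  rosen <- function(p) 100 * (p[2] - p[1]^2)^2 + (1 - p[1])^2
  d2 <- de_minimize(rosen, c(-2, -2), c(2, 2),
                    control = de_control(seed = 3, pop_size = 40,
                                         max_generations = 200))
  expect_lt(d2$value, 1e-4)
})

test_that("invalid objectives and bounds are rejected", {
  expect_error(ga_staged(function(X) rep(NaN, nrow(X)), -1, 1,
                         ga_control(seed = 1, n_stages = 1,
                                    restarts_per_stage = 1), vectorized = TRUE),
               "NaN")
  expect_error(de_minimize(function(p) NaN, -1, 1, de_control(seed = 1)), "NaN")
  expect_error(ga_staged(function(X) rowSums(X), c(0, 0), c(0, 1),
                         ga_control(seed = 1)), "upper > lower")
})
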