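# Bounded global minimisers: a staged range-narrowing real-coded GA and
# classic rand/1/bin differential evolution, both seeded and traceable.

# draw one integer uniformly from [a, b] (safe for a == b)
.sample_range <- function(a, b) if (a >= b) as.integer(a) else sample(seq.int(a, b), 1)

# run fn with a private RNG stream so callers' RNG state is untouched
.with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  fn()
}

#' Control settings for the staged genetic algorithm
#'
#' Defaults follow common real-coded GA practice: tournament selection
#' (k = 3), blend (BLX-alpha) crossover, Gaussian mutation with a standard
#' deviation of 10% of each parameter's current range, and one elite
#' individual per generation. Population sizes and generation counts are
#' drawn uniformly from `pop_range` and `gen_range` for every restart;
#' after each stage the search box shrinks to the envelope of the restart
#' optima (never expanding past the original bounds).
#'
#' @param pop_range integer interval the population size is drawn from.
#' @param gen_range integer interval the generation budget is drawn from.
#' @param n_stages number of range-narrowing stages.
#' @param restarts_per_stage independent GA runs per stage.
#' @param seed integer seed; the whole run is reproducible given it.
#' @param elitism number of elites copied unchanged.
#' @param tournament_k tournament size.
#' @param p_crossover crossover probability.
#' @param blend_alpha BLX-alpha expansion factor.
#' @param mut_sigma_frac mutation standard deviation as a fraction of range.
#' @param p_mutation per-gene mutation probability (default 1/dimension).
#' @param stagnation_gens,stagnation_tol stop a run early when the best value
#'   improves by less than `stagnation_tol` over `stagnation_gens`
#'   consecutive generations.
#' @return a list of class `ga_control`.
#' @export
ga_control <- function(pop_range = c(20L, 100L), gen_range = c(100L, 1000L),
                       n_stages = 3L, restarts_per_stage = 5L, seed = 1L,
                       elitism = 1L, tournament_k = 3L, p_crossover = 0.9,
                       blend_alpha = 0.5, mut_sigma_frac = 0.1,
                       p_mutation = NULL,
                       stagnation_gens = 50L, stagnation_tol = 1e-10) {
  stopifnot(pop_range[1] >= 20, pop_range[2] >= pop_range[1],
            gen_range[2] >= gen_range[1], n_stages >= 1, restarts_per_stage >= 1)
  structure(as.list(environment()), class = "ga_control")
}

.ga_run <- function(fn, lower, upper, pop, gens, ctrl) {
  d <- length(lower)
  pmut <- ctrl$p_mutation %||% (1 / d)
  X <- matrix(stats::runif(pop * d, rep(lower, each = pop), rep(upper, each = pop)),
              nrow = pop)
  f <- fn(X)
  best_hist <- numeric(gens)
  for (g in seq_len(gens)) {
    ord <- order(f)
    elite <- X[ord[seq_len(ctrl$elitism)], , drop = FALSE]
    # tournament selection of 2*(pop - elitism) parents
    nkids <- pop - ctrl$elitism
    pick <- function(n) {
      idx <- matrix(sample.int(pop, n * ctrl$tournament_k, replace = TRUE),
                    nrow = n)
      idx[cbind(seq_len(n), max.col(-matrix(f[idx], nrow = n)))]
    }
    p1 <- pick(nkids); p2 <- pick(nkids)
    A <- X[p1, , drop = FALSE]; B <- X[p2, , drop = FALSE]
    # BLX-alpha blend crossover
    do_x <- stats::runif(nkids) < ctrl$p_crossover
    lo <- pmin(A, B); hi <- pmax(A, B); span <- hi - lo
    kids <- matrix(stats::runif(nkids * d,
                                lo - ctrl$blend_alpha * span,
                                hi + ctrl$blend_alpha * span), nrow = nkids)
    kids[!do_x, ] <- A[!do_x, , drop = FALSE]
    # Gaussian mutation, sigma = fraction of box range
    sig <- ctrl$mut_sigma_frac * (upper - lower)
    mut <- matrix(stats::runif(nkids * d) < pmut, nrow = nkids)
    noise <- matrix(stats::rnorm(nkids * d, 0, rep(sig, each = nkids)), nrow = nkids)
    kids <- kids + mut * noise
    # clip into the box
    kids <- pmin(pmax(kids, rep(lower, each = nkids)), rep(upper, each = nkids))
    X <- rbind(elite, kids)
    f <- fn(X)
    best_hist[g] <- min(f)
    if (g > ctrl$stagnation_gens &&
        best_hist[g - ctrl$stagnation_gens] - best_hist[g] < ctrl$stagnation_tol) {
      best_hist <- best_hist[seq_len(g)]
      break
    }
  }
  i <- which.min(f)
  list(par = X[i, ], value = f[i], generations = length(best_hist))
}

#' Staged range-narrowing genetic-algorithm minimisation
#'
#' Runs several independently seeded GA instances over the initial box; each
#' subsequent stage restricts the box to the envelope (componentwise min and
#' max) of the previous stage's restart optima and repeats, so the search
#' progressively concentrates around the consensus region. Population size
#' and generation budget are redrawn from their configured ranges for every
#' restart.
#'
#' @param fn objective to minimise. With `vectorized = TRUE`, `fn` receives a
#'   matrix whose rows are candidates and must return one value per row;
#'   otherwise it receives a single parameter vector.
#' @param lower,upper finite bounds, one per parameter.
#' @param control a [ga_control()].
#' @param vectorized whether `fn` is matrix-vectorised.
#' @return list with `par`, `value`, `trace` (one row per restart: stage,
#'   restart, population, generations used, best value) and `bounds_history`.
#' @examples
#' sphere <- function(X) rowSums(X^2)
#' ga_staged(sphere, c(-5, -5, -5), c(5, 5, 5),
#'           control = ga_control(seed = 7, gen_range = c(100, 200)),
#'           vectorized = TRUE)$value
#' @export
ga_staged <- function(fn, lower, upper, control = ga_control(),
                      vectorized = FALSE) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(upper > lower))
  if (!vectorized) {
    fn_raw <- fn
    fn <- function(X) apply(X, 1, fn_raw)
  }
  fn_checked <- function(X) {
    v <- fn(X)
    if (any(is.na(v))) stop("objective returned NaN/NA", call. = FALSE)
    v
  }
  lower0 <- lower; upper0 <- upper
  .with_seed(control$seed, function() {
    trace <- NULL
    bounds_hist <- list()
    best <- NULL
    lo <- lower0; up <- upper0
    for (stage in seq_len(control$n_stages)) {
      bounds_hist[[stage]] <- cbind(lower = lo, upper = up)
      optima <- matrix(NA_real_, control$restarts_per_stage, length(lo))
      for (r in seq_len(control$restarts_per_stage)) {
        pop <- .sample_range(control$pop_range[1], control$pop_range[2])
        gens <- .sample_range(control$gen_range[1], control$gen_range[2])
        run <- .ga_run(fn_checked, lo, up, pop, gens, control)
        optima[r, ] <- run$par
        trace <- rbind(trace, data.frame(stage = stage, restart = r, pop = pop,
                                         gens = gens, used = run$generations,
                                         value = run$value))
        if (is.null(best) || run$value < best$value) best <- run
      }
      # narrow to the envelope of this stage's optima, never expanding
      lo <- pmax(apply(optima, 2, min), lower0)
      up <- pmin(apply(optima, 2, max), upper0)
      fix <- up - lo < 1e-12 * (upper0 - lower0)
      if (any(fix)) {  # reopen collapsed dimensions a little
        pad <- 1e-6 * (upper0 - lower0)
        lo[fix] <- pmax(lo[fix] - pad[fix], lower0[fix])
        up[fix] <- pmin(up[fix] + pad[fix], upper0[fix])
      }
    }
    list(par = best$par, value = best$value, trace = trace,
         bounds_history = bounds_hist)
  })
}

#' Control settings for differential evolution
#'
#' @param pop_size population size (default 15 x dimension, set when `NULL`).
#' @param max_generations generation budget.
#' @param F differential weight in (0, 2].
#' @param CR crossover probability in \[0, 1\].
#' @param seed integer seed.
#' @param stagnation_gens,stagnation_tol early-stopping rule as in
#'   [ga_control()].
#' @return a list of class `de_control`.
#' @export
de_control <- function(pop_size = NULL, max_generations = 200L, F = 0.7,
                       CR = 0.9, seed = 1L,
                       stagnation_gens = 50L, stagnation_tol = 1e-10) {
  stopifnot(F > 0, F <= 2, CR >= 0, CR <= 1)
  structure(as.list(environment()), class = "de_control")
}

#' Differential-evolution minimisation (rand/1/bin)
#'
#' Classic Storn-Price differential evolution: each target vector is
#' perturbed by the weighted difference of two randomly chosen population
#' members added to a third, mixed with the target by binomial crossover,
#' and the trial replaces the target only if it is at least as good
#' (one-to-one selection).
#'
#' @inheritParams ga_staged
#' @param control a [de_control()].
#' @return list with `par`, `value` and `trace` (best value per generation).
#' @examples
#' rosen <- function(p) 100 * (p[2] - p[1]^2)^2 + (1 - p[1])^2
#' de_minimize(rosen, c(-2, -2), c(2, 2),
#'             control = de_control(seed = 3, pop_size = 40))$value
#' @export
de_minimize <- function(fn, lower, upper, control = de_control(),
                        vectorized = FALSE) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(upper > lower))
  d <- length(lower)
  np <- control$pop_size %||% (15L * d)
  if (np < 4) np <- 4L
  if (!vectorized) {
    fn_raw <- fn
    fn <- function(X) apply(X, 1, fn_raw)
  }
  .with_seed(control$seed, function() {
    X <- matrix(stats::runif(np * d, rep(lower, each = np), rep(upper, each = np)),
                nrow = np)
    f <- fn(X)
    if (any(is.na(f))) stop("objective returned NaN/NA", call. = FALSE)
    trace <- numeric(0)
    for (g in seq_len(control$max_generations)) {
      trial <- X
      for (i in seq_len(np)) {
        r <- sample(setdiff(seq_len(np), i), 3)
        v <- X[r[1], ] + control$F * (X[r[2], ] - X[r[3], ])
        v <- pmin(pmax(v, lower), upper)
        jrand <- sample.int(d, 1)
        cross <- stats::runif(d) < control$CR
        cross[jrand] <- TRUE
        trial[i, cross] <- v[cross]
      }
      ft <- fn(trial)
      if (any(is.na(ft))) stop("objective returned NaN/NA", call. = FALSE)
      better <- ft <= f
      X[better, ] <- trial[better, , drop = FALSE]
      f[better] <- ft[better]
      trace[g] <- min(f)
      if (g > control$stagnation_gens &&
          trace[g - control$stagnation_gens] - trace[g] < control$stagnation_tol)
        break
    }
    i <- which.min(f)
    list(par = X[i, ], value = f[i], trace = trace)
  })
}
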