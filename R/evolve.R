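#' Selection gradient on the dominant's paternity share
#'
#' Derivative of the dominant's brood-share payoff `(1 - c) f*(c)` with
#' respect to `c` for interior parameters: `(1 - 2c) / (2 wbar p)`.
#' Positive below the equilibrium share 1/2, zero at it, negative above —
#' selection pushes the share toward 1/2 from either side.
#'
#' @inheritParams beta_best_response
#' @return Gradient (fitness per unit share), same length as `c`.
#' @examples
#' selection_gradient(skew_params(1, 1), c = c(0.25, 0.5, 0.75))
#' @export
selection_gradient <- function(params, c) {
  params <- as_skew_params(params)
  check_unit_interval(c, "c")
  (1 - 2 * c) / (2 * params$wbar * params$p)
}

#' Deterministic adaptive dynamics of the paternity share
#'
#' Euler integration of `dc/dt = selection_gradient(c)` clamped to
#' `[0, 1]`. For interior parameters the flow has the closed-form solution
#' `1/2 + (c0 - 1/2) exp(-t / (wbar p))` and converges monotonically to the
#' equilibrium share 1/2.
#'
#' @inheritParams mortality_hazard
#' @param c0 Initial share in `[0, 1]`.
#' @param step Euler time step, `> 0`. Default 0.1.
#' @param steps Number of steps. Default 2000.
#' @return A tibble with columns `time` and `c` (`steps + 1` rows,
#'   including the initial state).
#' @examples
#' traj <- adaptive_dynamics(skew_params(1, 1), c0 = 0.1)
#' tail(traj, 1)
#' @export
adaptive_dynamics <- function(params, c0, step = 0.1, steps = 2000L) {
  params <- as_skew_params(params)
  check_unit_interval(c0, "c0")
  if (!is.numeric(step) || step <= 0) stop("`step` must be > 0.", call. = FALSE)
  stopifnot(steps >= 1L)
  cc <- numeric(steps + 1L)
  cc[1L] <- c0
  for (i in seq_len(steps)) {
    cc[i + 1L] <- min(1, max(0, cc[i] + step * selection_gradient(params, cc[i])))
  }
  tibble::tibble(time = step * (0:steps), c = cc)
}

#' Simulation configuration for the Wright-Fisher trait model
#'
#' @param population_size Number of dominant territories (and, when
#'   coevolving, of subordinate lineages), `>= 2`. Default 500.
#' @param generations Number of generations to simulate, `>= 1`.
#'   Default 300.
#' @param mutation_rate Per-birth probability of a trait mutation.
#'   Default 0.05.
#' @param mutation_sd Standard deviation of the Gaussian trait perturbation,
#'   `> 0` (set `mutation_sd` tiny and `mutation_rate = 0` for a
#'   mutation-free run). Default 0.02.
#' @param initial_c_mean,initial_c_sd Mean and spread of the founding
#'   population's paternity-share trait. Defaults 0.2 and 0.02.
#' @param coevolve_beta Also evolve the subordinates' feeding reaction norm
#'   `f = min(a * c, 1)` (one heritable slope `a` per lineage)?
#'   Default `FALSE`.
#' @param initial_a_mean Mean founding reaction-norm slope (only used when
#'   coevolving). Default 0.2.
#' @param seed Integer seed; required, no silent default.
#' @return A list of class `skew_sim_config`.
#' @export
sim_config <- function(population_size = 500L, generations = 300L,
                       mutation_rate = 0.05, mutation_sd = 0.02,
                       initial_c_mean = 0.2, initial_c_sd = 0.02,
                       coevolve_beta = FALSE, initial_a_mean = 0.2,
                       seed) {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required: stochastic runs must be reproducible.", call. = FALSE)
  }
  stopifnot(
    population_size >= 2L, generations >= 1L,
    mutation_rate >= 0, mutation_rate <= 1,
    mutation_sd > 0, initial_c_sd >= 0
  )
  structure(
    list(
      population_size = as.integer(population_size),
      generations = as.integer(generations),
      mutation_rate = mutation_rate, mutation_sd = mutation_sd,
      initial_c_mean = initial_c_mean, initial_c_sd = initial_c_sd,
      coevolve_beta = isTRUE(coevolve_beta), initial_a_mean = initial_a_mean,
      seed = as.integer(seed)
    ),
    class = "skew_sim_config"
  )
}

# reflect values into [lo, hi] (single reflection is enough for the small
# mutation kernels used; iterate to be safe)
reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  while (any(x < lo | x > hi)) {
    x <- ifelse(x < lo, 2 * lo - x, x)
    x <- ifelse(x > hi, 2 * hi - x, x)
  }
  x
}

#' Wright-Fisher mutation-selection simulation of the skew game
#'
#' Each generation, every dominant `i` with heritable paternity-share trait
#' `c_i` interacts with a subordinate who feeds at the best response
#' `f*(c_i)` (or, when coevolving, at `min(a_j c_i, 1)` given the
#' subordinate lineage's heritable slope `a_j`, with lineages paired to
#' territories uniformly at random). Per-period fitnesses — dominant
#' `W_beta + W_alpha`, subordinate `w` — are floored at 0 and used as
#' sampling weights for fitness-proportional (Wright-Fisher) reproduction.
#' Offspring traits mutate with probability `mutation_rate` by a
#' zero-mean Gaussian of sd `mutation_sd`, reflected into the trait range
#' (`[0, 1]` for `c`; `[0, 1/(wbar p)]` for the slope `a`, whose
#' best-response target is `1/(2 wbar p)`).
#'
#' The long-run population mean of `c` recovers the analytic equilibrium
#' share 1/2 (interior parameters), and the mean slope recovers
#' `1/(2 wbar p)` — the dynamic counterpart of the ESS claim.
#'
#' @inheritParams mortality_hazard
#' @param config A [sim_config()] object.
#' @return A tibble of class `skew_trajectory` with one row per generation
#'   (including generation 0): `generation`, `mean_c`, `sd_c`, `mean_a`
#'   (`NA` unless coevolving), `mean_alpha_fitness`, `mean_beta_fitness`,
#'   `gini` (population fitness Gini over all males). The config is
#'   attached as attribute `config`.
#' @examples
#' cfg <- sim_config(population_size = 100, generations = 50, seed = 1)
#' traj <- simulate_evolution(skew_params(1, 1), cfg)
#' tail(traj, 2)
#' @export
simulate_evolution <- function(params, config) {
  params <- as_skew_params(params)
  if (!inherits(config, "skew_sim_config")) {
    stop("`config` must be built with sim_config().", call. = FALSE)
  }
  N <- config$population_size
  G <- config$generations
  own <- alpha_own_brood_optimum(params)
  a_max <- 1 / (params$wbar * params$p)

  set.seed(config$seed)
  c_pop <- reflect_into(
    stats::rnorm(N, config$initial_c_mean, config$initial_c_sd), 0, 1
  )
  a_pop <- if (config$coevolve_beta) {
    reflect_into(stats::rnorm(N, config$initial_a_mean, config$initial_c_sd), 0, a_max)
  } else NULL

  rec <- vector("list", G + 1L)
  record <- function(gen, c_pop, a_pop, w_alpha, w_beta) {
    tibble::tibble(
      generation = gen,
      mean_c = mean(c_pop), sd_c = stats::sd(c_pop),
      mean_a = if (is.null(a_pop)) NA_real_ else mean(a_pop),
      mean_alpha_fitness = mean(w_alpha), mean_beta_fitness = mean(w_beta),
      gini = gini_general(c(w_alpha, w_beta))$gini
    )
  }

  mutate_traits <- function(x, lo, hi) {
    hit <- stats::runif(length(x)) < config$mutation_rate
    if (any(hit)) {
      x[hit] <- x[hit] + stats::rnorm(sum(hit), 0, config$mutation_sd)
      x <- reflect_into(x, lo, hi)
    }
    x
  }

  for (gen in 0:G) {
    if (config$coevolve_beta) {
      pairing <- sample.int(N) # which Beta lineage sits on territory i
      f <- pmin(a_pop[pairing] * c_pop, 1)
    } else {
      f <- as.numeric(beta_best_response(params, c_pop))
    }
    w_beta <- beta_period_fitness(params, c_pop, f)
    w_alpha <- (1 - c_pop) * f + own$W_alpha
    fit_a <- pmax(w_alpha, 0)
    fit_b <- pmax(w_beta, 0)
    rec[[gen + 1L]] <- record(gen, c_pop, a_pop, pmax(w_alpha, 0), pmax(w_beta, 0))
    if (gen == G) break

    if (sum(fit_a) == 0 || (config$coevolve_beta && sum(fit_b) == 0)) {
      stop(sprintf("All fitnesses zero at generation %d; selection is undefined.", gen),
           call. = FALSE)
    }
    parents <- sample.int(N, N, replace = TRUE, prob = fit_a)
    c_pop <- mutate_traits(c_pop[parents], 0, 1)
    stopifnot(all(c_pop >= 0 & c_pop <= 1))
    if (config$coevolve_beta) {
      # Beta lineage j's fitness is what it earned on the territory it drew
      fit_lineage <- numeric(N)
      fit_lineage[pairing] <- fit_b
      b_parents <- sample.int(N, N, replace = TRUE, prob = fit_lineage)
      a_pop <- mutate_traits(a_pop[b_parents], 0, a_max)
    }
  }

  out <- dplyr::bind_rows(rec)
  class(out) <- c("skew_trajectory", class(out))
  attr(out, "config") <- config
  attr(out, "params") <- params
  out
}

#' Write a trajectory to a delimited file
#'
#' One comma-separated row per generation with the header
#' `generation, mean_c, sd_c, mean_a, mean_alpha_fitness,
#' mean_beta_fitness, gini`.
#'
#' @param trajectory A `skew_trajectory` tibble from [simulate_evolution()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}

#' Summarize an evolutionary trajectory
#'
#' @param x A `skew_trajectory` tibble.
#' @param ... Unused.
#' @param tail_fraction Fraction of final generations to average for the
#'   long-run summaries. Default 0.25.
#' @return One-row tibble: number of generations, long-run means of the
#'   paternity-share trait, reaction-norm slope and both fitnesses, and the
#'   analytic targets `c_target = 1/2`-equivalent and
#'   `a_target = 1/(2 wbar p)` for comparison.
#' @export
glance.skew_trajectory <- function(x, ..., tail_fraction = 0.25) {
  params <- attr(x, "params")
  keep <- x$generation >= stats::quantile(x$generation, 1 - tail_fraction)
  uncon <- unconstrained_equilibrium(params)
  tibble::tibble(
    generations = max(x$generation),
    longrun_mean_c = mean(x$mean_c[keep]),
    longrun_mean_a = mean(x$mean_a[keep]),
    longrun_alpha_fitness = mean(x$mean_alpha_fitness[keep]),
    longrun_beta_fitness = mean(x$mean_beta_fitness[keep]),
    c_target = uncon$c_star,
    a_target = 1 / (2 * params$wbar * params$p)
  )
}
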