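#' Grid-search best response (oracle)
#'
#' Brute-force argmax of [beta_period_fitness()] over an even grid on
#' `[0, 1]`, refined by three rounds of local grid zoom around the incumbent
#' maximizer. Ties break toward smaller effort. Used as an oracle for the
#' closed-form best response, never as the solver.
#'
#' @inheritParams beta_best_response
#' @param grid_points Points per grid pass, `>= 3`. Default 1001.
#' @param zoom_rounds Local refinement passes. Default 3.
#' @return Approximate best-response effort in `[0, 1]`.
#' @examples
#' grid_best_response(skew_params(1, 1), c = 0.5)
#' @export
grid_best_response <- function(params, c, grid_points = 1001L, zoom_rounds = 3L) {
  params <- as_skew_params(params)
  check_unit_interval(c, "c")
  stopifnot(grid_points >= 3L)
  lo <- 0; hi <- 1
  best <- 0
  for (round in seq_len(zoom_rounds + 1L)) {
    f <- seq(lo, hi, length.out = grid_points)
    vals <- beta_period_fitness(params, c, f)
    best <- f[which.max(vals)] # which.max takes the first (smallest f) tie
    step <- (hi - lo) / (grid_points - 1)
    lo <- max(0, best - step)
    hi <- min(1, best + step)
  }
  best
}

#' Verify a strategy profile is a Nash equilibrium by grid search
#'
#' Scans unilateral deviations on even grids: the dominant's paternity share
#' `c` (with the subordinate re-best-responding, respecting the sequential
#' first-mover structure), the subordinate's effort `f` (holding `c`
#' fixed), and the dominant's own-brood effort `F`. Reports the best gain
#' found on each axis; the profile passes when no gain exceeds `tolerance`.
#'
#' @inheritParams beta_best_response
#' @param profile Named list or one-row data frame with `c`, `f`, `F` in
#'   `[0, 1]`.
#' @param tolerance Fitness-gain tolerance for accepting the profile.
#'   Default `1e-7`.
#' @param grid_points Deviation-grid size per axis. Default 1001.
#' @return A list of class `skew_nash_report`: `is_nash` plus, per axis, the
#'   best deviating strategy and its fitness gain.
#' @examples
#' verify_nash(skew_params(1, 1), list(c = 0.5, f = 0.25, F = 0.5))
#' @export
verify_nash <- function(params, profile, tolerance = 1e-7, grid_points = 1001L) {
  params <- as_skew_params(params)
  c0 <- profile$c; f0 <- profile$f; F0 <- profile$F
  check_unit_interval(c0, "profile$c")
  check_unit_interval(f0, "profile$f")
  check_unit_interval(F0, "profile$F")
  grid <- seq(0, 1, length.out = grid_points)

  base_alpha <- (1 - c0) * f0 + F0 - params$wbar * params$p * F0^2
  base_beta <- beta_period_fitness(params, c0, f0)

  # Alpha deviates in c; Beta re-optimizes f (Alpha moves first)
  alpha_vals <- alpha_beta_brood_fitness(params, grid) +
    F0 - params$wbar * params$p * F0^2
  i <- which.max(alpha_vals)
  alpha_dev <- list(c = grid[i], gain = alpha_vals[i] - base_alpha)

  # Beta deviates in f holding c fixed
  beta_vals <- beta_period_fitness(params, c0, grid)
  i <- which.max(beta_vals)
  beta_dev <- list(f = grid[i], gain = beta_vals[i] - base_beta)

  # Alpha deviates in own-brood effort F alone
  own_vals <- (1 - c0) * f0 + grid - params$wbar * params$p * grid^2
  i <- which.max(own_vals)
  own_dev <- list(F = grid[i], gain = own_vals[i] - base_alpha)

  gains <- c(alpha_dev$gain, beta_dev$gain, own_dev$gain)
  structure(
    list(
      is_nash = all(gains <= tolerance),
      best_alpha_deviation = alpha_dev,
      best_beta_deviation = beta_dev,
      best_alpha_own_deviation = own_dev,
      grid_resolution = 1 / (grid_points - 1),
      tolerance = tolerance
    ),
    class = "skew_nash_report"
  )
}

#' @export
print.skew_nash_report <- function(x, ...) {
  cat("<skew_nash_report>  is_nash:", x$is_nash, "\n")
  cat(sprintf("  best c deviation: c = %.4g (gain %.3g)\n",
              x$best_alpha_deviation$c, x$best_alpha_deviation$gain))
  cat(sprintf("  best f deviation: f = %.4g (gain %.3g)\n",
              x$best_beta_deviation$f, x$best_beta_deviation$gain))
  cat(sprintf("  best F deviation: F = %.4g (gain %.3g)\n",
              x$best_alpha_own_deviation$F, x$best_alpha_own_deviation$gain))
  invisible(x)
}

#' Invasion fitness of a mutant dominant strategy
#'
#' Fitness differential `W_total(mutant) - W_total(resident)` for a rare
#' mutant dominant playing paternity share `mutant_c` in a resident
#' population playing `resident_c`, each subordinate best-responding to the
#' share he actually faces. Fitness depends only on the focal territory's
#' interaction, so rarity enters only through whom the mutant meets.
#' The interior equilibrium share 1/2 is an ESS: every mutant has negative
#' invasion fitness.
#'
#' @inheritParams mortality_hazard
#' @param resident_c,mutant_c Paternity shares in `[0, 1]`. `mutant_c` may
#'   be a vector.
#' @return Fitness differential(s).
#' @examples
#' invasion_fitness(skew_params(1, 1), resident_c = 0.5, mutant_c = 0.6)
#' @export
invasion_fitness <- function(params, resident_c, mutant_c) {
  params <- as_skew_params(params)
  check_unit_interval(resident_c, "resident_c")
  check_unit_interval(mutant_c, "mutant_c")
  own <- alpha_own_brood_optimum(params)
  (alpha_beta_brood_fitness(params, mutant_c) + own$W_alpha) -
    (alpha_beta_brood_fitness(params, resident_c) + own$W_alpha)
}

#' Search for a Pareto improvement over a strategy profile
#'
#' Scans the `(c, f)` grid (dominant's own-brood effort held at its
#' optimum) for allocations that give both males strictly higher fitness
#' than at the supplied profile; among improvements, returns the one
#' maximizing the smaller of the two gains. The fitness-maximizing
#' equilibrium always admits such an improvement (slightly more paternity
#' conceded, slightly more food provided) — it is not Pareto-efficient.
#'
#' @inheritParams beta_best_response
#' @param profile Named list with `c`, `f`, `F` in `[0, 1]`.
#' @param grid_points Grid size per axis. Default 201.
#' @return A list of class `skew_pareto_report`: `is_efficient`,
#'   `improving_allocation` (`c`, `f` or `NULL`) and `gains`
#'   (`beta_gain`, `alpha_gain` or `NULL`).
#' @examples
#' eq <- unconstrained_equilibrium(skew_params(1, 1))
#' find_pareto_improvement(skew_params(1, 1),
#'                         list(c = eq$c_star, f = eq$f_star, F = eq$F_star))
#' @export
find_pareto_improvement <- function(params, profile, grid_points = 201L) {
  params <- as_skew_params(params)
  c0 <- profile$c; f0 <- profile$f; F0 <- profile$F
  check_unit_interval(c0, "profile$c")
  check_unit_interval(f0, "profile$f")
  check_unit_interval(F0, "profile$F")
  own <- alpha_own_brood_optimum(params)

  base <- fitness_breakdown(params, c0, f0, F0)
  grid <- seq(0, 1, length.out = grid_points)
  cf <- tidyr::expand_grid(c = grid, f = grid)
  w <- beta_period_fitness(params, cf$c, cf$f)
  W <- (1 - cf$c) * cf$f + own$W_alpha
  beta_gain <- w - base$w
  alpha_gain <- W - base$W_total
  improving <- beta_gain > 0 & alpha_gain > 0

  if (!any(improving)) {
    report <- list(is_efficient = TRUE, improving_allocation = NULL, gains = NULL)
  } else {
    min_gain <- pmin(beta_gain, alpha_gain)
    min_gain[!improving] <- -Inf
    i <- which.max(min_gain)
    report <- list(
      is_efficient = FALSE,
      improving_allocation = list(c = cf$c[i], f = cf$f[i]),
      gains = list(beta_gain = beta_gain[i], alpha_gain = alpha_gain[i])
    )
  }
  structure(report, class = "skew_pareto_report")
}

#' @export
print.skew_pareto_report <- function(x, ...) {
  cat("<skew_pareto_report>  is_efficient:", x$is_efficient, "\n")
  if (!x$is_efficient) {
    cat(sprintf("  improvement at (c = %.4g, f = %.4g): Beta +%.3g, Alpha +%.3g\n",
                x$improving_allocation$c, x$improving_allocation$f,
                x$gains$beta_gain, x$gains$alpha_gain))
  }
  invisible(x)
}

#' Maximize joint total fitness over the paternity share
#'
#' Grid-plus-zoom argmax of [joint_total_fitness()] over `c` in `[0, 1]`.
#' For interior parameters the maximum sits at full concession `c = 1`,
#' where the two males' fitnesses are equal and skew vanishes — the
#' equilibrium therefore shrinks the total pie.
#'
#' @inheritParams mortality_hazard
#' @param grid_points Grid size. Default 1001.
#' @return A list with `c_max` and `joint_max`.
#' @examples
#' maximize_joint_fitness(skew_params(1, 1))
#' @export
maximize_joint_fitness <- function(params, grid_points = 1001L) {
  params <- as_skew_params(params)
  grid <- seq(0, 1, length.out = grid_points)
  vals <- joint_total_fitness(params, grid)
  i <- which.max(vals)
  list(c_max = grid[i], joint_max = vals[i])
}
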