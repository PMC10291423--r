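#' Mortality hazard of feeding
#'
#' The probability that a male feeding at fractional effort `f` dies before
#' realizing his future lifetime fitness: `p * f^2`. Quadratic in effort, so
#' the marginal mortality cost of provisioning rises with effort.
#'
#' @param params A [skew_params()] object.
#' @param f Feeding effort, fraction of the biological maximum, in `[0, 1]`.
#'   Vectorized.
#' @return Hazard probability in `[0, 1]`, same length as `f`.
#' @examples
#' mortality_hazard(skew_params(1, 1), f = 0.25)
#' @export
mortality_hazard <- function(params, f) {
  params <- as_skew_params(params)
  check_unit_interval(f, "f")
  params$p * f^2
}

#' Subordinate per-period fitness
#'
#' The single-period contribution to the subordinate's (Beta's) fitness:
#' the paternity flow `c * f` minus the expected loss of future lifetime
#' fitness through feeding mortality, `wbar * p * f^2`. Off-optimum effort
#' can make this negative; the value is returned as-is.
#'
#' @inheritParams mortality_hazard
#' @param c Paternity share of the Beta-paired female's brood granted to the
#'   subordinate, in `[0, 1]`. Vectorized with `f`.
#' @return Per-period fitness `c * f - wbar * p * f^2`.
#' @examples
#' beta_period_fitness(skew_params(1, 1), c = 0.5, f = 0.25)
#' @export
beta_period_fitness <- function(params, c, f) {
  params <- as_skew_params(params)
  check_unit_interval(c, "c")
  check_unit_interval(f, "f")
  c * f - params$wbar * params$p * f^2
}

#' Subordinate expected lifetime fitness
#'
#' This period's paternity flow plus the survival-weighted future stock:
#' `c * f + (1 - p * f^2) * wbar`. Identically equal to
#' [beta_period_fitness()] plus `wbar`.
#'
#' @inheritParams beta_period_fitness
#' @return Expected lifetime fitness.
#' @export
beta_lifetime_fitness <- function(params, c, f) {
  params <- as_skew_params(params)
  check_unit_interval(c, "c")
  check_unit_interval(f, "f")
  c * f + (1 - params$p * f^2) * params$wbar
}

#' Subordinate's best-response feeding effort
#'
#' The effort maximizing [beta_period_fitness()] over `f` in `[0, 1]` for a
#' given paternity share: the interior first-order condition gives
#' `f* = c / (2 * wbar * p)`, clamped to 1 when the analytic optimum exceeds
#' the feasible maximum. This is the incentive-compatibility constraint the
#' dominant faces: more copulations buy more care.
#'
#' @inheritParams beta_period_fitness
#' @return Best-response effort in `[0, 1]`, same length as `c`, with
#'   attribute `clamped` (logical, same length) marking components where the
#'   analytic optimum was truncated at 1.
#' @examples
#' beta_best_response(skew_params(1, 1), c = 0.5)
#' @export
beta_best_response <- function(params, c) {
  params <- as_skew_params(params)
  check_unit_interval(c, "c")
  raw <- c / (2 * params$wbar * params$p)
  structure(pmin(raw, 1), clamped = raw > 1)
}

#' Dominant's fitness from the subordinate's brood
#'
#' The dominant's share `(1 - c)` of the offspring the subordinate's pair
#' rears when the subordinate plays his best response:
#' `(1 - c) * f*(c)`.
#'
#' @inheritParams beta_best_response
#' @return Fitness contribution, non-negative on `[0, 1]`.
#' @export
alpha_beta_brood_fitness <- function(params, c) {
  params <- as_skew_params(params)
  check_unit_interval(c, "c")
  (1 - c) * as.numeric(beta_best_response(params, c))
}

#' Dominant's own-brood optimum
#'
#' The dominant feeds his own (genetically exclusive) brood at effort `F`
#' with payoff `F - wbar * p * F^2`; the optimum is `F* = 1 / (2 wbar p)`,
#' clamped to 1, with value `F* - wbar * p * F*^2` (equal to `1 / (4 wbar p)`
#' when interior).
#'
#' @inheritParams mortality_hazard
#' @return A named list with `F_star` (effort), `W_alpha` (fitness) and
#'   `clamped` (logical).
#' @examples
#' alpha_own_brood_optimum(skew_params(1, 1))
#' @export
alpha_own_brood_optimum <- function(params) {
  params <- as_skew_params(params)
  raw <- 1 / (2 * params$wbar * params$p)
  F_star <- min(raw, 1)
  list(
    F_star = F_star,
    W_alpha = F_star - params$wbar * params$p * F_star^2,
    clamped = raw > 1
  )
}

#' Joint total fitness of the two males
#'
#' Sum of the subordinate's per-period fitness, the dominant's share of the
#' subordinate's brood, and the dominant's own-brood payoff, with the
#' subordinate playing his best response and the dominant feeding his own
#' brood optimally. For interior parameters this is
#' `c^2/(4 wbar p) + c(1 - c)/(2 wbar p) + 1/(4 wbar p)`, strictly
#' increasing in `c` on `[0, 1]`: the equilibrium share `c* = 1/2` leaves
#' pie on the table.
#'
#' @inheritParams beta_best_response
#' @return Joint fitness, same length as `c`.
#' @examples
#' joint_total_fitness(skew_params(1, 1), c = c(0, 0.5, 1))
#' @export
joint_total_fitness <- function(params, c) {
  params <- as_skew_params(params)
  check_unit_interval(c, "c")
  f <- as.numeric(beta_best_response(params, c))
  own <- alpha_own_brood_optimum(params)
  beta_period_fitness(params, c, f) + (1 - c) * f + own$W_alpha
}

# Full fitness breakdown at an arbitrary strategy profile (c, f, F).
# W_total = W_beta + W_alpha and joint = w + W_total hold by construction.
fitness_breakdown <- function(params, c, f, F) {
  params <- as_skew_params(params)
  w <- beta_period_fitness(params, c, f)
  W_beta <- (1 - c) * f
  W_alpha <- F - params$wbar * params$p * F^2
  list(
    w = w,
    w_lifetime = w + params$wbar,
    W_beta = W_beta,
    W_alpha = W_alpha,
    W_total = W_beta + W_alpha,
    joint = w + W_beta + W_alpha
  )
}

#' Unconstrained fitness-maximizing equilibrium
#'
#' Solves the sequential game in which the dominant, moving first, picks the
#' paternity share `c` maximizing his gain from the subordinate's brood
#' `(1 - c) f*(c)`, anticipating the subordinate's best response, and feeds
#' his own brood optimally. For interior parameters (`wbar * p >= 1/2`) the
#' closed forms apply: `c* = 1/2`, `f* = 1/(4 wbar p)`, `F* = 1/(2 wbar p)`,
#' with fitnesses `w* = 1/(16 wbar p)`, `W_beta* = 1/(8 wbar p)`,
#' `W_alpha* = 1/(4 wbar p)`, `W* = 3/(8 wbar p)`. Otherwise the dominant's
#' objective is maximized numerically with the subordinate's effort clamped
#' at the feasible maximum and `boundary_clamped` is set.
#'
#' Outside options are ignored here; see [constrained_equilibrium()] for the
#' ecologically constrained version.
#'
#' @inheritParams mortality_hazard
#' @return A `skew_equilibrium` object: list with `c_star`, `f_star`,
#'   `F_star`, `fitness` (see [tidy.skew_equilibrium()] for the fields),
#'   `regime` (here always `"incentive_binding"`), `gini` and
#'   `boundary_clamped`.
#' @examples
#' eq <- unconstrained_equilibrium(skew_params(1, 1))
#' eq$c_star
#' eq$gini
#' @export
unconstrained_equilibrium <- function(params) {
  params <- as_skew_params(params)
  wp <- params$wbar * params$p
  own <- alpha_own_brood_optimum(params)
  if (params$interior) {
    c_star <- 0.5
    clamped <- own$clamped
  } else {
    # Beta's response clamps at f = 1 for c >= 2*wbar*p; maximize Alpha's
    # piecewise objective numerically over [0, 1].
    opt <- stats::optimize(function(cc) alpha_beta_brood_fitness(params, cc),
                           interval = c(0, 1), maximum = TRUE, tol = 1e-12)
    c_star <- opt$maximum
    clamped <- TRUE
  }
  f_star <- as.numeric(beta_best_response(params, c_star))
  fit <- fitness_breakdown(params, c_star, f_star, own$F_star)
  new_skew_equilibrium(
    params = params, c_star = c_star, f_star = f_star, F_star = own$F_star,
    fitness = fit, regime = "incentive_binding",
    gini = gini_two(fit$w, fit$W_total)$gini,
    boundary_clamped = clamped
  )
}

new_skew_equilibrium <- function(params, c_star, f_star, F_star, fitness,
                                 regime, gini, boundary_clamped) {
  structure(
    list(
      params = params, c_star = c_star, f_star = f_star, F_star = F_star,
      fitness = fitness, regime = regime, gini = gini,
      boundary_clamped = boundary_clamped
    ),
    class = "skew_equilibrium"
  )
}

#' @export
print.skew_equilibrium <- function(x, ...) {
  cat("<skew_equilibrium>  regime:", x$regime, "\n")
  if (x$regime == "no_employment") {
    cat(sprintf("  no helper engaged; Alpha breeds alone: W_total = %.6g\n",
                x$fitness$W_total))
  } else {
    cat(sprintf("  c* = %.6g  f* = %.6g  F* = %.6g%s\n",
                x$c_star, x$f_star, x$F_star,
                if (isTRUE(x$boundary_clamped)) "  [boundary clamped]" else ""))
    cat(sprintf("  w = %.6g  W_beta = %.6g  W_alpha = %.6g  W_total = %.6g\n",
                x$fitness$w, x$fitness$W_beta, x$fitness$W_alpha, x$fitness$W_total))
    cat(sprintf("  joint = %.6g  Gini = %.6g\n", x$fitness$joint, x$gini))
  }
  invisible(x)
}

#' Tidy an equilibrium into a one-row tibble
#'
#' @param x A `skew_equilibrium` object.
#' @param ... Unused.
#' @return One-row tibble with the parameters, strategies, fitness
#'   components, regime, Gini and clamp flag. Strategy and subordinate
#'   fitness columns are `NA` in the `no_employment` regime.
#' @export
tidy.skew_equilibrium <- function(x, ...) {
  tibble::tibble(
    wbar = x$params$wbar, p = x$params$p, z = x$params$z, Z = x$params$Z,
    regime = x$regime,
    c_star = x$c_star %||% NA_real_,
    f_star = x$f_star %||% NA_real_,
    F_star = x$F_star %||% NA_real_,
    w = x$fitness$w %||% NA_real_,
    W_beta = x$fitness$W_beta %||% NA_real_,
    W_alpha = x$fitness$W_alpha,
    W_total = x$fitness$W_total,
    joint = x$fitness$joint %||% NA_real_,
    gini = x$gini %||% NA_real_,
    boundary_clamped = isTRUE(x$boundary_clamped)
  )
}

#' One-line equilibrium summary
#'
#' @param x A `skew_equilibrium` object.
#' @param ... Unused.
#' @return One-row tibble with `regime`, `gini`, `joint` fitness and the
#'   efficiency gap to the joint-fitness maximum at full paternity
#'   concession (`c = 1`).
#' @export
glance.skew_equilibrium <- function(x, ...) {
  joint_max <- joint_total_fitness(x$params, 1)
  tibble::tibble(
    regime = x$regime,
    gini = x$gini %||% NA_real_,
    joint = x$fitness$joint %||% x$fitness$W_total,
    joint_max = joint_max,
    efficiency_gap = joint_max - (x$fitness$joint %||% x$fitness$W_total)
  )
}
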