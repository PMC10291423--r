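#' Minimum acceptable paternity share
#'
#' The smallest share `c` the dominant can offer that still attracts the
#' subordinate to the territory: the share at which the subordinate's
#' best-response fitness equals his outside option `z`. For interior
#' parameters the best-response fitness is `c^2 / (4 wbar p)`, giving the
#' closed form `c_bar = sqrt(4 wbar p z)`; when the subordinate's effort
#' clamps at the feasible maximum the share is found by inverting the
#' clamped payoff `c - wbar * p` instead. The result is truncated at 1.
#'
#' @inheritParams mortality_hazard
#' @return Minimum share in `[0, 1]`.
#' @examples
#' min_acceptable_share(skew_params(1, 1, z = 0.09))
#' @export
min_acceptable_share <- function(params) {
  params <- as_skew_params(params)
  wp <- params$wbar * params$p
  if (params$z == 0) return(0)
  c_bar <- sqrt(4 * wp * params$z)
  # past the clamp point c = 2*wp Beta feeds at f = 1 and earns c - wp
  if (c_bar > 2 * wp) c_bar <- params$z + wp
  min(c_bar, 1)
}

# Closed-form regime thresholds on z, valid across the clamped cases too.
# Interior (wp >= 1/2): the quadratic closed forms. For wp < 1/2 the
# subordinate's effort clamps at 1 before c reaches 1, so the upper
# threshold is his clamped payoff at c = 1 (1 - wp); for wp < 1/4 the
# dominant's unconstrained optimum sits at the clamp kink c = 2*wp, where
# the subordinate earns wp.
regime_thresholds <- function(wp) {
  if (wp >= 0.5) {
    c(z_low = 1 / (16 * wp), z_high = 1 / (4 * wp))
  } else if (wp >= 0.25) {
    c(z_low = 1 / (16 * wp), z_high = 1 - wp)
  } else {
    c(z_low = wp, z_high = 1 - wp)
  }
}

#' Classify the binding-constraint regime
#'
#' Which constraint shapes the equilibrium depends on the subordinate's
#' outside option `z` relative to two thresholds:
#' \itemize{
#'   \item `z <= 1/(16 wbar p)`: the incentive-compatibility constraint
#'     binds; the unconstrained optimum `c* = 1/2` already pays the
#'     subordinate at least `z` (regime `incentive_binding`).
#'   \item `1/(16 wbar p) < z < 1/(4 wbar p)`: the participation constraint
#'     binds; the dominant must concede `c = c_bar > 1/2`
#'     (regime `participation_binding`).
#'   \item `z >= 1/(4 wbar p)`: attracting the subordinate would require
#'     conceding the whole brood, leaving the dominant no gain
#'     (regime `no_employment`).
#' }
#' Boundary values follow the inequality directions above. The thresholds
#' quoted are the interior-parameter (`wbar * p >= 1/2`) closed forms; for
#' boundary-clamped parameter sets the piecewise analogues accounting for
#' effort clamping at 1 are used, so the classification always agrees with
#' [constrained_equilibrium()].
#'
#' @inheritParams mortality_hazard
#' @return A tibble with one row: `regime` (character), `c_bar`,
#'   `z_low_threshold` (`1/(16 wbar p)`) and `z_high_threshold`
#'   (`1/(4 wbar p)`).
#' @examples
#' classify_regime(skew_params(1, 1, z = 0.16))
#' @export
classify_regime <- function(params) {
  params <- as_skew_params(params)
  wp <- params$wbar * params$p
  thr <- regime_thresholds(wp)
  z_low <- thr[["z_low"]]
  z_high <- thr[["z_high"]]
  regime <- if (params$z <= z_low) {
    "incentive_binding"
  } else if (params$z < z_high) {
    "participation_binding"
  } else {
    "no_employment"
  }
  tibble::tibble(
    regime = regime,
    c_bar = min_acceptable_share(params),
    z_low_threshold = z_low,
    z_high_threshold = z_high
  )
}

#' Ecologically constrained equilibrium
#'
#' The dominant's fitness-maximizing strategy subject to both males'
#' participation constraints. In the `incentive_binding` regime this is the
#' unconstrained equilibrium; in the `participation_binding` regime the
#' dominant concedes exactly the minimum acceptable share `c_bar` (his
#' brood-share payoff is decreasing in `c` above the unconstrained optimum),
#' so the subordinate earns exactly his outside option `z`; in
#' `no_employment` no helper is engaged and the dominant breeds alone at his
#' own-brood optimum. If the engaged outcome would leave the dominant below
#' his own outside option `Z`, the result is downgraded to `no_employment`.
#'
#' @inheritParams mortality_hazard
#' @return A `skew_equilibrium` object (see [unconstrained_equilibrium()]).
#'   In the `no_employment` regime the strategy fields and subordinate
#'   fitness components are `NULL` and no Gini is defined.
#' @examples
#' constrained_equilibrium(skew_params(1, 1, z = 0.16))
#' @export
constrained_equilibrium <- function(params) {
  params <- as_skew_params(params)
  own <- alpha_own_brood_optimum(params)
  uncon <- unconstrained_equilibrium(params)
  c_bar <- min_acceptable_share(params)

  no_employment <- function() {
    fit <- list(w = NULL, w_lifetime = NULL, W_beta = NULL,
                W_alpha = own$W_alpha, W_total = own$W_alpha, joint = NULL)
    new_skew_equilibrium(
      params = params, c_star = NULL, f_star = NULL, F_star = NULL,
      fitness = fit, regime = "no_employment", gini = NULL,
      boundary_clamped = own$clamped
    )
  }

  # c_bar >= 1 means attracting Beta requires the whole brood: no gain.
  if (c_bar >= 1 && params$z > 0) return(no_employment())

  # tolerance absorbs optimize() jitter in the clamped-case numeric c*
  eq <- if (c_bar <= uncon$c_star + 1e-9) {
    uncon
  } else {
    f_star <- as.numeric(beta_best_response(params, c_bar))
    fit <- fitness_breakdown(params, c_bar, f_star, own$F_star)
    new_skew_equilibrium(
      params = params, c_star = c_bar, f_star = f_star, F_star = own$F_star,
      fitness = fit, regime = "participation_binding",
      gini = gini_two(fit$w, fit$W_total)$gini,
      boundary_clamped = uncon$boundary_clamped ||
        isTRUE(attr(beta_best_response(params, c_bar), "clamped"))
    )
  }

  # Alpha's participation: engaging the helper must beat his outside option.
  if (eq$fitness$W_total < params$Z) return(no_employment())
  eq
}
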