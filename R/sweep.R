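#' Solve equilibria over a data frame of parameter sets
#'
#' Pipeline-friendly solver: takes a data frame with columns `wbar`, `p`
#' and optionally `z`, `Z` (missing columns default to 0) and returns one
#' equilibrium row per input row. Invalid parameter combinations are kept
#' and flagged via the `error` column rather than dropped.
#'
#' @param data Data frame of parameter sets.
#' @return A tibble with the input parameters plus `regime`, `c_star`,
#'   `f_star`, `F_star`, `w`, `W_beta`, `W_alpha`, `W_total`, `joint`,
#'   `gini`, `boundary_clamped` and `error` (`NA` when the row solved).
#' @examples
#' tibble::tibble(wbar = 1, p = 1, z = c(0, 0.16)) |> solve_equilibria()
#' @export
solve_equilibria <- function(data) {
  stopifnot(is.data.frame(data), all(c("wbar", "p") %in% names(data)))
  data <- tibble::as_tibble(data)
  if (!"z" %in% names(data)) data$z <- 0
  if (!"Z" %in% names(data)) data$Z <- 0
  purrr::pmap(
    data[c("wbar", "p", "z", "Z")],
    function(wbar, p, z, Z) {
      res <- tryCatch(
        tidy(constrained_equilibrium(skew_params(wbar, p, z, Z))),
        error = function(e) NULL
      )
      if (is.null(res)) {
        tibble::tibble(wbar = wbar, p = p, z = z, Z = Z,
                       regime = NA_character_, error = "invalid parameters")
      } else {
        dplyr::mutate(res, error = NA_character_)
      }
    }
  ) |>
    dplyr::bind_rows()
}

#' Comparative-statics sweep over parameter grids
#'
#' Solves the constrained equilibrium on the Cartesian product of the
#' supplied grids, in deterministic grid order (`Z` fastest). The resulting
#' table exposes the model's comparative statics — e.g. the equilibrium
#' Gini falling from 0.71 toward 0 as the subordinate's outside option `z`
#' sweeps the participation-binding range.
#'
#' @param wbar,p,z,Z Numeric vectors of grid values (each non-empty).
#' @return A tibble as in [solve_equilibria()], one row per grid point.
#' @examples
#' run_sweep(wbar = 1, p = 1, z = c(0, 0.05, 0.16, 0.30))
#' @export
run_sweep <- function(wbar, p, z = 0, Z = 0) {
  stopifnot(length(wbar) > 0, length(p) > 0, length(z) > 0, length(Z) > 0)
  tidyr::expand_grid(wbar = wbar, p = p, z = z, Z = Z) |>
    solve_equilibria()
}

#' Generate reproducible parameter fixtures spanning all regimes
#'
#' Draws parameter sets stratified across the three constraint regimes
#' (incentive-binding, participation-binding, no-employment) and across
#' interior vs boundary-clamped cases (`wbar * p` above or below 1/2), each
#' labelled with its expected regime. Intended for round-trip and
#' property-style testing.
#'
#' @param seed Integer seed.
#' @param count Number of parameter sets, `>= 1`. Default 30.
#' @return A tibble with columns `wbar`, `p`, `z`, `Z`, `interior` and
#'   `expected_regime`.
#' @examples
#' generate_fixtures(seed = 1, count = 9)
#' @export
generate_fixtures <- function(seed, count = 30L) {
  stopifnot(count >= 1L)
  set.seed(seed)
  regimes <- rep(c("incentive_binding", "participation_binding", "no_employment"),
                 length.out = count)
  # alternate interior / clamped within each regime stratum
  interior <- rep(c(TRUE, TRUE, FALSE), length.out = count)
  purrr::map2(regimes, interior, function(reg, int) {
    wp <- if (int) stats::runif(1, 0.5, 4) else stats::runif(1, 0.05, 0.45)
    wbar <- stats::runif(1, max(wp, 0.2), max(wp, 0.2) + 4)
    p <- wp / wbar
    thr <- regime_thresholds(wp)
    z_low <- thr[["z_low"]]
    z_high <- thr[["z_high"]]
    z <- switch(reg,
      incentive_binding = stats::runif(1, 0, z_low),
      participation_binding = stats::runif(1, z_low * 1.01, z_high * 0.99),
      no_employment = stats::runif(1, z_high, 2 * z_high)
    )
    tibble::tibble(wbar = wbar, p = p, z = z, Z = 0,
                   interior = int, expected_regime = reg)
  }) |>
    dplyr::bind_rows()
}
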