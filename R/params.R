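#' Model parameters for the dominant-subordinate skew game
#'
#' Bundles and validates the ecological and physiological constants that
#' define one instance of the game between a dominant male (Alpha) and a
#' subordinate helper (Beta).
#'
#' Feeding at fractional effort `f` imposes a mortality probability
#' `p * f^2` on the feeder, who thereby risks losing an expected future
#' lifetime fitness of `wbar`. Because the hazard must be a probability on
#' the feasible effort range `[0, 1]`, `p` must lie in `[0, 1]`.
#'
#' The closed-form best responses of the model lie inside `[0, 1]` for every
#' paternity share `c` exactly when `wbar * p >= 1/2`; parameter sets below
#' that product are valid but are solved with effort clamped at the feasible
#' maximum (see [unconstrained_equilibrium()]).
#'
#' @param wbar Expected future (mature) lifetime fitness of a male; must be
#'   positive. Fitness units.
#' @param p Mortality cost coefficient; the hazard of feeding at effort `f`
#'   is `p * f^2`. Must lie in `(0, 1]`.
#' @param z Subordinate's outside-option per-period fitness (expected fitness
#'   if he disperses instead of helping); non-negative. Default 0.
#' @param Z Dominant's outside-option per-period fitness beyond his own-brood
#'   optimum; non-negative. Default 0, i.e. the dominant's fallback is
#'   breeding alone.
#'
#' @return An object of class `skew_params`: a named list with fields
#'   `wbar`, `p`, `z`, `Z` and the derived logical `interior` flag
#'   (`wbar * p >= 1/2`).
#' @examples
#' pars <- skew_params(wbar = 1, p = 1)
#' pars$interior
#' @export
skew_params <- function(wbar, p, z = 0, Z = 0) {
  stopifnot(
    "wbar must be a single finite number" = is.numeric(wbar) && length(wbar) == 1L && is.finite(wbar),
    "p must be a single finite number"    = is.numeric(p) && length(p) == 1L && is.finite(p),
    "z must be a single finite number"    = is.numeric(z) && length(z) == 1L && is.finite(z),
    "Z must be a single finite number"    = is.numeric(Z) && length(Z) == 1L && is.finite(Z)
  )
  if (wbar <= 0) stop("`wbar` must be > 0 (expected future lifetime fitness).", call. = FALSE)
  if (p <= 0) stop("`p` must be > 0 (mortality cost coefficient).", call. = FALSE)
  if (p > 1) {
    stop("`p` must be <= 1 so that the feeding hazard p * f^2 is a probability on f in [0, 1].",
         call. = FALSE)
  }
  if (z < 0) stop("`z` must be >= 0 (subordinate outside option).", call. = FALSE)
  if (Z < 0) stop("`Z` must be >= 0 (dominant outside option).", call. = FALSE)
  structure(
    list(wbar = wbar, p = p, z = z, Z = Z, interior = wbar * p >= 0.5),
    class = "skew_params"
  )
}

#' @export
print.skew_params <- function(x, ...) {
  cat("<skew_params>\n")
  cat(sprintf("  wbar = %g, p = %g, z = %g, Z = %g\n", x$wbar, x$p, x$z, x$Z))
  cat(sprintf("  wbar * p = %g (%s best responses)\n",
              x$wbar * x$p, if (x$interior) "interior" else "boundary-clamped"))
  invisible(x)
}

# Accept either a skew_params object or a bare list/row with the right names;
# re-validates bare input so internal code can rely on the invariants.
as_skew_params <- function(params) {
  if (inherits(params, "skew_params")) return(params)
  if (is.list(params) && all(c("wbar", "p") %in% names(params))) {
    return(skew_params(
      wbar = params$wbar, p = params$p,
      z = params$z %||% 0, Z = params$Z %||% 0
    ))
  }
  stop("`params` must be a skew_params object or a list with fields wbar, p (and optionally z, Z).",
       call. = FALSE)
}

check_unit_interval <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must lie in [0, 1].", name), call. = FALSE)
  }
  invisible(x)
}
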