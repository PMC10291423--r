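#' Gini coefficient between two individuals
#'
#' Reproductive-skew summary for a dominant-subordinate pair: the Gini
#' coefficient of their fitnesses with the small-sample correction
#' `n/(n - 1) = 2`, which for two values reduces to
#' `|a - b| / (a + b)`. At the unconstrained equilibrium fitnesses
#' `1/(16 wbar p)` and `3/(8 wbar p)` this gives `5/7 = 0.714...`.
#' The uncorrected convention (half that value) is available via
#' `corrected = FALSE`.
#'
#' @param fitness_a,fitness_b Non-negative fitnesses, not both zero.
#' @param corrected Apply the small-sample `n/(n-1)` correction
#'   (default `TRUE`).
#' @return A tibble with `gini`, `corrected` and `n = 2`.
#' @examples
#' gini_two(1 / 16, 3 / 8)
#' @export
gini_two <- function(fitness_a, fitness_b, corrected = TRUE) {
  if (!is.numeric(fitness_a) || !is.numeric(fitness_b) ||
      fitness_a < 0 || fitness_b < 0) {
    stop("Fitnesses must be non-negative numbers.", call. = FALSE)
  }
  if (fitness_a + fitness_b == 0) {
    stop("Gini is undefined when both fitnesses are zero.", call. = FALSE)
  }
  g <- abs(fitness_a - fitness_b) / (fitness_a + fitness_b)
  if (!corrected) g <- g / 2
  tibble::tibble(gini = g, corrected = corrected, n = 2L)
}

#' Gini coefficient of a fitness vector
#'
#' Mean absolute difference over all ordered pairs divided by twice the
#' mean, i.e. `sum_{i,j} |x_i - x_j| / (2 n^2 mean(x))`, optionally
#' multiplied by the small-sample factor `n/(n - 1)`. With `n = 2` and the
#' correction this reduces exactly to [gini_two()].
#'
#' @param values Non-negative fitnesses, at least one positive.
#' @param corrected Apply the `n/(n-1)` correction (default `FALSE`:
#'   population-level summaries use the plain estimator).
#' @return A tibble with `gini`, `corrected` and `n`.
#' @examples
#' gini_general(c(0, 0, 1))
#' @export
gini_general <- function(values, corrected = FALSE) {
  if (!is.numeric(values) || length(values) < 2L || any(values < 0)) {
    stop("`values` must be >= 2 non-negative numbers.", call. = FALSE)
  }
  if (sum(values) == 0) {
    stop("Gini is undefined when all values are zero.", call. = FALSE)
  }
  n <- length(values)
  # O(n log n) via the sorted-rank identity, equivalent to the pairwise sum
  x <- sort(values)
  g <- sum((2 * seq_len(n) - n - 1) * x) / (n^2 * mean(x))
  if (corrected) g <- g * n / (n - 1)
  tibble::tibble(gini = g, corrected = corrected, n = n)
}

#' Equilibrium fitness Gini between the two males
#'
#' The two-male Gini ([gini_two()], corrected) of the subordinate's and
#' dominant's per-period fitnesses at the ecologically constrained
#' equilibrium. Equals `5/7 = 0.71` whenever the incentive constraint binds
#' (parameter-free by scale invariance) and falls toward 0 as the
#' subordinate's outside option `z` rises through the participation-binding
#' range.
#'
#' @inheritParams mortality_hazard
#' @return Gini value (scalar).
#' @examples
#' equilibrium_gini(skew_params(1, 1, z = 0.16))
#' @export
equilibrium_gini <- function(params) {
  eq <- constrained_equilibrium(params)
  if (eq$regime == "no_employment") {
    stop("No employment interaction at these parameters; the two-male Gini is undefined.",
         call. = FALSE)
  }
  eq$gini
}
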