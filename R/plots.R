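#' Plot an evolutionary trajectory
#'
#' Population-mean paternity-share trait (ribbon: +/- 1 sd) over
#' generations, with the analytic equilibrium share as a dashed reference
#' line; when the subordinate reaction norm coevolves, its mean slope is
#' shown with its own target `1/(2 wbar p)`.
#'
#' @param object A `skew_trajectory` tibble from [simulate_evolution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.skew_trajectory <- function(object, ...) {
  params <- attr(object, "params")
  uncon <- unconstrained_equilibrium(params)
  df <- tibble::tibble(
    generation = object$generation,
    trait = "paternity share c",
    mean = object$mean_c,
    lo = pmax(object$mean_c - object$sd_c, 0),
    hi = pmin(object$mean_c + object$sd_c, 1),
    target = uncon$c_star
  )
  if (!all(is.na(object$mean_a))) {
    df <- dplyr::bind_rows(df, tibble::tibble(
      generation = object$generation,
      trait = "reaction-norm slope a",
      mean = object$mean_a, lo = NA_real_, hi = NA_real_,
      target = 1 / (2 * params$wbar * params$p)
    ))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$target),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$trait), scales = "free_y") +
    ggplot2::labs(x = "generation", y = "population mean trait") +
    ggplot2::theme_minimal()
}

#' Plot equilibrium skew against the subordinate's outside option
#'
#' The comparative-statics picture: equilibrium Gini (reproductive skew)
#' as a function of the subordinate's outside option `z`, colored by the
#' binding-constraint regime.
#'
#' @param sweep A sweep tibble from [run_sweep()] or [solve_equilibria()].
#' @return A ggplot object.
#' @export
plot_skew_vs_outside_option <- function(sweep) {
  stopifnot(is.data.frame(sweep), all(c("z", "gini", "regime") %in% names(sweep)))
  ggplot2::ggplot(
    dplyr::filter(sweep, !is.na(.data$gini)),
    ggplot2::aes(x = .data$z, y = .data$gini, colour = .data$regime)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(group = 1), alpha = 0.4) +
    ggplot2::labs(x = "subordinate outside option z",
                  y = "equilibrium fitness Gini") +
    ggplot2::theme_minimal()
}

#' Plot the subordinate's best-response function
#'
#' Feeding effort `f*(c)` against the paternity share, with the clamped
#' region (if any) visible as the plateau at the feasible maximum.
#'
#' @inheritParams mortality_hazard
#' @param n Number of grid points. Default 201.
#' @return A ggplot object.
#' @export
plot_best_response <- function(params, n = 201L) {
  params <- as_skew_params(params)
  cc <- seq(0, 1, length.out = n)
  df <- tibble::tibble(c = cc, f = as.numeric(beta_best_response(params, cc)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$c, y = .data$f)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "paternity share c", y = "best-response effort f*(c)") +
    ggplot2::theme_minimal()
}
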