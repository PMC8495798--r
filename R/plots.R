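#' Interval plot of plot-environment effects
#'
#' Posterior means (points) and 95% credible intervals (lines) of the
#' latitude, pH, silt and clay effects on the focal demographic
#' parameter, with a dashed zero line: the display convention of the
#' environmental-effects figure.
#'
#' @param fit An `sb_fit`.
#' @return A ggplot object.
#' @export
plot_effects <- function(fit) {
  tab <- effect_table(fit)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$mean,
                                    y = .data$covariate)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lower,
                                       xend = .data$upper,
                                       yend = .data$covariate),
                          colour = "grey50") +
    ggplot2::geom_point(colour = "red", size = 2) +
    ggplot2::labs(x = paste0("effect on logit(", fit$focal, ")"),
                  y = NULL,
                  title = paste0("Environmental effects on ",
                                 fit$focal)) +
    ggplot2::theme_minimal()
}

#' Slopes of management-practice response versus seed mass
#'
#' Per-species posterior-mean coefficients (points) with 95% credible
#' intervals (lines) against standardized log seed mass, the fitted
#' population line `gamma + beta * seed mass` (solid), faceted by
#' practice, with the explained variance annotated per panel.
#'
#' @param x An `sb_fit` or an `sb_slope_fit` from [slope_trait_table()].
#' @return A ggplot object.
#' @export
plot_slope_trait <- function(x) {
  st <- if (inherits(x, "sb_slope_fit")) x else slope_trait_table(x)
  lab <- st$hyper |>
    dplyr::mutate(label = sprintf("R² = %.2f", .data$r2))
  ggplot2::ggplot(st$species,
                  ggplot2::aes(x = .data$log_seed_mass_std,
                               y = .data$slope_mean)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted",
                        colour = "grey60") +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$log_seed_mass_std,
                                       y = .data$lower,
                                       yend = .data$upper),
                          colour = "grey50") +
    ggplot2::geom_point(colour = "red", size = 1.5) +
    ggplot2::geom_line(data = st$line,
                       ggplot2::aes(y = .data$fit), colour = "blue") +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(label = .data$label),
                       x = Inf, y = -Inf, hjust = 1.1, vjust = -0.6,
                       inherit.aes = FALSE, size = 3) +
    ggplot2::facet_wrap(~practice) +
    ggplot2::labs(x = "seed mass (standardized log scale)",
                  y = paste0("effect on logit(", st$focal, ")")) +
    ggplot2::theme_minimal()
}

#' Trace plot of posterior draws
#'
#' @param fit An `sb_fit`.
#' @param pars Parameter names (default: the three seed-mass slopes).
#' @param inc_warmup Include warmup draws (default `FALSE`).
#' @return A ggplot object.
#' @export
plot_trace <- function(fit, pars = NULL, inc_warmup = FALSE) {
  stopifnot(inherits(fit, "sb_fit"))
  if (is.null(pars)) {
    pars <- paste0("beta[", c("mowing", "tillage", "herbicide"), "]")
  }
  tab <- purrr::imap_dfr(
    posterior_draws(fit, pars, inc_warmup = inc_warmup),
    function(d, ch) {
      tibble::as_tibble(d) |>
        dplyr::mutate(chain = factor(ch),
                      iteration = dplyr::row_number()) |>
        tidyr::pivot_longer(-c("chain", "iteration"),
                            names_to = "term", values_to = "value")
    })
  ggplot2::ggplot(tab, ggplot2::aes(.data$iteration, .data$value,
                                    colour = .data$chain)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' @rdname plot_effects
#' @param object An `sb_fit`.
#' @param ... Unused.
#' @export
autoplot.sb_fit <- function(object, ...) plot_effects(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
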