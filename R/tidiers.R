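#' Tidy a fitted multilevel seed-bank HMM
#'
#' One row per hyper-parameter (or any requested scalar) with posterior
#' mean, credible bounds and convergence diagnostics, in broom style.
#'
#' @param x An `sb_fit`.
#' @param pars Parameters to include (default: hyper-parameters).
#' @param conf.level Credible level (default 0.95).
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `conf.low`, `conf.high`,
#'   `rhat`, `ess`.
#' @export
tidy.sb_fit <- function(x, pars = NULL, conf.level = 0.95, ...) {
  summarize_posterior(x, pars = pars, level = conf.level) |>
    dplyr::rename(estimate = "mean", conf.low = "lower",
                  conf.high = "upper")
}

#' Glance at a fitted multilevel seed-bank HMM
#'
#' @param x An `sb_fit`.
#' @param ... Unused.
#' @return One-row tibble with fit dimensions, mean log-density, maximum
#'   split-Rhat over hyper-parameters and the convergence flag.
#' @export
glance.sb_fit <- function(x, ...) {
  lp <- do.call(rbind, posterior_draws(x, "lp__"))[, 1]
  tibble::tibble(focal = x$focal, chains = x$chains, iter = x$iter,
                 warmup = x$warmup,
                 n_plots = length(x$plots),
                 n_species = length(x$species),
                 lp_mean = mean(lp),
                 max_rhat = x$max_rhat %||% NA_real_,
                 converged = x$converged %||% NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
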