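#' Posterior summaries with convergence diagnostics
#'
#' Posterior mean, equal-tailed 95% credible interval, split-chain
#' potential scale reduction (Rhat; each chain is split in half before
#' comparing between- to within-sequence variance) and effective sample
#' size per scalar parameter. Warmup draws are excluded for an `sb_fit`.
#'
#' @param x An `sb_fit`, a list of per-chain draw matrices, or a single
#'   matrix (iterations x parameters).
#' @param pars Parameter names to summarize; default for an `sb_fit` is
#'   the hyper-parameters (population means, seed-mass slopes,
#'   random-effect SDs) plus `lp__`; use `"all"` for every scalar.
#' @param level Credible level (default 0.95, equal-tailed).
#' @param thin Keep every `thin`-th draw (default 1).
#' @return A tibble with columns `term`, `mean`, `lower`, `upper`,
#'   `rhat`, `ess`.
#' @export
summarize_posterior <- function(x, pars = NULL, level = 0.95, thin = 1) {
  chains <- draws_chains(x, pars)
  stopifnot(level > 0, level < 1, thin >= 1)
  if (thin > 1) {
    chains <- lapply(chains, function(d)
      d[seq(1, nrow(d), by = thin), , drop = FALSE])
  }
  a <- (1 - level) / 2
  all_d <- do.call(rbind, chains)
  single <- length(chains) == 1
  if (single) {
    warning("single chain: split-Rhat not computed", call. = FALSE)
  }
  purrr::map_dfr(colnames(all_d), function(p) {
    v <- all_d[, p]
    qs <- unname(quantile(v, c(a, 1 - a), names = FALSE))
    tibble::tibble(
      term = p, mean = mean(v), lower = qs[1], upper = qs[2],
      rhat = if (single) NA_real_
             else split_rhat(vapply(chains, function(d) d[, p],
                                    numeric(nrow(chains[[1]])))),
      ess = ess_chains(lapply(chains, function(d) d[, p])))
  })
}

draws_chains <- function(x, pars = NULL) {
  if (inherits(x, "sb_fit")) {
    if (is.null(pars)) pars <- hyper_param_names(x)
    if (identical(pars, "all")) pars <- NULL
    return(posterior_draws(x, pars))
  }
  if (is.matrix(x)) x <- list(x)
  stopifnot(is.list(x), all(vapply(x, is.matrix, logical(1))))
  x <- lapply(x, function(d) {
    if (is.null(colnames(d))) {
      colnames(d) <- paste0("par", seq_len(ncol(d)))
    }
    d
  })
  if (!is.null(pars) && !identical(pars, "all")) {
    x <- lapply(x, function(d) d[, pars, drop = FALSE])
  }
  x
}

#' Split-chain potential scale reduction factor
#'
#' Each chain is split into halves; Rhat is
#' `sqrt(((n - 1)/n * W + B/n) / W)` over the resulting sequences, with
#' `W` the mean within-sequence variance and `B` the between-sequence
#' variance. Equals 1 exactly for identical constant chains.
#'
#' @param x Matrix of draws, iterations in rows, chains in columns (or a
#'   single vector, treated as one chain to split).
#' @return Rhat (>= 1 up to numerical noise).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- n %/% 2
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[seq_len(h), j], x[(n - h + 1):n, j])
  }))
  m <- ncol(halves); nn <- nrow(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  W <- mean(vars)
  B <- nn * var(means)
  if (W < 1e-300) {
    return(if (B < 1e-300) 1 else Inf)
  }
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

ess_chains <- function(vlist) {
  sum(vapply(vlist, function(v) {
    if (sd(v) < 1e-300) return(length(v))
    unname(coda::effectiveSize(coda::mcmc(v)))
  }, numeric(1)))
}

#' Significance by the credible-interval rule
#'
#' An effect is declared significant when its 95% credible interval
#' excludes zero. Zero exactly on an endpoint counts as not excluded
#' (conservative tie-break).
#'
#' @param lower,upper Interval endpoints (vectorized).
#' @return Logical vector.
#' @examples
#' is_significant(0.1, 0.5)   # TRUE
#' is_significant(-0.5, 0)    # FALSE: boundary inclusive
#' @export
is_significant <- function(lower, upper) {
  stopifnot(length(lower) == length(upper), all(lower <= upper | is.na(lower)))
  lower > 0 | upper < 0
}

#' Multilevel explained variance of the seed-mass regression
#'
#' Proportion of the across-species variance in the management-practice
#' coefficients `alpha_kj` explained by the seed-mass line
#' `gamma_k + beta_k * trait`:
#' `R2 = 1 - E[V_j(alpha_kj - gamma_k - beta_k trait_j)] / E[V_j(alpha_kj)]`,
#' with `V_j` the finite-sample variance across species and expectations
#' over posterior draws. Clipped to `[0, 1]`. With degenerate draws
#' (point masses) and the least-squares line this reduces to the
#' classical regression R-squared.
#'
#' @param alpha_draws Draws x species matrix of coefficient draws.
#' @param gamma_draws,beta_draws Draw vectors of the line parameters.
#' @param trait Standardized log seed mass per species (length >= 3).
#' @return Scalar R-squared in `[0, 1]`.
#' @export
explained_variance <- function(alpha_draws, gamma_draws, beta_draws,
                               trait) {
  alpha_draws <- as.matrix(alpha_draws)
  J <- ncol(alpha_draws)
  if (J < 3) stop("explained variance needs at least 3 species")
  stopifnot(length(trait) == J,
            length(gamma_draws) == nrow(alpha_draws),
            length(beta_draws) == nrow(alpha_draws))
  resid <- alpha_draws - outer(gamma_draws, rep(1, J)) -
    outer(beta_draws, trait)
  ev_res <- mean(apply(resid, 1, var))
  ev_tot <- mean(apply(alpha_draws, 1, var))
  if (ev_tot <= 0) return(0)
  min(max(1 - ev_res / ev_tot, 0), 1)
}

#' Plot-environment effect table
#'
#' Posterior summaries of the population-level effects of latitude, pH,
#' silt and clay on the focal demographic parameter — the data behind the
#' interval plot of environmental effects.
#'
#' @param fit An `sb_fit`.
#' @param level Credible level (default 0.95).
#' @return Tibble with one row per covariate: `parameter` (focal),
#'   `covariate`, `mean`, `lower`, `upper`, `rhat`, `ess`,
#'   `significant`.
#' @export
effect_table <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "sb_fit"))
  covs <- c("latitude", "pH", "silt", "clay")
  s <- summarize_posterior(fit, pars = paste0("alpha_bar[", covs, "]"),
                           level = level)
  s |>
    dplyr::mutate(parameter = fit$focal,
                  covariate = covs,
                  significant = is_significant(.data$lower, .data$upper)) |>
    dplyr::select("parameter", "covariate", "mean", "lower", "upper",
                  "rhat", "ess", "significant")
}

#' Slope-versus-seed-mass tables
#'
#' For each management practice (mowing, tillage, herbicide): the
#' per-species posterior-mean coefficient with its 95% credible interval,
#' the fitted population line `gamma_k + beta_k * seed mass` evaluated on
#' a grid spanning the standardized log seed masses, the `beta_k`
#' summary, and the multilevel explained variance — the data behind each
#' slope-versus-seed-mass panel.
#'
#' @param fit An `sb_fit`.
#' @param n_grid Grid points for the fitted line (default 50).
#' @param level Credible level (default 0.95).
#' @return A list of class `sb_slope_fit` with tibbles `species`
#'   (per-species slopes), `line` (fitted line on the trait grid) and
#'   `hyper` (`gamma`/`beta` summaries and `r2` per practice).
#' @export
slope_trait_table <- function(fit, n_grid = 50, level = 0.95) {
  stopifnot(inherits(fit, "sb_fit"))
  practices <- c("mowing", "tillage", "herbicide")
  m <- fit$traits$log_seed_mass_std
  grid <- seq(min(m), max(m), length.out = n_grid)
  a <- (1 - level) / 2

  species_tab <- list(); line_tab <- list(); hyper_tab <- list()
  for (p in practices) {
    anames <- paste0("alpha_", p, "[", fit$species, "]")
    ad <- do.call(rbind, posterior_draws(fit, anames))
    gd <- do.call(rbind, posterior_draws(fit, paste0("gamma[", p, "]")))[, 1]
    bd <- do.call(rbind, posterior_draws(fit, paste0("beta[", p, "]")))[, 1]
    qs <- apply(ad, 2, quantile, probs = c(a, 1 - a), names = FALSE)
    species_tab[[p]] <- tibble::tibble(
      practice = p, species_id = fit$species,
      seed_mass_mg = fit$traits$seed_mass_mg,
      log_seed_mass_std = m,
      slope_mean = colMeans(ad), lower = qs[1, ], upper = qs[2, ])
    line_tab[[p]] <- tibble::tibble(
      practice = p, log_seed_mass_std = grid,
      fit = mean(gd) + mean(bd) * grid)
    bq <- quantile(bd, c(a, 1 - a), names = FALSE)
    hyper_tab[[p]] <- tibble::tibble(
      practice = p, gamma_mean = mean(gd), beta_mean = mean(bd),
      beta_lower = bq[1], beta_upper = bq[2],
      significant = is_significant(bq[1], bq[2]),
      r2 = explained_variance(ad, gd, bd, m))
  }
  structure(list(species = dplyr::bind_rows(species_tab),
                 line = dplyr::bind_rows(line_tab),
                 hyper = dplyr::bind_rows(hyper_tab),
                 focal = fit$focal),
            class = "sb_slope_fit")
}

#' @export
print.sb_slope_fit <- function(x, ...) {
  cat("<sb_slope_fit> management-practice slopes vs seed mass (",
      x$focal, ")\n", sep = "")
  print(x$hyper)
  invisible(x)
}

#' Per-species demographic parameter summaries
#'
#' Posterior mean and credible interval of the focal demographic
#' parameter per species, evaluated at covariate means (covariates are
#' standardized, so the species intercept alone sets the level), plus
#' the non-focal parameters from their species intercepts.
#'
#' @param fit An `sb_fit`.
#' @param level Credible level (default 0.95).
#' @return Tibble with one row per species and demographic parameter.
#' @export
species_parameter_table <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "sb_fit"))
  a <- (1 - level) / 2
  nf <- nonfocal_names(fit$focal)
  rows <- list()
  for (j in seq_along(fit$species)) {
    sp <- fit$species[j]
    cols <- c(paste0("alpha_intercept[", sp, "]"),
              paste0("eta_", nf[1], "[", sp, "]"),
              paste0("eta_", nf[2], "[", sp, "]"))
    d <- plogis(do.call(rbind, posterior_draws(fit, cols)))
    qs <- apply(d, 2, quantile, probs = c(a, 1 - a), names = FALSE)
    rows[[j]] <- tibble::tibble(
      species_id = sp, parameter = c(fit$focal, nf),
      mean = colMeans(d), lower = qs[1, ], upper = qs[2, ])
  }
  dplyr::bind_rows(rows)
}
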