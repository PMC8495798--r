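#' Demographic probability from species coefficients and plot covariates
#'
#' The focal demographic parameter of plot i and species j is
#' `inverse_logit(alpha_0j + alpha_1j latitude_i + alpha_2j pH_i +
#' alpha_3j silt_i + alpha_4j clay_i + alpha_5j mowing_i +
#' alpha_6j tillage_i + alpha_7j herbicide_i)` with standardized
#' covariates.
#'
#' @param effects Numeric vector of length 8: species coefficients
#'   (intercept first).
#' @param covariate_row Numeric vector of the 7 standardized covariates in
#'   the order latitude, pH, silt, clay, mowing, tillage, herbicide.
#' @return A probability in (0, 1).
#' @examples
#' link_theta(c(qlogis(0.8), rep(0, 7)), rep(0, 7))  # 0.8 at covariate means
#' @export
link_theta <- function(effects, covariate_row) {
  stopifnot(length(effects) == 8, length(covariate_row) == 7)
  eta <- effects[1] + sum(effects[-1] * covariate_row)
  if (!is.finite(eta)) stop("non-finite linear predictor")
  plogis(eta)
}

#' Population mean of a species coefficient
#'
#' Coefficients of the intercept and plot-environment covariates
#' (k = 0..4) share a common mean `alpha_bar_k`; management-practice
#' coefficients (k = 5 mowing, 6 tillage, 7 herbicide) have mean
#' `gamma_k + beta_k * seed mass` (standardized log scale), so seed mass
#' drives interspecific variation in disturbance response.
#'
#' @param k Coefficient index, 0..7.
#' @param hyper List with `alpha_bar` (length 5), `gamma`, `beta`
#'   (length 3 each).
#' @param trait Standardized log seed mass of the species.
#' @return The mean of `alpha_kj`.
#' @export
species_effect_mean <- function(k, hyper, trait) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k != as.integer(k) ||
      k < 0 || k > 7) {
    stop("`k` must be a single integer in 0..7")
  }
  k <- as.integer(k)
  if (k <= 4) hyper$alpha_bar[k + 1]
  else hyper$gamma[k - 4] + hyper$beta[k - 4] * trait
}

nonfocal_names <- function(focal) setdiff(c("g", "s", "c"), focal)

param_names <- function(focal, species) {
  practices <- c("mowing", "tillage", "herbicide")
  nf <- nonfocal_names(focal)
  c(paste0("alpha_bar[", COEF_LABELS[1:5], "]"),
    paste0("gamma[", practices, "]"),
    paste0("beta[", practices, "]"),
    paste0("sigma[", COEF_LABELS, "]"),
    paste0("mu[", nf[1], "]"), paste0("tau[", nf[1], "]"),
    paste0("mu[", nf[2], "]"), paste0("tau[", nf[2], "]"),
    as.vector(vapply(species, function(sp)
      paste0("alpha_", COEF_LABELS, "[", sp, "]"), character(8))),
    paste0("eta_", nf[1], "[", species, "]"),
    paste0("eta_", nf[2], "[", species, "]"),
    paste0("p0[", species, "]"),
    "lp__")
}

#' Joint log-density of the multilevel seed-bank HMM
#'
#' Sum of the forward log-likelihood over every plot-by-species series plus
#' the log prior and random-effect densities, for one parameter state.
#' Used for testing and diagnostics; the sampler evaluates the same
#' quantities internally. A random-effect SD outside its uniform support
#' returns `-Inf` (the state is rejected, not an error).
#'
#' @param data An `sb_data` from [assemble_dataset()].
#' @param state Parameter state: list with `alpha` (species x 8 matrix),
#'   `alpha_bar` (5), `gamma` (3), `beta` (3), `sigma` (8), `eta1`,
#'   `eta2` (non-focal species intercepts), `mu` (2), `tau` (2), `p0`
#'   (per species).
#' @param focal Focal demographic parameter, `"g"`, `"s"` or `"c"`.
#' @param prior_sd SD of the normal priors on regression coefficients.
#' @param sd_upper Upper bound of the uniform priors on random-effect SDs.
#' @return Log-density (finite for interior states).
#' @export
log_posterior <- function(data, state, focal = c("g", "s", "c"),
                          prior_sd = 1.5, sd_upper = 5) {
  focal <- match.arg(focal)
  stopifnot(inherits(data, "sb_data"))
  I <- length(data$plots); J <- length(data$species)
  if (any(state$sigma <= 0) || any(state$sigma > sd_upper) ||
      any(state$tau <= 0) || any(state$tau > sd_upper)) {
    return(-Inf)
  }
  if (any(state$p0 < 0) || any(state$p0 > 1)) return(-Inf)

  theta_f <- plogis(data$X %*% t(state$alpha))
  th1 <- matrix(plogis(state$eta1), I, J, byrow = TRUE)
  th2 <- matrix(plogis(state$eta2), I, J, byrow = TRUE)
  G <- switch(focal, g = theta_f, s = th1, c = th1)
  S <- switch(focal, g = th1, s = theta_f, c = th2)
  C <- switch(focal, g = th2, s = th2, c = theta_f)

  ll <- 0
  for (i in seq_len(I)) {
    for (j in seq_len(J)) {
      ll <- ll + forward_loglik(data$y[i, j, ], state$p0[j],
                                G[i, j], S[i, j], C[i, j])
    }
  }
  m <- data$traits$log_seed_mass_std
  lp <- ll +
    sum(dnorm(state$alpha_bar, 0, prior_sd, log = TRUE)) +
    sum(dnorm(state$gamma, 0, prior_sd, log = TRUE)) +
    sum(dnorm(state$beta, 0, prior_sd, log = TRUE)) +
    sum(dnorm(state$mu, 0, prior_sd, log = TRUE)) -
    10 * log(sd_upper)
  for (k in 0:7) {
    mean_k <- vapply(m, function(mm)
      species_effect_mean(k, state_hyper(state), mm), numeric(1))
    lp <- lp + sum(dnorm(state$alpha[, k + 1], mean_k, state$sigma[k + 1],
                         log = TRUE))
  }
  lp + sum(dnorm(state$eta1, state$mu[1], state$tau[1], log = TRUE)) +
    sum(dnorm(state$eta2, state$mu[2], state$tau[2], log = TRUE))
}

state_hyper <- function(state) {
  list(alpha_bar = state$alpha_bar, gamma = state$gamma, beta = state$beta)
}

#' Fit the multilevel seed-bank HMM by MCMC
#'
#' One fit per focal demographic parameter: the focal parameter (g, s or
#' c) carries the full plot-covariate structure with species random
#' slopes whose management-practice means depend on seed mass; the two
#' non-focal parameters get species logit-normal random intercepts, and
#' `p0` is Uniform(0,1) per species. Priors are Normal(0, `prior_sd`^2)
#' on regression coefficients and Uniform(0, `sd_upper`) on random-effect
#' SDs. Sampling is adaptive random-walk Metropolis within Gibbs over the
#' marginalized forward likelihood (hidden states are never sampled);
#' proposal scales adapt only during warmup. Chain 1 starts from the
#' prior center, later chains from independent prior draws, and chain
#' seeds derive deterministically from `seed`.
#'
#' @param data An `sb_data` from [assemble_dataset()] or
#'   [generate_dataset()].
#' @param focal Focal demographic parameter, `"g"`, `"s"` or `"c"`.
#' @param chains Number of chains (default 2).
#' @param iter Total iterations per chain, including warmup (default
#'   10,000).
#' @param warmup Burn-in iterations discarded from summaries (default
#'   2,500); raw draws keep them.
#' @param seed Master RNG seed.
#' @param prior_sd,sd_upper Prior hyper-values (see above).
#' @param adapt Adapt proposal scales during warmup (default `TRUE`).
#' @return An object of class `sb_fit`: raw per-chain draw matrices (one
#'   column per scalar parameter plus `lp__`), the warmup size, focal
#'   parameter, data dimensions and convergence diagnostics for the
#'   hyper-parameters. If any hyper-parameter split-Rhat exceeds 1.1 a
#'   prominent warning flags non-convergence.
#' @export
fit_seedbank <- function(data, focal = c("g", "s", "c"), chains = 2,
                         iter = 10000, warmup = 2500, seed = 1,
                         prior_sd = 1.5, sd_upper = 5, adapt = TRUE) {
  focal <- match.arg(focal)
  stopifnot(inherits(data, "sb_data"), chains >= 1, iter > warmup,
            warmup >= 0)
  I <- length(data$plots); J <- length(data$species)
  T_ <- length(data$years)
  m <- data$traits$log_seed_mass_std
  yarr <- data$y
  storage.mode(yarr) <- "integer"
  focal_i <- match(focal, c("g", "s", "c")) - 1L

  set.seed(seed)
  chain_seeds <- sample.int(2147483646L, chains)
  nm <- param_names(focal, data$species)

  draws <- vector("list", chains)
  accept <- numeric(chains)
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    init <- if (ch == 1) init_center(J, sd_upper)
            else init_prior_draw(J, m, prior_sd, sd_upper)
    out <- sampler_cpp(as.vector(yarr), I, J, T_, data$X, m, focal_i,
                       as.integer(iter), as.integer(warmup),
                       prior_sd, sd_upper, init, adapt)
    colnames(out$draws) <- nm
    draws[[ch]] <- out$draws
    accept[ch] <- out$accept_rate
  }

  fit <- structure(list(draws = draws, warmup = as.integer(warmup),
                        iter = as.integer(iter), chains = chains,
                        focal = focal, species = data$species,
                        plots = data$plots,
                        traits = data$traits, scaling = data$scaling,
                        seed = seed, chain_seeds = chain_seeds,
                        priors = list(prior_sd = prior_sd,
                                      sd_upper = sd_upper),
                        accept_rate = accept),
                   class = "sb_fit")
  hyper <- hyper_param_names(fit)
  diag <- summarize_posterior(fit, pars = hyper)
  fit$max_rhat <- max(diag$rhat, na.rm = TRUE)
  fit$converged <- is.finite(fit$max_rhat) && fit$max_rhat < 1.1
  if (!fit$converged) {
    warning("NON-CONVERGENCE: max split-Rhat over hyper-parameters is ",
            round(fit$max_rhat, 3),
            " (> 1.1); inspect traces and rerun longer", call. = FALSE)
  }
  fit
}

#' Fit with the full-length MCMC protocol
#'
#' Convenience wrapper running 2 chains of 10,000 iterations with a
#' 2,500-iteration burn-in — the protocol used for the full survey
#' analyses.
#'
#' @inheritParams fit_seedbank
#' @export
fit_full_protocol <- function(data, focal = c("g", "s", "c"), seed = 1) {
  fit_seedbank(data, focal, chains = 2, iter = 10000, warmup = 2500,
               seed = seed)
}

init_center <- function(J, sd_upper) {
  list(alpha_bar = rep(0, 5), gamma = rep(0, 3), beta = rep(0, 3),
       sigma = rep(sd_upper / 2, 8), mu1 = 0, mu2 = 0,
       tau1 = sd_upper / 2, tau2 = sd_upper / 2,
       alpha = matrix(0, J, 8), eta1 = rep(0, J), eta2 = rep(0, J),
       p0 = rep(0.5, J))
}

init_prior_draw <- function(J, m, prior_sd, sd_upper) {
  hyper <- list(alpha_bar = rnorm(5, 0, prior_sd),
                gamma = rnorm(3, 0, prior_sd),
                beta = rnorm(3, 0, prior_sd))
  sigma <- runif(8, 0, sd_upper)
  alpha <- vapply(0:7, function(k) {
    mu <- vapply(m, function(mm) species_effect_mean(k, hyper, mm),
                 numeric(1))
    rnorm(J, mu, sigma[k + 1])
  }, numeric(J))
  if (J == 1) alpha <- matrix(alpha, 1, 8)
  mu1 <- rnorm(1, 0, prior_sd); mu2 <- rnorm(1, 0, prior_sd)
  tau1 <- runif(1, 0, sd_upper); tau2 <- runif(1, 0, sd_upper)
  list(alpha_bar = hyper$alpha_bar, gamma = hyper$gamma, beta = hyper$beta,
       sigma = sigma, mu1 = mu1, mu2 = mu2, tau1 = tau1, tau2 = tau2,
       alpha = alpha, eta1 = rnorm(J, mu1, tau1), eta2 = rnorm(J, mu2, tau2),
       p0 = runif(J))
}

hyper_param_names <- function(fit) {
  nm <- colnames(fit$draws[[1]])
  nm[c(1:23, length(nm))]
}

#' @export
print.sb_fit <- function(x, ...) {
  cat("<sb_fit> multilevel seed-bank HMM\n")
  cat("  focal parameter: ", x$focal, "\n", sep = "")
  cat("  chains: ", x$chains, ", iterations: ", x$iter,
      " (warmup ", x$warmup, ")\n", sep = "")
  cat("  plots: ", length(x$plots), ", species: ", length(x$species),
      "\n", sep = "")
  cat("  max split-Rhat (hyper-parameters): ",
      round(x$max_rhat, 3),
      if (isTRUE(x$converged)) "" else "  ** NOT CONVERGED **",
      "\n", sep = "")
  invisible(x)
}

#' Extract post-warmup draws as a matrix
#'
#' @param fit An `sb_fit`.
#' @param pars Optional character vector of parameter names.
#' @param inc_warmup Keep warmup draws (default `FALSE`).
#' @return List of per-chain matrices.
#' @export
posterior_draws <- function(fit, pars = NULL, inc_warmup = FALSE) {
  stopifnot(inherits(fit, "sb_fit"))
  lapply(fit$draws, function(d) {
    if (!inc_warmup && fit$warmup > 0) d <- d[-seq_len(fit$warmup), ,
                                              drop = FALSE]
    if (!is.null(pars)) {
      missing <- setdiff(pars, colnames(d))
      if (length(missing)) stop("unknown parameters: ",
                                paste(missing, collapse = ", "))
      d <- d[, pars, drop = FALSE]
    }
    d
  })
}

#' Serialize posterior draws to CSV
#'
#' Columnar CSV with `chain` and `iteration` columns plus one column per
#' scalar parameter, and a JSON sidecar echoing the fit settings.
#'
#' @param fit An `sb_fit`.
#' @param path Output CSV path; the sidecar gets extension `.json`.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "sb_fit"))
  tabs <- purrr::imap(fit$draws, function(d, ch) {
    tibble::as_tibble(d) |>
      dplyr::mutate(chain = ch, iteration = dplyr::row_number(),
                    .before = 1)
  })
  readr::write_csv(dplyr::bind_rows(tabs), path)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(
    list(focal = fit$focal, chains = fit$chains, iter = fit$iter,
         warmup = fit$warmup, seed = fit$seed, priors = fit$priors,
         species = fit$species, plots = fit$plots),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read serialized draws back as a fit-like object
#'
#' @param path CSV path written by [write_draws()].
#' @return An `sb_fit` (without data-dependent extras beyond the sidecar).
#' @export
read_draws <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  draws <- lapply(sort(unique(tab$chain)), function(ch) {
    d <- as.matrix(tab[tab$chain == ch,
                       setdiff(names(tab), c("chain", "iteration"))])
    d
  })
  structure(list(draws = draws, warmup = side$warmup, iter = side$iter,
                 chains = side$chains, focal = side$focal,
                 species = side$species, plots = side$plots,
                 seed = side$seed, priors = side$priors),
            class = "sb_fit")
}
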