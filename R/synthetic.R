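#' Design of a synthetic multi-year flora survey
#'
#' Describes a vineyard-style monitoring design: a set of plots surveyed
#' annually for the presence of each species, with survey-level
#' missingness, plot covariates (latitude, soil pH, silt and clay
#' fractions, mean annual counts of mowing, tillage and herbicide
#' treatments) and a seed-mass trait per species. The default mirrors the
#' study design the package emulates: 46 plots, 30 species, 7 annual
#' surveys (2006-2012), seed mass spanning 0.1-14.5 mg, about 10% of
#' plot-years unsurveyed.
#'
#' `truth` holds the hyper-parameters of the generative model for the
#' focal demographic parameter (`alpha_bar` for intercept + latitude, pH,
#' silt, clay; `gamma`, `beta` for mowing, tillage, herbicide intercepts
#' and seed-mass slopes; `sigma` for the 8 random-effect SDs) and the
#' logit-normal intercepts of the two non-focal parameters
#' (`mu_nonfocal`, `tau_nonfocal`, in the order the remaining two of
#' (g, s, c) appear). `p0` is drawn Uniform(0,1) per species unless
#' `truth$p0` fixes it.
#'
#' @param n_plots,n_species Design size.
#' @param years Integer vector of survey years.
#' @param missing_rate Probability a plot-year is unsurveyed (whole-survey
#'   missingness, identical across species).
#' @param focal Which demographic parameter carries the covariate
#'   structure: `"g"`, `"s"` or `"c"`.
#' @param truth List of generative hyper-parameters; defaults give a null
#'   plot-environment (all `alpha_bar` covariate effects 0, intercept 0),
#'   management intercepts `gamma = (0,0,0)`, seed-mass slopes
#'   `beta = (0.4, 0.6, 0.8)`, random-effect SDs 0.3, and moderate
#'   non-focal levels.
#' @param covariates List of generator settings for the plot covariates
#'   (uniform latitude range, normal pH, Dirichlet soil texture, Poisson
#'   management count means).
#' @param seed_mass_range Seed mass range in mg (log-uniform draw).
#' @param seed Optional integer seed; `generate_dataset()` seeds the RNG
#'   with it when present.
#' @return A list of class `sb_design`.
#' @export
sb_design <- function(n_plots = 46, n_species = 30, years = 2006:2012,
                      missing_rate = 0.1, focal = c("g", "s", "c"),
                      truth = list(), covariates = list(),
                      seed_mass_range = c(0.1, 14.5), seed = NULL) {
  focal <- match.arg(focal)
  stopifnot(n_plots >= 1, n_species >= 1,
            missing_rate >= 0, missing_rate < 1,
            length(seed_mass_range) == 2, all(seed_mass_range > 0))
  truth_def <- list(
    alpha_bar = c(0, 0, 0, 0, 0),
    gamma = c(0, 0, 0),
    beta = c(0.4, 0.6, 0.8),
    sigma = rep(0.3, 8),
    mu_nonfocal = c(qlogis(0.45), qlogis(0.25)),
    tau_nonfocal = c(0.5, 0.5))
  truth <- utils::modifyList(truth_def, truth)
  stopifnot(length(truth$alpha_bar) == 5, length(truth$gamma) == 3,
            length(truth$beta) == 3, length(truth$sigma) == 8,
            all(truth$sigma >= 0), length(truth$mu_nonfocal) == 2,
            length(truth$tau_nonfocal) == 2, all(truth$tau_nonfocal >= 0))
  cov_def <- list(latitude_range = c(43.5, 49.5),
                  pH_mean = 7.3, pH_sd = 0.8,
                  texture_alpha = c(sand = 2, silt = 2, clay = 2),
                  mowing_mean = 2, tillage_mean = 2, herbicide_mean = 1.5)
  covariates <- utils::modifyList(cov_def, covariates)
  structure(list(n_plots = as.integer(n_plots),
                 n_species = as.integer(n_species),
                 years = as.integer(years),
                 missing_rate = missing_rate, focal = focal,
                 truth = truth, covariates = covariates,
                 seed_mass_range = seed_mass_range, seed = seed),
            class = "sb_design")
}

#' Generate plot covariates for a synthetic design
#'
#' Latitude uniform over the design range, pH normal, soil texture from a
#' Dirichlet draw over (sand, silt, clay) so silt + clay never exceeds 1,
#' and management counts as per-plot means of yearly Poisson counts.
#' Uses the current RNG state.
#'
#' @param design An [sb_design()].
#' @return A raw (unstandardized) covariate tibble.
#' @export
generate_covariates <- function(design) {
  stopifnot(inherits(design, "sb_design"))
  I <- design$n_plots
  cv <- design$covariates
  n_years <- length(design$years)
  tex <- matrix(rgamma(3 * I, shape = rep(cv$texture_alpha, each = I)),
                nrow = I)
  tex <- tex / rowSums(tex)
  mean_count <- function(mu) {
    rowMeans(matrix(rpois(I * n_years, mu), nrow = I))
  }
  tibble::tibble(
    plot_id = sprintf("plot%02d", seq_len(I)),
    latitude = runif(I, cv$latitude_range[1], cv$latitude_range[2]),
    pH = rnorm(I, cv$pH_mean, cv$pH_sd),
    silt = tex[, 2],
    clay = tex[, 3],
    mowing = mean_count(cv$mowing_mean),
    tillage = mean_count(cv$tillage_mean),
    herbicide = mean_count(cv$herbicide_mean))
}

#' Generate species seed masses for a synthetic design
#'
#' Seed mass is log-uniform over the design range (default 0.1-14.5 mg,
#' the span observed across common vineyard weeds). Uses the current RNG
#' state.
#'
#' @param design An [sb_design()].
#' @return A trait tibble with `log_seed_mass_std`.
#' @export
generate_traits <- function(design) {
  stopifnot(inherits(design, "sb_design"))
  J <- design$n_species
  lr <- log10(design$seed_mass_range)
  validate_traits(tibble::tibble(
    species_id = sprintf("sp%02d", seq_len(J)),
    seed_mass_mg = 10^runif(J, lr[1], lr[2])))
}

#' Generate a complete synthetic survey dataset with known truth
#'
#' Draws plot covariates and seed masses, species coefficients
#' `alpha_kj ~ N(mean_k(seed mass), sigma_k^2)` for the focal demographic
#' parameter, logit-normal intercepts for the two non-focal parameters,
#' `p0_j ~ Uniform(0,1)`, then simulates every plot-by-species series from
#' the hidden Markov chain and masks unsurveyed plot-years (one mask per
#' plot-year, shared by all species). Covariates are standardized before
#' entering the linear predictor, exactly as in fitting.
#'
#' @param design An [sb_design()]; if `design$seed` (or `seed`) is set the
#'   RNG is seeded first, making output fully deterministic.
#' @param seed Optional override of `design$seed`.
#' @return A list with `data` (an `sb_data`, ready for [fit_seedbank()]),
#'   the raw `panel`, `covariates` and `traits` tibbles, and `truth`
#'   (hyper-parameters, per-species `alpha` matrix, non-focal intercepts
#'   `eta1`/`eta2`, `p0`, the per-plot-species probability matrices
#'   `g`, `s`, `c`, and the hidden seed-bank states).
#' @export
generate_dataset <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "sb_design"))
  if (!is.null(seed)) set.seed(seed)
  I <- design$n_plots; J <- design$n_species
  years <- design$years; T_ <- length(years)
  tr <- design$truth

  covariates <- generate_covariates(design)
  traits <- generate_traits(design)
  cov_std <- standardize_covariates(covariates)
  X <- cbind(1, as.matrix(cov_std[, COVARIATE_COLS]))
  m <- traits$log_seed_mass_std

  mean_k <- vapply(0:7, function(k) {
    vapply(m, function(mm) species_effect_mean(k, tr, mm), numeric(1))
  }, numeric(J))                                   # J x 8
  alpha <- mean_k + matrix(rnorm(J * 8, sd = rep(tr$sigma, each = J)),
                           nrow = J)
  eta1 <- rnorm(J, tr$mu_nonfocal[1], tr$tau_nonfocal[1])
  eta2 <- rnorm(J, tr$mu_nonfocal[2], tr$tau_nonfocal[2])
  p0 <- if (is.null(tr$p0)) runif(J) else rep_len(tr$p0, J)

  theta_f <- plogis(X %*% t(alpha))                # I x J
  th1 <- matrix(plogis(eta1), I, J, byrow = TRUE)
  th2 <- matrix(plogis(eta2), I, J, byrow = TRUE)
  G <- switch(design$focal, g = theta_f, s = th1, c = th1)
  S <- switch(design$focal, g = th1, s = theta_f, c = th2)
  C <- switch(design$focal, g = th2, s = th2, c = theta_f)

  y <- array(NA_integer_, dim = c(I, J, T_))
  seed_bank <- array(NA_integer_, dim = c(I, J, T_))
  for (i in seq_len(I)) {
    for (j in seq_len(J)) {
      sim <- simulate_chain(p0[j], G[i, j], S[i, j], C[i, j], T_)
      y[i, j, ] <- sim$obs
      seed_bank[i, j, ] <- sim$seed_bank
    }
  }
  surveyed <- matrix(runif(I * T_) >= design$missing_rate, I, T_)
  panel <- tidyr::expand_grid(plot_id = covariates$plot_id,
                              species_id = traits$species_id,
                              year = years)
  ii <- match(panel$plot_id, covariates$plot_id)
  jj <- match(panel$species_id, traits$species_id)
  tt <- match(panel$year, years)
  panel$present <- y[cbind(ii, jj, tt)]
  panel <- panel[surveyed[cbind(ii, tt)], ]

  data <- assemble_dataset(panel, covariates,
                           traits[, c("species_id", "seed_mass_mg")],
                           year_range = years)
  truth <- list(focal = design$focal, hyper = tr, alpha = alpha,
                eta1 = eta1, eta2 = eta2, p0 = p0,
                g = G, s = S, c = C, seed_bank = seed_bank,
                surveyed = surveyed)
  list(data = data, panel = panel, covariates = covariates,
       traits = traits, truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Writes the three CSVs (`panel.csv`, `covariates.csv`, `traits.csv`)
#' plus `truth.json` with the generative hyper-parameters.
#'
#' @param sim Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_panel(sim$panel, file.path(dir, "panel.csv"))
  readr::write_csv(sim$covariates, file.path(dir, "covariates.csv"))
  readr::write_csv(sim$traits[, c("species_id", "seed_mass_mg")],
                   file.path(dir, "traits.csv"))
  jsonlite::write_json(sim$truth$hyper, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
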