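# Small shared fixtures, built in code at test time.

tiny_design <- function(seed = 42, ...) {
  sb_design(n_plots = 6, n_species = 4, years = 2006:2011,
            missing_rate = 0.1, seed = seed, ...)
}

toy_panel <- function() {
  tidyr::expand_grid(plot_id = c("A", "B", "C"),
                     species_id = c("X", "Y"),
                     year = 2006:2009) |>
    dplyr::mutate(present = rep(c(1L, 0L, 1L, 0L), 6))
}

toy_covariates <- function() {
  tibble::tibble(plot_id = c("A", "B", "C"),
                 latitude = c(43.6, 46.1, 49.2),
                 pH = c(7.9, 6.8, 7.4),
                 silt = c(0.30, 0.45, 0.25),
                 clay = c(0.20, 0.15, 0.35),
                 mowing = c(2, 1, 3),
                 tillage = c(1, 2, 0),
                 herbicide = c(0, 1, 2))
}

toy_traits <- function() {
  tibble::tibble(species_id = c("X", "Y"), seed_mass_mg = c(0.4, 6))
}

random_params <- function() {
  list(p0 = runif(1), g = runif(1), s = runif(1), c = runif(1))
}

# one small fit reused across reporting/tidier tests (computed lazily once)
.fixture_env <- new.env(parent = emptyenv())

shared_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    sim <- generate_dataset(tiny_design(seed = 99))
    .fixture_env$sim <- sim
    .fixture_env$fit <- suppressWarnings(
      fit_seedbank(sim$data, "g", chains = 2, iter = 800, warmup = 400,
                   seed = 5))
  }
  .fixture_env$fit
}

shared_sim <- function() {
  shared_fit()
  .fixture_env$sim
}
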