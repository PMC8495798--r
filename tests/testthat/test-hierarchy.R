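test_that("inverse-logit link maps coefficients to probabilities", {
  expect_equal(link_theta(rep(0, 8), rnorm(7)), 0.5)
  expect_equal(link_theta(c(qlogis(0.8), rep(0, 7)), rep(0, 7)), 0.8)
  # tillage is the 6th covariate slot (index 7 with the intercept)
  eff <- rep(0, 8); eff[7] <- 1
  x <- rep(0, 7); x[6] <- 2
  expect_equal(link_theta(eff, x), plogis(2), tolerance = 1e-12)
  expect_equal(plogis(2), 0.8807971, tolerance = 1e-7)
  expect_error(link_theta(c(Inf, rep(0, 7)), rep(0, 7)), "non-finite")
})

test_that("coefficient means switch from shared to trait-dependent at k=5", {
  hyper <- list(alpha_bar = c(0.5, 0.1, 0.3, 0, 0),
                gamma = c(0.1, 0.2, 0.1), beta = c(0.5, 0.3, 0.5))
  expect_equal(species_effect_mean(2, hyper, trait = 4), 0.3)
  expect_equal(species_effect_mean(7, hyper, trait = 1), 0.6)
  expect_equal(species_effect_mean(5, hyper, trait = -2), 0.1 - 1)
  # beta = 0 collapses to an exchangeable model
  hyper0 <- hyper; hyper0$beta <- c(0, 0, 0)
  expect_equal(species_effect_mean(6, hyper0, 1),
               species_effect_mean(6, hyper0, -1))
  expect_error(species_effect_mean(8, hyper, 0), "0..7")
  expect_error(species_effect_mean(-1, hyper, 0), "0..7")
})

random_state <- function(J, sd_upper = 5) {
  list(alpha = matrix(rnorm(J * 8, 0, 0.7), J, 8),
       alpha_bar = rnorm(5, 0, 1), gamma = rnorm(3, 0, 1),
       beta = rnorm(3, 0, 1), sigma = runif(8, 0.2, 2),
       eta1 = rnorm(J, 0, 1), eta2 = rnorm(J, 0, 1),
       mu = rnorm(2, 0, 1), tau = runif(2, 0.2, 2), p0 = runif(J))
}

test_that("joint log-density is finite inside and -Inf outside support", {
  sim <- generate_dataset(tiny_design(seed = 31))
  set.seed(31)
  for (i in 1:20) {
    st <- random_state(4)
    lp <- log_posterior(sim$data, st, "g")
    expect_true(is.finite(lp))
  }
  st <- random_state(4)
  st$sigma[3] <- 7      # outside Uniform(0, 5) support
  expect_identical(log_posterior(sim$data, st, "g"), -Inf)
  st <- random_state(4); st$p0[1] <- 1.4
  expect_identical(log_posterior(sim$data, st, "g"), -Inf)
})

test_that("log-likelihood is additive over independent plot sets", {
  sim <- generate_dataset(tiny_design(seed = 32))
  panel2 <- sim$panel |> dplyr::mutate(plot_id = paste0(plot_id, "_b"))
  cov2 <- sim$covariates |> dplyr::mutate(plot_id = paste0(plot_id, "_b"))
  dbl <- assemble_dataset(dplyr::bind_rows(sim$panel, panel2),
                          dplyr::bind_rows(sim$covariates, cov2),
                          sim$traits[, c("species_id", "seed_mass_mg")])
  set.seed(32)
  st <- random_state(4)
  lp1 <- log_posterior(sim$data, st, "g")
  lp2 <- log_posterior(dbl, st, "g")
  # same priors, doubled likelihood: the difference is the likelihood term,
  # recomputed naively series by series
  ll <- 0
  th_f <- plogis(sim$data$X %*% t(st$alpha))
  for (i in 1:6) {
    for (j in 1:4) {
      ll <- ll + forward_loglik(sim$data$y[i, j, ], st$p0[j], th_f[i, j],
                                plogis(st$eta1[j]), plogis(st$eta2[j]))
    }
  }
  expect_equal(lp2 - lp1, ll, tolerance = 1e-8)
})

test_that("joint log-density is exactly invariant to species relabeling", {
  sim <- generate_dataset(tiny_design(seed = 33))
  set.seed(33)
  st <- random_state(4)
  lp <- log_posterior(sim$data, st, "s")
  perm <- c(3, 1, 4, 2)
  data_p <- sim$data
  data_p$y <- sim$data$y[, perm, , drop = FALSE]
  data_p$traits <- sim$data$traits[perm, ]
  data_p$species <- sim$data$species[perm]
  st_p <- st
  st_p$alpha <- st$alpha[perm, ]
  st_p$eta1 <- st$eta1[perm]; st_p$eta2 <- st$eta2[perm]
  st_p$p0 <- st$p0[perm]
  expect_equal(log_posterior(data_p, st_p, "s"), lp, tolerance = 1e-12)
})

test_that("the sampler runs end-to-end on a tiny dataset", {
  sim <- generate_dataset(sb_design(n_plots = 3, n_species = 2,
                                    years = 2006:2009, seed = 34))
  fit <- suppressWarnings(fit_seedbank(sim$data, "g", chains = 2,
                                       iter = 500, warmup = 250, seed = 3))
  expect_s3_class(fit, "sb_fit")
  d <- do.call(rbind, posterior_draws(fit))
  expect_true(all(is.finite(d)))
  expect_equal(nrow(d), 2 * 250)
  expect_true(all(d[, grep("^sigma", colnames(d))] > 0))
  expect_true(all(d[, grep("^sigma", colnames(d))] < 5))
  p0 <- d[, grep("^p0", colnames(d))]
  expect_true(all(p0 > 0 & p0 < 1))
})

test_that("fits are reproducible given the same seed", {
  sim <- generate_dataset(sb_design(n_plots = 3, n_species = 2,
                                    years = 2006:2009, seed = 35))
  f1 <- suppressWarnings(fit_seedbank(sim$data, "c", chains = 1,
                                      iter = 200, warmup = 100, seed = 8))
  f2 <- suppressWarnings(fit_seedbank(sim$data, "c", chains = 1,
                                      iter = 200, warmup = 100, seed = 8))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(fit_seedbank(sim$data, "c", chains = 1,
                                      iter = 200, warmup = 100, seed = 9))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("draws serialize to CSV and read back", {
  fit <- shared_fit()
  f <- withr::local_tempfile(fileext = ".csv")
  write_draws(fit, f)
  back <- read_draws(f)
  expect_equal(back$focal, fit$focal)
  expect_equal(back$warmup, fit$warmup)
  expect_equal(unname(back$draws[[2]]), unname(fit$draws[[2]]),
               tolerance = 1e-12)
  s1 <- summarize_posterior(fit, pars = "beta[tillage]")
  s2 <- summarize_posterior(back, pars = "beta[tillage]")
  expect_equal(s1$mean, s2$mean, tolerance = 1e-10)
})
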