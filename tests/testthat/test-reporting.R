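test_that("posterior summaries recover closed-form quantiles", {
  set.seed(41)
  chains <- list(matrix(rnorm(10000), ncol = 1,
                        dimnames = list(NULL, "z")),
                 matrix(rnorm(10000), ncol = 1,
                        dimnames = list(NULL, "z")))
  s <- summarize_posterior(chains)
  expect_equal(s$mean, 0, tolerance = 0.05)
  expect_equal(s$lower, -1.96, tolerance = 0.08)
  expect_equal(s$upper, 1.96, tolerance = 0.08)
  expect_lt(s$rhat, 1.01)
  expect_gt(s$ess, 5000)
})

test_that("identical constant chains give rhat exactly 1, zero width", {
  chains <- list(matrix(2, 100, 1), matrix(2, 100, 1))
  s <- summarize_posterior(chains)
  expect_identical(s$rhat, 1)
  expect_identical(s$upper - s$lower, 0)
  expect_identical(s$mean, 2)
})

test_that("diverging chains are flagged by a large rhat", {
  set.seed(42)
  chains <- list(matrix(rnorm(2000, 0), ncol = 1),
                 matrix(rnorm(2000, 10), ncol = 1))
  s <- summarize_posterior(chains)
  expect_gt(s$rhat, 3)
})

test_that("a single chain reports rhat as missing with a warning", {
  set.seed(43)
  expect_warning(s <- summarize_posterior(matrix(rnorm(1000), ncol = 1)),
                 "single chain")
  expect_true(is.na(s$rhat))
  expect_true(is.finite(s$ess))
})

test_that("summaries are stable under chain relabeling and thinning", {
  fit <- shared_fit()
  pars <- c("beta[tillage]", "sigma[intercept]")
  s <- summarize_posterior(fit, pars = pars)
  rev_chains <- posterior_draws(fit, pars)[c(2, 1)]
  s_rev <- summarize_posterior(rev_chains)
  expect_equal(s_rev$mean, s$mean, tolerance = 1e-12)
  expect_equal(s_rev$rhat, s$rhat, tolerance = 1e-12)
  s_thin <- summarize_posterior(fit, pars = pars, thin = 2)
  expect_equal(s_thin$mean, s$mean, tolerance = 0.1)
  expect_equal(s_thin$upper, s$upper, tolerance = 0.2)
})

test_that("significance follows the interval rule with inclusive boundary", {
  expect_true(is_significant(0.1, 0.5))
  expect_true(is_significant(-0.5, -0.1))
  expect_false(is_significant(-0.2, 0.3))
  expect_false(is_significant(-0.5, 0))   # zero on the endpoint
  expect_false(is_significant(0, 0.5))
  # monotone: widening an interval can only flip significant -> not
  set.seed(44)
  for (i in 1:100) {
    lo <- rnorm(1); hi <- lo + rexp(1)
    w <- rexp(2, 10)
    if (!is_significant(lo, hi)) {
      expect_false(is_significant(lo - w[1], hi + w[2]))
    }
  }
})

test_that("explained variance has the stated degenerate limits", {
  m <- seq(-1.5, 1.5, length.out = 10)
  alpha <- matrix(0.3 + 0.8 * m, nrow = 1)      # exactly on the line
  expect_equal(explained_variance(alpha, 0.3, 0.8, m), 1)
  set.seed(45)
  a <- rnorm(10)
  # flat line at the mean of the coefficients explains nothing
  expect_equal(explained_variance(matrix(a, 1), mean(a), 0, m), 0)
  expect_error(explained_variance(matrix(1:2, 1), 0, 0, 1:2),
               "at least 3 species")
})

test_that("explained variance reduces to classical R2 for point masses", {
  set.seed(46)
  m <- rnorm(20)
  y <- 0.5 + 0.9 * m + rnorm(20, sd = 0.5)
  ols <- lm(y ~ m)
  r2 <- explained_variance(matrix(y, 1), coef(ols)[1], coef(ols)[2], m)
  expect_equal(r2, summary(ols)$r.squared, tolerance = 1e-12)
})

test_that("explained variance estimates a known variance decomposition", {
  # population R2 = b^2 V(m) / (b^2 V(m) + s2) set to 0.8 at 30 species
  set.seed(47)
  m <- rnorm(30); b <- 1
  s2 <- b^2 * mean((m - mean(m))^2) / 4
  r2s <- replicate(20, {
    a <- b * m + rnorm(30, sd = sqrt(s2))
    draws <- matrix(rep(a, each = 50), nrow = 50) +
      matrix(rnorm(50 * 30, sd = 0.05), 50)
    explained_variance(draws, rep(0, 50), rep(b, 50), m)
  })
  expect_lt(abs(median(r2s) - 0.8), 0.1)
})

test_that("effect table has one row per covariate with significance", {
  fit <- shared_fit()
  tab <- effect_table(fit)
  expect_equal(nrow(tab), 4)
  expect_setequal(tab$covariate, c("latitude", "pH", "silt", "clay"))
  expect_true(all(tab$lower <= tab$mean & tab$mean <= tab$upper))
  expect_identical(tab$significant,
                   is_significant(tab$lower, tab$upper))
  expect_equal(unique(tab$parameter), "g")
})

test_that("slope-trait tables cover the trait range for each practice", {
  fit <- shared_fit()
  st <- slope_trait_table(fit, n_grid = 25)
  expect_s3_class(st, "sb_slope_fit")
  expect_equal(nrow(st$hyper), 3)
  expect_true(all(st$hyper$r2 >= 0 & st$hyper$r2 <= 1))
  m <- fit$traits$log_seed_mass_std
  for (p in c("mowing", "tillage", "herbicide")) {
    g <- st$line[st$line$practice == p, ]
    expect_equal(range(g$log_seed_mass_std), range(m))
    expect_equal(nrow(g), 25)
    sp <- st$species[st$species$practice == p, ]
    expect_equal(nrow(sp), length(fit$species))
    expect_true(all(sp$lower <= sp$slope_mean &
                      sp$slope_mean <= sp$upper))
  }
})

test_that("species parameter table stays inside the unit interval", {
  tab <- species_parameter_table(shared_fit())
  expect_equal(nrow(tab), 4 * 3)
  expect_true(all(tab$lower >= 0 & tab$upper <= 1))
  expect_setequal(unique(tab$parameter), c("g", "s", "c"))
})
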