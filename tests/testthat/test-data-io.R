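test_that("panel round-trips through CSV up to row order", {
  panel <- toy_panel()
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, f)
  back <- read_panel(f)
  key <- function(d) d[order(d$plot_id, d$species_id, d$year), ]
  expect_equal(key(back), key(panel))
})

test_that("panel validation rejects duplicates and malformed values", {
  panel <- toy_panel()
  dup <- dplyr::bind_rows(panel, panel[3, ])
  expect_error(validate_panel(dup), "duplicate")
  expect_error(validate_panel(dup),
               paste0(panel$plot_id[3], ", ", panel$species_id[3]))
  bad <- panel; bad$present[2] <- 2L
  expect_error(validate_panel(bad), "outside \\{0, 1, NA\\}.*2")
  nay <- panel; nay$year[4] <- NA
  expect_error(validate_panel(nay), "year")
  expect_error(validate_panel(panel[, 1:3]), "missing columns")
})

test_that("a simple series survives the panel representation", {
  panel <- tibble::tibble(plot_id = "A", species_id = "X",
                          year = 2006:2008, present = c(1L, 0L, 1L))
  cov <- toy_covariates()[1, ]
  tr <- toy_traits()[1, ]
  # single plot: covariates are constant, flagged
  d <- suppressWarnings(assemble_dataset(panel, cov, tr))
  expect_equal(as.vector(d$y[1, 1, ]), c(1L, 0L, 1L))
})

test_that("covariate standardization has the stated closed form", {
  cov <- toy_covariates()
  cov$latitude <- c(10, 20, 30)
  std <- standardize_covariates(cov)
  expect_equal(std$latitude, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  sc <- attr(std, "scaling")
  expect_equal(sc$center[sc$covariate == "latitude"], 20)
  expect_equal(sc$scale[sc$covariate == "latitude"], sqrt(200 / 3))
  for (v in c("latitude", "pH", "silt", "clay")) {
    expect_lt(abs(mean(std[[v]])), 1e-10)
    expect_lt(abs(sqrt(mean((std[[v]] - mean(std[[v]]))^2)) - 1), 1e-10)
  }
})

test_that("standardization is idempotent and flags constant covariates", {
  std1 <- standardize_covariates(toy_covariates())
  std2 <- standardize_covariates(tibble::as_tibble(std1))
  for (v in c("latitude", "pH", "mowing", "tillage", "herbicide")) {
    expect_equal(std2[[v]], std1[[v]], tolerance = 1e-12)
  }
  cov <- toy_covariates(); cov$pH <- c(5, 5, 5)
  expect_warning(std <- standardize_covariates(cov), "constant")
  expect_equal(std$pH, c(0, 0, 0))
  expect_true(attr(std, "scaling")$constant[
    attr(std, "scaling")$covariate == "pH"])
})

test_that("silt/clay unit auto-detection normalizes percentages", {
  cov <- toy_covariates()
  cov$silt <- cov$silt * 100
  expect_message(v <- validate_covariates(cov), "percent")
  expect_equal(v$silt, toy_covariates()$silt)
})

test_that("assembly builds rectangular series with explicit gaps", {
  panel <- toy_panel() |> dplyr::filter(!(plot_id == "A" & year == 2007))
  d <- assemble_dataset(panel, toy_covariates(), toy_traits())
  expect_equal(dim(d$y), c(3, 2, 4))
  expect_true(all(is.na(d$y["A", , "2007"])))
  expect_true(all(!is.na(d$y["B", , ])))
  # year_range can force slots beyond the observed years
  d2 <- assemble_dataset(panel, toy_covariates(), toy_traits(),
                         year_range = 2006:2010)
  expect_equal(dim(d2$y)[3], 5)
  expect_true(all(is.na(d2$y[, , "2010"])))
})

test_that("assembly is invariant to input row order", {
  panel <- toy_panel()
  set.seed(7)
  d1 <- assemble_dataset(panel, toy_covariates(), toy_traits())
  d2 <- assemble_dataset(panel[sample(nrow(panel)), ],
                         toy_covariates()[c(3, 1, 2), ],
                         toy_traits()[c(2, 1), ])
  expect_identical(d1$y, d2$y)
  expect_equal(d1$X, d2$X)
  expect_equal(d1$traits, d2$traits)
})

test_that("assembly rejects unmatched identifiers and partial surveys", {
  panel <- toy_panel()
  expect_error(assemble_dataset(panel, toy_covariates()[1:2, ],
                                toy_traits()), "missing from covariates.*C")
  expect_error(assemble_dataset(panel, toy_covariates(),
                                toy_traits()[1, ]), "missing from traits.*Y")
  expect_error(assemble_dataset(panel, toy_covariates(),
                                toy_traits()[0, ]), "empty")
  half <- panel |> dplyr::filter(!(plot_id == "A" & species_id == "X" &
                                     year == 2006))
  expect_error(assemble_dataset(half, toy_covariates(), toy_traits()),
               "only some species.*A/2006")
})

test_that("seed-mass extremes map to the extreme standardized log values", {
  tr <- tibble::tibble(species_id = sprintf("s%02d", 1:10),
                       seed_mass_mg = c(0.1, 14.5, 10^runif(8, -0.9, 1.1)))
  v <- validate_traits(tr)
  expect_lt(abs(mean(v$log_seed_mass_std)), 1e-10)
  expect_equal(which.min(v$log_seed_mass_std), 1L)
  expect_equal(which.max(v$log_seed_mass_std), 2L)
  expect_error(validate_traits(tibble::tibble(species_id = "a",
                                              seed_mass_mg = 0)), "> 0")
  # single species: centering convention gives exactly zero
  expect_identical(standardize_trait(3.2), 0)
})

test_that("management counts can enter as study-period totals", {
  d_mean <- assemble_dataset(toy_panel(), toy_covariates(), toy_traits())
  d_tot <- assemble_dataset(toy_panel(), toy_covariates(), toy_traits(),
                            management = "total")
  sc_mean <- d_mean$scaling
  sc_tot <- d_tot$scaling
  expect_equal(sc_tot$center[sc_tot$covariate == "tillage"],
               4 * sc_mean$center[sc_mean$covariate == "tillage"])
  # standardized values are scale-invariant
  expect_equal(d_tot$X[, "tillage"], d_mean$X[, "tillage"])
})
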