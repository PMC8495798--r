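#' Read a plot-by-species-by-year presence panel
#'
#' The panel is a long CSV with columns `plot_id`, `species_id`, `year`
#' and `present` (0/1, empty for an unsurveyed year). One record per
#' (plot, species, year); duplicates are an error.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @export
read_panel <- function(path) {
  stopifnot(file.exists(path))
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          plot_id = readr::col_character(),
                          species_id = readr::col_character(),
                          year = readr::col_integer(),
                          present = readr::col_integer()))
  validate_panel(df)
}

#' @rdname read_panel
#' @param panel A panel tibble.
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(validate_panel(panel), path)
  invisible(path)
}

#' Validate a presence panel
#'
#' Checks the column set, that `present` is 0/1/`NA`, that `year` is an
#' integer, and that (plot, species, year) keys are unique.
#'
#' @param panel A data frame.
#' @return The panel as a tibble, invisibly validated.
#' @export
validate_panel <- function(panel) {
  need <- c("plot_id", "species_id", "year", "present")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("panel is missing columns: ",
                         paste(miss, collapse = ", "))
  panel <- tibble::as_tibble(panel)
  bad <- which(!is.na(panel$year) & panel$year != as.integer(panel$year))
  if (anyNA(panel$year) || length(bad)) {
    stop("malformed `year` in panel rows: ",
         paste(head(c(which(is.na(panel$year)), bad), 5), collapse = ", "))
  }
  bad <- which(!(panel$present %in% c(0, 1) | is.na(panel$present)))
  if (length(bad)) {
    stop("`present` outside {0, 1, NA} in panel rows: ",
         paste(head(bad, 5), collapse = ", "))
  }
  key <- paste(panel$plot_id, panel$species_id, panel$year, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (plot, species, year) records, e.g. row ", dup[1],
         ": (", panel$plot_id[dup[1]], ", ", panel$species_id[dup[1]],
         ", ", panel$year[dup[1]], ")")
  }
  panel$year <- as.integer(panel$year)
  panel$present <- as.integer(panel$present)
  panel
}

#' Read plot covariates
#'
#' One row per plot: `plot_id`, `latitude`, `pH`, `silt`, `clay` and the
#' mean annual counts of `mowing`, `tillage` and `herbicide` treatments.
#' Silt and clay may come as percentages or proportions; values above 1
#' are taken to be percent and divided by 100 (a message notes the
#' conversion).
#'
#' @param path Path to a CSV file.
#' @return A tibble with silt/clay as proportions.
#' @export
read_covariates <- function(path) {
  stopifnot(file.exists(path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_covariates(df)
}

#' Validate a plot covariate table
#'
#' Checks the column set, uniqueness of `plot_id`, non-negativity of
#' texture fractions and management counts, and converts silt/clay given
#' as percentages to proportions.
#'
#' @param cov A data frame of raw (unstandardized) plot covariates.
#' @return The validated tibble.
#' @export
validate_covariates <- function(cov) {
  need <- c("plot_id", COVARIATE_COLS)
  miss <- setdiff(need, names(cov))
  if (length(miss)) stop("covariate table is missing columns: ",
                         paste(miss, collapse = ", "))
  cov <- tibble::as_tibble(cov)
  if (anyDuplicated(cov$plot_id)) stop("duplicated plot_id in covariates")
  for (v in c("silt", "clay")) {
    if (any(cov[[v]] < 0, na.rm = TRUE)) stop("`", v, "` must be >= 0")
    if (any(cov[[v]] > 1, na.rm = TRUE)) {
      message("`", v, "` looks like percent; converting to proportion")
      cov[[v]] <- cov[[v]] / 100
    }
  }
  for (v in c("mowing", "tillage", "herbicide")) {
    if (any(cov[[v]] < 0, na.rm = TRUE)) stop("`", v, "` must be >= 0")
  }
  cov
}

#' Read species traits
#'
#' One row per species: `species_id` and `seed_mass_mg` (oven-dry mass per
#' seed in milligrams, strictly positive).
#'
#' @param path Path to a CSV file.
#' @return A tibble with a `log_seed_mass_std` column added (log10 seed
#'   mass, centered and scaled across species).
#' @export
read_traits <- function(path) {
  stopifnot(file.exists(path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_traits(df)
}

#' Validate a species trait table
#'
#' Checks the column set, uniqueness of `species_id` and positivity of
#' seed mass, and adds the standardized log seed mass.
#'
#' @param traits A data frame with `species_id` and `seed_mass_mg`.
#' @return The validated tibble with `log_seed_mass_std` added.
#' @export
validate_traits <- function(traits) {
  need <- c("species_id", "seed_mass_mg")
  miss <- setdiff(need, names(traits))
  if (length(miss)) stop("trait table is missing columns: ",
                         paste(miss, collapse = ", "))
  traits <- tibble::as_tibble(traits)
  if (nrow(traits) == 0) stop("trait table is empty")
  if (anyDuplicated(traits$species_id)) {
    stop("duplicated species_id in traits")
  }
  if (any(!is.finite(traits$seed_mass_mg)) ||
      any(traits$seed_mass_mg <= 0)) {
    stop("`seed_mass_mg` must be finite and > 0")
  }
  traits$log_seed_mass_std <- standardize_trait(traits$seed_mass_mg)
  traits
}

#' Standardize seed mass on the log scale
#'
#' `log10` of seed mass, centered and scaled by the population standard
#' deviation across species. With a single species (or zero spread) the
#' standardized value is 0.
#'
#' @param seed_mass_mg Positive numeric vector.
#' @return Numeric vector with mean 0.
#' @export
standardize_trait <- function(seed_mass_mg) {
  x <- log10(seed_mass_mg)
  x <- x - mean(x)
  s <- sqrt(mean(x^2))
  if (s > 0) x <- x / s
  x
}

#' Center and scale plot covariates
#'
#' Each covariate column is centered and divided by its population
#' standard deviation (`sqrt(mean((x - mean(x))^2))`), so coefficient
#' magnitudes are comparable across predictors. The per-covariate
#' `(center, scale)` pairs are kept in the `"scaling"` attribute for
#' back-transformation. A constant covariate cannot be scaled: it is set
#' to 0, flagged in the scaling table, and a warning is raised.
#'
#' @param cov A validated covariate tibble.
#' @return The tibble with standardized covariate columns; attribute
#'   `scaling` holds a tibble of `covariate`, `center`, `scale`,
#'   `constant`.
#' @export
standardize_covariates <- function(cov) {
  miss <- setdiff(c("plot_id", COVARIATE_COLS), names(cov))
  if (length(miss)) stop("covariate table is missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(cov$plot_id)) stop("duplicated plot_id in covariates")
  cov <- tibble::as_tibble(cov)
  scaling <- purrr::map_dfr(COVARIATE_COLS, function(v) {
    x <- cov[[v]]
    ctr <- mean(x)
    scl <- sqrt(mean((x - ctr)^2))
    constant <- scl < 1e-12
    tibble::tibble(covariate = v, center = ctr,
                   scale = ifelse(constant, NA_real_, scl),
                   constant = constant)
  })
  for (i in seq_len(nrow(scaling))) {
    v <- scaling$covariate[i]
    if (scaling$constant[i]) {
      warning("covariate `", v, "` is constant; set to 0 and flagged",
              call. = FALSE)
      cov[[v]] <- rep(0, nrow(cov))
    } else {
      cov[[v]] <- (cov[[v]] - scaling$center[i]) / scaling$scale[i]
    }
  }
  attr(cov, "scaling") <- scaling
  cov
}

#' Assemble the model-ready dataset
#'
#' Reshapes the long panel into per-(plot, species) observation series over
#' a common year range, with explicit `NA` slots for unsurveyed plot-years
#' (never imputed; the likelihood marginalizes them), standardizes the
#' covariates, and standardizes log seed mass. A survey observes all
#' species at once, so for any surveyed plot-year the panel must contain a
#' record for every species in the trait table.
#'
#' @param panel Long presence panel (see [read_panel()]).
#' @param covariates Plot covariate table (raw or standardized).
#' @param traits Species trait table.
#' @param year_range Optional integer vector; defaults to
#'   `min(year):max(year)` of the panel.
#' @param management Either `"mean"` (default; counts enter as mean annual
#'   counts, as supplied) or `"total"` (counts multiplied by the number of
#'   years before standardization). Affects only the management columns.
#' @return An object of class `sb_data`: list with the observation array
#'   `y` (plots x species x years), design matrix `X` (intercept +
#'   standardized covariates), `traits`, id/year indices and the scaling
#'   attributes.
#' @export
assemble_dataset <- function(panel, covariates, traits, year_range = NULL,
                             management = c("mean", "total")) {
  management <- match.arg(management)
  panel <- validate_panel(panel)
  covariates <- validate_covariates(covariates)
  traits <- validate_traits(traits)

  plots <- sort(unique(covariates$plot_id))
  species <- sort(unique(traits$species_id))
  extra_p <- setdiff(unique(panel$plot_id), plots)
  if (length(extra_p)) {
    stop("panel plots missing from covariates: ",
         paste(extra_p, collapse = ", "))
  }
  extra_s <- setdiff(unique(panel$species_id), species)
  if (length(extra_s)) {
    stop("panel species missing from traits: ",
         paste(extra_s, collapse = ", "))
  }
  if (is.null(year_range)) {
    year_range <- seq(min(panel$year), max(panel$year))
  }
  year_range <- sort(unique(as.integer(year_range)))
  if (!all(panel$year %in% year_range)) {
    stop("panel years outside year_range: ",
         paste(setdiff(unique(panel$year), year_range), collapse = ", "))
  }

  I <- length(plots); J <- length(species); T_ <- length(year_range)
  y <- array(NA_integer_, dim = c(I, J, T_),
             dimnames = list(plot = plots, species = species,
                             year = year_range))
  y[cbind(match(panel$plot_id, plots),
          match(panel$species_id, species),
          match(panel$year, year_range))] <- panel$present

  # a flora survey records all species: missingness must be survey-level
  obs_count <- apply(!is.na(y), c(1, 3), sum)
  partial <- which(obs_count > 0 & obs_count < J, arr.ind = TRUE)
  if (nrow(partial)) {
    bad <- paste0(plots[partial[, 1]], "/", year_range[partial[, 2]])
    stop("plot-years with records for only some species ",
         "(a survey observes all species): ",
         paste(head(bad, 5), collapse = ", "))
  }

  if (management == "total") {
    for (v in c("mowing", "tillage", "herbicide")) {
      covariates[[v]] <- covariates[[v]] * T_
    }
  }
  covariates <- covariates[match(plots, covariates$plot_id), ]
  cov_std <- standardize_covariates(covariates)
  X <- cbind(1, as.matrix(cov_std[, COVARIATE_COLS]))
  colnames(X) <- COEF_LABELS
  traits <- traits[match(species, traits$species_id), ]

  structure(list(y = y, X = X,
                 covariates = cov_std, traits = traits,
                 plots = plots, species = species, years = year_range,
                 n_surveys = sum(obs_count == J),
                 scaling = attr(cov_std, "scaling")),
            class = "sb_data")
}

#' @export
print.sb_data <- function(x, ...) {
  cat("<sb_data> seed-bank HMM dataset\n")
  cat("  plots:   ", length(x$plots), "\n")
  cat("  species: ", length(x$species), "\n")
  cat("  years:   ", paste(range(x$years), collapse = "-"),
      " (", length(x$years), ")\n", sep = "")
  cat("  surveys: ", x$n_surveys, " observed plot-years\n", sep = "")
  invisible(x)
}
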