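#' Initial state probabilities of the seed-bank HMM
#'
#' The chain runs on three states coding the pair (seed bank last year,
#' standing flora this year): state 1 = (0,0) no seeds and no plants,
#' state 2 = (1,0) seeds but no plants, state 3 = (1,1) seeds and plants.
#' At the first survey the seed bank may already be occupied with
#' probability `p0`; if seeds are present, plants emerge with the
#' germination probability `g`.
#'
#' @param p0 Probability that seeds were in the soil the year before the
#'   first survey.
#' @param g Germination probability (joint probability of germination
#'   success and survival to adulthood).
#' @return Numeric vector `(1 - p0, p0 (1 - g), p0 g)`, summing to 1.
#' @examples
#' build_initial(0.5, 0.2)
#' @export
build_initial <- function(p0, g) {
  check_prob(p0, "p0")
  check_prob(g, "g")
  c(1 - p0, p0 * (1 - g), p0 * g)
}

#' Observation probabilities of the seed-bank HMM
#'
#' Emission is deterministic: the species is recorded absent (observation 0)
#' in states 1 and 2 and present (observation 1) in state 3. There is no
#' detection error in the model.
#'
#' @return A 3 x 2 matrix, states in rows, observations (absent, present)
#'   in columns.
#' @export
build_emission <- function() {
  matrix(c(1, 1, 0,
           0, 0, 1), nrow = 3,
         dimnames = list(state = c("(0,0)", "(1,0)", "(1,1)"),
                         obs = c("absent", "present")))
}

#' Transition probabilities of the seed-bank HMM
#'
#' From an empty plot (state 1) seeds can only arrive from outside, with
#' colonization probability `c`. From a seed bank without standing flora
#' (state 2) seeds persist with survival probability `s` or arrive anew,
#' so the bank remains occupied with probability `1 - (1 - c)(1 - s)`.
#' Standing flora (state 3) replenishes the bank with certainty, hence the
#' structural zero at (3,1). Whenever seeds are present next year, plants
#' emerge with probability `g`.
#'
#' @param g,s,c Germination, seed-bank survival and external colonization
#'   probabilities.
#' @return A 3 x 3 row-stochastic matrix (rows: state at t-1).
#' @examples
#' build_transition(0.5, 0.5, 0.5)
#' @export
build_transition <- function(g, s, c) {
  check_prob(g, "g"); check_prob(s, "s"); check_prob(c, "c")
  q <- 1 - (1 - c) * (1 - s)
  m <- matrix(c(1 - c,             c * (1 - g),  c * g,
                (1 - c) * (1 - s), q * (1 - g),  q * g,
                0,                 1 - g,        g),
              nrow = 3, byrow = TRUE)
  dimnames(m) <- list(from = c("(0,0)", "(1,0)", "(1,1)"),
                      to = c("(0,0)", "(1,0)", "(1,1)"))
  m
}

#' Exact marginal log-likelihood of one presence/absence series
#'
#' Runs the forward algorithm over the hidden three-state chain, with
#' per-step normalization (log normalizers accumulated) so long series do
#' not underflow. An `NA` observation marks an unsurveyed year and is
#' marginalized over both outcomes; the year step is still taken, so gaps
#' never collapse the chain. Probabilities are clamped to
#' `[1e-12, 1 - 1e-12]` before use.
#'
#' @param series Integer vector of 0/1 observations, `NA` for unsurveyed
#'   years; length >= 1.
#' @param p0,g,s,c Demographic probabilities (see [build_transition()]).
#' @return `log P(series | p0, g, s, c)`; 0 for an all-`NA` series.
#' @examples
#' forward_loglik(c(1, 0, 1), p0 = 0.6, g = 0.4, s = 0.7, c = 0.1)
#' @export
forward_loglik <- function(series, p0, g, s, c) {
  series <- check_series(series)
  check_prob(p0, "p0"); check_prob(g, "g"); check_prob(s, "s")
  check_prob(c, "c")
  forward_loglik_cpp(series, p0, g, s, c)
}

#' Enumeration oracle for the series log-likelihood
#'
#' Sums the joint probability of every one of the `3^T` hidden-state paths,
#' built directly from [build_initial()], [build_transition()] and
#' [build_emission()]. Exponential cost; intended as an independent check
#' of [forward_loglik()] on short series.
#'
#' @inheritParams forward_loglik
#' @param max_length Refuse series longer than this (default 12).
#' @return Log-likelihood, `-Inf` if the series is impossible.
#' @export
brute_force_loglik <- function(series, p0, g, s, c, max_length = 12L) {
  series <- check_series(series)
  T_ <- length(series)
  if (T_ > max_length) {
    stop("brute-force enumeration capped at length ", max_length,
         " (cost 3^T); got ", T_)
  }
  init <- build_initial(p0, g)
  trans <- build_transition(g, s, c)
  emit <- build_emission()
  paths <- as.matrix(expand.grid(rep(list(1:3), T_)))
  p <- init[paths[, 1]]
  if (T_ > 1) {
    for (t in 2:T_) p <- p * trans[cbind(paths[, t - 1], paths[, t])]
  }
  for (t in seq_len(T_)) {
    if (!is.na(series[t])) p <- p * emit[cbind(paths[, t], series[t] + 1L)]
  }
  tot <- sum(p)
  if (tot <= 0) -Inf else log(tot)
}

#' Simulate one plot-by-species trajectory
#'
#' Draws the hidden chain from [build_initial()] and [build_transition()];
#' the observation is deterministic given the state (state 3 is the only
#' one with standing flora). Uses the current R random number generator
#' state; seed it with [set.seed()] for reproducibility.
#'
#' @inheritParams forward_loglik
#' @param T_ Number of years (series length), >= 1.
#' @return A list with integer vectors `state` (1..3), `obs` (0/1) and
#'   `seed_bank` (0/1, the hidden seed presence S entering each year).
#' @export
simulate_chain <- function(p0, g, s, c, T_) {
  stopifnot(is.numeric(T_), length(T_) == 1, T_ >= 1)
  T_ <- as.integer(T_)
  init <- build_initial(p0, g)
  trans <- build_transition(g, s, c)
  state <- integer(T_)
  u <- runif(T_)
  cp <- cumsum(init)
  state[1] <- findInterval(u[1], cp, left.open = TRUE) + 1L
  if (T_ > 1) {
    cpt <- t(apply(trans, 1, cumsum))
    for (t in 2:T_) {
      state[t] <- findInterval(u[t], cpt[state[t - 1], ],
                               left.open = TRUE) + 1L
    }
  }
  list(state = state,
       obs = as.integer(state == 3L),
       seed_bank = as.integer(state >= 2L))
}

#' Stationary distribution of the transition matrix
#'
#' Left eigenvector of [build_transition()] for eigenvalue 1, normalized to
#' sum to one.
#'
#' @inheritParams build_transition
#' @return Probability 3-vector.
#' @export
stationary_distribution <- function(g, s, c) {
  trans <- build_transition(g, s, c)
  e <- eigen(t(trans))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop("`", name, "` must be a single probability in [0, 1]",
         call. = FALSE)
  }
  invisible(x)
}

check_series <- function(series) {
  if (length(series) < 1) stop("series must have length >= 1", call. = FALSE)
  if (!all(series %in% c(0L, 1L) | is.na(series))) {
    stop("series values must be 0, 1 or NA", call. = FALSE)
  }
  as.integer(series)
}
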