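#' Parameters of the neutral colonization-extinction model
#'
#' The model is the stochastic island-biogeography description of richness at
#' a site: `dS/dt = c (S_P - S) - e S`, where `S_P` is the species-pool size
#' and `c`, `e` are the per-species colonization and extinction rates.  Solved
#' per species it yields a two-state Markov chain (absent/present) whose
#' stationary occupancy is `c/(c+e)` and whose lag-`dt` autocorrelation is
#' `exp(-(c+e) dt)`.  Equilibrium richness is `c/(c+e) * S_P`.
#'
#' @param c,e Colonization and extinction rates per species per unit time
#'   (both > 0).
#' @param S_P Species-pool size (positive integer).
#' @param S_0 Initial richness, `0 <= S_0 <= S_P`.
#' @param dt Sampling interval in years (default 1).
#' @param n_steps Number of sampled time points.
#' @param seed Optional random seed for [simulate_series()].
#' @return A `neutral_params` list.
#' @export
neutral_params <- function(c, e, S_P, S_0, dt = 1, n_steps, seed = NULL) {
  if (c <= 0 || e <= 0) stop("rates 'c' and 'e' must be positive")
  S_P <- as.integer(S_P)
  S_0 <- as.integer(S_0)
  if (S_P < 1L) stop("'S_P' must be a positive integer")
  if (S_0 < 0L || S_0 > S_P) stop("'S_0' must lie in [0, S_P]")
  if (dt <= 0) stop("'dt' must be positive")
  n_steps <- as.integer(n_steps)
  if (n_steps < 2L) stop("'n_steps' must be at least 2")
  structure(list(c = c, e = e, S_P = S_P, S_0 = S_0, dt = dt,
                 n_steps = n_steps, seed = seed),
            class = "neutral_params")
}

#' @export
#' @method print neutral_params
print.neutral_params <- function(x, ...) {
  cat(sprintf(
    "<neutral_params> c=%.4g e=%.4g S_P=%d S_0=%d dt=%g steps=%d\n",
    x$c, x$e, x$S_P, x$S_0, x$dt, x$n_steps))
  cat(sprintf("  equilibrium richness %.2f, lag-1 autocorrelation %.4f\n",
              x$c / (x$c + x$e) * x$S_P, exp(-(x$c + x$e) * x$dt)))
  invisible(x)
}

#' Transition matrix of the per-species occupancy chain
#'
#' Row-stochastic 2x2 matrix over states (absent, present) for a time step of
#' length `dt`:
#' `P(0 -> 1) = c/(c+e) * (1 - exp(-(c+e) dt))` and
#' `P(1 -> 1) = c/(c+e) + e/(c+e) * exp(-(c+e) dt)`.
#' This equals the matrix exponential of the rate matrix
#' `[[-c, c], [e, -e]]` times `dt`.
#'
#' @inheritParams neutral_params
#' @return 2x2 matrix with dimnames `c("absent", "present")`.
#' @export
transition_probs <- function(c, e, dt = 1) {
  if (c <= 0 || e <= 0) stop("rates 'c' and 'e' must be positive")
  if (dt < 0) stop("'dt' must be non-negative")
  s <- c + e
  decay <- exp(-s * dt)
  p01 <- c / s * (1 - decay)
  p11 <- c / s + e / s * decay
  matrix(c(1 - p01, p01, 1 - p11, p11), nrow = 2, byrow = TRUE,
         dimnames = list(c("absent", "present"), c("absent", "present")))
}

#' Expected richness of the neutral model at time t
#'
#' Closed-form solution of `dS/dt = c (S_P - S) - e S`:
#' `S* + (S_0 - S*) exp(-(c+e) t)` with `S* = c/(c+e) S_P`.  Also the mean of
#' the Markov ensemble at time `t` when starting from `S_0` random occupants.
#'
#' @param params A [neutral_params()] object.
#' @param t Time (or vector of times) since the initial condition, >= 0.
#' @return Expected richness at each `t`.
#' @export
expected_richness <- function(params, t) {
  stopifnot(inherits(params, "neutral_params"), all(t >= 0))
  s_star <- params$c / (params$c + params$e) * params$S_P
  s_star + (params$S_0 - s_star) * exp(-(params$c + params$e) * t)
}

#' Lag-dt autocorrelation of the per-species occupancy chain
#'
#' @inheritParams transition_probs
#' @return `exp(-(c+e) dt)`, the correlation between a species' occupancy at
#'   two samples `dt` apart under stationarity.
#' @export
lag1_autocorrelation <- function(c, e, dt = 1) {
  if (c <= 0 || e <= 0) stop("rates 'c' and 'e' must be positive")
  exp(-(c + e) * dt)
}

#' Solve rates from a target autocorrelation and imbalance ratio
#'
#' Inverse of [lag1_autocorrelation()]: given the lag-`dt` autocorrelation
#' `rho` and the ratio `c/e`, returns the unique `(c, e)` with
#' `c + e = -log(rho)/dt` split so that `c/e = ratio`.
#'
#' @param rho Target autocorrelation in (0, 1).
#' @param ratio Colonization/extinction imbalance `c/e` (> 0); 1 is the
#'   balanced null.
#' @param dt Sampling interval.
#' @return Named numeric vector `c(c = ..., e = ...)`.
#' @export
rates_from_autocorrelation <- function(rho, ratio = 1, dt = 1) {
  if (rho <= 0 || rho >= 1) stop("'rho' must lie strictly in (0, 1)")
  if (ratio <= 0) stop("'ratio' must be positive")
  s <- -log(rho) / dt
  e <- s / (1 + ratio)
  c(c = s - e, e = e)
}

#' Simulate a presence-absence community series under the neutral model
#'
#' Runs `S_P` independent per-species two-state Markov chains.  Exactly `S_0`
#' species (chosen uniformly at random) are present at the first sample; each
#' later sample is drawn from [transition_probs()].  With `years` supplied,
#' gaps in the sampling grid use the real elapsed time in the transition
#' kernel rather than assuming consecutive samples.
#'
#' @param params A [neutral_params()] object.
#' @param years Optional vector of sampled years (strictly increasing,
#'   length `n_steps`); defaults to `start_year + (0:(n_steps-1)) * dt`.
#' @param start_year First sampled year when `years` is not given.
#' @return A [community_series()].  Note that pool species never observed are
#'   dropped by the constructor, so the matrix may have fewer than `S_P` rows.
#' @export
simulate_series <- function(params, years = NULL, start_year = 1L) {
  stopifnot(inherits(params, "neutral_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  if (is.null(years)) {
    years <- as.integer(round(start_year + (seq_len(params$n_steps) - 1L) * params$dt))
  }
  years <- as.integer(years)
  if (length(years) != params$n_steps || any(diff(years) <= 0L))
    stop("'years' must be strictly increasing with length n_steps")
  occ <- simulate_occupancy(params$c, params$e, params$S_P, params$S_0, years)
  community_series(series_id = paste0("sim", sample.int(.Machine$integer.max, 1L)),
                   years = years, occupancy = occ)
}

# Raw occupancy simulation on a given year grid (no class wrapping, no seed
# handling).  Shared by simulate_series() and the scenario generators.
simulate_occupancy <- function(c, e, S_P, S_0, years) {
  n <- length(years)
  occ <- matrix(0L, nrow = S_P, ncol = n,
                dimnames = list(paste0("sp", seq_len(S_P)), years))
  state <- integer(S_P)
  if (S_0 > 0L) state[sample.int(S_P, S_0)] <- 1L
  occ[, 1L] <- state
  gaps <- diff(years)
  for (j in seq_len(n - 1L)) {
    P <- transition_probs(c, e, dt = gaps[j])
    p_up <- ifelse(state == 1L, P["present", "present"], P["absent", "present"])
    state <- as.integer(stats::runif(S_P) < p_up)
    occ[, j + 1L] <- state
  }
  occ
}

#' Estimate colonization and extinction rates from a series
#'
#' Empirical rates are event counts over the series duration: the number of
#' per-species 0->1 transitions between consecutive sampled years, divided by
#' the length of the time series (and symmetrically 1->0 for extinction).
#'
#' @param series A [community_series()].
#' @param length_type How to measure series length: `"span"` (last year minus
#'   first year, the default) or `"n_years"` (count of sampled years).
#' @param per_species Divide additionally by the number of species rows, to
#'   calibrate per-species rates `c` and `e` rather than community totals.
#' @return Named numeric vector `c(c_hat = ..., e_hat = ...)`.
#' @export
estimate_rates <- function(series, length_type = c("span", "n_years"),
                           per_species = FALSE) {
  stopifnot(inherits(series, "community_series"))
  length_type <- match.arg(length_type)
  occ <- series$occupancy
  if (ncol(occ) < 2L) stop("need at least 2 sampled years to estimate rates")
  d <- occ[, -1L, drop = FALSE] - occ[, -ncol(occ), drop = FALSE]
  n_col <- sum(d == 1L)
  n_ext <- sum(d == -1L)
  len <- switch(length_type,
                span = diff(range(series$years)),
                n_years = length(series$years))
  denom <- len * if (per_species) nrow(occ) else 1
  c(c_hat = n_col / denom, e_hat = n_ext / denom)
}
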