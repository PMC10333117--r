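#' Specification of a synthetic survey-style dataset
#'
#' Describes a batch of independent neutral community series whose summary
#' structure emulates large survey compilations: per-series sampled-year
#' counts drawn from a discretized normal truncated at a minimum length,
#' species-pool sizes from a lognormal, and per-species dynamics from the
#' neutral colonization-extinction chain at a target lag-1 autocorrelation
#' and colonization/extinction imbalance.
#'
#' Two presets approximate the moment structure of the empirical compilations
#' the method is aimed at: `"fish"` (riverine fish style: 12 sampled years on
#' average, sd 6.6, modest pools) and `"bird"` (breeding-bird style: mean 29,
#' sd 12.5, larger pools).  They are moment-matched approximations, not
#' reproductions of any empirical histogram.
#'
#' @param n_series Number of series to generate.
#' @param preset `"fish"`, `"bird"`, or `"custom"`.
#' @param length_mean,length_sd,length_min Sampled-year count distribution
#'   (discretized normal, truncated below at `length_min`, default 10 — the
#'   usual inclusion filter for trend analyses).
#' @param pool_meanlog,pool_sdlog Lognormal parameters for species-pool size.
#' @param rho Target lag-1 autocorrelation `exp(-(c+e))` in (0, 1).
#' @param ratio Colonization/extinction imbalance `c/e`; 1 = balanced null.
#' @param init `"stationary"` draws initial richness from the stationary
#'   binomial; `"fraction"` fixes initial occupancy at `init_occupancy`.
#' @param init_occupancy Initial occupancy fraction when `init = "fraction"`.
#' @param year_range Calendar window within which series are placed.
#' @param seed Master seed; series `i` derives its own seed from it.
#' @return A `dataset_spec` list.
#' @export
dataset_spec <- function(n_series = 100L,
                         preset = c("custom", "fish", "bird"),
                         length_mean = 20, length_sd = 8, length_min = 10L,
                         pool_meanlog = log(30), pool_sdlog = 0.4,
                         rho = 0.6, ratio = 1,
                         init = c("stationary", "fraction"),
                         init_occupancy = NULL,
                         year_range = c(1951L, 2019L), seed = 1L) {
  preset <- match.arg(preset)
  init <- match.arg(init)
  if (preset == "fish") {
    length_mean <- 12; length_sd <- 6.6
    pool_meanlog <- log(15); pool_sdlog <- 0.4
    year_range <- c(1951L, 2019L)
  } else if (preset == "bird") {
    length_mean <- 29; length_sd <- 12.5
    pool_meanlog <- log(60); pool_sdlog <- 0.3
    year_range <- c(1966L, 2021L)
  }
  if (rho <= 0 || rho >= 1) stop("'rho' must lie in (0, 1)")
  if (init == "fraction" &&
      (is.null(init_occupancy) || init_occupancy < 0 || init_occupancy > 1))
    stop("'init_occupancy' in [0,1] required when init = 'fraction'")
  structure(list(n_series = as.integer(n_series), preset = preset,
                 length_mean = length_mean, length_sd = length_sd,
                 length_min = as.integer(length_min),
                 pool_meanlog = pool_meanlog, pool_sdlog = pool_sdlog,
                 rho = rho, ratio = ratio, init = init,
                 init_occupancy = init_occupancy,
                 year_range = as.integer(year_range), seed = as.integer(seed)),
            class = "dataset_spec")
}

#' @export
#' @method print dataset_spec
print.dataset_spec <- function(x, ...) {
  cat(sprintf(
    "<dataset_spec> %d series (preset %s): length ~ N(%g, %g) >= %d, rho=%g, c/e=%g\n",
    x$n_series, x$preset, x$length_mean, x$length_sd, x$length_min,
    x$rho, x$ratio))
  invisible(x)
}

draw_length <- function(mean, sd, min, cap = 1000L) {
  for (i in seq_len(cap)) {
    l <- as.integer(round(stats::rnorm(1, mean, sd)))
    if (l >= min) return(l)
  }
  stop("length distribution rarely exceeds the minimum; check spec")
}

#' Generate a collection of neutral community series
#'
#' Draws `n_series` independent series per the [dataset_spec()]: length, pool
#' size and initial richness per series, then neutral per-species dynamics via
#' [simulate_series()] at the spec's autocorrelation and imbalance.
#' Reproducible: series `i` is simulated under seed `spec$seed + i`.
#'
#' @param spec A [dataset_spec()].
#' @return A `series_collection`; each series carries its generating
#'   [neutral_params()] in attribute `"params"` (ground truth for recovery
#'   tests).
#' @export
generate_neutral_dataset <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  rates <- rates_from_autocorrelation(spec$rho, ratio = spec$ratio)
  occ_star <- rates["c"] / (rates["c"] + rates["e"])
  series <- vector("list", spec$n_series)
  for (i in seq_len(spec$n_series)) {
    set.seed(spec$seed + i)
    len <- draw_length(spec$length_mean, spec$length_sd, spec$length_min)
    S_P <- max(2L, as.integer(round(stats::rlnorm(1, spec$pool_meanlog,
                                                  spec$pool_sdlog))))
    S_0 <- switch(spec$init,
                  stationary = stats::rbinom(1L, S_P, occ_star),
                  fraction = as.integer(round(spec$init_occupancy * S_P)))
    start_max <- spec$year_range[2L] - len + 1L
    start <- if (start_max > spec$year_range[1L])
      sample(spec$year_range[1L]:start_max, 1L) else spec$year_range[1L]
    params <- neutral_params(c = rates["c"], e = rates["e"], S_P = S_P,
                             S_0 = S_0, dt = 1, n_steps = len)
    occ <- simulate_occupancy(params$c, params$e, S_P, S_0,
                              years = start + 0:(len - 1L))
    s <- community_series(sprintf("synth%04d", i), start + 0:(len - 1L), occ)
    attr(s, "params") <- params
    series[[i]] <- s
  }
  series_collection(series,
                    source = sprintf("synthetic neutral (%s preset)", spec$preset),
                    filters = sprintf("min_years>=%d", spec$length_min))
}

#' Winners/losers turnover scenario
#'
#' Steady compositional change: `n_losers` species start present and flip
#' permanently absent at `window start + extinction_lag` (plus uniform
#' jitter), `n_winners` start absent and flip permanently present at
#' `window start + colonization_lag` (plus jitter); the rest of the pool is
#' persistent background.  With equal winner and loser counts but
#' colonizations earlier than extinctions, observed richness rises over the
#' finite window even though total turnover is balanced.
#'
#' @param n_pool Total species pool (>= winners + losers).
#' @param n_winners,n_losers Numbers of colonizing and declining species.
#' @param years Sampled years of the window.
#' @param colonization_lag,extinction_lag Mean years from window start to the
#'   flips (>= 0).
#' @param jitter_span Half-width of the uniform jitter on flip times.
#' @param seed Optional seed.
#' @return A [community_series()]; flips landing beyond the window leave the
#'   species in its initial state throughout (censored, still valid).
#' @export
generate_turnover_scenario <- function(n_pool, n_winners, n_losers, years,
                                       colonization_lag, extinction_lag,
                                       jitter_span = 2, seed = NULL) {
  stopifnot(n_pool >= n_winners + n_losers,
            colonization_lag >= 0, extinction_lag >= 0)
  if (!is.null(seed)) set.seed(seed)
  years <- as.integer(years)
  n <- length(years)
  start <- years[1L]
  n_bg <- n_pool - n_winners - n_losers
  occ <- matrix(0L, n_pool, n)
  rownames(occ) <- c(sprintf("bg%03d", seq_len(n_bg)),
                     sprintf("loser%03d", seq_len(n_losers)),
                     sprintf("winner%03d", seq_len(n_winners)))[seq_len(n_pool)]
  if (n_bg > 0L) occ[seq_len(n_bg), ] <- 1L
  jit <- function(m) stats::runif(m, -jitter_span, jitter_span)
  if (n_losers > 0L) {
    flips <- start + extinction_lag + jit(n_losers)
    for (i in seq_len(n_losers))
      occ[n_bg + i, years <= flips[i]] <- 1L
  }
  if (n_winners > 0L) {
    flips <- start + colonization_lag + jit(n_winners)
    for (i in seq_len(n_winners))
      occ[n_bg + n_losers + i, years >= flips[i]] <- 1L
  }
  community_series("turnover", years, occ)
}

#' Directional change scenario (extinction debt / immigration credit)
#'
#' Neutral dynamics with a step change in the rates at a configurable sample:
#' the community starts at the equilibrium of the initial rates and then
#' relaxes exponentially toward the new equilibrium with half-life
#' `log(2)/(c2+e2)` — delayed richness loss after degradation (extinction
#' debt) or delayed gain after improvement (immigration credit).
#'
#' @param kind `"decline"` (extinction rate multiplied by `shift`, lower
#'   equilibrium) or `"improvement"` (colonization rate multiplied).
#' @param S_P Species-pool size.
#' @param n_steps Number of sampled years.
#' @param change_at Sample index at which the rates change.
#' @param c,e Initial rates.
#' @param shift Multiplicative size of the step (> 1).
#' @param seed Optional seed.
#' @return A [community_series()] with attributes `"params_before"` and
#'   `"params_after"` ([neutral_params()], ground truth).
#' @export
generate_directional_scenario <- function(kind = c("decline", "improvement"),
                                          S_P = 100L, n_steps = 40L,
                                          change_at = 10L, c = 0.15, e = 0.15,
                                          shift = 2, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(shift > 1, change_at >= 2L, change_at < n_steps)
  if (!is.null(seed)) set.seed(seed)
  c2 <- if (kind == "improvement") c * shift else c
  e2 <- if (kind == "decline") e * shift else e
  S_0 <- as.integer(round(c / (c + e) * S_P))
  years <- seq_len(n_steps)
  occ1 <- simulate_occupancy(c, e, S_P, S_0, years = years[seq_len(change_at)])
  # continue each chain from its state at the change point under new rates
  occ2 <- matrix(0L, S_P, n_steps - change_at)
  state <- occ1[, change_at]
  P <- transition_probs(c2, e2, dt = 1)
  for (j in seq_len(ncol(occ2))) {
    p_up <- ifelse(state == 1L, P["present", "present"], P["absent", "present"])
    state <- as.integer(stats::runif(S_P) < p_up)
    occ2[, j] <- state
  }
  occ <- cbind(occ1, occ2)
  rownames(occ) <- paste0("sp", seq_len(S_P))
  s <- community_series(paste0(kind, "_scenario"), years, occ)
  attr(s, "params_before") <- neutral_params(c, e, S_P, S_0, 1, n_steps)
  attr(s, "params_after") <- neutral_params(c2, e2, S_P, S_0, 1, n_steps)
  s
}
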