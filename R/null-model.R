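#' Chronosequence randomization of a community series
#'
#' The temporal null model: each species' yearly chronosequence is permuted
#' across the series' sampled years, destroying year-to-year autocorrelation
#' in species dynamics while conserving every per-species occupancy total and
#' the sampling grid exactly.  With `unit = "year"`, whole community columns
#' are permuted instead, additionally preserving species co-occurrence within
#' years; both variants zero species-level temporal autocorrelation.
#'
#' Abundances, when present, travel with their presence cells.
#'
#' @param series A [community_series()].
#' @param seed Optional seed for reproducibility.
#' @param unit Permute each `"species"` row independently (default) or whole
#'   `"year"` columns.
#' @return A randomized `community_series` (id suffixed `"_null"`).
#' @export
randomize_chronosequences <- function(series, seed = NULL,
                                      unit = c("species", "year")) {
  stopifnot(inherits(series, "community_series"))
  unit <- match.arg(unit)
  if (!is.null(seed)) set.seed(seed)
  occ <- series$occupancy
  ab <- series$abundance
  n <- ncol(occ)
  if (unit == "species") {
    for (i in seq_len(nrow(occ))) {
      p <- sample.int(n)
      occ[i, ] <- occ[i, p]
      if (!is.null(ab)) ab[i, ] <- ab[i, p]
    }
  } else {
    p <- sample.int(n)
    occ <- occ[, p, drop = FALSE]
    if (!is.null(ab)) ab <- ab[, p, drop = FALSE]
  }
  colnames(occ) <- series$years
  if (!is.null(ab)) colnames(ab) <- series$years
  community_series(paste0(series$series_id, "_null"), series$years, occ,
                   abundance = ab)
}

#' Ensemble of chronosequence randomizations
#'
#' Runs [randomize_chronosequences()] `n_rand` times with seeds derived
#' deterministically from `seed`, and summarises each randomization with its
#' log-richness trend (and optionally its final NICE).
#'
#' @param series A [community_series()].
#' @param n_rand Number of randomizations (>= 1).
#' @param seed Master seed; randomization `i` uses `seed + i`.
#' @param unit Passed to [randomize_chronosequences()].
#' @param nice Also compute each randomization's NICE trajectory final value
#'   (slower; needs OLE per randomization).
#' @return List of class `null_ensemble`: `series` (the randomized series),
#'   `summary` (data.frame with `rep`, `slope`, `se`, `p_value` and, if
#'   requested, `final_nice`).
#' @export
null_ensemble <- function(series, n_rand, seed = 1L,
                          unit = c("species", "year"), nice = FALSE) {
  stopifnot(inherits(series, "community_series"), n_rand >= 1L)
  unit <- match.arg(unit)
  reps <- vector("list", n_rand)
  rows <- vector("list", n_rand)
  for (i in seq_len(n_rand)) {
    r <- randomize_chronosequences(series, seed = seed + i, unit = unit)
    reps[[i]] <- r
    fit <- richness_trend(r)
    rows[[i]] <- data.frame(rep = i, slope = fit$slope, se = fit$se,
                            p_value = fit$p_value,
                            final_nice = if (nice)
                              final_nice(nice_trajectory(r)) else NA_real_)
  }
  out <- list(series = reps, summary = do.call(rbind, rows),
              source_id = series$series_id, unit = unit)
  class(out) <- "null_ensemble"
  out
}

#' @export
#' @method print null_ensemble
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %d randomizations of series %s (unit=%s)\n",
              length(x$series), x$source_id, x$unit))
  cat(sprintf("  mean richness slope %.4g (sd %.4g)\n",
              mean(x$summary$slope), stats::sd(x$summary$slope)))
  invisible(x)
}
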