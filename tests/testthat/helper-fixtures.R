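# Shared fixtures and independent oracles used across the suite.

# Random small community series with a fixed seed.
random_series <- function(seed, n_species = 8L, n_years = 12L,
                          p_present = 0.5, gaps = FALSE, abundance = FALSE) {
  set.seed(seed)
  years <- if (gaps) sort(sample(2000:2030, n_years)) else 2000L + seq_len(n_years) - 1L
  occ <- matrix(rbinom(n_species * n_years, 1L, p_present), n_species, n_years)
  # every species observed at least once, every sampled year non-empty
  # (matching real survey tables, where a sample exists only if something
  # was recorded)
  empty <- rowSums(occ) == 0L
  occ[cbind(which(empty), sample.int(n_years, sum(empty), replace = TRUE))] <- 1L
  empty_yr <- colSums(occ) == 0L
  occ[cbind(sample.int(n_species, sum(empty_yr), replace = TRUE),
            which(empty_yr))] <- 1L
  rownames(occ) <- sprintf("sp%02d", seq_len(n_species))
  ab <- NULL
  if (abundance) {
    ab <- occ * matrix(rpois(length(occ), 4) + 1L, nrow(occ))
  }
  community_series(paste0("rs", seed), years, occ, abundance = ab)
}

# Brute-force GLS oracle for the OLE weights: minimise w' L w subject to
# sum(w) = 1 by solving the augmented KKT system with qr.solve, building L
# with direct gamma() calls.  Independent of the package's lgamma/solve path.
ole_oracle_estimate <- function(sighting_years) {
  t <- rev(sort(unique(as.numeric(sighting_years))))
  k <- length(t)
  v <- sum(log((t[1] - t[k]) / (t[1] - t[2:(k - 1)]))) / (k - 1)
  L <- outer(seq_len(k), seq_len(k), function(i, j) {
    lo <- pmin(i, j); hi <- pmax(i, j)
    gamma(2 * v + hi) * gamma(v + lo) / (gamma(v + hi) * gamma(lo))
  })
  A <- rbind(cbind(2 * L, rep(1, k)), c(rep(1, k), 0))
  sol <- qr.solve(A, c(rep(0, k), 1))
  list(weights = sol[seq_len(k)], estimate = sum(sol[seq_len(k)] * t))
}

# Direct access to the package-internal weight routine for oracle comparisons.
ole_pkg_weights <- function(t_desc) {
  getFromNamespace("ole_weights", "nicetrends")(t_desc)
}

# Occupancy simulation shortcut on the internal routine (no class wrapper).
sim_occ <- function(c, e, S_P, S_0, years) {
  getFromNamespace("simulate_occupancy", "nicetrends")(c, e, S_P, S_0, years)
}
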