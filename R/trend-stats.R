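#' Per-series trend in log species richness
#'
#' Ordinary least squares of `log(richness)` on calendar year, the year
#' covariate centered within the series so the intercept is the mid-window log
#' richness.  The slope is the proportional change in richness per calendar
#' year.
#'
#' Simulated series can hit zero richness in a sampled year; such years are
#' dropped by default (`zero_years = "drop"`) or kept via `log1p`
#' (`zero_years = "log1p"`).  Empirical survey series never contain them.
#'
#' @param series A [community_series()], or a numeric vector of richness
#'   values with `years` supplied.
#' @param years Sampled years when `series` is a plain richness vector.
#' @param zero_years How to treat zero-richness years.
#' @return An object of class `trend_fit`: `slope`, `se`, `p_value`,
#'   `n_years`, `r_squared`, `series_id`.
#' @export
richness_trend <- function(series, years = NULL,
                           zero_years = c("drop", "log1p")) {
  zero_years <- match.arg(zero_years)
  if (inherits(series, "community_series")) {
    rich <- as.numeric(richness(series))
    years <- series$years
    id <- series$series_id
  } else {
    rich <- as.numeric(series)
    if (is.null(years)) stop("'years' required for a plain richness vector")
    id <- NA_character_
  }
  if (zero_years == "drop") {
    keep <- rich > 0
    rich <- rich[keep]
    years <- years[keep]
    y <- log(rich)
  } else {
    y <- log1p(rich)
  }
  if (length(y) < 3L) stop("need at least 3 usable years for a trend")
  x <- years - mean(years)
  if (stats::var(x) == 0) stop("zero variance in year covariate")
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exact fits; the degenerate case is handled below
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2L])
  se <- sm$coefficients[2L, 2L]
  p <- sm$coefficients[2L, 4L]
  if (!is.finite(se)) se <- 0
  if (sm$sigma < 1e-12 * max(1, abs(mean(y)))) {
    # perfect fit: the t statistic is 0/0 noise; report the boundary values
    se <- 0
    p <- if (abs(slope) < 1e-12) 1 else 0
  }
  if (!is.finite(p)) p <- if (abs(slope) < 1e-12) 1 else 0
  structure(list(slope = slope, se = se, p_value = p,
                 n_years = length(y), r_squared = sm$r.squared,
                 series_id = id),
            class = "trend_fit")
}

#' @export
#' @method print trend_fit
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "<trend_fit> series %s: slope %.4g /yr (se %.3g, p %.3g, n=%d years)\n",
    x$series_id, x$slope, x$se, x$p_value, x$n_years))
  invisible(x)
}

#' @export
coef.trend_fit <- function(object, ...) c(slope = object$slope)

#' Long table of per-year (log) richness for a collection
#'
#' @param coll A `series_collection`.
#' @param log Return `log(richness)` (default) or raw richness.
#' @param zero_years Zero-richness policy, as in [richness_trend()].
#' @return data.frame with columns `series_id`, `year`, `value`.
#' @export
richness_long <- function(coll, log = TRUE,
                          zero_years = c("drop", "log1p")) {
  stopifnot(inherits(coll, "series_collection"))
  zero_years <- match.arg(zero_years)
  rows <- lapply(coll$series, function(s) {
    r <- as.numeric(richness(s))
    yr <- s$years
    if (zero_years == "drop") {
      keep <- r > 0
      r <- r[keep]; yr <- yr[keep]
      v <- if (log) base::log(r) else r
    } else {
      v <- if (log) log1p(r) else r
    }
    if (!length(v)) return(NULL)
    data.frame(series_id = s$series_id, year = yr, value = v,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Shared linear-mixed-model machinery: value ~ year (centered per series)
# with by-series random intercepts and slopes, REML, Wald p-values,
# Nakagawa-style marginal/conditional R2 (random-slope extension: the random
# variance entering R2 is the mean of diag(Z V Z')).
fit_mixed_trend <- function(df, response_label) {
  stopifnot(all(c("series_id", "year", "value") %in% names(df)))
  df <- df[is.finite(df$value), , drop = FALSE]
  if (length(unique(df$series_id)) < 2L)
    stop("mixed trend needs at least 2 series")
  df$year_c <- df$year - stats::ave(df$year, df$series_id)
  form <- value ~ year_c + (1 + year_c | series_id)
  structure_used <- "intercept+slope"
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(form, data = df, REML = TRUE))),
    error = function(err) NULL)
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) {
    if (!is.null(fit))
      warning("random slope+intercept fit singular; refitting intercept-only")
    fit2 <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(value ~ year_c + (1 | series_id), data = df, REML = TRUE))),
      error = function(err) NULL)
    if (!is.null(fit2)) {
      if (is.null(fit)) {
        fit <- fit2
        structure_used <- "intercept"
      } else if (lme4::isSingular(fit, tol = 1e-5) &&
                 !lme4::isSingular(fit2, tol = 1e-5)) {
        fit <- fit2
        structure_used <- "intercept"
      }
    }
    if (is.null(fit)) stop("mixed model failed to fit")
  }
  beta <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- beta[["year_c"]] / se[2L]
  p <- 2 * stats::pnorm(-abs(z))
  # variance components for R2
  sigma2 <- stats::sigma(fit)^2
  X <- stats::model.matrix(fit)
  var_fixed <- stats::var(as.numeric(X %*% beta))
  v00 <- vc$vcov[vc$grp == "series_id" & vc$var1 == "(Intercept)" &
                   is.na(vc$var2)]
  v11 <- vc$vcov[vc$grp == "series_id" & vc$var1 == "year_c" & is.na(vc$var2)]
  v01 <- vc$vcov[vc$grp == "series_id" & vc$var1 == "(Intercept)" &
                   !is.na(vc$var2) & vc$var2 == "year_c"]
  if (!length(v11)) v11 <- 0
  if (!length(v01)) v01 <- 0
  xc <- df$year_c
  var_rand <- mean(v00 + 2 * v01 * xc + v11 * xc^2)
  tot <- var_fixed + var_rand + sigma2
  structure(list(fixed_slope = unname(beta[["year_c"]]),
                 fixed_se = unname(se[2L]), p_value = unname(p),
                 marginal_R2 = var_fixed / tot,
                 conditional_R2 = (var_fixed + var_rand) / tot,
                 varcomp = c(intercept = v00, slope = v11, cov = v01,
                             residual = sigma2),
                 n_series = length(unique(df$series_id)), n_obs = nrow(df),
                 random_structure = structure_used,
                 response = response_label, fit = fit),
            class = "mixed_fit")
}

#' Cross-series mixed-effects trend in log richness
#'
#' Linear mixed model of log richness on year (centered per series) with
#' by-series random intercepts and slopes, fitted by REML through
#' \pkg{lme4}.  The fixed slope is the overall per-year trend across series;
#' Wald p-values; marginal and conditional R-squared follow the standard
#' variance-partition formulas for mixed models (fixed vs fixed+random
#' variance over total).  Singular random-slope fits fall back to
#' random intercepts only, with a warning.
#'
#' @param x A `series_collection`, or a data.frame with columns `series_id`,
#'   `year`, `value` (the response, already transformed).
#' @param zero_years Zero-richness policy when `x` is a collection.
#' @return An object of class `mixed_fit`.
#' @export
mixed_trend <- function(x, zero_years = c("drop", "log1p")) {
  if (inherits(x, "series_collection"))
    x <- richness_long(x, log = TRUE, zero_years = match.arg(zero_years))
  fit_mixed_trend(x, response_label = "log richness")
}

#' Cross-series mixed-effects trend in NICE
#'
#' Same mixed-model contract as [mixed_trend()] with the per-year NICE value
#' as response.  Years where NICE is undefined (no events counted yet) are
#' excluded.
#'
#' @param trajectories A list of [nice_trajectory()] objects, or a data.frame
#'   with columns `series_id`, `year`, `value`.
#' @return An object of class `mixed_fit`.
#' @export
nice_trend <- function(trajectories) {
  if (is.data.frame(trajectories)) {
    df <- trajectories
  } else {
    rows <- lapply(trajectories, function(tr) {
      stopifnot(inherits(tr, "nice_trajectory"))
      data.frame(series_id = attr(tr, "series_id"), year = tr$year,
                 value = tr$nice, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  df <- df[!is.na(df$value), , drop = FALSE]
  fit_mixed_trend(df, response_label = "NICE")
}

#' @export
#' @method print mixed_fit
print.mixed_fit <- function(x, ...) {
  cat(sprintf("<mixed_fit> %s ~ year, %d series / %d observations\n",
              x$response, x$n_series, x$n_obs))
  cat(sprintf("  fixed slope %.4g /yr (se %.3g, Wald p %.3g)\n",
              x$fixed_slope, x$fixed_se, x$p_value))
  cat(sprintf("  marginal R2 %.3f, conditional R2 %.3f (random: %s)\n",
              x$marginal_R2, x$conditional_R2, x$random_structure))
  invisible(x)
}

#' @export
coef.mixed_fit <- function(object, ...) c(slope = object$fixed_slope)

#' @export
#' @method summary mixed_fit
summary.mixed_fit <- function(object, ...) {
  print(object)
  cat("  variance components:\n")
  print(round(object$varcomp, 6))
  invisible(object)
}

#' One-sample t-test on final NICE values
#'
#' Two-sided Student's t-test of whether the mean final NICE across series
#' differs from 0 (i.e. whether counted colonizations and extinctions are in
#' balance at the end of the observation windows).
#'
#' @param values Final NICE values, one per series; `NA`s dropped.
#' @return List of class `nice_test`: `mean`, `sd`, `t`, `p_value`, `df`, `n`.
#' @export
nice_final_test <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) stop("need at least 2 non-missing final NICE values")
  if (stats::sd(v) == 0)
    stop("degenerate sample: all final NICE values identical")
  tt <- stats::t.test(v, mu = 0)
  structure(list(mean = unname(tt$estimate), sd = stats::sd(v),
                 t = unname(tt$statistic), p_value = tt$p.value,
                 df = unname(tt$parameter), n = length(v)),
            class = "nice_test")
}

#' @export
#' @method print nice_test
print.nice_test <- function(x, ...) {
  cat(sprintf(
    "<nice_test> mean final NICE %.3f (sd %.3f, n=%d): t=%.2f, p=%.3g\n",
    x$mean, x$sd, x$n, x$t, x$p_value))
  invisible(x)
}
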