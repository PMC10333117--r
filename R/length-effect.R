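#' Heteroscedastic-normal model of trend estimates against series length
#'
#' Short time series give noisier trend estimates: both the mean and the
#' spread of per-series slopes can depend on series length.  This model fits
#' `trend_i ~ Normal(mu_i, sigma_i^2)` with
#' `mu_i = a0 + a1 * L_i` (identity link) and
#' `log(sigma_i) = b0 + b1 * L_i` (log link, so fitted standard deviations are
#' positive everywhere), jointly by maximum likelihood.  It is the
#' two-parameter location-scale analogue of the GAMLSS family commonly used
#' for this question, restricted to linear terms.
#'
#' A negative `b1` means longer series give tighter trend estimates — the
#' funnel shape typical of length-vs-slope scatter in survey compilations.
#'
#' @param trends Numeric vector of per-series trend estimates (e.g. slopes
#'   from [richness_trend()]), or a list of `trend_fit` objects.
#' @param lengths Per-series length (sampled-year counts), same order.
#' @return Object of class `hetnorm_fit` with components `coefficients`
#'   (`a0`, `a1`, `b0`, `b1`), `se`, `p_values` (Wald), `vcov`, `logLik`,
#'   `logLik_homosced` (constrained `b1 = 0` submodel), `pseudo_R2`
#'   (Cox-Snell against the intercept-only homoscedastic null), `n`, `data`.
#' @examples
#' set.seed(1)
#' L <- sample(10:50, 400, replace = TRUE)
#' y <- rnorm(400, mean = 0.01, sd = exp(-1 - 0.04 * L))
#' fit <- length_effect(y, L)
#' coef(fit)
#' predict(fit, lengths = c(10, 30, 50), quantiles = c(0.05, 0.5, 0.95))
#' @export
length_effect <- function(trends, lengths) {
  if (is.list(trends) && all(vapply(trends, inherits, logical(1), "trend_fit")))
    trends <- vapply(trends, `[[`, numeric(1), "slope")
  y <- as.numeric(trends)
  L <- as.numeric(lengths)
  stopifnot(length(y) == length(L))
  keep <- is.finite(y) & is.finite(L)
  y <- y[keep]; L <- L[keep]
  if (length(y) < 10L) stop("need at least 10 series")
  if (length(unique(L)) < 2L) stop("need at least 2 distinct lengths")

  nll <- function(theta) {
    mu <- theta[1L] + theta[2L] * L
    ls <- theta[3L] + theta[4L] * L
    if (any(ls > 50) || any(ls < -50)) return(1e10)
    sum(0.5 * log(2 * pi) + ls + 0.5 * ((y - mu) / exp(ls))^2)
  }
  ols <- stats::lm(y ~ L)
  start <- c(stats::coef(ols)[1L], stats::coef(ols)[2L],
             log(stats::sd(stats::resid(ols))), 0)
  opt <- stats::optim(start, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0)
    stop("heteroscedastic fit did not converge (code ", opt$convergence, ")")
  theta <- opt$par
  names(theta) <- c("a0", "a1", "b0", "b1")
  vc <- tryCatch(solve(opt$hessian), error = function(err)
    matrix(NA_real_, 4, 4))
  dimnames(vc) <- list(names(theta), names(theta))
  se <- sqrt(pmax(diag(vc), 0))
  p <- 2 * stats::pnorm(-abs(theta / se))
  ll <- -opt$value

  # nested submodels for the likelihood comparisons
  nll_hom <- function(th) nll(c(th[1L], th[2L], th[3L], 0))
  opt_hom <- stats::optim(start[1:3], nll_hom, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12))
  ll_hom <- -opt_hom$value
  ll_null <- sum(stats::dnorm(y, mean(y), stats::sd(y) *
                                sqrt((length(y) - 1) / length(y)), log = TRUE))
  pseudo_R2 <- 1 - exp(-2 * (ll - ll_null) / length(y))

  structure(list(coefficients = theta, se = se, p_values = p, vcov = vc,
                 logLik = ll, logLik_homosced = ll_hom, logLik_null = ll_null,
                 pseudo_R2 = pseudo_R2, n = length(y),
                 data = data.frame(trend = y, length = L)),
            class = "hetnorm_fit")
}

#' @export
#' @method print hetnorm_fit
print.hetnorm_fit <- function(x, ...) {
  cat(sprintf("<hetnorm_fit> heteroscedastic normal, n=%d series\n", x$n))
  cat(sprintf("  mean:    %.4g %+.4g * length  (p_slope = %.3g)\n",
              x$coefficients["a0"], x$coefficients["a1"], x$p_values["a1"]))
  cat(sprintf("  log sd:  %.4g %+.4g * length  (p_slope = %.3g)\n",
              x$coefficients["b0"], x$coefficients["b1"], x$p_values["b1"]))
  cat(sprintf("  logLik %.2f, pseudo-R2 %.3f\n", x$logLik, x$pseudo_R2))
  invisible(x)
}

#' @export
coef.hetnorm_fit <- function(object, ...) object$coefficients

#' @export
vcov.hetnorm_fit <- function(object, ...) object$vcov

#' @export
logLik.hetnorm_fit <- function(object, ...) {
  structure(object$logLik, df = 4L, nobs = object$n, class = "logLik")
}

#' @export
#' @method summary hetnorm_fit
summary.hetnorm_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `Pr(>|z|)` = object$p_values)
  print(object)
  cat("\nCoefficients:\n")
  stats::printCoefmat(tab, P.values = TRUE, has.Pvalue = TRUE)
  invisible(object)
}

#' Percentile curves from a heteroscedastic length-effect fit
#'
#' @param object A `hetnorm_fit`.
#' @param lengths Grid of series lengths to evaluate.
#' @param quantiles Probabilities of the percentile curves.
#' @param ... Unused.
#' @return data.frame with `length`, `mu`, `sigma`, and one `q<p>` column per
#'   requested quantile.
#' @export
predict.hetnorm_fit <- function(object, lengths,
                                quantiles = c(0.05, 0.25, 0.5, 0.75, 0.95),
                                ...) {
  th <- object$coefficients
  mu <- th["a0"] + th["a1"] * lengths
  sigma <- exp(th["b0"] + th["b1"] * lengths)
  out <- data.frame(length = lengths, mu = mu, sigma = sigma)
  for (q in quantiles)
    out[[paste0("q", q)]] <- stats::qnorm(q, mu, sigma)
  out
}

#' @export
simulate.hetnorm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  th <- object$coefficients
  L <- object$data$length
  mu <- th["a0"] + th["a1"] * L
  sigma <- exp(th["b0"] + th["b1"] * L)
  out <- as.data.frame(replicate(nsim, stats::rnorm(length(L), mu, sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.hetnorm_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$length, d$trend, pch = 16, col = "grey40",
                 xlab = "Series length (sampled years)",
                 ylab = "Trend estimate", ...)
  grid_L <- seq(min(d$length), max(d$length), length.out = 100)
  pc <- predict(x, grid_L)
  for (col in grep("^q", names(pc), value = TRUE))
    graphics::lines(grid_L, pc[[col]], lwd = ifelse(col == "q0.5", 2, 1))
  invisible(x)
}
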