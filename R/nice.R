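#' Net imbalance between cumulative colonizations and extinctions
#'
#' `NICE = (C_cum - E_cum) / (C_cum + E_cum)`, a signed, bounded measure of
#' turnover imbalance: 0 is perfect balance, +1 all colonizations, -1 all
#' extinctions.  Undefined (returned as `NA`) while no event has yet been
#' counted — 0 must mean exact balance, never "nothing happened".
#'
#' @param C_cum,E_cum Cumulative counted colonizations and extinctions
#'   (non-negative; vectorised).
#' @return Numeric in `[-1, 1]`, `NA` where `C_cum + E_cum == 0`.
#' @export
nice_value <- function(C_cum, E_cum) {
  if (any(C_cum < 0) || any(E_cum < 0))
    stop("cumulative event counts must be non-negative")
  tot <- C_cum + E_cum
  out <- (C_cum - E_cum) / tot
  out[tot == 0] <- NA_real_
  out
}

#' NICE trajectory of a community series
#'
#' For each sampled year `y`, counts the species whose counted colonization
#' time is `<= y` (`C_cum`) and whose counted extinction time is `<= y`
#' (`E_cum`), and evaluates [nice_value()].  Event times are real-valued OLE
#' output compared against the sampled-year grid.  The value at the last
#' sampled year is the series' "final NICE".
#'
#' @param series A [community_series()].
#' @param events Result of [infer_events()] for that series (computed on the
#'   fly when omitted).
#' @return A data.frame of class `nice_trajectory` with columns `year`,
#'   `C_cum`, `E_cum`, `nice`.
#' @export
nice_trajectory <- function(series, events = infer_events(series)) {
  stopifnot(inherits(series, "community_series"),
            inherits(events, "event_estimates"))
  col_times <- events$col_time[events$col_counted]
  ext_times <- events$ext_time[events$ext_counted]
  C_cum <- vapply(series$years, function(y) sum(col_times <= y), integer(1))
  E_cum <- vapply(series$years, function(y) sum(ext_times <= y), integer(1))
  out <- data.frame(year = series$years, C_cum = C_cum, E_cum = E_cum,
                    nice = nice_value(C_cum, E_cum))
  attr(out, "series_id") <- series$series_id
  class(out) <- c("nice_trajectory", "data.frame")
  out
}

#' Final NICE value of a trajectory
#'
#' @param x A `nice_trajectory`.
#' @return The NICE value at the last sampled year (`NA` if no events were
#'   ever counted).
#' @export
final_nice <- function(x) {
  stopifnot(inherits(x, "nice_trajectory"))
  x$nice[nrow(x)]
}

#' @export
#' @method print nice_trajectory
print.nice_trajectory <- function(x, ...) {
  cat(sprintf("<nice_trajectory> series %s, %d sampled years\n",
              attr(x, "series_id"), nrow(x)))
  cat(sprintf("  final: C_cum=%d E_cum=%d NICE=%s\n",
              x$C_cum[nrow(x)], x$E_cum[nrow(x)],
              format(final_nice(x), digits = 3)))
  invisible(x)
}

#' @export
plot.nice_trajectory <- function(x, ...) {
  graphics::plot(x$year, x$nice, type = "b", pch = 16, ylim = c(-1, 1),
                 xlab = "Year", ylab = "NICE",
                 main = attr(x, "series_id"), ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}
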