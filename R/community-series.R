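#' Construct a community time series
#'
#' A `community_series` holds one site's survey history: the sampled years
#' (strictly increasing integers, gaps allowed) and a species-by-year
#' presence/absence matrix, optionally accompanied by abundances.  Presence is
#' defined at yearly resolution: a species is present in a sampled year if it
#' has at least one record that year.  Unsampled years are missing, not zeros;
#' downstream analyses see only the sampled grid but real calendar spacing is
#' preserved in `years`.
#'
#' Species never observed in the series are dropped: every retained species
#' row has at least one presence.
#'
#' @param series_id Identifier for the series (coerced to character).
#' @param years Integer vector of sampled years, strictly increasing.
#' @param occupancy Binary matrix, species in rows, sampled years in columns.
#'   Row names are the species identifiers.
#' @param abundance Optional non-negative matrix of the same shape;
#'   `abundance > 0` must imply `occupancy == 1`.
#'
#' @return An object of class `community_series` with elements `series_id`,
#'   `years`, `species_ids`, `occupancy` and (possibly `NULL`) `abundance`.
#' @seealso [richness()], [read_long_table()], [simulate_series()]
#' @export
community_series <- function(series_id, years, occupancy, abundance = NULL) {
  years <- as.integer(years)
  if (anyNA(years)) stop("'years' must be integers")
  if (length(years) < 2L) stop("a community series needs at least 2 sampled years")
  if (any(diff(years) <= 0L)) stop("'years' must be strictly increasing")
  occupancy <- as.matrix(occupancy)
  if (ncol(occupancy) != length(years))
    stop("occupancy must have one column per sampled year")
  if (!all(occupancy %in% c(0, 1)))
    stop("occupancy entries must be 0 or 1")
  storage.mode(occupancy) <- "integer"
  if (is.null(rownames(occupancy)))
    rownames(occupancy) <- paste0("sp", seq_len(nrow(occupancy)))
  if (anyDuplicated(rownames(occupancy)))
    stop("species identifiers must be unique")
  colnames(occupancy) <- years
  if (!is.null(abundance)) {
    abundance <- as.matrix(abundance)
    if (!identical(dim(abundance), dim(occupancy)))
      stop("abundance must match occupancy in shape")
    if (any(abundance < 0, na.rm = TRUE)) stop("abundance must be non-negative")
    if (any(abundance > 0 & occupancy == 0L, na.rm = TRUE))
      stop("positive abundance requires presence")
    dimnames(abundance) <- dimnames(occupancy)
  }
  seen <- rowSums(occupancy) > 0L
  occupancy <- occupancy[seen, , drop = FALSE]
  if (!is.null(abundance)) abundance <- abundance[seen, , drop = FALSE]
  structure(
    list(series_id = as.character(series_id), years = years,
         species_ids = rownames(occupancy), occupancy = occupancy,
         abundance = abundance),
    class = "community_series")
}

#' Species richness per sampled year
#'
#' @param x A `community_series`.
#' @return Named integer vector (names are the sampled years) of the number of
#'   species present each year: the column sums of the occupancy matrix.
#' @export
richness <- function(x) {
  stopifnot(inherits(x, "community_series"))
  r <- colSums(x$occupancy)
  storage.mode(r) <- "integer"
  r
}

#' @export
#' @method print community_series
print.community_series <- function(x, ...) {
  cat("<community_series> ", x$series_id, "\n", sep = "")
  cat("  years:   ", length(x$years), " sampled (", x$years[1L], "-",
      x$years[length(x$years)], ")\n", sep = "")
  cat("  species: ", length(x$species_ids), "\n", sep = "")
  r <- richness(x)
  cat("  richness: ", r[1L], " -> ", r[length(r)],
      if (is.null(x$abundance)) "  (presence only)" else "  (with abundance)",
      "\n", sep = "")
  invisible(x)
}

#' Bundle community series into a collection
#'
#' @param series List of `community_series` with unique ids.
#' @param source Free-text provenance label.
#' @param filters Character vector describing filters already applied.
#' @return A `series_collection`.
#' @export
series_collection <- function(series, source = "unspecified",
                              filters = character()) {
  stopifnot(all(vapply(series, inherits, logical(1), "community_series")))
  ids <- vapply(series, `[[`, character(1), "series_id")
  if (anyDuplicated(ids)) stop("series ids must be unique within a collection")
  names(series) <- ids
  structure(list(series = series, source = source, filters = filters),
            class = "series_collection")
}

#' @export
#' @method print series_collection
print.series_collection <- function(x, ...) {
  cat("<series_collection> ", length(x$series), " series (source: ",
      x$source, ")\n", sep = "")
  if (length(x$filters))
    cat("  filters: ", paste(x$filters, collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' @export
length.series_collection <- function(x) length(x$series)

#' @export
#' @method summary series_collection
summary.series_collection <- function(object, ...) {
  n_years <- vapply(object$series, function(s) length(s$years), integer(1))
  n_sp <- vapply(object$series, function(s) length(s$species_ids), integer(1))
  out <- list(n_series = length(object$series),
              years_mean = mean(n_years), years_sd = stats::sd(n_years),
              pool_mean = mean(n_sp), pool_sd = stats::sd(n_sp),
              source = object$source, filters = object$filters)
  class(out) <- "summary.series_collection"
  out
}

#' @export
#' @method print summary.series_collection
print.summary.series_collection <- function(x, ...) {
  cat("Series collection:", x$n_series, "series from", x$source, "\n")
  cat(sprintf("  sampled years per series: mean %.1f (sd %.1f)\n",
              x$years_mean, x$years_sd))
  cat(sprintf("  observed species per series: mean %.1f (sd %.1f)\n",
              x$pool_mean, x$pool_sd))
  invisible(x)
}

#' Keep series with a minimum number of sampled years
#'
#' Survey compilations are commonly restricted to series with at least 10
#' sampled years before trend estimation; that is the default threshold used
#' throughout this package.
#'
#' @param coll A `series_collection`.
#' @param min_years Minimum count of sampled years (>= 2).
#' @return The filtered collection; provenance records the filter applied.
#' @export
filter_min_years <- function(coll, min_years = 10L) {
  stopifnot(inherits(coll, "series_collection"), min_years >= 2L)
  keep <- vapply(coll$series, function(s) length(s$years) >= min_years,
                 logical(1))
  series_collection(coll$series[keep], source = coll$source,
                    filters = c(coll$filters,
                                sprintf("min_years>=%d", as.integer(min_years))))
}
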