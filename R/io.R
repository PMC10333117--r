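#' Column dialect for long-format survey tables
#'
#' Long-format tables have one row per series x year x species record.  The
#' default column names mirror the RivFishTIME-style layout
#' (`TimeSeriesID`, `Year`, `Species`, `Abundance`); remap them here for other
#' sources.
#'
#' @param series,year,species,abundance Column names in the file.  Set
#'   `abundance = NULL` for presence-only tables.
#' @return A named list usable as the `dialect` argument of
#'   [read_long_table()] and [write_long_table()].
#' @export
long_dialect <- function(series = "TimeSeriesID", year = "Year",
                         species = "Species", abundance = "Abundance") {
  list(series = series, year = year, species = species, abundance = abundance)
}

infer_sep <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a long-format community survey table
#'
#' Builds one [community_series()] per distinct series id.  Within-year
#' repeated records are collapsed: presence is "any record that year" and
#' abundance is summed.  Duplicate years are deduplicated the same way.
#'
#' @param path Delimited text file (comma- or tab-separated, inferred from the
#'   extension unless `sep` is given).
#' @param dialect Column-name mapping, see [long_dialect()].
#' @param sep Field separator override.
#' @return A `series_collection`.
#' @export
read_long_table <- function(path, dialect = long_dialect(), sep = NULL) {
  if (is.null(sep)) sep <- infer_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) {
    warning("empty table: returning an empty collection")
    return(series_collection(list(), source = path))
  }
  need <- c(dialect$series, dialect$year, dialect$species)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  yr_raw <- df[[dialect$year]]
  yr <- suppressWarnings(as.numeric(yr_raw))
  bad <- which(is.na(yr) | yr != round(yr))
  if (length(bad))
    stop("non-integer year at row(s): ", paste(utils::head(bad, 5L), collapse = ", "))
  has_ab <- !is.null(dialect$abundance) && dialect$abundance %in% names(df)
  sid <- as.character(df[[dialect$series]])
  spp <- as.character(df[[dialect$species]])
  ab <- if (has_ab) as.numeric(df[[dialect$abundance]]) else NULL
  series <- lapply(split(seq_len(nrow(df)), sid), function(idx) {
    years <- sort(unique(as.integer(yr[idx])))
    if (length(years) < 2L) return(NULL)
    sp <- sort(unique(spp[idx]))
    occ <- matrix(0L, length(sp), length(years), dimnames = list(sp, years))
    abm <- if (has_ab) occ * 0 else NULL
    ri <- match(spp[idx], sp)
    ci <- match(as.integer(yr[idx]), years)
    for (k in seq_along(idx)) {
      occ[ri[k], ci[k]] <- 1L
      if (has_ab) abm[ri[k], ci[k]] <- abm[ri[k], ci[k]] + ab[idx[k]]
    }
    community_series(sid[idx[1L]], years, occ, abundance = abm)
  })
  dropped <- vapply(series, is.null, logical(1))
  if (any(dropped))
    warning(sum(dropped), " series with a single sampled year dropped")
  series_collection(series[!dropped], source = path)
}

#' Write a collection back to a long-format table
#'
#' Emits one row per (series, year, species) presence, so
#' `read_long_table(write_long_table(x))` reproduces every occupancy matrix
#' exactly.  One caveat is inherent to the long format: a sampled year in
#' which no species at all was recorded leaves no row, so it is
#' indistinguishable from an unsampled year on re-read.  Empirical survey
#' tables never contain such years; simulated collections can.  The abundance
#' column is written only when at least one series carries abundances.
#'
#' @param coll A `series_collection`.
#' @param path Output file; separator inferred from the extension.
#' @param dialect Column names to use, see [long_dialect()].
#' @return `path`, invisibly.
#' @export
write_long_table <- function(coll, path, dialect = long_dialect()) {
  stopifnot(inherits(coll, "series_collection"))
  sep <- infer_sep(path)
  any_ab <- any(vapply(coll$series, function(s) !is.null(s$abundance),
                       logical(1)))
  rows <- lapply(coll$series, function(s) {
    idx <- which(s$occupancy == 1L, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    out <- data.frame(series = s$series_id,
                      year = s$years[idx[, 2L]],
                      species = s$species_ids[idx[, 1L]],
                      stringsAsFactors = FALSE)
    if (any_ab)
      out$abundance <- if (is.null(s$abundance)) NA_real_ else s$abundance[idx]
    out
  })
  rows <- Filter(Negate(is.null), rows)
  df <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else {
    d <- data.frame(series = character(), year = integer(),
                    species = character())
    if (any_ab) d$abundance <- numeric()
    d
  }
  names(df) <- c(dialect$series, dialect$year, dialect$species,
                 if (any_ab) dialect$abundance)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}
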