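#' Biological seasons used for network analyses
#'
#' Seasonal windows for female white-tailed deer: `gestation` (Jan 1 -- May
#' 14), `fawning` (May 15 -- Aug 31) and `rut` (Sep 1 -- Dec 31) partition the
#' year; `early_gestation` (Jan 1 -- Mar 10) is the restricted window used for
#' cross-population (global) comparisons. Windows are inclusive at both ends
#' and never span a year boundary.
#'
#' @return A data frame with columns `season`, `start` and `end` (month-day
#'   strings, `"mm-dd"`).
#' @export
#' @examples
#' deer_seasons()
deer_seasons <- function() {
  data.frame(
    season = c("gestation", "fawning", "rut", "early_gestation"),
    start  = c("01-01", "05-15", "09-01", "01-01"),
    end    = c("05-14", "08-31", "12-31", "03-10"),
    stringsAsFactors = FALSE
  )
}

season_window <- function(season, year) {
  s <- deer_seasons()
  row <- s[s$season == season, ]
  if (nrow(row) != 1L)
    stop("unknown season '", season, "'; expected one of ",
         paste(s$season, collapse = ", "))
  list(
    start = as.Date(paste0(year, "-", row$start)),
    end   = as.Date(paste0(year, "-", row$end))
  )
}

#' Validate a fix table
#'
#' A fix table holds GPS collar locations: one row per fix with columns
#' `animal_id` (character), `timestamp` (POSIXct, UTC) and projected planar
#' coordinates `x`, `y` in metres. All timestamps are treated as UTC
#' instants; local times must be converted before import. The rows for each
#' animal form that animal's trajectory.
#'
#' @param fixes A data frame with columns `animal_id`, `timestamp`, `x`, `y`.
#' @return The fix table, sorted by animal and time, invisibly checked.
#' @export
validate_fixes <- function(fixes) {
  need <- c("animal_id", "timestamp", "x", "y")
  miss <- setdiff(need, names(fixes))
  if (length(miss))
    stop("fix table missing column(s): ", paste(miss, collapse = ", "))
  if (!inherits(fixes$timestamp, "POSIXct"))
    stop("timestamp must be POSIXct (UTC)")
  if (anyNA(fixes$timestamp)) stop("missing timestamps in fix table")
  if (!is.numeric(fixes$x) || !is.numeric(fixes$y))
    stop("coordinates must be numeric (projected metres)")
  if (any(!is.finite(fixes$x)) || any(!is.finite(fixes$y)))
    stop("non-finite coordinates in fix table")
  fixes <- fixes[order(fixes$animal_id, fixes$timestamp), , drop = FALSE]
  dup <- duplicated(fixes[, c("animal_id", "timestamp")])
  if (any(dup))
    stop("duplicated (animal_id, timestamp) rows, e.g. animal ",
         fixes$animal_id[which(dup)[1]], " at ",
         format(fixes$timestamp[which(dup)[1]], tz = "UTC"))
  rownames(fixes) <- NULL
  fixes
}

#' Read GPS fixes from CSV
#'
#' Reads a fix CSV with header `animal_id,timestamp,x,y`; timestamps are ISO
#' 8601 in UTC, coordinates projected metres. Rows are sorted by animal and
#' time; duplicate (animal, timestamp) pairs and malformed fields are
#' rejected with an error naming the offending row.
#'
#' @param path Path to a CSV file.
#' @return A fix table (see [validate_fixes()]).
#' @seealso [write_fixes()] for the inverse; the pair round-trips exactly at
#'   whole-second timestamps.
#' @export
read_fixes <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  need <- c("animal_id", "timestamp", "x", "y")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("fix CSV missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(raw) == 0L) {
    return(data.frame(animal_id = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      x = numeric(), y = numeric()))
  }
  ts <- parse_iso8601(raw$timestamp)
  bad <- which(is.na(ts))
  if (length(bad))
    stop("malformed timestamp in row ", bad[1], ": '", raw$timestamp[bad[1]], "'")
  x <- suppressWarnings(as.numeric(raw$x))
  y <- suppressWarnings(as.numeric(raw$y))
  bad <- which(is.na(x) | is.na(y))
  if (length(bad))
    stop("non-numeric coordinate in row ", bad[1])
  validate_fixes(data.frame(animal_id = raw$animal_id, timestamp = ts,
                            x = x, y = y, stringsAsFactors = FALSE))
}

parse_iso8601 <- function(s) {
  s <- sub("Z$", "", s)
  s <- sub("T", " ", s, fixed = TRUE)
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}[ ]\\d{2}:\\d{2}(:\\d{2}(\\.\\d+)?)?$", s)
  out <- as.POSIXct(rep(NA_character_, length(s)), tz = "UTC")
  if (any(ok))
    out[ok] <- as.POSIXct(s[ok], tz = "UTC",
                          tryFormats = c("%Y-%m-%d %H:%M:%OS",
                                         "%Y-%m-%d %H:%M"))
  out
}

#' Write GPS fixes to CSV
#'
#' @param fixes A fix table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixes <- function(fixes, path) {
  fixes <- validate_fixes(fixes)
  out <- data.frame(
    animal_id = fixes$animal_id,
    timestamp = format(fixes$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    x = format(fixes$x, digits = 17, scientific = FALSE, trim = TRUE),
    y = format(fixes$y, digits = 17, scientific = FALSE, trim = TRUE)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Subset fixes to a seasonal window
#'
#' Retains fixes whose UTC calendar date falls inside the inclusive window of
#' the given season and year. A fix at 23:59 on the season's last day is
#' retained; midnight of the following day is not. The three main seasons
#' partition any year's fixes with none lost or duplicated.
#'
#' @param fixes A fix table.
#' @param season One of `"gestation"`, `"fawning"`, `"rut"`,
#'   `"early_gestation"`.
#' @param year Calendar year (integer).
#' @return The subset fix table (possibly zero rows).
#' @export
split_by_season <- function(fixes, season, year) {
  fixes <- validate_fixes(fixes)
  w <- season_window(season, year)
  d <- as.Date(fixes$timestamp, tz = "UTC")
  out <- fixes[d >= w$start & d <= w$end, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Regularize fixes to a nominal schedule
#'
#' Snaps each animal's fixes to interval-aligned slots anchored at midnight
#' UTC, keeping at most one fix per slot: the fix nearest in time to the slot
#' centre, within `tolerance`; ties go to the earlier fix. Used to thin
#' collar data to the common 2-hour schedule. Idempotent.
#'
#' @param fixes A fix table.
#' @param interval Slot interval in seconds (default 7200 = 2 h).
#' @param tolerance Maximum |fix time - slot time| in seconds (default 1800).
#' @return The thinned fix table.
#' @export
regularize <- function(fixes, interval = 7200, tolerance = 1800) {
  fixes <- validate_fixes(fixes)
  if (interval <= 0) stop("interval must be positive")
  if (nrow(fixes) == 0L) return(fixes)
  t <- as.numeric(fixes$timestamp)  # seconds since epoch (midnight UTC anchor)
  slot <- round(t / interval)
  off <- abs(t - slot * interval)
  keep <- rep(FALSE, nrow(fixes))
  key <- paste(fixes$animal_id, slot)
  # rows are time-sorted per animal, so which.min takes the earlier fix on ties
  for (g in split(seq_len(nrow(fixes)), key)) {
    best <- g[which.min(off[g])]
    if (off[best] <= tolerance) keep[best] <- TRUE
  }
  out <- fixes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
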