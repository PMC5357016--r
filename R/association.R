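#' Match temporally simultaneous fixes of two animals
#'
#' Greedy chronological nearest-time matching: walking both trajectories in
#' time order, fixes are paired one-to-one whenever their timestamps differ
#' by at most `max_dt` seconds and neither fix has a strictly closer
#' available partner; ties are broken toward the earlier candidate. Each fix
#' is used at most once. For 2-hourly collar schedules with only minutes of
#' jitter the pairing is unambiguous and equals the optimal assignment.
#'
#' @param traj_i,traj_j Fix tables, each for a single animal.
#' @param max_dt Maximum timestamp difference in seconds (default 180 = 3 min).
#' @return A data frame of paired fixes with columns `t_i`, `x_i`, `y_i`,
#'   `t_j`, `x_j`, `y_j`, `dt` (seconds, `t_i - t_j`) and `distance` (metres).
#' @export
match_simultaneous <- function(traj_i, traj_j, max_dt = 180) {
  if (max_dt < 0) stop("max_dt must be nonnegative")
  traj_i <- validate_fixes(traj_i)
  traj_j <- validate_fixes(traj_j)
  if (length(unique(traj_i$animal_id)) > 1L ||
      length(unique(traj_j$animal_id)) > 1L)
    stop("each trajectory must contain a single animal")
  ti <- as.numeric(traj_i$timestamp)
  tj <- as.numeric(traj_j$timestamp)
  ni <- length(ti); nj <- length(tj)
  ai <- integer(0); aj <- integer(0)
  a <- 1L; b <- 1L
  while (a <= ni && b <= nj) {
    d <- ti[a] - tj[b]
    if (d < -max_dt) { a <- a + 1L; next }
    if (d >  max_dt) { b <- b + 1L; next }
    # candidate pair (a, b); defer if a strictly closer partner is available
    # for either member just ahead
    gap <- abs(d)
    gap_a_next <- if (b < nj) abs(ti[a] - tj[b + 1L]) else Inf
    gap_b_next <- if (a < ni) abs(ti[a + 1L] - tj[b]) else Inf
    if (gap_a_next < gap && gap_a_next <= gap_b_next) { b <- b + 1L; next }
    if (gap_b_next < gap) { a <- a + 1L; next }
    ai <- c(ai, a); aj <- c(aj, b)
    a <- a + 1L; b <- b + 1L
  }
  data.frame(
    t_i = traj_i$timestamp[ai], x_i = traj_i$x[ai], y_i = traj_i$y[ai],
    t_j = traj_j$timestamp[aj], x_j = traj_j$x[aj], y_j = traj_j$y[aj],
    dt = ti[ai] - tj[aj],
    distance = sqrt((traj_i$x[ai] - traj_j$x[aj])^2 +
                    (traj_i$y[ai] - traj_j$y[aj])^2)
  )
}

#' Association rate of a dyad from paired fixes
#'
#' The association rate is the number of simultaneous fix pairs in which the
#' two animals were within `threshold` metres of one another, divided by the
#' number of simultaneous fix pairs.
#'
#' @param pairs Paired fixes from [match_simultaneous()].
#' @param threshold Proximity threshold in metres (default 25).
#' @return A list with `n_simultaneous`, `n_associations` and
#'   `association_rate`.
#' @export
association_rate <- function(pairs, threshold = 25) {
  if (threshold <= 0) stop("threshold must be positive")
  n <- nrow(pairs)
  if (n == 0L)
    stop("no simultaneous fixes: association rate undefined")
  a <- sum(pairs$distance <= threshold)
  list(n_simultaneous = n, n_associations = a, association_rate = a / n)
}

#' Dyadic association table for a set of animals
#'
#' Computes, for every unordered pair of animals in a fix table, the number
#' of simultaneous fixes and the association rate.
#'
#' @param fixes A fix table covering two or more animals.
#' @param max_dt Simultaneity window in seconds (default 180).
#' @param threshold Proximity threshold in metres (default 25).
#' @return A data frame with one row per dyad: `animal_i`, `animal_j`
#'   (ordered so `animal_i < animal_j`), `n_simultaneous`, `n_associations`,
#'   `association_rate`. Dyads with no simultaneous fixes get
#'   `n_simultaneous = 0` and `NA` rate.
#' @export
dyad_table <- function(fixes, max_dt = 180, threshold = 25) {
  fixes <- validate_fixes(fixes)
  ids <- sort(unique(fixes$animal_id))
  if (length(ids) < 2L) stop("need at least two animals")
  by_id <- split(fixes, fixes$animal_id)
  pairs <- utils::combn(ids, 2L)
  out <- data.frame(
    animal_i = pairs[1L, ], animal_j = pairs[2L, ],
    n_simultaneous = 0L, n_associations = 0L,
    association_rate = NA_real_, stringsAsFactors = FALSE
  )
  for (k in seq_len(ncol(pairs))) {
    m <- match_simultaneous(by_id[[pairs[1L, k]]], by_id[[pairs[2L, k]]],
                            max_dt = max_dt)
    if (nrow(m) > 0L) {
      r <- association_rate(m, threshold = threshold)
      out$n_simultaneous[k] <- r$n_simultaneous
      out$n_associations[k] <- r$n_associations
      out$association_rate[k] <- r$association_rate
    }
  }
  out
}

#' Subsampling sufficiency curve for a dyad
#'
#' Diagnoses how many simultaneous locations are needed for a stable
#' association-rate estimate: for each subsample size, the dyad's
#' simultaneous fixes are subsampled at random `reps` times and the rate
#' recomputed. The tolerance band is the rate the dyad would have shown with
#' one more or one fewer association over the full season, `(a - 1)/N` to
#' `(a + 1)/N`; `n_required` is the smallest size whose mean subsampled rate
#' falls inside that band.
#'
#' @param traj_i,traj_j Single-animal fix tables.
#' @param sizes Increasing vector of subsample sizes.
#' @param reps Replicates per size (default 100).
#' @param seed Integer seed for reproducibility.
#' @param max_dt,threshold Matching window (s) and proximity threshold (m).
#' @return A list with `sizes`, `mean_rate`, `ci_low`, `ci_high` (2.5% and
#'   97.5% quantiles across replicates), `full_rate`, `tolerance_band`, and
#'   `n_required` (NA if no size qualifies).
#' @export
sufficiency_curve <- function(traj_i, traj_j, sizes, reps = 100, seed = 1L,
                              max_dt = 180, threshold = 25) {
  if (reps < 1) stop("reps must be >= 1")
  if (is.unsorted(sizes, strictly = TRUE)) stop("sizes must be increasing")
  pairs <- match_simultaneous(traj_i, traj_j, max_dt = max_dt)
  N <- nrow(pairs)
  if (any(sizes > N))
    stop("subsample size exceeds available simultaneous fixes (", N, ")")
  assoc <- pairs$distance <= threshold
  a <- sum(assoc)
  full_rate <- a / N
  band <- c(max(0, (a - 1) / N), (a + 1) / N)
  set.seed(seed)
  mean_rate <- ci_low <- ci_high <- numeric(length(sizes))
  for (s in seq_along(sizes)) {
    rates <- vapply(seq_len(reps), function(r) {
      mean(assoc[sample.int(N, sizes[s])])
    }, numeric(1))
    mean_rate[s] <- mean(rates)
    ci_low[s] <- stats::quantile(rates, 0.025, names = FALSE)
    ci_high[s] <- stats::quantile(rates, 0.975, names = FALSE)
  }
  inside <- mean_rate >= band[1] & mean_rate <= band[2]
  list(sizes = sizes, mean_rate = mean_rate, ci_low = ci_low,
       ci_high = ci_high, full_rate = full_rate, tolerance_band = band,
       n_required = if (any(inside)) sizes[which(inside)[1]] else NA_integer_)
}

#' Bi-monthly bias in association rates
#'
#' Splits a dyad's paired fixes into two-month calendar blocks (Jan-Feb,
#' Mar-Apr, ...) and reports the signed difference between each block's
#' association rate and the rate over all supplied pairs. Used to decide
#' whether dyads monitored only during part of a season carry biased rates.
#'
#' @param pairs Paired fixes from [match_simultaneous()].
#' @param threshold Proximity threshold in metres (default 25).
#' @return A data frame with `block` (e.g. `"Jan-Feb"`), `n_pairs`,
#'   `block_rate` and `difference` (block minus overall rate).
#' @export
bimonthly_bias <- function(pairs, threshold = 25) {
  if (nrow(pairs) == 0L) stop("no paired fixes")
  labs <- c("Jan-Feb", "Mar-Apr", "May-Jun", "Jul-Aug", "Sep-Oct", "Nov-Dec")
  mon <- as.integer(format(pairs$t_i, "%m", tz = "UTC"))
  block <- labs[(mon + 1L) %/% 2L]
  assoc <- pairs$distance <= threshold
  overall <- mean(assoc)
  present <- labs[labs %in% block]
  data.frame(
    block = present,
    n_pairs = vapply(present, function(b) sum(block == b), integer(1)),
    block_rate = vapply(present, function(b) mean(assoc[block == b]),
                        numeric(1)),
    difference = vapply(present, function(b) mean(assoc[block == b]) - overall,
                        numeric(1)),
    row.names = NULL
  )
}

#' Filter dyads by data sufficiency and spatial overlap
#'
#' Retains dyads with at least `min_simultaneous` simultaneous locations in
#' the season and strictly positive home-range overlap; pairs that were
#' never monitored together or whose ranges do not neighbour each other are
#' dropped.
#'
#' @param records A dyad table (see [dyad_table()]).
#' @param overlaps A data frame `animal_i`, `animal_j`, `overlap` giving an
#'   overlap index per dyad (order-insensitive); required for all records.
#' @param min_simultaneous Minimum simultaneous locations (default 600).
#' @return The filtered dyad table with an `overlap` column appended.
#' @export
filter_dyads <- function(records, overlaps, min_simultaneous = 600) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  ov <- stats::setNames(overlaps$overlap,
                        key(overlaps$animal_i, overlaps$animal_j))
  k <- key(records$animal_i, records$animal_j)
  if (anyNA(ov[k]))
    stop("missing overlap value for dyad ",
         records$animal_i[which(is.na(ov[k]))[1]], "-",
         records$animal_j[which(is.na(ov[k]))[1]])
  records$overlap <- unname(ov[k])
  records[records$n_simultaneous >= min_simultaneous & records$overlap > 0, ,
          drop = FALSE]
}

#' Lowest expected nonzero association rate in a season
#'
#' With one fix every two hours, a season of `d` days yields at most
#' `12 * d` simultaneous locations, so the smallest nonzero association rate
#' a dyad monitored all season can show is `1 / (12 * d)`. For gestation
#' (134 days) this is 1/1608, approximately 0.00062: the value used to stand
#' in for zero-weight edges in local networks must lie below it.
#'
#' @param season Season name (see [deer_seasons()]).
#' @param year Calendar year used to count days (default 2005, a non-leap
#'   year).
#' @param fixes_per_day Scheduled fixes per day (default 12).
#' @return A list with `max_simultaneous` and `min_rate`.
#' @export
min_expected_rate <- function(season, year = 2005, fixes_per_day = 12) {
  w <- season_window(season, year)
  days <- as.integer(w$end - w$start) + 1L
  n <- days * fixes_per_day
  list(max_simultaneous = n, min_rate = 1 / n)
}
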