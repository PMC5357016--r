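#' Configuration for a synthetic land-cover scene
#'
#' @param extent Scene size in metres, a single value (square) or
#'   `c(width, height)`. Default 6000 (6 x 6 km).
#' @param cellsize Cell size in metres (default 30).
#' @param class_mix Named proportions over land-cover classes (must sum to
#'   1). Default a forest/agriculture/grassland/water mosaic.
#' @param patch_scale Spatial autocorrelation length in metres controlling
#'   patch size (default 300; must be at least `cellsize`).
#' @param seed Integer seed.
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(extent = 6000, cellsize = 30,
                             class_mix = c(forest = 0.40, agriculture = 0.30,
                                           grassland = 0.25, water = 0.05),
                             patch_scale = 300, seed = 1L) {
  if (length(extent) == 1) extent <- c(extent, extent)
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class proportions must sum to 1")
  if (any(class_mix < 0)) stop("class proportions must be nonnegative")
  if (is.null(names(class_mix)) || any(!nzchar(names(class_mix))))
    stop("class_mix must be named")
  if (patch_scale < cellsize) stop("patch_scale must be >= cellsize")
  if (any(extent < patch_scale)) stop("extent smaller than patch scale")
  structure(list(extent = extent, cellsize = cellsize, class_mix = class_mix,
                 patch_scale = patch_scale, seed = as.integer(seed)),
            class = "landscape_config")
}

#' Generate a patchy categorical land-cover raster
#'
#' A Gaussian white-noise field is smoothed by circular convolution with a
#' Gaussian kernel of standard deviation `patch_scale`, then thresholded at
#' the empirical quantiles implied by the class mix, so realized class
#' proportions match the target to within one cell per class. Deterministic
#' given the configuration (seed included).
#'
#' @param config A [landscape_config()].
#' @return A `grid_raster` with integer class codes and `levels` set to the
#'   class names.
#' @export
gen_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  nc <- as.integer(round(config$extent[1] / config$cellsize))
  nr <- as.integer(round(config$extent[2] / config$cellsize))
  set.seed(config$seed)
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  mix <- config$class_mix
  if (sum(mix > 0) > 1) {
    s <- config$patch_scale / config$cellsize
    torus_dist <- function(n) pmin(0:(n - 1), n - 0:(n - 1))
    ky <- stats::dnorm(torus_dist(nr), sd = s)
    kx <- stats::dnorm(torus_dist(nc), sd = s)
    K <- outer(ky, kx)
    field <- Re(stats::fft(stats::fft(z) * stats::fft(K), inverse = TRUE))
  } else {
    field <- z
  }
  ord <- order(as.vector(field))
  n_cells <- nr * nc
  counts <- floor(cumsum(mix) * n_cells)
  counts <- diff(c(0, counts))
  counts[length(counts)] <- n_cells - sum(counts[-length(counts)])
  codes <- integer(n_cells)
  codes[ord] <- rep(seq_along(mix), counts)
  grid_raster(matrix(codes, nr, nc), xll = 0, yll = 0,
              cellsize = config$cellsize, levels = names(mix))
}

#' Configuration for a synthetic collared population
#'
#' Defines matrilineal-style social groups on a landscape: each animal is
#' pulled toward its own activity centre (offset from its group's centre),
#' and scheduled pairwise meetings induce within-group and between-group
#' associations at known rates — the auditable ground truth for
#' parameter-recovery checks.
#'
#' @param n_groups Number of social groups (default 4).
#' @param deer_per_group Animals per group (default 2).
#' @param group_spacing Distance between neighbouring group centres, metres
#'   (default 1500).
#' @param within_offset Radius of individual activity centres around the
#'   group centre, metres (default 250).
#' @param attraction Mean-reversion pull toward the activity centre per
#'   2-hour step, in (0, 1\] (default 0.3).
#' @param step_sd Random step standard deviation per axis, metres
#'   (default 75).
#' @param within_group_cohesion Probability that a within-group dyad meets
#'   (comes within the proximity threshold) at any given fix (default 0.2).
#' @param between_group_rate Meeting probability per fix for dyads in
#'   adjacent groups (default 0.02); non-adjacent dyads never meet.
#' @param monitoring_days Monitoring span in days (default 134, the length
#'   of the gestation season, giving 1608 two-hourly fixes).
#' @param fix_interval_hours Scheduled fix interval (default 2).
#' @param time_jitter_sd SD of Gaussian fix-time jitter in seconds
#'   (default 60; must keep intended simultaneity inside the 3-minute
#'   matching window).
#' @param position_error_median Median collar position error in metres
#'   (default 8.8, the closed-canopy stationary-collar figure).
#' @param fix_loss Probability a scheduled fix is missed (default 0).
#' @param start_date First fix date, UTC (default "2005-01-01").
#' @param seed Integer seed.
#' @return A list of class `population_config`.
#' @export
population_config <- function(n_groups = 4, deer_per_group = 2,
                              group_spacing = 1500, within_offset = 250,
                              attraction = 0.3, step_sd = 75,
                              within_group_cohesion = 0.2,
                              between_group_rate = 0.02,
                              monitoring_days = 134, fix_interval_hours = 2,
                              time_jitter_sd = 60,
                              position_error_median = 8.8, fix_loss = 0,
                              start_date = "2005-01-01", seed = 1L) {
  if (within_group_cohesion < 0 || within_group_cohesion > 1 ||
      between_group_rate < 0 || between_group_rate > 1)
    stop("meeting rates must lie in [0, 1]")
  if (fix_loss < 0 || fix_loss >= 1) stop("fix_loss must lie in [0, 1)")
  if (attraction <= 0 || attraction > 1) stop("attraction must be in (0, 1]")
  if (time_jitter_sd > 180)
    stop("time jitter SD above 180 s breaks the simultaneity window")
  structure(list(
    n_groups = n_groups, deer_per_group = deer_per_group,
    group_spacing = group_spacing, within_offset = within_offset,
    attraction = attraction, step_sd = step_sd,
    within_group_cohesion = within_group_cohesion,
    between_group_rate = between_group_rate,
    monitoring_days = monitoring_days,
    fix_interval_hours = fix_interval_hours,
    time_jitter_sd = time_jitter_sd,
    position_error_median = position_error_median,
    fix_loss = fix_loss, start_date = start_date, seed = as.integer(seed)
  ), class = "population_config")
}

# Deterministic spatial layout: groups on a square grid, animals on a circle
# around their group centre.
population_layout <- function(pop, origin = c(0, 0)) {
  ngx <- ceiling(sqrt(pop$n_groups))
  ngy <- ceiling(pop$n_groups / ngx)
  g <- seq_len(pop$n_groups) - 1L
  gx <- origin[1] + (g %% ngx) * pop$group_spacing
  gy <- origin[2] + (g %/% ngx) * pop$group_spacing
  rows <- lapply(seq_len(pop$n_groups), function(k) {
    a <- seq_len(pop$deer_per_group)
    th <- 2 * pi * (a - 1) / pop$deer_per_group
    data.frame(
      animal_id = sprintf("g%02d_d%02d", k, a),
      group = k,
      cx = gx[k] + pop$within_offset * cos(th),
      cy = gy[k] + pop$within_offset * sin(th),
      group_x = gx[k], group_y = gy[k], stringsAsFactors = FALSE
    )
  })
  layout <- do.call(rbind, rows)
  centers <- data.frame(group = seq_len(pop$n_groups), x = gx, y = gy)
  list(animals = layout, groups = centers)
}

# Dyad table with configured meeting probability. Groups are adjacent when
# their centres are within 1.25 * group_spacing (rook neighbours on the
# layout grid; diagonals are non-adjacent).
dyad_config <- function(pop) {
  lay <- population_layout(pop)
  an <- lay$animals
  pr <- utils::combn(nrow(an), 2L)
  gi <- an$group[pr[1, ]]; gj <- an$group[pr[2, ]]
  gd <- sqrt((lay$groups$x[gi] - lay$groups$x[gj])^2 +
             (lay$groups$y[gi] - lay$groups$y[gj])^2)
  p <- ifelse(gi == gj, pop$within_group_cohesion,
              ifelse(gd <= 1.25 * pop$group_spacing,
                     pop$between_group_rate, 0))
  data.frame(animal_i = an$animal_id[pr[1, ]],
             animal_j = an$animal_id[pr[2, ]],
             same_group = gi == gj, true_rate = p,
             stringsAsFactors = FALSE)
}

#' Ground-truth association rates of a synthetic population
#'
#' The configured per-fix meeting probability for every dyad:
#' `within_group_cohesion` for groupmates, `between_group_rate` for dyads
#' in adjacent groups, 0 for non-adjacent groups. Covers all
#' `choose(n_animals, 2)` dyads.
#'
#' @param pop A [population_config()].
#' @return Data frame `animal_i`, `animal_j`, `same_group`, `true_rate`.
#' @export
true_association_table <- function(pop) {
  dyad_config(pop)
}

#' Simulate group-structured movement paths
#'
#' Discrete-time mean-reverting (Ornstein-Uhlenbeck-style) movement at the
#' fix schedule: each animal takes Gaussian steps pulled toward its own
#' activity centre. Scheduled pairwise meetings (Bernoulli per dyad per fix
#' at the configured rates, allocated to slots where both animals are free)
#' relocate one member next to the other, inducing associations with exact,
#' auditable ground truth. Optionally, steps can be biased toward
#' high-value cells of a raster (e.g. a conductance surface) to synthesise
#' landscape-coupled sociality scenarios.
#'
#' @param pop A [population_config()].
#' @param land Optional land-cover `grid_raster`; when given, the layout is
#'   centred in its extent.
#' @param bias_raster Optional `grid_raster`; with `bias_strength > 0`,
#'   each step picks the better of two candidate displacements with
#'   probability increasing in the raster-value difference.
#' @param bias_strength Nonnegative scalar (default 0: no landscape
#'   response).
#' @return A list of class `deer_sim`: `x`, `y` (animal x slot matrices of
#'   true positions), `times` (POSIXct slot times), `animals` (layout),
#'   `meetings` (slot, i, j), `truth` (configured dyad rates), `pop`.
#' @export
simulate_movement <- function(pop, land = NULL, bias_raster = NULL,
                              bias_strength = 0) {
  origin <- c(0, 0)
  if (!is.null(land)) {
    w <- land$ncol * land$cellsize; h <- land$nrow * land$cellsize
    ngx <- ceiling(sqrt(pop$n_groups))
    ngy <- ceiling(pop$n_groups / ngx)
    span_x <- (ngx - 1) * pop$group_spacing
    span_y <- (ngy - 1) * pop$group_spacing
    if (span_x + 2 * pop$within_offset > w ||
        span_y + 2 * pop$within_offset > h)
      stop("group layout does not fit inside the landscape extent")
    origin <- c(land$xll + (w - span_x) / 2, land$yll + (h - span_y) / 2)
  }
  lay <- population_layout(pop, origin)
  an <- lay$animals
  n_an <- nrow(an)
  n_slots <- as.integer(pop$monitoring_days * 24 / pop$fix_interval_hours)
  set.seed(pop$seed)
  X <- matrix(0, n_an, n_slots)
  Y <- matrix(0, n_an, n_slots)
  X[, 1] <- an$cx; Y[, 1] <- an$cy
  a <- pop$attraction; s <- pop$step_sd
  for (k in seq_len(n_slots - 1L)) {
    px <- X[, k] + a * (an$cx - X[, k]) + stats::rnorm(n_an, 0, s)
    py <- Y[, k] + a * (an$cy - Y[, k]) + stats::rnorm(n_an, 0, s)
    if (!is.null(bias_raster) && bias_strength > 0) {
      qx <- X[, k] + a * (an$cx - X[, k]) + stats::rnorm(n_an, 0, s)
      qy <- Y[, k] + a * (an$cy - Y[, k]) + stats::rnorm(n_an, 0, s)
      vp <- raster_value_at(bias_raster, px, py)
      vq <- raster_value_at(bias_raster, qx, qy)
      take_q <- stats::runif(n_an) < stats::plogis(bias_strength * (vq - vp))
      px[take_q] <- qx[take_q]; py[take_q] <- qy[take_q]
    }
    X[, k + 1L] <- px; Y[, k + 1L] <- py
  }
  # schedule meetings: exactly round(rate * n_slots) per dyad, placed
  # uniformly among slots where both animals are still free, so configured
  # rates are exact in truth and not eroded by conflicts
  dy <- dyad_config(pop)
  busy <- matrix(FALSE, n_an, n_slots)
  ms <- mi <- mj <- integer(0)
  for (d in seq_len(nrow(dy))) {
    if (dy$true_rate[d] == 0) next
    i <- match(dy$animal_i[d], an$animal_id)
    j <- match(dy$animal_j[d], an$animal_id)
    n_meet <- round(dy$true_rate[d] * n_slots)
    free <- which(!busy[i, ] & !busy[j, ])
    n_meet <- min(n_meet, length(free))
    if (n_meet == 0) next
    slots <- sample(free, n_meet)
    busy[i, slots] <- TRUE; busy[j, slots] <- TRUE
    ms <- c(ms, slots); mi <- c(mi, rep(i, n_meet)); mj <- c(mj, rep(j, n_meet))
  }
  # realize meetings: j joins i (within a metre or two)
  X[cbind(mj, ms)] <- X[cbind(mi, ms)] + stats::rnorm(length(ms), 0, 1)
  Y[cbind(mj, ms)] <- Y[cbind(mi, ms)] + stats::rnorm(length(ms), 0, 1)
  t0 <- as.POSIXct(paste(pop$start_date, "00:00:00"), tz = "UTC")
  times <- t0 + (seq_len(n_slots) - 1L) * pop$fix_interval_hours * 3600
  structure(list(x = X, y = Y, times = times, animals = an,
                 meetings = data.frame(slot = ms, i = mi, j = mj),
                 truth = dy, pop = pop),
            class = "deer_sim")
}

raster_value_at <- function(r, x, y) {
  loc <- locate_cells(r, x, y)
  out <- rep(0, length(x))
  inside <- !is.na(loc$row)
  out[inside] <- r$values[cbind(loc$row[inside], loc$col[inside])]
  out
}

#' Sample GPS fixes from simulated paths
#'
#' Observes the true paths at the fix schedule with Gaussian time jitter,
#' isotropic Gaussian position error scaled so the median displacement
#' equals the configured collar error, and optional random fix loss.
#'
#' @param sim A `deer_sim` from [simulate_movement()].
#' @param seed Seed for the observation noise (defaults to the population
#'   seed + 1, a stream separate from the movement draw).
#' @return A fix table (see [validate_fixes()]).
#' @export
sample_gps <- function(sim, seed = NULL) {
  pop <- sim$pop
  if (is.null(seed)) seed <- pop$seed + 1L
  set.seed(seed)
  n_an <- nrow(sim$animals)
  n_slots <- length(sim$times)
  n <- n_an * n_slots
  # Rayleigh median = sigma * sqrt(2 log 2)
  sigma <- pop$position_error_median / sqrt(2 * log(2))
  fixes <- data.frame(
    animal_id = rep(sim$animals$animal_id, times = n_slots),
    timestamp = rep(sim$times, each = n_an) +
      stats::rnorm(n, 0, pop$time_jitter_sd),
    x = as.vector(sim$x) + stats::rnorm(n, 0, sigma),
    y = as.vector(sim$y) + stats::rnorm(n, 0, sigma)
  )
  if (pop$fix_loss > 0)
    fixes <- fixes[stats::runif(n) >= pop$fix_loss, , drop = FALSE]
  validate_fixes(fixes)
}

#' One-call synthetic study
#'
#' Generates a landscape (optional), simulates movement with scheduled
#' meetings, and samples GPS fixes; returns everything needed to run the
#' pipeline against known truth.
#'
#' @param pop A [population_config()].
#' @param land_config Optional [landscape_config()].
#' @return A list with `fixes`, `truth`, `sim` and `land` (NULL when no
#'   landscape was requested).
#' @export
simulate_study <- function(pop, land_config = NULL) {
  land <- if (!is.null(land_config)) gen_landscape(land_config)
  sim <- simulate_movement(pop, land = land)
  list(fixes = sample_gps(sim), truth = sim$truth, sim = sim, land = land)
}
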