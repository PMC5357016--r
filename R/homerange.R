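#' Reference bandwidth for bivariate kernel density estimation
#'
#' The bivariate reference ("href") rule with a pooled-axis scale:
#' `h = sigma * n^(-1/6)` where `sigma = sqrt((var(x) + var(y)) / 2)` uses
#' sample variances. This is the default smoothing used for utilization
#' distributions.
#'
#' @param x,y Fix coordinates (metres).
#' @return Bandwidth in metres (kernel standard deviation).
#' @export
href_bandwidth <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("x and y lengths differ")
  if (n < 5) stop("need at least 5 fixes for a bandwidth")
  s2 <- (stats::var(x) + stats::var(y)) / 2
  if (s2 <= 0) stop("degenerate positions: zero variance")
  sqrt(s2) * n^(-1 / 6)
}

#' Build an estimation grid around fixes
#'
#' Bounding box of the fixes padded by `margin` bandwidths on every side,
#' discretised into square cells.
#'
#' @param x,y Fix coordinates.
#' @param h Bandwidth (metres).
#' @param cellsize Cell size in metres (default 50).
#' @param margin Padding in bandwidths (default 3).
#' @return A `grid_raster` of zeros covering the padded box.
#' @export
ud_grid <- function(x, y, h, cellsize = 50, margin = 3) {
  pad <- margin * h
  xll <- floor((min(x) - pad) / cellsize) * cellsize
  yll <- floor((min(y) - pad) / cellsize) * cellsize
  nc <- ceiling((max(x) + pad - xll) / cellsize)
  nr <- ceiling((max(y) + pad - yll) / cellsize)
  grid_raster(matrix(0, nr, nc), xll = xll, yll = yll, cellsize = cellsize)
}

#' Kernel utilization distribution
#'
#' Bivariate Gaussian kernel density estimate on a grid, with the same
#' bandwidth on both axes, renormalized so the gridded density integrates to
#' one. Errors if more than 1% of the kernel mass falls outside the grid
#' (the grid is too small).
#'
#' @param x,y Fix coordinates (metres).
#' @param h Bandwidth in metres; defaults to [href_bandwidth()].
#' @param grid A `grid_raster` defining the estimation grid; defaults to
#'   [ud_grid()] around the fixes.
#' @param animal_id Optional id stored with the result.
#' @return A `grid_raster` with density values (1/m^2) and extra fields `h`,
#'   `n` and `animal_id`; class `c("utilization_distribution",
#'   "grid_raster")`.
#' @export
kde_ud <- function(x, y, h = NULL, grid = NULL, animal_id = NULL) {
  if (is.null(h)) h <- href_bandwidth(x, y)
  if (h <= 0) stop("bandwidth must be positive")
  if (is.null(grid)) grid <- ud_grid(x, y, h)
  cc <- cell_centers(grid)
  n <- length(x)
  # density[r, c] = mean over fixes of the product kernel
  dx <- outer(cc$x, x, "-")        # ncol x n
  dy <- outer(cc$y, y, "-")        # nrow x n
  kx <- stats::dnorm(dx, sd = h)
  ky <- stats::dnorm(dy, sd = h)
  dens <- (ky %*% t(kx)) / n
  mass <- sum(dens) * grid$cellsize^2
  if (mass < 0.99)
    stop(sprintf(paste("grid clips %.1f%% of the kernel mass;",
                       "enlarge the grid margin"), 100 * (1 - mass)))
  ud <- grid_raster(dens / mass, xll = grid$xll, yll = grid$yll,
                    cellsize = grid$cellsize)
  ud$h <- h; ud$n <- n; ud$animal_id <- animal_id
  class(ud) <- c("utilization_distribution", class(ud))
  ud
}

#' Isopleth home range of a utilization distribution
#'
#' Cells are accumulated in decreasing density order (ties broken in
#' row-major order) until the contained probability mass reaches `p`; the
#' result is the minimal superset: dropping its lowest-density cell would
#' fall below `p`.
#'
#' @param ud A utilization distribution from [kde_ud()].
#' @param p Target probability mass (default 0.95).
#' @return A list of class `home_range`: `mask` (logical matrix on the UD
#'   grid), `cells` (cell indices, column-major), `contained_mass`, `area`
#'   (m^2), `p`, and the grid geometry (`xll`, `yll`, `cellsize`, `nrow`,
#'   `ncol`).
#' @export
isopleth <- function(ud, p = 0.95) {
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  d <- ud$values
  cell_area <- ud$cellsize^2
  # row-major rank as tie-break: cells in reading order
  rowmajor <- as.vector(matrix(seq_len(length(d)), nrow(d), ncol(d),
                               byrow = TRUE))
  ord <- order(-as.vector(d), rowmajor)
  mass <- cumsum(d[ord]) * cell_area
  k <- which(mass >= p)[1]
  if (is.na(k)) k <- length(ord)  # density barely under p from rounding
  cells <- ord[seq_len(k)]
  mask <- matrix(FALSE, nrow(d), ncol(d))
  mask[cells] <- TRUE
  structure(
    list(mask = mask, cells = cells, contained_mass = mass[k],
         area = k * cell_area, p = p, xll = ud$xll, yll = ud$yll,
         cellsize = ud$cellsize, nrow = ud$nrow, ncol = ud$ncol),
    class = "home_range"
  )
}

#' Directional home-range overlap (PHR)
#'
#' The probability of animal i being inside animal j's home range: the
#' integral of i's utilization distribution over j's isopleth cells. The
#' index is directional (`phr(ud_i, hr_j)` generally differs from
#' `phr(ud_j, hr_i)`). If the two grids differ, j's cells are integrated by
#' sampling i's density at their centres; disjoint extents give 0.
#'
#' @param ud_i Utilization distribution of the focal animal.
#' @param hr_j Home range (isopleth) of the neighbour.
#' @return A proportion in \[0, 1\].
#' @export
phr <- function(ud_i, hr_j) {
  grid_j <- grid_raster(matrix(0, hr_j$nrow, hr_j$ncol), hr_j$xll, hr_j$yll,
                        hr_j$cellsize)
  if (same_grid(ud_i, grid_j))
    return(min(1, sum(ud_i$values[hr_j$mask]) * ud_i$cellsize^2))
  cc <- cell_centers(grid_j)
  rc <- which(hr_j$mask, arr.ind = TRUE)
  px <- cc$x[rc[, 2]]; py <- cc$y[rc[, 1]]
  loc <- locate_cells(ud_i, px, py)
  inside <- !is.na(loc$row)
  if (!any(inside)) return(0)
  dens <- ud_i$values[cbind(loc$row[inside], loc$col[inside])]
  min(1, sum(dens) * hr_j$cellsize^2)
}

#' Volume of intersection (VI) of two utilization distributions
#'
#' The integral of the pointwise minimum of two UDs on a shared grid: 0 for
#' disjoint distributions, 1 for identical ones. Symmetric. Computed over
#' the full UDs (not truncated to an isopleth); truncation can be requested
#' with `p`.
#'
#' @param ud_i,ud_j Utilization distributions on the same grid.
#' @param p Optional isopleth level; when given, each UD is zeroed outside
#'   its own `p` isopleth before the intersection (kept `NULL` by default).
#' @return A proportion in \[0, 1\].
#' @export
vi <- function(ud_i, ud_j, p = NULL) {
  if (!same_grid(ud_i, ud_j))
    stop("VI requires both UDs on the same grid; refit on a shared grid")
  di <- ud_i$values; dj <- ud_j$values
  if (!is.null(p)) {
    di[!isopleth(ud_i, p)$mask] <- 0
    dj[!isopleth(ud_j, p)$mask] <- 0
  }
  min(1, sum(pmin(di, dj)) * ud_i$cellsize^2)
}

#' Mean home-range overlap of a focal animal with its neighbours
#'
#' Arithmetic mean of the directional PHR of each neighbour being inside the
#' focal animal's home range, over all simultaneously monitored neighbours.
#'
#' @param animal Focal animal id.
#' @param neighbors Character vector of neighbour ids (at least one).
#' @param phr_table Data frame `animal_i`, `animal_j`, `phr` where `phr` is
#'   the probability of `animal_i` being inside `animal_j`'s range.
#' @return The mean overlap (proportion).
#' @export
mean_overlap <- function(animal, neighbors, phr_table) {
  if (length(neighbors) < 1) stop("need at least one neighbour")
  vals <- vapply(neighbors, function(nb) {
    hit <- phr_table$animal_i == nb & phr_table$animal_j == animal
    if (!any(hit)) stop("no PHR entry for ", nb, " in ", animal, "'s range")
    phr_table$phr[which(hit)[1]]
  }, numeric(1))
  mean(vals)
}
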