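#' Binary presence layer from a categorical land-cover raster
#'
#' @param landcover A `grid_raster` whose integer values index its `levels`
#'   (e.g. forest, agriculture, grassland, water).
#' @param classes Character vector of level names coded as presence (1).
#' @return A `grid_raster` of 0/1 values.
#' @export
binary_layer <- function(landcover, classes) {
  if (is.null(landcover$levels)) stop("landcover raster has no class levels")
  if (length(classes) == 0) stop("classes must be non-empty")
  unknown <- setdiff(classes, landcover$levels)
  if (length(unknown))
    stop("unknown land-cover class(es): ", paste(unknown, collapse = ", "))
  codes <- match(classes, landcover$levels)
  out <- landcover
  out$values <- matrix(as.numeric(landcover$values %in% codes),
                       landcover$nrow, landcover$ncol)
  out$levels <- NULL
  out
}

#' Forest-agriculture edge layer
#'
#' A cell is edge habitat when it is forest with a 4-neighbouring
#' agriculture cell, or agriculture with a 4-neighbouring forest cell: the
#' edge is the two one-cell-wide stripes flanking every forest/agriculture
#' boundary.
#'
#' @param forest,agriculture Binary `grid_raster`s on the same grid.
#' @return A binary `grid_raster` marking edge cells.
#' @export
edge_layer <- function(forest, agriculture) {
  if (!same_grid(forest, agriculture))
    stop("forest and agriculture rasters must share a grid")
  f <- forest$values; a <- agriculture$values
  if (any(f == 1 & a == 1))
    stop("cells classified as both forest and agriculture")
  nr <- nrow(f); nc <- ncol(f)
  touches <- function(src) {
    # TRUE where a 4-neighbour of the cell is 1 in src
    t <- matrix(FALSE, nr, nc)
    if (nr > 1) {
      t[-1, ] <- t[-1, ] | src[-nr, ] == 1
      t[-nr, ] <- t[-nr, ] | src[-1, ] == 1
    }
    if (nc > 1) {
      t[, -1] <- t[, -1] | src[, -nc] == 1
      t[, -nc] <- t[, -nc] | src[, -1] == 1
    }
    t
  }
  edge <- (f == 1 & touches(a)) | (a == 1 & touches(f))
  out <- forest
  out$values <- matrix(as.numeric(edge), nr, nc)
  out
}

#' Conductance surface from a binary habitat layer
#'
#' Presence cells get high conductance, absence cells a floor value, so
#' current (random-walker throughput) concentrates in the habitat.
#'
#' @param binary A binary `grid_raster`.
#' @param presence,absence Conductance assigned to 1 and 0 cells
#'   (defaults 101 and 1).
#' @return A `grid_raster` of conductances.
#' @export
conductance_surface <- function(binary, presence = 101, absence = 1) {
  if (presence <= 0 || absence <= 0) stop("conductances must be positive")
  out <- binary
  out$values <- ifelse(binary$values == 1, presence, absence)
  out
}

#' Equally spaced sites around a buffered region perimeter
#'
#' Places `n` sites at equal arc length along the perimeter of the
#' rectangular region grown by `buffer` on every side, starting at the
#' lower-left corner and proceeding counter-clockwise. Spacing is
#' `perimeter / n`; a 30 km square with a 7.5 km buffer and 50 sites gives
#' 3.6 km spacing.
#'
#' @param extent Region extent `c(xmin, xmax, ymin, ymax)` (metres).
#' @param buffer Buffer width in metres (default 0).
#' @param n Number of sites (default 50).
#' @return A list of class `site_ring` with `x`, `y`, `spacing`, `n` and the
#'   buffered extent.
#' @export
perimeter_sites <- function(extent, buffer = 0, n = 50) {
  if (n < 2) stop("need at least 2 sites")
  if (buffer < 0) stop("buffer must be nonnegative")
  xmin <- extent[1] - buffer; xmax <- extent[2] + buffer
  ymin <- extent[3] - buffer; ymax <- extent[4] + buffer
  w <- xmax - xmin; h <- ymax - ymin
  if (w <= 0 || h <= 0) stop("degenerate extent")
  per <- 2 * (w + h)
  spacing <- per / n
  s <- (seq_len(n) - 1) * spacing  # arc length from lower-left corner, CCW
  x <- y <- numeric(n)
  for (k in seq_len(n)) {
    d <- s[k]
    if (d < w) { x[k] <- xmin + d; y[k] <- ymin }
    else if (d < w + h) { x[k] <- xmax; y[k] <- ymin + (d - w) }
    else if (d < 2 * w + h) { x[k] <- xmax - (d - w - h); y[k] <- ymax }
    else { x[k] <- xmin; y[k] <- ymax - (d - 2 * w - h) }
  }
  structure(list(x = x, y = y, spacing = spacing, n = n,
                 extent = c(xmin, xmax, ymin, ymax)),
            class = "site_ring")
}

# Edge list of the 8-neighbour lattice over a conductance raster.
# Edge conductance is the arithmetic mean of the two cell conductances;
# diagonal edges are divided by sqrt(2) for the longer span.
circuit_edges <- function(cond) {
  v <- cond$values
  if (any(!is.finite(v)) || any(v <= 0))
    stop("conductance values must be positive and finite")
  nr <- nrow(v); nc <- ncol(v)
  id <- matrix(seq_len(nr * nc), nr, nc)
  ei <- ej <- integer(0); g <- numeric(0)
  add <- function(a, b, scale) {
    a <- as.vector(a); b <- as.vector(b)  # keep linear indexing
    ei <<- c(ei, a); ej <<- c(ej, b)
    g <<- c(g, (v[a] + v[b]) / 2 * scale)
  }
  if (nc > 1) add(id[, -nc], id[, -1], 1)              # east
  if (nr > 1) add(id[-nr, ], id[-1, ], 1)              # south
  if (nr > 1 && nc > 1) {
    add(id[-nr, -nc], id[-1, -1], 1 / sqrt(2))         # south-east
    add(id[-1, -nc], id[-nr, -1], 1 / sqrt(2))         # north-east
  }
  list(i = ei, j = ej, g = g, n = nr * nc, nrow = nr, ncol = nc)
}

circuit_laplacian <- function(edges) {
  n <- edges$n
  A <- Matrix::sparseMatrix(i = c(edges$i, edges$j),
                            j = c(edges$j, edges$i),
                            x = c(edges$g, edges$g), dims = c(n, n))
  Matrix::Diagonal(n, Matrix::rowSums(A)) - A
}

# Per-cell current from node potentials: half the sum of absolute currents
# on incident edges; source and sink cells carry the full sum (= injected
# current by Kirchhoff's law).
node_currents <- function(edges, v, terminals) {
  cur <- abs(edges$g * (v[edges$i] - v[edges$j]))
  acc <- numeric(edges$n)
  s1 <- rowsum(cur, edges$i)
  acc[as.integer(rownames(s1))] <- s1
  s2 <- rowsum(cur, edges$j)
  acc[as.integer(rownames(s2))] <- acc[as.integer(rownames(s2))] + s2
  out <- acc / 2
  out[terminals] <- acc[terminals]
  out
}

#' Pairwise current map on a conductance raster
#'
#' Cells are circuit nodes joined to their 8 neighbours; edge conductance is
#' the mean of the two cell conductances (diagonals divided by sqrt(2)). A
#' unit current is injected at `src` and withdrawn at `dst`; node potentials
#' solve the graph-Laplacian linear system (sparse Cholesky, sink grounded)
#' and each cell's current is half the sum of absolute currents on its
#' incident edges (full sum, equal to 1, at the two terminals).
#'
#' @param cond A `grid_raster` of positive conductances.
#' @param src,dst Cells as `c(row, col)` or single cell indices
#'   (column-major).
#' @return A list with `current` (a `grid_raster`), `potentials` (vector,
#'   sink at 0) and `effective_resistance`.
#' @export
pair_current <- function(cond, src, dst) {
  edges <- circuit_edges(cond)
  s <- as_cell_index(src, edges)
  t <- as_cell_index(dst, edges)
  if (s == t) stop("src and dst must differ")
  comp <- lattice_components(edges)
  if (comp[s] != comp[t])
    stop("src and dst are not connected on the raster")
  L <- circuit_laplacian(edges)
  keep <- which(comp == comp[s])
  sol <- solve_pairs(L, keep, ground = t,
                     pairs = matrix(c(s, t), nrow = 2))
  v <- sol[, 1]
  cur <- node_currents(edges, v, c(s, t))
  out <- grid_raster(matrix(cur, edges$nrow, edges$ncol),
                     xll = cond$xll, yll = cond$yll, cellsize = cond$cellsize)
  list(current = out, potentials = v, effective_resistance = v[s] - v[t])
}

as_cell_index <- function(cell, edges) {
  if (length(cell) == 2L) {  # (row, col)
    r <- cell[1]; c <- cell[2]
    if (r < 1 || r > edges$nrow || c < 1 || c > edges$ncol)
      stop("cell (", r, ",", c, ") outside raster")
    return(as.integer((c - 1L) * edges$nrow + r))
  }
  if (cell < 1 || cell > edges$n) stop("cell index outside raster")
  as.integer(cell)
}

lattice_components <- function(edges) {
  gph <- igraph::graph_from_edgelist(cbind(edges$i, edges$j),
                                     directed = FALSE)
  gph <- igraph::add_vertices(gph, max(0, edges$n - igraph::vcount(gph)))
  igraph::components(gph)$membership
}

# Solve the grounded Laplacian system for many source/sink pairs sharing one
# factorization. `keep` is the connected component's node set (must contain
# ground and all pair endpoints); returns a dense matrix of potentials
# (n x npairs) with ground fixed at 0.
solve_pairs <- function(L, keep, ground, pairs) {
  stopifnot(ground %in% keep)
  sub <- setdiff(keep, ground)
  Lsub <- L[sub, sub, drop = FALSE]
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Lsub), LDL = FALSE)
  npair <- ncol(pairs)
  pos <- match(pairs, sub)
  dim(pos) <- dim(pairs)
  B <- matrix(0, length(sub), npair)
  for (k in seq_len(npair)) {
    if (!is.na(pos[1, k])) B[pos[1, k], k] <- B[pos[1, k], k] + 1
    if (!is.na(pos[2, k])) B[pos[2, k], k] <- B[pos[2, k], k] - 1
  }
  Vsub <- as.matrix(Matrix::solve(ch, B, system = "A"))
  V <- matrix(0, nrow(L), npair)
  V[sub, ] <- Vsub
  V
}

#' Omnidirectional current-density map
#'
#' Sums the pairwise current maps over all site pairs of a perimeter ring,
#' then clips the buffer margin off the output extent so current biased by
#' arbitrary site placement is discarded. Sites are snapped to their nearest
#' raster cells (co-located sites merge into one terminal). Pairs separated
#' from the main component are skipped with a warning.
#'
#' @param cond A `grid_raster` of positive conductances covering the
#'   buffered region.
#' @param sites A `site_ring` from [perimeter_sites()], or a two-column
#'   matrix of site coordinates.
#' @param buffer Buffer width (metres) to clip from every side of the
#'   output; defaults to 0 (no clipping).
#' @return A list with `current` (clipped `grid_raster`), `n_site_pairs`
#'   (pairs solved) and `n_skipped` (disconnected pairs).
#' @export
omnidirectional_current <- function(cond, sites, buffer = 0) {
  if (inherits(sites, "site_ring")) {
    sx <- sites$x; sy <- sites$y
  } else {
    sx <- sites[, 1]; sy <- sites[, 2]
  }
  edges <- circuit_edges(cond)
  # snap sites to nearest cell centre (clamp to the raster)
  cs <- cond$cellsize
  col <- pmin(pmax(ceiling((sx - cond$xll) / cs), 1L), cond$ncol)
  row <- pmin(pmax(cond$nrow - ceiling((sy - cond$yll) / cs) + 1L, 1L),
              cond$nrow)
  cells <- unique((col - 1L) * cond$nrow + row)
  if (length(cells) < 2) stop("need at least 2 distinct site cells")
  comp <- lattice_components(edges)
  main <- as.integer(names(which.max(table(comp[cells]))))
  ok <- cells[comp[cells] == main]
  all_pairs <- utils::combn(cells, 2L)
  use <- comp[all_pairs[1, ]] == main & comp[all_pairs[2, ]] == main
  n_skip <- sum(!use)
  if (n_skip > 0)
    warning(n_skip, " site pair(s) skipped: disconnected from main component")
  pairs <- all_pairs[, use, drop = FALSE]
  L <- circuit_laplacian(edges)
  keep <- which(comp == main)
  V <- solve_pairs(L, keep, ground = ok[1], pairs = pairs)
  total <- numeric(edges$n)
  for (k in seq_len(ncol(pairs))) {
    total <- total + node_currents(edges, V[, k], pairs[, k])
  }
  full <- grid_raster(matrix(total, edges$nrow, edges$ncol),
                      xll = cond$xll, yll = cond$yll, cellsize = cs)
  list(current = clip_margin(full, buffer),
       n_site_pairs = ncol(pairs), n_skipped = n_skip)
}

# Remove a margin of the given width (in map units) from every side.
clip_margin <- function(r, margin) {
  if (margin <= 0) return(r)
  k <- round(margin / r$cellsize)
  if (2 * k >= r$nrow || 2 * k >= r$ncol)
    stop("margin consumes the whole raster")
  vals <- r$values[(k + 1):(r$nrow - k), (k + 1):(r$ncol - k), drop = FALSE]
  grid_raster(vals, xll = r$xll + k * r$cellsize, yll = r$yll + k * r$cellsize,
              cellsize = r$cellsize)
}

# Resolve a region argument (logical mask, cell indices, or a home_range on
# its own grid) to the raster values it selects.
region_values <- function(region, r) {
  if (inherits(region, "home_range")) {
    hr_grid <- grid_raster(matrix(0, region$nrow, region$ncol), region$xll,
                           region$yll, region$cellsize)
    if (same_grid(hr_grid, r)) return(r$values[region$mask])
    cc <- cell_centers(hr_grid)
    rc <- which(region$mask, arr.ind = TRUE)
    loc <- locate_cells(r, cc$x[rc[, 2]], cc$y[rc[, 1]])
    inside <- !is.na(loc$row)
    if (!any(inside)) stop("region does not intersect the raster extent")
    return(r$values[cbind(loc$row[inside], loc$col[inside])])
  }
  if (is.logical(region)) {
    if (!all(dim(region) == dim(r$values)))
      stop("mask dimensions do not match the raster")
    if (!any(region)) stop("empty region")
    return(r$values[region])
  }
  if (length(region) == 0) stop("empty region")
  r$values[as.integer(region)]
}

#' Mean current density within a region
#'
#' The landscape-connectivity index used as a predictor: arithmetic mean of
#' current over the region's cells (e.g. a seasonal home range).
#'
#' @param region A logical mask on the map grid, cell indices, or a
#'   `home_range` (sampled at cell centres if its grid differs).
#' @param map A `grid_raster` of current density (or the list returned by
#'   [omnidirectional_current()]).
#' @return Mean current (same units as the map).
#' @export
mean_current_in <- function(region, map) {
  if (!inherits(map, "grid_raster") && !is.null(map$current))
    map <- map$current
  mean(region_values(region, map))
}

#' Proportion of presence cells within a region
#'
#' @param region As in [mean_current_in()].
#' @param binary A binary `grid_raster` (e.g. forest presence).
#' @return Fraction of region cells with value 1.
#' @export
proportion_in <- function(region, binary) {
  mean(region_values(region, binary) == 1)
}
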