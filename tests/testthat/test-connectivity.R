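lc_levels <- c("forest", "agriculture", "grassland", "water")

lc_raster <- function(codes) {
  grid_raster(codes, cellsize = 30, levels = lc_levels)
}

test_that("binary layers code class presence and complement correctly", {
  lc <- lc_raster(matrix(1L, 5, 5))
  expect_true(all(binary_layer(lc, "forest")$values == 1))
  expect_true(all(binary_layer(lc, "agriculture")$values == 0))
  expect_error(binary_layer(lc, "swamp"), "unknown")
  expect_error(binary_layer(lc, character(0)), "non-empty")
  # checkerboard: complement classes give the complement layer
  chk <- lc_raster(matrix(rep_len(c(1L, 2L), 36), 6, 6))
  f <- binary_layer(chk, "forest")
  rest <- binary_layer(chk, c("agriculture", "grassland", "water"))
  expect_equal(f$values + rest$values, matrix(1, 6, 6))
})

test_that("edge layer marks the two stripes along a forest-agriculture boundary", {
  codes <- matrix(2L, 10, 10)
  codes[, 1:5] <- 1L   # west half forest, east half agriculture
  lc <- lc_raster(codes)
  ed <- edge_layer(binary_layer(lc, "forest"), binary_layer(lc, "agriculture"))
  expect_true(all(ed$values[, c(5, 6)] == 1))
  expect_true(all(ed$values[, -c(5, 6)] == 0))
  # forest surrounded by grassland only -> no edge
  codes2 <- matrix(3L, 8, 8); codes2[4:5, 4:5] <- 1L
  lc2 <- lc_raster(codes2)
  ed2 <- edge_layer(binary_layer(lc2, "forest"),
                    binary_layer(lc2, "agriculture"))
  expect_true(all(ed2$values == 0))
  # overlapping presence is rejected
  ones <- grid_raster(matrix(1, 3, 3), cellsize = 30)
  expect_error(edge_layer(ones, ones), "both")
})

test_that("edge layer equals a brute-force neighbour scan on random mosaics", {
  set.seed(17)
  for (rep in 1:5) {
    codes <- matrix(sample(1:4, 144, replace = TRUE), 12, 12)
    lc <- lc_raster(codes)
    f <- binary_layer(lc, "forest"); a <- binary_layer(lc, "agriculture")
    ed <- edge_layer(f, a)
    oracle <- matrix(0, 12, 12)
    for (r in 1:12) for (c in 1:12) {
      nb <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
      nb <- nb[nb[, 1] >= 1 & nb[, 1] <= 12 & nb[, 2] >= 1 & nb[, 2] <= 12, ,
               drop = FALSE]
      nbv <- codes[nb]
      if ((codes[r, c] == 1 && any(nbv == 2)) ||
          (codes[r, c] == 2 && any(nbv == 1))) oracle[r, c] <- 1
    }
    expect_equal(ed$values, oracle)
  }
})

test_that("perimeter sites are equally spaced with conserved total arc", {
  ring <- perimeter_sites(c(0, 30000, 0, 30000), buffer = 7500, n = 50)
  expect_equal(ring$spacing, 3600)
  expect_equal(ring$n, 50L)
  # all sites on the buffered rectangle boundary
  expect_true(all(ring$x >= -7500 - 1e-9 & ring$x <= 37500 + 1e-9))
  on_edge <- abs(ring$x + 7500) < 1e-9 | abs(ring$x - 37500) < 1e-9 |
    abs(ring$y + 7500) < 1e-9 | abs(ring$y - 37500) < 1e-9
  expect_true(all(on_edge))
  # spacing times count recovers the perimeter
  expect_equal(ring$spacing * ring$n, 4 * 45000)
  unit <- perimeter_sites(c(0, 1, 0, 1), buffer = 0, n = 4)
  expect_equal(unit$spacing, 1)
  expect_equal(sort(round(unit$x, 9)), c(0, 0, 1, 1))
})

test_that("a uniform strip behaves as a series circuit", {
  cond <- grid_raster(matrix(2, 1, 6), cellsize = 1)
  pc <- pair_current(cond, c(1, 1), c(1, 6))
  expect_equal(as.vector(pc$current$values), rep(1, 6))
  expect_equal(pc$effective_resistance, 5 / 2)  # 5 edges of conductance 2
  expect_error(pair_current(cond, c(1, 2), c(1, 2)), "differ")
})

test_that("2x2 uniform lattice matches the analytic effective resistance", {
  cond <- grid_raster(matrix(1, 2, 2), cellsize = 1)
  pc <- pair_current(cond, c(1, 1), c(2, 2))
  # direct diagonal (1/sqrt(2)) in parallel with two 2-edge paths: R = 2 - sqrt(2)
  expect_equal(pc$effective_resistance, 2 - sqrt(2), tolerance = 1e-12)
})

test_that("sparse circuit solve matches the dense oracle and obeys its laws", {
  set.seed(23)
  for (rep in 1:8) {
    nr <- sample(2:6, 1); nc <- sample(2:6, 1)
    vals <- matrix(stats::runif(nr * nc, 0.2, 5), nr, nc)
    cond <- grid_raster(vals, cellsize = 1)
    n <- nr * nc
    st <- sample(n, 2)
    pc <- pair_current(cond, st[1], st[2])
    oracle <- dense_pair_current(vals, st[1], st[2])
    expect_lt(max(abs(pc$potentials - oracle$potentials)), 1e-8)
    expect_lt(max(abs(as.vector(pc$current$values) - oracle$current)), 1e-8)
    expect_equal(pc$effective_resistance, oracle$reff, tolerance = 1e-10)
    # reciprocity
    rev <- pair_current(cond, st[2], st[1])
    expect_lt(max(abs(rev$current$values - pc$current$values)), 1e-10)
    # conductance scaling: currents invariant, resistance scales as 1/c
    sc <- pair_current(grid_raster(vals * 4, cellsize = 1), st[1], st[2])
    expect_lt(max(abs(sc$current$values - pc$current$values)), 1e-10)
    expect_equal(sc$effective_resistance, pc$effective_resistance / 4,
                 tolerance = 1e-10)
    # terminals carry the injected unit current
    expect_equal(pc$current$values[st], c(1, 1), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("omnidirectional current sums pair maps and clips the buffer", {
  set.seed(29)
  vals <- matrix(stats::runif(100, 0.5, 2), 10, 10)
  cond <- grid_raster(vals, cellsize = 1)
  sites <- cbind(c(0.5, 9.5, 5.5), c(0.5, 0.5, 9.5))
  om <- omnidirectional_current(cond, sites, buffer = 2)
  # direct summation oracle over the three pairs
  snap <- function(p) {
    col <- min(max(ceiling((p[1] - 0) / 1), 1), 10)
    row <- min(max(10 - ceiling((p[2] - 0) / 1) + 1, 1), 10)
    (col - 1) * 10 + row
  }
  cells <- apply(sites, 1, snap)
  total <- matrix(0, 10, 10)
  for (pp in list(c(1, 2), c(1, 3), c(2, 3))) {
    total <- total + pair_current(cond, cells[pp[1]], cells[pp[2]])$current$values
  }
  clipped <- total[3:8, 3:8]
  expect_equal(om$n_site_pairs, 3L)
  expect_lt(max(abs(om$current$values - clipped)), 1e-8)
  expect_equal(dim(om$current$values), c(6L, 6L))
  expect_equal(om$current$xll, 2)
})

test_that("uniform conductance yields a dihedrally symmetric clipped map", {
  # odd cell count so edge-midpoint sites snap to symmetric cells
  cond <- grid_raster(matrix(1, 13, 13), cellsize = 1)
  ring <- perimeter_sites(c(3, 10, 3, 10), buffer = 3, n = 8)
  om <- omnidirectional_current(cond, ring, buffer = 3)
  m <- om$current$values
  expect_lt(max(abs(m - t(m))), 1e-6)
  expect_lt(max(abs(m - m[rev(seq_len(nrow(m))), ])), 1e-6)
  expect_lt(max(abs(m - m[, rev(seq_len(ncol(m)))])), 1e-6)
})

test_that("a high-conductance corridor attains the map maximum (pinch point)", {
  vals <- matrix(1, 9, 15)
  vals[5, ] <- 101   # single corridor through hostile matrix
  cond <- grid_raster(vals, cellsize = 1)
  ring <- perimeter_sites(c(3, 12, 3, 6), buffer = 3, n = 6)
  om <- omnidirectional_current(cond, ring, buffer = 3)
  peak <- which(om$current$values == max(om$current$values), arr.ind = TRUE)
  expect_true(all(peak[, 1] == 5 - 3))  # corridor row after 3-cell clip
})

test_that("regional summaries are exact means and proportions", {
  m <- grid_raster(matrix(1:24, 4, 6), cellsize = 1)
  expect_equal(mean_current_in(5L, m), 5)
  mask <- matrix(FALSE, 4, 6); mask[1:2, 1:3] <- TRUE
  expect_equal(mean_current_in(mask, m), mean(m$values[1:2, 1:3]))
  # linearity: whole mean is the weighted mean of half means
  left <- matrix(FALSE, 4, 6); left[, 1:3] <- TRUE
  right <- !left
  expect_equal(mean(m$values),
               (mean_current_in(left, m) * 12 + mean_current_in(right, m) * 12) / 24)
  # uniform map
  u <- grid_raster(matrix(3.5, 4, 6), cellsize = 1)
  expect_equal(mean_current_in(mask, u), 3.5)
  expect_error(mean_current_in(matrix(FALSE, 4, 6), m), "empty")
  # proportions equal brute-force cell counting
  set.seed(31)
  b <- grid_raster(matrix(sample(0:1, 24, replace = TRUE), 4, 6), cellsize = 1)
  expect_equal(proportion_in(mask, b), sum(b$values[mask] == 1) / sum(mask))
  allones <- grid_raster(matrix(1, 4, 6), cellsize = 1)
  expect_equal(proportion_in(mask, allones), 1)
})

test_that("ESRI ASCII grids round-trip through read and write", {
  r <- grid_raster(matrix(c(1.5, -2, 0, 4.25, NA, 7), 2, 3),
                   xll = 100, yll = 200, cellsize = 30)
  path <- withr::local_tempfile(fileext = ".asc")
  write_asc(r, path)
  back <- read_asc(path)
  expect_equal(back$values, r$values)
  expect_equal(back$xll, 100)
  expect_equal(back$yll, 200)
  expect_equal(back$cellsize, 30)
})
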