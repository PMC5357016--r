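#' Planar grid raster
#'
#' Minimal north-up raster container used across the package: a numeric (or
#' integer) matrix whose first row is the northernmost, plus the lower-left
#' corner of the extent and a square cell size in metres. Cell centres are at
#' `xll + (col - 0.5) * cellsize` and `yll + (nrow - row + 0.5) * cellsize`.
#'
#' @param values A matrix (row 1 = north edge).
#' @param xll,yll Lower-left corner of the raster extent (metres).
#' @param cellsize Cell edge length (metres).
#' @param levels Optional character vector naming the categories when
#'   `values` holds integer class codes (1-based).
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, xll = 0, yll = 0, cellsize = 30,
                        levels = NULL) {
  if (!is.matrix(values)) stop("values must be a matrix")
  if (cellsize <= 0) stop("cellsize must be positive")
  structure(
    list(values = values, xll = xll, yll = yll, cellsize = cellsize,
         nrow = nrow(values), ncol = ncol(values), levels = levels),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  cat("grid_raster:", x$nrow, "x", x$ncol, "cells of", x$cellsize, "m,",
      "lower-left (", x$xll, ",", x$yll, ")\n")
  if (!is.null(x$levels))
    cat("  levels:", paste(x$levels, collapse = ", "), "\n")
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  a$nrow == b$nrow && a$ncol == b$ncol &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Cell centre coordinates of a raster
#'
#' @param r A `grid_raster`.
#' @return A list with vectors `x` (west to east, length `ncol`) and `y`
#'   (south to north order reversed to match rows: element i is the centre
#'   of row i, i.e. north to south).
#' @export
cell_centers <- function(r) {
  list(
    x = r$xll + (seq_len(r$ncol) - 0.5) * r$cellsize,
    y = r$yll + (r$nrow - seq_len(r$nrow) + 0.5) * r$cellsize
  )
}

# row/col of the cell containing planar points; NA outside the extent
locate_cells <- function(r, x, y) {
  col <- ceiling((x - r$xll) / r$cellsize)
  row <- r$nrow - ceiling((y - r$yll) / r$cellsize) + 1L
  # points exactly on the ll corner of the extent fall in the first cell
  col[x == r$xll] <- 1L
  row[y == r$yll] <- r$nrow
  bad <- col < 1L | col > r$ncol | row < 1L | row > r$nrow
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Read an ESRI ASCII grid
#'
#' Parses the plain-text ESRI ASCII raster format (`ncols`, `nrows`,
#' `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`, `cellsize`,
#' `NODATA_value`, then rows north to south). NODATA cells become `NA`.
#'
#' @param path Path to a `.asc` file.
#' @return A `grid_raster`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ESRI ASCII header missing ", paste(setdiff(need, names(hdr)),
                                             collapse = ", "))
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
         else hdr$xllcenter - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
         else hdr$yllcenter - cs / 2
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("expected ", nr * nc, " cell values, found ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  grid_raster(m, xll = xll, yll = yll, cellsize = cs)
}

#' Write an ESRI ASCII grid
#'
#' @param r A `grid_raster`; `NA` cells are written as the NODATA value.
#' @param path Output path.
#' @param nodata NODATA code (default -9999).
#' @return `path`, invisibly.
#' @export
write_asc <- function(r, path, nodata = -9999) {
  m <- r$values
  m[is.na(m)] <- nodata
  hdr <- c(
    paste("ncols", r$ncol),
    paste("nrows", r$nrow),
    paste("xllcorner", format(r$xll, digits = 15)),
    paste("yllcorner", format(r$yll, digits = 15)),
    paste("cellsize", format(r$cellsize, digits = 15)),
    paste("NODATA_value", nodata)
  )
  rows <- apply(m, 1L, function(v)
    paste(format(v, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
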