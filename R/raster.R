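#' Create a raster layer
#'
#' @param grid A \linkS4class{GridSpec}.
#' @param values Numeric matrix \code{[nRows, nCols]} (row 1 = south) or a
#'   vector in column-major cell order.
#' @param mask Logical matrix of valid cells; defaults to finite values.
#' @return A \linkS4class{RasterLayer}.
#' @export
RasterLayer <- function(grid, values, mask = NULL) {
  if (!is.matrix(values)) values <- matrix(values, grid@nRows, grid@nCols)
  if (is.null(mask)) mask <- is.finite(values)
  storage.mode(values) <- "double"
  values[!mask] <- 0
  new("RasterLayer", grid = grid, values = values, mask = mask)
}

#' @export
setMethod("show", "RasterLayer", function(object) {
  v <- object@values[object@mask]
  cat(sprintf("RasterLayer: %d x %d cells, %d valid; range [%g, %g]\n",
              nrow(object@values), ncol(object@values), sum(object@mask),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

#' Convert a raster layer to a (lon, lat, value) data frame
#'
#' @param layer A \linkS4class{RasterLayer}.
#' @param validOnly Drop nodata cells (default TRUE).
#' @return A data frame with columns lon, lat, value.
#' @export
layerToDataFrame <- function(layer, validOnly = TRUE) {
  cc <- cellCenters(layer@grid)
  df <- data.frame(lon = cc[, 1], lat = cc[, 2],
                   value = as.vector(layer@values))
  if (validOnly) df <- df[as.vector(layer@mask), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Nearest-neighbour resampling to a new resolution
#'
#' Each target cell takes the value of the source cell containing its
#' center; the extent is preserved to within one source cell. Refining by
#' an integer factor turns every source cell into an exact block of copies.
#'
#' @param layer A \linkS4class{RasterLayer}.
#' @param newResDeg New resolution in degrees (> 0).
#' @return A \linkS4class{RasterLayer} on the refined/coarsened grid.
#' @export
resampleLayer <- function(layer, newResDeg) {
  stopifnot(newResDeg > 0)
  src <- layer@grid
  if (isTRUE(all.equal(newResDeg, src@resDeg))) return(layer)
  extLon <- src@nCols * src@resDeg
  extLat <- src@nRows * src@resDeg
  nCols <- max(1L, as.integer(round(extLon / newResDeg)))
  nRows <- max(1L, as.integer(round(extLat / newResDeg)))
  dst <- GridSpec(src@lonMin, src@latMin, newResDeg, nCols, nRows)
  # source row/col containing each target center, clamped to the edge cells
  srcCol <- pmin(pmax(floor((gridLons(dst) - src@lonMin) / src@resDeg) + 1, 1), src@nCols)
  srcRow <- pmin(pmax(floor((gridLats(dst) - src@latMin) / src@resDeg) + 1, 1), src@nRows)
  new("RasterLayer", grid = dst,
      values = layer@values[srcRow, srcCol, drop = FALSE],
      mask = layer@mask[srcRow, srcCol, drop = FALSE])
}

#' Rasterize the convex hull of a point set
#'
#' Returns the cells whose center lies inside or on the convex hull of the
#' vertices, always including the cells that contain the vertices
#' themselves. Degenerate inputs (fewer than 3 distinct points, or
#' collinear points) degrade to the cells containing the points and the
#' straight lines between consecutive points.
#'
#' @param vertices Two-column matrix (lon, lat) in degrees.
#' @param grid A \linkS4class{GridSpec}.
#' @return Sorted integer vector of linear cell indices (cells outside the
#'   grid are dropped).
#' @export
rasterizeHull <- function(vertices, grid) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2)
  pts <- unique(round(vertices, 12))
  vertexCells <- cellFromLonLat(grid, vertices[, 1], vertices[, 2])
  degenerate <- nrow(pts) < 3
  if (!degenerate) {
    h <- grDevices::chull(pts[, 1], pts[, 2])
    degenerate <- length(h) < 3
  }
  if (degenerate) {
    cells <- vertexCells
    if (nrow(pts) >= 2) {
      for (i in seq_len(nrow(pts) - 1)) {
        a <- pts[i, ]; b <- pts[i + 1, ]
        nStep <- max(2L, ceiling(max(abs(b - a)) / (grid@resDeg / 4)) + 1L)
        t <- seq(0, 1, length.out = nStep)
        cells <- c(cells, cellFromLonLat(grid, a[1] + t * (b[1] - a[1]),
                                         a[2] + t * (b[2] - a[2])))
      }
    }
    return(sort(unique(cells[!is.na(cells)])))
  }
  poly <- pts[h, , drop = FALSE]
  # candidate cells: bounding box of the hull, padded by one cell
  colLo <- max(1L, floor((min(poly[, 1]) - grid@lonMin) / grid@resDeg))
  colHi <- min(grid@nCols, ceiling((max(poly[, 1]) - grid@lonMin) / grid@resDeg) + 1L)
  rowLo <- max(1L, floor((min(poly[, 2]) - grid@latMin) / grid@resDeg))
  rowHi <- min(grid@nRows, ceiling((max(poly[, 2]) - grid@latMin) / grid@resDeg) + 1L)
  if (colLo > colHi || rowLo > rowHi)
    return(sort(unique(vertexCells[!is.na(vertexCells)])))
  cols <- colLo:colHi; rows <- rowLo:rowHi
  cx <- grid@lonMin + (rep(cols, each = length(rows)) - 0.5) * grid@resDeg
  cy <- grid@latMin + (rep(rows, times = length(cols)) - 0.5) * grid@resDeg
  inside <- pracma::inpolygon(cx, cy, poly[, 1], poly[, 2], boundary = TRUE)
  idx <- (rep(cols, each = length(rows)) - 1L) * grid@nRows +
    rep(rows, times = length(cols))
  cells <- c(idx[inside], vertexCells)
  sort(unique(cells[!is.na(cells)]))
}

#' Read/write rasters as ESRI ASCII grids
#'
#' Plain-text single-band georeferenced raster format
#' (ncols/nrows/xllcorner/yllcorner/cellsize header, rows north to south).
#'
#' @param layer A \linkS4class{RasterLayer}.
#' @param path File path.
#' @param digits Significant digits written (default 10).
#' @return \code{readAsciiGrid} returns a \linkS4class{RasterLayer};
#'   \code{writeAsciiGrid} returns \code{path} invisibly.
#' @export
writeAsciiGrid <- function(layer, path, digits = 10) {
  g <- layer@grid
  v <- layer@values
  v[!layer@mask] <- NA
  hdr <- c(sprintf("ncols %d", g@nCols), sprintf("nrows %d", g@nRows),
           sprintf("xllcorner %.10g", g@lonMin),
           sprintf("yllcorner %.10g", g@latMin),
           sprintf("cellsize %.10g", g@resDeg),
           "NODATA_value -9999")
  rows <- vapply(rev(seq_len(g@nRows)), function(r) {
    x <- v[r, ]
    x <- ifelse(is.na(x), "-9999", formatC(x, digits = digits, format = "g"))
    paste(x, collapse = " ")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- tolower(vapply(hdr, `[`, "", 1))
  val <- as.numeric(vapply(hdr, `[`, "", 2))
  names(val) <- key
  g <- GridSpec(val[["xllcorner"]], val[["yllcorner"]], val[["cellsize"]],
                val[["ncols"]], val[["nrows"]])
  body <- lapply(lines[-(1:6)], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, body)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # back to south-first rows
  m[m == val[["nodata_value"]]] <- NA
  RasterLayer(g, m)
}
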