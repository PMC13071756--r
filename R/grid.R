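#' Create a grid specification
#'
#' @param lonMin,latMin West/south edges in degrees.
#' @param resDeg Cell size in degrees (square cells).
#' @param nCols,nRows Grid dimensions.
#' @return A \linkS4class{GridSpec}.
#' @export
#' @examples
#' GridSpec(100, 25, 0.1, 50, 50)
GridSpec <- function(lonMin, latMin, resDeg, nCols, nRows) {
  new("GridSpec", lonMin = as.numeric(lonMin), latMin = as.numeric(latMin),
      resDeg = as.numeric(resDeg), nCols = as.integer(nCols),
      nRows = as.integer(nRows))
}

#' @export
setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells at %g deg, origin (%g, %g), extent lon [%g, %g] lat [%g, %g]\n",
              object@nRows, object@nCols, object@resDeg,
              object@lonMin, object@latMin,
              object@lonMin, object@lonMin + object@nCols * object@resDeg,
              object@latMin, object@latMin + object@nRows * object@resDeg))
})

#' @export
setMethod("dim", "GridSpec", function(x) c(x@nRows, x@nCols))

#' Cell-center coordinates of a grid
#'
#' @param grid A \linkS4class{GridSpec}.
#' @return \code{gridLons}/\code{gridLats}: numeric vectors of the column /
#'   row center coordinates. \code{cellCenters}: an \code{nCells x 2} matrix
#'   (lon, lat) in column-major (cell linear index) order.
#' @export
gridLons <- function(grid) grid@lonMin + (seq_len(grid@nCols) - 0.5) * grid@resDeg

#' @rdname gridLons
#' @export
gridLats <- function(grid) grid@latMin + (seq_len(grid@nRows) - 0.5) * grid@resDeg

#' @rdname gridLons
#' @export
cellCenters <- function(grid) {
  lons <- gridLons(grid); lats <- gridLats(grid)
  cbind(lon = rep(lons, each = grid@nRows), lat = rep(lats, times = grid@nCols))
}

#' Map lon/lat points to grid cells
#'
#' Cells are half-open \code{[edge, edge + res)}; points outside the grid
#' map to \code{NA}.
#'
#' @param grid A \linkS4class{GridSpec}.
#' @param lon,lat Numeric vectors of coordinates in degrees.
#' @return Integer vector of linear cell indices (column-major:
#'   \code{(col - 1) * nRows + row}), \code{NA} outside the grid.
#' @export
cellFromLonLat <- function(grid, lon, lat) {
  col <- floor((lon - grid@lonMin) / grid@resDeg) + 1
  row <- floor((lat - grid@latMin) / grid@resDeg) + 1
  bad <- col < 1 | col > grid@nCols | row < 1 | row > grid@nRows |
    !is.finite(lon) | !is.finite(lat)
  idx <- (col - 1) * grid@nRows + row
  idx[bad] <- NA_integer_
  as.integer(idx)
}

#' Spherical area of grid cells
#'
#' Exact area of a lon/lat cell on a sphere of radius 6371 km:
#' \code{R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))}. All cells in a
#' row share the same area, so the function is indexed by row. Being an
#' analytic equal-area computation, it is area-equivalent to summing cells
#' after any equal-area (e.g. Eckert IV) reprojection.
#'
#' @param grid A \linkS4class{GridSpec}.
#' @param row Integer row index (1 = southernmost), vectorized.
#' @return Area(s) in km^2.
#' @export
#' @examples
#' g <- GridSpec(0, -0.05, 0.1, 1, 1)  # 0.1 deg cell centered on the equator
#' cellArea(g, 1)  # ~123.6 km^2
cellArea <- function(grid, row) {
  if (any(row < 1 | row > grid@nRows)) .stopf("row index out of range")
  phiBot <- (grid@latMin + (row - 1) * grid@resDeg) * pi / 180
  phiTop <- (grid@latMin + row * grid@resDeg) * pi / 180
  dLambda <- grid@resDeg * pi / 180
  EARTH_RADIUS_KM^2 * dLambda * (sin(phiTop) - sin(phiBot))
}

#' Meridional metric cell size of a grid
#'
#' North-south extent of one cell in km (constant over the grid); the
#' east-west extent at latitude phi is this value times \code{cos(phi)}.
#' Used by the dispersal engine to compare a species' annual dispersal
#' distance with the grid resolution.
#'
#' @param grid A \linkS4class{GridSpec}.
#' @return Cell size in km.
#' @export
cellSizeKm <- function(grid) grid@resDeg * KM_PER_DEG
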