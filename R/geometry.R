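#' Validate a closed polygon contour
#'
#' Contours are ordered vertex lists in pixel coordinates, implicitly closed.
#' The package convention is 1-based \code{(row, col)} matrix coordinates with
#' row increasing downward; external CSV files use 0-based coordinates (see
#' [read_contours()]).
#'
#' @param polygon numeric matrix with columns \code{row}, \code{col} (>= 3
#'   vertices). A trailing vertex equal to the first is tolerated and dropped.
#' @param check_simple if \code{TRUE}, test all non-adjacent edge pairs for
#'   crossings and fail on self-intersection.
#' @return the cleaned polygon matrix, invisibly usable downstream.
#' @keywords internal
validate_polygon <- function(polygon, check_simple = TRUE) {
  polygon <- as.matrix(polygon)
  if (!is.numeric(polygon) || ncol(polygon) != 2L)
    stop("invalid contour: polygon must be a numeric matrix with 2 columns (row, col)")
  n <- nrow(polygon)
  if (n >= 2L && all(polygon[1L, ] == polygon[n, ])) {
    polygon <- polygon[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3L)
    stop("invalid contour: a closed polygon needs at least 3 distinct vertices")
  if (anyNA(polygon) || any(!is.finite(polygon)))
    stop("invalid contour: non-finite vertex coordinates")
  if (check_simple && polygon_self_intersects(polygon))
    stop("invalid contour: polygon is self-intersecting")
  polygon
}

# Proper-crossing test between all pairs of non-adjacent edges. Shared
# endpoints between adjacent edges are not intersections.
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  a <- p
  b <- p[c(2:n, 1L), , drop = FALSE]
  cross <- function(o, u, v) (u[, 1] - o[, 1]) * (v[, 2] - o[, 2]) -
    (u[, 2] - o[, 2]) * (v[, 1] - o[, 1])
  for (i in seq_len(n - 2L)) {
    j <- (i + 2L):n
    j <- j[!(i == 1L & j == n)]          # edge n is adjacent to edge 1
    if (!length(j)) next
    ai <- a[rep(i, length(j)), , drop = FALSE]
    bi <- b[rep(i, length(j)), , drop = FALSE]
    aj <- a[j, , drop = FALSE]
    bj <- b[j, , drop = FALSE]
    d1 <- cross(ai, bi, aj); d2 <- cross(ai, bi, bj)
    d3 <- cross(aj, bj, ai); d4 <- cross(aj, bj, bi)
    if (any(((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
            ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))))
      return(TRUE)
  }
  FALSE
}

# Even-odd (horizontal ray crossing) membership test at arbitrary points.
# Half-open convention: points on "lower" edges are inside, on "upper" edges
# outside, so abutting polygons tile without overlap.
point_in_polygon <- function(pr, pc, polygon) {
  n <- nrow(polygon)
  vr <- polygon[, 1]; vc <- polygon[, 2]
  inside <- logical(length(pr))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vr[i] > pr) != (vr[j] > pr)) &
      (pc < (vc[j] - vc[i]) * (pr - vr[i]) / (vr[j] - vr[i]) + vc[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize a closed contour to a pixel mask
#'
#' A pixel belongs to the mask when its center lies inside the polygon under
#' the even-odd rule with the half-open convention (centers exactly on the
#' low-coordinate boundary are inside, on the high side outside), so an
#' axis-aligned square with corners (10,10)-(20,20) covers exactly 100 pixels.
#' Pixel centers sit at integer 1-based \code{(row, col)} coordinates.
#'
#' @param polygon numeric matrix of vertices, columns \code{(row, col)},
#'   1-based pixel coordinates (may be fractional).
#' @param grid_shape integer vector \code{c(nrow, ncol)}.
#' @return logical matrix of dimension \code{grid_shape}.
#' @examples
#' sq <- cbind(c(10, 10, 20, 20), c(10, 20, 20, 10))
#' sum(rasterize_contour(sq, c(64, 64)))  # 100
#' @export
rasterize_contour <- function(polygon, grid_shape) {
  polygon <- validate_polygon(polygon)
  grid_shape <- as.integer(grid_shape)
  mask <- matrix(FALSE, grid_shape[1], grid_shape[2])
  r0 <- max(1L, floor(min(polygon[, 1])))
  r1 <- min(grid_shape[1], ceiling(max(polygon[, 1])))
  c0 <- max(1L, floor(min(polygon[, 2])))
  c1 <- min(grid_shape[2], ceiling(max(polygon[, 2])))
  if (r0 > r1 || c0 > c1) return(mask)
  rows <- r0:r1; cols <- c0:c1
  pr <- rep(rows, times = length(cols))
  pc <- rep(cols, each = length(rows))
  inside <- point_in_polygon(pr, pc, polygon)
  mask[cbind(pr[inside], pc[inside])] <- TRUE
  mask
}

#' Build wall compartment masks from lumen, scaffold and vessel contours
#'
#' The scaffolded vessel wall is split into the lumen-scaffold compartment
#' (inside the scaffold contour, outside the lumen) and the scaffold-vessel
#' compartment (inside the vessel/EEM contour, outside the scaffold); the
#' total wall is everything between lumen and vessel. Where the scaffold
#' contour locally dips inside the lumen the clipped pixels belong to neither
#' sub-compartment but stay in the total wall.
#'
#' @param contours a list with elements \code{lumen}, \code{scaffold},
#'   \code{vessel}, each a polygon matrix as for [rasterize_contour()]. The
#'   scaffold-vessel mask is clipped by the lumen as well, so both
#'   compartments always stay inside the total wall.
#' @param grid_shape integer vector \code{c(nrow, ncol)}.
#' @return list of logical masks \code{lumen_scaffold}, \code{scaffold_vessel},
#'   \code{total_wall}, plus the raw region masks \code{lumen}, \code{scaffold},
#'   \code{vessel}.
#' @export
build_compartments <- function(contours, grid_shape) {
  stopifnot(all(c("lumen", "scaffold", "vessel") %in% names(contours)))
  lum <- rasterize_contour(contours$lumen, grid_shape)
  sca <- rasterize_contour(contours$scaffold, grid_shape)
  ves <- rasterize_contour(contours$vessel, grid_shape)
  total <- ves & !lum
  if (!any(total)) {
    warning("degenerate geometry: vessel does not enclose tissue outside the lumen; empty masks")
    empty <- matrix(FALSE, grid_shape[1], grid_shape[2])
    return(list(lumen_scaffold = empty, scaffold_vessel = empty,
                total_wall = empty, lumen = lum, scaffold = sca, vessel = ves))
  }
  list(
    lumen_scaffold = sca & !lum & ves,
    scaffold_vessel = ves & !sca & !lum,
    total_wall = total,
    lumen = lum, scaffold = sca, vessel = ves
  )
}

#' Physical area of a pixel mask
#'
#' @param mask logical matrix.
#' @param pixel_spacing_mm isotropic pixel size in mm (> 0).
#' @return area in mm^2: (number of TRUE pixels) * spacing^2.
#' @export
area_mm2 <- function(mask, pixel_spacing_mm) {
  stopifnot(is.numeric(pixel_spacing_mm), pixel_spacing_mm > 0)
  sum(mask) * pixel_spacing_mm^2
}

# Minimum Euclidean distance (pixels) from points to a polygon boundary,
# vectorized over points, looped over edges.
dist_to_polygon <- function(pr, pc, polygon) {
  n <- nrow(polygon)
  vr <- polygon[, 1]; vc <- polygon[, 2]
  d2 <- rep(Inf, length(pr))
  j <- n
  for (i in seq_len(n)) {
    er <- vr[i] - vr[j]; ec <- vc[i] - vc[j]
    len2 <- er * er + ec * ec
    if (len2 == 0) {
      dd <- (pr - vr[j])^2 + (pc - vc[j])^2
    } else {
      t <- ((pr - vr[j]) * er + (pc - vc[j]) * ec) / len2
      t <- pmin(1, pmax(0, t))
      dd <- (pr - (vr[j] + t * er))^2 + (pc - (vc[j] + t * ec))^2
    }
    d2 <- pmin(d2, dd)
    j <- i
  }
  sqrt(d2)
}
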