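#' Grey-level histogram over 0..255
#'
#' @param x integer grey levels in \code{[0, 255]} (vector or matrix).
#' @return integer vector of length 256; element \code{g + 1} counts level
#'   \code{g}.
#' @export
grey_histogram <- function(x) {
  x <- as.integer(x)
  if (length(x) && (min(x) < 0L || max(x) > 255L))
    stop("grey levels must lie in [0, 255]")
  tabulate(x + 1L, nbins = 256L)
}

#' Otsu's threshold from a 256-bin histogram
#'
#' Returns the grey level \code{t} in 1..255 maximizing the between-class
#' variance \eqn{\sigma^2_B(t) = \omega_0 \omega_1 (\mu_0 - \mu_1)^2}, where
#' class 0 holds levels \code{< t} and class 1 levels \code{>= t}. Ties are
#' broken toward the smallest maximizing \code{t}, so the result is
#' deterministic.
#'
#' @param histogram integer vector of length 256 (counts for levels 0..255).
#' @return integer threshold in \code{[1, 255]}.
#' @export
otsu_threshold <- function(histogram) {
  stopifnot(length(histogram) == 256L)
  h <- as.numeric(histogram)
  if (any(h < 0)) stop("histogram counts must be non-negative")
  if (sum(h > 0) < 2L)
    stop("degenerate histogram: need at least 2 distinct grey levels with counts")
  levels <- 0:255
  n <- sum(h)
  cw <- cumsum(h)                     # pixels with level <= g
  cm <- cumsum(h * levels)            # intensity mass with level <= g
  # candidate thresholds t = 1..255: class0 = levels < t <=> levels <= t-1
  w0 <- cw[1:255]
  w1 <- n - w0
  m0 <- cm[1:255]
  m1 <- cm[256] - m0
  sigma <- rep(-Inf, 255)
  ok <- w0 > 0 & w1 > 0
  sigma[ok] <- w0[ok] * w1[ok] * (m0[ok] / w0[ok] - m1[ok] / w1[ok])^2
  which.max(sigma)                    # which.max returns the first maximum
}

#' Build the adventitial reference ring mask
#'
#' The reference adventitia is the band of pixels outside the vessel (EEM)
#' contour whose Euclidean distance to the contour boundary lies between
#' \code{d_min} and \code{d_max} (defaults 0.01 and 0.21 mm), clipped at the
#' image borders.
#'
#' @param vessel_polygon vessel contour, matrix \code{(row, col)}.
#' @param pixel_spacing_mm pixel size in mm.
#' @param grid_shape \code{c(nrow, ncol)}.
#' @param d_min,d_max band limits in mm, \code{d_max > d_min >= 0}.
#' @return logical ring mask.
#' @export
build_ring <- function(vessel_polygon, pixel_spacing_mm, grid_shape,
                       d_min = 0.01, d_max = 0.21) {
  stopifnot(d_min >= 0, d_max >= d_min, pixel_spacing_mm > 0)
  vessel_polygon <- validate_polygon(vessel_polygon)
  grid_shape <- as.integer(grid_shape)
  mask <- matrix(FALSE, grid_shape[1], grid_shape[2])
  pad <- d_max / pixel_spacing_mm + 1
  r0 <- max(1L, floor(min(vessel_polygon[, 1]) - pad))
  r1 <- min(grid_shape[1], ceiling(max(vessel_polygon[, 1]) + pad))
  c0 <- max(1L, floor(min(vessel_polygon[, 2]) - pad))
  c1 <- min(grid_shape[2], ceiling(max(vessel_polygon[, 2]) + pad))
  if (r0 > r1 || c0 > c1) {
    warning("empty ring: reference band lies entirely off-image")
    return(mask)
  }
  rows <- r0:r1; cols <- c0:c1
  pr <- rep(rows, times = length(cols))
  pc <- rep(cols, each = length(rows))
  inside <- point_in_polygon(pr, pc, vessel_polygon)
  pr <- pr[!inside]; pc <- pc[!inside]
  if (length(pr)) {
    d_mm <- dist_to_polygon(pr, pc, vessel_polygon) * pixel_spacing_mm
    keep <- d_mm >= d_min & d_mm <= d_max
    if (any(keep)) mask[cbind(pr[keep], pc[keep])] <- TRUE
  }
  if (!any(mask)) warning("empty ring: no pixels fall in the reference band")
  mask
}

# Angle of pixels around the catheter center, degrees in [0, 360),
# counterclockwise from the positive column axis (row axis points down).
pixel_angles_deg <- function(pr, pc, center) {
  deg <- atan2(-(pr - center[1]), pc - center[2]) * 180 / pi
  deg %% 360
}

# TRUE where angles (degrees) fall in interval [a, b) allowing wrap-around.
angle_in_interval <- function(deg, a, b) {
  a <- a %% 360; b <- b %% 360
  if (a == b) rep(TRUE, length(deg))   # full-circle interval
  else if (a < b) deg >= a & deg < b
  else deg >= a | deg < b
}

#' Select reference sectors of the adventitial ring
#'
#' The ring is divided into 180 sectors of 2 degrees around the catheter
#' center (sector \code{s} covers \code{[2s, 2s+2)} degrees, counterclockwise
#' from the positive column axis). A sector is excluded when strictly more
#' than half of its ring pixels lie strictly below the adaptive (Otsu)
#' threshold, when it intersects the guidewire angular mask, or when it holds
#' no ring pixels.
#'
#' @param pixels integer grey-level matrix of the frame.
#' @param ring_mask logical ring mask from [build_ring()].
#' @param center catheter center \code{c(row, col)}.
#' @param adaptive_threshold Otsu threshold computed on the full ring.
#' @param guidewire optional guidewire angular mask: list of
#'   \code{c(start_deg, end_deg)} intervals (end exclusive, may wrap 360).
#' @param sector_deg angular sector width in degrees (default 2).
#' @return logical vector of \code{360 / sector_deg} inclusion flags.
#' @export
exclude_sectors <- function(pixels, ring_mask, center, adaptive_threshold,
                            guidewire = NULL, sector_deg = 2) {
  if (!any(ring_mask)) stop("empty ring mask")
  n_sectors <- as.integer(round(360 / sector_deg))
  idx <- which(ring_mask, arr.ind = TRUE)
  deg <- pixel_angles_deg(idx[, 1], idx[, 2], center)
  sector <- pmin(floor(deg / sector_deg), n_sectors - 1L)
  grey <- pixels[ring_mask]
  n_pix <- tabulate(sector + 1L, nbins = n_sectors)
  n_dark <- tabulate((sector + 1L)[grey < adaptive_threshold], nbins = n_sectors)
  included <- n_pix > 0L & n_dark * 2L <= n_pix     # "more than half" is strict
  if (!is.null(guidewire)) {
    lo <- (seq_len(n_sectors) - 1L) * sector_deg
    hi <- lo + sector_deg
    for (iv in guidewire) {
      a <- iv[1] %% 360; b <- iv[2] %% 360
      # sector [lo, hi) intersects guidewire [a, b)?
      hit <- if (a < b) lo < b & hi > a
             else if (a == b) rep(TRUE, n_sectors)
             else lo < b | hi > a
      included[hit] <- FALSE
    }
  }
  included
}

#' Per-frame adventitial reference
#'
#' Builds the ring, computes the adaptive Otsu threshold over all ring pixels,
#' drops low-signal and guidewire sectors, and records the grey-level
#' histogram of the retained reference pixels.
#'
#' @inheritParams exclude_sectors
#' @param vessel_polygon vessel (EEM) contour.
#' @param pixel_spacing_mm pixel size in mm.
#' @param d_min,d_max reference band limits in mm.
#' @return list with \code{ring_mask}, \code{sector_included},
#'   \code{adaptive_threshold}, \code{histogram} (256 counts over included
#'   reference pixels), \code{n_ring_pixels}, \code{n_included_sectors}.
#' @export
frame_reference <- function(pixels, vessel_polygon, center, pixel_spacing_mm,
                            d_min = 0.01, d_max = 0.21, guidewire = NULL,
                            sector_deg = 2) {
  ring <- build_ring(vessel_polygon, pixel_spacing_mm, dim(pixels),
                     d_min = d_min, d_max = d_max)
  if (!any(ring)) {
    return(list(ring_mask = ring, sector_included = logical(0),
                adaptive_threshold = NA_integer_,
                histogram = integer(256), n_ring_pixels = 0L,
                n_included_sectors = 0L))
  }
  thr <- tryCatch(otsu_threshold(grey_histogram(pixels[ring])),
                  error = function(e) NA_integer_)
  if (is.na(thr)) {
    # single-valued ring: keep everything (no adaptive exclusion possible)
    incl <- exclude_sectors(pixels, ring, center, adaptive_threshold = 0L,
                            guidewire = guidewire, sector_deg = sector_deg)
  } else {
    incl <- exclude_sectors(pixels, ring, center, thr,
                            guidewire = guidewire, sector_deg = sector_deg)
  }
  idx <- which(ring, arr.ind = TRUE)
  deg <- pixel_angles_deg(idx[, 1], idx[, 2], center)
  sector <- pmin(floor(deg / sector_deg), length(incl) - 1L)
  keep <- incl[sector + 1L]
  hist <- grey_histogram(pixels[ring][keep])
  list(ring_mask = ring, sector_included = incl,
       adaptive_threshold = thr, histogram = hist,
       n_ring_pixels = sum(ring), n_included_sectors = sum(incl))
}

#' Pool per-frame adventitial references into the global reference
#'
#' Histograms of the retained reference pixels of all frames are summed and
#' the (lower) median grey level of the pooled distribution becomes the
#' hypo/hyper classification threshold.
#'
#' @param references list of per-frame references from [frame_reference()].
#' @return list with \code{pooled_histogram} (256 counts) and
#'   \code{median_threshold} (smallest level whose cumulative count reaches
#'   half the pooled total).
#' @export
pool_reference <- function(references) {
  pooled <- integer(256)
  for (ref in references) pooled <- pooled + as.integer(ref$histogram)
  n <- sum(pooled)
  if (n == 0L)
    stop("no reference: all frames have empty included-sector histograms; pullback unanalyzable")
  target <- ceiling(n / 2)
  med <- which(cumsum(pooled) >= target)[1L] - 1L
  list(pooled_histogram = pooled, median_threshold = as.integer(med))
}
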