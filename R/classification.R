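#' Tissue class codes
#'
#' Integer codes used in label maps: 0 outside the wall, 1 hypoechogenic,
#' 2 hyperechogenic, 3 upperechogenic, 4 calcified, 5 unknown (acoustic
#' shadow).
#'
#' @format named integer vector.
#' @export
ECHO_CLASSES <- c(outside = 0L, hypo = 1L, hyper = 2L, upper = 3L,
                  calcified = 4L, unknown = 5L)

#' Display palette for label maps
#'
#' Hypo = dark green, hyper = light green, upper = light blue, calcified =
#' white, unknown = dark grey, outside = black.
#' @export
ECHO_PALETTE <- c(outside = "#000000", hypo = "#1b6b2a", hyper = "#8fe08f",
                  upper = "#9fc8ff", calcified = "#ffffff", unknown = "#404040")

#' 8-connected component labeling
#'
#' Labels connected sets of TRUE pixels using 8-neighbourhood by iterative
#' max-propagation; deterministic, labels renumbered 1..k in first-pixel
#' (column-major) order.
#'
#' @param mask logical matrix.
#' @return integer matrix; 0 outside components.
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0, nr, nc)
  lab[mask] <- which(mask)            # seed with linear index
  shift <- function(m, dr, dc) {
    out <- matrix(0, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    new <- lab
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      new <- pmax(new, shift(lab, dr, dc))
    }
    new[!mask] <- 0
    if (identical(new, lab)) break
    lab <- new
  }
  u <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, nr, nc)
  if (length(u)) out[lab > 0] <- match(lab[lab > 0], u)
  out
}

# Per-grid polar coordinates around the catheter center (pixels/degrees).
polar_grid <- function(grid_shape, center) {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  pr <- matrix(seq_len(nr), nr, nc)
  pc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  list(
    radius = sqrt((pr - center[1])^2 + (pc - center[2])^2),
    angle = pixel_angles_deg(as.vector(pr), as.vector(pc), center) |>
      matrix(nr, nc)
  )
}

#' Acoustic shadow test for one highly echogenic component
#'
#' Casts radial rays from the catheter center through every angular position
#' covered by the component and samples the pixels radially beyond the
#' component's outer edge up to \code{shadow_depth_mm} (or the image edge).
#' The component casts a shadow when the mean grey level of that behind
#' region, pooled over rays, is below
#' \code{shadow_fraction * reference_median}.
#'
#' @param pixels integer grey-level matrix.
#' @param component_mask logical mask of one connected component.
#' @param center catheter center \code{c(row, col)}.
#' @param reference_median global adventitial median grey level.
#' @param pixel_spacing_mm pixel size in mm.
#' @param shadow_depth_mm how far behind the component to look (default 0.5).
#' @param shadow_fraction brightness fraction of the reference median below
#'   which the behind region counts as shadow (default 0.25).
#' @param ray_deg angular ray spacing in degrees (default 1).
#' @return logical: TRUE when the component casts an acoustic shadow. A
#'   component with no assessable behind region (touching the image border)
#'   returns FALSE with a warning.
#' @export
detect_shadow <- function(pixels, component_mask, center, reference_median,
                          pixel_spacing_mm, shadow_depth_mm = 0.5,
                          shadow_fraction = 0.25, ray_deg = 1) {
  behind <- behind_region(dim(pixels), component_mask, center,
                          shadow_depth_mm / pixel_spacing_mm, ray_deg)
  if (!length(behind)) {
    warning("component has no assessable behind-region (touches image border); no shadow")
    return(FALSE)
  }
  mean(pixels[behind]) < shadow_fraction * reference_median
}

# Angular cover of a component: per ray bin, the outermost radius of any
# component pixel whose angular footprint touches the bin. A pixel at radius
# r subtends about (1/r) rad, so thin arcs still cover their full span.
component_cover <- function(pol, component_mask, ray_deg) {
  n_bins <- as.integer(round(360 / ray_deg))
  idx <- which(component_mask)
  ang <- pol$angle[idx]; rad <- pol$radius[idx]
  hw <- 0.5 * (180 / pi) / pmax(rad, 0.5)      # half angular width, degrees
  r_out <- rep(NA_real_, n_bins)
  for (p in seq_along(idx)) {
    b0 <- floor((ang[p] - hw[p]) / ray_deg)
    b1 <- floor((ang[p] + hw[p]) / ray_deg)
    bins <- (b0:b1) %% n_bins + 1L
    r_out[bins] <- pmax(r_out[bins], rad[p], na.rm = TRUE)
  }
  r_out
}

# Linear indices of pixels radially behind a component: rays through each
# covered angular bin, from just past the component's outer edge to depth_px.
behind_region <- function(grid_shape, component_mask, center, depth_px,
                          ray_deg = 1) {
  if (!any(component_mask)) return(integer(0))
  pol <- polar_grid(grid_shape, center)
  r_out <- component_cover(pol, component_mask, ray_deg)
  nr <- grid_shape[1]; nc <- grid_shape[2]
  hits <- integer(0)
  for (b in which(!is.na(r_out))) {
    theta <- (b - 0.5) * ray_deg * pi / 180
    radii <- seq(r_out[b] + 1, r_out[b] + depth_px, by = 0.5)
    if (!length(radii)) next
    rr <- round(center[1] - radii * sin(theta))
    cc <- round(center[2] + radii * cos(theta))
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    hits <- c(hits, (cc[ok] - 1L) * nr + rr[ok])
  }
  hits <- unique(hits)
  hits[!component_mask[hits]]
}

#' Classify one frame into the five echogenicity tissue classes
#'
#' Within the total wall, pixels strictly below the global adventitial median
#' are hypoechogenic and pixels at or above it hyperechogenic (the
#' equal-to-median tie goes to hyper so the two classes partition; set
#' \code{tie = "hypo"} to flip). Pixels strictly above the high-intensity
#' threshold form candidate highly echogenic regions, grouped into
#' 8-connected components: a component casting an acoustic shadow is
#' calcified and its shadow pixels (within the wall) are unknown; without a
#' shadow it is upperechogenic.
#'
#' @param pixels integer grey-level matrix.
#' @param masks compartment masks from [build_compartments()].
#' @param thresholds list with \code{median_threshold} and
#'   \code{high_threshold}.
#' @param center catheter center \code{c(row, col)}.
#' @param pixel_spacing_mm pixel size in mm.
#' @param shadow_depth_mm,shadow_fraction,ray_deg shadow detector settings,
#'   see [detect_shadow()].
#' @param tie class for grey exactly equal to the median.
#' @return integer label matrix with codes from [ECHO_CLASSES].
#' @export
classify_frame <- function(pixels, masks, thresholds, center,
                           pixel_spacing_mm, shadow_depth_mm = 0.5,
                           shadow_fraction = 0.25, ray_deg = 1,
                           tie = c("hyper", "hypo")) {
  tie <- match.arg(tie)
  med <- thresholds$median_threshold
  high <- thresholds$high_threshold
  wall <- masks$total_wall
  lab <- matrix(ECHO_CLASSES[["outside"]], nrow(pixels), ncol(pixels))
  g <- pixels[wall]
  hypo <- if (tie == "hyper") g < med else g <= med
  lab[wall] <- ifelse(hypo, ECHO_CLASSES[["hypo"]], ECHO_CLASSES[["hyper"]])
  cand <- wall & pixels > high
  if (any(cand)) {
    comp <- label_components(cand)
    depth_px <- shadow_depth_mm / pixel_spacing_mm
    for (k in seq_len(max(comp))) {
      cm <- comp == k
      shadowed <- detect_shadow(pixels, cm, center, med, pixel_spacing_mm,
                                shadow_depth_mm = shadow_depth_mm,
                                shadow_fraction = shadow_fraction,
                                ray_deg = ray_deg)
      if (shadowed) {
        lab[cm] <- ECHO_CLASSES[["calcified"]]
        sh <- shadow_wall_pixels(dim(pixels), cm, center, wall, cand, ray_deg)
        lab[sh] <- ECHO_CLASSES[["unknown"]]
      } else {
        lab[cm] <- ECHO_CLASSES[["upper"]]
      }
    }
  }
  lab
}

# Wall pixels radially behind a calcified component (its full shadow, not
# depth-limited), excluding bright-candidate pixels.
shadow_wall_pixels <- function(grid_shape, component_mask, center, wall_mask,
                               cand_mask, ray_deg = 1) {
  pol <- polar_grid(grid_shape, center)
  r_out <- component_cover(pol, component_mask, ray_deg)
  all_bin <- pmin(floor(pol$angle / ray_deg), length(r_out) - 1L) + 1L
  sel <- !is.na(r_out[all_bin]) & pol$radius > r_out[all_bin]
  sel <- matrix(sel, grid_shape[1], grid_shape[2])
  which(sel & wall_mask & !cand_mask & !component_mask)
}
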