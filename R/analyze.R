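#' Analysis configuration
#'
#' All method constants are defaults here, not hard-coded: the adventitial
#' reference band (0.01-0.21 mm outside the EEM), the 2-degree sector width,
#' the acoustic-shadow look-behind depth (0.5 mm) and brightness fraction
#' (0.25), the pooling mode for the per-frame high-intensity thresholds, the
#' equal-to-median tie class and the clamp of a high threshold that falls
#' below the reference median.
#'
#' @param ring_dmin_mm,ring_dmax_mm reference band limits outside the vessel
#'   contour (mm).
#' @param sector_deg angular sector width for reference selection (degrees).
#' @param shadow_depth_mm,shadow_fraction,ray_deg shadow detector settings.
#' @param high_mode \code{"median"} of per-frame iterated-Otsu thresholds or
#'   \code{"pooled"} histogram mode.
#' @param tie class receiving grey levels exactly equal to the median.
#' @param clamp_high clamp \code{high < median} up to the median.
#' @return an \code{echo_config} list.
#' @export
echo_config <- function(ring_dmin_mm = 0.01, ring_dmax_mm = 0.21,
                        sector_deg = 2, shadow_depth_mm = 0.5,
                        shadow_fraction = 0.25, ray_deg = 1,
                        high_mode = c("median", "pooled"),
                        tie = c("hyper", "hypo"), clamp_high = TRUE) {
  high_mode <- match.arg(high_mode)
  tie <- match.arg(tie)
  structure(as.list(environment()), class = "echo_config")
}

#' Differential echogenicity analysis of an IVUS pullback
#'
#' The main entry point. For each analyzed frame the adventitial reference
#' ring just outside the vessel (EEM) contour is built, low-signal sectors
#' are dropped with Otsu's adaptive threshold, and the retained grey-level
#' histograms are pooled across frames; the pooled median splits hypo- from
#' hyperechogenic wall tissue. A high-intensity threshold from three-stage
#' iterated Otsu separates highly echogenic structures, which an acoustic
#' shadow detector splits into upperechogenic versus calcified plus unknown
#' (shadow). Class areas are integrated into compartment volumes.
#'
#' @param frames list of integer grey-level matrices (0-255, square).
#' @param contours per-frame list of \code{lumen}, \code{scaffold},
#'   \code{vessel} polygons (1-based \code{(row, col)} pixel coordinates), or
#'   a single such list reused for all frames.
#' @param pixel_spacing_mm,frame_spacing_mm pixel size and inter-frame
#'   spacing (mm).
#' @param center catheter center \code{c(row, col)}; default frame center.
#' @param guidewire optional list of angular intervals
#'   \code{c(start_deg, end_deg)} masked out of the reference.
#' @param config an [echo_config()].
#' @return object of class \code{echo_pullback} with elements
#'   \code{thresholds}, \code{global_reference}, \code{per_frame} (reference
#'   diagnostics), \code{labels} (per-frame label matrices), \code{masks},
#'   \code{volumes} (an \code{echo_volumes} table), \code{config}.
#' @examples
#' ph <- phantom_pullback(phantom_config(n_frames = 2, seed = 7))
#' fit <- analyze_pullback(ph$frames, ph$contours,
#'                         ph$meta$pixel_spacing_mm, ph$meta$frame_spacing_mm)
#' fit
#' @export
analyze_pullback <- function(frames, contours, pixel_spacing_mm,
                             frame_spacing_mm, center = NULL,
                             guidewire = NULL, config = echo_config()) {
  stopifnot(length(frames) >= 1L)
  if (!is.null(contours$lumen)) contours <- rep(list(contours), length(frames))
  if (length(contours) != length(frames))
    stop("need one contour set per frame (or a single shared set)")
  shp <- dim(frames[[1L]])
  if (is.null(center)) center <- (shp + 1) / 2
  # geometry cache: identical contour sets share masks and rings
  sig <- vapply(contours, function(ct)
    paste(format(c(ct$lumen, ct$scaffold, ct$vessel), digits = 12),
          collapse = ","), character(1))
  uniq <- !duplicated(sig)
  geo_cache <- list()
  for (i in which(uniq)) {
    m <- build_compartments(contours[[i]], shp)
    ring <- build_ring(contours[[i]]$vessel, pixel_spacing_mm, shp,
                       d_min = config$ring_dmin_mm, d_max = config$ring_dmax_mm)
    geo_cache[[sig[i]]] <- list(masks = m, ring = ring)
  }
  masks <- lapply(sig, function(s) geo_cache[[s]]$masks)

  refs <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    ring <- geo_cache[[sig[i]]]$ring
    px <- frames[[i]]
    if (!any(ring)) {
      refs[[i]] <- list(histogram = integer(256), adaptive_threshold = NA_integer_,
                        n_ring_pixels = 0L, n_included_sectors = 0L,
                        sector_included = logical(0), ring_mask = ring)
      next
    }
    thr <- tryCatch(otsu_threshold(grey_histogram(px[ring])),
                    error = function(e) NA_integer_)
    incl <- exclude_sectors(px, ring, center,
                            adaptive_threshold = if (is.na(thr)) 0L else thr,
                            guidewire = guidewire,
                            sector_deg = config$sector_deg)
    idx <- which(ring, arr.ind = TRUE)
    sector <- pmin(floor(pixel_angles_deg(idx[, 1], idx[, 2], center) /
                           config$sector_deg), length(incl) - 1L)
    hist <- grey_histogram(px[ring][incl[sector + 1L]])
    refs[[i]] <- list(histogram = hist, adaptive_threshold = thr,
                      n_ring_pixels = sum(ring),
                      n_included_sectors = sum(incl),
                      sector_included = incl, ring_mask = ring)
  }
  global_ref <- pool_reference(refs)
  ht <- high_threshold(frames, mode = config$high_mode,
                       median_threshold = global_ref$median_threshold,
                       clamp = config$clamp_high)
  thresholds <- list(median_threshold = global_ref$median_threshold,
                     high_threshold = ht$high_threshold,
                     per_frame_high = ht$per_frame,
                     high_mode = config$high_mode)
  labels <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    labels[[i]] <- classify_frame(frames[[i]], masks[[i]], thresholds, center,
                                  pixel_spacing_mm,
                                  shadow_depth_mm = config$shadow_depth_mm,
                                  shadow_fraction = config$shadow_fraction,
                                  ray_deg = config$ray_deg,
                                  tie = config$tie)
  }
  volumes <- integrate_volumes(labels, masks, pixel_spacing_mm,
                               frame_spacing_mm)
  structure(list(
    thresholds = thresholds,
    global_reference = global_ref,
    per_frame = data.frame(
      frame_index = seq_along(frames) - 1L,
      n_ring_pixels = vapply(refs, `[[`, integer(1), "n_ring_pixels"),
      n_included_sectors = vapply(refs, `[[`, integer(1), "n_included_sectors"),
      adaptive_threshold = vapply(refs, `[[`, integer(1), "adaptive_threshold"),
      high_threshold = ht$per_frame
    ),
    references = refs,
    labels = labels,
    masks = masks,
    volumes = volumes,
    center = center,
    pixel_spacing_mm = pixel_spacing_mm,
    frame_spacing_mm = frame_spacing_mm,
    config = config,
    call = match.call()
  ), class = "echo_pullback")
}

#' @export
print.echo_pullback <- function(x, ...) {
  cat("Differential echogenicity analysis\n")
  cat(sprintf("  frames analyzed      : %d (%.1f mm at %.2f mm spacing)\n",
              length(x$labels), attr(x$volumes, "scaffold_length_mm"),
              x$frame_spacing_mm))
  cat(sprintf("  reference median     : %d (pooled adventitia, %d px)\n",
              x$thresholds$median_threshold,
              sum(x$global_reference$pooled_histogram)))
  cat(sprintf("  high threshold       : %d (%s of per-frame iterated Otsu)\n",
              x$thresholds$high_threshold, x$thresholds$high_mode))
  g <- attr(x$volumes, "geometry")
  cat(sprintf("  volumes (mm^3)       : vessel %.1f, lumen %.1f, scaffold %.1f, neointima %.1f\n",
              g["vessel"], g["lumen"], g["scaffold"], g["neointima"]))
  tw <- x$volumes[x$volumes$compartment == "total", ]
  cat("  total wall composition:\n")
  for (i in seq_len(nrow(tw)))
    cat(sprintf("    %-10s %7.2f mm^3  %5.1f %%\n", tw$class[i],
                tw$volume_mm3[i], tw$percent[i]))
  invisible(x)
}

#' @export
summary.echo_pullback <- function(object, ...) {
  structure(list(volumes = object$volumes,
                 thresholds = object$thresholds,
                 per_frame = object$per_frame), class = "summary.echo_pullback")
}

#' @export
print.summary.echo_pullback <- function(x, ...) {
  cat("Thresholds: median =", x$thresholds$median_threshold,
      "| high =", x$thresholds$high_threshold, "\n\n")
  print.data.frame(as.data.frame(x$volumes), row.names = FALSE, digits = 4)
  cat("\nPer-frame reference diagnostics:\n")
  print.data.frame(x$per_frame, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.echo_pullback <- function(x, ...) {
  as.data.frame(x$volumes)
}

#' Plot a classified frame
#'
#' Shows the tissue label map of one analyzed frame with the standard
#' palette (hypo = dark green, hyper = light green, upper = light blue,
#' calcified = white, unknown = dark grey).
#'
#' @param x an \code{echo_pullback}.
#' @param frame 1-based frame number.
#' @param ... passed to [graphics::image()].
#' @export
plot.echo_pullback <- function(x, frame = 1L, ...) {
  lab <- x$labels[[frame]]
  graphics::image(t(lab[nrow(lab):1, ]), col = ECHO_PALETTE,
                  breaks = seq(-0.5, 5.5, by = 1), axes = FALSE, asp = 1,
                  main = sprintf("frame %d tissue classes", frame), ...)
  graphics::legend("topright", legend = names(ECHO_CLASSES),
                   fill = ECHO_PALETTE, cex = 0.7, bg = "white")
  invisible(x)
}

#' Analyze a cohort of pullbacks and join molecular weights
#'
#' Runs [analyze_pullback()] on every pullback of a [degradation_cohort()]
#' (or any named list of phantom-dialect pullbacks with a matching table)
#' and returns the one-row-per-scaffold volume summary joined with the
#' molecular weights, ready for [pearson_r()] / [linreg()] /
#' [ward_cluster()].
#'
#' @param cohort list with \code{pullbacks} and \code{table} as returned by
#'   [degradation_cohort()].
#' @param config an [echo_config()].
#' @return data frame: one row per scaffold, wide volume columns plus
#'   \code{timepoint_months} and \code{mw_kDa}.
#' @export
analyze_cohort <- function(cohort, config = echo_config()) {
  rows <- vector("list", length(cohort$pullbacks))
  for (i in seq_along(cohort$pullbacks)) {
    ph <- cohort$pullbacks[[i]]
    fit <- suppressWarnings(
      analyze_pullback(ph$frames, ph$contours, ph$meta$pixel_spacing_mm,
                       ph$meta$frame_spacing_mm, config = config))
    rows[[i]] <- volumes_row(fit, names(cohort$pullbacks)[i])
  }
  merge(do.call(rbind, rows), cohort$table, by = "scaffold_id")
}
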