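#' Integrate per-frame class areas into compartment volumes
#'
#' Volumes use the rectangular rule standard in IVUS volumetrics: each
#' analyzed frame (one per 0.5 mm of pullback by default) contributes its
#' class area times the inter-frame spacing. Percentages are class volume
#' over compartment volume. Geometric volumes (lumen, scaffold, vessel,
#' neointima = vessel - lumen) are integrated the same way.
#'
#' @param labels list of per-frame label matrices from [classify_frame()].
#' @param masks list of per-frame compartment masks from
#'   [build_compartments()].
#' @param pixel_spacing_mm pixel size in mm.
#' @param frame_spacing_mm longitudinal spacing between analyzed frames (mm).
#' @return object of class \code{echo_volumes}: a data frame with columns
#'   \code{compartment}, \code{class}, \code{volume_mm3}, \code{percent};
#'   attributes \code{geometry} (named geometric volumes in mm^3),
#'   \code{scaffold_length_mm} and \code{n_frames}.
#' @export
integrate_volumes <- function(labels, masks, pixel_spacing_mm,
                              frame_spacing_mm) {
  stopifnot(length(labels) >= 1L, length(labels) == length(masks),
            pixel_spacing_mm > 0, frame_spacing_mm > 0)
  classes <- setdiff(names(ECHO_CLASSES), "outside")
  comps <- c("lumen_scaffold", "scaffold_vessel", "total")
  vol <- matrix(0, nrow = length(comps), ncol = length(classes),
                dimnames = list(comps, classes))
  geom <- c(lumen = 0, scaffold = 0, vessel = 0, neointima = 0)
  px_area <- pixel_spacing_mm^2
  for (i in seq_along(labels)) {
    lab <- labels[[i]]; m <- masks[[i]]
    cmask <- list(lumen_scaffold = m$lumen_scaffold,
                  scaffold_vessel = m$scaffold_vessel,
                  total = m$total_wall)
    for (cp in comps) {
      inlab <- lab[cmask[[cp]]]
      cnt <- tabulate(inlab, nbins = 5L)     # codes 1..5
      vol[cp, ] <- vol[cp, ] + cnt[ECHO_CLASSES[classes]] * px_area * frame_spacing_mm
    }
    geom["lumen"] <- geom["lumen"] + sum(m$lumen) * px_area * frame_spacing_mm
    geom["scaffold"] <- geom["scaffold"] + sum(m$scaffold) * px_area * frame_spacing_mm
    geom["vessel"] <- geom["vessel"] + sum(m$vessel) * px_area * frame_spacing_mm
  }
  geom["neointima"] <- geom["vessel"] - geom["lumen"]
  comp_tot <- rowSums(vol)
  tab <- data.frame(
    compartment = rep(comps, each = length(classes)),
    class = rep(classes, times = length(comps)),
    volume_mm3 = as.vector(t(vol)),
    stringsAsFactors = FALSE
  )
  denom <- rep(comp_tot, each = length(classes))
  tab$percent <- ifelse(denom > 0, 100 * tab$volume_mm3 / denom, NA_real_)
  if (any(comp_tot == 0))
    warning("zero-area compartment(s): ",
            paste(comps[comp_tot == 0], collapse = ", "),
            "; percentages reported as NA")
  structure(tab,
            geometry = geom,
            scaffold_length_mm = length(labels) * frame_spacing_mm,
            n_frames = length(labels),
            class = c("echo_volumes", "data.frame"))
}

#' Normalize pullback volumes by the cohort mean length
#'
#' Scaffolds of different lengths are put on an equal footing by scaling
#' every volume by \code{mean_length_mm / pullback length}; percentages are
#' ratios and stay unchanged.
#'
#' @param volumes an \code{echo_volumes} table.
#' @param mean_length_mm cohort mean scaffold length in mm.
#' @return the table with \code{volume_mm3} (and geometric volumes) scaled;
#'   attribute \code{normalized_to_mm} records the target length.
#' @export
normalize_by_mean_length <- function(volumes, mean_length_mm) {
  len <- attr(volumes, "scaffold_length_mm")
  if (is.null(len) || !is.finite(len) || len <= 0)
    stop("pullback length must be positive for length normalization")
  stopifnot(mean_length_mm > 0)
  f <- mean_length_mm / len
  volumes$volume_mm3 <- volumes$volume_mm3 * f
  attr(volumes, "geometry") <- attr(volumes, "geometry") * f
  attr(volumes, "normalized_to_mm") <- mean_length_mm
  volumes
}
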