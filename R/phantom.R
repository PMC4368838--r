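#' Configuration for the synthetic IVUS phantom
#'
#' Builds the parameter list consumed by [phantom_pullback()]. The phantom
#' emulates a non-atherosclerotic scaffolded coronary cross-section: speckled
#' concentric tissue layers (blood, neointima, media), a bright adventitial
#' band outside the vessel contour, hyperechogenic strut blocks between the
#' scaffold and vessel contours whose brightness scales with residual
#' molecular weight, an optional low-intensity wedge overlapping the
#' adventitia (pericardium/side-branch analogue) and an optional calcified
#' arc casting a radial acoustic shadow.
#'
#' @param grid_size frame side length in pixels (square, >= 64).
#' @param pixel_spacing_mm isotropic pixel size (mm).
#' @param frame_spacing_mm longitudinal spacing of analyzed frames (mm).
#' @param n_frames frames per pullback.
#' @param lumen_r,scaffold_r,vessel_r layer radii in mm.
#' @param wobble_amp_mm,wobble_lobes radial perturbation of the contours
#'   (sinusoidal, shared by all layers; phase drawn per pullback).
#' @param mean_blood,mean_neointima,mean_media,mean_adventitia,mean_background
#'   layer mean grey levels (0-255).
#' @param adventitia_width_mm rendered thickness of the bright adventitial
#'   band.
#' @param speckle_amp multiplicative Rayleigh speckle amplitude in [0, 1];
#'   0 = noiseless, 1 = fully developed speckle.
#' @param n_struts,strut_width_deg,strut_thickness_mm,strut_peak strut block
#'   geometry and full-brightness grey level.
#' @param mw,mw_ref residual molecular weight (kDa) and the reference weight
#'   at which struts reach full brightness.
#' @param brightness_map \code{"linear"} (0 at Mw = 0 to 1 at \code{mw_ref})
#'   or \code{"sigmoid"} mapping from Mw to the strut brightness fraction.
#' @param wedge \code{NULL} or \code{list(start_deg, span_deg, grey)}:
#'   low-intensity wedge covering the adventitia over that angular span.
#' @param calcification \code{NULL} or \code{list(start_deg, span_deg, grey,
#'   shadow_grey)}: bright arc in the scaffold-vessel compartment with a
#'   radial shadow behind it.
#' @param seed RNG seed; fixed seed gives bit-identical frames.
#' @return a \code{phantom_config} list.
#' @export
phantom_config <- function(grid_size = 128L,
                           pixel_spacing_mm = 0.03,
                           frame_spacing_mm = 0.5,
                           n_frames = 7L,
                           lumen_r = 1.0, scaffold_r = 1.25, vessel_r = 1.55,
                           wobble_amp_mm = 0.04, wobble_lobes = 3L,
                           mean_blood = 15, mean_neointima = 45,
                           mean_media = 45, mean_adventitia = 180,
                           mean_background = 25,
                           adventitia_width_mm = 0.45,
                           speckle_amp = 0.35,
                           n_struts = 8L, strut_width_deg = 14,
                           strut_thickness_mm = 0.15, strut_peak = 250,
                           mw = 92.9, mw_ref = 92.9,
                           brightness_map = c("linear", "sigmoid"),
                           wedge = NULL, calcification = NULL,
                           seed = 1L) {
  brightness_map <- match.arg(brightness_map)
  if (grid_size < 64L) stop("grid_size must be >= 64")
  if (!(lumen_r < scaffold_r && scaffold_r < vessel_r))
    stop("config error: layer radii must satisfy lumen < scaffold < vessel")
  half_fov <- (grid_size / 2 - 1) * pixel_spacing_mm
  if (vessel_r + 0.25 > half_fov)
    stop("config error: vessel plus reference band does not fit the grid")
  means <- c(mean_blood, mean_neointima, mean_media, mean_adventitia,
             mean_background, strut_peak)
  if (any(means < 0 | means > 255)) stop("layer means must lie in [0, 255]")
  rm(half_fov, means)
  structure(as.list(environment()), class = "phantom_config")
}

# Strut brightness fraction f(Mw), monotone increasing, f(0)=0, f(mw_ref)=1.
mw_brightness <- function(mw, mw_ref, map = "linear") {
  x <- pmax(0, pmin(1, mw / mw_ref))
  if (map == "linear") x
  else (1 / (1 + exp(-8 * (x - 0.5))) - 1 / (1 + exp(4))) /
    (1 / (1 + exp(-4)) - 1 / (1 + exp(4)))
}

#' Generate a synthetic IVUS pullback with ground truth
#'
#' Renders \code{n_frames} cross-sections from a [phantom_config()]: a
#' layered mean-intensity scene modulated by multiplicative Rayleigh speckle
#' (blended toward its mean by \code{speckle_amp}, emulating the smoothed
#' texture of scan-converted B-mode exports), together with the matching
#' lumen/scaffold/vessel contours and per-pixel ground-truth labels.
#' Truth labels use the nominal contrast: wall background is hypoechogenic,
#' strut blocks upperechogenic, the calcified arc calcified and its shadow
#' (within the wall) unknown.
#'
#' @param config a [phantom_config()] list.
#' @return object of class \code{echo_phantom}: list with \code{frames}
#'   (integer matrices), \code{contours} (per frame: lumen/scaffold/vessel
#'   polygons), \code{truth} (per-frame label matrices and per-class pixel
#'   counts), \code{meta} (spacing and center) and \code{mw}.
#' @export
phantom_pullback <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  cf <- config
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(cf$seed)
  n <- cf$grid_size
  center <- c((n + 1) / 2, (n + 1) / 2)
  sp <- cf$pixel_spacing_mm
  pol <- polar_grid(c(n, n), center)
  rad_mm <- pol$radius * sp
  ang <- pol$angle * pi / 180
  phase <- stats::runif(1, 0, 2 * pi)
  r_of <- function(r0, theta) r0 + cf$wobble_amp_mm * sin(cf$wobble_lobes * theta + phase)
  r_lum <- r_of(cf$lumen_r, ang)
  r_sca <- r_of(cf$scaffold_r, ang)
  r_ves <- r_of(cf$vessel_r, ang)

  mean_map0 <- matrix(cf$mean_background, n, n)
  mean_map0[rad_mm < r_ves + cf$adventitia_width_mm] <- cf$mean_adventitia
  mean_map0[rad_mm < r_ves] <- cf$mean_media
  mean_map0[rad_mm < r_sca] <- cf$mean_neointima
  mean_map0[rad_mm < r_lum] <- cf$mean_blood

  deg <- pol$angle
  strut_mask <- matrix(FALSE, n, n)
  if (cf$n_struts > 0) {
    centers <- (360 * (seq_len(cf$n_struts) - 1) / cf$n_struts + 360 / (2 * cf$n_struts)) %% 360
    in_band <- rad_mm >= r_sca & rad_mm < pmin(r_sca + cf$strut_thickness_mm, r_ves)
    for (a0 in centers) {
      dd <- abs((deg - a0 + 180) %% 360 - 180)
      strut_mask <- strut_mask | (in_band & dd < cf$strut_width_deg / 2)
    }
  }
  strut_grey <- cf$strut_peak * mw_brightness(cf$mw, cf$mw_ref, cf$brightness_map)

  wedge_mask <- matrix(FALSE, n, n)
  if (!is.null(cf$wedge)) {
    w <- cf$wedge
    wedge_mask <- angle_in_interval(as.vector(deg), w$start_deg,
                                    w$start_deg + w$span_deg) &
      as.vector(rad_mm >= r_ves)
    wedge_mask <- matrix(wedge_mask, n, n)
  }
  calc_mask <- shadow_mask <- matrix(FALSE, n, n)
  if (!is.null(cf$calcification)) {
    cc <- cf$calcification
    span <- angle_in_interval(as.vector(deg), cc$start_deg,
                              cc$start_deg + cc$span_deg)
    span <- matrix(span, n, n)
    calc_inner <- r_sca + 0.03
    calc_outer <- calc_inner + 0.12
    calc_mask <- span & rad_mm >= calc_inner & rad_mm < calc_outer
    shadow_mask <- span & rad_mm >= calc_outer
  }

  # per-frame truth template (contours fixed within a pullback)
  contours1 <- phantom_contours(cf, center, phase)
  masks <- build_compartments(contours1, c(n, n))
  wall <- masks$total_wall
  truth1 <- matrix(ECHO_CLASSES[["outside"]], n, n)
  truth1[wall] <- ECHO_CLASSES[["hypo"]]
  truth1[strut_mask & wall] <- ECHO_CLASSES[["upper"]]
  truth1[calc_mask & wall] <- ECHO_CLASSES[["calcified"]]
  truth1[shadow_mask & wall] <- ECHO_CLASSES[["unknown"]]

  e_ray <- sqrt(pi / 2)
  frames <- vector("list", cf$n_frames)
  for (f in seq_len(cf$n_frames)) {
    mm <- mean_map0
    mm[strut_mask] <- strut_grey
    if (any(wedge_mask)) mm[wedge_mask] <- cf$wedge$grey
    if (any(calc_mask)) mm[calc_mask] <- cf$calcification$grey
    if (any(shadow_mask)) mm[shadow_mask] <- cf$calcification$shadow_grey
    ray <- matrix(sqrt(-2 * log(stats::runif(n * n))), n, n)
    px <- mm * (1 - cf$speckle_amp + cf$speckle_amp * ray / e_ray)
    frames[[f]] <- matrix(as.integer(pmax(0, pmin(255, round(px)))), n, n)
  }
  counts <- tabulate(truth1 + 1L, nbins = 6L)
  names(counts) <- names(ECHO_CLASSES)
  structure(list(
    frames = frames,
    contours = rep(list(contours1), cf$n_frames),
    truth = list(labels = rep(list(truth1), cf$n_frames),
                 class_pixels = counts,
                 strut_mask = strut_mask, calc_mask = calc_mask,
                 shadow_mask = shadow_mask, wall_mask = wall),
    meta = list(pixel_spacing_mm = sp, frame_spacing_mm = cf$frame_spacing_mm,
                center = center, grid_size = n, n_frames = cf$n_frames),
    mw = cf$mw,
    config = cf
  ), class = "echo_phantom")
}

# Polygonal contours (90 vertices) matching the rendered layer radii.
phantom_contours <- function(cf, center, phase) {
  theta <- seq(0, 2 * pi, length.out = 91L)[-91L]
  mk <- function(r0) {
    r <- (r0 + cf$wobble_amp_mm * sin(cf$wobble_lobes * theta + phase)) /
      cf$pixel_spacing_mm
    cbind(row = center[1] - r * sin(theta), col = center[2] + r * cos(theta))
  }
  list(lumen = mk(cf$lumen_r), scaffold = mk(cf$scaffold_r),
       vessel = mk(cf$vessel_r))
}

#' Generate a degradation cohort of phantom pullbacks
#'
#' One pullback per scaffold, with strut brightness tied to the scaffold's
#' residual molecular weight via the configured brightness map. The default
#' schedule follows the GPC means of the porcine Absorb series (1 to 42
#' months): 92.9, 84.2, 76, 47.1, 26.2, 7.9, 4.7, 3.9 and 0 kDa.
#'
#' @param n_per_timepoint scaffolds per timepoint.
#' @param mw_schedule monotone non-increasing molecular weights (kDa), one
#'   per timepoint.
#' @param timepoint_months timepoint labels, same length as the schedule.
#' @param seed master seed; per-scaffold seeds are derived from it.
#' @param ... overrides passed to [phantom_config()].
#' @return list with \code{pullbacks} (list of \code{echo_phantom}) and
#'   \code{table} (data frame: scaffold_id, timepoint_months, mw_kDa, seed).
#' @export
degradation_cohort <- function(n_per_timepoint = 3L,
                               mw_schedule = c(92.9, 84.2, 76, 47.1, 26.2,
                                               7.9, 4.7, 3.9, 0),
                               timepoint_months = c(1, 3, 6, 12, 18, 24, 30,
                                                    36, 42),
                               seed = 1L, ...) {
  stopifnot(length(mw_schedule) == length(timepoint_months))
  if (any(diff(mw_schedule) > 0))
    stop("mw_schedule must be monotone non-increasing")
  n_t <- length(mw_schedule)
  ids <- character(0); rows <- list(); pullbacks <- list()
  k <- 0L
  for (t in seq_len(n_t)) for (s in seq_len(n_per_timepoint)) {
    k <- k + 1L
    sid <- sprintf("scaffold_%02d_%02d", t, s)
    sseed <- (seed * 131L + t * 17L + s) %% .Machine$integer.max
    cfg <- phantom_config(mw = mw_schedule[t], seed = sseed, ...)
    pullbacks[[k]] <- phantom_pullback(cfg)
    rows[[k]] <- data.frame(scaffold_id = sid,
                            timepoint_months = timepoint_months[t],
                            mw_kDa = mw_schedule[t], seed = sseed,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  names(pullbacks) <- tab$scaffold_id
  list(pullbacks = pullbacks, table = tab)
}
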