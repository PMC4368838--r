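#' Read / write pullback contour tables
#'
#' Contour CSV dialect: columns \code{frame_index} (0-based),
#' \code{contour_type} in \code{lumen|scaffold|vessel}, \code{vertex_order},
#' \code{row}, \code{col} (0-based pixel coordinates, may be fractional).
#' Internally the package uses 1-based matrix coordinates; conversion happens
#' here.
#'
#' @param path CSV file path.
#' @return list (one element per frame, ordered by frame_index) of lists with
#'   \code{lumen}, \code{scaffold}, \code{vessel} polygon matrices.
#' @export
read_contours <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_index", "contour_type", "vertex_order", "row", "col")
  if (!all(need %in% names(df)))
    stop("contour CSV must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (fi in sort(unique(df$frame_index))) {
    sub <- df[df$frame_index == fi, ]
    ct <- list()
    for (ty in c("lumen", "scaffold", "vessel")) {
      s <- sub[sub$contour_type == ty, ]
      if (!nrow(s)) stop("frame ", fi, " is missing a ", ty, " contour")
      s <- s[order(s$vertex_order), ]
      ct[[ty]] <- cbind(row = s$row + 1, col = s$col + 1)
    }
    out[[length(out) + 1L]] <- ct
    names(out)[length(out)] <- as.character(fi)
  }
  out
}

#' @rdname read_contours
#' @param contours per-frame contour list (internal 1-based coordinates).
#' @export
write_contours <- function(contours, path) {
  rows <- list()
  for (i in seq_along(contours)) {
    for (ty in c("lumen", "scaffold", "vessel")) {
      p <- contours[[i]][[ty]]
      rows[[length(rows) + 1L]] <- data.frame(
        frame_index = i - 1L, contour_type = ty,
        vertex_order = seq_len(nrow(p)) - 1L,
        row = p[, 1] - 1, col = p[, 2] - 1)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a pullback dataset to disk
#'
#' Emits the dialect the analyzer consumes: 8-bit grey frames (zero-padded
#' PNGs, or one multi-page TIFF), \code{contours.csv} and a \code{meta.json}
#' sidecar (pixel_spacing_mm, frame_spacing_mm, 0-based center, n_frames).
#' For phantoms the ground-truth label maps go to \code{truth/} as indexed
#' PNGs.
#'
#' @param x an \code{echo_phantom}, or a list with \code{frames},
#'   \code{contours}, \code{meta}.
#' @param dir output directory (created).
#' @param format \code{"png"} or \code{"tiff"}.
#' @param truth also write ground-truth label maps when present.
#' @return \code{dir}, invisibly.
#' @export
write_pullback <- function(x, dir, format = c("png", "tiff"), truth = TRUE) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frames <- x$frames
  if (format == "png") {
    for (i in seq_along(frames))
      png::writePNG(frames[[i]] / 255,
                    file.path(dir, sprintf("frame_%04d.png", i - 1L)))
  } else {
    tiff::writeTIFF(lapply(frames, function(f) f / 255),
                    file.path(dir, "frames.tiff"), bits.per.sample = 8L)
  }
  write_contours(x$contours, file.path(dir, "contours.csv"))
  meta <- list(pixel_spacing_mm = x$meta$pixel_spacing_mm,
               frame_spacing_mm = x$meta$frame_spacing_mm,
               center = x$meta$center - 1,
               n_frames = length(frames),
               grid_size = nrow(frames[[1L]]))
  if (!is.null(x$mw)) meta$mw_kDa <- x$mw
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (truth && !is.null(x$truth)) {
    tdir <- file.path(dir, "truth")
    dir.create(tdir, showWarnings = FALSE)
    for (i in seq_along(x$truth$labels))
      png::writePNG(x$truth$labels[[i]] / 255,
                    file.path(tdir, sprintf("truth_%04d.png", i - 1L)))
  }
  invisible(dir)
}

#' Read a pullback dataset from disk
#'
#' Accepts a directory holding \code{frame_*.png} files or a
#' \code{frames.tiff} multi-page stack, plus \code{contours.csv} and
#' \code{meta.json} as written by [write_pullback()].
#'
#' @param dir dataset directory.
#' @return list with \code{frames}, \code{contours}, \code{meta} (center
#'   converted to internal 1-based coordinates).
#' @export
read_pullback <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("missing meta.json in ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  tif <- file.path(dir, "frames.tiff")
  if (file.exists(tif)) {
    pages <- tiff::readTIFF(tif, all = TRUE)
    frames <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1L]
      matrix(as.integer(round(p * 255)), nrow(p), ncol(p))
    })
  } else {
    fl <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                          full.names = TRUE))
    if (!length(fl)) stop("no frames found in ", dir)
    frames <- lapply(fl, function(f) {
      p <- png::readPNG(f)
      if (length(dim(p)) == 3L) p <- p[, , 1L]
      matrix(as.integer(round(p * 255)), nrow(p), ncol(p))
    })
  }
  contours <- read_contours(file.path(dir, "contours.csv"))
  meta$center <- unlist(meta$center) + 1
  list(frames = frames, contours = contours, meta = meta)
}

#' Write a tissue label map as a paletted PNG
#'
#' @param labels integer label matrix (codes from [ECHO_CLASSES]).
#' @param path output PNG path.
#' @export
write_label_png <- function(labels, path) {
  cols <- grDevices::col2rgb(ECHO_PALETTE) / 255
  arr <- array(0, c(nrow(labels), ncol(labels), 3L))
  for (ch in 1:3)
    arr[, , ch] <- matrix(cols[ch, labels + 1L], nrow(labels), ncol(labels))
  png::writePNG(arr, path)
  invisible(path)
}

#' One-row wide volume summary of an analyzed pullback
#'
#' Flattens an \code{echo_volumes} table into the Table-1-style single row
#' used by the cohort CSV: per compartment and class a \code{*_mm3} and
#' \code{*_pct} column, hyper+upper composites, geometric volumes and
#' scaffold length.
#'
#' @param fit an \code{echo_pullback}.
#' @param scaffold_id identifier for the row.
#' @return one-row data frame.
#' @export
volumes_row <- function(fit, scaffold_id = "pullback") {
  v <- fit$volumes
  out <- data.frame(scaffold_id = scaffold_id, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(v))) {
    key <- paste0(v$compartment[i], "_", v$class[i])
    out[[paste0(key, "_mm3")]] <- v$volume_mm3[i]
    out[[paste0(key, "_pct")]] <- v$percent[i]
  }
  for (cp in unique(v$compartment)) {
    hv <- sum(v$volume_mm3[v$compartment == cp & v$class %in% c("hyper", "upper")])
    out[[paste0(cp, "_hyperupper_mm3")]] <- hv
  }
  g <- attr(v, "geometry")
  for (nm in names(g)) out[[paste0(nm, "_mm3")]] <- unname(g[nm])
  out$scaffold_length_mm <- attr(v, "scaffold_length_mm")
  out
}

#' Write the full analysis result bundle
#'
#' Per-frame label PNGs, reference diagnostics CSV, the pullback volume CSVs
#' (long and one-row wide), a thresholds/global-reference JSON and the run
#' configuration for provenance.
#'
#' @param fit an \code{echo_pullback}.
#' @param dir output directory (created).
#' @param scaffold_id row identifier in the wide CSV.
#' @return \code{dir}, invisibly.
#' @export
write_analysis <- function(fit, dir, scaffold_id = "pullback") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(fit$labels))
    write_label_png(fit$labels[[i]],
                    file.path(dir, sprintf("labels_%04d.png", i - 1L)))
  utils::write.csv(fit$per_frame, file.path(dir, "reference.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(fit$volumes),
                   file.path(dir, "volumes_long.csv"), row.names = FALSE)
  utils::write.csv(volumes_row(fit, scaffold_id),
                   file.path(dir, "volumes.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(median_threshold = fit$thresholds$median_threshold,
         high_threshold = fit$thresholds$high_threshold,
         high_mode = fit$thresholds$high_mode,
         per_frame_high = fit$thresholds$per_frame_high,
         pooled_histogram = fit$global_reference$pooled_histogram),
    file.path(dir, "thresholds.json"), auto_unbox = TRUE, digits = NA)
  cfg <- unclass(fit$config)
  cfg$package_version <- as.character(utils::packageVersion("ivusecho"))
  jsonlite::write_json(cfg, file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
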