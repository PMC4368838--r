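#' High-intensity threshold by three-stage iterated Otsu
#'
#' Otsu's method is applied to the full grey-level histogram of a frame; in
#' each of the next two iterations it is re-applied to the histogram
#' restricted to levels strictly above the previous threshold. The third
#' threshold separates highly echogenic structures (struts, calcium) from the
#' bright end of ordinary tissue. If a restriction leaves fewer than two
#' populated levels the last valid threshold is returned with a
#' \code{saturated-iteration} warning.
#'
#' @param histogram 256-bin grey-level histogram of the whole frame.
#' @param n_iter number of Otsu stages (default 3).
#' @return integer threshold (the last stage's Otsu level).
#' @export
iterated_otsu <- function(histogram, n_iter = 3L) {
  stopifnot(length(histogram) == 256L, n_iter >= 1L)
  h <- as.numeric(histogram)
  t_cur <- NA_integer_
  for (k in seq_len(n_iter)) {
    if (sum(h > 0) < 2L) {
      warning(sprintf("saturated iteration: stage %d histogram degenerate; returning stage-%d threshold",
                      k, k - 1L))
      return(t_cur)
    }
    t_cur <- otsu_threshold(h)
    h[seq_len(t_cur + 1L)] <- 0   # keep levels strictly above t_cur
  }
  t_cur
}

#' Pullback-level high-intensity threshold
#'
#' The three-stage iterated Otsu threshold is computed per frame on the full
#' frame histogram; across a pullback the per-frame values are combined
#' either as their lower median (\code{mode = "median"}, default) or by
#' running the iterated Otsu once on the pooled full-frame histogram
#' (\code{mode = "pooled"}). When the result falls below the global reference
#' median it is clamped up to it with a warning (configurable).
#'
#' @param frames list of integer grey-level matrices.
#' @param mode \code{"median"} or \code{"pooled"}.
#' @param median_threshold global reference median, used for the clamp.
#' @param clamp clamp \code{high < median} up to the median (default TRUE).
#' @return list with \code{high_threshold}, \code{per_frame} (stage-3
#'   thresholds per frame) and \code{mode}.
#' @export
high_threshold <- function(frames, mode = c("median", "pooled"),
                           median_threshold = NULL, clamp = TRUE) {
  mode <- match.arg(mode)
  per_frame <- vapply(frames, function(f) {
    as.integer(iterated_otsu(grey_histogram(f)))
  }, integer(1))
  if (mode == "median") {
    s <- sort(per_frame)
    high <- s[ceiling(length(s) / 2)]          # lower median: usable grey level
  } else {
    pooled <- integer(256)
    for (f in frames) pooled <- pooled + grey_histogram(f)
    high <- as.integer(iterated_otsu(pooled))
  }
  if (!is.null(median_threshold) && !is.na(high) && high < median_threshold) {
    if (clamp) {
      warning(sprintf("high threshold %d below reference median %d; clamped",
                      high, median_threshold))
      high <- as.integer(median_threshold)
    } else {
      warning(sprintf("high threshold %d below reference median %d",
                      high, median_threshold))
    }
  }
  list(high_threshold = high, per_frame = per_frame, mode = mode)
}
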