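# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from its definition, without calling the package
# internals they check.

# Exhaustive Otsu: try every threshold t in 1..255, compute class weights and
# means directly from the histogram, return smallest maximizer.
otsu_brute <- function(h) {
  levels <- 0:255
  best_t <- NA_integer_; best_s <- -1
  for (t in 1:255) {
    lo <- levels < t
    w0 <- sum(h[lo]); w1 <- sum(h[!lo])
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[lo] * levels[lo]) / w0
    m1 <- sum(h[!lo] * levels[!lo]) / w1
    s <- w0 * w1 * (m0 - m1)^2
    if (s > best_s) { best_s <- s; best_t <- t }
  }
  best_t
}

# Literal three-stage iterated Otsu: restrict to levels strictly above the
# previous threshold, re-run the exhaustive search.
iterated_otsu_brute <- function(h, n_iter = 3L) {
  t_cur <- NA_integer_
  for (k in seq_len(n_iter)) {
    if (sum(h > 0) < 2L) return(t_cur)
    t_cur <- otsu_brute(h)
    h[0:255 <= t_cur] <- 0
  }
  t_cur
}

# Random histogram supported on n_lev random grey levels.
random_histogram <- function(n_lev = 16L) {
  h <- numeric(256)
  lev <- sample(0:255, n_lev)
  h[lev + 1] <- sample(1:50, n_lev, replace = TRUE)
  h
}

# Random simple star-shaped polygon around a center: evenly spaced angles
# with jitter keep every angular gap below 180 degrees, which guarantees
# simplicity; non-integer vertices mean no pixel center falls on an edge a.s.
random_star_polygon <- function(center, r_min, r_max, n = 12L) {
  step <- 2 * pi / n
  theta <- (0:(n - 1)) * step + stats::runif(n, 0.05, 0.95) * step
  r <- stats::runif(n, r_min, r_max)
  cbind(row = center[1] - r * sin(theta), col = center[2] + r * cos(theta))
}

# mgcv's independent point-in-polygon test, mapped to (row, col) points.
in_out_oracle <- function(polygon, pr, pc) {
  bnd <- rbind(polygon, polygon[1, ])
  mgcv::in.out(bnd, cbind(pr, pc))
}

# Brute-force Ward merging: at every step compute, for every active cluster
# pair, the increase in total within-cluster sum of squares caused by the
# merge, straight from the member coordinates; merge the smallest (ties to
# the lexicographically smallest active-index pair).
ward_brute <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  members <- as.list(1:n)
  id <- -(1:n)
  active <- rep(TRUE, n)
  merges <- matrix(0L, n - 1L, 2L)
  d_wss <- numeric(n - 1L)
  wss <- function(m) { if (length(m) == 1) return(0)
    xs <- x[m, , drop = FALSE]; sum(sweep(xs, 2, colMeans(xs))^2) }
  for (s in seq_len(n - 1L)) {
    best <- c(NA, NA); best_inc <- Inf
    for (i in which(active)) for (j in which(active)) {
      if (j <= i) next
      inc <- wss(c(members[[i]], members[[j]])) - wss(members[[i]]) - wss(members[[j]])
      if (inc < best_inc - 1e-12) { best_inc <- inc; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    merges[s, ] <- sort(c(id[i], id[j]))
    d_wss[s] <- best_inc
    members[[i]] <- c(members[[i]], members[[j]])
    active[j] <- FALSE
    id[i] <- s
  }
  list(merge = merges, d_wss = d_wss)
}

# Circular vessel polygon in pixel coordinates.
circle_polygon <- function(center, radius_px, n = 72L) {
  theta <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(row = center[1] - radius_px * sin(theta),
        col = center[2] + radius_px * cos(theta))
}

# Small crafted frame with concentric circular contours, uniform grey wall.
flat_frame <- function(grid = 96L, wall_grey = 100L, lumen_r = 14,
                       scaffold_r = 22, vessel_r = 30) {
  ctr <- c((grid + 1) / 2, (grid + 1) / 2)
  ct <- list(lumen = circle_polygon(ctr, lumen_r),
             scaffold = circle_polygon(ctr, scaffold_r),
             vessel = circle_polygon(ctr, vessel_r))
  list(pixels = matrix(as.integer(wall_grey), grid, grid),
       contours = ct, center = ctr, grid = grid)
}
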