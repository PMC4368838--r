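test_that("Otsu picks the smallest maximizing threshold on a two-delta histogram", {
  h <- numeric(256); h[10 + 1] <- 50; h[200 + 1] <- 50
  expect_identical(otsu_threshold(h), 11L)
})

test_that("Otsu equals exhaustive between-class-variance search on random histograms", {
  set.seed(11)
  for (rep in 1:30) {
    h <- random_histogram(16L)
    expect_identical(otsu_threshold(h), otsu_brute(h))
  }
})

test_that("single-valued histograms are rejected as degenerate", {
  h <- numeric(256); h[129] <- 1000
  expect_error(otsu_threshold(h), "degenerate histogram")
  expect_error(otsu_threshold(numeric(256)), "degenerate histogram")
})

test_that("reference ring matches the analytic annulus for a circular vessel", {
  sp <- 0.02
  ctr <- c(128.5, 128.5)
  ring <- build_ring(circle_polygon(ctr, 2.0 / sp, n = 360), sp, c(256, 256),
                     d_min = 0.01, d_max = 0.21)
  expected <- pi * (2.21^2 - 2.01^2) / sp^2
  expect_equal(sum(ring), expected, tolerance = 0.05)
  # ring lies strictly outside the vessel
  vessel <- rasterize_contour(circle_polygon(ctr, 2.0 / sp, n = 360), c(256, 256))
  expect_false(any(ring & vessel))
})

test_that("degenerate band gives an at-most-one-pixel shell", {
  sp <- 0.02
  ctr <- c(64.5, 64.5)
  expect_warning(
    ring <- build_ring(circle_polygon(ctr, 20), sp, c(128, 128),
                       d_min = 0.1, d_max = 0.1),
    "empty ring")
  expect_lte(sum(ring), 400)  # a shell at most one pixel thick, likely empty
})

test_that("ring equals brute-force per-pixel distance computation on a convex polygon", {
  sp <- 0.05
  poly <- cbind(c(20, 18, 30, 42, 40, 28), c(20, 32, 42, 30, 18, 12))
  ring <- build_ring(poly, sp, c(64, 64), d_min = 0.05, d_max = 0.4)
  # plain double loop over pixels and edges
  brute <- matrix(FALSE, 64, 64)
  for (r in 1:64) for (c in 1:64) {
    if (in_out_oracle(poly, r, c)) next
    dmin <- Inf
    n <- nrow(poly)
    for (e in 1:n) {
      a <- poly[e, ]; b <- poly[if (e == n) 1 else e + 1, ]
      ab <- b - a; t <- sum((c(r, c) - a) * ab) / sum(ab^2)
      t <- min(1, max(0, t))
      dmin <- min(dmin, sqrt(sum((c(r, c) - (a + t * ab))^2)))
    }
    d <- dmin * sp
    brute[r, c] <- d >= 0.05 && d <= 0.4
  }
  expect_identical(ring, brute)
})

test_that("uniformly bright ring keeps all sectors", {
  f <- flat_frame(wall_grey = 200L)
  ring <- build_ring(f$contours$vessel, 0.02, c(f$grid, f$grid))
  incl <- exclude_sectors(f$pixels, ring, f$center, adaptive_threshold = 100L)
  expect_length(incl, 180)
  expect_true(all(incl))
})

test_that("dark half-ring excludes exactly the dark sectors", {
  f <- flat_frame(wall_grey = 200L)
  ring <- build_ring(f$contours$vessel, 0.02, c(f$grid, f$grid))
  px <- f$pixels
  idx <- which(ring, arr.ind = TRUE)
  deg <- atan2(-(idx[, 1] - f$center[1]), idx[, 2] - f$center[2]) * 180 / pi
  deg <- deg %% 360
  lin <- which(ring)
  px[lin[deg >= 180]] <- 20L
  thr <- otsu_threshold(grey_histogram(px[ring]))
  expect_true(thr > 20 && thr <= 200)
  incl <- exclude_sectors(px, ring, f$center, thr)
  # sectors 90..179 cover angles [180, 360)
  expect_true(all(!incl[91:180]))
  expect_true(all(incl[1:90]))
})

test_that("guidewire mask dominates brightness", {
  f <- flat_frame(wall_grey = 200L)
  ring <- build_ring(f$contours$vessel, 0.02, c(f$grid, f$grid))
  incl <- exclude_sectors(f$pixels, ring, f$center, adaptive_threshold = 0L,
                          guidewire = list(c(350, 10)))
  expect_true(all(!incl[1:5]))     # sectors covering [0, 10)
  expect_true(all(!incl[176:180])) # sectors covering [350, 360)
  expect_true(all(incl[6:175]))
})

test_that("sector exclusion is monotone in pixel brightness", {
  f <- flat_frame(wall_grey = 150L)
  ring <- build_ring(f$contours$vessel, 0.02, c(f$grid, f$grid))
  set.seed(5)
  px <- f$pixels
  lin <- which(ring)
  px[lin] <- as.integer(sample(c(40L, 200L), length(lin), replace = TRUE,
                               prob = c(0.4, 0.6)))
  thr <- 100L
  incl <- exclude_sectors(px, ring, f$center, thr)
  # brighten every pixel of an included sector: stays included
  px_b <- px; px_b[lin] <- pmin(255L, px[lin] + 30L)
  incl_b <- exclude_sectors(px_b, ring, f$center, thr)
  expect_true(all(incl_b[incl]))
  # darken every ring pixel: excluded sectors stay excluded
  px_d <- px; px_d[lin] <- pmax(0L, px[lin] - 60L)
  incl_d <- exclude_sectors(px_d, ring, f$center, thr)
  expect_true(all(!incl_d[!incl]))
})

test_that("pooled reference median follows the stated lower-median convention", {
  ref <- function(h) list(histogram = h)
  h97 <- numeric(256); h97[97 + 1] <- 123
  expect_identical(pool_reference(list(ref(h97), ref(h97)))$median_threshold, 97L)
  # frame A uniform over 0..9, frame B uniform over 10..19, equal counts:
  # lower median = smallest level whose cumulative count reaches half (9)
  hA <- numeric(256); hA[1:10] <- 10
  hB <- numeric(256); hB[11:20] <- 10
  expect_identical(pool_reference(list(ref(hA), ref(hB)))$median_threshold, 9L)
})

test_that("pooled median equals the brute-force median of the pooled pixel list", {
  set.seed(21)
  for (rep in 1:20) {
    hs <- replicate(3, random_histogram(12L), simplify = FALSE)
    pooled <- pool_reference(lapply(hs, function(h) list(histogram = h)))
    pixels <- unlist(lapply(hs, function(h) rep(0:255, h)))
    n <- length(pixels)
    lower_median <- sort(pixels)[ceiling(n / 2)]
    expect_identical(pooled$median_threshold, as.integer(lower_median))
    expect_equal(sum(pooled$pooled_histogram), n)
  }
})

test_that("adding a frame at the current median leaves the median unchanged", {
  set.seed(8)
  hs <- replicate(3, random_histogram(12L), simplify = FALSE)
  refs <- lapply(hs, function(h) list(histogram = h))
  med <- pool_reference(refs)$median_threshold
  extra <- numeric(256); extra[med + 1] <- 500
  expect_identical(pool_reference(c(refs, list(list(histogram = extra))))$median_threshold,
                   med)
})

test_that("all-empty reference raises the no-reference error", {
  expect_error(pool_reference(list(list(histogram = integer(256)))),
               "no reference")
})
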