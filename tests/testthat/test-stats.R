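test_that("pearson_r handles perfect linear relations and matches the direct formula", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  set.seed(10)
  a <- rnorm(10); b <- rnorm(10)
  r_direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_r(a, b)$r, r_direct, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
})

test_that("pearson_r is invariant under affine transforms up to sign", {
  set.seed(20)
  x <- rnorm(12); y <- rnorm(12)
  r0 <- pearson_r(x, y)$r
  expect_equal(pearson_r(3 * x + 5, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_r(-2 * x, y)$r, -r0, tolerance = 1e-12)
})

test_that("linreg matches the closed-form normal equations", {
  x <- c(0, 1, 2, 4)
  fit <- suppressWarnings(linreg(x, 3 * x - 2))  # exact fit warns in summary.lm
  expect_equal(fit$slope, 3, tolerance = 1e-12)
  expect_equal(fit$intercept, -2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  set.seed(30)
  a <- rnorm(15); b <- 0.5 * a + rnorm(15)
  f2 <- linreg(a, b)
  sl <- cov(a, b) / var(a)
  expect_equal(f2$slope, sl, tolerance = 1e-10)
  expect_equal(f2$intercept, mean(b) - sl * mean(a), tolerance = 1e-10)
  ss_res <- sum((b - (f2$intercept + f2$slope * a))^2)
  expect_equal(f2$r_squared, 1 - ss_res / sum((b - mean(b))^2),
               tolerance = 1e-10)
  # response orthogonal to predictor
  y_orth <- rnorm(15); y_orth <- resid(lm(y_orth ~ a))
  expect_lt(linreg(a, y_orth)$r_squared, 1e-20)
})

test_that("Ward clustering separates well-separated clouds", {
  set.seed(1)
  x <- rbind(matrix(rnorm(20, 0, 0.3), ncol = 2),
             matrix(rnorm(20, 10, 0.3), ncol = 2))
  cl <- ward_cluster(x, k = 2)
  expect_equal(length(unique(cl$labels[1:10])), 1)
  expect_equal(length(unique(cl$labels[11:20])), 1)
  expect_false(cl$labels[1] == cl$labels[11])
})

test_that("two-point merge height equals the squared Euclidean distance", {
  x <- rbind(c(0, 0), c(3, 4))
  cl <- ward_cluster(x, k = 1)
  expect_equal(cl$height, 25)           # Ward linkage on squared distances
  expect_equal(cl$labels, c(1L, 1L))
})

test_that("Ward merge tree equals brute-force minimal-WSS merging on random points", {
  set.seed(55)
  for (rep in 1:10) {
    x <- matrix(rnorm(16), ncol = 2)
    cl <- ward_cluster(x, k = 1)
    br <- ward_brute(x)
    expect_identical(cl$merge, br$merge)
    expect_equal(cl$height, 2 * br$d_wss, tolerance = 1e-9)
  }
})

test_that("Ward merge heights are non-decreasing", {
  set.seed(66)
  x <- matrix(rnorm(40), ncol = 2)
  cl <- ward_cluster(x, k = 1)
  expect_true(all(diff(cl$height) >= -1e-9))
})

test_that("Ward merge order agrees with stats::hclust ward.D on squared distances", {
  set.seed(91)
  x <- matrix(rnorm(24), ncol = 2)
  cl <- ward_cluster(x, k = 3)
  hc <- stats::hclust(stats::dist(x)^2, method = "ward.D")
  expect_equal(cl$height, hc$height, tolerance = 1e-9)
  ours <- stats::cutree(structure(list(merge = cl$merge, height = cl$height,
                                       order = 1:12, labels = NULL,
                                       method = "ward.D"), class = "hclust"),
                        k = 3)
  theirs <- stats::cutree(hc, k = 3)
  expect_equal(length(unique(paste(ours, theirs))), 3)  # identical partitions
})

test_that("duplicated readings give ICC = 1 and offsets penalize ICC(2,1) only", {
  set.seed(70)
  y <- rnorm(20, 50, 10)
  expect_equal(icc(cbind(y, y))$icc, 1)
  shifted <- cbind(y, y + 25)
  expect_lt(icc(shifted, model = "ICC2")$icc,
            icc(shifted, model = "ICC3")$icc)
  expect_equal(icc(shifted, model = "ICC3")$icc, 1, tolerance = 1e-9)
  expect_error(icc(cbind(rep(1, 5), rep(1, 5))), "zero total variance")
})

test_that("ICC(2,1) recovers the generating intraclass correlation", {
  set.seed(80)
  # two-way random model: y_ij = a_i + b_j + e_ij
  sa <- 2; sb <- 0.5; se <- 1
  target <- sa^2 / (sa^2 + sb^2 + se^2)
  est <- replicate(100, {
    n <- 100; k <- 2
    a <- rnorm(n, 0, sa); b <- rnorm(k, 0, sb)
    y <- outer(a, b, "+") + matrix(rnorm(n * k, 0, se), n, k)
    icc(y)$icc
  })
  expect_lt(abs(mean(est) - target), 0.05)
})

test_that("one-way ANOVA matches the t-test identity and degenerates cleanly", {
  g <- rep(c("a", "b"), each = 6)
  set.seed(90)
  v <- rnorm(12)
  res <- anova_oneway(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  expect_equal(anova_oneway(rep(5, 10), rep(c("a", "b"), 5))$F, 0)
  # random groups vs sums-of-squares oracle
  g3 <- rep(c("a", "b", "c"), each = 5)
  v3 <- rnorm(15)
  res3 <- anova_oneway(v3, g3)
  grand <- mean(v3)
  ssb <- sum(tapply(v3, g3, function(z) length(z) * (mean(z) - grand)^2))
  ssw <- sum(tapply(v3, g3, function(z) sum((z - mean(z))^2)))
  f_oracle <- (ssb / 2) / (ssw / 12)
  expect_equal(res3$F, f_oracle, tolerance = 1e-10)
})

test_that("pairwise post-hoc comparisons apply the requested correction", {
  set.seed(95)
  v <- c(rnorm(8, 0), rnorm(8, 5), rnorm(8, 0.2))
  g <- rep(c("a", "b", "c"), each = 8)
  p_b <- posthoc_pairwise(v, g, method = "bonferroni")
  p_n <- posthoc_pairwise(v, g, method = "none")
  expect_true(all(p_b >= p_n - 1e-12, na.rm = TRUE))
  expect_lt(p_b["b", "a"], 0.05)
})
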