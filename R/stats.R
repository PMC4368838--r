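#' Pearson correlation with two-sided test
#'
#' @param x,y numeric vectors of equal length, n >= 3, non-constant.
#' @return list with \code{r}, \code{p}, \code{n}.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Ordinary least-squares regression of y on x
#'
#' @param x predictor; @param y response.
#' @return list with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{p} (slope t-test) and the underlying \code{lm} fit.
#' @export
linreg <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       p = unname(s$coefficients[2, 4]),
       fit = fit)
}

#' Ward hierarchical clustering on squared Euclidean distances
#'
#' Agglomerative clustering with Ward's minimum-variance linkage via the
#' Lance-Williams update on squared Euclidean distances. At every step the
#' pair with the smallest linkage distance is merged; exact ties go to the
#' lowest-index pair, so the merge tree is fully deterministic. The stored
#' merge height is the Ward linkage distance, which equals twice the
#' within-cluster sum-of-squares increase of the merge.
#'
#' @param x numeric matrix (observations x features) or data frame.
#' @param k number of clusters to cut to (1 <= k <= n).
#' @return list with \code{labels} (cluster assignment 1..k, renumbered in
#'   order of first appearance), \code{merge} ((n-1) x 2 matrix, negative =
#'   singleton as in [stats::hclust()]), \code{height} (linkage distance per
#'   merge).
#' @export
ward_cluster <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n >= 1L)
  if (k > n || k < 1L) stop("k must lie in 1..n")
  if (n == 1L) return(list(labels = 1L, merge = matrix(0L, 0, 2), height = numeric(0)))
  d <- as.matrix(stats::dist(x))^2
  diag(d) <- Inf
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  id <- -(1:n)                       # hclust convention: negatives = singletons
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  member <- as.list(1:n)
  for (step in seq_len(n - 1L)) {
    dd <- d
    dd[!active, ] <- Inf; dd[, !active] <- Inf
    pos <- which(dd == min(dd), arr.ind = TRUE)
    # lowest-index pair: order candidates by (i, j) with i < j
    pos <- pos[pos[, 1] < pos[, 2], , drop = FALSE]
    pos <- pos[order(pos[, 1], pos[, 2]), , drop = FALSE]
    i <- pos[1, 1]; j <- pos[1, 2]
    height[step] <- d[i, j]
    merge[step, ] <- sort(c(id[i], id[j]))
    # Lance-Williams update for Ward on squared distances
    others <- which(active & seq_len(n) != i & seq_len(n) != j)
    ni <- size[i]; nj <- size[j]
    for (m in others) {
      nm <- size[m]
      d[i, m] <- d[m, i] <- ((ni + nm) * d[i, m] + (nj + nm) * d[j, m] -
                               nm * d[i, j]) / (ni + nj + nm)
    }
    size[i] <- ni + nj
    active[j] <- FALSE
    id[i] <- step
    member[[i]] <- c(member[[i]], member[[j]])
  }
  labels <- cut_merge(merge, n, k)
  list(labels = labels, merge = merge, height = height)
}

# Replay the first n - k merges and number clusters by first appearance.
cut_merge <- function(merge, n, k) {
  grp <- 1:n
  steps <- n - k
  if (steps > 0) for (s in seq_len(steps)) {
    a <- node_members(merge, merge[s, 1])
    b <- node_members(merge, merge[s, 2])
    grp[c(a, b)] <- min(grp[c(a, b)])
  }
  u <- unique(grp)
  match(grp, u)
}

# Observation indices under a merge-tree node (negative = singleton).
node_members <- function(merge, v) {
  if (v < 0) return(-v)
  c(node_members(merge, merge[v, 1]), node_members(merge, merge[v, 2]))
}

#' Intraclass correlation coefficient for paired readings
#'
#' Single-measure ICC from the two-way crossed ANOVA mean squares (subjects x
#' raters). The default \code{"ICC2"} is the two-way random-effects,
#' absolute-agreement form ICC(2,1), the standard for method-agreement in
#' imaging; \code{"ICC3"} is the consistency form ICC(3,1), insensitive to a
#' fixed rater offset.
#'
#' @param readings numeric matrix or data frame, one row per subject, one
#'   column per reader/reading (n >= 3 rows, >= 2 columns).
#' @param model \code{"ICC2"} (absolute agreement) or \code{"ICC3"}
#'   (consistency).
#' @return list with \code{icc}, \code{model}, \code{n}, \code{k} and the
#'   mean squares \code{msr}, \code{msc}, \code{mse}.
#' @export
icc <- function(readings, model = c("ICC2", "ICC3")) {
  model <- match.arg(model)
  y <- as.matrix(readings)
  y <- y[stats::complete.cases(y), , drop = FALSE]
  n <- nrow(y); k <- ncol(y)
  if (n < 3L || k < 2L) stop("need >= 3 subjects and >= 2 readings")
  grand <- mean(y)
  if (all(y == grand)) stop("undefined ICC: zero total variance")
  rm_ <- rowMeans(y); cm_ <- colMeans(y)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sst <- sum((y - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  est <- if (model == "ICC2") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  list(icc = est, model = model, n = n, k = k, msr = msr, msc = msc, mse = mse)
}

#' One-way analysis of variance
#'
#' @param values numeric vector of observations.
#' @param groups factor (or coercible) of group membership; >= 2 groups with
#'   n >= 2 each.
#' @return list with \code{F}, \code{p}, \code{df_between}, \code{df_within}.
#' @export
anova_oneway <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(droplevels(groups)) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs n >= 2")
  if (stats::sd(values) == 0) {
    # all observations identical: F = 0 by convention, p = 1
    tb <- table(groups)
    return(list(F = 0, p = 1, df_between = nlevels(groups) - 1L,
                df_within = length(values) - nlevels(groups)))
  }
  ow <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(ow$statistic), p = ow$p.value,
       df_between = unname(ow$parameter[1]),
       df_within = unname(ow$parameter[2]))
}

#' Pairwise post-hoc group comparisons
#'
#' Pairwise two-sample t tests with multiplicity adjustment (Bonferroni by
#' default), as used after a significant one-way ANOVA.
#'
#' @inheritParams anova_oneway
#' @param method a [stats::p.adjust()] method.
#' @return the p-value matrix from [stats::pairwise.t.test()].
#' @export
posthoc_pairwise <- function(values, groups, method = "bonferroni") {
  groups <- as.factor(groups)
  stats::pairwise.t.test(values, groups, p.adjust.method = method,
                         pool.sd = FALSE)$p.value
}
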