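#' PCA on the regional disorder feature matrix
#'
#' Centered, unit-variance PCA (via [stats::prcomp()]) of the per-sample
#' feature matrix. Samples with missing features are dropped with a warning,
#' as are constant features (scaling is undefined for them). Loading signs
#' follow a deterministic convention: within each component the
#' largest-magnitude loading is positive.
#'
#' @param feature_matrix Samples-by-features numeric matrix.
#' @return List with `scores`, `loadings` and `variance_explained`.
#' @export
pca_features <- function(feature_matrix) {
  x <- as.matrix(feature_matrix)
  complete <- complete.cases(x)
  if (!all(complete)) {
    .warnf("%d sample(s) with missing features dropped from PCA", sum(!complete))
    x <- x[complete, , drop = FALSE]
  }
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    .warnf("constant feature(s) dropped from PCA: %s",
           paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (nrow(x) < 2L || ncol(x) < 2L) .stopf("PCA needs >= 2 complete samples and >= 2 varying features")
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2L, flip, `*`)
  pc$x <- sweep(pc$x, 2L, flip, `*`)
  list(scores = pc$x, loadings = pc$rotation,
       variance_explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Quartile stratification with relative risk
#'
#' Orders samples by a continuous value (ties keep input order), splits them
#' into four groups as equal as possible (any remainder going to the lower
#' quartiles), and reports per-quartile positive-label counts and rates plus
#' the relative risk of the upper half (Q3+Q4) versus the lower half (Q1+Q2).
#'
#' @param values Stratifying values (e.g. multiscale disorder).
#' @param binary_labels Logical or 0/1 vector (TRUE/1 = positive, e.g.
#'   mutant).
#' @return List with `quartiles` (data.frame n, n_positive, rate),
#'   `relative_risk` (NA when the lower-half rate is 0 or labels are
#'   constant) and `overall_rate`.
#' @export
quartile_stratify <- function(values, binary_labels) {
  stopifnot(length(values) == length(binary_labels))
  n <- length(values)
  if (n < 4L) .stopf("need >= 4 samples for quartile stratification")
  lab <- as.logical(binary_labels)
  ord <- order(values)                       # stable: ties keep input order
  base <- n %/% 4L; rem <- n %% 4L
  sizes <- base + as.integer(seq_len(4L) <= rem)   # remainder to lower quartiles
  qidx <- rep(1:4, times = sizes)
  npos <- vapply(1:4, function(q) sum(lab[ord][qidx == q]), 0L)
  qt <- data.frame(quartile = 1:4, n = sizes, n_positive = npos,
                   rate = npos / sizes)
  lo <- sum(npos[1:2]) / sum(sizes[1:2])
  hi <- sum(npos[3:4]) / sum(sizes[3:4])
  rr <- if (lo == 0 || all(lab) || !any(lab)) NA_real_ else hi / lo
  list(quartiles = qt, relative_risk = rr, overall_rate = mean(lab))
}

#' Three-dimensional heterogeneity coefficients of variation
#'
#' For each group, quantifies disorder heterogeneity along three axes:
#' inter-sample (CV across the group's samples of their genome-wide mean
#' window disorder), inter-gene (CV across genes of the group-mean,
#' gene-averaged window disorder) and inter-region (CV across the eight
#' regional features of the group-mean feature vector). CV = SD/mean; a zero
#' mean yields a missing CV.
#'
#' @param window_lpmd Windows-by-samples disorder matrix.
#' @param window_genes List of gene vectors per window (from
#'   [annotate_windows()]).
#' @param region_features Samples-by-features matrix from
#'   [region_features()]; the first eight columns are the regional means.
#' @param groups Per-sample group labels.
#' @return Matrix with rows per group and columns `cv_sample`, `cv_gene`,
#'   `cv_region`.
#' @export
heterogeneity_cv <- function(window_lpmd, window_genes, region_features, groups) {
  cv <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L || mean(v) == 0) return(NA_real_)
    sd(v) / mean(v)
  }
  glev <- unique(as.character(groups))
  out <- matrix(NA_real_, length(glev), 3,
                dimnames = list(glev, c("cv_sample", "cv_gene", "cv_region")))
  # windows -> genes map (a window may carry several genes)
  gl <- lapply(window_genes, function(g) unique(g[nzchar(g)]))
  win_rep <- rep(seq_along(gl), lengths(gl))
  gene_of <- unlist(gl)
  keep <- length(gene_of) > 0L
  for (g in glev) {
    sel <- which(as.character(groups) == g)
    if (length(sel) < 2L) next
    sample_means <- colMeans(window_lpmd[, sel, drop = FALSE], na.rm = TRUE)
    out[g, "cv_sample"] <- cv(sample_means)
    group_win <- rowMeans(window_lpmd[, sel, drop = FALSE], na.rm = TRUE)
    if (keep) {
      gene_means <- tapply(group_win[win_rep], gene_of, mean, na.rm = TRUE)
      out[g, "cv_gene"] <- cv(as.numeric(gene_means))
    }
    reg <- colMeans(region_features[sel, 1:8, drop = FALSE], na.rm = TRUE)
    out[g, "cv_region"] <- cv(reg)
  }
  out
}

#' Power of a two-sided two-sample t-test
#'
#' Exact power from the non-central t distribution, with non-centrality
#' `d * sqrt(n1*n2/(n1+n2))` and `n1 + n2 - 2` degrees of freedom.
#'
#' @param d Cohen's d effect size.
#' @param n1,n2 Group sizes (>= 2).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in \[0, 1\].
#' @export
power_two_sample_t <- function(d, n1, n2, alpha = 0.05) {
  stopifnot(n1 >= 2, n2 >= 2, alpha > 0, alpha < 1)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tc <- qt(1 - alpha / 2, df)
  pt(-tc, df, ncp = ncp) + 1 - pt(tc, df, ncp = ncp)
}

#' Minimum detectable effect size at a target power
#'
#' Smallest Cohen's d whose two-sided two-sample t-test power reaches the
#' target, found by bisection on [power_two_sample_t()] to 1e-6.
#'
#' @param power_target Target power in (alpha, 1).
#' @param n1,n2 Group sizes.
#' @param alpha Significance level.
#' @return Scalar d.
#' @export
min_detectable_d <- function(power_target = 0.80, n1, n2, alpha = 0.05) {
  stopifnot(power_target > alpha, power_target < 1)
  lo <- 0; hi <- 1
  while (power_two_sample_t(hi, n1, n2, alpha) < power_target) hi <- hi * 2
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (power_two_sample_t(mid, n1, n2, alpha) >= power_target) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Directional consistency between two DMDR tables
#'
#' Fraction of windows present in both tables whose effect signs agree.
#'
#' @param dmdrs_a,dmdrs_b Data.frames with `window` and `d` columns.
#' @return List with `consistency` (NA if the intersection is empty) and
#'   `n_shared`.
#' @export
directional_consistency <- function(dmdrs_a, dmdrs_b) {
  shared <- intersect(dmdrs_a$window, dmdrs_b$window)
  if (!length(shared)) return(list(consistency = NA_real_, n_shared = 0L))
  da <- dmdrs_a$d[match(shared, dmdrs_a$window)]
  db <- dmdrs_b$d[match(shared, dmdrs_b$window)]
  list(consistency = mean(sign(da) == sign(db)), n_shared = length(shared))
}

#' Jaccard index of two sets
#'
#' @param set_a,set_b Vectors treated as sets.
#' @return |intersection| / |union|; NA for two empty sets.
#' @export
jaccard_index <- function(set_a, set_b) {
  u <- union(set_a, set_b)
  if (!length(u)) return(NA_real_)
  length(intersect(set_a, set_b)) / length(u)
}

#' Bland-Altman agreement statistics
#'
#' @param x,y Paired measurements (length >= 3).
#' @return List with `bias` (mean of x - y), `lower_loa`, `upper_loa`
#'   (bias -/+ 1.96 SD of differences).
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, lower_loa = bias - 1.96 * s, upper_loa = bias + 1.96 * s)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measure — the standard
#' choice for method-comparison studies. Computed from the two-way ANOVA mean
#' squares: `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param x,y Paired measurements from the two methods (length >= 3).
#' @return ICC value; NA when the pairs have no variance.
#' @export
icc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  n <- length(x); k <- 2
  mat <- cbind(x, y)
  if (var(as.vector(mat)) == 0) return(NA_real_)
  row_means <- rowMeans(mat)
  col_means <- colMeans(mat)
  grand <- mean(mat)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sse <- sum((mat - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom == 0) return(NA_real_)
  (msr - mse) / denom
}

#' Permutation test for a group-contrast statistic
#'
#' Empirical one-sided p-value with the add-one estimator
#' `p = (1 + #{permuted >= observed}) / (n_iter + 1)`, permuting the labels.
#'
#' @param values Per-sample values.
#' @param labels Per-sample labels passed to `statistic`.
#' @param statistic Function of `(values, labels)` returning a scalar.
#' @param n_iter Number of permutations (default 1000).
#' @param seed Mandatory RNG seed.
#' @return List with `p`, `observed`, `n_iter`.
#' @export
permutation_test <- function(values, labels, statistic, n_iter = 1000, seed) {
  if (missing(seed)) .stopf("permutation_test requires an explicit seed")
  obs <- statistic(values, labels)
  set.seed(seed)
  perm <- vapply(seq_len(n_iter), function(i) {
    statistic(values, sample(labels))
  }, 0)
  list(p = (1 + sum(perm >= obs)) / (n_iter + 1), observed = obs,
       n_iter = n_iter)
}

#' Percentile bootstrap confidence interval
#'
#' @param data Vector (or rows of a matrix/data.frame) to resample.
#' @param statistic Function of the resampled data returning a scalar.
#' @param n_iter Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Mandatory RNG seed.
#' @return List with `lower`, `upper`, `estimate`.
#' @export
bootstrap_ci <- function(data, statistic, n_iter = 1000, level = 0.95, seed) {
  if (missing(seed)) .stopf("bootstrap_ci requires an explicit seed")
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  pick <- if (is.null(dim(data))) function(i) data[i] else function(i) data[i, , drop = FALSE]
  set.seed(seed)
  stats <- vapply(seq_len(n_iter), function(b) {
    statistic(pick(sample.int(n, n, replace = TRUE)))
  }, 0)
  alpha <- (1 - level) / 2
  ci <- quantile(stats, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(lower = ci[1L], upper = ci[2L], estimate = statistic(data))
}
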