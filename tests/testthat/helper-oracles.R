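# Independent brute-force oracles and tiny fixture builders used across the
# suite. Oracles deliberately avoid the package's code paths.

# hand-built manifest: columns as read_manifest() would return
make_manifest <- function(chrom, pos, feature_class = "Body",
                          cpg_relation = "OpenSea", genes = NULL) {
  n <- length(pos)
  df <- data.frame(probe_id = sprintf("cg%05d", seq_len(n)),
                   chrom = rep_len(chrom, n), pos = as.integer(pos),
                   feature_class = rep_len(feature_class, n),
                   cpg_relation = rep_len(cpg_relation, n),
                   stringsAsFactors = FALSE)
  df$genes <- if (is.null(genes)) replicate(n, character(), simplify = FALSE) else genes
  ord <- order(df$chrom, df$pos)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

make_beta <- function(manifest, values, sample_ids = NULL) {
  m <- matrix(values, nrow = nrow(manifest))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(ncol(m)))
  dimnames(m) <- list(manifest$probe_id, sample_ids)
  m
}

# naive window statistics: double loop over candidate tiles and samples
oracle_window_stats <- function(manifest, beta, size, step, min_cpg) {
  out <- list()
  for (ch in sort(unique(manifest$chrom))) {
    sel <- manifest$chrom == ch
    idx0 <- manifest$pos[sel] - 1L
    ids <- manifest$probe_id[sel]
    for (s in seq(0, max(idx0), by = step)) {
      member <- ids[idx0 >= s & idx0 < s + size]
      if (length(member) < min_cpg) next
      key <- paste0(ch, ":", s, "-", s + size)
      st <- sapply(colnames(beta), function(smp) {
        x <- beta[member, smp]
        x <- x[!is.na(x)]
        if (length(x) < min_cpg) return(rep(NA_real_, 6))
        c(mean(x), median(x), sd(x),
          quantile(x, 0.75, names = FALSE, type = 7),
          quantile(x, 0.90, names = FALSE, type = 7), max(x))
      })
      rownames(st) <- c("mean", "median", "sd", "q75", "q90", "max")
      out[[key]] <- st
    }
  }
  out
}

# step-up BH by sort and reverse cumulative minimum
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# trapezoidal ROC integration (handles ties via threshold blocks)
oracle_auc_trapezoid <- function(scores, y) {
  y <- as.logical(y)
  th <- sort(unique(scores), decreasing = TRUE)
  sens <- c(0, vapply(th, function(t) mean(scores[y] >= t), 0))
  fpr <- c(0, vapply(th, function(t) mean(scores[!y] >= t), 0))
  sum(diff(fpr) * (head(sens, -1) + tail(sens, -1)) / 2)
}

# Welch t from the textbook formula
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# ICC(2,1) via two-way ANOVA mean squares from stats::aov
oracle_icc_aov <- function(x, y) {
  n <- length(x)
  d <- data.frame(v = c(x, y), subj = factor(rep(seq_len(n), 2)),
                  meth = factor(rep(1:2, each = n)))
  ms <- anova(aov(v ~ meth + subj, data = d))
  msr <- ms["subj", "Mean Sq"]
  msc <- ms["meth", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

# JT statistic by explicit pair counting
oracle_jt_stat <- function(groups) {
  jt <- 0
  k <- length(groups)
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    for (a in groups[[i]]) for (b in groups[[j]]) {
      jt <- jt + (a < b) + 0.5 * (a == b)
    }
  }
  jt
}

# exact JT null distribution by enumerating group assignments (tiny n only)
oracle_jt_exact_p <- function(groups, alternative = "decreasing") {
  values <- unlist(groups)
  sizes <- lengths(groups)
  obs <- oracle_jt_stat(groups)
  assignments <- list()
  recurse <- function(remaining_idx, gi, acc) {
    if (gi > length(sizes)) {
      assignments[[length(assignments) + 1L]] <<- acc
      return(invisible())
    }
    picks <- combn(remaining_idx, sizes[gi], simplify = FALSE)
    for (p in picks) recurse(setdiff(remaining_idx, p), gi + 1L, c(acc, list(p)))
  }
  recurse(seq_along(values), 1L, list())
  stats <- vapply(assignments, function(a) {
    oracle_jt_stat(lapply(a, function(i) values[i]))
  }, 0)
  if (alternative == "decreasing") mean(stats <= obs) else mean(stats >= obs)
}

# directly parameterised logistic data for panel tests
make_logistic_data <- function(n, p_noise, coefs, seed) {
  set.seed(seed)
  p_sig <- length(coefs)
  X <- matrix(rnorm(n * (p_sig + p_noise)), n)
  colnames(X) <- c(sprintf("sig%02d", seq_len(p_sig)),
                   sprintf("noise%03d", seq_len(p_noise)))
  eta <- drop(X[, seq_len(p_sig), drop = FALSE] %*% coefs)
  y <- runif(n) < plogis(eta)
  list(X = X, y = y)
}
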