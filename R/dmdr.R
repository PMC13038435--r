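#' Pooled-SD Cohen's d
#'
#' Standardised mean difference `(mean_a - mean_b) / s_pooled` with
#' `s_pooled = sqrt(((n_a-1)s_a^2 + (n_b-1)s_b^2) / (n_a+n_b-2))`. By
#' convention `group_a` is the mutant/case group, so positive d means higher
#' values in mutants. When the pooled SD is zero, equal means give d = 0 and
#' unequal means give a signed infinity (degenerate, flagged by a warning).
#'
#' @param group_a,group_b Numeric vectors (>= 2 non-missing values each).
#' @return Scalar d.
#' @export
cohens_d <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) < 2L || length(b) < 2L) .stopf("each group needs >= 2 non-missing values")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  dm <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (dm == 0) return(0)
    .warnf("zero pooled SD with unequal means; Cohen's d is infinite")
    return(sign(dm) * Inf)
  }
  dm / sqrt(sp2)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value. The degenerate case of zero variance in both groups
#' with equal means returns t = 0, p = 1.
#'
#' @param group_a,group_b Numeric vectors (>= 2 non-missing values each).
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) < 2L || length(b) < 2L) .stopf("each group needs >= 2 non-missing values")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0))
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH q-values. Missing p-values stay missing and do not count
#' towards the family size m.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) .stopf("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p_values))
  q[ok] <- p.adjust(p_values[ok], method = "BH")
  q
}

#' Effect-size tier for a DMDR
#'
#' Tier 1 (high): |d| > 1.5; tier 2 (moderate): |d| > 1.0; tier 3
#' (potential): |d| > 0.8; tier 4 (exploratory): |d| > 0.5. Boundaries are
#' strict, so |d| = 1.5 is tier 2. Values with |d| <= 0.5 are not DMDRs and
#' raise an error.
#'
#' @param d Cohen's d (vectorised).
#' @return Integer tier(s) in 1..4.
#' @export
assign_tier <- function(d) {
  ad <- abs(d)
  if (any(ad <= 0.5, na.rm = TRUE)) .stopf("assign_tier requires |d| > 0.5 (not a DMDR)")
  ifelse(ad > 1.5, 1L, ifelse(ad > 1.0, 2L, ifelse(ad > 0.8, 3L, 4L)))
}

#' Functional weight for DMDR prioritisation
#'
#' 1.5 for promoter-group windows, else 1.3 for CpG-island windows, else 1.0
#' (promoter takes precedence over island).
#'
#' @param feature_group,cpg_group Window labels from [annotate_windows()].
#' @return Numeric weight(s).
#' @export
functional_weight <- function(feature_group, cpg_group) {
  ifelse(feature_group == "Promoter", 1.5,
         ifelse(cpg_group == "Island", 1.3, 1.0))
}

#' DMDR priority score
#'
#' `|d| * (-log10 FDR) * functional weight`. FDR values are floored at 1e-300
#' so the score stays finite; an input FDR of exactly 0 is clamped with a
#' warning.
#'
#' @param d Cohen's d.
#' @param fdr BH-adjusted q-value in (0, 1\].
#' @param weight Functional weight (see [functional_weight()]).
#' @return Numeric score(s) >= 0.
#' @export
priority_score <- function(d, fdr, weight = 1.0) {
  if (any(fdr == 0, na.rm = TRUE)) .warnf("FDR of 0 clamped to 1e-300")
  abs(d) * (-log10(pmax(fdr, 1e-300))) * weight
}

#' Call differentially methylated disorder regions
#'
#' Compares window-level disorder between two groups using an
#' effect-size-first strategy: per window, pooled-SD Cohen's d
#' (mutant minus wild-type) and a Welch t-test; BH adjustment over all tested
#' windows; windows with `|d| > d_threshold` are reported as DMDRs regardless
#' of FDR. Windows with fewer than two non-missing values in either group are
#' untestable and excluded from the BH family (their count is reported).
#'
#' @param window_lpmd Windows-by-samples disorder matrix from
#'   [window_lpmd()].
#' @param groups Per-sample labels; `case_level` vs everything else.
#' @param d_threshold Calling threshold on |d| (default 0.5).
#' @param case_level Label of the case/mutant group (default `"mutant"`).
#' @param labels Optional window annotation from [annotate_windows()]; used
#'   for functional weights and gene lists.
#' @return A list with `dmdrs` (data.frame of records sorted by priority then
#'   |d|), `tested` (data.frame of all tested windows with d/p/fdr) and
#'   `n_untestable`.
#' @export
call_dmdrs <- function(window_lpmd, groups, d_threshold = 0.5,
                       case_level = "mutant", labels = NULL) {
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(window_lpmd))
  a_idx <- which(groups == case_level)
  b_idx <- which(groups != case_level)
  if (!length(a_idx) || !length(b_idx)) .stopf("one of the groups is empty")

  keys <- rownames(window_lpmd)
  n_a <- rowSums(!is.na(window_lpmd[, a_idx, drop = FALSE]))
  n_b <- rowSums(!is.na(window_lpmd[, b_idx, drop = FALSE]))
  testable <- n_a >= 2L & n_b >= 2L
  tested_idx <- which(testable)

  d <- p <- tstat <- rep(NA_real_, length(tested_idx))
  for (i in seq_along(tested_idx)) {
    w <- tested_idx[i]
    a <- window_lpmd[w, a_idx]
    b <- window_lpmd[w, b_idx]
    d[i] <- suppressWarnings(cohens_d(a, b))
    wt <- welch_t(a, b)
    tstat[i] <- wt$t
    p[i] <- wt$p
  }
  fdr <- bh_fdr(p)
  tested <- data.frame(window = keys[tested_idx],
                       d = d, t_stat = tstat, p_value = p, fdr = fdr,
                       stringsAsFactors = FALSE)

  call <- is.finite(d) & abs(d) > d_threshold
  rec <- tested[call, , drop = FALSE]
  if (nrow(rec)) {
    rec$direction <- ifelse(rec$d > 0, "increased", "decreased")
    rec$tier <- assign_tier(rec$d)
    if (!is.null(labels)) {
      li <- match(rec$window, rownames(labels))
      rec$feature_group <- labels$feature_group[li]
      rec$cpg_group <- labels$cpg_group[li]
      rec$functional_weight <- functional_weight(rec$feature_group, rec$cpg_group)
      rec$genes <- labels$genes[li]
    } else {
      rec$feature_group <- NA_character_
      rec$cpg_group <- NA_character_
      rec$functional_weight <- 1.0
      rec$genes <- replicate(nrow(rec), character(), simplify = FALSE)
    }
    rec$priority <- priority_score(rec$d, rec$fdr, rec$functional_weight)
    rec <- rec[order(-rec$priority, -abs(rec$d)), , drop = FALSE]
  } else {
    rec$direction <- character(); rec$tier <- integer()
    rec$feature_group <- character(); rec$cpg_group <- character()
    rec$functional_weight <- numeric(); rec$priority <- numeric()
    rec$genes <- list()
  }
  rownames(rec) <- NULL
  list(dmdrs = rec, tested = tested, n_untestable = sum(!testable))
}

#' Gene recurrence across DMDRs
#'
#' Counts, for each gene, the number of distinct DMDR windows whose gene list
#' contains it (a gene listed twice within one window counts once).
#'
#' @param dmdrs DMDR data.frame with a `genes` list-column.
#' @return Named integer vector, sorted by decreasing count.
#' @export
gene_recurrence <- function(dmdrs) {
  genes <- unlist(lapply(dmdrs$genes, unique))
  if (!length(genes)) return(setNames(integer(), character()))
  tab <- table(genes)
  counts <- setNames(as.integer(tab), names(tab))
  sort(counts, decreasing = TRUE)
}

#' Export DMDRs as BED6
#'
#' Score column is `min(1000, round(priority * 10))`; strand is `.`.
#'
#' @param dmdrs DMDR table from [call_dmdrs()].
#' @param path Output path.
#' @export
write_dmdr_bed <- function(dmdrs, path) {
  parts <- regmatches(dmdrs$window,
                      regexec("^(.+):([0-9]+)-([0-9]+)$", dmdrs$window))
  bed <- data.frame(chrom = vapply(parts, `[`, "", 2L),
                    start = as.integer(vapply(parts, `[`, "", 3L)),
                    end = as.integer(vapply(parts, `[`, "", 4L)),
                    name = dmdrs$window,
                    score = pmin(1000, round(dmdrs$priority * 10)),
                    strand = ".",
                    stringsAsFactors = FALSE)
  .write_atomic(function(tmp) {
    write.table(bed, tmp, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }, path)
}
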