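#' Build a sliding-window grid over a probe manifest
#'
#' Windows are fixed genomic tiles of `size` bp anchored at every
#' non-negative multiple of `step` from coordinate 0 on each chromosome
#' (0-based half-open \[start, start+size)). A probe with 1-based position p
#' belongs to a window iff `start <= p-1 < start+size`; consecutive windows
#' overlap when `step < size` and a probe may belong to several. Only windows
#' holding at least `min_cpg` probes are retained.
#'
#' @param manifest Probe manifest sorted by (chrom, pos), as from
#'   [read_manifest()].
#' @param size Window width in bp (default 1000).
#' @param step Step between window starts in bp (default 500).
#' @param min_cpg Minimum member CpGs per retained window (default 3).
#' @return An object of class `lpmd_grid`: a list with `windows` (data.frame
#'   chrom, start, end, n_cpg), `members` (list of probe-id vectors) and the
#'   grid parameters.
#' @export
build_windows <- function(manifest, size = 1000, step = 500, min_cpg = 3) {
  if (step > size) .stopf("step (%d) > size (%d) would leave coverage gaps", step, size)
  idx0 <- manifest$pos - 1L                 # 0-based probe index
  k_lo <- ceiling((idx0 - size + 1) / step)
  k_lo <- pmax(k_lo, 0L)
  k_hi <- floor(idx0 / step)
  reps <- pmax(k_hi - k_lo + 1L, 0L)
  probe_row <- rep.int(seq_len(nrow(manifest)), reps)
  k <- unlist(lapply(seq_len(nrow(manifest)),
                     function(i) if (reps[i] > 0L) seq.int(k_lo[i], k_hi[i]) else integer()))
  start <- as.numeric(k) * step
  key <- paste0(manifest$chrom[probe_row], ":", start)
  members <- split(manifest$probe_id[probe_row], key)
  meta_chrom <- vapply(split(manifest$chrom[probe_row], key), `[`, "", 1L)
  meta_start <- vapply(split(start, key), `[`, 0, 1L)
  n_cpg <- lengths(members)
  keep <- n_cpg >= min_cpg
  members <- members[keep]
  if (!any(keep)) {
    return(structure(list(windows = data.frame(chrom = character(),
                                               start = numeric(),
                                               end = numeric(),
                                               n_cpg = integer()),
                          members = setNames(list(), character()),
                          size = size, step = step, min_cpg = min_cpg),
                     class = "lpmd_grid"))
  }
  win <- data.frame(chrom = meta_chrom[keep], start = meta_start[keep],
                    end = meta_start[keep] + size, n_cpg = n_cpg[keep],
                    stringsAsFactors = FALSE)
  ord <- order(win$chrom, win$start)
  win <- win[ord, , drop = FALSE]
  members <- members[ord]
  rownames(win) <- NULL
  names(members) <- paste0(win$chrom, ":", win$start, "-", win$end)
  structure(list(windows = win, members = members,
                 size = size, step = step, min_cpg = min_cpg),
            class = "lpmd_grid")
}

#' @export
print.lpmd_grid <- function(x, ...) {
  cat(sprintf("lpmd_grid: %d windows (%d bp, step %d, min %d CpGs) on %d chromosome(s)\n",
              nrow(x$windows), x$size, x$step, x$min_cpg,
              length(unique(x$windows$chrom))))
  invisible(x)
}

#' Per-window, per-sample summary statistics
#'
#' For every (window, sample) pair, computes the count of non-missing member
#' betas and their mean, median, sample SD (n-1), 75th and 90th percentiles
#' (linear interpolation, R type 7) and maximum. Entries with fewer than
#' `grid$min_cpg` valid CpGs are missing.
#'
#' @param beta Probes-by-samples beta matrix covering the grid's probes.
#' @param grid An `lpmd_grid`.
#' @return An object of class `lpmd_window_stats`: list of windows-by-samples
#'   matrices `n_valid`, `mean`, `median`, `sd`, `q75`, `q90`, `max`, plus the
#'   grid.
#' @export
window_stats <- function(beta, grid) {
  missing_probes <- setdiff(unique(unlist(grid$members)), rownames(beta))
  if (length(missing_probes)) {
    .stopf("beta matrix lacks %d probes referenced by the grid (e.g. %s)",
           length(missing_probes), missing_probes[1L])
  }
  nw <- nrow(grid$windows)
  ns <- ncol(beta)
  stat_names <- c("n_valid", "mean", "median", "sd", "q75", "q90", "max")
  tensor <- lapply(stat_names, function(.) {
    matrix(NA_real_, nw, ns, dimnames = list(names(grid$members), colnames(beta)))
  })
  names(tensor) <- stat_names
  # type-7 quantile on an already sorted vector
  q7 <- function(xs, n, p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, n)] - xs[lo])
  }
  for (w in seq_len(nw)) {
    sub <- beta[grid$members[[w]], , drop = FALSE]
    for (s in seq_len(ns)) {
      x <- sub[, s]
      x <- x[!is.na(x)]
      n <- length(x)
      tensor$n_valid[w, s] <- n
      if (n < grid$min_cpg) next
      xs <- sort.int(x, method = "quick")
      mu <- sum(xs) / n
      tensor$mean[w, s] <- mu
      tensor$median[w, s] <- q7(xs, n, 0.5)
      tensor$sd[w, s] <- sqrt(sum((xs - mu)^2) / (n - 1))
      tensor$q75[w, s] <- q7(xs, n, 0.75)
      tensor$q90[w, s] <- q7(xs, n, 0.90)
      tensor$max[w, s] <- xs[n]
    }
  }
  structure(c(tensor, list(grid = grid)), class = "lpmd_window_stats")
}

#' Window-level disorder (LPMD) matrix
#'
#' The per-window, per-sample disorder score is the within-window standard
#' deviation of beta values across member CpGs — high when neighbouring CpGs
#' disagree, zero when they are concordant. An alternative statistic from the
#' window tensor can be selected for sensitivity analysis.
#'
#' @param tensor An `lpmd_window_stats` object.
#' @param metric Which tensor statistic to use (default `"sd"`).
#' @return Windows-by-samples numeric matrix.
#' @export
window_lpmd <- function(tensor, metric = "sd") {
  stopifnot(inherits(tensor, "lpmd_window_stats"))
  if (!metric %in% c("mean", "median", "sd", "q75", "q90", "max")) {
    .stopf("unknown window metric '%s'", metric)
  }
  tensor[[metric]]
}

#' Genome-wide disorder metrics per sample
#'
#' Seven complementary metrics summarising each sample's window tensor:
#' `window_mean`, `window_median`, `window_q75`, `window_q90` and
#' `window_max` are the standard deviations (n-1), across a sample's valid
#' windows, of the per-window mean/median/q75/q90/max; `window_std` is the
#' mean of the per-window SDs. The seventh metric, `multiscale_lpmd`, is
#' computed by [multiscale_lpmd()] from the beta matrix directly since it
#' needs grids at several scales.
#'
#' @param tensor An `lpmd_window_stats` object.
#' @return Samples-by-6 numeric matrix. Samples with fewer than two valid
#'   windows get missing metrics with a warning.
#' @export
genome_metrics <- function(tensor) {
  stopifnot(inherits(tensor, "lpmd_window_stats"))
  samples <- colnames(tensor$mean)
  out <- matrix(NA_real_, length(samples), 6,
                dimnames = list(samples,
                                c("window_mean", "window_median", "window_std",
                                  "window_q75", "window_q90", "window_max")))
  for (s in seq_along(samples)) {
    ok <- !is.na(tensor$mean[, s])
    if (sum(ok) < 2L) {
      .warnf("sample %s has %d valid windows; genome metrics are missing",
             samples[s], sum(ok))
      next
    }
    out[s, "window_mean"] <- sd(tensor$mean[ok, s])
    out[s, "window_median"] <- sd(tensor$median[ok, s])
    out[s, "window_std"] <- mean(tensor$sd[ok, s])
    out[s, "window_q75"] <- sd(tensor$q75[ok, s])
    out[s, "window_q90"] <- sd(tensor$q90[ok, s])
    out[s, "window_max"] <- sd(tensor$max[ok, s])
  }
  out
}

#' Multiscale disorder metric
#'
#' Recomputes the per-sample base metric on window grids at several scales
#' (by default 500 bp, 1 kb and 2 kb, each with step = scale/2 and the same
#' CpG threshold) and returns their weighted average. Weights are normalised
#' to sum to one; a scale yielding no valid windows is dropped with a warning
#' and the remaining weights renormalised (per sample, over that sample's
#' non-missing scales).
#'
#' @param beta Probes-by-samples beta matrix.
#' @param manifest Probe manifest.
#' @param scales Window sizes in bp.
#' @param weights Non-negative weights, one per scale.
#' @param base_metric Genome metric to combine (default `"window_std"`).
#' @param min_cpg Minimum CpGs per window (default 3).
#' @return Named per-sample numeric vector.
#' @export
multiscale_lpmd <- function(beta, manifest, scales = c(500, 1000, 2000),
                            weights = c(0.25, 0.50, 0.25),
                            base_metric = "window_std", min_cpg = 3) {
  stopifnot(length(scales) == length(weights), all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  per_scale <- matrix(NA_real_, ncol(beta), length(scales),
                      dimnames = list(colnames(beta), as.character(scales)))
  for (i in seq_along(scales)) {
    grid <- build_windows(manifest, size = scales[i], step = scales[i] / 2,
                          min_cpg = min_cpg)
    if (nrow(grid$windows) == 0L) {
      .warnf("scale %d bp has no valid windows; dropped from multiscale average",
             scales[i])
      next
    }
    gm <- suppressWarnings(genome_metrics(window_stats(beta, grid)))
    per_scale[, i] <- gm[, base_metric]
  }
  apply(per_scale, 1L, function(v) {
    ok <- !is.na(v)
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * weights[ok]) / sum(weights[ok])
  })
}

#' Annotate windows with functional labels
#'
#' Each window gets a grouped functional-region label and a grouped
#' CpG-relation label by majority vote over its member probes, plus the union
#' of member-probe gene symbols. Probe classes are first collapsed to groups
#' (Promoter = TSS1500/TSS200; 5UTR_Exon1 = 5'UTR/first exon; GeneBody;
#' 3UTR; Other = enhancer/intergenic; Island; Shore = N/S shore; Shelf = N/S
#' shelf; OpenSea). Vote ties break by fixed precedence: Promoter >
#' 5UTR_Exon1 > GeneBody > 3UTR > Other, and Island > Shore > Shelf >
#' OpenSea.
#'
#' @param grid An `lpmd_grid`.
#' @param manifest The manifest the grid was built from.
#' @return A data.frame with one row per window: chrom, start, end,
#'   `feature_group`, `cpg_group` and a `genes` list-column.
#' @export
annotate_windows <- function(grid, manifest) {
  fg <- setNames(.feature_group(manifest$feature_class), manifest$probe_id)
  cg <- setNames(.cpg_group(manifest$cpg_relation), manifest$probe_id)
  gene_map <- setNames(manifest$genes, manifest$probe_id)

  vote <- function(labels, levels) {
    tab <- table(factor(labels, levels = levels))
    levels[which.max(tab)]   # which.max takes the first (highest precedence) on ties
  }
  feature_group <- vapply(grid$members, function(ids) vote(fg[ids], .feature_group_levels), "")
  cpg_group <- vapply(grid$members, function(ids) vote(cg[ids], .cpg_group_levels), "")
  genes <- lapply(grid$members, function(ids) sort(unique(unlist(gene_map[ids]))))
  out <- cbind(grid$windows[, c("chrom", "start", "end")],
               data.frame(feature_group = feature_group, cpg_group = cpg_group,
                          stringsAsFactors = FALSE))
  out$genes <- genes
  rownames(out) <- names(grid$members)
  out
}

#' Eleven-feature regional disorder summary per sample
#'
#' For each sample: the mean window-level disorder over windows in each of
#' eight genomic categories (CpG Island, Shore, Shelf from the window's
#' CpG-relation label; Promoter, 5'UTR/Exon 1, Gene Body, 3'UTR and Other
#' from its functional label), plus the 90th percentile and median of the
#' sample's window-level disorder distribution and the multiscale metric.
#' A category with no windows yields a missing feature.
#'
#' @param tensor An `lpmd_window_stats` object.
#' @param window_labels Output of [annotate_windows()] for the same grid.
#' @param multiscale_values Per-sample vector from [multiscale_lpmd()].
#' @return Samples-by-11 numeric matrix.
#' @export
region_features <- function(tensor, window_labels, multiscale_values) {
  lp <- window_lpmd(tensor)
  samples <- colnames(lp)
  cats <- list(lpmd_island = window_labels$cpg_group == "Island",
               lpmd_shore = window_labels$cpg_group == "Shore",
               lpmd_shelf = window_labels$cpg_group == "Shelf",
               lpmd_promoter = window_labels$feature_group == "Promoter",
               lpmd_5utr_exon1 = window_labels$feature_group == "5UTR_Exon1",
               lpmd_genebody = window_labels$feature_group == "GeneBody",
               lpmd_3utr = window_labels$feature_group == "3UTR",
               lpmd_other = window_labels$feature_group == "Other")
  out <- matrix(NA_real_, length(samples), 11,
                dimnames = list(samples,
                                c(names(cats), "p90_window_lpmd",
                                  "median_window_lpmd", "multiscale_lpmd")))
  for (j in seq_along(cats)) {
    sel <- cats[[j]]
    if (any(sel)) {
      out[, j] <- colMeans(lp[sel, , drop = FALSE], na.rm = TRUE)
    }
  }
  out[, "p90_window_lpmd"] <- apply(lp, 2L, function(v)
    if (all(is.na(v))) NA_real_ else quantile(v, 0.90, na.rm = TRUE, names = FALSE))
  out[, "median_window_lpmd"] <- apply(lp, 2L, median, na.rm = TRUE)
  out[, "multiscale_lpmd"] <- multiscale_values[samples]
  out[is.nan(out)] <- NA_real_
  out
}
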