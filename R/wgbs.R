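#' Read WGBS methylation calls
#'
#' Accepts two tab-delimited dialects, auto-detected by column count:
#' Bismark coverage files with six columns (chrom, start, end, methylation
#' percentage, methylated count, unmethylated count; 1-based inclusive
#' coordinates) and four-column tables (chrom, pos, methylated count, total
#' count). Files may or may not carry a header; a header is detected when the
#' position field of the first line is non-numeric.
#'
#' @param path Path to the calls file.
#' @return A data.frame with columns `chrom`, `pos` (1-based), `meth_reads`,
#'   `total_reads`.
#' @export
read_wgbs_calls <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  has_header <- length(first) >= 2L &&
    is.na(suppressWarnings(as.numeric(first[2L])))
  df <- read.delim(path, sep = "\t", header = has_header,
                   stringsAsFactors = FALSE)
  if (ncol(df) == 6L) {           # Bismark coverage
    out <- data.frame(chrom = as.character(df[[1L]]),
                      pos = as.integer(df[[2L]]),
                      meth_reads = as.integer(df[[5L]]),
                      total_reads = as.integer(df[[5L]]) + as.integer(df[[6L]]),
                      stringsAsFactors = FALSE)
  } else if (ncol(df) == 4L) {
    out <- data.frame(chrom = as.character(df[[1L]]),
                      pos = as.integer(df[[2L]]),
                      meth_reads = as.integer(df[[3L]]),
                      total_reads = as.integer(df[[4L]]),
                      stringsAsFactors = FALSE)
  } else {
    .stopf("unrecognised WGBS dialect: %d columns (expect 4 or 6)", ncol(df))
  }
  if (any(out$total_reads <= 0L)) .stopf("total_reads must be positive")
  if (any(out$meth_reads < 0L | out$meth_reads > out$total_reads)) {
    .stopf("meth_reads must lie in [0, total_reads]")
  }
  out
}

#' Aggregate WGBS calls to array probe positions
#'
#' For each manifest probe, pools CpG calls with at least `min_cov` total
#' reads whose position lies within `half_window` bp of the probe coordinate
#' (a 50 bp window by default), and computes beta as pooled methylated reads
#' over pooled total reads. Probes with no qualifying CpG are missing.
#'
#' @param calls MethCall data.frame from [read_wgbs_calls()].
#' @param manifest Probe manifest.
#' @param half_window Pooling half-width in bp (default 25).
#' @param min_cov Minimum per-CpG coverage (default 10).
#' @return Named numeric vector of beta values, one per manifest probe.
#' @export
aggregate_wgbs_to_probes <- function(calls, manifest, half_window = 25,
                                     min_cov = 10) {
  keep <- calls$total_reads >= min_cov
  calls <- calls[keep, , drop = FALSE]
  out <- setNames(rep(NA_real_, nrow(manifest)), manifest$probe_id)
  for (ch in unique(manifest$chrom)) {
    m_idx <- which(manifest$chrom == ch)
    c_sub <- calls[calls$chrom == ch, , drop = FALSE]
    if (!nrow(c_sub)) next
    ord <- order(c_sub$pos)
    cpos <- c_sub$pos[ord]
    cmeth <- cumsum(c(0, c_sub$meth_reads[ord]))
    ctot <- cumsum(c(0, c_sub$total_reads[ord]))
    lo <- findInterval(manifest$pos[m_idx] - half_window - 0.5, cpos)
    hi <- findInterval(manifest$pos[m_idx] + half_window + 0.5, cpos)
    tot <- ctot[hi + 1L] - ctot[lo + 1L]
    meth <- cmeth[hi + 1L] - cmeth[lo + 1L]
    out[m_idx] <- ifelse(tot > 0, meth / tot, NA_real_)
  }
  out
}
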