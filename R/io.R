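#' Read a beta-value matrix
#'
#' Reads a probes-by-samples table of methylation beta values (fractions in
#' \[0, 1\]). The first column holds probe ids, the header row sample ids.
#' Tokens `NA`, `NaN` and the empty string become missing values; any other
#' non-numeric token, or a numeric value outside \[0, 1\], is an error.
#'
#' @param path Path to a delimited text file.
#' @param delimiter Field separator; defaults to tab.
#' @return A numeric matrix with probe ids as rownames and sample ids as
#'   colnames.
#' @export
read_beta_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  raw <- read.delim(path, sep = delimiter, header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    na.strings = NULL)
  if (ncol(raw) < 2L) .stopf("malformed header in %s: need probe id column plus >=1 sample", path)
  probe_ids <- raw[[1L]]
  if (anyDuplicated(probe_ids)) .stopf("duplicate probe ids in %s", path)
  sample_ids <- colnames(raw)[-1L]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  is_na_tok <- matrix(vals %in% .na_tokens, nrow = nrow(vals))
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad_tok <- which(is.na(num) & !is_na_tok, arr.ind = TRUE)
  if (nrow(bad_tok) > 0L) {
    .stopf("non-numeric value '%s' at probe %s, sample %s",
           vals[bad_tok[1L, 1L], bad_tok[1L, 2L]],
           probe_ids[bad_tok[1L, 1L]], sample_ids[bad_tok[1L, 2L]])
  }
  num[is_na_tok] <- NA_real_
  bad_rng <- which(!is.na(num) & (num < 0 | num > 1), arr.ind = TRUE)
  if (nrow(bad_rng) > 0L) {
    .stopf("beta value %s outside [0,1] at probe %s, sample %s",
           format(num[bad_rng[1L, 1L], bad_rng[1L, 2L]]),
           probe_ids[bad_rng[1L, 1L]], sample_ids[bad_rng[1L, 2L]])
  }
  dimnames(num) <- list(probe_ids, sample_ids)
  num
}

#' Write a beta-value matrix
#'
#' Inverse of [read_beta_matrix()]; full-precision values, atomic write.
#'
#' @param beta Numeric matrix with probe rownames and sample colnames.
#' @param path Output path.
#' @param delimiter Field separator.
#' @export
write_beta_matrix <- function(beta, path, delimiter = "\t") {
  df <- data.frame(probe_id = rownames(beta),
                   format(beta, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[-1L][is.na(beta)] <- "NA"
  .write_atomic(function(tmp) {
    write.table(df, tmp, sep = delimiter, quote = FALSE, row.names = FALSE)
  }, path)
}

#' Read a 450K-style probe manifest
#'
#' Expects a delimited table with columns `probe_id`, `chrom`, `pos` (1-based
#' CpG coordinate), `feature_class` (one of TSS1500, TSS200, 5UTR, Exon1,
#' Body, 3UTR, Enhancer, Intergenic), `cpg_relation` (Island, N_Shore,
#' S_Shore, N_Shelf, S_Shelf, OpenSea) and `genes` (semicolon-separated,
#' possibly empty). Rows are sorted by (chrom, pos) on load; the sort is
#' stable for equal keys.
#'
#' @param path Path to the manifest TSV.
#' @return A data.frame with a list-column `genes`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character", check.names = FALSE,
                   na.strings = NULL)
  need <- c("probe_id", "chrom", "pos", "feature_class", "cpg_relation", "genes")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols)) .stopf("manifest missing columns: %s", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$probe_id)) .stopf("duplicate probe ids in manifest")
  pos <- suppressWarnings(as.integer(df$pos))
  if (anyNA(pos) || any(pos < 1L)) .stopf("manifest pos must be integers >= 1")
  bad_f <- setdiff(unique(df$feature_class), .manifest_feature_levels)
  if (length(bad_f)) {
    .stopf("unknown feature_class '%s'; allowed: %s", bad_f[1L],
           paste(.manifest_feature_levels, collapse = ", "))
  }
  bad_c <- setdiff(unique(df$cpg_relation), .manifest_cpg_levels)
  if (length(bad_c)) {
    .stopf("unknown cpg_relation '%s'; allowed: %s", bad_c[1L],
           paste(.manifest_cpg_levels, collapse = ", "))
  }
  out <- data.frame(probe_id = df$probe_id, chrom = df$chrom, pos = pos,
                    feature_class = df$feature_class,
                    cpg_relation = df$cpg_relation,
                    stringsAsFactors = FALSE)
  out$genes <- lapply(strsplit(df$genes, ";", fixed = TRUE),
                      function(g) g[nzchar(g)])
  ord <- order(out$chrom, out$pos)  # stable radix/shell order
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a probe manifest
#'
#' @param manifest Manifest data.frame as returned by [read_manifest()].
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  df <- manifest
  df$genes <- vapply(manifest$genes, paste, "", collapse = ";")
  .write_atomic(function(tmp) {
    write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  }, path)
}

#' Read a sample sheet
#'
#' Requires a `sample_id` column; recognised optional columns are
#' `patient_id`, `group` (mutant/wildtype), `response`
#' (responder/non_responder), `months_on_treatment` and `is_diagnosis`.
#'
#' @param path Path to a TSV.
#' @return A data.frame keyed by unique `sample_id`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = .na_tokens)
  if (!"sample_id" %in% colnames(df)) .stopf("sample sheet needs a sample_id column")
  if (anyDuplicated(df$sample_id)) .stopf("duplicate sample ids in sample sheet")
  if ("group" %in% colnames(df)) {
    bad <- setdiff(na.omit(unique(df$group)), c("mutant", "wildtype"))
    if (length(bad)) .stopf("unknown group label '%s'; allowed: mutant, wildtype", bad[1L])
  }
  if ("response" %in% colnames(df)) {
    bad <- setdiff(na.omit(unique(df$response)), c("responder", "non_responder"))
    if (length(bad)) .stopf("unknown response label '%s'; allowed: responder, non_responder", bad[1L])
  }
  if ("months_on_treatment" %in% colnames(df) &&
      any(df$months_on_treatment < 0, na.rm = TRUE)) {
    .stopf("months_on_treatment must be non-negative")
  }
  df
}

#' Array-style probe quality-control filter
#'
#' Applies the standard 450K probe filters: detection p-value, missingness,
#' known SNP-associated probes and sex-chromosome probes. Rules are applied
#' in that order and each probe is attributed to the first rule that removes
#' it; the order of the remaining probes is preserved.
#'
#' @param beta Probes-by-samples beta matrix.
#' @param detection_p Optional matrix of detection p-values, same shape as
#'   `beta`.
#' @param manifest Probe manifest (used for chromosome lookup).
#' @param max_missing_frac Drop probes missing in more than this fraction of
#'   samples (default 0.05).
#' @param detection_threshold Detection p-value cutoff (default 0.01).
#' @param detection_mode `"any"` drops a probe whose detection p exceeds the
#'   threshold in any sample; `"frac:<x>"` drops it when the failing fraction
#'   exceeds `x`.
#' @param drop_snp_probes Character vector of SNP-associated probe ids.
#' @param drop_sex_chroms Remove chrX/chrY probes (default TRUE).
#' @return A list with `beta` (filtered matrix), `removal_counts` (named
#'   integer vector per rule) and `removed_probes` (named list of probe ids).
#' @export
qc_filter <- function(beta, detection_p = NULL, manifest,
                      max_missing_frac = 0.05, detection_threshold = 0.01,
                      detection_mode = "any",
                      drop_snp_probes = character(), drop_sex_chroms = TRUE) {
  probes <- rownames(beta)
  drop <- setNames(rep(FALSE, length(probes)), probes)
  attributed <- setNames(rep(NA_character_, length(probes)), probes)

  mark <- function(ids, rule) {
    new <- ids[!drop[ids]]
    drop[new] <<- TRUE
    attributed[new] <<- rule
  }

  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(beta))) {
      .stopf("detection_p must have the same shape as beta")
    }
    fail <- detection_p > detection_threshold
    fail[is.na(fail)] <- FALSE
    if (identical(detection_mode, "any")) {
      bad <- rowSums(fail) > 0L
    } else if (grepl("^frac:", detection_mode)) {
      fr <- as.numeric(sub("^frac:", "", detection_mode))
      bad <- rowMeans(fail) > fr
    } else {
      .stopf("detection_mode must be 'any' or 'frac:<x>'")
    }
    mark(probes[bad], "detection_p")
  }

  miss_frac <- rowMeans(is.na(beta))
  mark(probes[miss_frac > max_missing_frac], "missingness")

  if (length(drop_snp_probes)) {
    unknown <- setdiff(drop_snp_probes, probes)
    if (length(unknown)) {
      .warnf("%d SNP-list probes not present in beta matrix", length(unknown))
    }
    mark(intersect(drop_snp_probes, probes), "snp")
  }

  if (drop_sex_chroms) {
    chrom <- manifest$chrom[match(probes, manifest$probe_id)]
    sex <- probes[!is.na(chrom) & .is_sex_chrom(chrom)]
    mark(sex, "sex_chrom")
  }

  rules <- c("detection_p", "missingness", "snp", "sex_chrom")
  counts <- vapply(rules, function(r) sum(attributed == r, na.rm = TRUE), 0L)
  list(beta = beta[!drop, , drop = FALSE],
       removal_counts = counts,
       removed_probes = lapply(setNames(rules, rules),
                               function(r) probes[!is.na(attributed) & attributed == r]))
}
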