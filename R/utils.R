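## internal helpers shared across modules

# tokens treated as missing in all tabular inputs
.na_tokens <- c("NA", "NaN", "")

.manifest_feature_levels <- c("TSS1500", "TSS200", "5UTR", "Exon1",
                              "Body", "3UTR", "Enhancer", "Intergenic")
.manifest_cpg_levels <- c("Island", "N_Shore", "S_Shore",
                          "N_Shelf", "S_Shelf", "OpenSea")

# grouped labels used for window annotation and the regional feature vector
.feature_group_levels <- c("Promoter", "5UTR_Exon1", "GeneBody", "3UTR", "Other")
.cpg_group_levels <- c("Island", "Shore", "Shelf", "OpenSea")

.feature_group <- function(feature_class) {
  out <- rep(NA_character_, length(feature_class))
  out[feature_class %in% c("TSS1500", "TSS200")] <- "Promoter"
  out[feature_class %in% c("5UTR", "Exon1")] <- "5UTR_Exon1"
  out[feature_class == "Body"] <- "GeneBody"
  out[feature_class == "3UTR"] <- "3UTR"
  out[feature_class %in% c("Enhancer", "Intergenic")] <- "Other"
  out
}

.cpg_group <- function(cpg_relation) {
  out <- rep(NA_character_, length(cpg_relation))
  out[cpg_relation == "Island"] <- "Island"
  out[cpg_relation %in% c("N_Shore", "S_Shore")] <- "Shore"
  out[cpg_relation %in% c("N_Shelf", "S_Shelf")] <- "Shelf"
  out[cpg_relation == "OpenSea"] <- "OpenSea"
  out
}

.is_sex_chrom <- function(chrom) {
  toupper(sub("^chr", "", chrom, ignore.case = TRUE)) %in% c("X", "Y")
}

# atomic write: tempfile in the target directory, then rename
.write_atomic <- function(writer, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {  # cross-device fallback
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
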