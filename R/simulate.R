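#' Simulation specification
#'
#' Bundles the parameters of the synthetic methylome generator. Defaults
#' mirror the study conditions the analysis modules target: a 15 mutant vs 53
#' wild-type cohort, beta values drawn per CpG from a Beta distribution
#' parameterised by a per-block mean and a per-group concentration kappa
#' (lower kappa = higher within-window SD = more disorder, independent of
#' methylation level), CpG-dense island blocks at gene promoters, and a
#' five-timepoint longitudinal design with a step decrease in disorder at the
#' 3-5 month bin.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length_bp Length of each chromosome.
#' @param spacing_bp Mean background CpG spacing (exponential gaps).
#' @param island_spacing_bp Mean CpG spacing inside islands.
#' @param n_mutant,n_wildtype Cohort group sizes.
#' @param kappa_wt,kappa_mut Beta concentration per group (kappa_mut defaults
#'   to kappa_wt: a null cohort).
#' @param sample_kappa_sdlog SD (log scale) of the per-sample multiplicative
#'   kappa factor.
#' @param block_sample_sdlog SD (log scale) of per-(sample, block) kappa
#'   noise; creates between-sample feature variance for response modelling.
#' @param block_size Generation-block width in bp; each block gets one mean
#'   beta and one kappa per group. Blocks are disjoint, unlike analysis
#'   windows.
#' @param implanted_dmdrs Optional data.frame (chrom, start, end,
#'   kappa_ratio): blocks overlapping a span get `kappa_mut = kappa_ratio *
#'   kappa_wt` in the mutant group (ratio < 1 = increased disorder).
#' @param response_model Optional list (`windows`: data.frame chrom, start,
#'   end; `coefficients`; `intercept`) generating a responder label from the
#'   per-sample latent disorder at those blocks.
#' @param longitudinal List with `n_patients`, `bin_n` (samples per
#'   timepoint bin) and `bin_lpmd_factors` (multiplicative disorder level per
#'   bin relative to diagnosis).
#' @param depth_mean Mean WGBS coverage for [simulate_wgbs()].
#' @return A list of class `lpmd_sim_spec`.
#' @export
simulation_spec <- function(n_chrom = 2,
                            chrom_length_bp = 125000,
                            spacing_bp = 150,
                            island_spacing_bp = 30,
                            n_mutant = 15,
                            n_wildtype = 53,
                            kappa_wt = 8,
                            kappa_mut = kappa_wt,
                            sample_kappa_sdlog = 0.15,
                            block_sample_sdlog = 0,
                            block_size = 1000,
                            implanted_dmdrs = NULL,
                            response_model = NULL,
                            longitudinal = list(
                              n_patients = 73,
                              bin_n = c(73, 17, 24, 19, 20),
                              bin_lpmd_factors = c(1, 0.994, 0.963, 0.965, 0.968)),
                            depth_mean = 25) {
  stopifnot(kappa_wt > 0, kappa_mut > 0, spacing_bp > 0, block_size > 0)
  if (!is.null(implanted_dmdrs)) {
    stopifnot(all(c("chrom", "start", "end", "kappa_ratio") %in%
                    colnames(implanted_dmdrs)),
              all(implanted_dmdrs$kappa_ratio > 0))
  }
  structure(as.list(environment()), class = "lpmd_sim_spec")
}

#' Simulate a probe manifest
#'
#' Lays out a deterministic gene/island architecture (one gene every 10 kb,
#' a CpG island of +/- 500 bp around each TSS, shores and shelves in 2 kb
#' bands beyond it, an enhancer block downstream of each gene) and draws CpG
#' positions with exponential gaps: dense inside islands, sparse elsewhere.
#'
#' @param spec An `lpmd_sim_spec`.
#' @param seed Mandatory RNG seed.
#' @return A manifest data.frame as from [read_manifest()].
#' @export
simulate_manifest <- function(spec, seed) {
  if (missing(seed)) .stopf("simulate_manifest requires an explicit seed")
  set.seed(seed)
  rows <- list()
  for (ci in seq_len(spec$n_chrom)) {
    chrom <- paste0("chr", ci)
    L <- spec$chrom_length_bp
    # genes every 10 kb; the +/-500 bp island around each TSS then spans one
    # 1 kb generation block exactly ([g-500, g+500) with g at x5500)
    gene_starts <- seq(5500, L - 6500, by = 10000)
    island <- cbind(gene_starts - 500, gene_starts + 500)
    in_island <- function(p) {
      any(p >= island[, 1] & p < island[, 2])
    }
    pos <- integer(0)
    p <- 1 + floor(runif(1, 0, spec$spacing_bp))
    while (p <= L) {
      pos <- c(pos, p)
      gap_mean <- if (in_island(p)) spec$island_spacing_bp else spec$spacing_bp
      p <- p + 1L + as.integer(rexp(1, 1 / gap_mean))
    }
    # CpG relation from distance to nearest island
    dist_signed <- vapply(pos, function(q) {
      d <- ifelse(q < island[, 1], island[, 1] - q,
                  ifelse(q >= island[, 2], q - island[, 2] + 1L, 0L))
      side <- ifelse(q < island[, 1], -1L, 1L)
      i <- which.min(d)
      d[i] * side[i]
    }, 0)
    ad <- abs(dist_signed)
    cpg_relation <- ifelse(ad == 0, "Island",
                           ifelse(ad <= 2000, ifelse(dist_signed < 0, "N_Shore", "S_Shore"),
                                  ifelse(ad <= 4000, ifelse(dist_signed < 0, "N_Shelf", "S_Shelf"),
                                         "OpenSea")))
    # functional class from position relative to the nearest gene
    feature_class <- rep("Intergenic", length(pos))
    genes <- vector("list", length(pos))
    for (k in seq_along(pos)) genes[[k]] <- character()
    for (gi in seq_along(gene_starts)) {
      g <- gene_starts[gi]
      gene_name <- sprintf("GENE%d_%02d", ci, gi)
      zones <- rbind(c(g - 1500, g - 200, 1), c(g - 200, g, 2),
                     c(g, g + 200, 3), c(g + 200, g + 500, 4),
                     c(g + 500, g + 4500, 5), c(g + 4500, g + 5000, 6))
      zone_class <- c("TSS1500", "TSS200", "5UTR", "Exon1", "Body", "3UTR")
      for (z in seq_len(nrow(zones))) {
        hit <- pos >= zones[z, 1] & pos < zones[z, 2]
        feature_class[hit] <- zone_class[z]
        for (k in which(hit)) genes[[k]] <- union(genes[[k]], gene_name)
      }
      enh <- pos >= g + 6500 & pos < g + 7000
      feature_class[enh] <- "Enhancer"
    }
    rows[[ci]] <- data.frame(chrom = chrom, pos = as.integer(pos),
                             feature_class = feature_class,
                             cpg_relation = cpg_relation,
                             stringsAsFactors = FALSE)
    rows[[ci]]$genes <- genes
  }
  out <- do.call(rbind, rows)
  out <- data.frame(probe_id = sprintf("cg%07d", seq_len(nrow(out))),
                    out, stringsAsFactors = FALSE)
  ord <- order(out$chrom, out$pos)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# block index (0-based start of generation block) per probe
.block_of <- function(manifest, block_size) {
  paste0(manifest$chrom, ":", (manifest$pos - 1L) %/% block_size * block_size)
}

# kappa_ratio per block from implant table (1 where no implant)
.implant_ratio <- function(blocks, manifest, spec) {
  ratio <- setNames(rep(1, length(blocks)), blocks)
  if (is.null(spec$implanted_dmdrs)) return(ratio)
  block_start <- as.numeric(sub("^.*:", "", blocks))
  block_chrom <- sub(":.*$", "", blocks)
  for (r in seq_len(nrow(spec$implanted_dmdrs))) {
    im <- spec$implanted_dmdrs[r, ]
    hit <- block_chrom == im$chrom &
      block_start < im$end & (block_start + spec$block_size) > im$start
    ratio[hit] <- im$kappa_ratio
  }
  ratio
}

#' Simulate a two-group methylation cohort
#'
#' Per disjoint generation block, draws a mean beta `mu`; per sample and CpG,
#' draws `beta ~ Beta(mu * kappa, (1 - mu) * kappa)` where kappa combines the
#' group concentration (`kappa_wt` / `kappa_mut`, the latter scaled by
#' `kappa_ratio` in implanted blocks), a per-sample lognormal factor and
#' optional per-(sample, block) lognormal noise. Lower kappa means higher
#' within-window SD, i.e. more disorder. When `spec$response_model` is set, a
#' responder label is drawn from a logistic model on the per-sample latent
#' (log-kappa) disorder at the model's blocks.
#'
#' @param manifest Manifest from [simulate_manifest()].
#' @param spec An `lpmd_sim_spec`.
#' @param seed Mandatory RNG seed.
#' @return List with `beta` (matrix), `sheet` (sample sheet data.frame) and
#'   `truth` (block means, implanted block keys, response probabilities).
#' @export
simulate_cohort <- function(manifest, spec, seed) {
  if (missing(seed)) .stopf("simulate_cohort requires an explicit seed")
  set.seed(seed)
  n <- spec$n_mutant + spec$n_wildtype
  sample_ids <- sprintf("S%03d", seq_len(n))
  group <- c(rep("mutant", spec$n_mutant), rep("wildtype", spec$n_wildtype))

  probe_block <- .block_of(manifest, spec$block_size)
  blocks <- unique(probe_block)
  mu <- setNames(0.05 + 0.9 * rbeta(length(blocks), 2, 2), blocks)
  ratio <- .implant_ratio(blocks, manifest, spec)
  kappa_group <- rbind(mutant = spec$kappa_mut * ratio,
                       wildtype = rep(spec$kappa_wt, length(blocks)))
  colnames(kappa_group) <- blocks
  sample_factor <- rlnorm(n, 0, spec$sample_kappa_sdlog)

  bs_noise <- if (spec$block_sample_sdlog > 0) {
    matrix(rlnorm(length(blocks) * n, 0, spec$block_sample_sdlog),
           length(blocks), n, dimnames = list(blocks, sample_ids))
  } else {
    matrix(1, length(blocks), n, dimnames = list(blocks, sample_ids))
  }

  bi <- match(probe_block, blocks)
  beta <- matrix(NA_real_, nrow(manifest), n,
                 dimnames = list(manifest$probe_id, sample_ids))
  for (s in seq_len(n)) {
    kappa <- kappa_group[group[s], bi] * sample_factor[s] * bs_noise[bi, s]
    mu_p <- mu[bi]
    beta[, s] <- rbeta(nrow(manifest), mu_p * kappa, (1 - mu_p) * kappa)
  }

  sheet <- data.frame(sample_id = sample_ids, patient_id = sample_ids,
                      group = group, stringsAsFactors = FALSE)
  resp_prob <- NULL
  if (!is.null(spec$response_model)) {
    rm <- spec$response_model
    keys <- paste0(rm$windows$chrom, ":", rm$windows$start)
    if (!all(keys %in% blocks)) .stopf("response-model windows must align to generation blocks")
    # latent disorder = -log of the block-specific kappa deviation (higher =
    # more disorder at that block); the global per-sample factor is excluded
    # so the response signal is localised to the model's blocks
    latent <- -log(bs_noise[keys, , drop = FALSE])
    z <- t(scale(t(latent)))
    eta <- drop(rm$intercept + crossprod(z, rm$coefficients))
    resp_prob <- plogis(eta)
    sheet$response <- ifelse(runif(n) < resp_prob, "responder", "non_responder")
  }

  implanted <- if (is.null(spec$implanted_dmdrs)) character() else {
    names(ratio)[ratio != 1]
  }
  list(beta = beta, sheet = sheet,
       truth = list(block_mu = mu, implanted_blocks = implanted,
                    response_prob = resp_prob, sample_factor = sample_factor))
}

#' Simulate a longitudinal treatment cohort
#'
#' Every patient contributes a diagnosis sample; later timepoint bins sample
#' random patient subsets of the configured sizes. Disorder follows the
#' per-bin multiplicative trajectory in `spec$longitudinal$bin_lpmd_factors`
#' (a factor r on the disorder scale is implemented as kappa / r^2, since the
#' within-block beta SD is ~ 1/sqrt(kappa + 1)), on top of a per-patient
#' lognormal disorder offset.
#'
#' @param manifest Manifest from [simulate_manifest()].
#' @param spec An `lpmd_sim_spec`.
#' @param seed Mandatory RNG seed.
#' @return List with `beta` and `sheet` (columns sample_id, patient_id,
#'   months_on_treatment, is_diagnosis, timepoint_bin).
#' @export
simulate_longitudinal <- function(manifest, spec, seed) {
  if (missing(seed)) .stopf("simulate_longitudinal requires an explicit seed")
  set.seed(seed)
  lg <- spec$longitudinal
  stopifnot(length(lg$bin_n) == 5L, length(lg$bin_lpmd_factors) == 5L)
  patients <- sprintf("P%03d", seq_len(lg$n_patients))
  rep_months <- c(NA, 1.5, 4, 8, 14)

  sheet <- list()
  for (b in seq_len(5L)) {
    nb <- min(lg$bin_n[b], lg$n_patients)
    pb <- if (b == 1L) patients[seq_len(nb)] else sample(patients, nb)
    sheet[[b]] <- data.frame(patient_id = pb,
                             bin_idx = b,
                             months_on_treatment = rep_months[b],
                             is_diagnosis = b == 1L,
                             stringsAsFactors = FALSE)
  }
  sheet <- do.call(rbind, sheet)
  sheet$sample_id <- sprintf("L%03d", seq_len(nrow(sheet)))
  sheet$timepoint_bin <- .timepoint_levels[sheet$bin_idx]

  probe_block <- .block_of(manifest, spec$block_size)
  blocks <- unique(probe_block)
  mu <- setNames(0.05 + 0.9 * rbeta(length(blocks), 2, 2), blocks)
  bi <- match(probe_block, blocks)
  patient_factor <- setNames(rlnorm(lg$n_patients, 0, spec$sample_kappa_sdlog),
                             patients)

  beta <- matrix(NA_real_, nrow(manifest), nrow(sheet),
                 dimnames = list(manifest$probe_id, sheet$sample_id))
  for (i in seq_len(nrow(sheet))) {
    r <- lg$bin_lpmd_factors[sheet$bin_idx[i]]
    kappa <- spec$kappa_wt / r^2 * patient_factor[sheet$patient_id[i]]
    beta[, i] <- rbeta(nrow(manifest), mu[bi] * kappa, (1 - mu[bi]) * kappa)
  }
  sheet$bin_idx <- NULL
  list(beta = beta, sheet = sheet[, c("sample_id", "patient_id",
                                      "months_on_treatment", "is_diagnosis",
                                      "timepoint_bin")])
}

#' Simulate WGBS read counts from a beta profile
#'
#' Per CpG, total reads ~ Poisson(depth_mean) floored at 1, methylated reads
#' ~ Binomial(total, beta). Probes with missing beta are skipped.
#'
#' @param manifest Manifest supplying CpG coordinates.
#' @param beta_column Named per-probe beta vector.
#' @param depth_mean Mean coverage (default 25).
#' @param seed Mandatory RNG seed.
#' @return MethCall data.frame (chrom, pos, meth_reads, total_reads).
#' @export
simulate_wgbs <- function(manifest, beta_column, depth_mean = 25, seed) {
  if (missing(seed)) .stopf("simulate_wgbs requires an explicit seed")
  set.seed(seed)
  b <- beta_column[manifest$probe_id]
  ok <- !is.na(b)
  total <- pmax(1L, rpois(sum(ok), depth_mean))
  meth <- rbinom(sum(ok), total, b[ok])
  data.frame(chrom = manifest$chrom[ok], pos = manifest$pos[ok],
             meth_reads = meth, total_reads = total,
             stringsAsFactors = FALSE)
}

#' Write WGBS calls in Bismark coverage format
#'
#' Six tab-separated columns: chrom, start, end (1-based inclusive),
#' methylation percentage, methylated count, unmethylated count.
#'
#' @param calls MethCall data.frame.
#' @param path Output path.
#' @export
write_wgbs_cov <- function(calls, path) {
  df <- data.frame(calls$chrom, calls$pos, calls$pos,
                   100 * calls$meth_reads / calls$total_reads,
                   calls$meth_reads, calls$total_reads - calls$meth_reads)
  .write_atomic(function(tmp) {
    write.table(df, tmp, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }, path)
}
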