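test_that("window tiling keeps dense tiles and drops sparse ones", {
  mf <- make_manifest("chr1", c(100, 400, 900))
  grid <- build_windows(mf, size = 1000, step = 500, min_cpg = 3)
  expect_identical(nrow(grid$windows), 1L)
  expect_identical(grid$windows$start, 0)
  expect_identical(grid$members[[1]], mf$probe_id)   # [500,1500) has 1 probe only

  # coordinate rule: 1-based pos p is member of [s, s+size) iff s <= p-1 <
  # s+size, so pos 1000 (0-based 999) sits in [0,1000) and [500,1500)
  mf2 <- make_manifest("chr1", 1000)
  g2 <- build_windows(mf2, size = 1000, step = 500, min_cpg = 1)
  expect_setequal(names(g2$members), c("chr1:0-1000", "chr1:500-1500"))
  # ... while pos 1001 (index 1000) opens [1000,2000) and leaves [0,1000)
  mf3 <- make_manifest("chr1", 1001)
  g3 <- build_windows(mf3, size = 1000, step = 500, min_cpg = 1)
  expect_setequal(names(g3$members), c("chr1:500-1500", "chr1:1000-2000"))

  expect_error(build_windows(mf, step = 2000), "gaps")
  # threshold above density empties the grid
  g_empty <- build_windows(make_manifest("chr1", c(100, 300)), min_cpg = 3)
  expect_identical(nrow(g_empty$windows), 0L)
})

test_that("window count is monotone non-increasing in min_cpg and nested in step", {
  set.seed(7)
  mf <- make_manifest("chr1", sort(sample(1:20000, 80)))
  counts <- vapply(1:6, function(k) nrow(build_windows(mf, min_cpg = k)$windows), 0L)
  expect_true(all(diff(counts) <= 0))
  coarse <- build_windows(mf, size = 1000, step = 1000, min_cpg = 3)
  fine <- build_windows(mf, size = 1000, step = 500, min_cpg = 3)
  expect_true(all(names(coarse$members) %in% names(fine$members)))
})

test_that("window statistics match hand values and the brute-force oracle", {
  mf <- make_manifest("chr1", c(100, 400, 900))
  beta <- make_beta(mf, c(0.2, 0.4, 0.6))
  ws <- window_stats(beta, build_windows(mf))
  expect_equal(ws$mean[1, 1], 0.4)
  expect_equal(ws$median[1, 1], 0.4)
  expect_equal(ws$sd[1, 1], 0.2)
  expect_equal(ws$max[1, 1], 0.6)

  # constant window: sd 0, all location stats equal the constant
  beta_c <- make_beta(mf, rep(0.3, 3))
  wc <- window_stats(beta_c, build_windows(mf))
  expect_equal(wc$sd[1, 1], 0)
  expect_equal(unname(c(wc$mean[1, 1], wc$median[1, 1], wc$q75[1, 1],
                        wc$q90[1, 1], wc$max[1, 1])), rep(0.3, 5))

  # a missing CpG invalidates the entry at min_cpg = 3
  beta_na <- beta
  beta_na[2, 1] <- NA
  wn <- window_stats(beta_na, build_windows(mf))
  expect_true(is.na(wn$mean[1, 1]))
  expect_equal(wn$n_valid[1, 1], 2)

  # oracle equivalence over 100 random small fixtures
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    mfr <- make_manifest(sample(c("chr1", "chr2"), 1), sort(sample(1:6000, n)))
    b <- make_beta(mfr, ifelse(runif(n * 3) < 0.1, NA, runif(n * 3)),
                   c("A", "B", "C"))
    size <- sample(c(500, 1000), 1)
    got <- window_stats(b, build_windows(mfr, size = size, step = size / 2, min_cpg = 2))
    want <- oracle_window_stats(mfr, b, size, size / 2, 2)
    expect_setequal(rownames(got$mean), names(want))
    for (key in names(want)) {
      for (st in c("mean", "median", "sd", "q75", "q90", "max")) {
        expect_equal(unname(got[[st]][key, ]), unname(want[[key]][st, ]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("genome metrics reduce the tensor as documented", {
  # two windows with means 0.2 and 0.6 -> window_mean = sd(c(.2,.6))
  mf <- make_manifest("chr1", c(100, 200, 300, 1100, 1200, 1300))
  beta <- make_beta(mf, c(0.1, 0.2, 0.3, 0.5, 0.6, 0.7))
  ws <- window_stats(beta, build_windows(mf, size = 1000, step = 1000))
  gm <- genome_metrics(ws)
  expect_equal(unname(gm[1, "window_mean"]), sd(c(0.2, 0.6)))
  expect_equal(unname(gm[1, "window_std"]), mean(c(sd(c(.1, .2, .3)), sd(c(.5, .6, .7)))))

  # identical windows: across-window SDs vanish, window_std = common sd
  beta2 <- make_beta(mf, rep(c(0.1, 0.2, 0.6), 2))
  gm2 <- genome_metrics(window_stats(beta2, build_windows(mf, size = 1000, step = 1000)))
  expect_equal(unname(gm2[1, "window_mean"]), 0)
  expect_equal(unname(gm2[1, "window_std"]), sd(c(0.1, 0.2, 0.6)))

  # fewer than two valid windows -> missing with warning
  expect_warning(gm3 <- genome_metrics(window_stats(beta[1:3, , drop = FALSE],
                                                    build_windows(mf[1:3, ], size = 1000, step = 1000))),
                 "valid windows")
  expect_true(all(is.na(gm3)))
})

test_that("metrics are invariant to window/sample order and equivariant in scale", {
  set.seed(3)
  mf <- make_manifest("chr1", sort(sample(1:15000, 60)))
  beta <- make_beta(mf, runif(60 * 4, 0.2, 0.6), c("A", "B", "C", "D"))
  grid <- build_windows(mf)
  gm <- genome_metrics(window_stats(beta, grid))
  # sample reorder
  gm_perm <- genome_metrics(window_stats(beta[, c(3, 1, 4, 2)], grid))
  expect_equal(gm_perm[rownames(gm), ], gm)
  # shifting betas leaves SD-based metrics unchanged; scaling scales them
  gm_shift <- genome_metrics(window_stats(beta + 0.1, grid))
  sd_cols <- c("window_mean", "window_median", "window_std", "window_q75",
               "window_q90")
  expect_equal(gm_shift[, sd_cols], gm[, sd_cols], tolerance = 1e-12)
  gm_scaled <- genome_metrics(window_stats(beta * 0.5, grid))
  expect_equal(gm_scaled[, sd_cols], 0.5 * gm[, sd_cols], tolerance = 1e-12)
})

test_that("multiscale combination is a convex average of per-scale metrics", {
  set.seed(5)
  mf <- make_manifest("chr1", sort(sample(1:20000, 120)))
  beta <- make_beta(mf, runif(120 * 2), c("A", "B"))
  # degenerate weights pick out a single scale exactly
  ms500 <- multiscale_lpmd(beta, mf, weights = c(1, 0, 0))
  gm500 <- genome_metrics(window_stats(beta, build_windows(mf, 500, 250)))
  expect_equal(ms500, gm500[, "window_std"])
  # equal metric at all scales returns that value for any weights
  per_scale <- sapply(c(500, 1000, 2000), function(sc)
    genome_metrics(window_stats(beta, build_windows(mf, sc, sc / 2)))[, "window_std"])
  ms <- multiscale_lpmd(beta, mf)
  expect_true(all(ms >= apply(per_scale, 1, min) - 1e-12 &
                    ms <= apply(per_scale, 1, max) + 1e-12))
  expect_equal(unname(ms), unname(drop(per_scale %*% c(0.25, 0.5, 0.25))))
})

test_that("window annotation votes with fixed tie precedence", {
  mf <- make_manifest("chr1", c(100, 200, 300),
                      feature_class = c("TSS200", "TSS200", "Body"),
                      cpg_relation = c("Island", "N_Shore", "S_Shore"),
                      genes = list("G1", c("G1", "G2"), character()))
  lab <- annotate_windows(build_windows(mf), mf)
  expect_identical(lab$feature_group, "Promoter")      # 2-1 majority
  expect_identical(lab$cpg_group, "Shore")             # shores merge: 2-1
  expect_identical(lab$genes[[1]], c("G1", "G2"))

  mf2 <- make_manifest("chr1", c(100, 200, 300, 400),
                       feature_class = c("TSS1500", "Body", "Body", "TSS200"))
  lab2 <- annotate_windows(build_windows(mf2), mf2)
  expect_identical(lab2$feature_group, "Promoter")     # 2-2 tie -> precedence

  mf3 <- make_manifest("chr1", c(100, 200, 300), feature_class = "Intergenic")
  expect_identical(annotate_windows(build_windows(mf3), mf3)$feature_group, "Other")
})

test_that("regional feature vector averages window disorder by category", {
  # uniform LPMD c: every regional feature, p90 and median equal c
  mf <- make_manifest("chr1", c(100, 200, 300, 1100, 1200, 1300),
                      feature_class = c(rep("TSS200", 3), rep("Body", 3)),
                      cpg_relation = c(rep("Island", 3), rep("OpenSea", 3)))
  grid <- build_windows(mf, size = 1000, step = 1000)
  beta <- make_beta(mf, rep(c(0.2, 0.5, 0.8), 2))  # identical sd in both windows
  ws <- window_stats(beta, grid)
  lab <- annotate_windows(grid, mf)
  rf <- region_features(ws, lab, multiscale_values = setNames(0.3, "S01"))
  cval <- sd(c(0.2, 0.5, 0.8))
  expect_equal(unname(rf[1, "lpmd_island"]), cval)
  expect_equal(unname(rf[1, "lpmd_promoter"]), cval)
  expect_equal(unname(rf[1, "p90_window_lpmd"]), cval)
  expect_equal(unname(rf[1, "median_window_lpmd"]), cval)
  expect_equal(unname(rf[1, "multiscale_lpmd"]), 0.3)
  expect_true(is.na(rf[1, "lpmd_shelf"]))           # empty category -> missing

  # two-category toy with distinct disorder levels
  beta2 <- make_beta(mf, c(0.4, 0.5, 0.6, 0.2, 0.5, 0.8))
  rf2 <- region_features(window_stats(beta2, grid), lab,
                         multiscale_values = setNames(NA_real_, "S01"))
  expect_equal(unname(rf2[1, "lpmd_promoter"]), sd(c(0.4, 0.5, 0.6)))
  expect_equal(unname(rf2[1, "lpmd_genebody"]), sd(c(0.2, 0.5, 0.8)))
})
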