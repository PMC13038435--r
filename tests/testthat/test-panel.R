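test_that("rank AUC equals the Mann-Whitney relation and trapezoid integration", {
  set.seed(6)
  for (rep in 1:60) {
    n <- sample(8:40, 1)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- rnorm(n)
    # tie-free: exact Mann-Whitney U relation
    u <- sum(outer(s[y], s[!y], ">"))
    expect_equal(auc_rank(s, y), u / (sum(y) * sum(!y)), tolerance = 1e-14)
    expect_equal(auc_rank(s, y), oracle_auc_trapezoid(s, y), tolerance = 1e-12)
    # with ties: still matches trapezoid ROC
    s_tied <- round(s, 1)
    expect_equal(auc_rank(s_tied, y), oracle_auc_trapezoid(s_tied, y),
                 tolerance = 1e-12)
  }
  expect_equal(auc_rank(rep(1, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)), 0.5)
})

test_that("univariate selection finds signal at the right false-positive rate", {
  set.seed(9)
  y <- rep(c(TRUE, FALSE), each = 25)
  X <- cbind(sig = y + rnorm(50, 0, 0.3),
             matrix(rnorm(50 * 30), 50, 30,
                    dimnames = list(NULL, sprintf("n%02d", 1:30))),
             const = rep(1, 50))
  sel <- select_univariate(X, y)
  expect_true("sig" %in% sel$selected)
  expect_identical(sel$selected[1], "sig")
  expect_false("const" %in% sel$selected)
  expect_identical(select_univariate(X, y, alpha = 0)$selected, character(0))
  # pure-noise selection rate is close to alpha
  rate <- mean(replicate(40, {
    Xn <- matrix(rnorm(40 * 20), 40, 20, dimnames = list(NULL, paste0("f", 1:20)))
    length(select_univariate(Xn, rep(c(TRUE, FALSE), each = 20))$selected) / 20
  }))
  expect_lt(abs(rate - 0.05), 0.035)
})

test_that("random-forest selection ranks an informative feature first and is deterministic", {
  hits <- 0
  for (s in 1:5) {
    d <- make_logistic_data(n = 80, p_noise = 15, coefs = 3, seed = 100 + s)
    sel <- select_random_forest(d$X, d$y, top_k = 5, seed = s)
    hits <- hits + (sel$selected[1] == "sig01")
  }
  expect_gte(hits, 4)   # far above the 1/16 chance rate
  d <- make_logistic_data(n = 60, p_noise = 10, coefs = 2, seed = 77)
  expect_identical(select_random_forest(d$X, d$y, seed = 3, top_k = 5),
                   select_random_forest(d$X, d$y, seed = 3, top_k = 5))
  expect_warning(sel_all <- select_random_forest(d$X, d$y, top_k = 99, seed = 1),
                 "exceeds")
  expect_identical(length(sel_all$selected), ncol(d$X))
  # a duplicated informative feature still outranks noise
  Xd <- cbind(d$X, sig_dup = d$X[, "sig01"])
  sd_sel <- select_random_forest(Xd, d$y, top_k = 3, seed = 5)
  expect_true(any(c("sig01", "sig_dup") %in% sd_sel$selected))
})

test_that("RFE keeps informative features and honours target size", {
  d <- make_logistic_data(n = 90, p_noise = 12, coefs = c(2.5, -2.5), seed = 41)
  sel <- suppressWarnings(select_rfe(d$X, d$y, target_size = 5, seed = 2))
  expect_identical(length(sel$selected), 5L)
  expect_true(all(c("sig01", "sig02") %in% sel$selected))
  # target_size = p is the identity set
  sel_id <- suppressWarnings(select_rfe(d$X, d$y, target_size = ncol(d$X), seed = 2))
  expect_setequal(sel_id$selected, colnames(d$X))
  expect_identical(suppressWarnings(select_rfe(d$X, d$y, target_size = 5, seed = 2)),
                   sel)
})

test_that("LASSO retains a strong predictor and prunes orthogonal noise", {
  d <- make_logistic_data(n = 150, p_noise = 10, coefs = 3, seed = 55)
  sel <- select_lasso(d$X, d$y, seed = 1)
  expect_identical(sel$selected[1], "sig01")
  expect_lt(length(sel$selected), ncol(d$X))
  expect_identical(select_lasso(d$X, d$y, seed = 1), sel)
})

test_that("consensus ranking orders by method count then mean rank then name", {
  sels <- list(list(method = "m1", selected = c("a", "b", "c")),
               list(method = "m2", selected = c("b", "a")),
               list(method = "m3", selected = c("b", "d")),
               list(method = "m4", selected = c("b", "a", "e")))
  cons <- consensus_features(sels)
  expect_identical(cons$ranking[1], "b")        # count 4
  expect_identical(cons$ranking[2], "a")        # count 3
  expect_identical(unname(cons$counts[c("b", "a", "c", "d", "e")]),
                   c(4L, 3L, 1L, 1L, 1L))
  # count-1 features order by mean rank (d: 2) then lexicographically (c, e
  # both have mean rank 3)
  expect_identical(cons$ranking[3:5], c("d", "c", "e"))
  disj <- consensus_features(list(list(method = "m1", selected = "x"),
                                  list(method = "m2", selected = "y")))
  expect_true(all(disj$counts == 1L))
  expect_error(consensus_features(sels[1]), ">= 2")
})

test_that("panel fitting separates a perfect feature and handles size 0", {
  y <- rep(c(TRUE, FALSE), each = 10)
  X <- cbind(perfect = ifelse(y, 1, 0) + rnorm(20, 0, 0.01),
             noise = rnorm(20))
  panel <- build_panel(X, y, ranking = c("perfect", "noise"), size = 1)
  expect_equal(auc_rank(predict_panel(panel, X), y), 1.0)
  expect_gt(panel$coefficients["perfect"], 0)
  p0 <- build_panel(X, y, ranking = colnames(X), size = 0)
  expect_equal(auc_rank(predict_panel(p0, X), y), 0.5)
  expect_error(build_panel(X, y, ranking = "perfect", size = 2), "exceeds")
  # coefficient signs track the generating log-odds
  d <- make_logistic_data(n = 200, p_noise = 0, coefs = c(2, -2), seed = 13)
  pf <- build_panel(d$X, d$y, ranking = colnames(d$X), size = 2)
  expect_gt(pf$coefficients["sig01"], 0)
  expect_lt(pf$coefficients["sig02"], 0)
})

test_that("cross-validated evaluation is calibrated on null data and finds signal", {
  set.seed(70)
  Xn <- matrix(rnorm(60 * 20), 60, 20, dimnames = list(NULL, paste0("f", 1:20)))
  yn <- rep(c(TRUE, FALSE), each = 30)
  cv_null <- evaluate_cv(Xn, yn, colnames(Xn), sizes = 5, k = 5, seed = 8)
  expect_lt(abs(cv_null$report$cv_auc - 0.5), 0.12)

  d <- make_logistic_data(n = 80, p_noise = 17, coefs = c(2, 2, -2), seed = 91)
  ranking <- c("sig01", "sig02", "sig03", sprintf("noise%03d", 1:17))
  cv_sig <- evaluate_cv(d$X, d$y, ranking, sizes = c(3, 10), k = 5, seed = 8)
  expect_gt(cv_sig$report$cv_auc[1], 0.7)
  expect_true(all(c("train_auc", "cv_auc", "overfit_gap", "sensitivity",
                    "specificity", "ppv", "npv") %in% colnames(cv_sig$report)))
  expect_equal(cv_sig$report$overfit_gap,
               cv_sig$report$train_auc - cv_sig$report$cv_auc)
  # reproducibility under a fixed seed
  expect_identical(evaluate_cv(d$X, d$y, ranking, sizes = c(3, 10), k = 5, seed = 8),
                   cv_sig)
  expect_error(evaluate_cv(d$X, d$y, ranking, k = 50, seed = 1), "reduce k")
})

test_that("LOOCV is deterministic and brackets chance on null data", {
  y <- rep(c(TRUE, FALSE), each = 12)
  X <- cbind(perfect = as.numeric(y) + rnorm(24, 0, 0.01),
             noise = rnorm(24))
  loo <- loocv_evaluate(X, y, "perfect")
  expect_equal(loo$auc, 1.0)
  expect_identical(loocv_evaluate(X, y, "perfect"), loo)
  set.seed(17)
  Xn <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  loo_null <- loocv_evaluate(Xn, rep(c(TRUE, FALSE), 20), c("a", "b", "c"))
  expect_lt(abs(loo_null$auc - 0.5), 0.25)
})

test_that("DeLong test matches pROC and honours its degenerate contracts", {
  skip_if_not_installed("pROC")
  set.seed(33)
  for (rep in 1:10) {
    n <- 40
    y <- rep(c(TRUE, FALSE), each = n / 2)
    sa <- as.numeric(y) + rnorm(n, 0, 1.2)
    sb <- as.numeric(y) + rnorm(n, 0, 2.0)
    got <- delong_test(sa, sb, y)
    roc_of <- function(s) pROC::roc(y, s, quiet = TRUE, direction = "<",
                                    levels = c(FALSE, TRUE))
    ref <- pROC::roc.test(roc_of(sa), roc_of(sb), method = "delong")
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
    expect_equal(got$auc_a, as.numeric(pROC::auc(roc_of(sa))), tolerance = 1e-12)
    # argument order flips AUCs but not the p-value
    swap <- delong_test(sb, sa, y)
    expect_equal(swap$p, got$p, tolerance = 1e-12)
  }
  y <- rep(c(TRUE, FALSE), each = 5)
  s <- rnorm(10)
  expect_equal(delong_test(s, s, y)$p, 1)
})
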