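#' Rank-based AUC
#'
#' Area under the ROC curve computed from the Mann-Whitney relation with
#' mid-ranks for ties: `AUC = (sum of positive-class ranks - m(m+1)/2) /
#' (m * n)`.
#'
#' @param scores Numeric predictor scores.
#' @param y Binary labels (logical or 0/1); TRUE/1 is the positive class.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, y) {
  y <- as.logical(y)
  m <- sum(y); n <- sum(!y)
  if (m == 0L || n == 0L) .stopf("AUC needs both classes present")
  r <- rank(scores)           # mid-ranks on ties
  (sum(r[y]) - m * (m + 1) / 2) / (m * n)
}

# ridge-penalised logistic regression by IRLS; penalty on slopes only
.ridge_logistic <- function(X, y, lambda = 1e-4, max_iter = 100, tol = 1e-10) {
  X1 <- cbind(`(Intercept)` = 1, as.matrix(X))
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- rep(0, p)
  yv <- as.numeric(y)
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (yv - mu) / w
    xtwx <- crossprod(X1 * w, X1) + pen
    new_beta <- drop(solve(xtwx, crossprod(X1 * w, z)))
    if (max(abs(new_beta - beta)) < tol) { beta <- new_beta; break }
    beta <- new_beta
  }
  beta
}

.predict_logit <- function(beta, X) {
  drop(cbind(1, as.matrix(X)) %*% beta)
}

# stratified k-fold assignment; seeded, errors if a class has < k members
.stratified_folds <- function(y, k, seed) {
  y <- as.logical(y)
  if (min(sum(y), sum(!y)) < k) {
    .stopf("stratified %d-fold CV needs >= %d members per class; reduce k", k, k)
  }
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in c(TRUE, FALSE)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Youden's J optimal threshold from scores/labels (maximises sens + spec - 1)
.youden_threshold <- function(scores, y) {
  y <- as.logical(y)
  cand <- sort(unique(scores))
  if (length(cand) == 1L) return(cand)
  cuts <- (cand[-1L] + cand[-length(cand)]) / 2
  j <- vapply(cuts, function(th) {
    mean(scores[y] > th) + mean(scores[!y] <= th) - 1
  }, 0)
  cuts[which.max(j)]
}

#' Univariate feature selection (rank-sum test)
#'
#' Selects features whose two-sided Wilcoxon rank-sum p-value between the two
#' classes is below `alpha`, ordered by p ascending. Constant features get
#' p = 1 and are never selected.
#'
#' @param X Samples-by-features matrix.
#' @param y Binary labels.
#' @param alpha Significance cutoff (default 0.05).
#' @return List with `method`, `selected` (ordered names) and `scores`
#'   (p-values for all features).
#' @export
select_univariate <- function(X, y, alpha = 0.05) {
  y <- as.logical(y)
  p <- vapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    if (length(unique(v)) == 1L) return(1)
    suppressWarnings(stats::wilcox.test(v[y], v[!y])$p.value)
  }, 0)
  names(p) <- colnames(X)
  sel <- names(sort(p[p < alpha]))
  list(method = "univariate", selected = sel, scores = p)
}

#' Random-forest importance selection
#'
#' Ranks features by mean-decrease-in-impurity importance from a
#' classification forest (`ntree` trees, `mtry = sqrt(p)` by default) and
#' keeps the top `top_k`.
#'
#' @param X Samples-by-features matrix.
#' @param y Binary labels.
#' @param ntree Number of trees (default 500).
#' @param mtry `"sqrt"` or an integer.
#' @param top_k Number of features to keep (default 50).
#' @param seed Mandatory RNG seed.
#' @return SelectionResult list (`method`, `selected`, `scores`).
#' @export
select_random_forest <- function(X, y, ntree = 500, mtry = "sqrt",
                                 top_k = 50, seed) {
  if (missing(seed)) .stopf("select_random_forest requires an explicit seed")
  if (top_k > ncol(X)) {
    .warnf("top_k (%d) exceeds feature count (%d); keeping all", top_k, ncol(X))
    top_k <- ncol(X)
  }
  m <- if (identical(mtry, "sqrt")) max(1L, floor(sqrt(ncol(X)))) else as.integer(mtry)
  set.seed(seed)
  fit <- randomForest::randomForest(x = as.data.frame(X),
                                    y = factor(as.logical(y)),
                                    ntree = ntree, mtry = m, importance = FALSE)
  imp <- fit$importance[, "MeanDecreaseGini"]
  ord <- order(-imp, colnames(X))
  list(method = "random_forest",
       selected = colnames(X)[ord][seq_len(top_k)],
       scores = imp)
}

#' Recursive feature elimination
#'
#' Backward elimination on a ridge-regularised logistic base learner: at each
#' step features are ranked by the magnitude of their standardised
#' coefficient and the weakest ~10% (at least one) are dropped, until
#' `target_size` remain. The cross-validated AUC of each intermediate set is
#' recorded with seeded stratified folds.
#'
#' @param X Samples-by-features matrix.
#' @param y Binary labels.
#' @param cv_folds Folds for the CV-AUC trace (default 10, reduced with a
#'   warning when a class is too small).
#' @param target_size Final feature-set size (default 20).
#' @param seed Mandatory RNG seed.
#' @return SelectionResult list; `scores` holds the CV-AUC per visited size.
#' @export
select_rfe <- function(X, y, cv_folds = 10, target_size = 20, seed) {
  if (missing(seed)) .stopf("select_rfe requires an explicit seed")
  y <- as.logical(y)
  target_size <- min(target_size, ncol(X))
  k <- min(cv_folds, sum(y), sum(!y))
  if (k < cv_folds) .warnf("reducing CV folds from %d to %d (small class)", cv_folds, k)

  cv_auc <- function(feats) {
    fold <- .stratified_folds(y, k, seed)
    scores <- numeric(length(y))
    for (f in seq_len(k)) {
      tr <- fold != f
      beta <- .ridge_logistic(X[tr, feats, drop = FALSE], y[tr], lambda = 1)
      scores[!tr] <- .predict_logit(beta, X[!tr, feats, drop = FALSE])
    }
    auc_rank(scores, y)
  }

  current <- colnames(X)
  trace <- c()
  while (length(current) > target_size) {
    trace[as.character(length(current))] <- cv_auc(current)
    beta <- .ridge_logistic(X[, current, drop = FALSE], y, lambda = 1)
    sds <- apply(X[, current, drop = FALSE], 2L, sd)
    importance <- abs(beta[-1L]) * sds
    n_drop <- max(1L, min(floor(length(current) * 0.1),
                          length(current) - target_size))
    current <- current[order(-importance, current)][seq_len(length(current) - n_drop)]
  }
  trace[as.character(length(current))] <- cv_auc(current)
  beta <- .ridge_logistic(X[, current, drop = FALSE], y, lambda = 1)
  sds <- apply(X[, current, drop = FALSE], 2L, sd)
  ord <- order(-(abs(beta[-1L]) * sds), current)
  list(method = "rfe", selected = current[ord], scores = trace)
}

#' LASSO feature selection
#'
#' L1-penalised logistic path (glmnet) with lambda chosen at minimum mean
#' cross-validated deviance; selected features are those with nonzero
#' coefficients at that lambda, ordered by |coefficient| descending.
#'
#' @param X Samples-by-features matrix.
#' @param y Binary labels.
#' @param cv_folds Folds for lambda selection (default 10).
#' @param seed Mandatory RNG seed.
#' @return SelectionResult list; `scores` holds |coefficients| at lambda_min.
#' @export
select_lasso <- function(X, y, cv_folds = 10, seed) {
  if (missing(seed)) .stopf("select_lasso requires an explicit seed")
  y <- as.logical(y)
  k <- min(cv_folds, sum(y), sum(!y))
  if (k < cv_folds) .warnf("reducing CV folds from %d to %d (small class)", cv_folds, k)
  set.seed(seed)
  cvfit <- glmnet::cv.glmnet(as.matrix(X), as.numeric(y), family = "binomial",
                             alpha = 1, nfolds = k, type.measure = "deviance")
  co <- as.matrix(coef(cvfit, s = "lambda.min"))[-1L, 1L]
  names(co) <- colnames(X)
  nz <- co[co != 0]
  if (!length(nz)) .warnf("LASSO selected no features at lambda_min")
  list(method = "lasso",
       selected = names(nz)[order(-abs(nz), names(nz))],
       scores = abs(co))
}

#' Consensus over several feature selections
#'
#' Counts, per feature, the number of selection methods that picked it, and
#' ranks features by (count descending, mean within-method rank ascending,
#' then lexicographically by feature name).
#'
#' @param selections List of >= 2 SelectionResult lists.
#' @return List with `counts` (named integer vector over all selected
#'   features) and `ranking` (ordered feature names).
#' @export
consensus_features <- function(selections) {
  if (length(selections) < 2L) .stopf("consensus needs >= 2 selection results")
  all_feats <- unique(unlist(lapply(selections, `[[`, "selected")))
  if (!length(all_feats)) return(list(counts = setNames(integer(), character()),
                                      ranking = character()))
  counts <- setNames(integer(length(all_feats)), all_feats)
  rank_sum <- setNames(numeric(length(all_feats)), all_feats)
  for (sel in selections) {
    s <- sel$selected
    counts[s] <- counts[s] + 1L
    rank_sum[s] <- rank_sum[s] + seq_along(s)
  }
  mean_rank <- rank_sum / pmax(counts, 1L)
  ord <- order(-counts, mean_rank, all_feats)
  list(counts = counts[ord], ranking = all_feats[ord])
}

#' Fit the logistic DMDR panel
#'
#' Logistic regression of the binary response on the top `size` features of
#' the consensus ranking, with a small L2 ridge (default 1e-4) so the fit
#' stays defined under perfect separation.
#'
#' @param X Samples-by-features matrix.
#' @param y Binary labels.
#' @param ranking Ordered feature names (see [consensus_features()]).
#' @param size Panel size (default 5; 0 gives an intercept-only model).
#' @param lambda Ridge penalty (default 1e-4).
#' @return List with `features`, `intercept`, `coefficients`, `lambda`.
#' @export
build_panel <- function(X, y, ranking, size = 5, lambda = 1e-4) {
  if (size > length(ranking)) .stopf("size (%d) exceeds ranked features (%d)",
                                     size, length(ranking))
  feats <- head(ranking, size)
  beta <- .ridge_logistic(X[, feats, drop = FALSE], as.logical(y), lambda = lambda)
  list(features = feats, intercept = beta[1L],
       coefficients = setNames(beta[-1L], feats), lambda = lambda)
}

#' Predict panel scores
#'
#' @param panel Fitted panel from [build_panel()].
#' @param X Samples-by-features matrix containing the panel features.
#' @param type `"link"` (log-odds, default) or `"response"` (probability).
#' @return Numeric vector of scores.
#' @export
predict_panel <- function(panel, X, type = c("link", "response")) {
  type <- match.arg(type)
  eta <- drop(as.matrix(X[, panel$features, drop = FALSE]) %*% panel$coefficients) +
    panel$intercept
  if (type == "response") plogis(eta) else eta
}

#' Stratified cross-validated panel evaluation
#'
#' For each panel size, fits the ridge-logistic panel on k-1 stratified folds
#' and scores the held-out fold. Reports pooled out-of-fold AUC (rank
#' method), the mean within-fold training AUC, the overfit gap (train minus
#' CV AUC), and sensitivity/specificity/PPV/NPV of pooled out-of-fold calls
#' using each training fold's Youden-J threshold.
#'
#' @param X Samples-by-features matrix.
#' @param y Binary labels (TRUE/1 = responder).
#' @param ranking Ordered feature names.
#' @param sizes Panel sizes to evaluate (default 5, 10, 15, 20).
#' @param k Number of folds (default 5).
#' @param seed Mandatory RNG seed.
#' @return List with `report` (data.frame per size), `folds` (assignment
#'   vector) and `seed`.
#' @export
evaluate_cv <- function(X, y, ranking, sizes = c(5, 10, 15, 20), k = 5, seed) {
  if (missing(seed)) .stopf("evaluate_cv requires an explicit seed")
  y <- as.logical(y)
  sizes <- sizes[sizes <= length(ranking)]
  if (!length(sizes)) .stopf("no panel size is <= the number of ranked features")
  fold <- .stratified_folds(y, k, seed)
  rows <- lapply(sizes, function(size) {
    feats <- head(ranking, size)
    oof_scores <- numeric(length(y))
    oof_call <- logical(length(y))
    train_aucs <- numeric(k)
    for (f in seq_len(k)) {
      tr <- fold != f
      beta <- .ridge_logistic(X[tr, feats, drop = FALSE], y[tr], lambda = 1e-4)
      tr_scores <- .predict_logit(beta, X[tr, feats, drop = FALSE])
      train_aucs[f] <- auc_rank(tr_scores, y[tr])
      te_scores <- .predict_logit(beta, X[!tr, feats, drop = FALSE])
      oof_scores[!tr] <- te_scores
      oof_call[!tr] <- te_scores > .youden_threshold(tr_scores, y[tr])
    }
    cv_auc <- auc_rank(oof_scores, y)
    tp <- sum(oof_call & y); fn <- sum(!oof_call & y)
    tn <- sum(!oof_call & !y); fp <- sum(oof_call & !y)
    data.frame(size = size,
               train_auc = mean(train_aucs),
               cv_auc = cv_auc,
               overfit_gap = mean(train_aucs) - cv_auc,
               sensitivity = tp / (tp + fn),
               specificity = tn / (tn + fp),
               ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
  })
  list(report = do.call(rbind, rows), folds = fold, seed = seed)
}

#' Leave-one-out cross-validated panel evaluation
#'
#' Refits the panel n times, each time holding out one sample; pools the
#' held-out scores into an AUC and classifies each held-out sample with the
#' Youden-J threshold of its training fit.
#'
#' @param X Samples-by-features matrix.
#' @param y Binary labels.
#' @param features Panel feature names.
#' @return List with `auc`, `accuracy`, `sensitivity`, `specificity`.
#' @export
loocv_evaluate <- function(X, y, features) {
  y <- as.logical(y)
  n <- length(y)
  scores <- numeric(n)
  call <- logical(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    beta <- .ridge_logistic(X[tr, features, drop = FALSE], y[tr], lambda = 1e-4)
    tr_scores <- .predict_logit(beta, X[tr, features, drop = FALSE])
    scores[i] <- .predict_logit(beta, X[i, features, drop = FALSE])
    call[i] <- scores[i] > .youden_threshold(tr_scores, y[tr])
  }
  list(auc = auc_rank(scores, y),
       accuracy = mean(call == y),
       sensitivity = sum(call & y) / sum(y),
       specificity = sum(!call & !y) / sum(!y))
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors on the same samples using DeLong's
#' variance estimate from mid-rank structural components (placements), with a
#' two-sided normal p-value. Identical AUCs with zero variance of the
#' difference give p = 1; a degenerate variance with differing AUCs yields a
#' missing p.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param y Binary labels.
#' @return List with `auc_a`, `auc_b`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, y) {
  y <- as.logical(y)
  m <- sum(y); n <- sum(!y)
  if (m < 2L || n < 2L) .stopf("DeLong test needs >= 2 samples per class")
  placements <- function(s) {
    pos <- s[y]; neg <- s[!y]
    v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), 0)
    v01 <- vapply(neg, function(x) mean((pos > x) + 0.5 * (pos == x)), 0)
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- pa$auc - pb$auc
  p <- if (var_diff <= 0) {
    if (diff == 0) 1 else NA_real_
  } else {
    2 * pnorm(-abs(diff) / sqrt(var_diff))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, p = p)
}
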