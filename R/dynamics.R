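.timepoint_levels <- c("diagnosis", "lt3m", "m3to5", "m6to11", "ge12m")

#' Bin months on treatment into the five study timepoints
#'
#' Diagnosis samples are distinguished only by the explicit flag; among
#' on-treatment samples, \[0, 3) months -> `lt3m`, \[3, 6) -> `m3to5`,
#' \[6, 12) -> `m6to11`, and >= 12 -> `ge12m`.
#'
#' @param months Non-negative months on treatment (vectorised; NA allowed
#'   when `is_diagnosis` is TRUE).
#' @param is_diagnosis Logical flag(s) marking diagnosis samples.
#' @return Ordered factor with levels diagnosis < lt3m < m3to5 < m6to11 <
#'   ge12m.
#' @export
bin_timepoint <- function(months, is_diagnosis = FALSE) {
  n <- max(length(months), length(is_diagnosis))
  months <- rep_len(months, n)
  is_diagnosis <- rep_len(is_diagnosis, n)
  if (any(!is_diagnosis & is.na(months))) .stopf("months required for non-diagnosis samples")
  if (any(months < 0, na.rm = TRUE)) .stopf("months on treatment must be non-negative")
  out <- ifelse(is_diagnosis, "diagnosis",
                ifelse(months < 3, "lt3m",
                       ifelse(months < 6, "m3to5",
                              ifelse(months < 12, "m6to11", "ge12m"))))
  factor(out, levels = .timepoint_levels, ordered = TRUE)
}

#' Relative change from baseline, in percent
#'
#' `100 * (value_t - baseline) / baseline`; a zero baseline gives NA.
#'
#' @param value_t Value at the later timepoint.
#' @param baseline Baseline value.
#' @return Percent change (vectorised).
#' @export
relative_change <- function(value_t, baseline) {
  n <- max(length(value_t), length(baseline))
  value_t <- rep_len(value_t, n)
  baseline <- rep_len(baseline, n)
  out <- 100 * (value_t - baseline) / baseline
  out[baseline == 0] <- NA_real_
  out
}

#' Jonckheere-Terpstra trend test
#'
#' Tests for a monotone trend across >= 3 ordered groups. The statistic is
#' the sum over ordered group pairs of Mann-Whitney counts (ties count 1/2);
#' Z uses the tie-corrected normal approximation. `alternative =
#' "decreasing"` (the default) tests for values decreasing along the group
#' order.
#'
#' @param groups_in_order List of numeric vectors, one per ordered group.
#' @param alternative `"decreasing"`, `"increasing"` or `"two.sided"`.
#' @return List with `JT`, `Z`, `p`.
#' @export
jonckheere_terpstra <- function(groups_in_order,
                                alternative = c("decreasing", "increasing", "two.sided")) {
  alternative <- match.arg(alternative)
  groups_in_order <- lapply(groups_in_order, function(g) g[!is.na(g)])
  if (length(groups_in_order) < 3L) .stopf("need >= 3 ordered groups")
  if (any(lengths(groups_in_order) < 1L)) .stopf("every group needs >= 1 value")
  k <- length(groups_in_order)
  jt <- 0
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      a <- groups_in_order[[i]]; b <- groups_in_order[[j]]
      cmp <- outer(a, b, "<")
      tie <- outer(a, b, "==")
      jt <- jt + sum(cmp) + 0.5 * sum(tie)
    }
  }
  ni <- lengths(groups_in_order)
  N <- sum(ni)
  values <- unlist(groups_in_order)
  tj <- as.numeric(table(values))           # tie-group sizes
  e_jt <- (N^2 - sum(ni^2)) / 4
  v1 <- (N * (N - 1) * (2 * N + 5) -
           sum(ni * (ni - 1) * (2 * ni + 5)) -
           sum(tj * (tj - 1) * (2 * tj + 5))) / 72
  v2 <- sum(ni * (ni - 1) * (ni - 2)) * sum(tj * (tj - 1) * (tj - 2)) /
    (36 * N * (N - 1) * (N - 2))
  v3 <- sum(ni * (ni - 1)) * sum(tj * (tj - 1)) / (8 * N * (N - 1))
  v_jt <- v1 + v2 + v3
  if (v_jt <= 0) return(list(JT = jt, Z = 0, p = 1))
  z <- (jt - e_jt) / sqrt(v_jt)
  p <- switch(alternative,
              decreasing = pnorm(z),
              increasing = pnorm(z, lower.tail = FALSE),
              two.sided = 2 * pnorm(-abs(z)))
  list(JT = jt, Z = z, p = p)
}

#' Mixed-effects longitudinal disorder trend
#'
#' Fits a linear mixed model of the per-sample disorder value on the ordinal
#' timepoint bin index (0-4, fixed effect) with a random intercept per
#' patient, and reports the fixed slope, its standard error and the
#' Satterthwaite p-value. When the random intercept is inestimable (e.g.
#' every patient contributes a single sample) the fit falls back to ordinary
#' least squares with a warning.
#'
#' @param series Data.frame with columns `patient_id`, `timepoint_bin`
#'   (factor with the [bin_timepoint()] levels) and `lpmd_value`.
#' @return List with `slope`, `se`, `p`, `method` ("mixed" or "ols").
#' @export
fit_longitudinal_trend <- function(series) {
  need <- c("patient_id", "timepoint_bin", "lpmd_value")
  if (!all(need %in% colnames(series))) {
    .stopf("series needs columns: %s", paste(need, collapse = ", "))
  }
  df <- data.frame(patient = as.character(series$patient_id),
                   t = as.integer(factor(series$timepoint_bin,
                                         levels = .timepoint_levels)) - 1L,
                   y = series$lpmd_value)
  df <- df[complete.cases(df), , drop = FALSE]
  n_multi <- sum(table(df$patient) >= 2L)
  if (n_multi >= 2L) {
    fit <- tryCatch(
      lmerTest::lmer(y ~ t + (1 | patient), data = df,
                     control = lme4::lmerControl(check.conv.singular = "ignore")),
      error = function(e) NULL)
    if (!is.null(fit)) {
      co <- summary(fit)$coefficients
      return(list(slope = co["t", "Estimate"], se = co["t", "Std. Error"],
                  p = co["t", "Pr(>|t|)"], method = "mixed"))
    }
  }
  .warnf("random-intercept model inestimable; falling back to ordinary regression (patient clustering ignored)")
  fit <- lm(y ~ t, data = df)
  co <- summary(fit)$coefficients
  list(slope = co["t", "Estimate"], se = co["t", "Std. Error"],
       p = co["t", "Pr(>|t|)"], method = "ols")
}

#' Longitudinal disorder trend summary
#'
#' Convenience wrapper combining per-bin means, relative change from the
#' diagnosis bin, the Jonckheere-Terpstra decreasing-trend test and the
#' mixed-effects slope.
#'
#' @param series Data.frame as in [fit_longitudinal_trend()].
#' @return List with `bin_means` (data.frame bin, n, mean,
#'   relative_change_pct), `jt` and `trend`.
#' @export
dynamics_summary <- function(series) {
  bins <- factor(series$timepoint_bin, levels = .timepoint_levels)
  means <- tapply(series$lpmd_value, bins, mean, na.rm = TRUE)
  ns <- tapply(!is.na(series$lpmd_value), bins, sum)
  ns[is.na(ns)] <- 0L
  baseline <- means[["diagnosis"]]
  bin_means <- data.frame(bin = .timepoint_levels,
                          n = as.integer(ns),
                          mean = as.numeric(means),
                          relative_change_pct = relative_change(as.numeric(means), baseline))
  present <- !is.na(means) & ns > 0L
  jt <- if (sum(present) >= 3L) {
    jonckheere_terpstra(split(series$lpmd_value, bins)[present],
                        alternative = "decreasing")
  } else NULL
  trend <- fit_longitudinal_trend(series)
  list(bin_means = bin_means, jt = jt, trend = trend)
}
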