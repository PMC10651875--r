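#' Ordinary least squares with optional HC3 robust covariance
#'
#' Fits OLS and computes either the classical covariance or the HC3
#' heteroskedasticity-consistent sandwich
#' `(X'X)^-1 X' diag(e_i^2 / (1 - h_ii)^2) X (X'X)^-1`, where `h_ii` are the
#' hat-matrix leverages. Confidence intervals and p-values use the t
#' distribution with n - p degrees of freedom. HC3 is the recommended
#' small-sample (< 250) robust estimator.
#'
#' @param y Response vector.
#' @param X Design matrix including any intercept column.
#' @param covariance `"HC3"` (default) or `"standard"`.
#' @param conf_level Confidence level (default 0.95).
#' @param term_labels Optional coefficient labels.
#' @return A list of class `"regression_result"`: `terms` (data frame with
#'   `term`, `beta`, `se`, `t`, `p`, `ci_lo`, `ci_hi`), `r_squared`,
#'   `adj_r_squared`, `f_statistic`, `f_df1`, `f_df2`, `f_p`,
#'   `covariance_type`, `n`, `residuals`, `fitted`.
#' @export
hc3_ols <- function(y, X, covariance = c("HC3", "standard"),
                    conf_level = 0.95, term_labels = NULL) {
  covariance <- match.arg(covariance)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) abort_field("y", "length must match nrow(X)")
  if (n <= p) abort_field("X", "needs more observations than parameters")
  qrX <- qr(X)
  if (qrX$rank < p) abort_field("X", "design matrix is rank deficient")
  xtx_inv <- chol2inv(qr.R(qrX))
  beta <- drop(xtx_inv %*% crossprod(X, y))
  fitted <- drop(X %*% beta)
  e <- y - fitted
  h <- rowSums((X %*% xtx_inv) * X)
  if (any(h >= 1 - 1e-12)) abort_field("X", "a leverage h_ii is 1; HC3 undefined")
  V <- if (covariance == "HC3") {
    meat <- crossprod(X * (e / (1 - h)), X * (e / (1 - h)))
    xtx_inv %*% meat %*% xtx_inv
  } else {
    sum(e^2) / (n - p) * xtx_inv
  }
  se <- sqrt(diag(V))
  tval <- beta / se
  df <- n - p
  pval <- 2 * stats::pt(-abs(tval), df)
  crit <- stats::qt(1 - (1 - conf_level) / 2, df)
  has_int <- any(apply(X, 2, function(col) all(col == col[1]) && col[1] != 0))
  tss <- if (has_int) sum((y - mean(y))^2) else sum(y^2)
  rss <- sum(e^2)
  r2 <- 1 - rss / tss
  k <- p - as.integer(has_int)
  adj_r2 <- 1 - (1 - r2) * (n - as.integer(has_int)) / (n - p)
  f <- if (k > 0) (tss - rss) / k / (rss / df) else NA_real_
  fp <- if (k > 0) stats::pf(f, k, df, lower.tail = FALSE) else NA_real_
  if (is.null(term_labels)) {
    term_labels <- colnames(X)
    if (is.null(term_labels)) term_labels <- paste0("x", seq_len(p))
  }
  structure(list(
    terms = data.frame(term = term_labels, beta = beta, se = se, t = tval,
                       p = pval, ci_lo = beta - crit * se,
                       ci_hi = beta + crit * se, stringsAsFactors = FALSE),
    r_squared = r2, adj_r_squared = adj_r2,
    f_statistic = f, f_df1 = k, f_df2 = df, f_p = fp,
    covariance_type = covariance, n = n, residuals = e, fitted = fitted),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> n=%d R2_adj=%.3f F(%d, %d)=%.2f p=%.3g [%s]\n",
              x$n, x$adj_r_squared, x$f_df1, x$f_df2, x$f_statistic, x$f_p,
              x$covariance_type))
  print(x$terms, digits = 3, row.names = FALSE)
  invisible(x)
}

zscore <- function(v) (v - mean(v)) / stats::sd(v)

#' Regression of band-power change on exponent, abundance and oscillation
#' changes
#'
#' Fits `delta band power ~ delta exponent + delta abundance + delta
#' oscillation power` (all pre-minus-post differences, z-scored so the
#' coefficients are standardized), restricted to patients whose oscillation
#' power is defined at both timepoints. Per-term alpha thresholds are Holm-
#' adjusted within the 3-main-effect family.
#'
#' @param features Per-patient feature table from [cohort_features()].
#' @param band `"delta"`, `"theta"` or `"alpha"`.
#' @param alpha Family-wise level for the Holm thresholds.
#' @param covariance Covariance type passed to [hc3_ols()] (the band-power
#'   models use the classical covariance by default).
#' @return A `"regression_result"` with an extra `holm` data frame for the
#'   three main effects and `band`, `n` fields.
#' @export
band_power_regression <- function(features, band, alpha = 0.05,
                                  covariance = "standard") {
  cols <- paste0(band, c("_power_diff", "_abundance_diff", "_osc_diff"))
  need <- c(cols, "exponent_diff")
  if (!all(need %in% names(features))) {
    abort_field("features", "missing band feature columns")
  }
  df <- features[stats::complete.cases(features[, need]), need]
  n <- nrow(df)
  if (n <= 5L) abort_field("features", "needs > 5 complete cases")
  y <- zscore(df[[cols[1]]])
  X <- cbind(intercept = 1,
             exponent = zscore(df$exponent_diff),
             abundance = zscore(df[[cols[2]]]),
             oscillation = zscore(df[[cols[3]]]))
  res <- hc3_ols(y, X, covariance = covariance)
  main <- res$terms[res$terms$term != "intercept", ]
  res$holm <- holm_bonferroni(main$p, main$term, alpha = alpha)
  res$band <- band
  res
}

#' Normalize a HAM-D score to the unit interval
#'
#' `(score - minimum) / (maximum - minimum)` with minimum 0 and maximum 52
#' for the 17-item scale or 76 for the 24-item scale, putting the two
#' instruments on a single linearized 0-1 severity scale.
#'
#' @param score Raw integer HAM-D score(s).
#' @param version 17 or 24.
#' @return Normalized value(s) in `[0, 1]`.
#' @export
normalize_hamd <- function(score, version) {
  version <- as.integer(version)
  maxima <- c(`17` = 52, `24` = 76)
  mx <- maxima[as.character(version)]
  if (any(is.na(mx))) abort_field("version", "must be 17 or 24")
  if (any(score < 0 | score > mx, na.rm = TRUE)) {
    abort_field("score", "must lie in [0, scale maximum]")
  }
  unname(score / mx)
}

#' Remission rate
#'
#' Percentage of patients whose symptom severity decreased by at least half:
#' `(pre - post) / pre >= 0.5`. Patients with a baseline score of zero are
#' excluded with a warning.
#'
#' @param pre,post Paired severity scores.
#' @return Percentage in `[0, 100]`.
#' @export
remission_rate <- function(pre, post) {
  keep <- !is.na(pre) & !is.na(post)
  pre <- pre[keep]; post <- post[keep]
  if (any(pre == 0)) {
    warning("excluding patients with baseline score 0")
    post <- post[pre > 0]; pre <- pre[pre > 0]
  }
  if (!length(pre)) abort_field("pre", "no usable patients")
  100 * mean((pre - post) / pre >= 0.5)
}

#' Exhaustive search for the EEG correlate of clinical outcome
#'
#' Predicts normalized post-treatment HAM-D from two fixed effects that are
#' always included -- normalized pre-treatment HAM-D and treatment type
#' (ECT = 0, MST = 1) -- plus candidate EEG features chosen by exhaustive
#' enumeration. By default each single candidate is tried and the model with
#' maximal adjusted R^2 wins (the selected model has exactly one searched
#' main effect); larger subsets can be searched via `max_features`. The
#' winning model is re-fit with HC3 robust covariance on z-scored response
#' and continuous predictors (the 0/1 treatment indicator is left as is).
#'
#' @param outcome Data frame with columns `hamd_pre_norm`, `hamd_post_norm`,
#'   `treatment` ("ECT"/"MST" or 0/1) and the candidate columns.
#' @param candidates Candidate column names (default: the seven-feature set
#'   of baseline exponent, baseline delta/theta abundance, changes in
#'   exponent and delta/theta abundance, and number of treatments).
#' @param max_features Largest candidate subset size searched (default 1).
#' @param conf_level Confidence level for the final model.
#' @return List: `selected` (candidate names), `result` (the HC3
#'   `"regression_result"` on standardized variables), `search` (data frame
#'   of every subset with its adjusted R^2), `n`.
#' @export
exhaustive_outcome_search <- function(outcome,
                                      candidates = c("exponent_pre",
                                                     "delta_abundance_pre",
                                                     "theta_abundance_pre",
                                                     "exponent_diff",
                                                     "delta_abundance_diff",
                                                     "theta_abundance_diff",
                                                     "n_treatments"),
                                      max_features = 1L,
                                      conf_level = 0.95) {
  need <- c("hamd_pre_norm", "hamd_post_norm", "treatment", candidates)
  if (!all(need %in% names(outcome))) {
    abort_field("outcome", "missing required columns")
  }
  df <- outcome[stats::complete.cases(outcome[, need]), need]
  n <- nrow(df)
  treat <- if (is.numeric(df$treatment)) df$treatment
           else as.integer(df$treatment == "MST")
  subsets <- unlist(lapply(seq_len(min(max_features, length(candidates))),
                           function(k) {
                             utils::combn(candidates, k, simplify = FALSE)
                           }), recursive = FALSE)
  rows <- list(); skipped <- character()
  best <- NULL; best_r2 <- -Inf
  for (s in subsets) {
    p <- 3L + length(s)
    if (n <= p) {
      skipped <- c(skipped, paste(s, collapse = "+"))
      next
    }
    X <- cbind(1, df$hamd_pre_norm, treat, as.matrix(df[, s, drop = FALSE]))
    fit <- stats::lm.fit(X, df$hamd_post_norm)
    if (fit$rank < ncol(X)) {
      skipped <- c(skipped, paste(s, collapse = "+"))
      next
    }
    rss <- sum(fit$residuals^2)
    tss <- sum((df$hamd_post_norm - mean(df$hamd_post_norm))^2)
    adj <- 1 - (1 - (1 - rss / tss)) * (n - 1) / (n - ncol(X))
    rows[[length(rows) + 1L]] <- data.frame(
      subset = paste(s, collapse = "+"), k = length(s), adj_r_squared = adj,
      stringsAsFactors = FALSE)
    if (adj > best_r2) {
      best_r2 <- adj
      best <- s
    }
  }
  if (is.null(best)) abort_field("outcome", "no candidate subset is estimable")
  if (length(skipped)) {
    message("skipped under-determined subsets: ", paste(skipped, collapse = ", "))
  }
  Xz <- cbind(intercept = 1,
              hamd_pre_norm = zscore(df$hamd_pre_norm),
              treatment = treat)
  for (v in best) Xz <- cbind(Xz, zscore(df[[v]]))
  colnames(Xz) <- c("intercept", "hamd_pre_norm", "treatment", best)
  result <- hc3_ols(zscore(df$hamd_post_norm), Xz, covariance = "HC3",
                    conf_level = conf_level)
  list(selected = best, result = result,
       search = do.call(rbind, rows), n = n)
}
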