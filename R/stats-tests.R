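#' Choose the paired-comparison branch from a normality check
#'
#' Shapiro-Wilk on the paired differences: the paired t-test is used when
#' normality is not rejected (p >= 0.05), otherwise the Wilcoxon signed-rank
#' test.
#'
#' @param diffs Paired differences (n >= 3).
#' @param alpha Normality rejection level (default 0.05).
#' @return `"paired_t"` or `"wilcoxon"`.
#' @export
shapiro_gate <- function(diffs, alpha = 0.05) {
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) < 3L) abort_field("diffs", "needs n >= 3")
  if (stats::sd(diffs) == 0) {
    warning("constant differences: normality undefined, using wilcoxon")
    return("wilcoxon")
  }
  p <- stats::shapiro.test(diffs)$p.value
  if (p >= alpha) "paired_t" else "wilcoxon"
}

#' Cliff's delta effect size
#'
#' `(#{x_i > y_j} - #{x_i < y_j}) / (n_x * n_y)` over all cross pairs,
#' computed by sorted counting rather than the quadratic double loop.
#' Conventional magnitudes: 0.147 small, 0.33 medium, 0.47 large.
#'
#' @param x,y Non-empty numeric samples.
#' @return Value in `[-1, 1]`.
#' @export
cliffs_delta <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) abort_field("x", "samples must be non-empty")
  ys <- sort(y)
  n_lt <- findInterval(x, ys, left.open = TRUE)  # per x_i: #{y_j < x_i}
  n_le <- findInterval(x, ys)                    # per x_i: #{y_j <= x_i}
  n_gt <- length(y) - n_le                       # per x_i: #{y_j > x_i}
  (sum(n_lt) - sum(n_gt)) / (length(x) * length(y))
}

#' Cohen's d_z for paired samples
#'
#' Mean of the paired differences divided by their standard deviation.
#'
#' @param diffs Paired differences.
#' @return Signed effect size.
#' @export
cohens_dz <- function(diffs) {
  mean(diffs) / stats::sd(diffs)
}

# Wilcoxon signed-rank: W = min rank sum, exact p when possible
signed_rank <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = NA_real_, n_effective = 0L, p = 1,
                degenerate = TRUE))
  }
  r <- rank(abs(d))
  t_pos <- sum(r[d > 0])
  t_neg <- sum(r[d < 0])
  w <- min(t_pos, t_neg)
  ties <- anyDuplicated(abs(d)) > 0L
  if (!ties && n <= 25L) {
    p <- min(1, 2 * stats::psignrank(w, n))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu + 0.5) / sqrt(sig2)   # continuity correction; w <= mu
    p <- min(1, 2 * stats::pnorm(z))
  }
  list(statistic = w, n_effective = n, p = p, degenerate = FALSE)
}

#' Paired pre/post comparison with matched effect size and descriptives
#'
#' The t branch reports the paired t statistic on pre minus post with n-1
#' degrees of freedom, Cohen's d_z, and mean/sd descriptives. The Wilcoxon
#' branch reports W (the smaller signed-rank sum, zero differences dropped;
#' exact p from the signed-rank distribution for n <= 25 without ties,
#' normal approximation with continuity correction otherwise), Cliff's delta
#' over all cross pairs, and median/IQR descriptives.
#'
#' @param pre,post Equal-length paired samples, n >= 3.
#' @param choice `"paired_t"`, `"wilcoxon"`, or `NULL` to decide via
#'   [shapiro_gate()].
#' @return A list of class `"paired_test_result"`: `test_name`, `statistic`,
#'   `dof` (t) or `n_effective` (W), `n`, `p`, `effect_type`, `effect`,
#'   `descriptives` (data frame), `degenerate`.
#' @export
paired_test <- function(pre, post, choice = NULL) {
  keep <- !is.na(pre) & !is.na(post)
  pre <- pre[keep]; post <- post[keep]
  n <- length(pre)
  if (n < 3L) abort_field("pre", "needs >= 3 complete pairs")
  d <- pre - post
  if (is.null(choice)) choice <- shapiro_gate(d)
  choice <- match.arg(choice, c("paired_t", "wilcoxon"))
  degenerate <- all(d == 0)
  if (choice == "paired_t") {
    if (degenerate || stats::sd(d) == 0) {
      res <- list(statistic = if (degenerate) 0 else NA_real_,
                  dof = n - 1L, p = 1, effect = 0, degenerate = TRUE)
    } else {
      tt <- stats::t.test(pre, post, paired = TRUE)
      res <- list(statistic = unname(tt$statistic), dof = n - 1L,
                  p = tt$p.value, effect = cohens_dz(d),
                  degenerate = FALSE)
    }
    desc <- data.frame(timepoint = c("pre", "post"),
                       mean = c(mean(pre), mean(post)),
                       sd = c(stats::sd(pre), stats::sd(post)))
    out <- c(list(test_name = "paired_t"), res,
             list(n = n, effect_type = "cohens_dz", descriptives = desc))
  } else {
    sr <- signed_rank(d)
    q <- function(v) stats::quantile(v, c(0.5, 0.25, 0.75), names = FALSE)
    qpre <- q(pre); qpost <- q(post)
    desc <- data.frame(timepoint = c("pre", "post"),
                       median = c(qpre[1], qpost[1]),
                       q25 = c(qpre[2], qpost[2]),
                       q75 = c(qpre[3], qpost[3]))
    out <- list(test_name = "wilcoxon", statistic = sr$statistic,
                n_effective = sr$n_effective, n = n, p = sr$p,
                effect_type = "cliffs_delta",
                effect = cliffs_delta(pre, post),
                degenerate = sr$degenerate, descriptives = desc)
  }
  structure(out, class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("<%s> n=%d stat=%.4g p=%.3g %s=%.3f%s\n",
              x$test_name, x$n, x$statistic, x$p, x$effect_type, x$effect,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Holm-Bonferroni step-down correction
#'
#' Sorts the p-values ascending (stable order for ties) and assigns rank-k
#' threshold `alpha / (m - k + 1)`. Two decisions are reported: the per-rank
#' comparison `p <= threshold`, and the classical step-down rule that stops
#' at the first failure (so the rejection set is always a prefix of the
#' sorted order).
#'
#' @param pvals P-values in `[0, 1]`.
#' @param labels Optional test labels.
#' @param alpha Family-wise error rate (default 0.05).
#' @return Data frame in the input order: `label`, `p`, `rank`, `alpha_adj`,
#'   `reject_at_rank`, `reject_stepdown`.
#' @export
holm_bonferroni <- function(pvals, labels = NULL, alpha = 0.05) {
  m <- length(pvals)
  if (m < 1L) abort_field("pvals", "needs >= 1 p-value")
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort_field("pvals", "must lie in [0, 1]")
  }
  if (is.null(labels)) labels <- paste0("test", seq_len(m))
  ord <- order(pvals)  # stable: ties keep declared order
  rank <- integer(m); rank[ord] <- seq_len(m)
  alpha_adj <- alpha / (m - rank + 1)
  at_rank <- pvals <= alpha_adj
  stepdown <- logical(m)
  stepdown[ord] <- cumprod(at_rank[ord]) > 0
  data.frame(label = labels, p = pvals, rank = rank, alpha_adj = alpha_adj,
             reject_at_rank = at_rank, reject_stepdown = stepdown,
             stringsAsFactors = FALSE)
}

#' Electrode-wise paired tests for scalp topographies
#'
#' Runs the same gated paired comparison per electrode on patient values and
#' returns the uncorrected p-value map together with the median post-minus-
#' pre change (the quantity displayed on topographic maps).
#'
#' @param pre,post Patients x electrodes matrices with matching dimnames.
#' @param gate_alpha Normality gate level.
#' @return Data frame: `electrode`, `median_change` (post - pre), `p`,
#'   `test`, `n`, `flagged` (TRUE when the electrode is missing in more than
#'   half the patients).
#' @export
electrode_topography_tests <- function(pre, post, gate_alpha = 0.05) {
  if (!identical(dim(pre), dim(post))) {
    abort_field("post", "matrix dimensions must match pre")
  }
  if (nrow(pre) < 3L) abort_field("pre", "needs >= 3 patients")
  labs <- colnames(pre)
  if (is.null(labs)) labs <- paste0("ch", seq_len(ncol(pre)))
  rows <- lapply(seq_len(ncol(pre)), function(j) {
    ok <- !is.na(pre[, j]) & !is.na(post[, j])
    flagged <- mean(ok) < 0.5
    if (sum(ok) < 3L) {
      return(data.frame(electrode = labs[j], median_change = NA_real_,
                        p = NA_real_, test = NA_character_,
                        n = sum(ok), flagged = TRUE))
    }
    res <- paired_test(pre[ok, j], post[ok, j])
    data.frame(electrode = labs[j],
               median_change = stats::median(post[ok, j] - pre[ok, j]),
               p = res$p, test = res$test_name, n = res$n,
               flagged = flagged)
  })
  do.call(rbind, rows)
}
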