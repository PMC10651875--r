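test_that("the normality gate picks the t-test for normal differences", {
  set.seed(1)
  picks <- vapply(1:200, function(i) shapiro_gate(rnorm(20)), character(1))
  expect_gt(mean(picks == "paired_t"), 0.90)
  picks_ln <- vapply(1:200, function(i) shapiro_gate(rlnorm(20) - 1),
                     character(1))
  expect_gt(mean(picks_ln == "wilcoxon"), 0.5)
  expect_error(shapiro_gate(c(1, 2)), "3")
  expect_warning(ch <- shapiro_gate(rep(0.3, 10)), "constant")
  expect_identical(ch, "wilcoxon")
})

test_that("paired tests report the documented statistics on both branches", {
  set.seed(5)
  pre <- rnorm(22, 0.88, 0.21)
  post <- pre + rnorm(22, 0.37, 0.18)
  res <- paired_test(pre, post, choice = "paired_t")
  d <- pre - post
  ref <- t.test(pre, post, paired = TRUE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
  expect_equal(res$effect, mean(d) / sd(d))
  expect_equal(res$dof, 21L)
  expect_equal(res$descriptives$mean, c(mean(pre), mean(post)))

  resw <- paired_test(pre, post, choice = "wilcoxon")
  refw <- wilcox.test(pre, post, paired = TRUE, exact = TRUE)
  expect_equal(resw$p, refw$p.value)
  r <- rank(abs(d))
  expect_equal(resw$statistic, min(sum(r[d > 0]), sum(r[d < 0])))
  expect_equal(resw$effect, cliffs_delta(pre, post))
  expect_equal(resw$descriptives$median, c(median(pre), median(post)))

  deg <- suppressWarnings(paired_test(rep(1, 5), rep(1, 5)))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
})

test_that("the exact signed-rank p matches full enumeration for small n", {
  set.seed(17)
  for (n in c(5, 8, 12)) {
    d <- round(rnorm(n, 0.2), 3)
    res <- paired_test(d, rep(0, n), choice = "wilcoxon")
    expect_equal(res$p, wilcoxon_enum_p(d), tolerance = 1e-12)
  }
  # ties force the normal approximation; compare against wilcox.test
  d <- c(1, 1, -1, 2, 3, 3, -2, 4, 5, 5, -3, 6)
  res <- suppressWarnings(paired_test(d, rep(0, length(d)),
                                      choice = "wilcoxon"))
  ref <- suppressWarnings(wilcox.test(d, exact = FALSE, correct = TRUE))
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
})

test_that("Cliff's delta matches the brute-force definition, ties included", {
  set.seed(3)
  x <- rnorm(40)
  y <- rnorm(35, 0.4)
  expect_equal(cliffs_delta(x, y), cliffs_brute(x, y))
  xi <- sample(1:5, 30, replace = TRUE)
  yi <- sample(2:6, 25, replace = TRUE)
  expect_equal(cliffs_delta(xi, yi), cliffs_brute(xi, yi))
  expect_equal(cliffs_delta(c(5, 6), c(1, 2)), 1)
  expect_equal(cliffs_delta(c(1, 2), c(5, 6)), -1)
  expect_equal(cliffs_delta(c(1, 1), c(1, 1)), 0)
})

test_that("Holm-Bonferroni produces the analytic adjusted-alpha ladders", {
  p8 <- c(1e-6, 2e-6, 3e-4, 0.002, 0.004, 0.009, 0.03, 0.2)
  h8 <- holm_bonferroni(p8, labels = paste0("t", 1:8))
  expect_equal(signif(h8$alpha_adj, 3),
               c(0.00625, 0.00714, 0.00833, 0.01, 0.0125, 0.0167, 0.025, 0.05))
  # step-down: rejection stops at the first failure
  expect_identical(h8$reject_stepdown,
                   c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  h3 <- holm_bonferroni(c(0.001, 0.2, 0.3), labels = c("a", "b", "c"))
  expect_equal(signif(h3$alpha_adj[1], 3), 0.0167)
  expect_identical(h3$reject_stepdown, c(TRUE, FALSE, FALSE))
  h1 <- holm_bonferroni(0.04, labels = "only")
  expect_equal(h1$alpha_adj, 0.05)
  expect_true(h1$reject_stepdown)
  # rejections are a prefix of the p-value ordering for random inputs
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(2:10, 1))
    h <- holm_bonferroni(p, labels = seq_along(p))
    rej <- h$reject_stepdown[order(h$rank)]
    expect_true(all(diff(as.integer(rej)) <= 0))
  }
})

test_that("HAM-D normalization and remission follow their definitions", {
  expect_equal(normalize_hamd(0, "17"), 0)
  expect_equal(normalize_hamd(52, "17"), 1)
  expect_equal(normalize_hamd(26, "17"), 0.5)
  expect_equal(normalize_hamd(38, "24"), 0.5)
  expect_error(normalize_hamd(60, "17"), "score")
  expect_error(normalize_hamd(-1, "24"), "score")
  expect_equal(remission_rate(c(20, 20, 20, 20), c(10, 11, 9, 20)), 50)
  expect_equal(remission_rate(c(24, 24), c(12, 13)), 50)
  expect_equal(remission_rate(c(24, 24), c(2, 3)), 100)
  expect_warning(r <- remission_rate(c(0, 20), c(0, 5)), "baseline")
  expect_equal(r, 100)
})

test_that("HC3 regression matches the reference implementation and a hand computation", {
  set.seed(12)
  n <- 60
  X <- cbind(rnorm(n), runif(n))
  y <- 1 + 0.5 * X[, 1] - 0.3 * X[, 2] + rnorm(n, 0, exp(X[, 1] / 2))
  res <- hc3_ols(y, cbind(1, X), term_labels = c("intercept", "x1", "x2"))
  fit <- lm(y ~ X)
  vc <- sandwich::vcovHC(fit, type = "HC3")
  expect_equal(res$terms$se, unname(sqrt(diag(vc))), tolerance = 1e-10)
  expect_equal(res$terms$beta, unname(coef(fit)), tolerance = 1e-12)
  expect_equal(res$r_squared, summary(fit)$r.squared, tolerance = 1e-12)

  # hand computation on a frozen 6-point toy problem
  xt <- c(0, 1, 2, 3, 4, 5)
  yt <- c(1.0, 1.8, 3.4, 3.1, 5.2, 5.9)
  Xm <- cbind(1, xt)
  beta <- solve(crossprod(Xm), crossprod(Xm, yt))
  e <- yt - Xm %*% beta
  h <- diag(Xm %*% solve(crossprod(Xm)) %*% t(Xm))
  meat <- t(Xm) %*% diag(as.numeric(e^2) / (1 - h)^2) %*% Xm
  vhand <- solve(crossprod(Xm)) %*% meat %*% solve(crossprod(Xm))
  rt <- hc3_ols(yt, Xm, term_labels = c("intercept", "x"))
  expect_equal(rt$terms$se, unname(sqrt(diag(vhand))), tolerance = 1e-10)

  # under homoskedasticity HC3 and classical errors agree closely
  set.seed(2)
  Xh <- cbind(1, matrix(rnorm(400), ncol = 2))
  yh <- drop(Xh %*% c(0.2, 1, -1)) + rnorm(200)
  rh <- hc3_ols(yh, Xh)
  rc <- hc3_ols(yh, Xh, covariance = "standard")
  expect_true(all(abs(rh$terms$se / rc$terms$se - 1) < 0.2))
  expect_error(hc3_ols(1:5, cbind(1:5, 2 * (1:5))), "rank")
})

test_that("band-power regression attributes broadband change to the exponent", {
  set.seed(30)
  n <- 60
  feats <- data.frame(
    patient = paste0("p", 1:n),
    exponent_diff = rnorm(n, -0.3, 0.15),
    delta_osc_diff = rnorm(n, 0, 0.1),
    delta_abundance_diff = rnorm(n, 0, 0.2))
  feats$delta_power_diff <- 0.9 * scale(feats$exponent_diff)[, 1] * 0.1 +
    rnorm(n, 0, 0.02)
  res <- band_power_regression(feats, "delta")
  expect_true(is.data.frame(res$holm))
  expect_identical(nrow(res$holm), 3L)
  ex_row <- res$terms[res$terms$term == "exponent", ]
  expect_lt(ex_row$p, 0.001)
  # the z-scored exponent coefficient recovers the planted loading
  expect_equal(ex_row$beta, 0.9 * 0.1 / sd(feats$delta_power_diff),
               tolerance = 0.15)
  expect_error(band_power_regression(feats[1:4, ], "delta"), "n")
})

test_that("the exhaustive outcome search prefers the truly predictive feature", {
  set.seed(40)
  n <- 33
  base <- data.frame(
    treatment = rep(c("ECT", "MST"), c(19, 14)),
    exponent_pre = rnorm(n, 0.9, 0.2),
    delta_abundance_pre = runif(n),
    theta_abundance_pre = runif(n),
    exponent_diff = rnorm(n, -0.3, 0.2),
    delta_abundance_diff = rnorm(n, 0, 0.2),
    theta_abundance_diff = rnorm(n, 0, 0.2),
    n_treatments = sample(6:15, n, replace = TRUE))
  base$hamd_pre_norm <- runif(n, 0.3, 0.7)
  base$hamd_post_norm <- base$hamd_pre_norm * 0.5 -
    0.15 * scale(base$exponent_pre)[, 1] + rnorm(n, 0, 0.03)
  sr <- exhaustive_outcome_search(base)
  expect_identical(sr$selected, "exponent_pre")
  expect_identical(nrow(sr$search), 7L)
  expect_true(all(c("hamd_pre_norm", "treatment", "exponent_pre") %in%
                    sr$result$terms$term))
  expect_equal(sr$n, 33L)
  # restricting the candidate set restricts the search
  sr1 <- exhaustive_outcome_search(base, candidates = "n_treatments")
  expect_identical(sr1$selected, "n_treatments")
})

test_that("electrode topography tests flag sparse electrodes and find planted shifts", {
  set.seed(50)
  n <- 20
  pre <- cbind(E1 = rnorm(n, 0.9, 0.1), E2 = rnorm(n, 0.9, 0.1))
  post <- cbind(E1 = pre[, 1] + rnorm(n, 0.4, 0.1),
                E2 = pre[, 2] + rnorm(n, 0, 0.05))
  tt <- electrode_topography_tests(pre, post)
  expect_identical(tt$electrode, c("E1", "E2"))
  expect_lt(tt$p[1], 0.001)
  expect_gt(tt$median_change[1], 0.3)
  expect_false(any(tt$flagged))
  # >50% missing pairs flags the electrode
  pre[1:11, 2] <- NA
  tf <- electrode_topography_tests(pre, post)
  expect_true(tf$flagged[2])
  expect_error(electrode_topography_tests(pre[1:2, ], post[1:2, ]), "3")
})
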