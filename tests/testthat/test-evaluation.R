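# Nonparametric tests, logistic calibration, ROC machinery.

test_that("exact Mann-Whitney matches full enumeration on small samples", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$method, "mann_whitney_exact")

  set.seed(14)
  for (rep in 1:60) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    # integer pools force ties in roughly half the draws
    x <- sample(1:6, nx, replace = TRUE)
    y <- sample(1:6, ny, replace = TRUE) + sample(0:1, 1)
    res <- mann_whitney_u(x, y, mode = "exact")
    expect_equal(res$p_value, brute_force_mw_p(x, y),
                 tolerance = 1e-12,
                 label = sprintf("x=%s y=%s", toString(x), toString(y)))
  }
})

test_that("exact Mann-Whitney agrees with wilcox.test on untied samples", {
  set.seed(5)
  for (rep in 1:40) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    x <- rnorm(nx); y <- rnorm(ny, 0.5)
    ours <- mann_whitney_u(x, y, mode = "exact")
    ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-10)
    expect_equal(ours$statistic, unname(ref$statistic))
  }
})

test_that("identical samples give p = 1 and the normal mode tracks exact", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  set.seed(21)
  x <- rnorm(7); y <- rnorm(7, 0.8)
  pe <- mann_whitney_u(x, y, mode = "exact")$p_value
  pn <- mann_whitney_u(x, y, mode = "normal")$p_value
  expect_lt(abs(pe - pn), 0.02)
  # auto mode switches to the normal approximation on large samples
  big <- mann_whitney_u(rnorm(400), rnorm(400))
  expect_equal(big$method, "mann_whitney_normal")
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Fisher's exact test matches hand enumeration and fisher.test", {
  expect_equal(fisher_exact(matrix(c(1, 1, 1, 1), 2))$p_value, 1)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2))$p_value, 2 / 252,
               tolerance = 1e-12)
  # non-survivor/survivor x shock/no-shock margins
  shock <- matrix(c(6, 4, 8, 96), nrow = 2)
  res <- fisher_exact(shock)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$p_value,
               stats::fisher.test(shock)$p.value, tolerance = 1e-9)
  set.seed(33)
  for (rep in 1:50) {
    tab <- matrix(rpois(4, 5), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9,
                 label = toString(tab))
  }
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("r x 2 Fisher generalisation matches fisher.test", {
  set.seed(8)
  for (rep in 1:15) {
    tab <- matrix(rpois(8, 4), nrow = 4)
    if (any(rowSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-8)
  }
})

test_that("IRLS logistic regression matches glm and recovers parameters", {
  set.seed(2)
  x <- rnorm(2000, 8, 4)
  y <- runif(2000) < 1 / (1 + exp(-(-3 + 0.5 * x)))
  fit <- fit_univariate_logistic(x, y)
  expect_true(fit$converged)
  ref <- stats::glm(y ~ x, family = stats::binomial())
  expect_equal(fit$beta0, unname(coef(ref)[1]), tolerance = 1e-6)
  expect_equal(fit$beta1, unname(coef(ref)[2]), tolerance = 1e-6)
  expect_equal(fit$log_likelihood, as.numeric(stats::logLik(ref)),
               tolerance = 1e-6)
  expect_equal(fit$se_beta1,
               unname(sqrt(diag(stats::vcov(ref)))[2]), tolerance = 1e-4)
  expect_lt(abs(fit$beta1 - 0.5), 0.1)
})

test_that("null scores give an insignificant slope; degenerate inputs error", {
  set.seed(77)
  x <- rnorm(3000)
  y <- sample(c(0, 1), 3000, replace = TRUE, prob = c(0.85, 0.15))
  fit <- fit_univariate_logistic(x, y)
  expect_lt(abs(fit$beta1), 3 * fit$se_beta1)
  expect_error(fit_univariate_logistic(1:10, rep(0, 10)), "single class")
  expect_error(fit_univariate_logistic(c(1, 2, 3, 7, 8, 9),
                                       c(0, 0, 0, 1, 1, 1)),
               "complete separation.*upward")
  expect_error(fit_univariate_logistic(c(7, 8, 9, 1, 2, 3),
                                       c(0, 0, 0, 1, 1, 1)),
               "complete separation.*downward")
})

test_that("predicted probabilities follow the logit formula exactly", {
  expect_equal(predict_probability(list(beta0 = 0, beta1 = 0), 17), 0.5)
  expect_equal(predict_probability(list(beta0 = 0, beta1 = 1), 0), 0.5)
  expect_equal(predict_probability(list(beta0 = 0, beta1 = 1), 1e4), 1)
  expect_equal(predict_probability(list(beta0 = -2, beta1 = 0.25), 8), 0.5)
  expect_equal(predict_probability(list(beta0 = -1.3, beta1 = 0.2), 4),
               1 / (1 + exp(-(-1.3 + 0.2 * 4))))
  p <- predict_probability(list(beta0 = -2, beta1 = 0.3), 0:20)
  expect_true(all(diff(p) > 0))
  expect_error(predict_probability(list(beta0 = NA, beta1 = 1), 1), "finite")
})

test_that("ROC curves have the stated shape and AUC values", {
  r <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(roc_curve(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)
  expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
  expect_equal(c(r$tpr[1], r$fpr[1]), c(0, 0))
  expect_equal(c(r$tpr[length(r$tpr)], r$fpr[length(r$fpr)]), c(1, 1))
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "both outcome classes")
})

test_that("AUC equals the normalised Mann-Whitney U statistic (ties half)", {
  set.seed(12)
  for (rep in 1:200) {
    n1 <- sample(2:12, 1); n0 <- sample(2:12, 1)
    pos <- sample(0:8, n1, replace = TRUE)
    neg <- sample(0:8, n0, replace = TRUE)
    auc <- roc_curve(c(pos, neg), rep(c(1, 0), c(n1, n0)))$auc
    u <- mann_whitney_u(pos, neg, mode = "normal")$statistic
    expect_equal(auc, u / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  scores <- sample(0:15, 80, replace = TRUE)
  y <- rbinom(80, 1, plogis(-2 + 0.25 * scores))
  if (sum(y) %in% c(0, 80)) skip("degenerate draw")
  ours <- roc_curve(scores, y)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(y, scores)))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("Youden cutoff maximises J with ties broken to specificity", {
  expect_equal(optimal_cutoff(roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))), 3)
  # uninformative: J = 0 everywhere; tie rule picks the most specific cutoff
  r <- roc_curve(rep(c(1, 2), 4), rep(c(0, 1), each = 4))
  expect_equal(max(r$tpr - r$fpr), 0)
  expect_equal(optimal_cutoff(r), 2)
  set.seed(44)
  scores <- sample(0:27, 300, replace = TRUE)
  y <- rbinom(300, 1, plogis(-3 + 0.2 * scores))
  r <- roc_curve(scores, y)
  cut <- optimal_cutoff(r)
  m <- confusion_metrics(scores, y, cut)
  j_all <- vapply(sort(unique(scores)), function(t) {
    mm <- confusion_metrics(scores, y, t)
    mm$sensitivity + mm$specificity - 1
  }, numeric(1))
  expect_equal(m$sensitivity + m$specificity - 1, max(j_all),
               tolerance = 1e-12)
})

test_that("confusion metrics identities hold on random count tables", {
  set.seed(3)
  for (rep in 1:100) {
    cts <- rpois(4, 20)
    if (cts[1] + cts[4] == 0 || cts[2] + cts[3] == 0) next
    m <- classifier_metrics(tp = cts[1], fp = cts[2], tn = cts[3],
                            fn = cts[4])
    expect_equal(m$accuracy, (cts[1] + cts[3]) / sum(cts))
    if (cts[1] + cts[2] > 0) expect_equal(m$ppv, cts[1] / (cts[1] + cts[2]))
    if (cts[3] + cts[4] > 0) expect_equal(m$npv, cts[3] / (cts[3] + cts[4]))
    expect_equal(m$tp + m$fn, cts[1] + cts[4])
    expect_equal(m$tn + m$fp, cts[2] + cts[3])
  }
  # extreme cutoffs
  scores <- c(1, 3, 5, 7); y <- c(0, 1, 0, 1)
  lo <- confusion_metrics(scores, y, 0)
  expect_equal(c(lo$sensitivity, lo$specificity), c(1, 0))
  hi <- confusion_metrics(scores, y, 100)
  expect_equal(c(hi$sensitivity, hi$specificity), c(0, 1))
})
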