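test_that("binary_metrics handles perfect and degenerate classifiers", {
  perfect <- binary_metrics(list(tp = 10, fp = 0, fn = 0, tn = 10))
  expect_equal(perfect$tpr, 1)
  expect_equal(perfect$tnr, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$balanced_accuracy, 1)

  degen <- binary_metrics(list(tp = 0, fp = 0, fn = 10, tn = 10))
  expect_equal(degen$tpr, 0)
  expect_equal(degen$mcc, 0)
  expect_true(degen$mcc_degenerate)

  expect_error(binary_metrics(list(tp = -1, fp = 0, fn = 0, tn = 0)),
               "negative")
  # undefined rate reported as absent
  nop <- binary_metrics(list(tp = 0, fp = 0, fn = 0, tn = 5))
  expect_true(is.na(nop$tpr))
})

test_that("exact AUC matches closed-form cases and is transform-invariant", {
  y <- c(0, 0, 1, 1)
  expect_equal(exact_auc(c(0, 0, 1, 1), y), 1.0)
  expect_equal(exact_auc(c(0.3, 0.8, 0.5, 0.9), y), 0.75)

  set.seed(61)
  p <- runif(2000)
  yy <- rbinom(2000, 1, p)
  a1 <- exact_auc(p, yy)
  a2 <- exact_auc(qlogis(p), yy)  # strictly monotone transform
  expect_equal(a1, a2)
})

test_that("quantile-grid ROC tracks the exact rank AUC", {
  # posteriors equal to the labels
  y <- rep(c(0, 1), 50)
  r <- roc_pr_by_quantiles(y + 0, y)
  expect_equal(r$auc, 1.0)

  # independent posteriors: AUC near 0.5 (fixed-seed permutation)
  set.seed(71)
  p <- runif(10000)
  y2 <- sample(rep(0:1, 5000))
  expect_lt(abs(roc_pr_by_quantiles(p, y2)$auc - 0.5), 0.02)

  expect_error(roc_pr_by_quantiles(runif(5), rep(1, 5)), "class")

  # grid AUC is invariant to monotone transforms within grid tolerance
  set.seed(72)
  p3 <- rnorm(3000)
  y3 <- rbinom(3000, 1, plogis(p3))
  a <- roc_pr_by_quantiles(p3, y3)$auc
  b <- roc_pr_by_quantiles(exp(p3), y3)$auc
  expect_lt(abs(a - b), 1e-3)
})

test_that("ols_fit recovers exact linear relations", {
  x <- 1:10
  fit1 <- ols_fit(x, x)
  expect_equal(fit1$r_squared, 1)
  expect_equal(fit1$slope, 1)
  expect_equal(fit1$intercept, 0)

  fit2 <- ols_fit(x, 2 * x + 1)
  expect_equal(fit2$slope, 2)
  expect_equal(fit2$intercept, 1)
  expect_equal(fit2$r_squared, 1)

  expect_error(ols_fit(rep(1, 5), 1:5), "variance")
  expect_error(ols_fit(1:2, 1:2), "n >= 3")
})

test_that("tmb_concordance regresses truth on the estimate", {
  s <- data.frame(true_tmb = c(1, 2, 3, 4), naive_tmb = c(1, 2, 3, 4) * 3 + 2)
  fit <- tmb_concordance(s, "naive")
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 1 / 3)
  expect_error(tmb_concordance(s, "missing"), "missing column")
  expect_error(tmb_concordance(s[1:2, ], "naive"), "n >= 3")
})

test_that("bias_report compares group TMB distributions by rank-sum", {
  set.seed(81)
  base <- rlnorm(67, log(3), 0.4)
  s <- data.frame(group = rep(c("white", "black"), c(55, 12)),
                  same_tmb = base,
                  shifted_tmb = base + ifelse(rep(c(TRUE, FALSE), c(55, 12)),
                                              0, 20))
  rep_ <- bias_report(s, "group")
  expect_gt(rep_$p_value[rep_$method == "same"], 0.05)
  expect_lt(rep_$p_value[rep_$method == "shifted"], 0.001)
  expect_equal(rep_$median_black[rep_$method == "shifted"],
               median(base[56:67]) + 20)

  s$group[1:65] <- "white"  # black shrinks below 3
  s$group[66:67] <- "black"
  expect_warning(expect_error(bias_report(s[1:66, ], "group"), "2 groups"),
                 "excluding")
})

test_that("explain_tpr recovers TPR = 1 - MVTSM and guards degenerate input", {
  s <- data.frame(mvtsm = seq(0.1, 0.45, length.out = 8))
  s$tpr <- 1 - s$mvtsm
  fit <- explain_tpr(s)
  expect_equal(fit$slope, -1)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  s$mvtsm <- 0.3
  expect_error(explain_tpr(s), "variance")
})

test_that("fp_tn_contingency tabulates feature prevalence", {
  # all-zero feature
  calls <- c(1, 1, 0, 0)
  labels <- c(0, 0, 0, 0)
  res <- fp_tn_contingency(calls, labels, rep(0, 4))
  expect_equal(res$prop_nonzero_fp, 0)
  expect_equal(res$prop_nonzero_tn, 0)
  expect_equal(res$p_value, 1)

  # symmetric 2x2 -> p = 1
  calls2 <- rep(c(1, 0), each = 10)
  labels2 <- rep(0, 20)
  feat2 <- rep(c(1, 0), 10)
  res2 <- fp_tn_contingency(calls2, labels2, feat2)
  expect_equal(unname(res2$table["FP", ]), c(5, 5))
  expect_equal(res2$p_value, 1)

  # empty FP stratum -> p absent
  res3 <- fp_tn_contingency(rep(0, 4), rep(0, 4), rep(1, 4))
  expect_true(is.na(res3$p_value))
})

test_that("patient_level_metrics computes per-sample confusion rates", {
  ids <- rep(c("S1", "S2"), each = 4)
  labels <- rep(c(1, 1, 0, 0), 2)
  calls <- c(1, 1, 0, 0,  1, 0, 1, 0)
  m <- patient_level_metrics(ids, calls, labels)
  expect_equal(m$tpr[m$sample_id == "S1"], 1)
  expect_equal(m$mcc[m$sample_id == "S1"], 1)
  expect_equal(m$tpr[m$sample_id == "S2"], 0.5)
  expect_equal(m$mcc[m$sample_id == "S2"], 0)
})
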