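# Benchmark metrics: confusion-matrix rates, MCC, quantile-threshold
# ROC/PR curves, exact rank-based AUC, TMB concordance regression, the
# germline-database bias report, and the performance-explanation analyses
# (TPR vs median somatic VAF; FP/TN COSMIC contingency).

#' Confusion counts from binary calls and truth labels
#'
#' Somatic (label 1) is the positive class: TP = somatic called somatic,
#' FP = germline called somatic, FN = somatic called germline, TN = germline
#' called germline.
#'
#' @param calls 0/1 predictions.
#' @param labels 0/1 truth.
#' @return list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(calls, labels) {
  stopifnot(length(calls) == length(labels))
  list(tp = sum(calls == 1 & labels == 1),
       fp = sum(calls == 1 & labels == 0),
       fn = sum(calls == 0 & labels == 1),
       tn = sum(calls == 0 & labels == 0))
}

#' Binary classification metrics from confusion counts
#'
#' TPR, TNR, PPV, NPV, MCC and balanced accuracy. A rate whose denominator
#' is zero is reported as `NA`; an MCC with a zero denominator is reported
#' as 0 with `mcc_degenerate = TRUE` (standard convention).
#'
#' @param counts list or vector with `tp`, `fp`, `fn`, `tn`.
#' @param auc optional AUC to carry through.
#' @param call_rate optional call rate in `[0, 100]`.
#' @return list of metrics.
#' @export
binary_metrics <- function(counts, auc = NA_real_, call_rate = NA_real_) {
  tp <- as.numeric(counts[["tp"]]); fp <- as.numeric(counts[["fp"]])
  fn <- as.numeric(counts[["fn"]]); tn <- as.numeric(counts[["tn"]])
  if (any(c(tp, fp, fn, tn) < 0)) stop("negative confusion counts")
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  tpr <- rate(tp, tp + fn)
  tnr <- rate(tn, tn + fp)
  ppv <- rate(tp, tp + fp)
  npv <- rate(tn, tn + fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  degenerate <- den == 0
  mcc <- if (degenerate) 0 else (tp * tn - fp * fn) / sqrt(den)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       tpr = tpr, tnr = tnr, ppv = ppv, npv = npv,
       mcc = mcc, mcc_degenerate = degenerate,
       balanced_accuracy = (tpr + tnr) / 2,
       auc = auc, call_rate = call_rate)
}

#' Exact rank-based AUC (Mann-Whitney)
#'
#' @param posteriors numeric scores.
#' @param labels 0/1 truth (both classes required).
#' @return AUC in `[0, 1]`.
#' @export
exact_auc <- function(posteriors, labels) {
  y <- as.numeric(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUC requires both classes")
  r <- rank(posteriors, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC and precision-recall curves over a posterior-quantile grid
#'
#' Thresholds are placed at `n_quantiles` quantiles of the posterior
#' distribution (the construction used for the benchmark curves); the ROC
#' sweep is completed with the (0,0) and (1,1) endpoints and AUC computed
#' by the trapezoid rule. Average precision is the step-function integral
#' of precision over recall.
#'
#' @param posteriors numeric scores.
#' @param labels 0/1 truth (both classes required).
#' @param n_quantiles grid size (default 500).
#' @return list with `roc` (threshold, fpr, tpr), `pr` (threshold, recall,
#'   precision), `auc`, `average_precision`.
#' @export
roc_pr_by_quantiles <- function(posteriors, labels, n_quantiles = 500L) {
  y <- as.numeric(if (is.data.frame(labels)) labels$label else labels)
  if (length(unique(y)) < 2L) stop("ROC requires both classes")
  grid <- sort(unique(quantile(posteriors, probs = seq(0, 1, length.out = n_quantiles),
                               names = FALSE, type = 7)), decreasing = TRUE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  pts <- vapply(grid, function(th) {
    call <- posteriors >= th
    tp <- sum(call & y == 1); fp <- sum(call & y == 0)
    c(fpr = fp / n0, tpr = tp / n1,
      precision = if (tp + fp > 0) tp / (tp + fp) else 1,
      recall = tp / n1)
  }, numeric(4))
  roc <- data.table(threshold = grid, fpr = pts["fpr", ], tpr = pts["tpr", ])
  fpr <- c(0, roc$fpr, 1)
  tpr <- c(0, roc$tpr, 1)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tail(tpr, -1L)) / 2)
  pr <- data.table(threshold = grid, recall = pts["recall", ],
                   precision = pts["precision", ])
  rec <- c(0, pr$recall)
  ap <- sum(diff(rec) * pr$precision)
  list(roc = roc, pr = pr, auc = auc, average_precision = ap)
}

#' Ordinary least squares of y on x
#'
#' @param x predictor.
#' @param y response.
#' @return list with `r_squared`, `slope`, `intercept`, `n`.
#' @export
ols_fit <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("regression requires n >= 3")
  if (var(x) == 0) stop("zero variance in predictor")
  fit <- lm(y ~ x)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  list(r_squared = r2,
       slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       n = length(x))
}

#' TMB concordance regression
#'
#' Regresses the matched-normal ("true") TMB on a tumor-only estimate, the
#' orientation under which germline leakage variance attenuates the slope:
#' an unreliable naive estimate yields slope and R-squared near 0, while a
#' well-corrected estimate yields a slope near 1. (Regressing the estimate
#' on truth instead would pin the expected slope at >= 1 under additive
#' leakage and could not reproduce the benchmark behavior.)
#'
#' @param samples per-sample `data.frame` with a `true_tmb` column and one
#'   `<method>_tmb` column per method.
#' @param method method name, e.g. `"naive"` or `"lgbm"`.
#' @return list with `r_squared`, `slope`, `intercept`, `n`.
#' @export
tmb_concordance <- function(samples, method) {
  s <- as.data.table(samples)
  col <- paste0(method, "_tmb")
  if (!(col %in% names(s))) stop("missing column: ", col)
  if (nrow(s) < 3L) stop("TMB concordance requires n >= 3 samples")
  ols_fit(x = s[[col]], y = s$true_tmb)
}

#' Racial-bias report for TMB methods
#'
#' For each TMB method, compares the per-sample TMB distributions between
#' groups (e.g., self-identified race) with group medians and a two-sided
#' Wilcoxon rank-sum test. Groups with fewer than 3 samples are excluded
#' with a warning. Exactly two (remaining) groups are required for the
#' rank-sum p-value.
#'
#' @param samples per-sample `data.frame` with `<method>_tmb` columns and a
#'   grouping column.
#' @param group_field name of the grouping column.
#' @param methods method names; default: every `<method>_tmb` column.
#' @return `data.table`: method, group medians (one column per group),
#'   `p_value`.
#' @export
bias_report <- function(samples, group_field = "group", methods = NULL) {
  s <- as.data.table(samples)
  if (!(group_field %in% names(s))) stop("missing group column: ", group_field)
  grp <- as.character(s[[group_field]])
  sizes <- table(grp)
  small <- names(sizes)[sizes < 3L]
  if (length(small)) {
    warning("excluding group(s) with < 3 samples: ", paste(small, collapse = ", "))
    keep <- !(grp %in% small)
    s <- s[keep]; grp <- grp[keep]
  }
  groups <- sort(unique(grp))
  if (length(groups) < 2L) stop("bias report requires >= 2 groups with >= 3 samples")
  methods <- methods %||% sub("_tmb$", "", grep("_tmb$", names(s), value = TRUE))
  out <- rbindlist(lapply(methods, function(m) {
    v <- s[[paste0(m, "_tmb")]]
    med <- vapply(groups, function(g) median(v[grp == g]), numeric(1))
    p <- if (length(groups) == 2L)
      suppressWarnings(wilcox.test(v[grp == groups[1L]], v[grp == groups[2L]],
                                   exact = FALSE)$p.value)
    else NA_real_
    dt <- data.table(method = m, p_value = p)
    for (g in groups) dt[, (paste0("median_", g)) := med[[g]]]
    dt
  }))
  out[]
}

#' Regression of per-patient sensitivity on median somatic VAF
#'
#' The median VAF of the true somatic mutations (MVTSM) approximates tumor
#' purity divided by 2; sensitivity falls as MVTSM rises (high purity means
#' somatic VAFs approach the germline heterozygous band), so across a
#' purity gradient the fitted slope is negative, approximating
#' TPR = 1 - MVTSM.
#'
#' @param samples per-sample `data.frame` with `tpr` and `mvtsm` columns.
#' @return list with `r_squared`, `slope`, `intercept`, `n`.
#' @export
explain_tpr <- function(samples) {
  s <- as.data.table(samples)
  stopifnot(all(c("tpr", "mvtsm") %in% names(s)))
  if (nrow(s) < 3L) stop("explain_tpr requires n >= 3 samples")
  ols_fit(x = s$mvtsm, y = s$tpr)
}

#' FP/TN contingency of a count feature
#'
#' Among germline variants (truth 0), cross-tabulates the prediction
#' outcome (FP vs TN) against whether `feature` is nonzero, with row
#' proportions and a two-sided Fisher exact p-value. Used to ask whether
#' false positives are enriched for COSMIC-recorded variants.
#'
#' @param calls 0/1 predictions.
#' @param labels 0/1 truth.
#' @param feature per-variant non-negative counts (e.g. `max_cosmic_count`).
#' @return list with `table` (2x2), `prop_nonzero_fp`, `prop_nonzero_tn`,
#'   `mean_feature_fp`, `mean_feature_tn`, `p_value` (NA when a stratum is
#'   empty).
#' @export
fp_tn_contingency <- function(calls, labels, feature) {
  stopifnot(length(calls) == length(labels), length(feature) == length(labels))
  fp <- calls == 1 & labels == 0
  tn <- calls == 0 & labels == 0
  tab <- matrix(c(sum(fp & feature > 0), sum(fp & feature == 0),
                  sum(tn & feature > 0), sum(tn & feature == 0)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("FP", "TN"), c("nonzero", "zero")))
  p <- if (any(rowSums(tab) == 0)) NA_real_ else fisher.test(tab)$p.value
  list(table = tab,
       prop_nonzero_fp = if (sum(fp)) tab["FP", "nonzero"] / sum(fp) else NA_real_,
       prop_nonzero_tn = if (sum(tn)) tab["TN", "nonzero"] / sum(tn) else NA_real_,
       mean_feature_fp = if (sum(fp)) mean(feature[fp]) else NA_real_,
       mean_feature_tn = if (sum(tn)) mean(feature[tn]) else NA_real_,
       p_value = p)
}

#' Per-sample (patient-level) metrics
#'
#' Computes confusion counts and rates per sample, the boxplot-style
#' summary used for patient-level benchmarking.
#'
#' @param sample_ids per-row sample ids.
#' @param calls 0/1 predictions.
#' @param labels 0/1 truth.
#' @return `data.table` with one row per sample (tp, fp, fn, tn, tpr, tnr,
#'   ppv, npv, mcc).
#' @export
patient_level_metrics <- function(sample_ids, calls, labels) {
  dt <- data.table(sample_id = sample_ids, call = calls, label = labels)
  dt[, {
    m <- binary_metrics(confusion_counts(call, label))
    m[c("tp", "fp", "fn", "tn", "tpr", "tnr", "ppv", "npv", "mcc")]
  }, by = sample_id][]
}
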