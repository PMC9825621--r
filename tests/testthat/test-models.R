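# helper: feature matrix whose rows differ only in chosen columns
toy_fm <- function(n = 80, alt_freq = NULL, cosmic = NULL, seed = 5) {
  set.seed(seed)
  y <- rep(c(1L, 0L), length.out = n)
  v <- toy_variants(n = n,
                    t_alt_freq = alt_freq %||% rep(0.25, n),
                    cosmic_count = cosmic %||% rep(0L, n),
                    tri_context = "ACG")
  fm <- assemble_feature_matrix(v, collect_informative_snps(v, toy_segments()),
                                toy_segments())
  list(fm = fm, y = y)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("train_classifier fits separable data and is deterministic", {
  d <- toy_fm(alt_freq = rep(c(0.1, 0.5), length.out = 80))
  for (kind in c("lgbm", "xgb")) {
    m <- train_classifier(d$fm, d$y, kind = kind, nrounds = 30)
    p <- predict(m, d$fm)
    expect_length(p, 80L)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(exact_auc(p, d$y), 1.0)
  }
  m1 <- train_classifier(d$fm, d$y, kind = "lgbm", nrounds = 25, seed = 7)
  m2 <- train_classifier(d$fm, d$y, kind = "lgbm", nrounds = 25, seed = 7)
  expect_identical(predict(m1, d$fm), predict(m2, d$fm))

  expect_error(train_classifier(d$fm, rep(0L, 80), nrounds = 5),
               "single class")
  expect_error(train_classifier(d$fm, d$y[-1], nrounds = 5), "aligned")
})

test_that("predict enforces the schema hash and ignores metadata", {
  d <- toy_fm(alt_freq = rep(c(0.1, 0.5), length.out = 80))
  m <- train_classifier(d$fm, d$y, nrounds = 10)
  p <- predict(m, d$fm)

  fm_bad <- d$fm
  fm_bad$schema_hash <- "00000000"
  expect_error(predict(m, fm_bad), "hash mismatch")

  fm_meta <- d$fm
  fm_meta$meta$sample_id <- rev(fm_meta$meta$sample_id)
  expect_identical(predict(m, fm_meta), p)

  empty <- d$fm
  empty$X <- d$fm$X[0L, , drop = FALSE]
  expect_length(predict(m, empty), 0L)
})

test_that("select_threshold maximizes F1 on the quantile grid", {
  th <- select_threshold(c(0.1, 0.4, 0.6, 0.9), c(0, 0, 1, 1))
  expect_gt(th, 0.4)
  expect_lte(th, 0.6)

  # all labels somatic: F1 maximized by calling everything
  expect_warning(th1 <- select_threshold(c(0.2, 0.5, 0.8), c(1, 1, 1)),
                 "single-class")
  expect_lte(th1, 0.2)

  expect_warning(th2 <- select_threshold(rep(0.4, 5), c(0, 1, 0, 1, 1)),
                 "distinct")
  expect_equal(th2, 0.5)
})

test_that("quantile-grid threshold equals an exhaustive scan", {
  f1_at <- function(th, p, y) {
    call <- p >= th
    tp <- sum(call & y == 1); fp <- sum(call & y == 0); fn <- sum(!call & y == 1)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  set.seed(41)
  for (rep in 1:10) {
    p <- round(runif(60), 1)  # few distinct values
    y <- as.integer(runif(60) < p)
    if (length(unique(y)) < 2L) next
    th <- select_threshold(p, y, n_quantiles = 501L)
    cands <- sort(unique(p))
    brute <- cands[which.max(vapply(cands, f1_at, numeric(1), p = p, y = y))]
    expect_equal(f1_at(th, p, y), f1_at(brute, p, y))
    expect_identical(p >= th, p >= brute)
  }
})

test_that("ensemble_average is the element-wise mean", {
  expect_equal(ensemble_average(list(0.2, 0.4, 0.6)), 0.4)
  x <- runif(5)
  expect_equal(ensemble_average(list(x, x, x)), x)
  expect_equal(ensemble_average(list(c(0, 1), c(1, 0))), c(0.5, 0.5))
  expect_error(ensemble_average(list(c(0.1, 0.2), 0.3)), "mismatch")
  expect_error(ensemble_average(list(c(0.1))), "length")
})

test_that("feature importance is normalized, ordered, and identifies signal", {
  d <- toy_fm(cosmic = rep(c(25L, 0L), length.out = 80))
  m <- train_classifier(d$fm, d$y, nrounds = 20)
  imp <- feature_importance(m)
  expect_equal(imp$feature[1L], "max_cosmic_count")
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(diff(imp$importance) <= 1e-12))
  # constant features never gain importance
  expect_equal(imp$importance[imp$feature == "t_maj_allele"], 0)
})

test_that("model artifacts round-trip through save/load", {
  d <- toy_fm(alt_freq = rep(c(0.1, 0.5), length.out = 80))
  m <- train_classifier(d$fm, d$y, kind = "lgbm", nrounds = 15)
  dir <- tempfile("model_")
  save_classifier(m, dir, thresholds = list(threshold_snv = 0.5,
                                            threshold_indel = 0.4,
                                            threshold_tmb = 0.5))
  m2 <- load_classifier(dir)
  expect_equal(predict(m2, d$fm), predict(m, d$fm))
  expect_equal(m2$schema_hash, m$schema_hash)
})

test_that("ensemble AUC is never below the worst member on synthetic replicates", {
  suite <- tiny_suite()
  for (seed in c(302, 303)) {
    co <- simulate_cohort(cohort_config(n_patients = c(low = 1L, mid = 1L,
                                                       high = 1L)), seed = seed)
    an <- analyze_cohort(co, use_pon = FALSE)
    post <- predict_suite(suite, an$fm)
    aucs <- vapply(post[c("lgbm", "xgb")], exact_auc, numeric(1),
                   labels = an$labels$label)
    expect_gte(exact_auc(post$ensemble, an$labels$label), min(aucs) - 1e-9)
  }
})

test_that("threshold_set selects per-category cutoffs with sane defaults", {
  set.seed(13)
  n <- 200
  cat <- sample(c("SNV", "indel"), n, TRUE, prob = c(0.8, 0.2))
  y <- rbinom(n, 1, 0.5)
  p <- plogis(qlogis(0.5) + (y - 0.5) * 3 + rnorm(n))
  ts <- threshold_set(p, y, cat)
  expect_true(ts$threshold_snv > 0 && ts$threshold_snv < 1)
  expect_true(ts$threshold_indel > 0 && ts$threshold_indel < 1)
  expect_equal(ts$threshold_tmb, 0.5)
  calls <- apply_thresholds(p, cat, ts)
  expect_true(all(calls %in% 0:1))
})
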