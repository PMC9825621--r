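# Gradient-boosted tabular classifiers, category-specific posterior
# thresholds, ensembling and feature importance.
#
# The boosting engine lives in src/gbt.cpp (there is no gradient-boosted
# tree package in the supported environment, so the engine is part of this
# package). Two presets mirror the published configurations: a LightGBM-
# style leaf-wise learner with the stated hyperparameters, and an XGBoost-
# default-like depth-wise learner.

#' Model hyperparameter presets
#'
#' `lgbm_params()` carries the stated configuration of the leaf-wise model:
#' binary objective, `num_iteration` 10000, `num_leaves` 30,
#' `learning_rate` 0.1, `bagging_fraction` 0.7, `feature_fraction` 0.7,
#' `bagging_freq` 5, `bagging_seed` 2018. `xgb_params()` mirrors XGBoost
#' defaults: depth-wise growth to depth 6, `eta` 0.3, L2 lambda 1, no
#' subsampling. The full 10000 iterations are a server-scale setting; pass
#' `nrounds` to [train_classifier()] to train at desk scale.
#'
#' @param ... overrides.
#' @return named list of hyperparameters.
#' @export
lgbm_params <- function(...) {
  p <- list(objective = "binary", growth = "leafwise", num_iteration = 10000L,
            num_leaves = 30L, max_depth = 9999L, learning_rate = 0.1,
            bagging_fraction = 0.7, feature_fraction = 0.7, bagging_freq = 5L,
            seed = 2018, lambda_l2 = 0, min_data_in_leaf = 20L,
            min_sum_hessian = 1e-3, max_bins = 63L)
  utils::modifyList(p, list(...))
}

#' @rdname lgbm_params
#' @export
xgb_params <- function(...) {
  p <- list(objective = "binary", growth = "depthwise", num_iteration = 100L,
            num_leaves = 9999L, max_depth = 6L, learning_rate = 0.3,
            bagging_fraction = 1.0, feature_fraction = 1.0, bagging_freq = 0L,
            seed = 0, lambda_l2 = 1, min_data_in_leaf = 1L,
            min_sum_hessian = 1.0, max_bins = 63L)
  utils::modifyList(p, list(...))
}

#' Train a somatic-vs-germline classifier
#'
#' @param fm `sv_feature_matrix` from [assemble_feature_matrix()].
#' @param labels label table from [label_variants()] (aligned by row) or a
#'   0/1 vector.
#' @param kind `"lgbm"` (leaf-wise preset) or `"xgb"` (depth-wise preset).
#' @param params hyperparameters; defaults to the preset for `kind`.
#' @param nrounds boosting iterations; defaults to `params$num_iteration`.
#' @param seed bagging/feature-sampling seed; defaults to `params$seed`.
#' @return object of class `sv_classifier` carrying the fitted engine
#'   model, hyperparameters, feature schema hash and training metadata.
#'   Training is reproducible given the seed; every prediction row receives
#'   a posterior (call rate 100%).
#' @export
train_classifier <- function(fm, labels, kind = c("lgbm", "xgb"),
                             params = NULL, nrounds = NULL, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(fm, "sv_feature_matrix"))
  y <- if (is.data.frame(labels)) labels$label else as.numeric(labels)
  if (length(y) != nrow(fm$X))
    stop("labels (", length(y), ") not aligned to feature matrix rows (",
         nrow(fm$X), ")")
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class")
  params <- params %||% if (kind == "lgbm") lgbm_params() else xgb_params()
  if (!is.null(seed)) params$seed <- seed
  nrounds <- as.integer(nrounds %||% params$num_iteration)
  eng <- list(nrounds = nrounds,
              num_leaves = as.integer(params$num_leaves),
              max_depth = as.integer(params$max_depth),
              min_data_in_leaf = as.integer(params$min_data_in_leaf),
              max_bins = as.integer(params$max_bins),
              bagging_freq = as.integer(params$bagging_freq),
              learning_rate = as.numeric(params$learning_rate),
              lambda_l2 = as.numeric(params$lambda_l2),
              min_sum_hessian = as.numeric(params$min_sum_hessian),
              bagging_fraction = as.numeric(params$bagging_fraction),
              feature_fraction = as.numeric(params$feature_fraction),
              growth = params$growth,
              seed = as.numeric(params$seed))
  model <- .gbt_train_cpp(fm$X, y, eng)
  structure(list(kind = kind, engine = model, params = params,
                 nrounds = nrounds,
                 feature_names = colnames(fm$X),
                 schema_hash = fm$schema_hash,
                 schema_version = fm$schema_version,
                 meta = list(seed = params$seed, n_rows = nrow(fm$X),
                             label_balance = mean(y))),
            class = "sv_classifier")
}

#' @export
print.sv_classifier <- function(x, ...) {
  cat("<sv_classifier> kind=", x$kind, ", ", x$nrounds, " rounds, ",
      length(x$feature_names), " features, trained on ", x$meta$n_rows,
      " rows (", round(100 * x$meta$label_balance, 1), "% somatic)\n", sep = "")
  invisible(x)
}

#' Predict somatic posterior probabilities
#'
#' @param object `sv_classifier`.
#' @param fm `sv_feature_matrix` with matching schema hash.
#' @param ... unused.
#' @return numeric vector of posteriors in `[0, 1]`, one per row.
#' @export
predict.sv_classifier <- function(object, fm, ...) {
  stopifnot(inherits(fm, "sv_feature_matrix"))
  if (!identical(fm$schema_hash, object$schema_hash))
    stop("feature schema hash mismatch: model ", object$schema_hash,
         " vs matrix ", fm$schema_hash)
  if (nrow(fm$X) == 0L) return(numeric())
  as.numeric(.gbt_predict_cpp(object$engine, fm$X))
}

#' Select a posterior-probability threshold on a quantile grid
#'
#' Scans `n_quantiles` quantiles of the posterior distribution and returns
#' the grid threshold maximizing F1 (calls are `posterior >= threshold`).
#' Ties break toward the smallest threshold, which maximizes sensitivity.
#'
#' @param posteriors numeric vector.
#' @param labels 0/1 truth labels.
#' @param categories optional per-row category vector; with `category` set,
#'   the scan is restricted to rows of that category.
#' @param category `"SNV"` or `"indel"` (optional).
#' @param n_quantiles grid size (default 500).
#' @return threshold in (0, 1).
#' @export
select_threshold <- function(posteriors, labels, categories = NULL,
                             category = NULL, n_quantiles = 500L) {
  if (!is.null(category)) {
    stopifnot(!is.null(categories), length(categories) == length(posteriors))
    sel <- categories == category
    posteriors <- posteriors[sel]
    labels <- labels[sel]
  }
  y <- if (is.data.frame(labels)) labels$label else as.numeric(labels)
  stopifnot(length(y) == length(posteriors))
  if (length(unique(posteriors)) < 2L) {
    warning("fewer than 2 distinct posteriors; returning 0.5")
    return(0.5)
  }
  grid <- sort(unique(quantile(posteriors, probs = seq(0, 1, length.out = n_quantiles),
                               names = FALSE, type = 7)))
  f1 <- vapply(grid, function(th) {
    call <- posteriors >= th
    tp <- sum(call & y == 1)
    fp <- sum(call & y == 0)
    fn <- sum(!call & y == 1)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  best <- max(f1)
  th <- grid[which(f1 >= best - 1e-12)[1L]]
  if (all(y == y[1L]))
    warning("single-class labels: threshold pinned at an extreme grid point")
  th
}

#' Build the category-specific threshold set
#'
#' Different thresholds are optimal for SNVs and indels; both are selected
#' on the training set by F1 over the quantile grid. The TMB threshold is
#' fixed at 0.5 by convention.
#'
#' @param posteriors training-set posteriors.
#' @param labels training labels.
#' @param categories per-row `"SNV"`/`"indel"`.
#' @param n_quantiles grid size.
#' @return list with `threshold_snv`, `threshold_indel`, `threshold_tmb`,
#'   `selection_metric`.
#' @export
threshold_set <- function(posteriors, labels, categories, n_quantiles = 500L) {
  y <- if (is.data.frame(labels)) labels$label else as.numeric(labels)
  pick <- function(cat) {
    sel <- categories == cat
    if (!any(sel) || length(unique(y[sel])) < 2L) {
      warning("category ", cat, " lacks both classes; threshold 0.5")
      return(0.5)
    }
    select_threshold(posteriors[sel], y[sel], n_quantiles = n_quantiles)
  }
  list(threshold_snv = pick("SNV"), threshold_indel = pick("indel"),
       threshold_tmb = 0.5, selection_metric = "F1")
}

#' Binary calls from posteriors using category-specific thresholds
#'
#' @param posteriors numeric vector.
#' @param categories per-row `"SNV"`/`"indel"`.
#' @param thresholds list from [threshold_set()].
#' @return integer 0/1 calls.
#' @export
apply_thresholds <- function(posteriors, categories, thresholds) {
  th <- ifelse(categories == "SNV", thresholds$threshold_snv,
               thresholds$threshold_indel)
  as.integer(posteriors >= th)
}

#' Ensemble average of aligned posterior lists
#'
#' @param posterior_lists list of k >= 2 equal-length numeric vectors.
#' @return element-wise arithmetic mean.
#' @export
ensemble_average <- function(posterior_lists) {
  stopifnot(is.list(posterior_lists), length(posterior_lists) >= 2L)
  n <- unique(lengths(posterior_lists))
  if (length(n) != 1L)
    stop("posterior lists have mismatched lengths: ",
         paste(lengths(posterior_lists), collapse = ", "))
  if (n == 0L) return(numeric())
  rowMeans(do.call(cbind, posterior_lists))
}

#' Global feature importance
#'
#' Total split gain per feature, normalized to sum to 1, in descending
#' order with ties broken by feature name.
#'
#' @param model `sv_classifier`.
#' @return `data.table` with `feature` and `importance`.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "sv_classifier"))
  g <- model$engine$feature_gain
  total <- sum(g)
  imp <- if (total > 0) g / total else rep(0, length(g))
  dt <- data.table(feature = model$feature_names, importance = imp)
  setorder(dt, -importance, feature)
  dt[]
}

#' Save / load a model artifact directory
#'
#' Serializes the engine model, hyperparameters, schema hash and (optional)
#' threshold set as JSON text files.
#'
#' @param model `sv_classifier`.
#' @param dir artifact directory (created).
#' @param thresholds optional list from [threshold_set()].
#' @export
save_classifier <- function(model, dir, thresholds = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(kind = model$kind, params = model$params, nrounds = model$nrounds,
         feature_names = model$feature_names, schema_hash = model$schema_hash,
         schema_version = model$schema_version, meta = model$meta,
         engine = model$engine),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(thresholds))
    jsonlite::write_json(thresholds, file.path(dir, "thresholds.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "model.json"))
  num <- function(v) as.numeric(unlist(v, use.names = FALSE)) %||% numeric()
  engine <- list(
    base_score = num(m$engine$base_score),
    trees = lapply(m$engine$trees, function(tr) lapply(tr, num)),
    edges = lapply(m$engine$edges, num),
    feature_gain = num(m$engine$feature_gain))
  structure(list(kind = m$kind, engine = engine,
                 params = lapply(m$params, function(x) unlist(x) %||% x),
                 nrounds = m$nrounds,
                 feature_names = as.character(unlist(m$feature_names)),
                 schema_hash = m$schema_hash, schema_version = m$schema_version,
                 meta = lapply(m$meta, unlist)),
            class = "sv_classifier")
}
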