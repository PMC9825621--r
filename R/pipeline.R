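# End-to-end orchestration on in-memory cohorts: leave-one-out PoN,
# pre-filtering, informative-SNP collection, feature assembly, labels and
# per-sample summaries. The file-based CLI subcommands (cli.R) are thin
# wrappers around these.

#' Run the tumor-only analysis front end on a cohort
#'
#' For every patient: build the leave-one-out panel of normals from the
#' other patients' normal call sets, remove panel hits from the tumor-only
#' calls, apply the pre-classification filter, and keep the result.
#' Informative SNPs are collected from the *unfiltered* call set (they are
#' common variants that the filters remove by design). Returns the merged
#' feature matrix, truth labels and a per-sample summary.
#'
#' @param cohort `sv_cohort` from [simulate_cohort()].
#' @param cfg [filter_config()].
#' @param use_pon whether to apply the leave-one-out panel of normals.
#' @return list with `fm` (`sv_feature_matrix`), `labels` (from
#'   [label_variants()]), `kept` (merged kept variant table), `snps`,
#'   `segments`, `samples` (per-sample summary with purity, group,
#'   true_tmb, mvtsm, count, n_pon_removed).
#' @export
analyze_cohort <- function(cohort, cfg = filter_config(), use_pon = TRUE) {
  stopifnot(inherits(cohort, "sv_cohort"))
  normal_sets <- lapply(cohort$samples, `[[`, "normal_keys")
  names(normal_sets) <- vapply(cohort$samples, `[[`, character(1), "sample_id")

  kept_list <- vector("list", length(cohort$samples))
  snp_list <- vector("list", length(cohort$samples))
  summ_list <- vector("list", length(cohort$samples))
  for (i in seq_along(cohort$samples)) {
    s <- cohort$samples[[i]]
    snp_list[[i]] <- collect_informative_snps(s$variants, s$segments,
                                              db_fields = cfg$db_fields)
    v <- s$variants
    n_pon <- 0L
    if (use_pon && length(normal_sets) >= 3L) {
      pon <- build_loo_pon(normal_sets, s$sample_id)
      part <- apply_pon(v, pon)
      v <- part$kept
      n_pon <- nrow(part$removed)
    }
    kept_list[[i]] <- apply_prefilter(v, cfg)$kept
    summ_list[[i]] <- data.table(
      sample_id = s$sample_id, group = s$group, subtype = s$subtype,
      purity = s$purity, true_tmb = s$true_tmb, mvtsm = mvtsm(s, cfg),
      n_pon_removed = n_pon)
  }
  kept <- rbindlist(kept_list)
  snps <- rbindlist(snp_list)
  segments <- rbindlist(lapply(cohort$samples, `[[`, "segments"))
  counts <- count_to_classify(kept)
  fm <- assemble_feature_matrix(kept, snps, segments, counts,
                                db_fields = cfg$db_fields)
  # kept is re-sorted inside assemble_feature_matrix; align by key+sample
  setorder(kept, sample_id, chrom, pos, ref, alt)
  somatic_keys <- kept[!is.na(truth_label) & truth_label == 1L,
                       .(sample_id, key)]
  labels <- label_variants(kept, somatic_keys)
  summ <- rbindlist(summ_list)
  summ[, count := as.integer(counts[sample_id])]
  summ[is.na(count), count := 0L]
  list(fm = fm, labels = labels, kept = kept, snps = snps,
       segments = segments, samples = summ)
}

#' Train the default model suite
#'
#' Trains the leaf-wise (LightGBM-style) and depth-wise (XGBoost-style)
#' gradient-boosted models and selects category-specific thresholds on the
#' training set.
#'
#' @param fm training `sv_feature_matrix`.
#' @param labels training labels.
#' @param nrounds boosting rounds per model (desk scale; the stored
#'   leaf-wise preset carries the published server-scale 10000).
#' @param seed bagging seed override (default: presets' own).
#' @return list with `models` (named list of `sv_classifier`),
#'   `thresholds` (from [threshold_set()], selected on the ensemble),
#'   `train_posteriors`.
#' @export
train_suite <- function(fm, labels, nrounds = 200L, seed = NULL) {
  models <- list(
    lgbm = train_classifier(fm, labels, kind = "lgbm", nrounds = nrounds,
                            seed = seed),
    xgb = train_classifier(fm, labels, kind = "xgb",
                           nrounds = max(50L, as.integer(nrounds / 2L)),
                           seed = seed))
  post <- lapply(models, predict, fm = fm)
  post$ensemble <- ensemble_average(post)
  thresholds <- threshold_set(post$ensemble, labels, fm$meta$variant_category)
  list(models = models, thresholds = thresholds, train_posteriors = post)
}

#' Predict with a model suite
#'
#' @param suite from [train_suite()].
#' @param fm `sv_feature_matrix`.
#' @return list of posterior vectors (one per model plus `ensemble`).
#' @export
predict_suite <- function(suite, fm) {
  post <- lapply(suite$models, predict, fm = fm)
  post$ensemble <- ensemble_average(post)
  post
}

#' Per-sample TMB table across methods
#'
#' Combines truth, naive and per-model corrected TMB into one wide table
#' keyed by sample, merged with the per-sample summary (group, purity,
#' mvtsm) so it feeds [tmb_concordance()], [bias_report()] and
#' [explain_tpr()] directly.
#'
#' @param analysis from [analyze_cohort()].
#' @param posteriors named list of posterior vectors aligned to the feature
#'   matrix rows (e.g. from [predict_suite()]).
#' @param norm_mb footprint normalization (default: the cohort config's).
#' @param threshold_tmb somatic posterior cutoff for corrected TMB.
#' @return `data.table`, one row per sample: true_tmb, naive_tmb, one
#'   `<model>_tmb` per posterior list, group, purity, mvtsm, count.
#' @export
tmb_table <- function(analysis, posteriors, norm_mb, threshold_tmb = 0.5) {
  kept <- analysis$kept
  base <- compute_tmb(kept, posteriors = NULL, norm_mb = norm_mb)
  wide <- data.table::dcast(base, sample_id ~ method, value.var = "tmb")
  setnames(wide, c("naive", "truth"), c("naive_tmb", "true_tmb"),
           skip_absent = TRUE)
  for (m in names(posteriors)) {
    est <- compute_tmb(kept, posteriors = posteriors[[m]],
                       threshold_tmb = threshold_tmb, norm_mb = norm_mb,
                       method_name = m)
    est <- est[method == m, .(sample_id, tmb)]
    setnames(est, "tmb", paste0(m, "_tmb"))
    wide <- merge(wide, est, by = "sample_id", all.x = TRUE)
  }
  out <- merge(analysis$samples, wide, by = "sample_id", all.x = TRUE)
  if ("true_tmb.y" %in% names(out)) {
    out[, true_tmb := true_tmb.x]
    out[, c("true_tmb.x", "true_tmb.y") := NULL]
  }
  out[]
}
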