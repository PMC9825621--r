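# Tumor mutational burden: mutations per megabase of capture footprint,
# computed naively (all kept coding variants), corrected (predicted-somatic
# at a posterior cutoff), and from truth labels when available.

#' Patient-weighted capture-footprint normalization constant
#'
#' Weighted average of per-kit footprints by patient counts, plus the
#' nearest-integer convenience constant used to normalize pooled cohorts
#' (the benchmark cohorts give (33.0, 37.3, 63.5) Mb weighted by
#' (105, 45, 45) patients -> 41.03 -> 41).
#'
#' @param kit_footprints_mb per-kit footprints in Mb.
#' @param patient_counts per-kit patient counts.
#' @return list with `weighted_mb` and `constant` (nearest integer).
#' @export
footprint_constant <- function(kit_footprints_mb, patient_counts) {
  if (length(kit_footprints_mb) != length(patient_counts))
    stop("footprints and patient counts have different lengths")
  stopifnot(all(kit_footprints_mb > 0), all(patient_counts > 0))
  w <- sum(kit_footprints_mb * patient_counts) / sum(patient_counts)
  list(weighted_mb = w, constant = round(w))
}

#' Per-sample TMB estimates by method
#'
#' Naive TMB counts every kept (coding, filtered-through) variant;
#' model-corrected TMB counts variants with somatic posterior at or above
#' `threshold_tmb` (default 0.5); truth TMB counts truth-somatic variants
#' when labels are present. Each count is divided by the footprint
#' normalization in megabases.
#'
#' @param kept_variants kept variant table (needs `sample_id`; `truth_label`
#'   used when present).
#' @param posteriors optional numeric vector aligned to `kept_variants`
#'   rows; enables the corrected estimate.
#' @param threshold_tmb somatic posterior cutoff (default 0.5).
#' @param norm_mb normalization footprint in megabases (> 0).
#' @param method_name label for the corrected method column.
#' @return `data.table`: sample_id, method, mutation_count, norm_mb, tmb.
#' @export
compute_tmb <- function(kept_variants, posteriors = NULL, threshold_tmb = 0.5,
                        norm_mb, method_name = "corrected") {
  if (norm_mb <= 0) stop("norm_mb must be > 0")
  v <- as.data.table(kept_variants)
  samples <- unique(v$sample_id)
  rows <- list()
  count_by <- function(sel) {
    tab <- v[sel, .N, by = sample_id]
    setNames(tab$N, tab$sample_id)[samples]
  }
  naive <- count_by(rep(TRUE, nrow(v)))
  naive[is.na(naive)] <- 0L
  rows$naive <- data.table(sample_id = samples, method = "naive",
                           mutation_count = as.integer(naive))
  if (!is.null(posteriors)) {
    stopifnot(length(posteriors) == nrow(v))
    corr <- count_by(posteriors >= threshold_tmb)
    corr[is.na(corr)] <- 0L
    rows$corr <- data.table(sample_id = samples, method = method_name,
                            mutation_count = as.integer(corr))
  }
  if ("truth_label" %in% names(v) && any(!is.na(v$truth_label))) {
    tr <- count_by(!is.na(v$truth_label) & v$truth_label == 1L)
    tr[is.na(tr)] <- 0L
    rows$truth <- data.table(sample_id = samples, method = "truth",
                             mutation_count = as.integer(tr))
  }
  out <- rbindlist(rows)
  out[, `:=`(norm_mb = norm_mb, tmb = mutation_count / norm_mb)]
  out[]
}
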