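# Somatic/germline truth labels: a tumor-only kept variant is somatic (1)
# iff its key was called somatic by the matched-normal pipeline; everything
# else in the tumor-only call set is germline (0). Coverage is total.

#' Label tumor-only variants with matched-normal truth
#'
#' @param tumor_only_kept kept variant table (after [apply_prefilter()]).
#' @param matched_somatic_keys character vector of somatic variant keys from
#'   the matched-normal pipeline (normalized identically).
#' @return `data.table` with `key`, `sample_id` and `label` (0/1), one row
#'   per kept variant in the matrix row order. Matched-somatic keys absent
#'   from the kept set are not injected; their count is attached as the
#'   `n_unseen_somatic` attribute (a sensitivity-ceiling diagnostic).
#' @export
label_variants <- function(tumor_only_kept, matched_somatic_keys) {
  v <- as.data.table(tumor_only_kept)
  if (is.data.frame(matched_somatic_keys)) {
    # per-sample somatic key sets: match on (sample_id, key)
    ms <- as.data.table(matched_somatic_keys)
    somatic <- unique(paste(ms$sample_id, ms$key, sep = "\r"))
    pair <- paste(v$sample_id, v$key, sep = "\r")
    out <- v[, .(sample_id, key, label = as.integer(pair %in% somatic))]
    n_unseen <- length(setdiff(somatic, pair))
  } else {
    somatic <- unique(as.character(matched_somatic_keys))
    out <- v[, .(sample_id, key, label = as.integer(key %in% somatic))]
    n_unseen <- length(setdiff(somatic, v$key))
  }
  if (n_unseen > 0L)
    message(n_unseen, " matched-somatic key(s) absent from the tumor-only kept set")
  attr(out, "n_unseen_somatic") <- n_unseen
  out[]
}
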