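# Pre-classification variant filtering: isolate passing, coding, rare
# variants before any feature engineering. Variants removed here are out of
# the game entirely -- they are not counted as true negatives downstream.

#' Pre-filter configuration
#'
#' Defaults encode the method's stated rules: population allele frequency
#' strictly below 0.01 across the germline databases, ontology restricted to
#' coding nonsynonymous classes, and both the caller filter and the
#' artifact filter required to be `"PASS"`.
#'
#' @param pop_max_threshold strict upper bound on `pop_max` (default 0.01).
#' @param allowed_ontologies coding ontology whitelist.
#' @param require_fpfilter_pass,require_caller_pass flags.
#' @param db_fields database fields feeding `pop_max`.
#' @export
filter_config <- function(pop_max_threshold = 0.01,
                          allowed_ontologies = c("missense", "nonsense",
                                                 "frameshift_indel", "inframe_indel"),
                          require_fpfilter_pass = TRUE,
                          require_caller_pass = TRUE,
                          db_fields = default_db_fields()) {
  stopifnot(pop_max_threshold > 0, pop_max_threshold <= 1,
            length(allowed_ontologies) > 0)
  structure(list(pop_max_threshold = pop_max_threshold,
                 allowed_ontologies = allowed_ontologies,
                 require_fpfilter_pass = require_fpfilter_pass,
                 require_caller_pass = require_caller_pass,
                 db_fields = db_fields),
            class = "sv_filter_config")
}

#' Apply the pre-classification filter
#'
#' Rules are evaluated in a fixed order (caller filter, artifact filter,
#' ontology, pop_max) and the first failing rule is recorded per removed
#' variant, so the removal log is reproducible and auditable.
#'
#' @param variants variant `data.table`.
#' @param cfg [filter_config()].
#' @return list with `kept` (variant table, with a `pop_max` column added)
#'   and `removal_log` (`data.table` of `sample_id`, `key`, `reason`).
#' @export
apply_prefilter <- function(variants, cfg = filter_config()) {
  v <- copy(as.data.table(variants))
  if (!nrow(v)) {
    return(list(kept = v,
                removal_log = as.data.table(list(sample_id = character(),
                                                 key = character(),
                                                 reason = character()))))
  }
  v[, pop_max := compute_pop_max(v, db_fields = cfg$db_fields)]
  reason <- rep(NA_character_, nrow(v))
  if (cfg$require_caller_pass)
    reason[is.na(reason) & v$caller_filter != "PASS"] <- "caller_filter"
  if (cfg$require_fpfilter_pass)
    reason[is.na(reason) & v$fpfilter != "PASS"] <- "fpfilter"
  reason[is.na(reason) & !(v$ontology %in% cfg$allowed_ontologies)] <- "ontology"
  reason[is.na(reason) & v$pop_max >= cfg$pop_max_threshold] <- "pop_max"
  keep <- is.na(reason)
  list(kept = v[keep],
       removal_log = as.data.table(list(sample_id = v$sample_id[!keep],
                                        key = v$key[!keep],
                                        reason = reason[!keep])))
}

#' Number of variants to classify per sample
#'
#' This per-sample count of filtered-through variants is itself a model
#' feature (`count`): it reflects the rare-germline load the databases
#' failed to remove plus the true somatic burden.
#'
#' @param kept variant table after [apply_prefilter()].
#' @return named integer vector, sample id -> count.
#' @export
count_to_classify <- function(kept) {
  v <- as.data.table(kept)
  if (!nrow(v)) return(setNames(integer(), character()))
  tab <- v[, .N, by = sample_id]
  setNames(tab$N, tab$sample_id)
}
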