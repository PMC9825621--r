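# Leave-one-out variant-level panel of normals.
#
# For each patient the panel is built from the N-1 normal samples of every
# *other* patient; a variant key enters the panel when it is seen in at
# least two of those normals. Applying the panel to a patient's tumor-only
# calls removes recurrent germline variants and technical artifacts without
# ever letting the patient's own normal leak into their panel.

#' Build a leave-one-out panel of normals
#'
#' @param normal_variant_sets named list: patient id -> character vector of
#'   variant keys (`chrom:pos:ref:alt`, alleles already trimmed) called in
#'   that patient's normal sample.
#' @param leave_out patient id excluded from the panel.
#' @param min_samples minimum number of member normals a key must occur in
#'   (the method's stated rule is 2; override exists but should not be
#'   needed).
#' @return object of class `sv_pon` with `excluded_patient`,
#'   `member_count`, and `variant_keys`.
#' @export
build_loo_pon <- function(normal_variant_sets, leave_out, min_samples = 2L) {
  if (!is.list(normal_variant_sets) || is.null(names(normal_variant_sets)))
    stop("normal_variant_sets must be a named list of key vectors")
  if (!(leave_out %in% names(normal_variant_sets)))
    stop("leave_out patient '", leave_out, "' not present in normal_variant_sets")
  if (length(normal_variant_sets) < 3L)
    stop("panel of normals requires at least 3 patients (got ",
         length(normal_variant_sets), ")")
  members <- normal_variant_sets[setdiff(names(normal_variant_sets), leave_out)]
  keys <- unlist(lapply(members, unique), use.names = FALSE)
  tab <- table(keys)
  panel <- sort(names(tab)[tab >= min_samples])
  structure(list(excluded_patient = leave_out,
                 member_count = length(members),
                 variant_keys = panel),
            class = "sv_pon")
}

#' @export
print.sv_pon <- function(x, ...) {
  cat("<sv_pon> leave-one-out panel of normals\n",
      " excluded patient: ", x$excluded_patient, "\n",
      " member normals:   ", x$member_count, "\n",
      " panel keys:       ", length(x$variant_keys), "\n", sep = "")
  invisible(x)
}

#' Apply a panel of normals to tumor-only variant calls
#'
#' Partitions the calls into `kept` (key not in the panel) and `removed`.
#' Errors if the panel was built excluding a different patient than the one
#' the variants belong to, which would leak the patient's own normal.
#'
#' @param variants variant `data.table` for one patient.
#' @param panel `sv_pon` from [build_loo_pon()].
#' @param patient_id patient owning the variants; defaults to their
#'   `sample_id`.
#' @return list with `kept` and `removed` variant tables.
#' @export
apply_pon <- function(variants, panel, patient_id = NULL) {
  stopifnot(inherits(panel, "sv_pon"))
  v <- as.data.table(variants)
  if (is.null(patient_id)) {
    ids <- unique(v$sample_id)
    if (length(ids) > 1L) stop("variants from multiple samples; pass patient_id")
    patient_id <- if (length(ids)) ids else panel$excluded_patient
  }
  if (!identical(as.character(patient_id), as.character(panel$excluded_patient)))
    stop("panel leakage guard: panel excludes '", panel$excluded_patient,
         "' but variants belong to '", patient_id, "'")
  hit <- v$key %in% panel$variant_keys
  list(kept = v[!hit], removed = v[hit])
}

#' Write / read a panel of normals as a sites-only VCF plus JSON sidecar
#'
#' @param panel `sv_pon`.
#' @param path output VCF path; the sidecar is written to `<path>.json`.
#' @export
write_pon_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "sv_pon"))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=somaticsieve_pon",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 sep = "\t"))
  if (length(panel$variant_keys)) {
    parts <- data.table::tstrsplit(panel$variant_keys, ":", fixed = TRUE)
    body <- paste(parts[[1L]], parts[[2L]], ".", parts[[3L]], parts[[4L]],
                  ".", "PASS", ".", sep = "\t")
    ord <- order(parts[[1L]], as.integer(parts[[2L]]))
    body <- body[ord]
  } else body <- character()
  writeLines(c(hdr, body), path)
  jsonlite::write_json(list(excluded_patient = panel$excluded_patient,
                            member_count = panel$member_count,
                            n_keys = length(panel$variant_keys)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pon_vcf
#' @export
read_pon_vcf <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  keys <- character()
  if (length(lines)) {
    f <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
    keys <- sort(paste(f[[1L]], f[[2L]], f[[4L]], f[[5L]], sep = ":"))
  }
  structure(list(excluded_patient = meta$excluded_patient,
                 member_count = meta$member_count,
                 variant_keys = keys),
            class = "sv_pon")
}
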