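# Feature engineering: the model-ready tabular representation of variants.
#
# Per variant: 5 scalar features (pop_max, per-sample count, t_alt_freq,
# t_maj_allele, max_cosmic_count), a 20-bin VAF histogram of the informative
# SNPs sharing the variant's copy-number segment, a 4-column coding-ontology
# one-hot, a 7-column pyrimidine-centered base-substitution one-hot
# (6 classes + non-SBS) and a 17-column flanking-context one-hot
# (16 5'x3' pairs + non-SBS-y): 53 columns, schema-versioned and hashed.

SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
FLANK_BASES <- c("A", "C", "G", "T")
ONT_FEATURES <- c("missense", "nonsense", "frameshift_indel", "inframe_indel")

#' Feature schema
#'
#' Ordered column names, version id and hash of the default feature schema.
#' @export
feature_schema <- function() {
  ctx <- as.vector(t(outer(FLANK_BASES, FLANK_BASES,
                           function(a, b) paste0("ctx_", a, b))))
  columns <- c("pop_max", "count", "t_alt_freq", "t_maj_allele",
               "max_cosmic_count",
               sprintf("snp_vaf_bin_%02d", 0:19),
               ONT_FEATURES,
               paste0("sub_", c(SUB_CLASSES, "non_SBS")),
               c(ctx, "ctx_non_SBS_y"))
  version <- "v1"
  list(version = version, columns = columns,
       hash = fnv1a(paste(version, paste(columns, collapse = ","))))
}

#' Collect informative SNPs
#'
#' Informative SNPs are heterozygous SNVs common in the germline databases
#' (`pop_max >= 0.01`), passing the artifact filter, whose VAF lies in the
#' heterozygous window (0.05, 0.95); each is assigned the copy-number
#' segment containing its position (SNPs outside all segments are dropped).
#' Their VAFs reflect the local copy state of the tumor.
#'
#' @param sample_variants *all* called variants for the cohort (including
#'   common and non-coding ones -- collect before any filtering).
#' @param segments segment table from [read_segments()]/[validate_segments()].
#' @param common_threshold minimum `pop_max` (default 0.01).
#' @param het_window VAF window declaring a SNP heterozygous (exclusive).
#' @param db_fields database fields feeding `pop_max`.
#' @return `data.table`: sample_id, chrom, pos, vaf, pop_max, segment_id.
#' @export
collect_informative_snps <- function(sample_variants, segments,
                                     common_threshold = 0.01,
                                     het_window = c(0.05, 0.95),
                                     db_fields = default_db_fields()) {
  v <- as.data.table(sample_variants)
  empty <- data.table(sample_id = character(), chrom = character(),
                      pos = integer(), vaf = numeric(), pop_max = numeric(),
                      segment_id = character())
  if (!nrow(v)) return(empty)
  if (!("pop_max" %in% names(v)))
    v <- copy(v)[, pop_max := compute_pop_max(v, db_fields = db_fields)]
  snp <- v[variant_class == "SNV" & fpfilter == "PASS" &
             pop_max >= common_threshold &
             t_alt_freq > het_window[1L] & t_alt_freq < het_window[2L],
           .(sample_id, chrom, pos, vaf = t_alt_freq, pop_max)]
  if (!nrow(snp)) return(empty)
  snp[, segment_id := assign_segment(snp, segments)]
  snp[!is.na(segment_id)][]
}

# segment containing each 1-based position (segments are 0-based half-open:
# start < pos <= end); NA when outside all segments for that sample/chrom
assign_segment <- function(points, segments) {
  seg <- as.data.table(segments)
  if (nrow(seg) && !("segment_id" %in% names(seg))) seg <- validate_segments(seg)
  pts <- as.data.table(points)
  out <- rep(NA_character_, nrow(pts))
  if (!nrow(seg) || !nrow(pts)) return(out)
  grp <- split(seq_len(nrow(pts)), paste(pts$sample_id, pts$chrom, sep = "\r"))
  for (g in names(grp)) {
    idx <- grp[[g]]
    sc <- strsplit(g, "\r", fixed = TRUE)[[1L]]
    s <- seg[sample_id == sc[1L] & chrom == sc[2L]]
    if (!nrow(s)) next
    setorder(s, start)
    hit <- findInterval(pts$pos[idx], s$start + 1L)
    ok <- hit >= 1L & pts$pos[idx] <= s$end[pmax(hit, 1L)]
    out[idx[ok]] <- s$segment_id[hit[ok]]
  }
  out
}

# 20-bin VAF histograms of informative SNPs, one row per segment_id.
# Bins are [i/20, (i+1)/20) with the last bin closed at 1.0.
segment_vaf_histograms <- function(snps) {
  s <- as.data.table(snps)
  if (!nrow(s)) {
    m <- matrix(integer(), 0L, 20L,
                dimnames = list(NULL, sprintf("snp_vaf_bin_%02d", 0:19)))
    return(m)
  }
  bin <- pmin(floor(s$vaf * 20), 19L)
  tab <- table(factor(s$segment_id), factor(bin, levels = 0:19))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), sprintf("snp_vaf_bin_%02d", 0:19)))
  m
}

#' VAF histogram of informative SNPs around one variant
#'
#' Counts the informative SNPs that share the variant's copy-number segment,
#' in 20 left-closed VAF bins `[i/20, (i+1)/20)` (VAF exactly 1 goes to the
#' last bin). A variant outside all segments gets an all-zero histogram
#' with a warning.
#'
#' @param variant single-row variant table (needs sample_id, chrom, pos).
#' @param snps informative SNPs from [collect_informative_snps()].
#' @param segments segment table.
#' @return integer vector of 20 counts named `snp_vaf_bin_00..19`.
#' @export
snp_vaf_histogram <- function(variant, snps, segments) {
  v <- as.data.table(variant)
  stopifnot(nrow(v) == 1L)
  seg_id <- assign_segment(v, segments)
  out <- setNames(integer(20L), sprintf("snp_vaf_bin_%02d", 0:19))
  if (is.na(seg_id)) {
    warning("variant ", v$chrom, ":", v$pos,
            " lies outside all copy-number segments; all-zero histogram")
    return(out)
  }
  h <- segment_vaf_histograms(snps)
  if (seg_id %in% rownames(h)) out[] <- h[seg_id, ]
  out
}

#' Pyrimidine-centered substitution and flanking-context encoding
#'
#' Single-base substitutions are mapped to the six pyrimidine-centered
#' classes used in mutational-signature analysis (purine-centered changes
#' are reverse-complemented), and the 5'/3' flanking bases of the
#' trinucleotide context to one of 16 pairs. Indels and MNVs map to
#' (`"non_SBS"`, `"non_SBS_y"`); an SNV whose context flanks are unknown
#' (`N`) keeps its substitution class but gets the `non_SBS_y` context.
#'
#' @param ref,alt allele strings (vectorized).
#' @param tri_context 3-base reference context (central base must equal
#'   `ref` for SNVs) or `"NON_SBS"`.
#' @return `data.table` with columns `class` and `context`.
#' @export
substitution_encoding <- function(ref, alt, tri_context) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(tri_context) == n)
  cls <- rep("non_SBS", n)
  ctx <- rep("non_SBS_y", n)
  is_snv <- nchar(ref) == 1L & nchar(alt) == 1L
  if (any(is_snv)) {
    i <- which(is_snv)
    tc <- tri_context[i]
    if (any(tc == "NON_SBS" | nchar(tc) != 3L))
      stop("SNV with missing or malformed tri_context")
    mid <- substr(tc, 2L, 2L)
    if (any(mid != ref[i]))
      stop("tri_context central base does not match ref allele for ",
           sum(mid != ref[i]), " variant(s)")
    r <- ref[i]; a <- alt[i]
    l5 <- substr(tc, 1L, 1L); r3 <- substr(tc, 3L, 3L)
    pur <- r %in% c("A", "G")
    # reverse-complement purine-centered substitutions
    if (any(pur)) {
      rr <- unname(DNA_COMP[r[pur]]); aa <- unname(DNA_COMP[a[pur]])
      new5 <- unname(DNA_COMP[r3[pur]]); new3 <- unname(DNA_COMP[l5[pur]])
      r[pur] <- rr; a[pur] <- aa; l5[pur] <- new5; r3[pur] <- new3
    }
    cls[i] <- paste0(r, ">", a)
    known <- l5 %in% FLANK_BASES & r3 %in% FLANK_BASES
    ctx[i[known]] <- paste0("ctx_", l5[known], r3[known])
  }
  data.table(class = cls, context = ctx)
}

#' Assemble the feature matrix
#'
#' One row per kept variant, deterministic row order
#' (sample_id, chrom, pos, ref, alt), full default schema with version id
#' and hash. Variants in segments with no informative SNPs (or outside all
#' segments) get all-zero histogram bins; the number of out-of-segment
#' variants is recorded.
#'
#' @param kept_variants variant table after [apply_prefilter()].
#' @param snps informative SNPs from [collect_informative_snps()].
#' @param segments segment table.
#' @param counts per-sample counts from [count_to_classify()]; defaults to
#'   counting `kept_variants` itself.
#' @param db_fields database fields feeding `pop_max`.
#' @return object of class `sv_feature_matrix`: list with `X` (numeric
#'   matrix), `meta` (keys + `variant_category`), `schema_version`,
#'   `schema_hash`, `n_no_segment`.
#' @export
assemble_feature_matrix <- function(kept_variants, snps, segments,
                                    counts = NULL,
                                    db_fields = default_db_fields()) {
  schema <- feature_schema()
  v <- copy(as.data.table(kept_variants))
  if (!nrow(v)) {
    X <- matrix(numeric(), 0L, length(schema$columns),
                dimnames = list(NULL, schema$columns))
    return(new_feature_matrix(X, meta = as.data.table(list(
      sample_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), key = character(),
      variant_category = character())), schema, 0L))
  }
  setorder(v, sample_id, chrom, pos, ref, alt)
  if (!("pop_max" %in% names(v)))
    v[, pop_max := compute_pop_max(v, db_fields = db_fields)]
  if (is.null(counts)) counts <- count_to_classify(v)
  if (!all(v$sample_id %in% names(counts)))
    stop("counts missing for sample(s): ",
         paste(setdiff(unique(v$sample_id), names(counts)), collapse = ", "))
  if (!all(v$ontology %in% ONT_FEATURES))
    stop("kept variants contain non-coding ontologies; run apply_prefilter first")

  n <- nrow(v)
  X <- matrix(0, n, length(schema$columns),
              dimnames = list(NULL, schema$columns))
  X[, "pop_max"] <- v$pop_max
  X[, "count"] <- as.numeric(counts[v$sample_id])
  X[, "t_alt_freq"] <- v$t_alt_freq
  X[, "t_maj_allele"] <- v$t_maj_allele
  X[, "max_cosmic_count"] <- v$cosmic_count

  seg_id <- assign_segment(v, segments)
  hists <- segment_vaf_histograms(snps)
  hit <- !is.na(seg_id) & seg_id %in% rownames(hists)
  if (any(hit)) X[hit, colnames(hists)] <- hists[seg_id[hit], , drop = FALSE]
  n_no_segment <- sum(is.na(seg_id))

  X[cbind(seq_len(n), match(v$ontology, schema$columns))] <- 1
  enc <- substitution_encoding(v$ref, v$alt, v$tri_context)
  X[cbind(seq_len(n), match(paste0("sub_", enc$class), schema$columns))] <- 1
  X[cbind(seq_len(n), match(ifelse(enc$context == "non_SBS_y",
                                   "ctx_non_SBS_y", enc$context),
                            schema$columns))] <- 1

  meta <- v[, .(sample_id, chrom, pos, ref, alt, key,
                variant_category = ifelse(variant_class == "SNV", "SNV", "indel"))]
  new_feature_matrix(X, meta, schema, n_no_segment)
}

new_feature_matrix <- function(X, meta, schema, n_no_segment) {
  structure(list(X = X, meta = meta,
                 schema_version = schema$version,
                 schema_hash = schema$hash,
                 n_no_segment = n_no_segment),
            class = "sv_feature_matrix")
}

#' @export
print.sv_feature_matrix <- function(x, ...) {
  cat("<sv_feature_matrix> ", nrow(x$X), " variants x ", ncol(x$X),
      " features (schema ", x$schema_version, ", hash ", x$schema_hash, ")\n",
      sep = "")
  invisible(x)
}

#' Row-bind feature matrices (e.g., cohorts)
#'
#' @param ... `sv_feature_matrix` objects sharing the same schema.
#' @export
rbind_feature_matrix <- function(...) {
  fms <- list(...)
  stopifnot(all(vapply(fms, inherits, logical(1), "sv_feature_matrix")))
  ref_cols <- colnames(fms[[1L]]$X)
  for (fm in fms[-1L]) {
    if (!identical(colnames(fm$X), ref_cols)) {
      diffs <- c(setdiff(ref_cols, colnames(fm$X)), setdiff(colnames(fm$X), ref_cols))
      stop("feature schema mismatch; offending column(s): ",
           paste(unique(diffs), collapse = ", "))
    }
  }
  structure(list(X = do.call(rbind, lapply(fms, `[[`, "X")),
                 meta = rbindlist(lapply(fms, `[[`, "meta")),
                 schema_version = fms[[1L]]$schema_version,
                 schema_hash = fms[[1L]]$schema_hash,
                 n_no_segment = sum(vapply(fms, `[[`, numeric(1), "n_no_segment"))),
            class = "sv_feature_matrix")
}

#' Write a feature matrix as TSV with a schema header comment
#'
#' @param fm `sv_feature_matrix`.
#' @param path output path.
#' @export
write_feature_matrix_tsv <- function(fm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#somaticsieve_features\t%s\t%s",
                     fm$schema_version, fm$schema_hash), con)
  dt <- cbind(fm$meta, as.data.table(fm$X))
  suppressWarnings(utils::write.table(dt, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  invisible(path)
}

#' @rdname write_feature_matrix_tsv
#' @export
read_feature_matrix_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  parts <- strsplit(first, "\t", fixed = TRUE)[[1L]]
  if (parts[1L] != "#somaticsieve_features")
    stop("not a somaticsieve feature matrix TSV: ", path)
  schema <- feature_schema()
  if (parts[3L] != schema$hash)
    stop("feature schema hash mismatch: file ", parts[3L], " vs package ",
         schema$hash)
  dt <- fread(path, sep = "\t", header = TRUE, skip = 1L)
  meta_cols <- c("sample_id", "chrom", "pos", "ref", "alt", "key",
                 "variant_category")
  X <- as.matrix(dt[, setdiff(names(dt), meta_cols), with = FALSE])
  new_feature_matrix(X, dt[, meta_cols, with = FALSE], schema, 0L)
}
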