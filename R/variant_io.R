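# Reading and writing the formats the pipeline touches: annotated VCFs,
# SEG/CNR copy-number tables, BED capture footprints, and the package's own
# TSV interchange for variant tables.
#
# Internal coordinate conventions: variant positions are 1-based (VCF);
# copy-number segments and capture intervals are 0-based half-open (BED).

#' Default germline population database fields
#'
#' The eight dbNSFP-style allele-frequency fields aggregated into `pop_max`.
#' The set is configurable in every function that consumes it.
#'
#' @export
default_db_fields <- function() {
  c("1000Gp3_AF", "TWINSUK_AF", "ALSPAC_AF", "UK10K_AF",
    "ExAC_AC", "ExAC_AF", "gnomAD_exomes_AF", "gnomAD_genomes_AF")
}

db_cols <- function(db_fields = default_db_fields()) paste0("db_", db_fields)

VARIANT_COLUMNS <- c("sample_id", "chrom", "pos", "ref", "alt", "variant_class",
                     "t_alt_freq", "t_maj_allele", "depth", "caller_filter",
                     "fpfilter", "ontology", "cosmic_count", "tri_context",
                     "truth_label")

ONTOLOGIES <- c("missense", "nonsense", "frameshift_indel", "inframe_indel", "other")

#' Build a variant table
#'
#' Constructs the package's canonical variant representation: one row per
#' (record, alt allele) with read statistics, filter flags, annotations and
#' one `db_<name>` column per germline database (`NA` = absent from that
#' database). Validates ranges and the internal consistency rules
#' (`variant_class == "SNV"` iff both alleles have length 1; `tri_context`
#' is `"NON_SBS"` iff the variant is not an SNV).
#'
#' @param df data.frame with at least the columns in `VARIANT_COLUMNS`
#'   (missing optional annotation columns are filled with defaults).
#' @param db_fields database field names; `db_<name>` columns are created
#'   when absent.
#' @return a `data.table` of variants with a `key` column.
#' @export
variant_table <- function(df, db_fields = default_db_fields()) {
  dt <- as.data.table(df)
  if (!("depth" %in% names(dt))) dt[, depth := NA_integer_]
  if (!("caller_filter" %in% names(dt))) dt[, caller_filter := "PASS"]
  if (!("fpfilter" %in% names(dt))) dt[, fpfilter := "PASS"]
  if (!("ontology" %in% names(dt))) dt[, ontology := "other"]
  if (!("cosmic_count" %in% names(dt))) dt[, cosmic_count := 0L]
  if (!("truth_label" %in% names(dt))) dt[, truth_label := NA_integer_]
  if (!("variant_class" %in% names(dt))) dt[, variant_class := classify_allele(ref, alt)]
  if (!("tri_context" %in% names(dt)))
    dt[, tri_context := ifelse(variant_class == "SNV", paste0("N", ref, "N"), "NON_SBS")]
  for (col in db_cols(db_fields)) if (!(col %in% names(dt))) dt[, (col) := NA_real_]

  stopifnot(all(dt$t_alt_freq >= 0 & dt$t_alt_freq <= 1),
            all(dt$t_maj_allele >= 0 & dt$t_maj_allele <= 1),
            all(is.na(dt$depth) | dt$depth >= 0),
            all(dt$cosmic_count >= 0),
            all(dt$ontology %in% ONTOLOGIES),
            all(is.na(dt$truth_label) | dt$truth_label %in% c(0L, 1L)))
  bad_class <- dt$variant_class != classify_allele(dt$ref, dt$alt)
  if (any(bad_class))
    stop("variant_class inconsistent with allele lengths for ",
         sum(bad_class), " variant(s)")
  bad_ctx <- (dt$variant_class == "SNV") == (dt$tri_context == "NON_SBS")
  if (any(bad_ctx))
    stop("tri_context must be NON_SBS exactly for non-SNV variants (",
         sum(bad_ctx), " violations)")
  dt[, key := variant_key(chrom, pos, ref, alt)]
  setorder(dt, sample_id, chrom, pos, ref, alt)
  dt[]
}

#' Maximum population allele frequency across germline databases
#'
#' A variant absent from every database gets `pop_max = 0` (maximally rare),
#' which is what lets novel variants pass the `< 0.01` rarity pre-filter.
#'
#' @param db_freqs either a named list/vector of per-database frequencies
#'   (entries may be missing or `NA`) or a variant `data.table` carrying
#'   `db_<name>` columns, in which case a vector is returned.
#' @param db_fields database field names considered.
#' @return numeric frequency (or vector) in `[0, 1]`.
#' @export
compute_pop_max <- function(db_freqs, db_fields = default_db_fields()) {
  if (is.data.frame(db_freqs)) {
    cols <- intersect(db_cols(db_fields), names(db_freqs))
    if (!length(cols)) return(rep(0, nrow(db_freqs)))
    m <- as.matrix(as.data.frame(db_freqs)[, cols, drop = FALSE])
    check_freq_range(m)
    out <- apply(m, 1L, function(r) if (all(is.na(r))) 0 else max(r, na.rm = TRUE))
    return(as.numeric(out))
  }
  v <- unlist(db_freqs, use.names = FALSE)
  v <- v[!is.na(v)]
  check_freq_range(v)
  if (!length(v)) 0 else max(v)
}

check_freq_range <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) && (any(v < 0) || any(v > 1)))
    stop("database allele frequency outside [0, 1]")
  invisible(TRUE)
}

#' Read annotated variants from a VCF file
#'
#' Parses a VCF 4.x file (via `VariantAnnotation`), splits multi-allelic
#' records into one variant per alt allele, and normalizes annotations into
#' the package's variant table. Expected INFO keys (all optional except the
#' genotype `AD` field): `ONT` (ontology), `FPF` (artifact-filter status),
#' `COSMIC_CNT`, `TRI` (trinucleotide reference context), `TRUTH`
#' (0 germline / 1 somatic), and one key per germline database field.
#' Missing annotations become: absent database entries, `cosmic_count = 0`,
#' `ontology = "other"`.
#'
#' `t_alt_freq` is the alt-allele depth fraction; `t_maj_allele` is the
#' fraction of the most-supported allele computed over *all* observed
#' alleles of the original record (before multi-allelic splitting).
#'
#' @param path VCF file path.
#' @param sample_id sample identifier attached to every variant.
#' @param db_fields germline database INFO keys.
#' @return variant `data.table` (see [variant_table()]).
#' @export
read_annotated_variants <- function(path, sample_id, db_fields = default_db_fields()) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  n <- length(vcf)
  if (n == 0L) {
    return(variant_table(data.table(sample_id = character(), chrom = character(),
                                    pos = integer(), ref = character(),
                                    alt = character(), variant_class = character(),
                                    t_alt_freq = numeric(), t_maj_allele = numeric(),
                                    depth = integer(), caller_filter = character(),
                                    fpfilter = character(), ontology = character(),
                                    cosmic_count = integer(), tri_context = character(),
                                    truth_label = integer()),
                         db_fields = db_fields))
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  geno <- VariantAnnotation::geno(vcf)
  if (!("AD" %in% names(geno)))
    stop("missing required genotype allele-depth (AD) field in ", path)
  ad <- geno$AD[, 1L]                      # list: per record c(ref, alt1, ...)
  alt_list <- VariantAnnotation::alt(vcf)  # DNAStringSetList
  n_alt <- S4Vectors::elementNROWS(alt_list)
  bad_ad <- which(lengths(ad) != n_alt + 1L | vapply(ad, anyNA, logical(1)))
  if (length(bad_ad))
    stop("record(s) with missing/incomplete AD depths: ",
         paste(head(names(rr)[bad_ad], 5L), collapse = ", "))

  depth_rec <- vapply(ad, sum, numeric(1))
  maj_rec <- ifelse(depth_rec > 0, vapply(ad, max, numeric(1)) / pmax(depth_rec, 1), 0)

  idx <- rep.int(seq_len(n), n_alt)        # expand per alt allele
  alt_rank <- sequence(n_alt)
  alt_depth <- mapply(function(a, k) a[k + 1L], ad[idx], alt_rank)

  get_info <- function(key, default, as_fun = as.numeric) {
    if (key %in% names(info)) {
      v <- info[[key]]
      if (is(v, "List") || is.list(v)) {
        v <- vapply(v, function(x) if (length(x)) x[1L] else NA, v[[1]][1])
      }
      out <- as_fun(v)[idx]
      out[is.na(out)] <- default
      out
    } else rep(default, length(idx))
  }

  df <- data.table(
    sample_id = sample_id,
    chrom = as.character(GenomicRanges::seqnames(rr))[idx],
    pos = BiocGenerics::start(rr)[idx],
    ref = as.character(VariantAnnotation::ref(vcf))[idx],
    alt = as.character(unlist(alt_list)),
    t_alt_freq = ifelse(depth_rec[idx] > 0, alt_depth / depth_rec[idx], 0),
    t_maj_allele = maj_rec[idx],
    depth = as.integer(depth_rec[idx]),
    caller_filter = as.character(rr$FILTER)[idx],
    fpfilter = get_info("FPF", "PASS", as.character),
    ontology = get_info("ONT", "other", as.character),
    cosmic_count = as.integer(get_info("COSMIC_CNT", 0L, as.integer)),
    tri_context = get_info("TRI", NA_character_, as.character)
  )
  df[, variant_class := classify_allele(ref, alt)]
  df[, tri_context := ifelse(variant_class == "SNV",
                             ifelse(is.na(tri_context), paste0("N", ref, "N"), tri_context),
                             "NON_SBS")]
  truth <- get_info("TRUTH", NA_real_)
  df[, truth_label := as.integer(truth)]
  for (f in db_fields) {
    df[, (paste0("db_", f)) := get_info(f, NA_real_)]
  }
  variant_table(df, db_fields = db_fields)
}

#' Write a variant table as an annotated VCF
#'
#' Inverse of [read_annotated_variants()] for pipeline artifacts (one sample
#' per file). Coordinates are written back in the 1-based VCF convention.
#'
#' @param variants variant `data.table` for a single sample.
#' @param path output path.
#' @param db_fields database fields to emit as INFO keys.
#' @export
write_annotated_vcf <- function(variants, path, db_fields = default_db_fields()) {
  v <- as.data.table(variants)
  stopifnot(length(unique(v$sample_id)) <= 1L)
  sid <- if (nrow(v)) v$sample_id[1L] else "SAMPLE"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=somaticsieve",
    "##INFO=<ID=ONT,Number=1,Type=String,Description=\"Variant ontology\">",
    "##INFO=<ID=FPF,Number=1,Type=String,Description=\"Artifact filter status\">",
    "##INFO=<ID=COSMIC_CNT,Number=1,Type=Integer,Description=\"COSMIC occurrence count\">",
    "##INFO=<ID=TRI,Number=1,Type=String,Description=\"Trinucleotide reference context\">",
    "##INFO=<ID=TRUTH,Number=1,Type=Integer,Description=\"Truth label 0 germline 1 somatic\">",
    vapply(db_fields, function(f) sprintf(
      "##INFO=<ID=%s,Number=1,Type=Float,Description=\"Population AF (%s)\">", f, f),
      character(1)),
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sid, sep = "\t")
  )
  if (!nrow(v)) { writeLines(hdr, path); return(invisible(path)) }
  alt_n <- pmax(0L, as.integer(round(v$t_alt_freq * v$depth)))
  ref_n <- pmax(0L, v$depth - alt_n)
  info_parts <- sprintf("ONT=%s;FPF=%s;COSMIC_CNT=%d;TRI=%s",
                        v$ontology, v$fpfilter, v$cosmic_count, v$tri_context)
  for (f in db_fields) {
    af <- v[[paste0("db_", f)]]
    has <- !is.na(af)
    info_parts[has] <- paste0(info_parts[has], sprintf(";%s=%.8g", f, af[has]))
  }
  has_truth <- !is.na(v$truth_label)
  info_parts[has_truth] <- paste0(info_parts[has_truth],
                                  sprintf(";TRUTH=%d", v$truth_label[has_truth]))
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", v$caller_filter,
                info_parts, "AD:DP",
                sprintf("%d,%d:%d", ref_n, alt_n, v$depth), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read copy-number segments
#'
#' Reads a tab-delimited SEG/CNR-style file with columns `chrom`, `start`,
#' `end`, `log2` (optional `sample_id`, `n_bins`; CNVkit-style `chromosome`
#' and `log2` headers are accepted). Internal convention is 0-based
#' half-open; set `one_based = TRUE` for SEG files with 1-based inclusive
#' starts.
#'
#' @param path file path.
#' @param sample_id fallback sample id when the file has no column.
#' @param one_based whether input starts are 1-based inclusive.
#' @return `data.table` of segments sorted by (chrom, start) with a
#'   `segment_id` column.
#' @export
read_segments <- function(path, sample_id = NULL, one_based = FALSE) {
  dt <- fread(path, header = TRUE)
  nm <- tolower(names(dt))
  setnames(dt, names(dt), nm)
  if ("chromosome" %in% nm) setnames(dt, "chromosome", "chrom")
  if ("loc.start" %in% nm) setnames(dt, c("loc.start", "loc.end"), c("start", "end"))
  if ("seg.mean" %in% nm) setnames(dt, "seg.mean", "log2")
  req <- c("chrom", "start", "end", "log2")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("segment file missing column(s): ", paste(miss, collapse = ", "))
  if (!("sample_id" %in% names(dt)))
    dt[, sample_id := sample_id %||% "SAMPLE"]
  if (!("n_bins" %in% names(dt))) dt[, n_bins := 1L]
  if (one_based) dt[, start := start - 1L]
  dt[, `:=`(chrom = as.character(chrom), start = as.integer(start),
            end = as.integer(end), log2 = as.numeric(log2))]
  validate_segments(dt)
}

#' Validate and canonicalize a segment table
#'
#' Checks `start < end` and that segments of one sample on one chromosome do
#' not overlap; sorts by (chrom, start) and assigns `segment_id`.
#'
#' @param segments data.frame with `sample_id, chrom, start, end, log2`.
#' @export
validate_segments <- function(segments) {
  dt <- as.data.table(segments)
  if (nrow(dt) == 0L) {
    dt[, segment_id := character()]
    return(dt[])
  }
  if (any(dt$start >= dt$end)) stop("segment with start >= end")
  setorder(dt, sample_id, chrom, start)
  ov <- dt[, .(bad = any(head(end, -1L) > tail(start, -1L))), by = .(sample_id, chrom)]
  if (any(ov$bad)) {
    pair <- dt[, .SD[which(head(end, -1L) > tail(start, -1L))[1L]],
               by = .(sample_id, chrom)]
    stop("overlapping segments within a sample, e.g. ",
         pair$sample_id[1L], " ", pair$chrom[1L], ":", pair$start[1L])
  }
  dt[, segment_id := paste0(sample_id, ":", chrom, ":", start, "-", end)]
  dt[]
}

#' Read a capture-kit footprint from a BED file
#'
#' Merges overlapping intervals and reports the merged footprint in
#' megabases.
#'
#' @param path BED3+ file (0-based half-open, no header).
#' @param kit_name label for the kit.
#' @return list with `kit_name`, `intervals` (merged `data.table`), and
#'   `footprint_mb`.
#' @export
read_footprint <- function(path, kit_name = basename(path)) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  dt <- if (file.size(path) > 0) fread(path, header = FALSE) else data.table()
  if (nrow(dt) == 0L) {
    warning("empty BED file: ", path)
    return(list(kit_name = kit_name,
                intervals = data.table(chrom = character(), start = integer(),
                                       end = integer()),
                footprint_mb = 0))
  }
  setnames(dt, seq_len(3L), c("chrom", "start", "end"))
  dt <- dt[, .(chrom = as.character(chrom), start = as.integer(start),
               end = as.integer(end))]
  if (any(dt$end <= dt$start)) stop("BED interval with end <= start in ", path)
  merge_footprint(dt, kit_name)
}

merge_footprint <- function(intervals, kit_name = "kit") {
  dt <- as.data.table(intervals)
  gr <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$start + 1L, dt$end))
  red <- GenomicRanges::reduce(gr)
  merged <- data.table(chrom = as.character(GenomicRanges::seqnames(red)),
                       start = BiocGenerics::start(red) - 1L,
                       end = BiocGenerics::end(red))
  setorder(merged, chrom, start)
  list(kit_name = kit_name, intervals = merged,
       footprint_mb = sum(as.numeric(merged$end - merged$start)) / 1e6)
}

TSV_HEADER <- "#somaticsieve_variants\tv1"

#' Write / read the package TSV interchange format for variant tables
#'
#' Numeric columns are serialized with 17 significant digits so that
#' re-reading reproduces every field bit-exactly. The first line is a
#' versioned header comment.
#'
#' @param variants variant `data.table`.
#' @param path output/input path.
#' @export
write_variants_tsv <- function(variants, path) {
  dt <- copy(as.data.table(variants))
  num <- names(dt)[vapply(dt, is.double, logical(1))]
  for (col in num) {
    v <- dt[[col]]
    s <- sprintf("%.17g", v)
    s[is.na(v)] <- NA_character_
    dt[, (col) := s]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(TSV_HEADER, paste0("#numeric\t", paste(num, collapse = "\t"))), con)
  suppressWarnings(utils::write.table(dt, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE, na = "NA"))
  invisible(path)
}

#' @rdname write_variants_tsv
#' @export
read_variants_tsv <- function(path) {
  if (!file.exists(path)) stop("variant TSV not found: ", path)
  first <- readLines(path, n = 2L)
  if (!identical(first[1L], TSV_HEADER))
    stop("not a somaticsieve variant TSV (bad header): ", path)
  num <- strsplit(sub("^#numeric\t?", "", first[2L]), "\t")[[1L]]
  dt <- fread(path, sep = "\t", header = TRUE, skip = 2L, na.strings = "NA",
              colClasses = list(character = num))
  for (col in intersect(num, names(dt))) dt[, (col) := as.numeric(get(col))]
  dt[]
}
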