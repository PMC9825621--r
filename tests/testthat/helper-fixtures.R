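# Shared fixtures. Everything is generated in code; heavier objects are
# memoized so independent test files can share one small trained pipeline.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# minimal annotated VCF writer for parser tests
write_toy_vcf <- function(records, path = tempfile(fileext = ".vcf")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ONT,Number=1,Type=String,Description=\"ontology\">",
    "##INFO=<ID=FPF,Number=1,Type=String,Description=\"fpfilter\">",
    "##INFO=<ID=COSMIC_CNT,Number=1,Type=Integer,Description=\"cosmic\">",
    "##INFO=<ID=TRI,Number=1,Type=String,Description=\"context\">",
    "##INFO=<ID=1000Gp3_AF,Number=1,Type=Float,Description=\"af\">",
    "##INFO=<ID=ExAC_AF,Number=1,Type=Float,Description=\"af\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"))
  writeLines(c(hdr, records), path)
  path
}

# hand-built variant table rows with sensible defaults
toy_variants <- function(n = 1, sample_id = "S1", chrom = "chr1",
                         pos = seq(1000, by = 1000, length.out = n),
                         ref = "C", alt = "T",
                         t_alt_freq = 0.25, t_maj_allele = 0.75, depth = 100L,
                         caller_filter = "PASS", fpfilter = "PASS",
                         ontology = "missense", cosmic_count = 0L,
                         tri_context = NULL, truth_label = NA_integer_, ...) {
  df <- data.frame(sample_id = sample_id, chrom = chrom, pos = pos,
                   ref = ref, alt = alt, t_alt_freq = t_alt_freq,
                   t_maj_allele = t_maj_allele, depth = depth,
                   caller_filter = caller_filter, fpfilter = fpfilter,
                   ontology = ontology, cosmic_count = cosmic_count,
                   truth_label = truth_label, stringsAsFactors = FALSE)
  if (!is.null(tri_context)) df$tri_context <- tri_context
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  variant_table(df)
}

toy_segments <- function(sample_id = "S1",
                         chrom = "chr1",
                         start = 0L, end = 1e6L, log2 = 0) {
  validate_segments(data.frame(sample_id = sample_id, chrom = chrom,
                               start = start, end = end, log2 = log2))
}

# small simulated world shared by model/pipeline tests: 6 patients,
# desk-scale boosting
tiny_cohort <- function() memo("tiny_cohort", {
  simulate_cohort(cohort_config(n_patients = c(low = 2L, mid = 2L, high = 2L)),
                  seed = 301)
})

tiny_analysis <- function() memo("tiny_analysis", analyze_cohort(tiny_cohort()))

tiny_suite <- function() memo("tiny_suite", {
  an <- tiny_analysis()
  train_suite(an$fm, an$labels, nrounds = 60L)
})
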