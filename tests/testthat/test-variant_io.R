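test_that("read_annotated_variants parses, splits and annotates records", {
  # header-only file
  empty <- read_annotated_variants(write_toy_vcf(character()), "S1")
  expect_equal(nrow(empty), 0L)

  recs <- c(
    # SNV with AD = 60,40 and full annotations
    "chr1\t100\t.\tC\tT\t.\tPASS\tONT=missense;FPF=PASS;COSMIC_CNT=3;TRI=ACG;1000Gp3_AF=0.002;ExAC_AF=0.005\tAD:DP\t60,40:100",
    # insertion: len(ref)=1, len(alt)=3
    "chr1\t200\t.\tA\tACG\t.\tPASS\tONT=frameshift_indel;FPF=PASS\tAD:DP\t70,30:100",
    # multi-allelic record, AD = 50,30,20
    "chr2\t300\t.\tG\tA,T\t.\tPASS\tONT=missense;FPF=PASS\tAD:DP\t50,30,20:100")
  v <- read_annotated_variants(write_toy_vcf(recs), "S1")

  expect_equal(nrow(v), 4L)  # multi-allelic split into two rows
  snv <- v[v$pos == 100]
  expect_equal(snv$t_alt_freq, 0.4)
  expect_equal(snv$t_maj_allele, 0.6)
  expect_equal(snv$variant_class, "SNV")
  expect_equal(snv$cosmic_count, 3L)
  expect_equal(snv$tri_context, "ACG")
  expect_equal(snv$db_1000Gp3_AF, 0.002)
  expect_equal(snv$db_ExAC_AF, 0.005)

  ins <- v[v$pos == 200]
  expect_equal(ins$variant_class, "insertion")
  expect_equal(ins$tri_context, "NON_SBS")
  expect_equal(ins$cosmic_count, 0L)  # missing annotation default

  multi <- v[v$chrom == "chr2"]
  expect_equal(sort(multi$alt), c("A", "T"))
  expect_equal(multi$t_alt_freq, c(0.3, 0.2))
  # t_maj_allele over all observed alleles of the original record
  expect_equal(multi$t_maj_allele, c(0.5, 0.5))
})

test_that("read_annotated_variants flags missing depth fields", {
  rec <- "chr1\t100\t.\tC\tT\t.\tPASS\tONT=missense\tDP\t100"
  expect_error(read_annotated_variants(write_toy_vcf(rec), "S1"),
               "AD")
})

test_that("annotated VCF writing round-trips through the parser", {
  v <- toy_variants(n = 3, ontology = c("missense", "nonsense", "missense"),
                    cosmic_count = c(0L, 5L, 2L), truth_label = c(1L, 0L, 1L),
                    db_ExAC_AF = c(NA, 0.004, NA))
  path <- tempfile(fileext = ".vcf")
  write_annotated_vcf(v, path)
  back <- read_annotated_variants(path, "S1")
  expect_equal(back$key, v$key)
  expect_equal(back$ontology, v$ontology)
  expect_equal(back$cosmic_count, v$cosmic_count)
  expect_equal(back$truth_label, v$truth_label)
  expect_equal(back$db_ExAC_AF, v$db_ExAC_AF, tolerance = 1e-7)
  expect_equal(back$t_alt_freq, v$t_alt_freq, tolerance = 1e-7)
})

test_that("compute_pop_max takes the maximum with absent-means-zero", {
  expect_equal(compute_pop_max(list()), 0)
  expect_equal(compute_pop_max(list(`1000Gp3` = 0.002, ExAC = 0.005)), 0.005)
  expect_equal(compute_pop_max(list(gnomAD_exomes = 0.5, TWINSUK = 0.01)), 0.5)
  expect_error(compute_pop_max(list(a = 1.2)), "outside")

  # monotone: adding an entry never decreases the result
  set.seed(11)
  for (i in 1:25) {
    n <- sample(0:5, 1)
    base <- as.list(runif(n))
    if (n > 0) names(base) <- paste0("db", seq_len(n))
    before <- compute_pop_max(base)
    base$extra <- runif(1)
    expect_gte(compute_pop_max(base), before)
  }

  # data.frame form matches elementwise
  v <- toy_variants(n = 2, db_ExAC_AF = c(0.3, NA), db_TWINSUK_AF = c(0.1, NA))
  expect_equal(compute_pop_max(v), c(0.3, 0))
})

test_that("read_segments types, sorts and validates", {
  path <- tempfile(fileext = ".seg")
  writeLines(c("sample_id\tchrom\tstart\tend\tlog2",
               "S1\tchr1\t1000\t5000\t-0.4",
               "S1\tchr1\t0\t1000\t0.0"), path)
  seg <- read_segments(path)
  expect_equal(seg$start, c(0L, 1000L))
  expect_equal(seg$log2, c(0, -0.4))

  writeLines("sample_id\tchrom\tstart\tend\tlog2", path)
  expect_equal(nrow(read_segments(path)), 0L)

  writeLines(c("sample_id\tchrom\tstart\tend\tlog2",
               "S1\tchr1\t0\t1000\t0.0",
               "S1\tchr1\t500\t2000\t0.1"), path)
  expect_error(read_segments(path), "overlap")
})

test_that("read_footprint merges intervals and reports megabases", {
  path <- tempfile(fileext = ".bed")
  writeLines("chr1\t0\t1000000", path)
  expect_equal(read_footprint(path)$footprint_mb, 1.0)

  writeLines(c("chr1\t0\t100", "chr1\t50\t200"), path)
  fp <- read_footprint(path)
  expect_equal(fp$footprint_mb, 2e-4)
  expect_equal(nrow(fp$intervals), 1L)

  file.create(path)
  expect_warning(fp0 <- read_footprint(path), "empty")
  expect_equal(fp0$footprint_mb, 0)

  writeLines("chr1\t100\t100", path)
  expect_error(read_footprint(path), "end")

  # merging is idempotent and order-independent
  set.seed(5)
  iv <- data.frame(chrom = sample(c("chr1", "chr2"), 30, TRUE),
                   start = sample.int(1e5, 30))
  iv$end <- iv$start + sample.int(5e4, 30)
  m1 <- somaticsieve:::merge_footprint(iv)
  m2 <- somaticsieve:::merge_footprint(iv[sample.int(30), ])
  m3 <- somaticsieve:::merge_footprint(m1$intervals)
  expect_equal(m1$intervals, m2$intervals)
  expect_equal(m1$footprint_mb, m3$footprint_mb)
})

test_that("TSV interchange round-trips variant tables exactly", {
  set.seed(21)
  v <- toy_variants(n = 5,
                    t_alt_freq = runif(5), t_maj_allele = runif(5, 0.5, 1),
                    cosmic_count = sample(0:9, 5, TRUE),
                    truth_label = c(0L, 1L, NA, 1L, 0L),
                    db_ExAC_AF = c(runif(3) / 200, NA, NA))
  path <- tempfile(fileext = ".tsv")
  write_variants_tsv(v, path)
  back <- read_variants_tsv(path)
  expect_identical(back$t_alt_freq, v$t_alt_freq)
  expect_identical(back$db_ExAC_AF, v$db_ExAC_AF)
  expect_identical(back$truth_label, v$truth_label)
  expect_identical(back$key, v$key)
  expect_error(read_variants_tsv(tempfile()), "not found")
})

test_that("variant_table enforces its invariants", {
  expect_error(toy_variants(t_alt_freq = 1.5), "t_alt_freq")
  expect_error(toy_variants(ref = "C", alt = "T", tri_context = "NON_SBS"),
               "NON_SBS")
  df <- data.frame(sample_id = "S1", chrom = "chr1", pos = 1L, ref = "C",
                   alt = "T", variant_class = "insertion", t_alt_freq = 0.5,
                   t_maj_allele = 0.5)
  expect_error(variant_table(df), "variant_class")
})

test_that("indel keys are trimmed to parsimonious alleles", {
  # GAC>GTC at 100: shared prefix G and suffix C trim to A>T at 101
  expect_equal(somaticsieve:::variant_key("chr1", 100L, "GAC", "GTC"),
               "chr1:101:A:T")
  expect_equal(somaticsieve:::variant_key("chr1", 100L, "ATT", "A"),
               "chr1:100:ATT:A")
})
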