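test_that("collect_informative_snps keeps common PASS heterozygous SNVs in segments", {
  seg <- toy_segments()
  v <- rbind(
    toy_variants(pos = 1000, t_alt_freq = 0.48, db_ExAC_AF = 0.3),    # in
    toy_variants(pos = 2000, t_alt_freq = 0.48, db_ExAC_AF = 0.001),  # not common
    toy_variants(pos = 3000, t_alt_freq = 0.99, db_ExAC_AF = 0.3),    # homozygous
    toy_variants(pos = 4000, t_alt_freq = 0.48, db_ExAC_AF = 0.3,
                 fpfilter = "FAIL"),                                   # artifact
    toy_variants(pos = 5000, ref = "C", alt = "CAT", t_alt_freq = 0.48,
                 db_ExAC_AF = 0.3),                                    # not SNV
    toy_variants(pos = 2e6, t_alt_freq = 0.48, db_ExAC_AF = 0.3))     # no segment
  snps <- collect_informative_snps(v, seg)
  expect_equal(snps$pos, 1000L)
  expect_equal(snps$segment_id, seg$segment_id[1L])
})

test_that("snp_vaf_histogram bins are left-closed with VAF 1 clamped to bin 19", {
  seg <- toy_segments()
  variant <- toy_variants(pos = 500)
  snps <- data.frame(sample_id = "S1", chrom = "chr1",
                     pos = c(100, 200, 300, 400),
                     vaf = c(0.02, 0.50, 0.52, 0.98),
                     pop_max = 0.3, segment_id = seg$segment_id[1L])
  h <- snp_vaf_histogram(variant, snps, seg)
  expect_equal(sum(h), 4L)
  expect_equal(unname(h[c("snp_vaf_bin_00", "snp_vaf_bin_10", "snp_vaf_bin_19")]),
               c(1L, 2L, 1L))

  snps$vaf <- c(1.0, 0.0, 0.05, 0.95)  # exact boundaries
  h2 <- snp_vaf_histogram(variant, snps, seg)
  expect_equal(unname(h2[c("snp_vaf_bin_19", "snp_vaf_bin_00", "snp_vaf_bin_01")]),
               c(2L, 1L, 1L))

  # no SNPs in the segment -> all zero
  expect_equal(sum(snp_vaf_histogram(variant, snps[0, ], seg)), 0L)

  # variant outside all segments -> warning + zeros
  out <- toy_variants(pos = 5e6)
  expect_warning(h3 <- snp_vaf_histogram(out, snps, seg), "outside")
  expect_equal(sum(h3), 0L)
})

test_that("substitution_encoding maps to pyrimidine-centered classes", {
  # purine-centered G>A in context TGC reverse-complements to C>T, flanks G/A
  enc <- substitution_encoding("G", "A", "TGC")
  expect_equal(enc$class, "C>T")
  expect_equal(enc$context, "ctx_GA")

  enc2 <- substitution_encoding("C", "T", "ACG")
  expect_equal(enc2$class, "C>T")
  expect_equal(enc2$context, "ctx_AG")

  enc3 <- substitution_encoding("A", "ACG", "NON_SBS")
  expect_equal(enc3$class, "non_SBS")
  expect_equal(enc3$context, "non_SBS_y")

  # unknown flanks keep the class but lose the context
  enc4 <- substitution_encoding("C", "A", "NCN")
  expect_equal(enc4$class, "C>A")
  expect_equal(enc4$context, "non_SBS_y")

  expect_error(substitution_encoding("C", "T", "AAG"), "central")
})

test_that("assemble_feature_matrix produces the 53-column schema", {
  seg <- toy_segments()
  v1 <- toy_variants(tri_context = "ACG")
  fm1 <- assemble_feature_matrix(v1, collect_informative_snps(v1, seg), seg)
  expect_equal(ncol(fm1$X), 53L)
  expect_equal(sum(fm1$X[1, sprintf("snp_vaf_bin_%02d", 0:19)]), 0)
  expect_equal(unname(fm1$X[1, "count"]), 1)
  expect_equal(unname(fm1$X[1, "missense"]), 1)
  expect_equal(unname(fm1$X[1, "sub_C>T"]), 1)
  expect_equal(unname(fm1$X[1, "ctx_AG"]), 1)
  # one-hot groups each sum to exactly 1
  sch <- feature_schema()
  ont <- c("missense", "nonsense", "frameshift_indel", "inframe_indel")
  subs <- grep("^sub_", sch$columns, value = TRUE)
  ctxs <- grep("^ctx_", sch$columns, value = TRUE)
  expect_equal(unname(rowSums(fm1$X[, ont, drop = FALSE])), 1)
  expect_equal(unname(rowSums(fm1$X[, subs, drop = FALSE])), 1)
  expect_equal(unname(rowSums(fm1$X[, ctxs, drop = FALSE])), 1)

  # count broadcast: samples with 3 and 1 kept variants
  v <- rbind(toy_variants(n = 3, sample_id = "S1"),
             toy_variants(n = 1, sample_id = "S2"))
  seg2 <- rbind(toy_segments("S1"), toy_segments("S2"))
  fm <- assemble_feature_matrix(v, collect_informative_snps(v, seg2), seg2)
  expect_equal(unname(fm$X[, "count"]), c(3, 3, 3, 1))
  expect_equal(fm$meta$variant_category, rep("SNV", 4))
})

test_that("histogram bins in the matrix sum to the per-segment SNP counts", {
  co <- tiny_cohort()
  s <- co$samples[[1]]
  snps <- collect_informative_snps(s$variants, s$segments)
  kept <- apply_prefilter(s$variants)$kept
  fm <- assemble_feature_matrix(kept, snps, s$segments)
  seg_of <- somaticsieve:::assign_segment(kept, s$segments)
  bins <- fm$X[, sprintf("snp_vaf_bin_%02d", 0:19), drop = FALSE]
  snp_per_seg <- table(snps$segment_id)
  in_seg <- !is.na(seg_of)
  expected <- ifelse(in_seg, as.integer(snp_per_seg[seg_of]), 0L)
  expected[is.na(expected)] <- 0L
  expect_equal(unname(rowSums(bins)), expected)
})

test_that("feature extraction is pure and order-invariant", {
  co <- tiny_cohort()
  s <- co$samples[[2]]
  snps <- collect_informative_snps(s$variants, s$segments)
  kept <- apply_prefilter(s$variants)$kept
  fm1 <- assemble_feature_matrix(kept, snps, s$segments)
  fm2 <- assemble_feature_matrix(kept, snps, s$segments)
  expect_identical(fm1$X, fm2$X)
  shuf <- kept[sample.int(nrow(kept)), ]
  fm3 <- assemble_feature_matrix(shuf, snps, s$segments)
  expect_identical(fm1$X, fm3$X)
  expect_identical(fm1$meta$key, fm3$meta$key)
})

test_that("rbind_feature_matrix enforces the schema and TSV IO checks hashes", {
  seg <- toy_segments()
  v <- toy_variants(tri_context = "ACG")
  fm <- assemble_feature_matrix(v, collect_informative_snps(v, seg), seg)
  broken <- fm
  colnames(broken$X)[6] <- "snp_vaf_bin_XX"
  expect_error(rbind_feature_matrix(fm, broken), "snp_vaf_bin")

  path <- tempfile(fileext = ".tsv")
  write_feature_matrix_tsv(fm, path)
  back <- read_feature_matrix_tsv(path)
  expect_equal(back$X, fm$X, ignore_attr = TRUE)
  expect_equal(back$meta$key, fm$meta$key)

  lines <- readLines(path)
  lines[1] <- "#somaticsieve_features\tv1\tdeadbeef"
  writeLines(lines, path)
  expect_error(read_feature_matrix_tsv(path), "hash mismatch")
})
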