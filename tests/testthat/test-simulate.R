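test_that("expected_vaf follows the purity/copy-number accounting", {
  expect_equal(expected_vaf(1, 2, 1), 0.5)
  expect_equal(expected_vaf(0.5, 2, 1), 0.25)
  expect_equal(expected_vaf(0.5, 2, 1, germline = TRUE), 0.5)
  # germline het VAF is 0.5 in a diploid segment at any purity
  for (p in c(0.2, 0.5, 0.9)) {
    expect_equal(expected_vaf(p, 2, 1, germline = TRUE), 0.5)
  }
  expect_equal(expected_vaf(0.6, 3, 2), 0.6 * 2 / (0.6 * 3 + 0.8))
  expect_error(expected_vaf(0.5, 2, 3), "exceeds")
  expect_error(expected_vaf(0, 2, 1), "purity")
})

test_that("simulation is deterministic for a fixed seed", {
  cfg <- cohort_config(n_patients = c(low = 1L, mid = 1L, high = 1L))
  a <- simulate_cohort(cfg, seed = 11)
  b <- simulate_cohort(cfg, seed = 11)
  expect_identical(cohort_truth(a), cohort_truth(b))
  expect_identical(a$samples[[2]]$variants, b$samples[[2]]$variants)
  expect_identical(a$samples[[3]]$segments, b$samples[[3]]$segments)
  c_ <- simulate_cohort(cfg, seed = 12)
  expect_false(identical(a$samples[[1]]$variants, c_$samples[[1]]$variants))
  # the caller's RNG state is untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_cohort(cfg, seed = 11)); after <- runif(1)
  expect_identical(before, after)
})

test_that("full database representation leaves almost no germline leakage", {
  cfg <- cohort_config(n_patients = c(low = 2L, mid = 1L, high = 1L),
                       ancestry = data.frame(group = "g", prob = 1, r_db = 1),
                       rare_db_low_prob = 0, artifact_rate = 0)
  co <- simulate_cohort(cfg, seed = 21)
  an <- analyze_cohort(co)
  tt <- tmb_table(an, list(), norm_mb = cfg$footprint_mb)
  # naive TMB collapses onto truth when the databases are complete
  expect_lt(max(abs(tt$naive_tmb - tt$true_tmb)), 0.5)
})

test_that("somatic VAF matches the expected purity scaling", {
  # clonal diploid tumor at purity 0.6: MVTSM ~ 0.30
  cfg <- cohort_config(n_patients = c(mid = 2L),
                       tmb_median = c(mid = 6),
                       purity_range = c(0.5999, 0.6001),
                       cn_state_probs = c(`2` = 1),
                       subclonal_prob = 0, multi_copy_prob = 0,
                       mean_depth = 100)
  co <- simulate_cohort(cfg, seed = 31)
  for (s in co$samples) {
    expect_gt(sum(s$variants$truth_label == 1L), 150)
    expect_lt(abs(mvtsm(s) - 0.30), 0.03)
  }
})

test_that("mvtsm is the median somatic VAF of filtered-through variants", {
  v <- toy_variants(n = 3, t_alt_freq = c(0.1, 0.3, 0.5), truth_label = 1L)
  expect_equal(mvtsm(list(variants = v)), 0.3)
  v1 <- toy_variants(n = 1, t_alt_freq = 0.42, truth_label = 1L)
  expect_equal(mvtsm(list(variants = v1)), 0.42)
  v0 <- toy_variants(n = 1, t_alt_freq = 0.42, truth_label = 0L)
  expect_true(is.na(mvtsm(list(variants = v0))))
})

test_that("emitted cohorts satisfy the structural contracts", {
  co <- tiny_cohort()
  for (s in co$samples) {
    v <- s$variants
    expect_true(all(!is.na(v$truth_label)))
    expect_true(all(v$t_alt_freq > 0 & v$t_alt_freq <= 1))
    expect_true(all(v$depth > 0))
    # caller floor: at least 3 supporting reads
    expect_true(all(round(v$t_alt_freq * v$depth) >= 3))
    # recorded true TMB matches the labeled coding somatic count
    coding <- v$truth_label == 1L & v$fpfilter == "PASS" &
      v$ontology %in% c("missense", "nonsense", "frameshift_indel",
                        "inframe_indel")
    expect_equal(s$true_tmb, sum(coding) / co$config$footprint_mb)
    # segments tile the genome without overlap (validated on construction)
    expect_true(all(s$segments$start < s$segments$end))
  }
  # ancestry-dependent leakage: under-represented group keeps more rare
  # germline variants past the pre-filter
  an <- tiny_analysis()
  tt <- tmb_table(an, list(), norm_mb = co$config$footprint_mb)
  excess <- tt$naive_tmb - tt$true_tmb
  if (length(unique(tt$group)) == 2L) {
    expect_gt(mean(excess[tt$group == "groupB"]),
              mean(excess[tt$group == "groupA"]))
  }
})

test_that("written cohorts read back through the standard-format parsers", {
  co <- simulate_cohort(cohort_config(n_patients = c(low = 1L, mid = 1L,
                                                     high = 1L)), seed = 41)
  dir <- tempfile("cohort_")
  write_cohort(co, dir)
  s1 <- co$samples[[1]]
  v <- read_annotated_variants(file.path(dir, paste0(s1$sample_id, ".vcf")),
                               s1$sample_id)
  expect_equal(nrow(v), nrow(s1$variants))
  expect_identical(v$key, s1$variants$key)
  expect_identical(v$ontology, s1$variants$ontology)
  expect_equal(v$t_alt_freq, s1$variants$t_alt_freq, tolerance = 5e-3)
  seg <- read_segments(file.path(dir, "segments.seg"))
  expect_equal(nrow(seg), sum(vapply(co$samples, function(s) nrow(s$segments),
                                     numeric(1))))
  normals <- jsonlite::read_json(file.path(dir, "normals.json"),
                                 simplifyVector = TRUE)
  expect_setequal(names(normals), vapply(co$samples, `[[`, character(1),
                                         "sample_id"))
})
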