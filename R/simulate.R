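# Synthetic tumor-only cohort simulator.
#
# Generates truth-labeled cohorts with the statistical structure the
# classifier exploits: per-patient purity, subtype-dependent true TMB,
# copy-number segments, clonal/subclonal somatic VAFs with binomial read
# sampling, rare het/hom germline variants whose presence in population
# databases depends on the patient's ancestry group (the database-bias
# mechanism), common heterozygous SNPs that act as informative SNPs for the
# local copy state, COSMIC-count and mutational-spectrum differences
# between somatic and germline variants, recurrent technical artifacts, and
# per-patient normal-sample call sets for leave-one-out panel construction.
#
# Defaults were calibrated once to the magnitudes seen in real tumor-only
# WES benchmarks (see the methods vignette) and are part of the stated
# world, not tuning knobs.

#' Expected variant allele fraction under purity and copy number
#'
#' Standard allele-fraction accounting for a bulk tumor biopsy with purity
#' `purity`, local tumor copy number `tumor_cn` and `mutant_copies` mutant
#' copies in the tumor. Somatic: `pm / (pC + 2(1-p))`. Germline het: the
#' contaminating normal carries one copy, `(pm + (1-p)) / (pC + 2(1-p))`.
#'
#' @param purity tumor purity in (0, 1].
#' @param tumor_cn local tumor copy number >= 1.
#' @param mutant_copies mutant allele copies, `1 <= m <= tumor_cn`.
#' @param germline whether the variant is a heterozygous germline variant.
#' @return expected VAF in `[0, 1]`.
#' @export
expected_vaf <- function(purity, tumor_cn, mutant_copies, germline = FALSE) {
  stopifnot(all(purity > 0), all(purity <= 1), all(tumor_cn >= 1))
  if (any(mutant_copies > tumor_cn))
    stop("mutant_copies exceeds tumor copy number")
  if (any(mutant_copies < 1)) stop("mutant_copies must be >= 1")
  denom <- purity * tumor_cn + 2 * (1 - purity)
  num <- purity * mutant_copies + if (isTRUE(germline)) (1 - purity) else 0
  num / denom
}

# internal general form allowing lost alleles (m = 0) and hom germline
# (normal_copies = 2)
vaf_general <- function(purity, tumor_cn, mutant_copies, normal_copies) {
  (purity * mutant_copies + (1 - purity) * normal_copies) /
    (purity * tumor_cn + 2 * (1 - purity))
}

#' Cohort simulation configuration
#'
#' The defaults describe the package's reference synthetic world: three
#' subtype strata spanning low to high mutational burden, purity uniform on
#' (0.2, 0.9), 120x mean coverage over a 41 Mb capture footprint, a rare
#' germline load of ~2500 variants per patient, and two ancestry groups
#' whose rare variants are represented in the germline databases with
#' probability `r_db` (0.85 for the well-represented group, 0.55 for the
#' under-represented group). See the methods vignette for the rationale
#' behind every default.
#'
#' @param n_patients named integer vector: patients per subtype.
#' @param tmb_median named numeric: median coding-somatic TMB (mut/Mb) per
#'   subtype; must share names with `n_patients`.
#' @param tmb_sdlog log-normal spread of true TMB within subtype.
#' @param purity_range uniform purity range (subset of (0, 1]).
#' @param footprint_mb capture footprint in megabases.
#' @param mean_depth mean sequencing depth (Poisson).
#' @param n_chrom,chrom_length synthetic genome shape.
#' @param seg_per_chrom_lambda Poisson rate of extra copy-number breakpoints
#'   per chromosome.
#' @param cn_state_probs distribution of integer tumor copy states.
#' @param rare_germline_meanlog,rare_germline_sdlog log-normal rare germline
#'   variant count per patient.
#' @param ancestry data.frame with `group`, `prob` (cohort fraction) and
#'   `r_db` (probability a rare germline variant is represented in the
#'   databases above the rarity-filter floor).
#' @param rare_db_low_prob probability an unrepresented rare variant still
#'   has a tiny (< 0.01) database frequency.
#' @param common_pool_size,rare_pool_size,artifact_pool_size population pool
#'   sizes shared by all patients (drive PoN recurrence).
#' @param artifact_rate per-patient presence probability of each artifact.
#' @param het_fraction_rare fraction of rare germline variants that are
#'   heterozygous.
#' @param subclonal_prob,subclonal_ccf two-clone somatic mixture: fraction
#'   of subclonal mutations and their cancer-cell fraction.
#' @param multi_copy_prob probability a somatic mutation sits on 2 copies
#'   when the local copy number allows it.
#' @param cosmic_nonzero_somatic,cosmic_nonzero_germline zero-inflation of
#'   COSMIC occurrence counts.
#' @param cosmic_geom_somatic,cosmic_geom_germline geometric parameter of
#'   the nonzero COSMIC counts.
#' @param ontology_somatic,ontology_germline ontology distributions
#'   (somatic is nonsense-enriched).
#' @param spectrum_somatic,spectrum_germline pyrimidine-centered
#'   substitution-class spectra.
#' @param fpfilter_fail_rate small random artifact-filter failure rate
#'   applied to real variants.
#' @param min_alt_reads caller sensitivity floor: variants with fewer alt
#'   reads are never emitted.
#' @return object of class `sv_cohort_config`.
#' @export
cohort_config <- function(n_patients = c(low = 10L, mid = 10L, high = 10L),
                          tmb_median = c(low = 1.5, mid = 3, high = 8),
                          tmb_sdlog = 0.35,
                          purity_range = c(0.2, 0.9),
                          footprint_mb = 41,
                          mean_depth = 120,
                          n_chrom = 22L,
                          chrom_length = 130e6,
                          seg_per_chrom_lambda = 0.8,
                          cn_state_probs = c(`1` = 0.08, `2` = 0.62,
                                             `3` = 0.20, `4` = 0.10),
                          rare_germline_meanlog = log(2500),
                          rare_germline_sdlog = 0.3,
                          ancestry = data.frame(
                            group = c("groupA", "groupB"),
                            prob = c(0.8, 0.2),
                            r_db = c(0.85, 0.55)),
                          rare_db_low_prob = 0.4,
                          common_pool_size = 4000L,
                          rare_pool_size = 500000L,
                          artifact_pool_size = 300L,
                          artifact_rate = 0.5,
                          het_fraction_rare = 0.95,
                          subclonal_prob = 0.3,
                          subclonal_ccf = 0.5,
                          multi_copy_prob = 0.1,
                          cosmic_nonzero_somatic = 0.25,
                          cosmic_nonzero_germline = 0.12,
                          cosmic_geom_somatic = 0.4,
                          cosmic_geom_germline = 0.7,
                          ontology_somatic = c(missense = 0.70, nonsense = 0.12,
                                               frameshift_indel = 0.08,
                                               inframe_indel = 0.05, other = 0.05),
                          ontology_germline = c(missense = 0.72, nonsense = 0.065,
                                                frameshift_indel = 0.045,
                                                inframe_indel = 0.04, other = 0.13),
                          spectrum_somatic = c(`C>A` = 0.28, `C>G` = 0.09,
                                               `C>T` = 0.30, `T>A` = 0.08,
                                               `T>C` = 0.15, `T>G` = 0.10),
                          spectrum_germline = c(`C>A` = 0.09, `C>G` = 0.09,
                                                `C>T` = 0.40, `T>A` = 0.06,
                                                `T>C` = 0.27, `T>G` = 0.09),
                          fpfilter_fail_rate = 0.02,
                          min_alt_reads = 3L) {
  stopifnot(identical(sort(names(n_patients)), sort(names(tmb_median))),
            all(purity_range > 0), all(purity_range <= 1),
            purity_range[1] < purity_range[2],
            mean_depth > 0, footprint_mb > 0,
            abs(sum(ancestry$prob) - 1) < 1e-9,
            all(ancestry$r_db >= 0 & ancestry$r_db <= 1))
  cfg <- as.list(environment())
  structure(cfg, class = "sv_cohort_config")
}

#' @export
print.sv_cohort_config <- function(x, ...) {
  cat("<sv_cohort_config> ", sum(x$n_patients), " patients (",
      paste(names(x$n_patients), x$n_patients, sep = "=", collapse = ", "),
      "); groups: ",
      paste(x$ancestry$group, "r_db=", x$ancestry$r_db, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

BASES <- c("A", "C", "G", "T")

# deterministic attributes of a population-pool variant id (exact for
# ids < 2^26 in double arithmetic); identity must be shared by every
# patient carrying the same pool variant or the panel of normals could
# never see recurrence
pool_variant <- function(id, n_chrom, chrom_length, prefix) {
  chrom <- paste0("chr", (id %% n_chrom) + 1)
  pos <- ((id * 48271 + 11) %% (chrom_length - 2)) + 2
  ri <- (id * 13) %% 4
  ai <- (ri + 1 + (id * 17) %% 3) %% 4
  list(chrom = chrom, pos = as.integer(pos),
       ref = BASES[ri + 1], alt = BASES[ai + 1],
       f5 = BASES[((id * 19) %% 4) + 1], f3 = BASES[((id * 23) %% 4) + 1])
}

# deterministic uniform in [0, 1) derived from a pool id
det_u <- function(id, salt) ((id * 2654435761 + salt * 97003) %% 999983) / 999983

# deterministic categorical draw from a probability vector
det_cat <- function(id, salt, probs) {
  u <- det_u(id, salt)
  names(probs)[findInterval(u, cumsum(probs) / sum(probs)) + 1L]
}

# deterministic indel alleles for pool variants
det_indel_alleles <- function(id, ontology, anchor) {
  len <- ifelse(ontology == "inframe_indel", 3L, 1L + (id %% 2))
  extra <- vapply(seq_along(id), function(k) {
    paste(BASES[((id[k] * 31 + 7 * seq_len(len[k])) %% 4) + 1], collapse = "")
  }, character(1))
  ins <- (id %% 3) < 2
  list(ref = ifelse(ins, anchor, paste0(anchor, extra)),
       alt = ifelse(ins, paste0(anchor, extra), anchor))
}

# build ref/alt/tri_context for SNVs from pyrimidine-centered class with a
# random strand; flanks given in the pyrimidine frame
snv_alleles <- function(class, f5, f3, flip) {
  from <- substr(class, 1L, 1L)
  to <- substr(class, 3L, 3L)
  ref <- ifelse(flip, unname(DNA_COMP[from]), from)
  alt <- ifelse(flip, unname(DNA_COMP[to]), to)
  ctx <- ifelse(flip,
                paste0(unname(DNA_COMP[f3]), ref, unname(DNA_COMP[f5])),
                paste0(f5, ref, f3))
  list(ref = ref, alt = alt, tri = ctx)
}

indel_alleles <- function(ontology) {
  n <- length(ontology)
  anchor <- sample(BASES, n, replace = TRUE)
  len <- ifelse(ontology == "inframe_indel", 3L,
                sample(c(1L, 2L), n, replace = TRUE))
  extra <- vapply(len, function(k) paste(sample(BASES, k, replace = TRUE),
                                         collapse = ""), character(1))
  ins <- runif(n) < 0.5
  ref <- ifelse(ins, anchor, paste0(anchor, extra))
  alt <- ifelse(ins, paste0(anchor, extra), anchor)
  list(ref = ref, alt = alt)
}

rcosmic <- function(n, p_nonzero, geom_p) {
  nz <- runif(n) < p_nonzero
  out <- integer(n)
  out[nz] <- 1L + rgeom(sum(nz), geom_p)
  out
}

# segments for one patient: chromosomes fully tiled by copy-number states
simulate_segments <- function(cfg, sample_id, purity) {
  states <- as.integer(names(cfg$cn_state_probs))
  segs <- lapply(seq_len(cfg$n_chrom), function(ci) {
    nb <- rpois(1L, cfg$seg_per_chrom_lambda)
    brk <- sort(unique(round(runif(nb, 1, cfg$chrom_length - 1))))
    bounds <- c(0, brk, cfg$chrom_length)
    cn <- states[sample.int(length(states), length(bounds) - 1L,
                            replace = TRUE, prob = cfg$cn_state_probs)]
    data.table(chrom = paste0("chr", ci),
               start = as.integer(head(bounds, -1L)),
               end = as.integer(tail(bounds, -1L)),
               cn = cn)
  })
  seg <- rbindlist(segs)
  seg[, sample_id := sample_id]
  seg[, log2 := log2((purity * cn + 2 * (1 - purity)) / 2)]
  seg[, n_bins := pmax(1L, as.integer((end - start) / 1e6))]
  validate_segments(seg[, .(sample_id, chrom, start, end, log2, n_bins, cn)])
}

# copy state at 1-based positions, from a patient's segment table
cn_at <- function(seg, chrom, pos) {
  out <- integer(length(pos))
  for (ch in unique(chrom)) {
    s <- seg[seg$chrom == ch, ]
    s <- s[order(s$start), ]
    i <- which(chrom == ch)
    hit <- findInterval(pos[i], s$start + 1L)
    hit[hit < 1L] <- 1L
    out[i] <- s$cn[hit]
  }
  out
}

read_sample_vaf <- function(n, vaf, mean_depth) {
  depth <- rpois(n, mean_depth)
  depth[depth < 1L] <- 1L
  alt <- rbinom(n, depth, pmin(pmax(vaf, 0), 1))
  list(depth = depth, alt = alt)
}

#' Simulate a synthetic tumor-only cohort
#'
#' Deterministic for a fixed `(config, seed)` pair: all randomness flows
#' through one seeded RNG stream, and the caller's RNG state is restored.
#'
#' @param config [cohort_config()].
#' @param seed integer seed.
#' @return object of class `sv_cohort`: list of samples (each with
#'   `sample_id`, `group`, `subtype`, `purity`, `true_tmb` (realized coding
#'   somatic count / footprint), `target_tmb` (drawn), `variants`
#'   (truth-labeled variant table including informative SNPs and
#'   artifacts), `segments`, `normal_keys`), plus `config` and `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "sv_cohort_config"))
  with_seed(seed, simulate_cohort_impl(config, seed))
}

simulate_cohort_impl <- function(cfg, seed) {
  n_total <- sum(cfg$n_patients)
  subtypes <- rep(names(cfg$n_patients), cfg$n_patients)

  # ancestry groups assigned with deterministic counts, stratified within
  # subtype so the group contrast is not confounded with subtype mix
  alloc <- function(n, probs) {
    counts <- floor(probs * n)
    rem <- n - sum(counts)
    if (rem > 0) {
      frac <- probs * n - counts
      counts[order(-frac)[seq_len(rem)]] <- counts[order(-frac)[seq_len(rem)]] + 1
    }
    counts
  }
  groups <- unlist(lapply(unname(cfg$n_patients), function(n)
    sample(rep(cfg$ancestry$group, alloc(n, cfg$ancestry$prob)))),
    use.names = FALSE)
  r_db_by_group <- setNames(cfg$ancestry$r_db, cfg$ancestry$group)

  # cohort-level common-SNP pool (population AFs fixed across patients)
  common_ids <- seq_len(cfg$common_pool_size)
  common_af <- runif(cfg$common_pool_size, 0.05, 0.5)

  db_fields <- default_db_fields()
  samples <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    sid <- sprintf("P%03d", i)
    samples[[i]] <- simulate_patient(cfg, sid, subtypes[i], groups[i],
                                     r_db_by_group[[groups[i]]],
                                     common_ids, common_af, db_fields)
  }
  structure(list(samples = samples, config = cfg, seed = seed),
            class = "sv_cohort")
}

#' @export
print.sv_cohort <- function(x, ...) {
  nv <- sum(vapply(x$samples, function(s) nrow(s$variants), numeric(1)))
  cat("<sv_cohort> ", length(x$samples), " patients, ", nv,
      " emitted variants (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

simulate_patient <- function(cfg, sid, subtype, group, r_db,
                             common_ids, common_af, db_fields) {
  purity <- runif(1L, cfg$purity_range[1L], cfg$purity_range[2L])
  seg <- simulate_segments(cfg, sid, purity)
  target_tmb <- rlnorm(1L, log(cfg$tmb_median[[subtype]]), cfg$tmb_sdlog)

  # database annotation matrix: af[k] placed in a random db column for
  # rows idx[k]; everything else absent (NA)
  db_table <- function(n, idx = integer(), af = numeric()) {
    m <- matrix(NA_real_, n, length(db_fields),
                dimnames = list(NULL, db_cols(db_fields)))
    if (length(idx))
      m[cbind(idx, sample.int(length(db_fields), length(idx), replace = TRUE))] <- af
    as.data.table(m)
  }

  ## --- somatic mutations ---------------------------------------------
  n_som <- rpois(1L, target_tmb * cfg$footprint_mb * 1.06)
  som <- NULL
  if (n_som > 0L) {
    seg_pick <- sample.int(nrow(seg), n_som, replace = TRUE,
                           prob = seg$end - seg$start)
    pos <- as.integer(floor(runif(n_som, seg$start[seg_pick] + 1,
                                  seg$end[seg_pick] + 1)))
    cn <- seg$cn[seg_pick]
    m <- ifelse(runif(n_som) < cfg$multi_copy_prob & cn >= 2L, 2L, 1L)
    ccf <- ifelse(runif(n_som) < cfg$subclonal_prob, cfg$subclonal_ccf, 1)
    vaf <- ccf * vaf_general(purity, cn, m, 0)
    ont <- sample(names(cfg$ontology_somatic), n_som, replace = TRUE,
                  prob = cfg$ontology_somatic)
    is_sbs <- !(ont %in% c("frameshift_indel", "inframe_indel"))
    cls <- sample(names(cfg$spectrum_somatic), n_som, replace = TRUE,
                  prob = cfg$spectrum_somatic)
    al <- snv_alleles(cls, sample(BASES, n_som, TRUE), sample(BASES, n_som, TRUE),
                      runif(n_som) < 0.5)
    ref <- al$ref; alt <- al$alt; tri <- al$tri
    if (any(!is_sbs)) {
      ia <- indel_alleles(ont[!is_sbs])
      ref[!is_sbs] <- ia$ref; alt[!is_sbs] <- ia$alt
      tri[!is_sbs] <- "NON_SBS"
    }
    rd <- read_sample_vaf(n_som, vaf, cfg$mean_depth)
    in_db <- which(runif(n_som) < 0.02)
    db <- db_table(n_som, in_db, runif(length(in_db), 1e-5, 0.005))
    som <- data.table(chrom = seg$chrom[seg_pick], pos = pos, ref = ref,
                      alt = alt, t_alt = rd$alt, depth = rd$depth,
                      ontology = ont, tri_context = tri,
                      cosmic_count = rcosmic(n_som, cfg$cosmic_nonzero_somatic,
                                             cfg$cosmic_geom_somatic),
                      truth_label = 1L)
    som <- cbind(som, db)
  }

  ## --- rare germline variants ----------------------------------------
  n_rare <- max(0L, round(rlnorm(1L, cfg$rare_germline_meanlog,
                                 cfg$rare_germline_sdlog)))
  rare_ids <- sort(sample.int(cfg$rare_pool_size, n_rare))
  pv <- pool_variant(rare_ids, cfg$n_chrom, cfg$chrom_length, "r")
  cn <- cn_at(seg, pv$chrom, pv$pos)
  het <- runif(n_rare) < cfg$het_fraction_rare
  # het: mutant allele on the amplified homolog or not; C=1 may lose it
  m_het <- ifelse(cn >= 2L, ifelse(runif(n_rare) < 0.5, 1L, cn - 1L),
                  ifelse(runif(n_rare) < 0.5, 0L, 1L))
  m <- ifelse(het, m_het, cn)
  g_norm <- ifelse(het, 1L, 2L)
  vaf <- vaf_general(purity, cn, m, g_norm)
  # ontology, substitution class and alleles are deterministic functions of
  # the pool id so two carriers of the same variant emit identical alleles
  ont <- if (n_rare) det_cat(rare_ids, 1, cfg$ontology_germline) else character()
  is_sbs <- !(ont %in% c("frameshift_indel", "inframe_indel"))
  cls <- if (n_rare) det_cat(rare_ids, 2, cfg$spectrum_germline) else character()
  al <- snv_alleles(cls, pv$f5, pv$f3, (rare_ids %% 2) == 1)
  ref <- al$ref; alt <- al$alt; tri <- al$tri
  if (any(!is_sbs)) {
    ia <- det_indel_alleles(rare_ids[!is_sbs], ont[!is_sbs], pv$ref[!is_sbs])
    ref[!is_sbs] <- ia$ref; alt[!is_sbs] <- ia$alt
    tri[!is_sbs] <- "NON_SBS"
  }
  rd <- read_sample_vaf(n_rare, vaf, cfg$mean_depth)
  represented <- runif(n_rare) < r_db
  low_db <- !represented & runif(n_rare) < cfg$rare_db_low_prob
  db <- db_table(n_rare,
                 c(which(represented), which(low_db)),
                 c(runif(sum(represented), 0.01, 0.10),
                   runif(sum(low_db), 1e-5, 0.009)))
  rare <- data.table(chrom = pv$chrom, pos = pv$pos, ref = ref, alt = alt,
                     t_alt = rd$alt, depth = rd$depth, ontology = ont,
                     tri_context = tri,
                     cosmic_count = rcosmic(n_rare, cfg$cosmic_nonzero_germline,
                                            cfg$cosmic_geom_germline),
                     truth_label = 0L)
  rare <- cbind(rare, db)
  rare_keys <- paste(pv$chrom, pv$pos, ref, alt, sep = ":")

  ## --- common SNPs (informative-SNP candidates) -----------------------
  p_carrier <- common_af * (2 - common_af)          # Hardy-Weinberg carrier
  carrier <- runif(length(common_ids)) < p_carrier
  cids <- common_ids[carrier]
  caf <- common_af[carrier]
  n_com <- length(cids)
  pvc <- pool_variant(cids, cfg$n_chrom, cfg$chrom_length, "c")
  hom <- runif(n_com) < caf / (2 - caf)             # hom given carrier
  cnc <- cn_at(seg, pvc$chrom, pvc$pos)
  m_c <- ifelse(hom, cnc,
                ifelse(cnc >= 2L, ifelse(runif(n_com) < 0.5, 1L, cnc - 1L),
                       ifelse(runif(n_com) < 0.5, 0L, 1L)))
  vafc <- vaf_general(purity, cnc, m_c, ifelse(hom, 2L, 1L))
  rdc <- read_sample_vaf(n_com, vafc, cfg$mean_depth)
  dbc <- db_table(n_com, seq_len(n_com), caf)
  com <- data.table(chrom = pvc$chrom, pos = pvc$pos, ref = pvc$ref,
                    alt = pvc$alt, t_alt = rdc$alt, depth = rdc$depth,
                    ontology = "other",
                    tri_context = paste0(pvc$f5, pvc$ref, pvc$f3),
                    cosmic_count = 0L, truth_label = 0L)
  com <- cbind(com, dbc)
  common_keys <- paste(pvc$chrom, pvc$pos, pvc$ref, pvc$alt, sep = ":")

  ## --- recurrent technical artifacts ----------------------------------
  art_ids <- which(runif(cfg$artifact_pool_size) < cfg$artifact_rate)
  n_art <- length(art_ids)
  pva <- pool_variant(art_ids + 7L * cfg$rare_pool_size, cfg$n_chrom,
                      cfg$chrom_length, "a")
  vafa <- stats::rbeta(n_art, 2, 18)
  rda <- read_sample_vaf(n_art, vafa, cfg$mean_depth)
  art <- data.table(chrom = pva$chrom, pos = pva$pos, ref = pva$ref,
                    alt = pva$alt, t_alt = rda$alt, depth = rda$depth,
                    ontology = "missense",
                    tri_context = paste0(pva$f5, pva$ref, pva$f3),
                    cosmic_count = 0L, truth_label = 0L)
  art <- cbind(art, db_table(n_art))
  art_keys <- paste(pva$chrom, pva$pos, pva$ref, pva$alt, sep = ":")
  # the same artifacts recur in normal samples
  art_in_normal <- art_keys[runif(n_art) < cfg$artifact_rate]

  ## --- assemble, apply the caller floor, label ------------------------
  all_v <- rbindlist(list(som, rare, com, art), use.names = TRUE)
  fpfail <- runif(nrow(all_v)) < cfg$fpfilter_fail_rate
  art_rows <- rep(FALSE, nrow(all_v))
  art_rows[seq.int(nrow(all_v) - n_art + 1L, length.out = n_art)] <- TRUE
  fpfail[art_rows] <- runif(n_art) < 0.6
  all_v[, `:=`(sample_id = sid,
               t_alt_freq = t_alt / depth,
               t_maj_allele = pmax(t_alt, depth - t_alt) / depth,
               caller_filter = "PASS",
               fpfilter = ifelse(fpfail, "FAIL", "PASS"))]
  emitted <- all_v[t_alt >= cfg$min_alt_reads]
  emitted[, t_alt := NULL]
  variants <- variant_table(emitted, db_fields = db_fields)

  # realized coding-somatic burden (what the matched-normal pipeline would
  # keep): somatic, coding ontology, passing filters
  coding <- variants$truth_label == 1L &
    variants$ontology %in% c("missense", "nonsense", "frameshift_indel",
                             "inframe_indel") &
    variants$fpfilter == "PASS"
  true_tmb <- sum(coding) / cfg$footprint_mb

  list(sample_id = sid, group = group, subtype = subtype, purity = purity,
       target_tmb = target_tmb, true_tmb = true_tmb,
       variants = variants,
       segments = seg[, .(sample_id, chrom, start, end, log2, n_bins)],
       normal_keys = unique(c(rare_keys, common_keys, art_in_normal)))
}

#' Median VAF of the true somatic mutations (MVTSM)
#'
#' Computed over the truth-somatic variants that survive the
#' pre-classification filter; approximately purity / 2 in a diploid clonal
#' tumor.
#'
#' @param sample one cohort sample (element of `sv_cohort$samples`).
#' @param cfg filter configuration.
#' @return median VAF, or `NA` when the sample has no somatic variants.
#' @export
mvtsm <- function(sample, cfg = filter_config()) {
  kept <- apply_prefilter(sample$variants, cfg)$kept
  v <- kept[!is.na(kept$truth_label) & kept$truth_label == 1L]
  if (!nrow(v)) return(NA_real_)
  median(v$t_alt_freq)
}

#' Write a cohort to disk in pipeline formats
#'
#' One annotated VCF per sample, a combined segments TSV, a truth/summary
#' TSV, and the per-patient normal call sets as JSON.
#'
#' @param cohort `sv_cohort`.
#' @param dir output directory (created).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sv_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seg_all <- rbindlist(lapply(cohort$samples, `[[`, "segments"))
  fwrite_tsv <- function(dt, path) utils::write.table(
    dt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  fwrite_tsv(seg_all, file.path(dir, "segments.seg"))
  summ <- cohort_truth(cohort)
  fwrite_tsv(summ, file.path(dir, "truth.tsv"))
  normals <- lapply(cohort$samples, `[[`, "normal_keys")
  names(normals) <- vapply(cohort$samples, `[[`, character(1), "sample_id")
  jsonlite::write_json(normals, file.path(dir, "normals.json"))
  for (s in cohort$samples)
    write_annotated_vcf(s$variants, file.path(dir, paste0(s$sample_id, ".vcf")))
  invisible(dir)
}

#' Per-sample truth summary of a cohort
#'
#' @param cohort `sv_cohort`.
#' @return `data.table`: sample_id, group, subtype, purity, target_tmb,
#'   true_tmb, mvtsm.
#' @export
cohort_truth <- function(cohort) {
  rbindlist(lapply(cohort$samples, function(s)
    data.table(sample_id = s$sample_id, group = s$group, subtype = s$subtype,
               purity = s$purity, target_tmb = s$target_tmb,
               true_tmb = s$true_tmb, mvtsm = mvtsm(s))))
}
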