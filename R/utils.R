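# Internal helpers shared across modules.

#' @useDynLib somaticsieve, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods is
NULL

#' @importFrom data.table data.table as.data.table := setorder rbindlist fread setnames copy set tstrsplit dcast
#' @importFrom stats rbinom rpois rlnorm runif rgeom median quantile lm coef var wilcox.test fisher.test setNames complete.cases
#' @importFrom utils head tail
NULL

# FNV-1a 32-bit hash of a character scalar; used for feature-schema hashes so
# the package has no dependency on an external digest library.
fnv1a <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    # xor the low 16 bits (bytes are < 256; the state is kept as a double
    # because R integers are 32-bit signed)
    lo <- bitwXor(as.integer(h %% 65536), as.integer(b))
    h <- (h %/% 65536) * 65536 + lo
    # 32-bit modular multiply by the FNV prime 16777619
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# variant identity key used everywhere: chrom:pos:ref:alt after allele trimming
variant_key <- function(chrom, pos, ref, alt) {
  tr <- trim_alleles(pos, ref, alt)
  paste(chrom, tr$pos, tr$ref, tr$alt, sep = ":")
}

# Trim shared allele suffix then shared prefix (bcftools-norm style parsimony;
# position advances with the trimmed prefix). Vectorized.
trim_alleles <- function(pos, ref, alt) {
  pos <- as.integer(pos)
  needs <- nchar(ref) > 1L & nchar(alt) > 1L
  if (any(needs)) {
    for (i in which(needs)) {
      r <- strsplit(ref[i], "", fixed = TRUE)[[1]]
      a <- strsplit(alt[i], "", fixed = TRUE)[[1]]
      # suffix
      while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
        r <- r[-length(r)]; a <- a[-length(a)]
      }
      # prefix
      while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
        r <- r[-1L]; a <- a[-1L]; pos[i] <- pos[i] + 1L
      }
      ref[i] <- paste(r, collapse = ""); alt[i] <- paste(a, collapse = "")
    }
  }
  list(pos = pos, ref = ref, alt = alt)
}

# classify an allele pair
classify_allele <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  out <- character(length(ref))
  out[nr == 1L & na == 1L] <- "SNV"
  out[na > nr] <- "insertion"
  out[na < nr] <- "deletion"
  out[nr == na & nr > 1L] <- "MNV"
  out
}

# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a reproducible child seed (kept below 2^31)
child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE), function(ch) {
    paste(rev(unname(DNA_COMP[ch])), collapse = "")
  }, character(1))
}
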