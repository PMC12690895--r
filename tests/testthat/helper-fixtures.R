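# Small in-code fixtures shared across test files.

# A tiny aligned dataset with named components, built deterministically.
make_tiny_dataset <- function(n = 60, n_probes = 12, n_snps = 6,
                              n_expo = 4, n_cov = 2, seed = 42) {
  set.seed(seed)
  ids <- sprintf("s%02d", seq_len(n))
  m <- matrix(rnorm(n * n_probes), n, n_probes,
              dimnames = list(ids, sprintf("cg%02d", seq_len(n_probes))))
  g <- matrix(rbinom(n * n_snps, 2, 0.3), n, n_snps,
              dimnames = list(ids, sprintf("rs%02d", seq_len(n_snps))))
  e <- matrix(rnorm(n * n_expo), n, n_expo,
              dimnames = list(ids, sprintf("EE_%d", seq_len(n_expo))))
  cv <- matrix(rnorm(n * n_cov), n, n_cov,
               dimnames = list(ids, sprintf("cov%d", seq_len(n_cov))))
  pm <- data.frame(probe_id = colnames(m), chrom = "chr1",
                   pos = seq(1000L, by = 5000L, length.out = n_probes),
                   stringsAsFactors = FALSE)
  sm <- data.frame(snp_id = colnames(g), chrom = "chr1",
                   pos = seq(2000L, by = 7000L, length.out = n_snps),
                   stringsAsFactors = FALSE)
  align_dataset(m, g, e, cv, pm, sm)
}

# Probe manifest helper for VML tests.
manifest_of <- function(ids, chrom, pos) {
  data.frame(probe_id = ids, chrom = chrom, pos = as.integer(pos),
             stringsAsFactors = FALSE)
}

# Methylation columns with a prescribed pairwise correlation via a shared
# latent factor.
correlated_probes <- function(n, ids, r, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  m <- vapply(ids, function(id) {
    sqrt(r) * z + sqrt(1 - r) * rnorm(n)
  }, numeric(n))
  rownames(m) <- sprintf("s%03d", seq_len(n))
  m
}
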