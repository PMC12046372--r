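# Shared helpers: small in-code datasets and independent oracles.

# HaplotypeSet from a plain 0/1 haplotype matrix (2 rows per sample)
toy_hapset <- function(hm, positions = NULL, chrom = "chr1",
                       sample_ids = NULL, ancestral = "ref") {
  hm <- as.matrix(hm)
  n <- nrow(hm) / 2L
  if (is.null(positions)) positions <- seq_len(ncol(hm)) * 1000L
  if (is.null(sample_ids)) sample_ids <- sprintf("s%02d", seq_len(n))
  haplotype_set(chrom, positions, rep("A", ncol(hm)), rep("T", ncol(hm)),
                hm, sample_ids, ancestral)
}

# random complete haplotype matrix (rows = haplotypes)
random_hapmat <- function(n_hap, m, p = 0.5) {
  matrix(rbinom(n_hap * m, 1L, p), nrow = n_hap)
}

# Independent EHH oracle: direct pairwise-identity counting at every
# marker between the core and m (inclusive), over rows `rows` of `hm`.
oracle_ehh <- function(hm, rows, core, marker) {
  span <- if (marker >= core) core:marker else marker:core
  sub <- hm[rows, span, drop = FALSE]
  n <- length(rows)
  same <- 0L
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      if (all(sub[i, ] == sub[j, ])) same <- same + 1L
  same / (n * (n - 1L) / 2L)
}

# per-base support-count oracle for interval set operations
oracle_support <- function(regionsets, axis_max) {
  cov <- integer(axis_max)
  for (d in regionsets)
    for (i in seq_len(nrow(d))) {
      ix <- d$start[i]:min(d$end[i], axis_max)
      cov[ix] <- cov[ix] + 1L
    }
  cov
}

# small neutral simulation used by several tests (cheap: ~2 s)
small_neutral_sim <- function(seed, migration = 0.5) {
  simulate_wf(sim_config(deme_size = 50, sample_size = 15,
                         chrom_length = 1e5, generations = 250,
                         migration = migration, seed = seed))
}
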