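# Variant quality control: MAF / call-rate filtering and PLINK-style
# greedy windowed LD pruning.

#' QC configuration
#'
#' Thresholds are exclusive on the keep side: a variant is kept iff
#' `MAF > maf_min` and `call rate > callrate_min` (variants at exactly the
#' threshold are excluded). LD pruning removes, within each sliding window
#' of `ld_window_snps` variants (slid by `ld_step_snps`), the later member
#' of any kept pair whose squared dosage correlation exceeds `ld_r2_max`.
#'
#' @param maf_min Minor-allele-frequency threshold (default 0.05).
#' @param callrate_min Required fraction of non-missing genotypes
#'   (default 0.95).
#' @param ld_r2_max r-squared pruning threshold (default 0.1).
#' @param ld_window_snps Pairwise-comparison window size in SNPs (50).
#' @param ld_step_snps Window slide in SNPs (5).
#' @return A `QcConfig` list.
#' @export
qc_config <- function(maf_min = 0.05, callrate_min = 0.95, ld_r2_max = 0.1,
                      ld_window_snps = 50L, ld_step_snps = 5L) {
  stopifnot(maf_min >= 0, maf_min < 0.5,
            callrate_min > 0, callrate_min <= 1,
            ld_r2_max > 0, ld_r2_max <= 1,
            ld_window_snps >= 2L, ld_step_snps >= 1L)
  structure(list(maf_min = maf_min, callrate_min = callrate_min,
                 ld_r2_max = ld_r2_max,
                 ld_window_snps = as.integer(ld_window_snps),
                 ld_step_snps = as.integer(ld_step_snps)),
            class = "QcConfig")
}

#' Filter variants on minor allele frequency and call rate
#'
#' MAF is computed on non-missing alleles. A variant failing both rules is
#' counted once, under MAF, and reported as dual-failing.
#'
#' @param h A `HaplotypeSet`.
#' @param cfg A [qc_config()].
#' @return List with elements `haplotypes` (filtered `HaplotypeSet`) and
#'   `report` (a `FilterReport`: input/kept counts and per-criterion
#'   removal counts).
#' @export
filter_variants <- function(h, cfg = qc_config()) {
  stopifnot(inherits(h, "HaplotypeSet"), n_variants(h) > 0L)
  af <- alt_frequency(h)
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0          # fully missing variant: no observed MAF
  callrate <- 1 - colMeans(h$missing)
  fail_maf <- maf <= cfg$maf_min
  fail_cr <- callrate <= cfg$callrate_min
  keep <- !fail_maf & !fail_cr
  if (!any(keep)) warning("all variants removed by QC filters")
  report <- structure(list(
    n_input = n_variants(h), n_kept = sum(keep),
    removed_maf = sum(fail_maf),
    removed_callrate = sum(fail_cr & !fail_maf),
    removed_dual = sum(fail_maf & fail_cr),
    maf_min = cfg$maf_min, callrate_min = cfg$callrate_min),
    class = "FilterReport")
  list(haplotypes = subset_haplotypes(h, variants = which(keep)),
       report = report)
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf(paste0("FilterReport: %d -> %d variants ",
                     "(MAF<=%.3g: %d, call rate<=%.3g: %d, dual: %d)\n"),
              x$n_input, x$n_kept, x$maf_min, x$removed_maf,
              x$callrate_min, x$removed_callrate, x$removed_dual))
  invisible(x)
}

#' Greedy windowed LD pruning
#'
#' PLINK-style pruning on diploid dosages: windows of `ld_window_snps`
#' variants are slid by `ld_step_snps`; within each window, every ordered
#' pair (i < j) of still-kept variants is tested and `j` is removed when
#' the squared Pearson correlation of 0/1/2 dosages (over samples
#' non-missing at both) exceeds `ld_r2_max`. Monomorphic variants give
#' r-squared 0 (never pruned by correlation). Deterministic for fixed
#' input.
#'
#' @param h A `HaplotypeSet` (variants sorted by position, as enforced by
#'   the container).
#' @param cfg A [qc_config()].
#' @return List with `kept` (integer indices of retained variants) and
#'   `removed` (count pruned).
#' @export
ld_prune <- function(h, cfg = qc_config()) {
  stopifnot(inherits(h, "HaplotypeSet"))
  m <- n_variants(h)
  if (m < 2L) return(list(kept = seq_len(m), removed = 0L))
  d <- dosage_matrix(h)
  keep <- rep(TRUE, m)
  starts <- unique(c(seq(1L, max(1L, m - 1L), by = cfg$ld_step_snps)))
  for (s in starts) {
    win <- s:min(m, s + cfg$ld_window_snps - 1L)
    if (length(win) < 2L) next
    idx <- win[keep[win]]
    if (length(idx) < 2L) next
    cc <- suppressWarnings(
      stats::cor(d[, idx, drop = FALSE], use = "pairwise.complete.obs"))
    cc[is.na(cc)] <- 0           # monomorphic or no overlap: r2 := 0
    r2 <- cc^2
    for (a in seq_len(length(idx) - 1L)) {
      if (!keep[idx[a]]) next
      for (b in (a + 1L):length(idx)) {
        if (keep[idx[b]] && r2[a, b] > cfg$ld_r2_max)
          keep[idx[b]] <- FALSE
      }
    }
  }
  list(kept = which(keep), removed = sum(!keep))
}
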