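# Windowed pooled heterozygosity Hp.

#' Windowed pooled heterozygosity (Hp)
#'
#' Per scored window, with `S_maj` and `S_min` the sums over the window's
#' SNPs of the major- and minor-allele counts observed in the population,
#'
#'   Hp = 2 * S_maj * S_min / (S_maj + S_min)^2 .
#'
#' Allele counts come from called genotypes (non-missing alleles only);
#' major/minor are determined per SNP within the population, ties broken
#' toward REF (Hp is symmetric in the two counts, so the tie-break cannot
#' change the value). Windows whose SNPs are all fully missing in the
#' population are undefined (`NA`).
#'
#' @param h A `HaplotypeSet`.
#' @param samples Sample ids of the population.
#' @param grid A `WindowGrid` with SNPs assigned ([assign_snps()]).
#' @return A `ScoreTrack` of statistic `"Hp"` (values in `[0, 0.5]`).
#' @export
window_hp <- function(h, samples, grid) {
  stopifnot(inherits(h, "HaplotypeSet"), inherits(grid, "WindowGrid"),
            length(samples) > 0L, !is.null(grid$snp_index))
  rows <- hap_rows(h, samples)
  hm <- h$haplotypes[rows, , drop = FALSE]
  n_alt <- colSums(hm, na.rm = TRUE)
  n_tot <- colSums(!is.na(hm))
  n_ref <- n_tot - n_alt
  n_maj <- pmax(n_ref, n_alt)      # ties -> REF count, value unaffected
  n_min <- pmin(n_ref, n_alt)
  vals <- rep(NA_real_, n_windows(grid))
  for (w in which(grid$scored)) {
    idx <- grid$snp_index[[w]]
    smaj <- sum(n_maj[idx]); smin <- sum(n_min[idx])
    tot <- smaj + smin
    if (tot == 0) next               # all member SNPs fully missing
    vals[w] <- 2 * smaj * smin / tot^2
  }
  score_track("Hp", samples_context(h, samples), grid, vals)
}

# label a context by population when the sample list equals a known set;
# callers pass the population name via names(samples) when available.
samples_context <- function(h, samples) {
  ctx <- attr(samples, "population")
  if (!is.null(ctx)) ctx else paste0(length(samples), "samples")
}

#' Attach a population label to a sample vector
#'
#' Convenience so tracks computed from raw sample vectors carry a readable
#' context label.
#'
#' @param samples Character vector of sample ids.
#' @param population Label to attach.
#' @return `samples` with a `population` attribute.
#' @export
labelled_samples <- function(samples, population) {
  attr(samples, "population") <- population
  samples
}
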