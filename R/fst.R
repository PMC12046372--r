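# Weir-Cockerham (1984) FST variance components, per SNP and windowed,
# plus observed heterozygosity.

#' Per-SNP Weir-Cockerham FST variance components for two populations
#'
#' For r = 2 populations with locus-specific non-missing sample sizes
#' n_i, ALT allele frequencies p_i and observed heterozygote proportions
#' h_i:
#' \deqn{\bar n = \sum n_i / r, \quad
#'       n_c = (r \bar n - \sum n_i^2 / (r \bar n)) / (r - 1)}
#' \deqn{\bar p = \sum n_i p_i / (r \bar n), \quad
#'       s^2 = \sum n_i (p_i - \bar p)^2 / ((r - 1) \bar n), \quad
#'       \bar h = \sum n_i h_i / (r \bar n)}
#' \deqn{a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}
#'       \left(\bar p(1-\bar p) - \frac{r-1}{r}s^2 -
#'       \frac{\bar h}{4}\right)\right]}
#' \deqn{b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) -
#'       \frac{r-1}{r}s^2 - \frac{2\bar n - 1}{4\bar n}\bar h\right],
#'       \quad c = \bar h / 2}
#' and the per-SNP estimator is theta = a / (a + b + c), undefined (`NA`,
#' not zero) where the denominator is zero (e.g. a globally monomorphic
#' site).
#'
#' @param h A `HaplotypeSet`.
#' @param samplesA,samplesB Sample ids of the two populations.
#' @return An `FstComponents` data frame with one row per variant:
#'   `a`, `b`, `c`, `theta`.
#' @export
wc_fst_components <- function(h, samplesA, samplesB) {
  stopifnot(inherits(h, "HaplotypeSet"))
  comp_pop <- function(samples) {
    i <- match(samples, h$sample_ids)
    if (anyNA(i)) stop("unknown sample(s)")
    h1 <- h$haplotypes[2L * i - 1L, , drop = FALSE]
    h2 <- h$haplotypes[2L * i, , drop = FALSE]
    n <- colSums(!is.na(h1))                       # non-missing diploids
    p <- (colSums(h1, na.rm = TRUE) + colSums(h2, na.rm = TRUE)) / (2 * n)
    het <- colSums(h1 != h2, na.rm = TRUE) / n
    list(n = n, p = p, h = het)
  }
  A <- comp_pop(samplesA)
  B <- comp_pop(samplesB)
  r <- 2
  nbar <- (A$n + B$n) / r
  valid <- A$n >= 1 & B$n >= 1 & nbar > 1
  nc <- (r * nbar - (A$n^2 + B$n^2) / (r * nbar)) / (r - 1)
  pbar <- (A$n * A$p + B$n * B$p) / (r * nbar)
  s2 <- (A$n * (A$p - pbar)^2 + B$n * (B$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (A$n * A$h + B$n * B$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a[!valid] <- NA_real_; b[!valid] <- NA_real_; cc[!valid] <- NA_real_
  denom <- a + b + cc
  theta <- ifelse(!is.na(denom) & denom != 0, a / denom, NA_real_)
  n_invalid <- sum(!valid)
  if (n_invalid)
    message(n_invalid, " variant(s) lack genotyped diploids in a ",
            "population; components undefined")
  structure(data.frame(a = a, b = b, c = cc, theta = theta),
            class = c("FstComponents", "data.frame"))
}

#' Weir-Cockerham theta at a single variant
#'
#' Convenience wrapper around [wc_fst_components()].
#'
#' @inheritParams wc_fst_components
#' @param variant Variant index.
#' @return One-row `FstComponents` data frame.
#' @export
wc_fst_snp <- function(h, samplesA, samplesB, variant) {
  wc_fst_components(subset_haplotypes(h, variants = variant),
                    samplesA, samplesB)
}

#' Windowed weighted Weir-Cockerham FST
#'
#' Per scored window the weighted (ratio-of-sums) estimator
#' `sum(a) / sum(a + b + c)` over member SNPs with defined components.
#' Negative window values are retained (clamping would bias the
#' downstream Z-standardization); windows with fewer than `min_snps`
#' defined SNPs, or a non-positive denominator, are undefined.
#'
#' @param components `FstComponents` from [wc_fst_components()] (one row
#'   per variant of the grid's HaplotypeSet).
#' @param grid A `WindowGrid` with SNPs assigned.
#' @param context Label for the population pair, e.g. `c("hot", "cold")`.
#' @return A `ScoreTrack` of statistic `"FST"`.
#' @export
windowed_fst <- function(components, grid, context = "A~B") {
  stopifnot(inherits(components, "FstComponents"),
            inherits(grid, "WindowGrid"), !is.null(grid$snp_index))
  defined <- !is.na(components$a)
  vals <- rep(NA_real_, n_windows(grid))
  cnt <- integer(n_windows(grid))
  for (w in seq_len(n_windows(grid))) {
    idx <- grid$snp_index[[w]]
    idx <- idx[defined[idx]]
    cnt[w] <- length(idx)
    if (length(idx) < grid$min_snps) next
    num <- sum(components$a[idx])
    den <- sum(components$a[idx] + components$b[idx] + components$c[idx])
    if (den <= 0) next
    vals[w] <- num / den
  }
  score_track("FST", context, grid, vals, n_snps = cnt)
}

#' Observed heterozygosity per sample and population
#'
#' Fraction of non-missing genotypes that are heterozygous, per sample;
#' the population value is the mean over samples.
#'
#' @param h A `HaplotypeSet`.
#' @param samples Sample ids of the population (default all).
#' @return List with `per_sample` (named numeric) and `population`
#'   (scalar mean).
#' @export
observed_heterozygosity <- function(h, samples = h$sample_ids) {
  stopifnot(inherits(h, "HaplotypeSet"), n_variants(h) >= 1L)
  i <- match(samples, h$sample_ids)
  if (anyNA(i)) stop("unknown sample(s)")
  h1 <- h$haplotypes[2L * i - 1L, , drop = FALSE]
  h2 <- h$haplotypes[2L * i, , drop = FALSE]
  het <- rowSums(h1 != h2, na.rm = TRUE) / rowSums(!is.na(h1))
  names(het) <- samples
  list(per_sample = het, population = mean(het))
}
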