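# Per-SNP haplotype scans: iHS (within population) and XP-EHH (between
# populations), plus windowed means of the standardized scores.

resolve_ancestral <- function(h, samples, policy) {
  switch(policy,
         flag = h$ancestral,
         ref = rep("ref", n_variants(h)),
         major = {
           f <- alt_frequency(h, samples)
           ifelse(f > 0.5, "alt", "ref")   # ancestral = major; ties -> ref
         },
         stop("unknown ancestral policy: ", policy))
}

#' iHS scan over one population
#'
#' For each qualifying core SNP (MAF above `maf_min`, at least two
#' carriers of each allele, neither direction truncated at the chromosome
#' end), the raw score is `ln(iHH_A / iHH_D)` with A the ancestral- and D
#' the derived-allele carriers. Raw scores are standardized within
#' derived-allele-frequency bins (`bins` equal-width bins over (0, 1)):
#' `z = (raw - bin mean) / bin sd` (population sd). Bins with fewer than
#' two scores (or zero spread) leave their SNPs unstandardized with
#' status `"skipped_bin"` and a warning.
#'
#' Requires complete genotypes; run [drop_missing_variants()] first.
#'
#' @param h A `HaplotypeSet`.
#' @param samples Sample ids of the population.
#' @param map Optional `GeneticMap` (default constant 1 cM/Mb).
#' @param maf_min Core-SNP minor-allele-frequency cutoff (default 0.05,
#'   exclusive).
#' @param cutoff EHH decay cutoff (default 0.05).
#' @param bins Number of equal-width frequency bins (default 50).
#' @param ancestral `"flag"` (use the per-variant ancestral flag, the
#'   default), `"ref"` (force REF ancestral) or `"major"` (population
#'   major allele as ancestral). This choice flips iHS signs; see the
#'   methods vignette.
#' @param keep_truncated Keep scores whose EHH never decayed below the
#'   cutoff before the chromosome end.
#' @return A `SnpScores` data frame: `variant`, `position`, `freq`
#'   (derived-allele frequency), `raw`, `z`, `status` in
#'   `c("ok", "skipped_maf", "skipped_truncated", "skipped_bin")`.
#' @export
ihs_scan <- function(h, samples = h$sample_ids, map = NULL, maf_min = 0.05,
                     cutoff = 0.05, bins = 50L, ancestral = "flag",
                     keep_truncated = FALSE) {
  stopifnot(inherits(h, "HaplotypeSet"))
  rows <- hap_rows(h, samples)
  hm <- h$haplotypes
  if (anyNA(hm[rows, ]))
    stop("iHS requires complete genotypes; run drop_missing_variants() first")
  anc <- resolve_ancestral(h, samples, ancestral)
  if (any(anc == "unknown"))
    stop("ancestral allele unknown at ", sum(anc == "unknown"),
         " variant(s); choose ancestral = \"ref\" or \"major\"")
  cm <- interpolate_cm(map, h$chrom, h$positions)
  m <- n_variants(h)
  derived_code <- ifelse(anc == "ref", 1L, 0L)
  hp <- hm[rows, , drop = FALSE]
  parts <- span_partitions(hp)
  freq_d <- vapply(seq_len(m), function(j)
    mean(hp[, j] == derived_code[j]), numeric(1))
  maf <- pmin(freq_d, 1 - freq_d)

  raw <- rep(NA_real_, m)
  status <- rep("skipped_maf", m)
  for (j in which(maf > maf_min)) {
    carD <- which(hp[, j] == derived_code[j])
    carA <- which(hp[, j] == 1L - derived_code[j])
    if (length(carD) < 2L || length(carA) < 2L) next
    if (keep_truncated) {
      vA <- ihh_rows_value(hp, carA, j, cm, cutoff)
      vD <- ihh_rows_value(hp, carD, j, cm, cutoff)
    } else {
      iA <- ihh_rows(hp, carA, j, cm, cutoff, parts)
      if (iA$status != "ok") { status[j] <- "skipped_truncated"; next }
      iD <- ihh_rows(hp, carD, j, cm, cutoff, parts)
      if (iD$status != "ok") { status[j] <- "skipped_truncated"; next }
      vA <- iA$value; vD <- iD$value
    }
    if (!is.finite(log(vA / vD))) { status[j] <- "skipped_truncated"; next }
    raw[j] <- log(vA / vD)
    status[j] <- "ok"
  }

  z <- rep(NA_real_, m)
  ok <- status == "ok"
  if (any(ok)) {
    bin <- pmin(as.integer(bins), pmax(1L, ceiling(freq_d * bins)))
    for (b in unique(bin[ok])) {
      in_bin <- ok & bin == b
      x <- raw[in_bin]
      mu <- mean(x)
      sdp <- sqrt(mean((x - mu)^2))
      if (length(x) < 2L || sdp == 0) {
        status[in_bin] <- "skipped_bin"
        warning("frequency bin ", b, " has <2 usable scores; ",
                sum(in_bin), " SNP(s) left unstandardized")
      } else {
        z[in_bin] <- (x - mu) / sdp
      }
    }
  } else {
    warning("iHS scan produced no usable scores")
  }
  snp_scores("iHS", samples_context(h, samples),
             data.frame(variant = seq_len(m), position = h$positions,
                        freq = freq_d, raw = raw, z = z, status = status,
                        stringsAsFactors = FALSE))
}

# integral including truncated curves (used when keep_truncated = TRUE)
ihh_rows_value <- function(hm, rows, core, cm, cutoff) {
  tot <- 0
  for (dir in c("left", "right")) {
    w <- ehh_walk(hm, rows, core, dir, cm, cutoff)
    tot <- tot + trapezoid_to_cutoff(w$dist, w$ehh, cutoff)
  }
  tot
}

snp_scores <- function(statistic, context, df) {
  structure(df, statistic = statistic, context = context,
            class = c("SnpScores", "data.frame"))
}

#' XP-EHH scan between two populations
#'
#' Per SNP, iHH is computed over all haplotypes of each population (not
#' split by allele) with a shared stopping rule: in each direction the
#' walk continues until both populations' EHH fall below `cutoff` (that
#' marker included) and both are integrated to that common boundary. The
#' raw score is `ln(iHH_A / iHH_B)`; positive values point to longer
#' haplotype homozygosity (a harder sweep) in population A.
#' Standardization is genome-wide: a single mean/sd (population sd) over
#' all scored SNPs.
#'
#' @param hA,hB `HaplotypeSet` views of the two populations on an
#'   identical variant grid (same chromosome and positions), e.g. from
#'   [subset_haplotypes()].
#' @param map Optional `GeneticMap` (default constant 1 cM/Mb).
#' @param cutoff EHH decay cutoff (default 0.05).
#' @param keep_truncated Keep scores where the shared decay never
#'   completed before the chromosome end.
#' @return A `SnpScores` data frame (`freq` is the pooled ALT frequency).
#' @export
xpehh_scan <- function(hA, hB, map = NULL, cutoff = 0.05,
                       keep_truncated = FALSE) {
  stopifnot(inherits(hA, "HaplotypeSet"), inherits(hB, "HaplotypeSet"))
  if (!identical(hA$positions, hB$positions) ||
      !identical(hA$chrom, hB$chrom))
    stop("the two populations must share an identical variant grid")
  if (nrow(hA$haplotypes) < 2L || nrow(hB$haplotypes) < 2L)
    stop("each population needs >= 2 haplotypes")
  if (anyNA(hA$haplotypes) || anyNA(hB$haplotypes))
    stop("XP-EHH requires complete genotypes; run drop_missing_variants()")
  cm <- interpolate_cm(map, hA$chrom, hA$positions)
  m <- n_variants(hA)
  mA <- hA$haplotypes; mB <- hB$haplotypes
  nA <- nrow(mA); nB <- nrow(mB)
  freq <- (colSums(mA) + colSums(mB)) / (nA + nB)

  raw <- rep(NA_real_, m)
  status <- rep("ok", m)
  partsA <- span_partitions(mA)
  partsB <- span_partitions(mB)
  rowsA <- seq_len(nA); rowsB <- seq_len(nB)
  for (j in seq_len(m)) {
    # shared stopping rule truncates iff either population's limiting
    # EHH stays at/above the cutoff out to the chromosome end
    if (!keep_truncated) {
      trunc <- FALSE
      for (dir in c("left", "right"))
        if (limit_ehh(partsA, rowsA, j, dir) >= cutoff ||
            limit_ehh(partsB, rowsB, j, dir) >= cutoff) {
          trunc <- TRUE
          break
        }
      if (trunc) { status[j] <- "skipped_truncated"; next }
    }
    iA <- 0; iB <- 0
    for (dir in c(-1L, 1L)) {
      markers <- if (dir == 1L) {
        if (j < m) (j + 1L):m else integer(0)
      } else {
        if (j > 1L) (j - 1L):1L else integer(0)
      }
      gA <- mA[, j] + 1L
      gB <- mB[, j] + 1L
      n_mk <- length(markers)
      dist <- numeric(n_mk + 1L); eA <- numeric(n_mk + 1L)
      eB <- numeric(n_mk + 1L)
      dist[1L] <- 0; eA[1L] <- 1; eB[1L] <- 1
      used <- 1L
      for (k in seq_len(n_mk)) {
        mk <- markers[k]
        kA <- gA * 2L + mA[, mk]; gA <- match(kA, unique(kA))
        kB <- gB * 2L + mB[, mk]; gB <- match(kB, unique(kB))
        used <- k + 1L
        dist[used] <- abs(cm[mk] - cm[j])
        eA[used] <- group_ehh(gA)
        eB[used] <- group_ehh(gB)
        if (eA[used] < cutoff && eB[used] < cutoff) break
      }
      keep <- seq_len(used)
      iA <- iA + trapezoid_segments(dist[keep], eA[keep])
      iB <- iB + trapezoid_segments(dist[keep], eB[keep])
    }
    if (iA <= 0 || iB <= 0) { status[j] <- "skipped_truncated"; next }
    raw[j] <- log(iA / iB)
  }

  z <- rep(NA_real_, m)
  ok <- status == "ok"
  if (sum(ok) >= 2L) {
    mu <- mean(raw[ok])
    sdp <- sqrt(mean((raw[ok] - mu)^2))
    if (sdp > 0) z[ok] <- (raw[ok] - mu) / sdp
    else { status[ok] <- "skipped_bin"; warning("XP-EHH scores have zero spread") }
  } else {
    warning("XP-EHH scan produced <2 usable scores; nothing standardized")
    status[ok] <- "skipped_bin"
  }
  ctxA <- samples_context(hA, hA$sample_ids)
  ctxB <- samples_context(hB, hB$sample_ids)
  snp_scores("XPEHH", paste(ctxA, ctxB, sep = "~"),
             data.frame(variant = seq_len(m), position = hA$positions,
                        freq = freq, raw = raw, z = z, status = status,
                        stringsAsFactors = FALSE))
}

# plain trapezoid over all provided points (shared-boundary integration)
trapezoid_segments <- function(dist, ehh) {
  if (length(dist) < 2L) return(0)
  sum(diff(dist) * (utils::head(ehh, -1L) + utils::tail(ehh, -1L)) / 2)
}

#' Windowed means of standardized per-SNP scores
#'
#' Per scored window, the mean over member SNPs with status `"ok"` of
#' `|z|` (`mode = "abs"`, the default, matching the one-tailed
#' extreme-high outlier rule) or of `z` (`mode = "signed"`). Windows with
#' fewer than `min_snps` usable SNPs are unscored.
#'
#' @param scores A `SnpScores` table from [ihs_scan()] or [xpehh_scan()].
#' @param grid A `WindowGrid`.
#' @param mode `"abs"` or `"signed"`.
#' @param min_snps Minimum usable SNPs per window (default: the grid's
#'   `min_snps`).
#' @return A `ScoreTrack` (`"iHS_win"` or `"XPEHH_win"`).
#' @export
window_mean_scores <- function(scores, grid, mode = c("abs", "signed"),
                               min_snps = grid$min_snps) {
  mode <- match.arg(mode)
  stopifnot(inherits(scores, "SnpScores"), inherits(grid, "WindowGrid"))
  ok <- scores$status == "ok" & !is.na(scores$z)
  pos <- scores$position[ok]
  zz <- scores$z[ok]
  if (mode == "abs") zz <- abs(zz)
  vals <- rep(NA_real_, n_windows(grid))
  cnt <- integer(n_windows(grid))
  lo <- findInterval(grid$windows$start - 0.5, pos) + 1L
  hi <- findInterval(grid$windows$end + 0.5, pos)
  for (w in seq_len(n_windows(grid))) {
    if (hi[w] - lo[w] + 1L < min_snps) { cnt[w] <- max(0L, hi[w] - lo[w] + 1L); next }
    vals[w] <- mean(zz[lo[w]:hi[w]])
    cnt[w] <- hi[w] - lo[w] + 1L
  }
  stat <- if (attr(scores, "statistic") == "iHS") "iHS_win" else "XPEHH_win"
  score_track(stat, attr(scores, "context"), grid, vals, n_snps = cnt,
              standardized = TRUE)
}
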