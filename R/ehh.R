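# Extended haplotype homozygosity (EHH) decay and its integral (iHH),
# the building blocks of iHS and XP-EHH.

# pair-homozygosity of a grouping vector: P(two random members identical)
group_ehh <- function(g) {
  n <- length(g)
  k <- tabulate(g)
  sum(k * (k - 1) / 2) / (n * (n - 1) / 2)
}

# Walk markers away from the core, refining the identity partition one
# marker at a time. Haplotype identity is over all markers between the
# core and the current marker, both inclusive. Stops after the first
# marker whose EHH falls below `cutoff`, or flags truncation at the
# chromosome end. `hm` is the full 0/1 matrix (no NA allowed on the path).
ehh_walk <- function(hm, rows, core, direction, cm, cutoff) {
  n <- length(rows)
  g <- hm[rows, core]
  if (anyNA(g))
    stop("missing genotype at the core; run drop_missing_variants() first")
  g <- g + 1L
  markers <- if (direction == "right") {
    if (core < ncol(hm)) (core + 1L):ncol(hm) else integer(0)
  } else {
    if (core > 1L) (core - 1L):1L else integer(0)
  }
  n_mk <- length(markers)
  dist <- numeric(n_mk + 1L)
  ehh <- numeric(n_mk + 1L)
  mk <- integer(n_mk + 1L)
  dist[1L] <- 0; ehh[1L] <- 1; mk[1L] <- core
  e <- 1
  used <- 1L
  for (k in seq_len(n_mk)) {
    col <- hm[rows, markers[k]]
    if (anyNA(col))
      stop("missing genotype in the scanned markers; ",
           "run drop_missing_variants() first")
    key <- g * 2L + col
    g <- match(key, unique(key))
    e <- group_ehh(g)
    used <- k + 1L
    dist[used] <- abs(cm[markers[k]] - cm[core])
    ehh[used] <- e
    mk[used] <- markers[k]
    if (e < cutoff) break
  }
  list(dist = dist[seq_len(used)], ehh = ehh[seq_len(used)],
       marker = mk[seq_len(used)],
       truncated = e >= cutoff)
}

#' EHH decay curve from a core variant
#'
#' EHH at marker m is the probability that two haplotypes drawn at random
#' from the carriers of `allele` at the core are identical over every
#' marker between the core and m (inclusive): with carrier groups of
#' sizes k_g under exact identity, `EHH(m) = sum(C(k_g, 2)) / C(n, 2)`.
#' The curve starts at (0 cM, 1), is monotone non-increasing, and extends
#' marker by marker until EHH drops below `cutoff` (that marker is the
#' last point) or the chromosome end is reached (curve flagged
#' `truncated`).
#'
#' Requires complete data over the scanned markers; use
#' [drop_missing_variants()] first.
#'
#' @param h A `HaplotypeSet`.
#' @param core Variant index of the core SNP.
#' @param allele `"derived"`, `"ancestral"` (resolved through the
#'   per-variant ancestral flag) or `"all"` (every haplotype, as used by
#'   XP-EHH).
#' @param direction `"left"` or `"right"`.
#' @param map Optional `GeneticMap`; default constant 1 cM/Mb.
#' @param cutoff EHH decay cutoff (default 0.05).
#' @param samples Restrict to these samples (default all).
#' @return An `EhhCurve`: core, allele, direction, `points`
#'   (`distance_cm`, `ehh`, `marker`), `truncated`, `n_carriers`.
#' @export
ehh_decay <- function(h, core, allele = c("derived", "ancestral", "all"),
                      direction = c("left", "right"), map = NULL,
                      cutoff = 0.05, samples = h$sample_ids) {
  allele <- match.arg(allele)
  direction <- match.arg(direction)
  rows <- hap_rows(h, samples)
  if (allele != "all") {
    anc <- h$ancestral[core]
    if (anc == "unknown")
      stop("ancestral allele unknown at core ", core,
           "; use allele = \"all\" or set an ancestral policy")
    derived_code <- if (anc == "ref") 1L else 0L
    want <- if (allele == "derived") derived_code else 1L - derived_code
    carrier <- h$haplotypes[rows, core] == want
    if (anyNA(carrier)) stop("missing genotype at the core; ",
                             "run drop_missing_variants() first")
    rows <- rows[carrier]
  }
  if (length(rows) < 2L)
    stop("need >= 2 carrier haplotypes for an EHH curve (got ",
         length(rows), ")")
  cm <- interpolate_cm(map, h$chrom, h$positions)
  w <- ehh_walk(h$haplotypes, rows, core, direction, cm, cutoff)
  structure(list(core = core, allele = allele, direction = direction,
                 points = data.frame(distance_cm = w$dist, ehh = w$ehh,
                                     marker = w$marker),
                 truncated = w$truncated, n_carriers = length(rows)),
            class = "EhhCurve")
}

#' @export
print.EhhCurve <- function(x, ...) {
  cat(sprintf("EhhCurve: core %d, %s allele, %s, %d carriers, %d points%s\n",
              x$core, x$allele, x$direction, x$n_carriers,
              nrow(x$points), if (x$truncated) " [truncated]" else ""))
  invisible(x)
}

# trapezoidal integral of an (distance, ehh) polyline truncated after the
# first point below cutoff
trapezoid_to_cutoff <- function(dist, ehh, cutoff) {
  below <- which(ehh < cutoff)
  if (length(below)) {
    k <- below[1L]
    dist <- dist[seq_len(k)]
    ehh <- ehh[seq_len(k)]
  }
  if (length(dist) < 2L) return(0)
  sum(diff(dist) * (utils::head(ehh, -1L) + utils::tail(ehh, -1L)) / 2)
}

#' Integrated haplotype homozygosity (iHH) from two EHH curves
#'
#' Trapezoidal integral of EHH against cM distance, summed over the left
#' and right curves of the same core/allele. Integration is truncated at
#' the first marker with EHH below `cutoff`: that marker's segment is
#' included, later ones excluded. If either curve is flagged truncated
#' (chromosome end reached before decay), the score is dropped
#' (`status = "skipped_truncated"`) unless `keep_truncated = TRUE`.
#'
#' @param curve_left,curve_right `EhhCurve`s for the two directions.
#' @param cutoff EHH decay cutoff (default 0.05).
#' @param keep_truncated Integrate truncated curves anyway.
#' @return List with `value` (iHH in cM, `NA` when skipped) and `status`
#'   (`"ok"` or `"skipped_truncated"`).
#' @export
ihh <- function(curve_left, curve_right, cutoff = 0.05,
                keep_truncated = FALSE) {
  stopifnot(inherits(curve_left, "EhhCurve"),
            inherits(curve_right, "EhhCurve"))
  if (nrow(curve_left$points) == 0L || nrow(curve_right$points) == 0L)
    stop("empty EHH curve")
  if (curve_left$core != curve_right$core ||
      curve_left$allele != curve_right$allele)
    stop("curves must come from the same core and allele")
  if ((curve_left$truncated || curve_right$truncated) && !keep_truncated)
    return(list(value = NA_real_, status = "skipped_truncated"))
  v <- trapezoid_to_cutoff(curve_left$points$distance_cm,
                           curve_left$points$ehh, cutoff) +
    trapezoid_to_cutoff(curve_right$points$distance_cm,
                        curve_right$points$ehh, cutoff)
  list(value = v, status = "ok")
}

# Prefix/suffix identity partitions of a complete 0/1 matrix, one
# incremental refinement pass per direction (O(n * m) total).
# left[, j] groups rows by identity over markers 1..j; right[, j] over
# j..m. The limiting EHH of ANY row subset at any core is then the
# restriction of these partitions — because EHH is monotone
# non-increasing, a decay walk is truncated (never drops below the
# cutoff before the chromosome end) iff that limiting EHH is >= cutoff,
# so doomed walks can be skipped without stepping through them.
span_partitions <- function(hm) {
  n <- nrow(hm); m <- ncol(hm)
  gl <- matrix(0L, n, m); gr <- matrix(0L, n, m)
  g <- rep(1L, n)
  for (j in seq_len(m)) {
    key <- g * 2L + hm[, j]; g <- match(key, unique(key)); gl[, j] <- g
  }
  g <- rep(1L, n)
  for (j in rev(seq_len(m))) {
    key <- g * 2L + hm[, j]; g <- match(key, unique(key)); gr[, j] <- g
  }
  list(left = gl, right = gr)
}

# limiting EHH of row subset `rows` at `core` using precomputed
# span_partitions
limit_ehh <- function(parts, rows, core, direction) {
  g <- if (direction == "right") parts$right[rows, core]
       else parts$left[rows, core]
  group_ehh(match(g, unique(g)))
}

# fast one-shot iHH for a fixed carrier row set (both directions), used
# by the scans; same math as ehh_decay + ihh without curve objects.
# `parts` (span_partitions of hm) enables the O(|rows|) truncation
# pre-check.
ihh_rows <- function(hm, rows, core, cm, cutoff, parts = NULL) {
  if (!is.null(parts)) {
    for (dir in c("left", "right"))
      if (limit_ehh(parts, rows, core, dir) >= cutoff)
        return(list(value = NA_real_, status = "skipped_truncated"))
  }
  tot <- 0
  for (dir in c("left", "right")) {
    w <- ehh_walk(hm, rows, core, dir, cm, cutoff)
    if (w$truncated)
      return(list(value = NA_real_, status = "skipped_truncated"))
    tot <- tot + trapezoid_to_cutoff(w$dist, w$ehh, cutoff)
  }
  list(value = tot, status = "ok")
}
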