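# Core container: phased biallelic haplotypes for one chromosome.

#' Construct a HaplotypeSet
#'
#' A `HaplotypeSet` holds phased biallelic variants for one chromosome:
#' a 0/1 haplotype matrix with two rows per diploid sample (rows `2i - 1`
#' and `2i` belong to sample `i`), strictly increasing 1-based positions,
#' single-base REF/ALT alleles, a per-variant ancestral-allele flag and a
#' genotype-level missingness mask. Encoding is fixed: 0 = REF, 1 = ALT;
#' ancestral orientation is carried as a flag, never by re-encoding.
#'
#' Missingness is genotype-level: when a diploid genotype is missing both
#' haplotype rows of that sample carry `NA` at the variant and the
#' `missing` mask entry is `TRUE`.
#'
#' @param chrom Chromosome name (length-1 character).
#' @param positions Integer vector of 1-based bp positions, strictly
#'   increasing.
#' @param ref,alt Character vectors of single-base alleles, one per variant.
#' @param haplotypes Integer/numeric matrix of 0/1 (NA = missing) with
#'   `2 * length(sample_ids)` rows and `length(positions)` columns.
#' @param sample_ids Character vector of sample names.
#' @param ancestral Per-variant flag in `c("ref", "alt", "unknown")`;
#'   default `"ref"` (REF treated as ancestral).
#' @param missing Optional logical matrix (samples x variants). Derived
#'   from `haplotypes` NAs when omitted.
#' @return An object of class `HaplotypeSet`.
#' @export
haplotype_set <- function(chrom, positions, ref, alt, haplotypes, sample_ids,
                          ancestral = NULL, missing = NULL) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  positions <- as.integer(positions)
  m <- length(positions)
  n <- length(sample_ids)
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (m > 1L && any(diff(positions) <= 0L))
    stop("positions must be strictly increasing")
  if (length(ref) != m || length(alt) != m)
    stop("ref/alt length must equal the number of variants")
  if (nrow(haplotypes) != 2L * n)
    stop("haplotype matrix must have 2 rows per sample (got ",
         nrow(haplotypes), " rows for ", n, " samples)")
  if (ncol(haplotypes) != m)
    stop("haplotype matrix must have one column per variant")
  vals <- haplotypes[!is.na(haplotypes)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    stop("non-missing haplotype entries must be 0 or 1")
  if (is.null(ancestral)) ancestral <- rep("ref", m)
  ancestral <- match.arg(as.character(ancestral), c("ref", "alt", "unknown"),
                         several.ok = TRUE)
  if (length(ancestral) == 1L) ancestral <- rep(ancestral, m)
  if (length(ancestral) != m) stop("ancestral flag length mismatch")
  if (is.null(missing)) {
    missing <- is.na(haplotypes[seq_len(n) * 2L - 1L, , drop = FALSE]) |
      is.na(haplotypes[seq_len(n) * 2L, , drop = FALSE])
  }
  missing <- as.matrix(missing)
  if (!identical(dim(missing), c(n, m)) && !(n == 0L && m == 0L))
    stop("missing mask must be samples x variants")
  # enforce genotype-level missingness on the matrix
  if (any(missing)) {
    idx <- which(missing, arr.ind = TRUE)
    haplotypes[cbind(2L * idx[, 1L] - 1L, idx[, 2L])] <- NA_integer_
    haplotypes[cbind(2L * idx[, 1L], idx[, 2L])] <- NA_integer_
  }
  rownames(haplotypes) <- paste0(rep(sample_ids, each = 2L), "_", c(1L, 2L))
  structure(list(chrom = chrom, positions = positions,
                 ref = as.character(ref), alt = as.character(alt),
                 haplotypes = haplotypes,
                 sample_ids = as.character(sample_ids),
                 ancestral = ancestral, missing = missing),
            class = "HaplotypeSet")
}

#' @export
print.HaplotypeSet <- function(x, ...) {
  cat(sprintf("HaplotypeSet: %s, %d samples (%d haplotypes), %d variants\n",
              x$chrom, n_samples(x), nrow(x$haplotypes), n_variants(x)))
  if (n_variants(x))
    cat(sprintf("  span %d-%d bp, %d missing genotypes\n",
                min(x$positions), max(x$positions), sum(x$missing)))
  invisible(x)
}

#' Number of diploid samples / variants in a HaplotypeSet
#' @param h A `HaplotypeSet`.
#' @return Integer count.
#' @export
n_samples <- function(h) length(h$sample_ids)

#' @rdname n_samples
#' @export
n_variants <- function(h) length(h$positions)

#' Haplotype row indices for a set of samples
#'
#' @param h A `HaplotypeSet`.
#' @param samples Character vector of sample ids (default: all).
#' @return Integer vector of row indices into `h$haplotypes`, two per
#'   sample, in sample order.
#' @export
hap_rows <- function(h, samples = h$sample_ids) {
  i <- match(samples, h$sample_ids)
  if (anyNA(i))
    stop("unknown sample(s): ", paste(samples[is.na(i)], collapse = ", "))
  as.vector(rbind(2L * i - 1L, 2L * i))
}

#' Subset a HaplotypeSet
#'
#' @param h A `HaplotypeSet`.
#' @param samples Sample ids to keep (in the given order).
#' @param variants Integer indices of variants to keep (increasing).
#' @return A new `HaplotypeSet`.
#' @export
subset_haplotypes <- function(h, samples = h$sample_ids,
                              variants = seq_len(n_variants(h))) {
  variants <- as.integer(variants)
  si <- match(samples, h$sample_ids)
  if (anyNA(si)) stop("unknown sample(s)")
  haplotype_set(h$chrom, h$positions[variants], h$ref[variants],
                h$alt[variants],
                h$haplotypes[as.vector(rbind(2L * si - 1L, 2L * si)),
                             variants, drop = FALSE],
                h$sample_ids[si], h$ancestral[variants],
                h$missing[si, variants, drop = FALSE])
}

#' Diploid dosage matrix (0/1/2 copies of the ALT allele)
#'
#' @param h A `HaplotypeSet`.
#' @return Integer matrix, samples x variants, `NA` where the genotype is
#'   missing.
#' @export
dosage_matrix <- function(h) {
  n <- n_samples(h)
  d <- h$haplotypes[seq_len(n) * 2L - 1L, , drop = FALSE] +
    h$haplotypes[seq_len(n) * 2L, , drop = FALSE]
  rownames(d) <- h$sample_ids
  d
}

#' Drop variants with any missing genotype
#'
#' Haplotype-based statistics (EHH, iHS, XP-EHH) require complete data;
#' this is the pre-pass that removes every variant with at least one
#' missing genotype.
#'
#' @param h A `HaplotypeSet`.
#' @return A `HaplotypeSet` with only complete variants.
#' @export
drop_missing_variants <- function(h) {
  keep <- which(colSums(h$missing) == 0L)
  subset_haplotypes(h, variants = keep)
}

#' Per-variant ALT allele frequency within a sample set
#'
#' Computed on non-missing alleles only.
#'
#' @param h A `HaplotypeSet`.
#' @param samples Sample ids (default all).
#' @return Numeric vector of ALT frequencies (NaN where no allele is
#'   observed).
#' @export
alt_frequency <- function(h, samples = h$sample_ids) {
  rows <- hap_rows(h, samples)
  hm <- h$haplotypes[rows, , drop = FALSE]
  colSums(hm, na.rm = TRUE) / colSums(!is.na(hm))
}
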