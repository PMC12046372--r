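# I/O for the standard formats the scan touches: phased VCF, population
# maps, genetic maps (PLINK .map), gene annotations (BED/GFF3).

#' Read a phased multi-sample VCF into a HaplotypeSet
#'
#' Only biallelic SNPs are admitted; multi-allelic and non-SNP records are
#' dropped and the count is reported via a message and the
#' `"dropped_records"` attribute. Genotypes must be phased (`|` separator);
#' unphased `/` genotypes are rejected unless `allow_unphased = TRUE`.
#' Missing genotypes (`./.`, `.|.` or `.`) are recorded in the
#' genotype-level missingness mask.
#'
#' Parsing is delegated to [VariantAnnotation::readVcf()]; malformed files
#' surface that parser's error.
#'
#' @param path Path to a VCF 4.x file (plain or bgzipped).
#' @param region Optional region string `"chrom"` or `"chrom:start-end"`
#'   used to subset records after reading.
#' @param allow_unphased Accept `/`-separated genotypes as if phased.
#' @return A [haplotype_set()] with attribute `dropped_records`.
#' @export
read_phased_vcf <- function(path, region = NULL, allow_unphased = FALSE) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chroms <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(n_alt))
  alt1[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))

  keep <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T")

  if (!is.null(region)) {
    rg <- parse_region(region)
    keep <- keep & chroms == rg$chrom
    if (!is.na(rg$start)) keep <- keep & pos >= rg$start & pos <= rg$end
  }
  dropped <- sum(n_alt != 1L | nchar(ref) != 1L |
                   ifelse(is.na(alt1), TRUE, nchar(alt1) != 1L))
  if (dropped > 0L)
    message(dropped, " multi-allelic/non-SNP record(s) dropped")

  idx <- which(keep)
  chrom_set <- unique(chroms[idx])
  if (length(chrom_set) > 1L)
    stop("VCF spans ", length(chrom_set),
         " chromosomes; pass `region` to select one")
  if (length(chrom_set) == 0L) chrom_set <- if (length(chroms)) chroms[1L] else "chr"

  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  gt <- gt[idx, , drop = FALSE]
  samples <- colnames(gt)
  n <- length(samples); m <- length(idx)

  sep <- substr(gt, 2L, 2L)
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  miss <- a1 == "." | a2 == "." | gt == "." | gt == ""
  if (any(!miss & !(a1 %in% c("0", "1") & a2 %in% c("0", "1"))))
    stop("unexpected allele codes in GT (biallelic records should code 0/1)")
  unphased <- !miss & sep == "/"
  if (any(unphased) && !allow_unphased)
    stop(sum(unphased), " unphased genotype(s) found; phase the data or ",
         "set allow_unphased = TRUE")

  hap <- matrix(NA_integer_, nrow = 2L * n, ncol = m)
  h1 <- suppressWarnings(as.integer(a1)); h1[miss] <- NA_integer_
  h2 <- suppressWarnings(as.integer(a2)); h2[miss] <- NA_integer_
  # gt is variants x samples; transpose into rows 2i-1 / 2i per sample
  hap[seq_len(n) * 2L - 1L, ] <- t(matrix(h1, nrow = m))
  hap[seq_len(n) * 2L, ] <- t(matrix(h2, nrow = m))

  anc <- rep("ref", m)
  info <- VariantAnnotation::info(vcf)
  if ("AA" %in% colnames(info)) {
    aa <- toupper(as.character(info$AA))[idx]
    anc[!is.na(aa) & aa == toupper(alt1[idx])] <- "alt"
    anc[is.na(aa) | !(aa %in% c("A", "C", "G", "T"))] <- "unknown"
  }

  ord <- order(pos[idx])
  h <- haplotype_set(chrom_set, pos[idx][ord], ref[idx][ord], alt1[idx][ord],
                     hap[, ord, drop = FALSE], samples, anc[ord],
                     t(matrix(miss, nrow = m))[, ord, drop = FALSE])
  attr(h, "dropped_records") <- dropped
  h
}

parse_region <- function(region) {
  mt <- regmatches(region, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
  if (length(mt) == 0L) stop("malformed region string: ", region)
  list(chrom = mt[2L],
       start = if (mt[4L] == "") NA_integer_ else as.integer(mt[4L]),
       end = if (mt[5L] == "") NA_integer_ else as.integer(mt[5L]))
}

#' Write a HaplotypeSet as a phased VCF
#'
#' Emits a minimal VCF 4.2 with phased `GT` (`|` separator, `.|.` for
#' missing genotypes). Round-trips exactly through [read_phased_vcf()].
#'
#' @param h A `HaplotypeSet`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(h, path) {
  n <- n_samples(h)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", h$chrom),
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", h$sample_ids), collapse = "\t")), con)
  if (n_variants(h) == 0L) return(invisible(path))
  aa <- ifelse(h$ancestral == "ref", h$ref,
               ifelse(h$ancestral == "alt", h$alt, "."))
  g1 <- h$haplotypes[seq_len(n) * 2L - 1L, , drop = FALSE]
  g2 <- h$haplotypes[seq_len(n) * 2L, , drop = FALSE]
  gt <- matrix(paste0(ifelse(is.na(g1), ".", g1), "|",
                      ifelse(is.na(g2), ".", g2)), nrow = n)
  lines <- paste(h$chrom, h$positions, ".", h$ref, h$alt, ".", "PASS",
                 paste0("AA=", aa), "GT",
                 apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Whitespace-delimited file with two or three columns: sample id,
#' population label, optional climate group (`hot`/`cold`/`other`).
#'
#' @param path Path to the map file.
#' @return A `PopulationMap`: list with `assignments` (named character,
#'   sample -> population) and `groups` (named character, population ->
#'   group, `"other"` when unstated).
#' @export
read_population_map <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("population map needs >= 2 columns")
  if (anyDuplicated(df[[1L]])) {
    dup <- unique(df[[1L]][duplicated(df[[1L]])])
    stop("duplicate sample id(s) in population map: ",
         paste(dup, collapse = ", "))
  }
  assignments <- stats::setNames(as.character(df[[2L]]), df[[1L]])
  pops <- unique(assignments)
  groups <- stats::setNames(rep("other", length(pops)), pops)
  if (ncol(df) >= 3L) {
    g <- tapply(as.character(df[[3L]]), df[[2L]], function(x) {
      u <- unique(x)
      if (length(u) > 1L) stop("conflicting group labels for one population")
      u
    })
    groups[names(g)] <- as.character(g)
  }
  structure(list(assignments = assignments, groups = groups),
            class = "PopulationMap")
}

#' @export
print.PopulationMap <- function(x, ...) {
  tab <- table(x$assignments)
  cat("PopulationMap:", length(tab), "population(s)\n")
  for (p in names(tab))
    cat(sprintf("  %s: %d samples [%s]\n", p, tab[[p]], x$groups[[p]]))
  invisible(x)
}

#' Samples belonging to one population
#' @param popmap A `PopulationMap`.
#' @param pop Population label.
#' @return Character vector of sample ids.
#' @export
pop_samples <- function(popmap, pop) {
  s <- names(popmap$assignments)[popmap$assignments == pop]
  if (!length(s)) stop("population not found or empty: ", pop)
  s
}

#' Construct a genetic map
#'
#' Anchors are (bp, cM) pairs per chromosome with cM non-decreasing in bp.
#' With no map, all positions are converted at a constant default rate of
#' 1 cM/Mb.
#'
#' @param anchors Named list of data frames with columns `bp` and `cm`,
#'   one per chromosome (>= 2 anchors each).
#' @return A `GeneticMap`.
#' @export
genetic_map <- function(anchors) {
  stopifnot(is.list(anchors), !is.null(names(anchors)))
  for (ch in names(anchors)) {
    a <- anchors[[ch]]
    stopifnot(all(c("bp", "cm") %in% names(a)))
    a <- a[order(a$bp), , drop = FALSE]
    if (nrow(a) < 2L) stop("chromosome ", ch, " needs >= 2 anchors")
    if (any(diff(a$cm) < 0)) stop("cM must be non-decreasing in bp (", ch, ")")
    anchors[[ch]] <- a
  }
  structure(list(anchors = anchors), class = "GeneticMap")
}

#' Read a PLINK-style .map file as a GeneticMap
#'
#' Columns: chromosome, variant id, cM position, bp position.
#'
#' @param path Path to the `.map` file.
#' @return A `GeneticMap`.
#' @export
read_genetic_map <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop(".map needs 4 columns: chrom, id, cM, bp")
  anchors <- lapply(split(df, df[[1L]]), function(d)
    data.frame(bp = as.numeric(d[[4L]]), cm = as.numeric(d[[3L]])))
  genetic_map(anchors)
}

#' Interpolate genetic-map position (cM) at base-pair coordinates
#'
#' Piecewise-linear interpolation between anchors with constant-rate
#' extrapolation beyond the anchored span (using the terminal segment
#' rate, or 1 cM/Mb for a degenerate flat end segment of width zero).
#' With `map = NULL`, the constant default 1 cM/Mb applies:
#' `cM = bp * 1e-6`.
#'
#' @param map A `GeneticMap` or `NULL`.
#' @param chrom Chromosome name.
#' @param bp Numeric vector of bp positions.
#' @return Numeric vector of cM positions.
#' @export
interpolate_cm <- function(map, chrom, bp) {
  if (is.null(map)) return(bp * 1e-6)
  stopifnot(inherits(map, "GeneticMap"))
  a <- map$anchors[[chrom]]
  if (is.null(a))
    stop("chromosome ", chrom, " not in genetic map and no fallback")
  k <- nrow(a)
  out <- stats::approx(a$bp, a$cm, xout = bp, rule = 2)$y
  # constant-rate extrapolation using the terminal segment slopes
  lo <- bp < a$bp[1L]
  if (any(lo)) {
    r <- (a$cm[2L] - a$cm[1L]) / (a$bp[2L] - a$bp[1L])
    out[lo] <- a$cm[1L] + (bp[lo] - a$bp[1L]) * r
  }
  hi <- bp > a$bp[k]
  if (any(hi)) {
    r <- (a$cm[k] - a$cm[k - 1L]) / (a$bp[k] - a$bp[k - 1L])
    out[hi] <- a$cm[k] + (bp[hi] - a$bp[k]) * r
  }
  out
}

#' Read a gene annotation table (BED or GFF3)
#'
#' Intervals are normalized to the package-wide 1-based inclusive
#' convention: a BED start `s` (0-based half-open) becomes `s + 1`. For
#' GFF3, only `gene`-type features are returned; a file without any emits
#' a warning and an empty table.
#'
#' @param path Path to the annotation file.
#' @param format `"bed"` or `"gff3"`.
#' @return A data frame of gene models: `gene_id`, `gene_name`, `chrom`,
#'   `start`, `end` (1-based inclusive), `strand`.
#' @export
read_gene_annotation <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  if (format == "gff3") {
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    if (length(gr) == 0L) {
      warning("no 'gene' features found in GFF3")
      return(data.frame(gene_id = character(), gene_name = character(),
                        chrom = character(), start = integer(),
                        end = integer(), strand = character()))
    }
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
      paste0("gene", seq_along(gr))
    nms <- if (!is.null(gr$Name)) as.character(gr$Name) else ids
  } else {
    ids <- if (!is.null(gr$name)) as.character(gr$name) else
      paste0("gene", seq_along(gr))
    nms <- ids
  }
  nms[is.na(nms)] <- ids[is.na(nms)]
  out <- data.frame(gene_id = ids, gene_name = nms,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  if (any(out$start < 1L) || any(out$start > out$end))
    stop("invalid gene coordinates after normalization")
  out
}

#' Write gene models as GFF3
#'
#' @param genes Data frame as returned by [read_gene_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    strand <- ifelse(genes$strand %in% c("+", "-"), genes$strand, ".")
    writeLines(paste(genes$chrom, "sweepscan", "gene", genes$start, genes$end,
                     ".", strand, ".",
                     sprintf("ID=%s;Name=%s", genes$gene_id, genes$gene_name),
                     sep = "\t"), con)
  }
  invisible(path)
}
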