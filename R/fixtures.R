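# Hand-constructed micro-datasets with known expected values, shared by
# the documentation examples and the test suite.

#' Built-in micro-fixtures with known expected values
#'
#' Returns small hand-constructed datasets paired with their expected
#' outputs:
#' \describe{
#'   \item{`ehh_toy`}{Four carrier haplotypes over three markers. All
#'     carry ALT at the core (marker 1); at marker 2 they split into
#'     groups of 3 and 1, so EHH(marker 2) = C(3,2)/C(4,2) = 0.5.}
#'   \item{`fst_toy`}{Two populations of 10 diploids fixed for different
#'     alleles at one SNP: Weir-Cockerham theta = 1.}
#'   \item{`window_toy`}{A 100-kb chromosome under the default 20-kb/
#'     10-kb geometry: 9 windows, first (1, 20000), last (80001,
#'     100000).}
#'   \item{`vcf_toy`}{VCF text with 3 samples and 10 records, one of
#'     them tri-allelic (dropped on read) and one genotype missing:
#'     9 variants survive.}
#' }
#'
#' @param kind One of `"ehh_toy"`, `"fst_toy"`, `"window_toy"`,
#'   `"vcf_toy"`.
#' @return List with `data` (fixture-specific) and `expected` (named
#'   list of reference values).
#' @export
make_fixture <- function(kind = c("ehh_toy", "fst_toy", "window_toy",
                                  "vcf_toy")) {
  kind <- match.arg(kind)
  switch(kind,
    ehh_toy = {
      # rows = 4 haplotypes (2 diploids); marker 1 is the core (all ALT),
      # marker 2 splits 3|1, marker 3 splits further
      hm <- rbind(c(1L, 0L, 0L),
                  c(1L, 0L, 0L),
                  c(1L, 0L, 1L),
                  c(1L, 1L, 0L))
      h <- haplotype_set("chr1", c(10000L, 20000L, 30000L),
                         rep("A", 3), rep("T", 3), hm, c("s1", "s2"))
      list(data = h,
           expected = list(core = 1L, allele = "derived",
                           ehh_marker2 = 0.5,
                           ehh_marker3 = 1 / 6))  # groups 2,1,1 -> 1/6
    },
    fst_toy = {
      ids <- c(sprintf("a%02d", 1:10), sprintf("b%02d", 1:10))
      hm <- matrix(c(rep(0L, 20), rep(1L, 20)), ncol = 1L)
      h <- haplotype_set("chr1", 5000L, "A", "G", hm, ids)
      list(data = list(haplotypes = h, popA = ids[1:10], popB = ids[11:20]),
           expected = list(theta = 1))
    },
    window_toy = {
      list(data = list(chrom_length = 1e5, window_size = 20000L,
                       step = 10000L),
           expected = list(n_windows = 9L, first = c(1L, 20000L),
                           last = c(80001L, 100000L)))
    },
    vcf_toy = {
      gt <- function(...) paste(..., sep = "\t")
      lines <- c(
        "##fileformat=VCFv4.2",
        "##contig=<ID=chr1>",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        gt("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
           "FORMAT", "s1", "s2", "s3"),
        gt("chr1", 100, ".", "A", "T", ".", "PASS", ".", "GT",
           "0|0", "0|1", "1|1"),
        gt("chr1", 200, ".", "C", "G", ".", "PASS", ".", "GT",
           "0|1", "0|0", "0|0"),
        gt("chr1", 300, ".", "G", "A,T", ".", "PASS", ".", "GT",
           "0|1", "0|2", "0|0"),               # tri-allelic: dropped
        gt("chr1", 400, ".", "T", "C", ".", "PASS", ".", "GT",
           "1|1", "0|0", "0|1"),
        gt("chr1", 500, ".", "A", "G", ".", "PASS", ".", "GT",
           "0|0", ".|.", "0|1"),               # missing genotype: s2
        gt("chr1", 600, ".", "C", "T", ".", "PASS", ".", "GT",
           "1|0", "0|0", "0|0"),
        gt("chr1", 700, ".", "G", "C", ".", "PASS", ".", "GT",
           "0|0", "1|1", "0|0"),
        gt("chr1", 800, ".", "T", "A", ".", "PASS", ".", "GT",
           "0|1", "1|0", "1|1"),
        gt("chr1", 900, ".", "A", "C", ".", "PASS", ".", "GT",
           "0|0", "0|0", "1|0"),
        gt("chr1", 1000, ".", "G", "T", ".", "PASS", ".", "GT",
           "1|1", "1|1", "0|0"))
      list(data = lines,
           expected = list(n_variants = 9L, n_samples = 3L, dropped = 1L,
                           missing_sample = "s2", missing_position = 500L))
    })
}
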