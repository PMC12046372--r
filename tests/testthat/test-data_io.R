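test_that("phased VCF reading applies the biallelic filter and missingness mask", {
  fx <- make_fixture("vcf_toy")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(fx$data, f)
  h <- suppressMessages(read_phased_vcf(f))
  expect_s3_class(h, "HaplotypeSet")
  expect_identical(n_variants(h), fx$expected$n_variants)
  expect_identical(n_samples(h), fx$expected$n_samples)
  expect_identical(attr(h, "dropped_records"), fx$expected$dropped)
  expect_identical(nrow(h$haplotypes), 2L * fx$expected$n_samples)
  # genotype-level missingness: both haplotypes of the sample are NA
  si <- match(fx$expected$missing_sample, h$sample_ids)
  vi <- match(fx$expected$missing_position, h$positions)
  expect_true(h$missing[si, vi])
  expect_true(all(is.na(h$haplotypes[c(2L * si - 1L, 2L * si), vi])))
  expect_identical(sum(h$missing), 1L)
})

test_that("unphased genotypes are rejected unless permitted", {
  fx <- make_fixture("vcf_toy")
  lines <- sub("0\\|1\t0\\|0\t0\\|0", "0/1\t0|0\t0|0", fx$data)
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(lines, f)
  expect_error(suppressMessages(read_phased_vcf(f)), "unphased")
  h <- suppressMessages(read_phased_vcf(f, allow_unphased = TRUE))
  expect_identical(n_variants(h), 9L)
})

test_that("VCF writing round-trips exactly", {
  set.seed(42)
  hm <- random_hapmat(12, 30)
  hm[3:4, 7] <- NA  # one missing genotype
  h <- toy_hapset(hm)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_phased_vcf(h, f)
  h2 <- read_phased_vcf(f)
  expect_identical(h2$positions, h$positions)
  expect_identical(h2$ref, h$ref)
  expect_identical(h2$alt, h$alt)
  expect_identical(unname(h2$haplotypes), unname(h$haplotypes))
  expect_identical(unname(h2$missing), unname(h$missing))
})

test_that("population map reading validates and fills groups", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("s1 popA hot", "s2 popA hot", "s3 popB cold", "s4 popB cold"), f)
  pm <- read_population_map(f)
  expect_identical(sort(unique(pm$assignments)), c("popA", "popB"))
  expect_identical(pop_samples(pm, "popA"), c("s1", "s2"))
  expect_identical(pm$groups[["popB"]], "cold")

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("s1 popA", "s1 popB"), f2)
  expect_error(read_population_map(f2), "duplicate")

  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("s1 popA", "s2 popB"), f3)
  pm3 <- read_population_map(f3)
  expect_identical(unname(pm3$groups), c("other", "other"))
})

test_that("genetic-map interpolation is piecewise linear with constant-rate fallback", {
  gm <- genetic_map(list(chr1 = data.frame(bp = c(0, 1e6), cm = c(0, 1))))
  expect_equal(interpolate_cm(gm, "chr1", 5e5), 0.5)
  # no map: 1 cM/Mb default
  expect_equal(interpolate_cm(NULL, "chr1", 250000), 0.25)
  # hand interpolation between unevenly spaced anchors
  gm2 <- genetic_map(list(chr1 = data.frame(bp = c(0, 1e5, 2e5),
                                            cm = c(0, 0.1, 0.5))))
  expect_equal(interpolate_cm(gm2, "chr1", 1.5e5), 0.3)
  # extrapolation uses the terminal segment rate
  expect_equal(interpolate_cm(gm2, "chr1", 2.5e5), 0.5 + 0.5 * 0.4)
  expect_error(interpolate_cm(gm2, "chrZ", 1), "not in genetic map")
  # PLINK .map round trip
  f <- withr::local_tempfile(fileext = ".map")
  writeLines(c("chr1\tsnp1\t0.0\t1", "chr1\tsnp2\t0.3\t300000"), f)
  gm3 <- read_genetic_map(f)
  expect_equal(interpolate_cm(gm3, "chr1", 150000.5), 0.15, tolerance = 1e-5)
})

test_that("gene annotation normalizes BED and GFF3 to 1-based inclusive", {
  fb <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t999\t2000\tgeneA", fb)
  g <- read_gene_annotation(fb, "bed")
  expect_identical(g$start, 1000L)
  expect_identical(g$end, 2000L)
  expect_identical(g$gene_id, "geneA")

  fg <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=g1;Name=GENE1"), fg)
  g2 <- read_gene_annotation(fg, "gff3")
  expect_identical(g2$start, 1000L)
  expect_identical(g2$end, 2000L)
  expect_identical(g2$gene_name, "GENE1")

  fe <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\texon\t10\t20\t.\t+\t.\tID=e1"), fe)
  expect_warning(ge <- read_gene_annotation(fe, "gff3"), "no 'gene'")
  expect_identical(nrow(ge), 0L)
})

test_that("gene GFF3 writing round-trips through the reader", {
  genes <- random_genes(1e5, density_per_mb = 50, seed = 1)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(genes, f)
  g2 <- read_gene_annotation(f, "gff3")
  expect_identical(g2$start, genes$start)
  expect_identical(g2$end, genes$end)
  expect_identical(g2$gene_id, genes$gene_id)
})

test_that("BED coordinate conversion is an exact inverse on random intervals", {
  set.seed(7)
  start1 <- sort(sample.int(1e6, 50))
  end1 <- start1 + sample.int(5e4, 50)
  bed_start <- start1 - 1L   # to BED
  expect_identical(bed_start + 1L, start1)  # and back
  grid <- build_window_grid(1e5, chrom = "chrX")
  bed <- grid_as_bed(grid)
  expect_identical(bed$start + 1L, grid$windows$start)
  expect_identical(bed$end, grid$windows$end)
})
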