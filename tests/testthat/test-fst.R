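# independent evaluation of the two-population Weir-Cockerham components
oracle_wc <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# build a HaplotypeSet with exact per-population genotype compositions:
# counts of (hom-ref, het, hom-alt) per population at one SNP
geno_fixture <- function(compA, compB) {
  mk <- function(comp) {
    g <- rep(0:2, comp)
    rbind(as.integer(g >= 1), as.integer(g == 2))
  }
  A <- mk(compA); B <- mk(compB)
  hm <- matrix(c(as.vector(A), as.vector(B)), ncol = 1)
  ids <- c(sprintf("a%02d", seq_len(sum(compA))),
           sprintf("b%02d", seq_len(sum(compB))))
  list(h = toy_hapset(hm, positions = 1000L, sample_ids = ids),
       popA = ids[seq_len(sum(compA))],
       popB = ids[sum(compA) + seq_len(sum(compB))])
}

test_that("fixed difference between populations gives theta = 1", {
  fx <- make_fixture("fst_toy")
  comp <- wc_fst_components(fx$data$haplotypes, fx$data$popA, fx$data$popB)
  expect_equal(comp$theta, fx$expected$theta)
  expect_equal(comp$b, 0)
  expect_equal(comp$c, 0)
  expect_gt(comp$a, 0)
})

test_that("identical allele frequencies give no among-population variance", {
  fx <- geno_fixture(c(5, 0, 5), c(5, 0, 5))   # p = 0.5 in both, h = 0
  comp <- wc_fst_components(fx$h, fx$popA, fx$popB)
  expect_true(is.na(comp$theta) || comp$theta <= 0)
})

test_that("components match hand evaluation on a mixed fixture", {
  # n1 = n2 = 10, p1(ALT) = 0.9, h1 = 0.2; p2 = 0.45, h2 = 0.5
  fx <- geno_fixture(c(0, 2, 8), c(3, 5, 2))
  comp <- wc_fst_components(fx$h, fx$popA, fx$popB)
  o <- oracle_wc(10, 0.9, 0.2, 10, 0.45, 0.5)
  expect_equal(comp$a, o$a, tolerance = 1e-12)
  expect_equal(comp$b, o$b, tolerance = 1e-12)
  expect_equal(comp$c, o$c, tolerance = 1e-12)
  expect_equal(comp$theta, o$theta, tolerance = 1e-12)
})

test_that("theta is symmetric and uses locus-specific non-missing counts", {
  set.seed(61)
  hm <- random_hapmat(40, 12, p = 0.4)
  hm[1:6, 3] <- NA
  h <- toy_hapset(hm)
  A <- h$sample_ids[1:10]; B <- h$sample_ids[11:20]
  cAB <- wc_fst_components(h, A, B)
  cBA <- wc_fst_components(h, B, A)
  expect_equal(cAB$theta, cBA$theta)
  expect_equal(cAB$a, cBA$a)
  # variant 3: popA has 7 genotyped diploids; check against the oracle
  dos <- dosage_matrix(h)
  dA <- dos[1:10, 3]; dB <- dos[11:20, 3]
  o <- oracle_wc(sum(!is.na(dA)), mean(dA, na.rm = TRUE) / 2,
                 mean(dA == 1, na.rm = TRUE),
                 sum(!is.na(dB)), mean(dB, na.rm = TRUE) / 2,
                 mean(dB == 1, na.rm = TRUE))
  expect_equal(cAB$theta[3], o$theta, tolerance = 1e-12)
})

test_that("globally monomorphic sites are undefined, not zero", {
  hm <- matrix(0L, 8, 1)
  h <- toy_hapset(hm)
  comp <- wc_fst_components(h, h$sample_ids[1:2], h$sample_ids[3:4])
  expect_true(is.na(comp$theta))
})

test_that("windowed FST is the ratio of summed components", {
  g <- build_window_grid(20000, 20000, 20000, min_snps = 2L, chrom = "chr1")
  comp <- structure(data.frame(a = c(0.1, -0.02), b = c(0.15, 0.17),
                               c = c(0.05, 0.05)),
                    class = c("FstComponents", "data.frame"))
  comp$theta <- comp$a / (comp$a + comp$b + comp$c)
  h <- toy_hapset(random_hapmat(8, 2), positions = c(5000L, 15000L))
  g <- assign_snps(g, h)
  tr <- windowed_fst(comp, g, c("A", "B"))
  expect_equal(tr$values[1], 0.08 / 0.5)   # = 0.16
  expect_identical(tr$statistic, "FST")
  # a window of all fixed differences gives exactly 1
  fxh <- toy_hapset(matrix(c(rep(0L, 20), rep(1L, 20)), nrow = 8),
                    positions = c(2000L, 4000L, 6000L, 8000L, 10000L))
  g2 <- assign_snps(build_window_grid(20000, 20000, 20000, min_snps = 2L,
                                      chrom = "chr1"), fxh)
  comp2 <- wc_fst_components(fxh, fxh$sample_ids[1:2], fxh$sample_ids[3:4])
  expect_equal(windowed_fst(comp2, g2, c("A", "B"))$values[1], 1)
  expect_true(all(windowed_fst(comp2, g2, c("A", "B"))$values <= 1,
                  na.rm = TRUE))
})

test_that("observed heterozygosity counts het fractions per sample", {
  hm <- rbind(c(0L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L),   # s1 all hom -> 0
              c(0L, 1L, 0L, 1L), c(1L, 0L, 0L, 0L))   # s2 het at 3 of 4
  h <- toy_hapset(hm)
  het <- observed_heterozygosity(h)
  expect_equal(unname(het$per_sample), c(0, 0.75))
  expect_equal(het$population, 0.375)
})

test_that("mean FST rises as migration falls in island simulations", {
  means <- vapply(c(0.1, 0.01, 0.001), function(m) {
    vals <- vapply(1:2, function(i) {
      sim <- small_neutral_sim(seed = 700 + i * 10 + round(-log10(m)),
                               migration = m)
      g <- assign_snps(build_window_grid(1e5, min_snps = 10L,
                                         chrom = "chr1"), sim$haplotypes)
      comp <- wc_fst_components(sim$haplotypes,
                                pop_samples(sim$popmap, "pop1"),
                                pop_samples(sim$popmap, "pop2"))
      mean(windowed_fst(comp, g, c("pop1", "pop2"))$values, na.rm = TRUE)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
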