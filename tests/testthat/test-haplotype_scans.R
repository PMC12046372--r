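# iHS and XP-EHH micro-fixtures with brute-force oracles.

# brute-force iHH for a carrier set: pairwise-identity EHH at every
# marker plus trapezoid integration with the truncation rule
oracle_ihh <- function(hm, rows, core, positions, cutoff = 0.05) {
  cm <- positions * 1e-6
  total <- 0
  for (dir in c(-1, 1)) {
    markers <- if (dir == 1) seq(core + 1, ncol(hm)) else seq(core - 1, 1)
    if (core + dir > ncol(hm) || core + dir < 1) return(NA_real_)
    dist <- 0; ehh <- 1
    decayed <- FALSE
    for (mk in markers) {
      e <- oracle_ehh(hm, rows, core, mk)
      dist <- c(dist, abs(cm[mk] - cm[core]))
      ehh <- c(ehh, e)
      if (e < cutoff) { decayed <- TRUE; break }
    }
    if (!decayed) return(NA_real_)   # truncated at the chromosome end
    total <- total + sum(diff(dist) * (head(ehh, -1) + tail(ehh, -1)) / 2)
  }
  total
}

test_that("iHS is 0 when ancestral and derived classes have identical structure", {
  set.seed(51)
  # mirror-image classes: derived carriers copy the ancestral haplotypes
  block <- random_hapmat(10, 41, p = 0.5)
  hm <- rbind(block, block)
  hm[1:10, 21] <- 0L
  hm[11:20, 21] <- 1L
  h <- toy_hapset(hm)
  sc <- suppressWarnings(ihs_scan(h, maf_min = 0.4))
  expect_equal(sc$raw[21], 0)
})

test_that("a long shared derived haplotype gives negative raw iHS equal to the oracle", {
  set.seed(52)
  m <- 41L
  anc <- random_hapmat(12, m, p = 0.5)
  base <- rbinom(m, 1, 0.5)
  der <- matrix(rep(base, each = 8), nrow = 8, byrow = FALSE)
  anc[, 21] <- 0L
  der[, 21] <- 1L
  # derived rows share one long haplotype, made fully distinct only at the
  # chromosome edges so iHH_D is large but finite (EHH reaches 0 there)
  for (i in 1:8) {
    der[i, i] <- 1L - der[i, i]
    der[i, m + 1L - i] <- 1L - der[i, m + 1L - i]
  }
  hm <- rbind(anc, der)
  h <- toy_hapset(hm)
  sc <- suppressWarnings(ihs_scan(h, maf_min = 0.1))
  iA <- oracle_ihh(hm, which(hm[, 21] == 0L), 21L, h$positions)
  iD <- oracle_ihh(hm, which(hm[, 21] == 1L), 21L, h$positions)
  expect_false(is.na(sc$raw[21]))
  expect_lt(sc$raw[21], 0)
  expect_equal(sc$raw[21], log(iA / iD), tolerance = 1e-12)
})

test_that("iHS standardization gives mean 0 / sd 1 within populated bins and is permutation invariant", {
  sim <- simulate_wf(sim_config(deme_size = 60, sample_size = 20,
                                chrom_length = 1.5e5, generations = 300,
                                seed = 301))
  h <- sim$haplotypes
  sc <- suppressWarnings(ihs_scan(h, bins = 10))
  ok <- sc$status == "ok"
  expect_gt(sum(ok), 10)
  bins <- ceiling(sc$freq[ok] * 10)
  for (b in unique(bins)) {
    z <- sc$z[ok][bins == b]
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-9)
  }
  # permuting sample order leaves every score unchanged
  perm <- sample(h$sample_ids)
  hp <- subset_haplotypes(h, samples = perm)
  sc2 <- suppressWarnings(ihs_scan(hp, bins = 10))
  expect_equal(sc$raw, sc2$raw)
  expect_equal(sc$z, sc2$z)
})

test_that("XP-EHH is 0 for identical populations and antisymmetric under swap", {
  set.seed(53)
  hm <- random_hapmat(16, 31, p = 0.5)
  hA <- toy_hapset(hm, sample_ids = sprintf("a%d", 1:8))
  hB <- toy_hapset(hm, sample_ids = sprintf("b%d", 1:8))
  scAB <- suppressWarnings(xpehh_scan(hA, hB))
  expect_true(all(scAB$raw[scAB$status == "ok"] == 0))

  hm2 <- random_hapmat(16, 31, p = 0.3)
  hC <- toy_hapset(hm2, sample_ids = sprintf("c%d", 1:8))
  scAC <- suppressWarnings(xpehh_scan(hA, hC))
  scCA <- suppressWarnings(xpehh_scan(hC, hA))
  expect_identical(scAC$status, scCA$status)
  ok <- scAC$status == "ok"
  expect_equal(scAC$raw[ok], -scCA$raw[ok], tolerance = 1e-14)
})

test_that("a homogeneous population gives positive XP-EHH matching a pair-counting oracle", {
  set.seed(54)
  m <- 31L
  one <- rbinom(m, 1, 0.5)
  A <- matrix(rep(one, each = 10), nrow = 10)   # one repeated haplotype
  B <- random_hapmat(10, m, p = 0.5)            # maximally diverse
  # give A minimal variation so sites are usable, B fully polymorphic
  A[1, c(2, 30)] <- 1L - A[1, c(2, 30)]
  hA <- toy_hapset(A, sample_ids = sprintf("a%d", 1:5))
  hB <- toy_hapset(B, sample_ids = sprintf("b%d", 1:5))
  # population A's EHH cannot decay below the cutoff on a finite
  # chromosome, so the shared stopping rule truncates every core: the
  # fixture is only scoreable with keep_truncated (integrate to the end)
  expect_true(all(suppressWarnings(xpehh_scan(hA, hB))$status ==
                    "skipped_truncated"))
  sc <- suppressWarnings(xpehh_scan(hA, hB, keep_truncated = TRUE))
  ok <- which(sc$status == "ok")
  expect_gt(length(ok), 0)
  expect_true(all(sc$raw[ok] > 0))
  # oracle at one interior ok SNP: joint walk, shared stopping boundary
  j <- ok[which.min(abs(ok - 16L))]
  cm <- hA$positions * 1e-6
  joint <- function(dirseq) {
    dist <- 0; eA <- 1; eB <- 1
    for (mk in dirseq) {
      ea <- oracle_ehh(A, 1:10, j, mk); eb <- oracle_ehh(B, 1:10, j, mk)
      dist <- c(dist, abs(cm[mk] - cm[j])); eA <- c(eA, ea); eB <- c(eB, eb)
      if (ea < 0.05 && eb < 0.05) break
    }
    trap <- function(e) sum(diff(dist) * (head(e, -1) + tail(e, -1)) / 2)
    c(trap(eA), trap(eB))
  }
  l <- joint(seq(j - 1, 1)); r <- joint(seq(j + 1, m))
  expect_equal(sc$raw[j], log((l[1] + r[1]) / (l[2] + r[2])),
               tolerance = 1e-12)
})

test_that("windowed means of standardized scores follow the abs/signed modes", {
  g <- build_window_grid(30000, 10000, 10000, min_snps = 2L)
  mk_scores <- function(pos, z) {
    structure(data.frame(variant = seq_along(pos), position = pos,
                         freq = 0.5, raw = z, z = z,
                         status = "ok", stringsAsFactors = FALSE),
              statistic = "iHS", context = "pop",
              class = c("SnpScores", "data.frame"))
  }
  sc <- mk_scores(c(1000, 5000, 12000, 15000, 22000, 25000, 28000),
                  c(-2, 2, 1, -3, 0.5, 1.5, -1))
  tr_abs <- window_mean_scores(sc, g, "abs")
  expect_equal(tr_abs$values, c(mean(c(2, 2)), mean(c(1, 3)),
                                mean(c(0.5, 1.5, 1))))
  tr_sgn <- window_mean_scores(sc, g, "signed")
  expect_equal(tr_sgn$values, c(0, -1, mean(c(0.5, 1.5, -1))))
  # windows below min_snps usable scores are unscored
  sc2 <- mk_scores(c(1000, 12000, 15000), c(1, 1, 1))
  expect_true(is.na(window_mean_scores(sc2, g, "abs")$values[1]))
})
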