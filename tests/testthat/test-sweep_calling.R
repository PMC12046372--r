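toy_track <- function(values, window_size = 1000L, chrom = "chr1") {
  n <- length(values)
  g <- build_window_grid(n * window_size, window_size, window_size,
                         min_snps = 0L, chrom = chrom)
  score_track("ZHp", "pop", g, values, standardized = TRUE)
}

test_that("the empirical tail rule selects the k most extreme windows with ties", {
  tr <- toy_track(as.numeric(1:1000))
  sel <- call_outlier_windows(tr, outlier_rule("ZHp", "high", q = 0.001))
  expect_identical(nrow(sel), 1L)
  expect_equal(sel$value, 1000)
  # low tail symmetric
  sel_lo <- call_outlier_windows(tr, outlier_rule("ZHp", "low", q = 0.001))
  expect_equal(sel_lo$value, 1)
  # boundary ties are all included
  v <- c(as.numeric(1:995), rep(1000, 5))
  sel_t <- call_outlier_windows(toy_track(v),
                                outlier_rule("ZHp", "high", q = 0.001))
  expect_identical(nrow(sel_t), 5L)
  # k = ceiling(q * N)
  sel_k <- call_outlier_windows(tr, outlier_rule("ZHp", "high", q = 0.0025))
  expect_identical(nrow(sel_k), 3L)   # ceiling(2.5) = 3
  expect_true(all(sel_k$value %in% 998:1000))
})

test_that("fixed thresholds override the empirical quantile", {
  v <- c(-4, -3.6, -3.5, -1, 0, 2, 3.4, 3.6, 5)
  tr <- toy_track(v)
  lo <- call_outlier_windows(tr, outlier_rule("ZHp", "low",
                                              threshold = -3.5))
  expect_equal(sort(lo$value), c(-4, -3.6, -3.5))   # <= is inclusive
  hi <- call_outlier_windows(tr, outlier_rule("XPEHH", "high",
                                              threshold = 3.5))
  expect_equal(sort(hi$value), c(3.6, 5))
  # undefined windows are ignored; empty track errors
  trna <- toy_track(c(NA, NA, NA))
  expect_error(call_outlier_windows(trna, outlier_rule("ZHp", "low")),
               "no defined windows")
})

test_that("merge_regions follows bedtools book-ended semantics", {
  w <- function(s, e, v = 1) data.frame(chrom = "chr1", start = s, end = e,
                                        value = v)
  # overlapping
  m1 <- merge_regions(rbind(w(1, 20000), w(10001, 30000)))
  expect_identical(nrow(m1), 1L)
  expect_identical(c(m1$start, m1$end), c(1L, 30000L))
  # book-ended: end + 1 == next start merges at max_gap = 0
  m2 <- merge_regions(rbind(w(1, 20000), w(20001, 40000)))
  expect_identical(nrow(m2), 1L)
  expect_identical(c(m2$start, m2$end), c(1L, 40000L))
  # separated by a true gap
  m3 <- merge_regions(rbind(w(1, 20000), w(30001, 50000)))
  expect_identical(nrow(m3), 2L)
  # gap bridged when max_gap covers it
  m4 <- merge_regions(rbind(w(1, 20000), w(30001, 50000)), max_gap = 10000L)
  expect_identical(nrow(m4), 1L)
  # peak score and window count aggregate; low tail takes the minimum
  wins <- rbind(w(1, 20000, -2), w(10001, 30000, -5), w(40001, 60000, -1))
  m5 <- merge_regions(wins, tail = "low", method = "ZHp", context = "p")
  expect_equal(m5$peak_score, c(-5, -1))
  expect_identical(m5$n_windows, c(2L, 1L))
  # idempotence: merging merged regions changes nothing
  again <- merge_regions(data.frame(chrom = m5$chrom, start = m5$start,
                                    end = m5$end, value = m5$peak_score),
                         tail = "low")
  expect_identical(again$start, m5$start)
  expect_identical(again$end, m5$end)
})

test_that("intersect_contexts matches a per-base support oracle", {
  rs <- function(s, e, method = "ZHp", context = "p")
    data.frame(chrom = "chr1", start = s, end = e, method = method,
               tail = "low", context = context, peak_score = 0,
               n_windows = 1L)
  sets <- list(rs(c(1, 120), c(100, 160)),
               rs(50, 150, context = "q"),
               rs(c(40, 90), c(60, 130), method = "ZFST"))
  cov <- oracle_support(sets, 200)
  for (k in 1:3) {
    got <- intersect_contexts(sets, "k_of_n", k = k)
    want <- integer(200)
    for (i in seq_len(nrow(got))) want[got$start[i]:got$end[i]] <- 1L
    expect_identical(want, as.integer(cov >= k))
  }
  # union = k=1, intersection = k=n; union covers intersection
  u <- intersect_contexts(sets, "union")
  i3 <- intersect_contexts(sets, "intersection")
  expect_identical(u, intersect_contexts(sets, "k_of_n", k = 1))
  expect_identical(i3, intersect_contexts(sets, "k_of_n", k = 3))
  # support labels carry the contributing sets
  two <- intersect_contexts(list(rs(1, 100), rs(1, 100, context = "q")),
                            "intersection")
  expect_identical(two$n_support, 2L)
  expect_match(two$support, "ZHp:p,ZHp:q")
  expect_error(intersect_contexts(list()), "empty")
  # simple interval algebra: (1-100) n (50-150) = (50-100)
  ab <- intersect_contexts(list(rs(1, 100), rs(50, 150, context = "q")),
                           "intersection")
  expect_identical(c(ab$start, ab$end), c(50L, 100L))
})

test_that("gene overlap annotation equals a brute-force double loop", {
  reg <- data.frame(chrom = "chr1", start = 1000L, end = 2000L)
  genes1 <- data.frame(gene_id = "g1", gene_name = "g1", chrom = "chr1",
                       start = 1500L, end = 3000L, strand = "+")
  expect_identical(annotate_genes(reg, genes1)$gene_id, "g1")
  genes2 <- transform(genes1, start = 2001L)   # adjacent, no shared bp
  expect_true(is.na(annotate_genes(reg, genes2)$gene_id))
  # gene fully containing a region counts
  genes3 <- transform(genes1, start = 1L, end = 9999L)
  expect_identical(annotate_genes(reg, genes3)$gene_id, "g1")

  set.seed(71)
  regions <- data.frame(chrom = "chr1",
                        start = sort(sample.int(5e4, 10)) * 10L)
  regions$end <- regions$start + 5000L
  genes <- random_genes(6e5, density_per_mb = 40, seed = 72)
  got <- annotate_genes(regions, genes)
  for (i in seq_len(nrow(regions))) {
    hits <- character(0)
    for (j in seq_len(nrow(genes)))
      if (genes$start[j] <= regions$end[i] &&
          genes$end[j] >= regions$start[i])
        hits <- c(hits, genes$gene_id[j])
    mine <- got$gene_id[got$region_id == i]
    if (length(hits)) expect_identical(sort(mine), sort(hits))
    else expect_true(is.na(mine))
  }
  # chromosome mismatch warns
  regZ <- data.frame(chrom = "chrZ", start = 1L, end = 10L)
  expect_warning(annotate_genes(regZ, genes), "absent")
})
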