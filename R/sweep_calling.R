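# From standardized tracks to candidate sweep regions: extreme-percentile
# outlier windows, bedtools-style consolidation, cross-context
# intersection and gene-overlap annotation.

#' Outlier rule for a scan statistic
#'
#' `q` is the tail fraction of the empirical distribution (default 0.001,
#' i.e. the extreme 0.1 percent of scored windows). A fixed `threshold`
#' overrides the empirical quantile, as used for report filters (e.g.
#' ZHp <= -3.5, iHS >= 6.5, ZFST > 4, XP-EHH > 3.5).
#'
#' @param method Statistic label (`"ZHp"`, `"iHS"`, `"ZFST"`, `"XPEHH"`).
#' @param tail `"high"` or `"low"`.
#' @param q Tail fraction, 0 < q < 0.5.
#' @param threshold Optional fixed threshold override.
#' @return An `OutlierRule`.
#' @export
outlier_rule <- function(method, tail = c("high", "low"), q = 0.001,
                         threshold = NULL) {
  tail <- match.arg(tail)
  stopifnot(q > 0, q < 0.5)
  structure(list(method = method, tail = tail, q = q, threshold = threshold),
            class = "OutlierRule")
}

#' Select extreme-percentile outlier windows from a track
#'
#' With N defined windows and `k = max(1, ceiling(q * N))`, the high tail
#' selects every window whose value is `>=` the k-th largest defined
#' value (boundary ties all included, deterministically); the low tail is
#' symmetric. A fixed `threshold` in the rule replaces the empirical
#' boundary (`>=` for high, `<=` for low).
#'
#' @param track A `ScoreTrack` (standardized, or raw with a fixed
#'   threshold).
#' @param rule An [outlier_rule()].
#' @return Data frame of selected windows: `chrom`, `start`, `end`,
#'   `value`, sorted by position, with attributes `method`, `tail`,
#'   `context`.
#' @export
call_outlier_windows <- function(track, rule) {
  stopifnot(inherits(track, "ScoreTrack"), inherits(rule, "OutlierRule"))
  df <- as.data.frame(track)
  def <- !is.na(df$value)
  if (!any(def)) stop("track has no defined windows")
  N <- sum(def)
  if (is.null(rule$threshold) && N < 1 / rule$q)
    warning("only ", N, " defined windows for tail fraction q = ", rule$q,
            "; the empirical quantile is coarse")
  if (!is.null(rule$threshold)) {
    boundary <- rule$threshold
  } else {
    k <- max(1L, ceiling(rule$q * N))
    v <- sort(df$value[def], decreasing = (rule$tail == "high"))
    boundary <- v[k]
  }
  sel <- if (rule$tail == "high") def & df$value >= boundary
         else def & df$value <= boundary
  out <- df[sel, c("chrom", "start", "end", "value")]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "method") <- rule$method
  attr(out, "tail") <- rule$tail
  attr(out, "context") <- track$context
  out
}

#' Consolidate outlier windows into candidate regions
#'
#' Intervals whose gap is `<= max_gap` are merged; in 1-based inclusive
#' coordinates a gap of 0 means book-ended intervals (`end + 1 == next
#' start`), which merge under the default, matching bedtools' default
#' merge distance. The peak score is the most extreme member value (max
#' for the high tail, min for the low tail).
#'
#' @param windows Output of [call_outlier_windows()] (or any data frame
#'   with `chrom`, `start`, `end`, `value` plus `method`/`tail`/`context`
#'   attributes or arguments).
#' @param max_gap Maximum gap (bp) merged across (default 0).
#' @param method,tail,context Metadata overrides; default from
#'   attributes.
#' @return A `CandidateRegions` data frame: `chrom`, `start`, `end`,
#'   `method`, `tail`, `context`, `peak_score`, `n_windows`.
#' @export
merge_regions <- function(windows, max_gap = 0L, method = NULL, tail = NULL,
                          context = NULL) {
  method <- method %||% attr(windows, "method") %||% "score"
  tail <- tail %||% attr(windows, "tail") %||% "high"
  context <- context %||% attr(windows, "context") %||% ""
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), method = character(),
                      tail = character(), context = character(),
                      peak_score = numeric(), n_windows = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(windows) == 0L)
    return(structure(empty, class = c("CandidateRegions", "data.frame")))
  out <- do.call(rbind, lapply(split(windows, windows$chrom), function(d) {
    ir <- IRanges::IRanges(start = d$start, end = d$end)
    red <- IRanges::reduce(ir, min.gapwidth = max_gap + 1L)
    ov <- IRanges::findOverlaps(ir, red)
    peak <- tapply(d$value[S4Vectors::queryHits(ov)],
                   S4Vectors::subjectHits(ov),
                   if (tail == "high") max else min)
    cnt <- tapply(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov),
                  length)
    data.frame(chrom = d$chrom[1L], start = IRanges::start(red),
               end = IRanges::end(red), method = method, tail = tail,
               context = context, peak_score = as.numeric(peak),
               n_windows = as.integer(cnt), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("CandidateRegions", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Combine candidate-region sets across methods or contrasts
#'
#' Interval algebra over one genome coordinate system: `"union"` keeps
#' every base covered by at least one set, `"intersection"` every base
#' covered by all sets, and `"k_of_n"` every base covered by at least `k`
#' sets. Each output region carries the supporting (method, context)
#' labels of the sets overlapping it and their count.
#'
#' @param regionsets Non-empty list of `CandidateRegions` data frames.
#' @param mode `"union"`, `"intersection"` or `"k_of_n"`.
#' @param k Minimum support for `"k_of_n"`.
#' @return Data frame: `chrom`, `start`, `end`, `support`
#'   (comma-separated `method:context` labels), `n_support`.
#' @export
intersect_contexts <- function(regionsets,
                               mode = c("union", "intersection", "k_of_n"),
                               k = 2L) {
  mode <- match.arg(mode)
  if (!length(regionsets)) stop("empty list of region sets")
  n <- length(regionsets)
  k <- switch(mode, union = 1L, intersection = n, k_of_n = as.integer(k))
  labels <- vapply(seq_len(n), function(i) {
    d <- regionsets[[i]]
    m <- if (nrow(d)) paste0(d$method[1L], ":", d$context[1L])
         else paste0("set", i)
    m
  }, character(1))
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), support = character(),
                      n_support = integer(), stringsAsFactors = FALSE)
  chroms <- sort(unique(unlist(lapply(regionsets, function(d) d$chrom))))
  if (!length(chroms)) return(empty)
  per_chrom <- lapply(chroms, function(ch) {
    irl <- lapply(regionsets, function(d) {
      d <- d[d$chrom == ch, , drop = FALSE]
      IRanges::reduce(IRanges::IRanges(d$start, d$end))
    })
    width <- max(1L, max(vapply(irl, function(ir)
      if (length(ir)) max(IRanges::end(ir)) else 0L, numeric(1))))
    cov <- Reduce(`+`, lapply(irl, IRanges::coverage, width = width))
    sl <- IRanges::slice(cov, lower = k, rangesOnly = TRUE)
    if (length(sl) == 0L) return(empty)
    support <- vapply(seq_along(sl), function(i) {
      hit <- vapply(irl, function(ir)
        length(IRanges::findOverlaps(sl[i], ir)) > 0L, logical(1))
      paste(labels[hit], collapse = ",")
    }, character(1))
    data.frame(chrom = ch, start = IRanges::start(sl),
               end = IRanges::end(sl), support = support,
               n_support = lengths(strsplit(support, ",")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_chrom)
  rownames(out) <- NULL
  out
}

#' Annotate candidate regions with overlapping genes
#'
#' A gene overlaps a region iff the 1-based inclusive intervals share at
#' least one bp (genes fully containing a region count). Regions without
#' any overlapping gene are reported with `NA` gene columns.
#'
#' @param regions `CandidateRegions` (or any data frame with `chrom`,
#'   `start`, `end`).
#' @param genes Gene table from [read_gene_annotation()].
#' @return Data frame with one row per (region, gene) pair plus one row
#'   per gene-less region: region columns, `gene_id`, `gene_name`,
#'   `gene_start`, `gene_end`.
#' @export
annotate_genes <- function(regions, genes) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)),
            all(c("chrom", "start", "end", "gene_id") %in% names(genes)))
  if (nrow(regions) && nrow(genes)) {
    unmatched <- setdiff(unique(regions$chrom), unique(genes$chrom))
    if (length(unmatched))
      warning(length(unmatched), " region chromosome(s) absent from the ",
              "gene annotation: ", paste(unmatched, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, , drop = FALSE]
    hit <- genes$chrom == r$chrom & genes$start <= r$end &
      genes$end >= r$start
    base <- data.frame(region_id = i, r[, c("chrom", "start", "end")],
                       row.names = NULL, stringsAsFactors = FALSE)
    if (!any(hit))
      return(cbind(base, gene_id = NA_character_,
                   gene_name = NA_character_, gene_start = NA_integer_,
                   gene_end = NA_integer_))
    g <- genes[hit, , drop = FALSE]
    cbind(base[rep(1L, nrow(g)), , drop = FALSE],
          gene_id = g$gene_id, gene_name = g$gene_name,
          gene_start = g$start, gene_end = g$end, row.names = NULL)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region_id = integer(), chrom = character(),
               start = integer(), end = integer(), gene_id = character(),
               gene_name = character(), gene_start = integer(),
               gene_end = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Export candidate regions as BED
#'
#' Converts the internal 1-based inclusive intervals to BED's 0-based
#' half-open convention.
#'
#' @param regions `CandidateRegions`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(regions))
    writeLines(paste(regions$chrom, regions$start - 1L, regions$end,
                     paste0(regions$method, "_", regions$context),
                     sprintf("%.6g", regions$peak_score),
                     sep = "\t"), con)
  invisible(path)
}
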