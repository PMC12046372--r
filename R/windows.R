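# Sliding-window grid shared by all four scan statistics.

#' Build a sliding-window grid
#'
#' Windows are anchored at position 1 and advance by `step`:
#' starts 1, 1 + step, 1 + 2*step, ... Only windows fully contained in
#' `[1, chrom_length]` are emitted unless `include_partial = TRUE`, which
#' appends one final truncated window. Coordinates are 1-based inclusive.
#' The default geometry (20-kb windows, 10-kb step) makes every interior
#' SNP a member of exactly two windows.
#'
#' @param chrom_length Chromosome length in bp.
#' @param window_size Window size in bp (default 20000).
#' @param step Step in bp (default 10000).
#' @param min_snps Minimum SNPs for a window to be scored (default 20).
#' @param chrom Chromosome name carried by the grid.
#' @param include_partial Emit a final truncated window.
#' @return A `WindowGrid`.
#' @export
build_window_grid <- function(chrom_length, window_size = 20000L,
                              step = 10000L, min_snps = 20L, chrom = "chr",
                              include_partial = FALSE) {
  stopifnot(window_size >= step, step >= 1L)
  chrom_length <- as.numeric(chrom_length)
  if (chrom_length < window_size) {
    warning("chromosome shorter than one window: empty grid")
    starts <- integer(0)
  } else {
    n_full <- floor((chrom_length - window_size) / step) + 1
    starts <- 1L + step * (seq_len(n_full) - 1L)
  }
  ends <- pmin(starts + window_size - 1L, chrom_length)
  if (include_partial && length(starts) &&
      max(ends) < chrom_length) {
    s <- max(starts) + step
    if (s <= chrom_length) {
      starts <- c(starts, s)
      ends <- c(ends, as.integer(chrom_length))
    }
  }
  structure(list(chrom = chrom, chrom_length = chrom_length,
                 window_size = as.integer(window_size),
                 step = as.integer(step), min_snps = as.integer(min_snps),
                 windows = data.frame(start = as.integer(starts),
                                      end = as.integer(ends)),
                 snp_index = NULL, n_snps = NULL, scored = NULL),
            class = "WindowGrid")
}

#' Number of windows in a grid
#' @param grid A `WindowGrid`.
#' @return Integer.
#' @export
n_windows <- function(grid) nrow(grid$windows)

#' @export
print.WindowGrid <- function(x, ...) {
  cat(sprintf("WindowGrid: %s, %d windows of %d bp, step %d bp\n",
              x$chrom, n_windows(x), x$window_size, x$step))
  if (!is.null(x$scored))
    cat(sprintf("  %d scored (>= %d SNPs), %d sparse\n",
                sum(x$scored), x$min_snps, sum(!x$scored)))
  invisible(x)
}

#' Assign SNPs of a HaplotypeSet to grid windows
#'
#' Membership is inclusive on both window ends. Windows with fewer than
#' `min_snps` members stay in the grid but are flagged unscored; only
#' scored windows receive statistic values and enter standardization.
#'
#' @param grid A `WindowGrid`.
#' @param h A `HaplotypeSet` on the same chromosome.
#' @return The grid with `snp_index`, `n_snps` and `scored` filled in.
#' @export
assign_snps <- function(grid, h) {
  stopifnot(inherits(grid, "WindowGrid"), inherits(h, "HaplotypeSet"))
  if (n_windows(grid) && !identical(grid$chrom, h$chrom))
    warning("grid chromosome (", grid$chrom, ") differs from data (",
            h$chrom, ")")
  pos <- h$positions
  # positions are sorted: each window's members are a contiguous index run
  lo <- findInterval(grid$windows$start - 0.5, pos) + 1L
  hi <- findInterval(grid$windows$end + 0.5, pos)
  grid$snp_index <- lapply(seq_len(n_windows(grid)), function(w)
    if (hi[w] >= lo[w]) lo[w]:hi[w] else integer(0))
  grid$n_snps <- hi - lo + 1L
  grid$n_snps[grid$n_snps < 0L] <- 0L
  grid$scored <- grid$n_snps >= grid$min_snps
  grid
}

#' Export a window grid as a BED data frame
#'
#' BED uses 0-based half-open coordinates; the conversion is exact and
#' invertible (`start - 1`, `end` unchanged).
#'
#' @param grid A `WindowGrid`.
#' @return Data frame with `chrom`, `start` (0-based), `end`.
#' @export
grid_as_bed <- function(grid) {
  data.frame(chrom = grid$chrom, start = grid$windows$start - 1L,
             end = grid$windows$end)
}
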