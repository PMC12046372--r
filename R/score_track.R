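# ScoreTrack: per-window values of one statistic for one population or
# population pair, plus the genome-wide Z-standardization used by every
# scan.

#' Construct a ScoreTrack
#'
#' @param statistic Statistic name (`"Hp"`, `"ZHp"`, `"FST"`, `"ZFST"`,
#'   `"iHS_win"`, `"XPEHH_win"`, ...).
#' @param context Population label, or `c(popA, popB)` for pairwise
#'   statistics.
#' @param grid The `WindowGrid` the values live on (SNPs assigned).
#' @param values Numeric vector, one per window; `NA` on unscored or
#'   undefined windows.
#' @param n_snps Per-window count of SNPs that produced the value
#'   (defaults to the grid's member counts).
#' @param standardized Whether `values` are Z-standardized.
#' @return A `ScoreTrack`.
#' @export
score_track <- function(statistic, context, grid, values, n_snps = NULL,
                        standardized = FALSE) {
  stopifnot(inherits(grid, "WindowGrid"), length(values) == n_windows(grid))
  if (is.null(n_snps))
    n_snps <- grid$n_snps %||% rep(NA_integer_, n_windows(grid))
  structure(list(statistic = statistic,
                 context = paste(context, collapse = "~"),
                 grid = grid, values = as.numeric(values),
                 n_snps = n_snps, standardized = isTRUE(standardized)),
            class = "ScoreTrack")
}

#' @export
print.ScoreTrack <- function(x, ...) {
  def <- sum(!is.na(x$values))
  cat(sprintf("ScoreTrack %s [%s]: %d/%d windows scored%s\n",
              x$statistic, x$context, def, length(x$values),
              if (x$standardized) " (standardized)" else ""))
  invisible(x)
}

#' @method as.data.frame ScoreTrack
#' @export
as.data.frame.ScoreTrack <- function(x, ...) {
  data.frame(chrom = x$grid$chrom, start = x$grid$windows$start,
             end = x$grid$windows$end, n_snps = x$n_snps,
             value = x$values, stringsAsFactors = FALSE)
}

#' Z-standardize a ScoreTrack genome-wide
#'
#' `z_w = (x_w - mean) / sd`, with mean and sd taken over all defined
#' (scored) windows of the track and the population form of the sd
#' (denominator N, ddof 0). Undefined windows stay undefined.
#'
#' @param track A `ScoreTrack`.
#' @param statistic Name for the standardized track; default prefixes
#'   `"Z"` (`Hp -> ZHp`, `FST -> ZFST`).
#' @return A standardized `ScoreTrack`.
#' @export
z_standardize <- function(track, statistic = NULL) {
  stopifnot(inherits(track, "ScoreTrack"))
  x <- track$values
  def <- !is.na(x)
  if (sum(def) < 2L)
    stop("track ", track$statistic, " [", track$context,
         "]: need >= 2 defined windows to standardize")
  mu <- mean(x[def])
  sdp <- sqrt(mean((x[def] - mu)^2))
  if (sdp == 0)
    stop("track ", track$statistic, " [", track$context,
         "]: zero standard deviation, cannot standardize")
  z <- (x - mu) / sdp
  if (is.null(statistic))
    statistic <- if (track$statistic %in% c("Hp", "FST"))
      paste0("Z", track$statistic) else paste0("Z_", track$statistic)
  out <- track
  out$statistic <- statistic
  out$values <- z
  out$standardized <- TRUE
  out
}

#' Write a ScoreTrack as a tab-delimited file
#'
#' Columns: chrom, start, end, n_snps, value. Values are printed with
#' `%.6g` so output bytes are deterministic.
#'
#' @param track A `ScoreTrack`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  df <- as.data.frame(track)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("chrom", "start", "end", "n_snps", track$statistic),
                   collapse = "\t"), con)
  writeLines(paste(df$chrom, df$start, df$end, df$n_snps,
                   ifelse(is.na(df$value), "NA", sprintf("%.6g", df$value)),
                   sep = "\t"), con)
  invisible(path)
}

#' Manhattan-style plot of a ScoreTrack
#'
#' Plots window midpoints against values with base graphics; intended for
#' quick inspection of scan output.
#'
#' @param track A `ScoreTrack`.
#' @param threshold Optional horizontal threshold line.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_track <- function(track, threshold = NULL, ...) {
  df <- as.data.frame(track)
  mid <- (df$start + df$end) / 2
  graphics::plot(mid, df$value, pch = 16, cex = 0.5,
                 xlab = paste0("position on ", track$grid$chrom, " (bp)"),
                 ylab = track$statistic,
                 main = paste(track$statistic, track$context), ...)
  if (!is.null(threshold))
    graphics::abline(h = threshold, col = "red", lty = 2)
  invisible(NULL)
}
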