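# Interval-feature statistics: quartile binning of intervals by length or
# CpG density against a signal column, overlap fractions between interval
# sets, and rank correlation — the analyses relating CGI properties to
# ChIP read counts.

.check_intervals <- function(x, need = character(0)) {
  if (!is.data.frame(x)) stop("intervals must be a data.frame")
  miss <- setdiff(c("chrom", "start", "end", need), names(x))
  if (length(miss))
    stop("interval table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(x) && any(x$end <= x$start)) stop("intervals require end > start")
  x
}

#' Quartile-bin intervals by a feature and summarize their signal
#'
#' Ranks intervals by `feature` (ties broken by stable input order, lower
#' ranks filling lower bins) and splits them into four equal-count bins,
#' reporting each bin's mean and median signal.  With a feature positively
#' related to the signal — as CGI length and CpG density are to H3K4me3 and
#' H3K27me3 read counts at bivalent islands — bin means increase from bin 1
#' to bin 4.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`, the
#'   chosen feature column and `signal`.  A `length` column is derived from
#'   the coordinates when absent.
#' @param feature `"length"` or `"cpg_density"` (or any numeric column
#'   name present in `intervals`).
#' @param signal_col name of the signal column (default `"signal"`).
#' @return data.frame of class `bin_summary` with one row per bin:
#'   `bin`, `feature_min`, `feature_max`, `n`, `mean_signal`,
#'   `median_signal`; attribute `feature`.
#' @export
quartile_bin <- function(intervals, feature = c("length", "cpg_density"),
                         signal_col = "signal") {
  feature <- if (is.character(feature) && length(feature) == 1L &&
                 !feature %in% c("length", "cpg_density")) feature
             else match.arg(feature)
  if (feature == "length" && !"length" %in% names(intervals))
    intervals$length <- intervals$end - intervals$start
  intervals <- .check_intervals(intervals, c(feature, signal_col))
  n <- nrow(intervals)
  if (n < 4L) stop("quartile binning requires at least 4 intervals")
  ord <- order(intervals[[feature]])          # stable: preserves input order on ties
  bin <- ceiling(seq_len(n) * 4 / n)          # equal-count bins, sizes differ <= 1
  f <- intervals[[feature]][ord]
  s <- intervals[[signal_col]][ord]
  out <- do.call(rbind, lapply(1:4, function(b) {
    i <- bin == b
    data.frame(bin = b, feature_min = min(f[i]), feature_max = max(f[i]),
               n = sum(i), mean_signal = mean(s[i]),
               median_signal = stats::median(s[i]))
  }))
  attr(out, "feature") <- feature
  class(out) <- c("bin_summary", "data.frame")
  out
}

#' Fraction of query intervals overlapping a subject set
#'
#' The fraction of query intervals sharing at least 1 bp with any subject
#' interval on the same chromosome — the "coincidence" statistic used to
#' ask what proportion of bivalent promoters fall on CGIs.
#'
#' @param query,subject interval data.frames with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return numeric fraction in \[0, 1\].
#' @export
overlap_fraction <- function(query, subject) {
  query <- .check_intervals(query)
  subject <- .check_intervals(subject)
  if (nrow(query) == 0L)
    stop("overlap fraction is undefined for an empty query set")
  if (nrow(subject) == 0L) return(0)
  gq <- GenomicRanges::GRanges(query$chrom,
                               IRanges::IRanges(query$start + 1L, query$end))
  gs <- GenomicRanges::GRanges(subject$chrom,
                               IRanges::IRanges(subject$start + 1L,
                                                subject$end))
  # disjoint chromosome sets are a legitimate zero-overlap case, not a
  # seqlevel mismatch worth warning about
  mean(suppressWarnings(IRanges::overlapsAny(gq, gs)))
}

#' Spearman rank correlation between an interval feature and signal
#'
#' @param intervals interval data.frame.
#' @param feature numeric feature column name.
#' @param signal_col signal column name.
#' @return Spearman correlation in \[-1, 1\].
#' @export
rank_correlation <- function(intervals, feature = "cpg_density",
                             signal_col = "signal") {
  intervals <- .check_intervals(intervals, c(feature, signal_col))
  if (nrow(intervals) < 3L) stop("rank correlation requires >= 3 intervals")
  f <- intervals[[feature]]; s <- intervals[[signal_col]]
  if (stats::sd(f) == 0 || stats::sd(s) == 0)
    stop("rank correlation undefined: zero variance")
  stats::cor(f, s, method = "spearman")
}
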