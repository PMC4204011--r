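# Composition metrics.  All metrics exclude N bases: N never counts as G or
# C, never forms part of a CpG, and is removed from the effective length.

#' G+C fraction of a DNA sequence
#'
#' Fraction of non-N bases that are G or C.  N bases are excluded from both
#' numerator and denominator.
#'
#' @param seq a DNA sequence (character scalar or Biostrings object).
#' @return numeric fraction in \[0, 1\].
#' @examples
#' gc_fraction("ACGT")  # 0.5
#' @export
gc_fraction <- function(seq) {
  r <- charToRaw(.as_seq(seq))
  eff <- sum(r != .RAW_N)
  if (eff == 0L)
    stop("undefined composition: sequence is empty or all-N")
  sum(r == .RAW_G | r == .RAW_C) / eff
}

#' Count CpG dinucleotides
#'
#' Number of positions carrying C immediately followed by G, scanned on the
#' plus strand only.  The CpG site is self-complementary, so plus-strand
#' counting covers the duplex without double-counting.
#'
#' @inheritParams gc_fraction
#' @return non-negative integer; 0 for sequences shorter than 2 bases.
#' @examples
#' count_cpg("CGCG")  # 2
#' count_cpg("GCGC")  # 1
#' @export
count_cpg <- function(seq) {
  r <- charToRaw(.as_seq(seq))
  n <- length(r)
  if (n < 2L) return(0L)
  sum(r[-n] == .RAW_C & r[-1L] == .RAW_G)
}

#' 0-based positions of CpG dinucleotides
#' @inheritParams gc_fraction
#' @return integer vector of 0-based positions of each CpG's C.
#' @export
cpg_positions <- function(seq) {
  r <- charToRaw(.as_seq(seq))
  n <- length(r)
  if (n < 2L) return(integer(0))
  which(r[-n] == .RAW_C & r[-1L] == .RAW_G) - 1L
}

#' CpG density per 100 bp
#'
#' @inheritParams gc_fraction
#' @return CpGs per 100 bp of effective (non-N) length.
#' @export
cpg_per_100bp <- function(seq) {
  seq <- .as_seq(seq)
  eff <- sum(charToRaw(seq) != .RAW_N)
  if (eff == 0L) stop("undefined composition: sequence is empty or all-N")
  100 * count_cpg(seq) / eff
}

#' Observed/expected CpG ratio
#'
#' The CpG count normalized by the count expected from the sequence's C and
#' G frequencies (Gardiner-Garden & Frommer convention):
#' \deqn{o/e = \frac{n_{CpG} \times L}{n_C \times n_G}}
#' with \eqn{L} the effective (non-N) length.  This corrects raw CpG density
#' for overall base composition, so A+T-rich sequences with CGI-level CpG
#' density score a high o/e.
#'
#' @inheritParams gc_fraction
#' @return non-negative numeric.
#' @examples
#' cpg_obs_exp("CCGG")  # 1
#' @export
cpg_obs_exp <- function(seq) {
  seq <- .as_seq(seq)
  r <- charToRaw(seq)
  n_c <- sum(r == .RAW_C)
  n_g <- sum(r == .RAW_G)
  if (n_c == 0L || n_g == 0L)
    stop("undefined o/e ratio: sequence has no C or no G")
  eff <- sum(r != .RAW_N)
  count_cpg(seq) * eff / (n_c * n_g)
}

#' Full composition summary of a sequence
#'
#' @inheritParams gc_fraction
#' @param id optional sequence label.
#' @return one-row data.frame with columns `id`, `length`,
#'   `effective_length` (non-N bases), `gc_fraction`, `n_cpg`,
#'   `cpg_per_100bp` and `cpg_obs_exp` (NA when no C or no G).
#' @examples
#' composition_stats("ACGTACGT")
#' @export
composition_stats <- function(seq, id = NA_character_) {
  seq <- .as_seq(seq)
  r <- charToRaw(seq)
  eff <- sum(r != .RAW_N)
  if (eff == 0L) stop("undefined composition: sequence is empty or all-N")
  n_c <- sum(r == .RAW_C)
  n_g <- sum(r == .RAW_G)
  ncpg <- count_cpg(seq)
  data.frame(
    id = id,
    length = length(r),
    effective_length = eff,
    gc_fraction = (n_c + n_g) / eff,
    n_cpg = ncpg,
    cpg_per_100bp = 100 * ncpg / eff,
    cpg_obs_exp = if (n_c > 0L && n_g > 0L) ncpg * eff / (n_c * n_g) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Sliding-window composition profile
#'
#' Computes per-window %G+C and CpG count along a sequence, the quantities
#' plotted in construct composition profiles (a %G+C track over a
#' CpGs-per-window track).  A CpG whose C is the window's final base (the G
#' falls in the next window) is assigned to the window containing the C.
#'
#' @inheritParams gc_fraction
#' @param window_size window width in bases (>= 2).
#' @param step offset between successive window starts (>= 1); `step ==
#'   window_size` gives non-overlapping tiling.
#' @param id optional sequence label stored on the result.
#' @return data.frame of class `cgi_profile` with columns `start`, `end`
#'   (0-based half-open), `gc_percent` and `cpg_count`, plus attributes
#'   `window_size`, `step` and `seq_id`.  Windows extending past the end of
#'   the sequence are not emitted; if the sequence is shorter than one
#'   window the profile is empty (with a warning).
#' @examples
#' sliding_profile(strrep("ACGT", 100), window_size = 100, step = 100)
#' @export
sliding_profile <- function(seq, window_size = 100L, step = window_size,
                            id = NA_character_) {
  seq <- .as_seq(seq)
  window_size <- as.integer(window_size)
  step <- as.integer(step)
  if (window_size < 2L) stop("window_size must be >= 2")
  if (step < 1L) stop("step must be >= 1")
  r <- charToRaw(seq)
  n <- length(r)
  if (window_size > n) {
    warning("window_size exceeds sequence length; empty profile")
    starts <- integer(0)
  } else {
    starts <- seq.int(0L, n - window_size, by = step)
  }
  if (length(starts) == 0L) {
    out <- data.frame(start = integer(0), end = integer(0),
                      gc_percent = numeric(0), cpg_count = integer(0))
  } else {
    # cumulative counts make every window an O(1) difference
    cum_gc <- c(0L, cumsum(r == .RAW_G | r == .RAW_C))
    is_cpg_c <- c(r[-n] == .RAW_C & r[-1L] == .RAW_G, FALSE)
    cum_cpg <- c(0L, cumsum(is_cpg_c))
    e1 <- starts + window_size             # 1-based last base
    gc <- cum_gc[e1 + 1L] - cum_gc[starts + 1L]
    cpg <- cum_cpg[e1 + 1L] - cum_cpg[starts + 1L]
    out <- data.frame(start = starts, end = starts + window_size,
                      gc_percent = 100 * gc / window_size,
                      cpg_count = as.integer(cpg))
  }
  attr(out, "window_size") <- window_size
  attr(out, "step") <- step
  attr(out, "seq_id") <- id
  class(out) <- c("cgi_profile", "data.frame")
  out
}

#' Plot a composition profile
#'
#' Two stacked panels: %G+C per window above, CpGs per window below — the
#' standard display for comparing constructs of differing base composition.
#'
#' @param x a `cgi_profile` from [sliding_profile()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @method plot cgi_profile
#' @export
plot.cgi_profile <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  mid <- (x$start + x$end) / 2
  graphics::plot(mid, x$gc_percent, type = "l", col = "darkblue",
                 xlab = "position (bp)", ylab = "% G+C", ylim = c(0, 100), ...)
  graphics::abline(h = 50, lty = 3)
  graphics::plot(mid, x$cpg_count, type = "h", col = "firebrick",
                 xlab = "position (bp)",
                 ylab = sprintf("CpGs / %d bp", attr(x, "window_size")), ...)
  invisible(x)
}

#' Classify a sequence as CpG-island-like
#'
#' The standard length / G+C / observed-expected rule: TRUE iff the sequence
#' is at least `min_length` bases, has `gc_fraction >= min_gc` and
#' `cpg_obs_exp >= min_oe`.  Defaults (200 bp, 0.50, 0.6) are the classical
#' CGI thresholds.
#'
#' @inheritParams gc_fraction
#' @param min_length minimum length in bases.
#' @param min_gc minimum G+C fraction.
#' @param min_oe minimum observed/expected CpG ratio.
#' @return logical scalar.  An undefined o/e (no C or no G) yields FALSE
#'   with a warning.
#' @export
classify_cgi <- function(seq, min_length = 200L, min_gc = 0.5, min_oe = 0.6) {
  if (min_length <= 0 || min_gc <= 0 || min_oe <= 0)
    stop("thresholds must be positive")
  seq <- .as_seq(seq)
  if (nchar(seq) < min_length) return(FALSE)
  if (gc_fraction(seq) < min_gc) return(FALSE)
  oe <- tryCatch(cpg_obs_exp(seq), error = function(e) NA_real_)
  if (is.na(oe)) {
    warning("o/e undefined (no C or no G); classifying as non-CGI")
    return(FALSE)
  }
  oe >= min_oe
}
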