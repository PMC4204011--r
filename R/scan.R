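# Genome scanning: fixed-window tiling, per-window composition, and maximal
# blocks of adjoining windows passing composition criteria — the machinery
# used to search a genome for atypical composition domains (A+T-rich yet
# CpG-rich, or G+C-rich yet CpG-poor).

#' Tile a genome into fixed non-overlapping windows
#'
#' Each chromosome is divided into consecutive `window_size`-bp windows from
#' coordinate 0; a trailing partial window is dropped.  A CpG whose C is the
#' last base of a window (its G in the next window) is assigned to the
#' window containing the C.  Windows containing any N are flagged via
#' `has_n`.
#'
#' @param genome a named character vector of chromosome sequences, a
#'   [Biostrings::DNAStringSet], or a path to a FASTA file.
#' @param window_size window width in bases (default 100).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `gc_fraction`, `cpg_count`, `has_n`, sorted by
#'   (chrom, start); attribute `window_size`.
#' @examples
#' tile_windows(c(chr1 = strrep("CG", 125)), window_size = 100)
#' @export
tile_windows <- function(genome, window_size = 100L) {
  genome <- .read_genome_arg(genome)
  window_size <- as.integer(window_size)
  if (window_size < 2L) stop("window_size must be >= 2")
  per_chrom <- lapply(seq_along(genome), function(i) {
    r <- charToRaw(genome[[i]])
    n <- length(r)
    if (n < window_size) return(NULL)
    nwin <- n %/% window_size
    starts <- (seq_len(nwin) - 1L) * window_size
    cum_gc <- cumsum(r == .RAW_G | r == .RAW_C)
    cum_n <- cumsum(r == .RAW_N)
    is_cpg_c <- c(r[-n] == .RAW_C & r[-1L] == .RAW_G, FALSE)
    cum_cpg <- cumsum(is_cpg_c)
    e1 <- starts + window_size
    s0 <- c(0L, cum_gc[starts[-1L]])
    n0 <- c(0L, cum_n[starts[-1L]])
    c0 <- c(0L, cum_cpg[starts[-1L]])
    data.frame(
      chrom = names(genome)[i],
      start = starts, end = e1,
      gc_fraction = (cum_gc[e1] - s0) / window_size,
      cpg_count = as.integer(cum_cpg[e1] - c0),
      has_n = (cum_n[e1] - n0) > 0L,
      stringsAsFactors = FALSE)
  })
  per_chrom <- per_chrom[!vapply(per_chrom, is.null, logical(1))]
  out <- if (length(per_chrom))
    do.call(rbind, c(per_chrom, list(make.row.names = FALSE)))
  else
    data.frame(chrom = character(0), start = integer(0),
               end = integer(0), gc_fraction = numeric(0),
               cpg_count = integer(0), has_n = logical(0))
  attr(out, "window_size") <- window_size
  out
}

#' Scan criteria for composition-block detection
#'
#' A window passes when its composition falls inside every bound that is
#' set; windows containing N always fail.  Blocks are maximal runs of
#' consecutive passing windows on one chromosome whose total length reaches
#' `min_block_length`.
#'
#' @param window_size tiling width in bases.
#' @param gc_min,gc_max optional G+C-fraction bounds (inclusive).
#' @param cpg_min,cpg_max optional per-window CpG-count bounds (inclusive).
#' @param min_block_length minimum block length in bases (>= `window_size`).
#' @param label criteria name, used in BED output.
#' @return object of class `scan_criteria`.
#' @export
scan_criteria <- function(window_size = 100L, gc_min = NULL, gc_max = NULL,
                          cpg_min = NULL, cpg_max = NULL,
                          min_block_length = 1000L, label = "custom") {
  if (is.null(gc_min) && is.null(gc_max) && is.null(cpg_min) &&
      is.null(cpg_max))
    stop("at least one composition bound must be set")
  if (min_block_length < window_size)
    stop("min_block_length must be >= window_size")
  structure(list(window_size = as.integer(window_size), gc_min = gc_min,
                 gc_max = gc_max, cpg_min = cpg_min, cpg_max = cpg_max,
                 min_block_length = as.integer(min_block_length),
                 label = label),
            class = "scan_criteria")
}

.windows_pass <- function(windows, criteria) {
  pass <- !windows$has_n
  if (!is.null(criteria$gc_min)) pass <- pass & windows$gc_fraction >= criteria$gc_min
  if (!is.null(criteria$gc_max)) pass <- pass & windows$gc_fraction <= criteria$gc_max
  if (!is.null(criteria$cpg_min)) pass <- pass & windows$cpg_count >= criteria$cpg_min
  if (!is.null(criteria$cpg_max)) pass <- pass & windows$cpg_count <= criteria$cpg_max
  pass
}

#' Find maximal blocks of adjoining passing windows
#'
#' @param windows a window table from [tile_windows()] (must carry its
#'   `window_size` attribute or match `criteria$window_size`).
#' @param criteria a [scan_criteria()].
#' @return data.frame with columns `chrom`, `start`, `end`, `n_windows`,
#'   `mean_gc`, `mean_cpg_per_100bp`, one row per block, disjoint and
#'   sorted; attribute `criteria`.
#' @export
find_blocks <- function(windows, criteria) {
  if (!inherits(criteria, "scan_criteria")) stop("criteria must be scan_criteria")
  ws <- attr(windows, "window_size")
  if (is.null(ws)) ws <- criteria$window_size
  windows <- windows[order(windows$chrom, windows$start), , drop = FALSE]
  .blocks_from_mask(windows, .windows_pass(windows, criteria), criteria, ws)
}

#' Scan for A+T-rich, CpG-rich domains
#'
#' Convenience wrapper over [tile_windows()] + [find_blocks()] with 100-bp
#' windows where a window passes iff its G+C fraction is below 0.50 and it
#' carries at least 5 CpGs — i.e. windows with >= 50% G+C or < 5 CpGs are
#' subtracted and blocks of adjoining surviving windows reported.  In the
#' mouse genome, domains of this composition at CGI-like dimensions are
#' absent.
#'
#' @inheritParams tile_windows
#' @param min_block_length minimum block length in bases (default 500, the
#'   relaxed CGI-scale setting; 1000 for full CGI-like dimensions).
#' @return block table as from [find_blocks()].
#' @export
scan_at_rich_cpg_rich <- function(genome, min_block_length = 500L) {
  crit <- scan_criteria(window_size = 100L, cpg_min = 5L,
                        min_block_length = min_block_length,
                        label = "at_rich_cpg_rich")
  windows <- tile_windows(genome, 100L)
  # the G+C bound is strict (< 0.50, i.e. windows at >= 50% are subtracted),
  # so it is applied here rather than through the inclusive gc_max field
  pass <- !windows$has_n & windows$gc_fraction < 0.5 & windows$cpg_count >= 5L
  .blocks_from_mask(windows, pass, crit, 100L)
}

#' Scan for G+C-rich, CpG-poor domains
#'
#' 100-bp windows pass iff G+C fraction >= 0.61 and CpG count <= 1 (at most
#' 1 CpG per 100 bp); maximal blocks of at least `min_block_length` are
#' reported.
#'
#' @inheritParams scan_at_rich_cpg_rich
#' @return block table as from [find_blocks()].
#' @export
scan_gc_rich_cpg_poor <- function(genome, min_block_length = 500L) {
  crit <- scan_criteria(window_size = 100L, gc_min = 0.61, cpg_max = 1L,
                        min_block_length = min_block_length,
                        label = "gc_rich_cpg_poor")
  windows <- tile_windows(genome, 100L)
  find_blocks(windows, crit)
}

# Shared run-collapsing for a precomputed pass mask.
.blocks_from_mask <- function(windows, pass, criteria, ws) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0),
                      mean_gc = numeric(0), mean_cpg_per_100bp = numeric(0))
  attr(empty, "criteria") <- criteria
  if (nrow(windows) == 0L || !any(pass)) return(empty)
  same_run <- c(FALSE, windows$chrom[-1L] == windows$chrom[-nrow(windows)] &
                         windows$start[-1L] == windows$end[-nrow(windows)])
  run_id <- cumsum(!(pass & same_run))
  keep <- which(pass)
  blocks <- lapply(split(keep, run_id[keep]), function(idx) {
    if (length(idx) * ws < criteria$min_block_length) return(NULL)
    data.frame(chrom = windows$chrom[idx[1L]],
               start = windows$start[idx[1L]],
               end = windows$end[idx[length(idx)]],
               n_windows = length(idx),
               mean_gc = mean(windows$gc_fraction[idx]),
               mean_cpg_per_100bp = mean(100 * windows$cpg_count[idx] / ws),
               stringsAsFactors = FALSE)
  })
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  if (length(blocks) == 0L) return(empty)
  out <- do.call(rbind, c(blocks, list(make.row.names = FALSE)))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "criteria") <- criteria
  out
}

#' Sample random fragments from a genome
#'
#' Draws `n` equal-sized fragments uniformly over all valid start positions
#' genome-wide (chromosomes weighted by their number of valid starts) and
#' returns each fragment's composition — the background cloud against which
#' CGI composition is compared in a CpG-density vs %G+C scatter.
#'
#' @inheritParams tile_windows
#' @param n number of fragments.
#' @param size fragment length in bases (default 1000).
#' @param seed integer seed; the fragment set is reproducible given it.
#' @return data.frame with columns `chrom`, `start`, `end`, `gc_fraction`,
#'   `cpg_per_100bp`, `cpg_obs_exp`.
#' @export
random_fragments <- function(genome, n, size = 1000L, seed) {
  genome <- .read_genome_arg(genome)
  size <- as.integer(size)
  n <- as.integer(n)
  lens <- nchar(genome)
  valid <- pmax(lens - size + 1L, 0L)
  if (n > 0L && sum(valid) == 0L)
    stop("no chromosome is long enough for fragments of ", size, " bp")
  if (n == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), gc_fraction = numeric(0),
                      cpg_per_100bp = numeric(0), cpg_obs_exp = numeric(0)))
  .with_seed(seed, {
    chrom_idx <- sample.int(length(genome), n, replace = TRUE,
                            prob = valid / sum(valid))
    starts <- vapply(chrom_idx, function(i) sample.int(valid[i], 1L) - 1L,
                     integer(1))
    frags <- substring(genome[chrom_idx], starts + 1L, starts + size)
    data.frame(
      chrom = names(genome)[chrom_idx],
      start = starts, end = starts + size,
      gc_fraction = vapply(frags, gc_fraction, numeric(1), USE.NAMES = FALSE),
      cpg_per_100bp = vapply(frags, cpg_per_100bp, numeric(1),
                             USE.NAMES = FALSE),
      cpg_obs_exp = vapply(frags, function(f)
        tryCatch(cpg_obs_exp(f), error = function(e) NA_real_), numeric(1),
        USE.NAMES = FALSE),
      stringsAsFactors = FALSE)
  })
}

# Accept a genome as named character vector, DNAStringSet, or FASTA path.
.read_genome_arg <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && is.null(names(genome)) &&
      file.exists(genome) && !grepl("^[ACGTNacgtn]+$", genome))
    genome <- read_fasta(genome)
  .as_genome(genome)
}
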