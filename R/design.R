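# Constrained random sequence design: the generator behind artificial
# CGI-like constructs.  Constraints are exact: length, CpG count and G+C
# base count (to the nearest whole base) are all hit precisely, and no CpG
# other than the deliberately placed ones exists in the output.

#' Specify one synthetic island design
#'
#' Bundles and validates the joint constraints defining one constrained
#' random sequence: length, target G+C fraction, CpG density (or count) and
#' the RNG seed.  Feasibility requires every CpG to fit without overlap
#' (`2 * cpg_count <= length`) and to be paid for out of the strong-base
#' budget (`round(gc * length) >= 2 * cpg_count`).
#'
#' @param length sequence length in bases.
#' @param gc target G+C fraction in \[0, 1\]; satisfied to the nearest whole
#'   base, i.e. the output carries exactly `round(gc * length)` G or C bases.
#' @param cpg_per_100bp target CpG density; converted to an exact count
#'   `round(length * cpg_per_100bp / 100)`.  Ignored when `cpg_count` is
#'   given directly.
#' @param cpg_count exact number of CpG dinucleotides to place.
#' @param seed integer seed; all randomness in [design_sequence()] derives
#'   from it.
#' @param label optional name for the design.
#' @return an object of class `design_spec`.
#' @examples
#' design_spec(1000, gc = 0.65, cpg_per_100bp = 10, seed = 1)
#' @export
design_spec <- function(length, gc, cpg_per_100bp = NULL, cpg_count = NULL,
                        seed, label = NA_character_) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("length must be a positive integer")
  if (!is.numeric(gc) || is.na(gc) || gc < 0 || gc > 1)
    stop("gc must be a fraction in [0, 1]")
  if (is.null(cpg_count)) {
    if (is.null(cpg_per_100bp))
      stop("give either cpg_per_100bp or cpg_count")
    if (cpg_per_100bp < 0) stop("cpg_per_100bp must be non-negative")
    cpg_count <- as.integer(round(length * cpg_per_100bp / 100))
  } else {
    cpg_count <- as.integer(cpg_count)
    if (is.na(cpg_count) || cpg_count < 0L)
      stop("cpg_count must be a non-negative integer")
  }
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("a seed is required: the generator has no global randomness")
  gc_bases <- as.integer(round(gc * length))
  if (2L * cpg_count > length)
    stop(sprintf(
      "infeasible design: 2 * cpg_count (%d) > length (%d)",
      2L * cpg_count, length))
  if (gc_bases < 2L * cpg_count)
    stop(sprintf(
      "infeasible design: round(gc * length) = %d G+C bases < 2 * cpg_count = %d (each CpG consumes one C and one G)",
      gc_bases, 2L * cpg_count))
  structure(
    list(length = length, gc_target = gc, cpg_count = cpg_count,
         cpg_per_100bp = 100 * cpg_count / length,
         gc_bases = gc_bases, seed = as.integer(seed), label = label),
    class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf(
    "design_spec%s: %d bp, %.1f%% G+C (%d strong bases), %d CpGs (%.2f / 100 bp), seed %d\n",
    if (is.na(x$label)) "" else paste0(" '", x$label, "'"),
    x$length, 100 * x$gc_target, x$gc_bases, x$cpg_count,
    x$cpg_per_100bp, x$seed))
  invisible(x)
}

# Uniform draw of k CpG start positions (1-based C positions) in 1..(L-1)
# with pairwise spacing >= 2, via the standard bijection with unrestricted
# k-subsets of 1..(L-k).
.draw_cpg_starts <- function(L, k) {
  if (k == 0L) return(integer(0))
  sort(sample.int(L - k, k)) + 0:(k - 1L)
}

#' Generate a random sequence satisfying a design spec exactly
#'
#' Places `cpg_count` non-overlapping CG dinucleotides uniformly at random,
#' then fills the free positions with `round(gc * length) - 2 * cpg_count`
#' additional G/C bases and A/T elsewhere, repairing any accidentally
#' created CpG (a C that lands immediately before a G is flipped to G; the
#' flip preserves the strong-base count and provably terminates).  The
#' result is verified against every constraint before return; the whole
#' procedure is deterministic given `spec$seed`.
#'
#' @param spec a [design_spec()].
#' @return character scalar of length `spec$length` with, exactly,
#'   `spec$cpg_count` CpGs and `spec$gc_bases` G+C bases, with attributes
#'   `label` and `spec`.
#' @examples
#' s <- design_sequence(design_spec(1000, 0.65, cpg_per_100bp = 10, seed = 1))
#' count_cpg(s)     # 100
#' gc_fraction(s)   # 0.65
#' @export
design_sequence <- function(spec) {
  if (!inherits(spec, "design_spec")) stop("spec must be a design_spec")
  .with_seed(spec$seed, .design_sequence_impl(spec))
}

# Core generator, run inside an established RNG stream (no seeding here) so
# callers such as synth_genome() can draw many designs from one stream.
.design_sequence_impl <- function(spec, max_restarts = 10L) {
  L <- spec$length
  k <- spec$cpg_count
  strong_total <- spec$gc_bases
  for (attempt in seq_len(max_restarts)) {
    starts <- .draw_cpg_starts(L, k)
    base <- character(L)
    base[starts] <- "C"
    base[starts + 1L] <- "G"
    free <- which(base == "")
    n_strong_free <- strong_total - 2L * k
    strong_free <- if (n_strong_free > 0L)
      sample(free, n_strong_free) else integer(0)
    weak_free <- setdiff(free, strong_free)
    base[weak_free] <- sample(c("A", "T"), length(weak_free), replace = TRUE)
    base[strong_free] <- sample(c("C", "G"), length(strong_free),
                                replace = TRUE)
    # repair pass: flip emergent CpGs' C to G (never touches placed CpGs;
    # each flip removes one C, so the loop terminates)
    placed <- logical(L)
    placed[starts] <- TRUE
    repeat {
      bad <- which(base[-L] == "C" & base[-1L] == "G" & !placed[-L])
      if (length(bad) == 0L) break
      base[bad] <- "G"
    }
    out <- paste(base, collapse = "")
    if (count_cpg(out) == k &&
        sum(base == "C" | base == "G") == strong_total &&
        nchar(out) == L) {
      attr(out, "label") <- spec$label
      attr(out, "spec") <- spec
      return(out)
    }
  }
  stop("generation failure: constraints unsatisfied after ", max_restarts,
       " restarts")
}

#' Generate a sequence with exact composition in every window
#'
#' A variant of [design_sequence()] that builds the sequence one
#' `window_size`-bp window at a time, so that \emph{every} window — not
#' just the whole sequence — carries exactly `round(gc * window_size)` G+C
#' bases and `round(window_size * cpg_per_100bp / 100)` CpGs, and no CpG
#' spans a window junction.  Use this when a sequence must pass (or fail) a
#' fixed-window composition scan uniformly along its whole length, the way
#' constructs with flat composition profiles do.
#'
#' @inheritParams design_spec
#' @param window_size width of the exact-composition windows; must divide
#'   `length`.
#' @return character scalar of `length` bases.
#' @examples
#' s <- design_windowed(1000, gc = 0.4, cpg_per_100bp = 10, seed = 1)
#' sliding_profile(s, 100, 100)$cpg_count  # all exactly 10
#' @export
design_windowed <- function(length, gc, cpg_per_100bp, window_size = 100L,
                            seed) {
  length <- as.integer(length)
  window_size <- as.integer(window_size)
  if (length %% window_size != 0L)
    stop("length must be a multiple of window_size")
  # validate per-window feasibility through the ordinary spec constructor
  wspec <- design_spec(window_size, gc = gc,
                       cpg_count = round(window_size * cpg_per_100bp / 100),
                       seed = seed)
  .with_seed(seed,
    .design_blockwise(length %/% window_size, window_size, gc,
                      wspec$cpg_count))
}

#' Concatenate an island with flanking sequence
#'
#' Returns `left + island + right` (e.g. an artificial CGI embedded in
#' gene-desert flanks) and reports any CpG created at either junction.
#' Junction CpGs are reported, not forbidden.
#'
#' @param island,left,right DNA sequences (character or Biostrings).
#' @return list with `sequence` (the concatenation), `island_start` /
#'   `island_end` (0-based half-open coordinates of the island within it)
#'   and `junction_cpgs` (0-based positions of CpGs spanning a junction;
#'   empty when none).
#' @export
embed_with_flanks <- function(island, left, right) {
  island <- .as_seq(island); left <- .as_seq(left); right <- .as_seq(right)
  if (nchar(island) == 0L || nchar(left) == 0L || nchar(right) == 0L)
    stop("all sequences must be non-empty")
  seqc <- paste0(left, island, right)
  nl <- nchar(left); ni <- nchar(island)
  junctions <- integer(0)
  if (substr(left, nl, nl) == "C" && substr(island, 1L, 1L) == "G")
    junctions <- c(junctions, nl - 1L)
  if (substr(island, ni, ni) == "C" && substr(right, 1L, 1L) == "G")
    junctions <- c(junctions, nl + ni - 1L)
  list(sequence = seqc, island_start = nl, island_end = nl + ni,
       junction_cpgs = junctions)
}

#' Verify a sequence against its design spec
#'
#' Recomputes the achieved composition with the composition metrics and
#' tabulates signed deviations from each constraint.  A compliant design has
#' zero deviation in length and CpG count and zero deviation in G+C bases
#' (the G+C target itself may be off by the sub-base rounding remainder).
#'
#' @param seq the sequence to audit.
#' @param spec the [design_spec()] it should satisfy.
#' @return list of class `design_report` with elements `spec`, `achieved`
#'   (a [composition_stats()] row) and `deviations` (named numeric:
#'   `length`, `cpg_count`, `gc_bases`).
#' @export
design_report <- function(seq, spec) {
  if (!inherits(spec, "design_spec")) stop("spec must be a design_spec")
  seq <- .as_seq(seq)
  ach <- composition_stats(seq, id = spec$label)
  r <- charToRaw(seq)
  dev <- c(length = nchar(seq) - spec$length,
           cpg_count = ach$n_cpg - spec$cpg_count,
           gc_bases = sum(r == .RAW_G | r == .RAW_C) - spec$gc_bases)
  structure(list(spec = spec, achieved = ach, deviations = dev),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  print(x$spec)
  cat(sprintf("achieved: %d bp, %.2f%% G+C, %d CpGs (%.2f / 100 bp), o/e %.2f\n",
              x$achieved$length, 100 * x$achieved$gc_fraction,
              x$achieved$n_cpg, x$achieved$cpg_per_100bp,
              x$achieved$cpg_obs_exp))
  cat("deviations:",
      paste(names(x$deviations), x$deviations, sep = " = ", collapse = ", "),
      "\n")
  invisible(x)
}
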