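# Bisulfite clone methylation calling.  Clones are Sanger reads of the
# bisulfite-converted top strand of a PCR amplicon: unmethylated cytosines
# read as T, methylated CpG cytosines read as C.  Non-CpG cytosines are
# essentially never methylated in ESC DNA, so their conversion measures
# bisulfite efficiency and provides the per-clone QC statistic.

#' Locate CpG and non-CpG cytosines in an amplicon reference
#'
#' @param reference amplicon reference sequence (untreated top strand).
#' @return object of class `bs_amplicon`: list with `reference`,
#'   `cpg_positions` (0-based positions of each CpG's C) and
#'   `non_cpg_c_positions` (0-based positions of all other Cs).
#' @examples
#' locate_sites("ACGTACGT")$cpg_positions  # 1 5
#' @export
locate_sites <- function(reference) {
  reference <- .as_seq(reference)
  if (nchar(reference) == 0L) stop("reference must be non-empty")
  r <- charToRaw(reference)
  all_c <- which(r == .RAW_C) - 1L
  cpg <- cpg_positions(reference)
  structure(list(reference = reference,
                 cpg_positions = cpg,
                 non_cpg_c_positions = setdiff(all_c, cpg)),
            class = "bs_amplicon")
}

#' @export
print.bs_amplicon <- function(x, ...) {
  cat(sprintf("bs_amplicon: %d bp, %d CpG sites, %d non-CpG Cs\n",
              nchar(x$reference), length(x$cpg_positions),
              length(x$non_cpg_c_positions)))
  invisible(x)
}

# Gapless alignment of a clone to the reference: the clone must match the
# reference length after trimming at most `max_trim` bases in total from
# the ends.  Returns the 0-based offset of clone position 0 on the
# reference, chosen to maximize bisulfite-space identity (ref C matches
# clone C or T; other bases must agree).
.align_clone <- function(amplicon, clone, max_trim = 5L) {
  ref <- amplicon$reference
  nr <- nchar(ref); nc <- nchar(clone)
  if (nc > nr) {
    if (nc - nr > max_trim)
      stop(sprintf("clone is %d bp longer than the reference (max trim %d)",
                   nc - nr, max_trim))
    # trim clone from the end; leading excess is handled as negative offset
    best <- NULL
    rr <- charToRaw(ref)
    cr <- charToRaw(clone)
    for (lead in 0:(nc - nr)) {
      sub <- cr[(lead + 1L):(lead + nr)]
      score <- .bs_matches(rr, sub)
      if (is.null(best) || score > best$score)
        best <- list(score = score, offset = 0L, clone_from = lead)
    }
    return(best)
  }
  if (nr - nc > max_trim)
    stop(sprintf("clone is %d bp shorter than the reference (max trim %d)",
                 nr - nc, max_trim))
  rr <- charToRaw(ref)
  cr <- charToRaw(clone)
  best <- NULL
  for (offset in 0:(nr - nc)) {
    sub <- rr[(offset + 1L):(offset + nc)]
    score <- .bs_matches(sub, cr)
    if (is.null(best) || score > best$score)
      best <- list(score = score, offset = offset, clone_from = 0L)
  }
  best
}

# bisulfite-space identity: positions where clone base is compatible with
# the reference assuming full or no conversion (ref C ~ clone C/T).
.bs_matches <- function(ref_raw, clone_raw) {
  same <- ref_raw == clone_raw
  conv <- ref_raw == .RAW_C & clone_raw == .RAW_T
  sum(same | conv)
}

#' Call per-CpG methylation for one clone
#'
#' At each CpG cytosine of the amplicon: a retained C is called methylated
#' (`M`), a T unmethylated (`U`), anything else ambiguous (`X`).  The
#' conversion rate is the fraction of non-CpG cytosines read as T; a
#' retained non-CpG C is a conversion failure.
#'
#' @param amplicon a [locate_sites()] result.
#' @param clone clone read (top strand, spanning the amplicon; gapless,
#'   with at most `max_trim` bases of total end-trimming tolerated).
#' @param max_trim maximum clone/reference length difference in bases.
#' @return list with `calls` (character vector M/U/X, one per CpG site),
#'   `conversion_rate` (NA when the amplicon has no non-CpG C) and
#'   `offset` (clone placement on the reference).
#' @examples
#' amp <- locate_sites("ACGTACGT")
#' call_clone(amp, "ATGTACGT")$calls  # "U" "M"
#' @export
call_clone <- function(amplicon, clone, max_trim = 5L) {
  if (!inherits(amplicon, "bs_amplicon")) stop("amplicon must be a bs_amplicon")
  clone <- .as_seq(clone)
  aln <- .align_clone(amplicon, clone, max_trim)
  nc <- nchar(clone) - aln$clone_from
  clone_raw <- charToRaw(clone)[(aln$clone_from + 1L):nchar(clone)]
  covered <- function(pos0) pos0 >= aln$offset & pos0 < aln$offset + nc
  base_at <- function(pos0) clone_raw[pos0 - aln$offset + 1L]
  calls <- vapply(amplicon$cpg_positions, function(p) {
    if (!covered(p)) return("X")
    b <- base_at(p)
    if (b == .RAW_C) "M" else if (b == .RAW_T) "U" else "X"
  }, character(1))
  ncc <- amplicon$non_cpg_c_positions
  ncc <- ncc[covered(ncc)]
  conversion_rate <- if (length(ncc) == 0L) NA_real_ else {
    b <- vapply(ncc, base_at, raw(1))
    sum(b == .RAW_T) / sum(b == .RAW_T | b == .RAW_C)
  }
  if (length(ncc) == 0L)
    warning("no non-CpG C in covered region: conversion rate undefined")
  list(calls = calls, conversion_rate = conversion_rate, offset = aln$offset)
}

#' Call a set of clones against one amplicon
#'
#' @param amplicon a [locate_sites()] result.
#' @param clones named character vector (or DNAStringSet / FASTA path) of
#'   clone reads.
#' @param max_trim per-clone end-trim tolerance, see [call_clone()].
#' @return object of class `meth_matrix`: list with `calls` (clones x sites
#'   character matrix over M/U/X), `conversion_rate` (per clone),
#'   `cpg_positions`, `clone_ids` and `amplicon`.
#' @export
call_clones <- function(amplicon, clones, max_trim = 5L) {
  clones <- .read_genome_arg(clones)
  if (length(clones) == 0L) stop("no clones supplied")
  res <- lapply(clones, function(cl)
    suppressWarnings(call_clone(amplicon, cl, max_trim)))
  calls <- do.call(rbind, lapply(res, `[[`, "calls"))
  rownames(calls) <- names(clones)
  colnames(calls) <- paste0("cpg_", amplicon$cpg_positions)
  structure(list(calls = calls,
                 conversion_rate = vapply(res, `[[`, numeric(1),
                                          "conversion_rate"),
                 cpg_positions = amplicon$cpg_positions,
                 clone_ids = names(clones),
                 amplicon = amplicon),
            class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d clones x %d CpG sites\n",
              nrow(x$calls), ncol(x$calls)))
  m <- sum(x$calls == "M"); u <- sum(x$calls == "U")
  if (m + u > 0)
    cat(sprintf("overall methylation: %.1f%% (%d M / %d U calls)\n",
                100 * m / (m + u), m, u))
  cat(sprintf("median conversion rate: %.3f\n",
              stats::median(x$conversion_rate, na.rm = TRUE)))
  invisible(x)
}

#' Lollipop plot of a methylation call matrix
#'
#' One row per clone, one column per CpG site; filled circles are
#' methylated calls, open circles unmethylated, crosses ambiguous.
#'
#' @param x a `meth_matrix`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @method plot meth_matrix
#' @export
plot.meth_matrix <- function(x, ...) {
  nc <- nrow(x$calls); ns <- ncol(x$calls)
  graphics::plot(NA, xlim = c(0.5, ns + 0.5), ylim = c(nc + 0.5, 0.5),
                 xlab = "CpG site", ylab = "clone", yaxt = "n", ...)
  graphics::axis(2, at = seq_len(nc), labels = x$clone_ids, las = 2,
                 cex.axis = 0.7)
  for (i in seq_len(nc)) {
    graphics::lines(c(1, ns), c(i, i), col = "grey70")
    for (j in seq_len(ns)) {
      v <- x$calls[i, j]
      if (v == "M") graphics::points(j, i, pch = 19)
      else if (v == "U") graphics::points(j, i, pch = 21, bg = "white")
      else graphics::points(j, i, pch = 4, col = "grey50")
    }
  }
  invisible(x)
}

#' Summarize a methylation call matrix
#'
#' Excludes clones whose bisulfite conversion rate falls below
#' `min_conversion` (clones with an undefined rate are kept but flagged),
#' then reports per-site, per-clone and overall percent methylation.
#' Ambiguous calls are excluded from all denominators.
#'
#' @param x a `meth_matrix` from [call_clones()].
#' @param min_conversion minimum per-clone conversion rate (default 0.95).
#' @return object of class `meth_summary`: list with `n_clones`,
#'   `n_excluded`, `excluded_clones`, `site_percent` (per-site %
#'   methylation), `clone_percent`, and `overall_percent`.  Zero passing
#'   clones yield an empty summary with a warning.
#' @export
summarize_methylation <- function(x, min_conversion = 0.95) {
  if (!inherits(x, "meth_matrix")) stop("x must be a meth_matrix")
  fail <- !is.na(x$conversion_rate) & x$conversion_rate < min_conversion
  keep <- which(!fail)
  if (length(keep) == 0L) {
    warning("no clone passes the conversion-rate threshold")
    return(structure(list(n_clones = 0L, n_excluded = sum(fail),
                          excluded_clones = x$clone_ids[fail],
                          site_percent = numeric(0),
                          clone_percent = numeric(0),
                          overall_percent = NA_real_),
                     class = "meth_summary"))
  }
  calls <- x$calls[keep, , drop = FALSE]
  pct <- function(v) {
    m <- sum(v == "M"); u <- sum(v == "U")
    if (m + u == 0L) NA_real_ else 100 * m / (m + u)
  }
  structure(list(
    n_clones = length(keep),
    n_excluded = sum(fail),
    excluded_clones = x$clone_ids[fail],
    site_percent = apply(calls, 2L, pct),
    clone_percent = apply(calls, 1L, pct),
    overall_percent = pct(calls)),
    class = "meth_summary")
}

#' @export
print.meth_summary <- function(x, ...) {
  cat(sprintf("meth_summary: %d clones (%d excluded by conversion QC)\n",
              x$n_clones, x$n_excluded))
  if (!is.na(x$overall_percent))
    cat(sprintf("overall methylation: %.1f%%\n", x$overall_percent))
  invisible(x)
}

#' Relate construct G+C content to methylation level
#'
#' Orders constructs by %G+C and locates the midpoint of the largest drop
#' in methylation between adjacent G+C values — an operational estimate of
#' the composition at which constructs switch from densely methylated
#' (A+T-rich) to methylation-free (G+C-rich).
#'
#' @param gc_percent construct G+C content in percent.
#' @param meth_percent overall percent methylation of each construct.
#' @param labels optional construct names.
#' @return list with `table` (constructs sorted by `gc_percent`) and
#'   `transition_gc` (midpoint of the adjacent pair with the largest
#'   methylation drop; NA if methylation never decreases).
#' @examples
#' gc_vs_methylation(c(40, 65), c(95, 5))$transition_gc  # 52.5
#' @export
gc_vs_methylation <- function(gc_percent, meth_percent, labels = NULL) {
  if (length(gc_percent) != length(meth_percent))
    stop("gc_percent and meth_percent must have equal length")
  if (length(gc_percent) < 2L)
    stop("at least two constructs are required")
  ord <- order(gc_percent)
  tab <- data.frame(
    label = if (is.null(labels)) paste0("construct_", seq_along(ord))
            else labels,
    gc_percent = gc_percent, meth_percent = meth_percent,
    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(tab) <- NULL
  drop <- tab$meth_percent[-nrow(tab)] - tab$meth_percent[-1L]
  transition <- if (all(drop <= 0)) NA_real_ else {
    i <- which.max(drop)
    (tab$gc_percent[i] + tab$gc_percent[i + 1L]) / 2
  }
  list(table = tab, transition_gc = transition)
}
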