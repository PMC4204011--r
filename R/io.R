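# File format plumbing: FASTA via Biostrings, BED/TSV as plain text.

#' Read a multi-record FASTA file
#'
#' @param path FASTA file (wrapped or unwrapped).
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA: ", path)
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  # keep only the first word of each header, the conventional sequence id
  names(out) <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector (or single sequence with `name`).
#' @param path output path.
#' @param name header used when `seqs` is a single unnamed sequence.
#' @param width line-wrap width.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, name = "seq1", width = 70L) {
  if (is.null(names(seqs))) {
    names(seqs) <- if (length(seqs) == 1L) name
      else paste0(name, "_", seq_along(seqs))
  }
  x <- Biostrings::DNAStringSet(unname(vapply(seqs, .as_seq, character(1))))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = as.integer(width))
  invisible(path)
}

#' Write composition blocks as BED6
#'
#' 0-based half-open coordinates; `name` is the criteria label and `score`
#' is the block's mean G+C fraction scaled to 0-1000.
#'
#' @param blocks a block table from [find_blocks()] or a scan wrapper.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_blocks_bed <- function(blocks, path) {
  crit <- attr(blocks, "criteria")
  label <- if (!is.null(crit)) crit$label else "block"
  df <- data.frame(blocks$chrom, blocks$start, blocks$end,
                   rep(label, nrow(blocks)),
                   as.integer(round(1000 * blocks$mean_gc)),
                   rep(".", nrow(blocks)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED-like interval table
#'
#' Reads at least (chrom, start, end); extra columns are kept under their
#' header names, or as `V4`, `V5`, ... when the file has no header.
#'
#' @param path TSV/BED path.
#' @param header does the file carry a header line?
#' @return data.frame with `chrom`, `start`, `end` plus any extra columns.
#' @export
read_bed <- function(path, header = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3L) stop("BED input needs at least 3 columns")
  names(df)[1:3] <- c("chrom", "start", "end")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' Write a data.frame as a headered TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
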