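# Internal sequence plumbing shared by every module.  Sequences are plain
# upper-case character scalars over {A,C,G,T,N}; Biostrings objects are
# accepted at the boundary and converted.

.RAW_A <- charToRaw("A")
.RAW_C <- charToRaw("C")
.RAW_G <- charToRaw("G")
.RAW_T <- charToRaw("T")
.RAW_N <- charToRaw("N")

#' Normalize a DNA sequence to an upper-case character scalar
#'
#' Accepts a character scalar, a [Biostrings::DNAString] or a length-one
#' [Biostrings::DNAStringSet].  Lower-case input is upper-cased; any
#' character outside \{A,C,G,T,N\} is an error.
#'
#' @param x the sequence.
#' @return upper-case character scalar.
#' @keywords internal
#' @noRd
.as_seq <- function(x) {
  if (methods::is(x, "DNAString") || methods::is(x, "DNAStringSet")) {
    if (methods::is(x, "DNAStringSet")) {
      if (length(x) != 1L) stop("expected a single sequence, got ", length(x))
      x <- x[[1L]]
    }
    x <- as.character(x)
  }
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("sequence must be a single character string")
  x <- toupper(x)
  r <- charToRaw(x)
  ok <- r == .RAW_A | r == .RAW_C | r == .RAW_G | r == .RAW_T | r == .RAW_N
  if (!all(ok))
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(unique(rawToChar(r[!ok], multiple = TRUE)), collapse = ", "))
  x
}

# A genome is a named character vector of sequences (or a DNAStringSet).
.as_genome <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    nm <- names(x)
    x <- as.character(x)
    names(x) <- nm
  }
  if (!is.character(x)) stop("genome must be a character vector or DNAStringSet")
  if (length(x) == 0L) return(stats::setNames(character(0), character(0)))
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
    names(x) <- paste0("chr", seq_along(x))
  vapply(x, .as_seq, character(1))
}

#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so no
#' package function touches global randomness.
#'
#' @keywords internal
#' @noRd
.with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) stop("a seed is required")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Reverse complement of a DNA string
#'
#' @param seq sequence (character, or Biostrings object).
#' @return character scalar; N maps to N.
#' @examples
#' reverse_complement("ACGTN")
#' @export
reverse_complement <- function(seq) {
  seq <- .as_seq(seq)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "", fixed = TRUE)[[1L]]),
                                 collapse = ""))
}
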