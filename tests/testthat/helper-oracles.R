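# Brute-force oracles, deliberately naive and independent of the package's
# vectorized implementations, plus small random-input helpers.

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

oracle_count_cpg <- function(s) {
  n <- nchar(s)
  if (n < 2) return(0L)
  hits <- 0L
  for (i in seq_len(n - 1)) {
    if (substr(s, i, i + 1) == "CG") hits <- hits + 1L
  }
  hits
}

oracle_gc_fraction <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  ch <- ch[ch != "N"]
  sum(ch %in% c("G", "C")) / length(ch)
}

oracle_obs_exp <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  eff <- sum(ch != "N")
  oracle_count_cpg(s) * eff / (sum(ch == "C") * sum(ch == "G"))
}

# Explicit per-window recount for one chromosome.
oracle_windows <- function(s, ws) {
  nwin <- nchar(s) %/% ws
  out <- NULL
  for (w in seq_len(nwin)) {
    start <- (w - 1) * ws
    win <- substr(s, start + 1, start + ws)
    # a CpG straddling the window end belongs to the window with the C
    straddle <- start + ws < nchar(s) &&
      substr(s, start + ws, start + ws + 1) == "CG"
    ch <- strsplit(win, "", fixed = TRUE)[[1]]
    out <- rbind(out, data.frame(
      start = start, end = start + ws,
      gc_fraction = sum(ch %in% c("G", "C")) / ws,
      cpg_count = oracle_count_cpg(win) + as.integer(straddle),
      has_n = any(ch == "N")))
  }
  out
}

# Explicit run search over a per-window pass vector for one chromosome.
oracle_blocks <- function(win, pass, ws, min_block_length) {
  blocks <- NULL
  i <- 1
  n <- length(pass)
  while (i <= n) {
    if (pass[i]) {
      j <- i
      while (j < n && pass[j + 1]) j <- j + 1
      if ((j - i + 1) * ws >= min_block_length) {
        blocks <- rbind(blocks, data.frame(
          start = win$start[i], end = win$end[j], n_windows = j - i + 1))
      }
      i <- j + 1
    } else i <- i + 1
  }
  blocks
}

oracle_overlap_fraction <- function(query, subject) {
  hit <- logical(nrow(query))
  for (i in seq_len(nrow(query))) {
    for (j in seq_len(nrow(subject))) {
      if (query$chrom[i] == subject$chrom[j] &&
          query$start[i] < subject$end[j] &&
          subject$start[j] < query$end[i]) {
        hit[i] <- TRUE
        break
      }
    }
  }
  mean(hit)
}
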