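# Seeded generators of synthetic test inputs with known ground truth:
# genomes with planted composition blocks, bisulfite clone sets, and
# feature-signal interval sets.  Every generator is fully determined by its
# seed.

#' Specify a synthetic genome with planted composition blocks
#'
#' The background of every chromosome is itself produced by the constrained
#' designer (at `background_gc` / `background_cpg_per_100bp`), so background
#' composition is exact rather than merely expected.  Planted blocks are
#' built window-by-window: each `window_size`-bp window of a plant is an
#' exact constrained design, and junctions are regenerated so that no CpG
#' spans a window or plant boundary.  Every window of a plant therefore
#' meets the plant's per-window composition exactly, which makes
#' plant-and-recover scanning deterministic.
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param background_gc background G+C fraction (default 0.40, bulk-genome
#'   level).
#' @param background_cpg_per_100bp background CpG density (default 1 per
#'   100 bp, bulk-genome level).
#' @param plants data.frame with columns `chrom`, `start`, `length`, `gc`,
#'   `cpg_per_100bp` (0-based starts; plants must lie within their
#'   chromosome and not overlap).  NULL for no plants.
#' @param window_size window width plants are built against (default 100).
#' @param seed integer seed.
#' @return object of class `genome_plant_spec`.
#' @export
genome_plant_spec <- function(chrom_lengths, background_gc = 0.40,
                              background_cpg_per_100bp = 1,
                              plants = NULL, window_size = 100L, seed) {
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  chrom_lengths <- vapply(chrom_lengths, as.integer, integer(1))
  if (missing(seed)) stop("a seed is required")
  if (!is.null(plants)) {
    need <- c("chrom", "start", "length", "gc", "cpg_per_100bp")
    if (!all(need %in% names(plants)))
      stop("plants needs columns: ", paste(need, collapse = ", "))
    for (i in seq_len(nrow(plants))) {
      p <- plants[i, ]
      if (!p$chrom %in% names(chrom_lengths))
        stop("plant on unknown chromosome: ", p$chrom)
      if (p$start < 0L || p$start + p$length > chrom_lengths[[p$chrom]])
        stop("plant out of chromosome range: ", p$chrom, ":", p$start)
      if (p$length %% window_size != 0L)
        stop("plant length must be a multiple of window_size")
    }
    # overlap check per chromosome
    for (ch in unique(plants$chrom)) {
      pc <- plants[plants$chrom == ch, , drop = FALSE]
      pc <- pc[order(pc$start), , drop = FALSE]
      if (nrow(pc) > 1L &&
          any(pc$start[-1L] < (pc$start + pc$length)[-nrow(pc)]))
        stop("planted blocks overlap on ", ch)
    }
  }
  structure(list(chrom_lengths = chrom_lengths, background_gc = background_gc,
                 background_cpg_per_100bp = background_cpg_per_100bp,
                 plants = plants, window_size = as.integer(window_size),
                 seed = as.integer(seed)),
            class = "genome_plant_spec")
}

# Build a sequence window-by-window so that EVERY window_size-bp window has
# exactly the requested per-window composition and no CpG spans a window
# junction.  Run inside an established RNG stream.
.design_blockwise <- function(n_windows, window_size, gc, cpg_per_window,
                              max_retries = 50L) {
  spec1 <- function() list(length = window_size,
                           gc_bases = as.integer(round(gc * window_size)),
                           cpg_count = as.integer(cpg_per_window))
  segs <- character(n_windows)
  for (w in seq_len(n_windows)) {
    s <- spec1()
    class(s) <- "design_spec"
    seg <- .design_sequence_impl(s)
    if (w > 1L) {
      prev_c <- substr(segs[w - 1L], window_size, window_size) == "C"
      tries <- 0L
      while (prev_c && substr(seg, 1L, 1L) == "G") {
        tries <- tries + 1L
        if (tries > max_retries) stop("could not avoid a junction CpG")
        seg <- .design_sequence_impl(s)
      }
    }
    segs[w] <- seg
  }
  paste(segs, collapse = "")
}

#' Generate a synthetic genome with planted blocks and its truth table
#'
#' @param spec a [genome_plant_spec()].
#' @return list with `genome` (named character vector), `truth` (BED-like
#'   data.frame of planted blocks: `chrom`, `start`, `end`, `gc`,
#'   `cpg_per_100bp`) and `spec`.  Byte-identical for identical seeds.
#' @export
synth_genome <- function(spec) {
  if (!inherits(spec, "genome_plant_spec"))
    stop("spec must be a genome_plant_spec")
  ws <- spec$window_size
  .with_seed(spec$seed, {
    genome <- vapply(names(spec$chrom_lengths), function(ch) {
      L <- spec$chrom_lengths[[ch]]
      s <- list(length = L,
                gc_bases = as.integer(round(spec$background_gc * L)),
                cpg_count = as.integer(round(
                  L * spec$background_cpg_per_100bp / 100)))
      class(s) <- "design_spec"
      .design_sequence_impl(s)
    }, character(1))
    truth <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), gc = numeric(0),
                        cpg_per_100bp = numeric(0))
    if (!is.null(spec$plants) && nrow(spec$plants) > 0L) {
      for (i in seq_len(nrow(spec$plants))) {
        p <- spec$plants[i, ]
        plant <- .design_blockwise(p$length %/% ws, ws, p$gc,
                                   round(ws * p$cpg_per_100bp / 100))
        chrom <- genome[[p$chrom]]
        # remove CpGs spanning the plant/background junctions by weakening
        # the adjacent background base (background has slack; the plant is
        # the ground truth and must not be altered)
        if (p$start > 0L &&
            substr(chrom, p$start, p$start) == "C" &&
            substr(plant, 1L, 1L) == "G")
          substr(chrom, p$start, p$start) <- "T"
        after <- p$start + p$length + 1L
        if (after <= nchar(chrom) &&
            substr(plant, p$length, p$length) == "C" &&
            substr(chrom, after, after) == "G")
          substr(chrom, after, after) <- "T"
        substr(chrom, p$start + 1L, p$start + p$length) <- plant
        genome[[p$chrom]] <- chrom
        truth <- rbind(truth, data.frame(
          chrom = p$chrom, start = p$start, end = p$start + p$length,
          gc = p$gc, cpg_per_100bp = p$cpg_per_100bp,
          stringsAsFactors = FALSE))
      }
    }
    list(genome = genome, truth = truth, spec = spec)
  })
}

#' Specify a simulated bisulfite clone experiment
#'
#' @param reference amplicon reference sequence (untreated top strand).
#' @param p_meth per-CpG-site methylation probabilities; recycled to the
#'   number of CpG sites if length 1.
#' @param conversion_efficiency probability that an unmethylated C (CpG or
#'   non-CpG) is read as T.
#' @param n_clones number of clones to simulate.
#' @param seed integer seed.
#' @return object of class `clone_sim_spec`.
#' @export
clone_sim_spec <- function(reference, p_meth, conversion_efficiency = 0.99,
                           n_clones = 20L, seed) {
  reference <- .as_seq(reference)
  amp <- locate_sites(reference)
  k <- length(amp$cpg_positions)
  if (length(p_meth) == 1L) p_meth <- rep(p_meth, k)
  if (length(p_meth) != k)
    stop("p_meth must have one probability per CpG site (", k, ")")
  if (any(p_meth < 0 | p_meth > 1)) stop("p_meth must lie in [0, 1]")
  if (conversion_efficiency < 0 || conversion_efficiency > 1)
    stop("conversion_efficiency must lie in [0, 1]")
  if (missing(seed)) stop("a seed is required")
  structure(list(reference = reference, amplicon = amp, p_meth = p_meth,
                 conversion_efficiency = conversion_efficiency,
                 n_clones = as.integer(n_clones), seed = as.integer(seed)),
            class = "clone_sim_spec")
}

#' Simulate bisulfite clone reads with known ground truth
#'
#' For each clone and CpG site, methylation is drawn Bernoulli(p_site);
#' unmethylated CpG cytosines and all non-CpG cytosines are converted to T
#' with probability `conversion_efficiency`.  Gs and A/T bases are
#' untouched (top-strand reads).
#'
#' @param spec a [clone_sim_spec()].
#' @return list with `clones` (named character vector of simulated reads),
#'   `truth` (logical clones x sites matrix of the methylation draws) and
#'   `spec`.
#' @export
synth_clones <- function(spec) {
  if (!inherits(spec, "clone_sim_spec")) stop("spec must be a clone_sim_spec")
  amp <- spec$amplicon
  k <- length(amp$cpg_positions)
  .with_seed(spec$seed, {
    truth <- matrix(FALSE, spec$n_clones, k,
                    dimnames = list(paste0("clone_", seq_len(spec$n_clones)),
                                    paste0("cpg_", amp$cpg_positions)))
    clones <- character(spec$n_clones)
    base <- strsplit(spec$reference, "", fixed = TRUE)[[1L]]
    for (i in seq_len(spec$n_clones)) {
      b <- base
      meth <- stats::runif(k) < spec$p_meth
      truth[i, ] <- meth
      # unmethylated CpG Cs convert with the given efficiency
      un <- amp$cpg_positions[!meth] + 1L
      conv <- un[stats::runif(length(un)) < spec$conversion_efficiency]
      b[conv] <- "T"
      # non-CpG Cs are never methylated; convert at the same efficiency
      ncc <- amp$non_cpg_c_positions + 1L
      conv2 <- ncc[stats::runif(length(ncc)) < spec$conversion_efficiency]
      b[conv2] <- "T"
      clones[i] <- paste(b, collapse = "")
    }
    names(clones) <- rownames(truth)
    list(clones = clones, truth = truth, spec = spec)
  })
}

#' Simulate a feature-signal interval set
#'
#' Draws interval lengths and CpG densities from log-normal/uniform
#' distributions sized like a bivalent-CGI set, and generates a read-count
#' style signal as a monotone function of a latent composition variable
#' plus unit-variance noise, with the monotone part scaled by
#' `dependence_strength`.  `dependence_strength = 0` gives pure noise
#' (rank correlation ~ 0); large values approach rank correlation 1.
#'
#' @param n number of intervals (>= 4).
#' @param dependence_strength non-negative scale of the feature-signal
#'   dependence (default 2).
#' @param seed integer seed.
#' @return data.frame with `chrom`, `start`, `end`, `length`,
#'   `cpg_density`, `signal`.
#' @export
synth_signal_intervals <- function(n, dependence_strength = 2, seed) {
  n <- as.integer(n)
  if (n < 4L) stop("n must be >= 4")
  if (dependence_strength < 0) stop("dependence_strength must be >= 0")
  .with_seed(seed, {
    z <- stats::rnorm(n)                       # latent composition axis
    length_bp <- pmax(200L, as.integer(round(exp(6.6 + 0.45 * z +
                                                 0.2 * stats::rnorm(n)))))
    cpg_density <- pmax(2, 8 + 2.5 * z + 0.8 * stats::rnorm(n))
    signal <- dependence_strength * z + stats::rnorm(n)
    signal <- signal - min(signal)             # read counts are non-negative
    start <- cumsum(c(0L, length_bp[-n] + 1000L))
    data.frame(chrom = "chr1", start = start, end = start + length_bp,
               length = length_bp, cpg_density = cpg_density,
               signal = signal, stringsAsFactors = FALSE)
  })
}
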