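test_that("tiling drops partial windows and counts straddling CpGs", {
  w <- tile_windows(c(chr1 = random_seq(250)), 100)
  expect_equal(nrow(w), 2L)
  expect_equal(w$end - w$start, c(100L, 100L))
  w2 <- tile_windows(c(chr1 = strrep("CG", 50)), 100)
  expect_equal(w2$cpg_count, 50L)
  expect_equal(w2$gc_fraction, 1.0)
  # CpG straddling a boundary belongs to the window with the C
  s <- paste0(strrep("A", 99), "C", "G", strrep("A", 99))
  w3 <- tile_windows(c(chr1 = s), 100)
  expect_equal(w3$cpg_count, c(1L, 0L))
  # N flags
  w4 <- tile_windows(c(chr1 = paste0(strrep("A", 99), "N", strrep("T", 100))),
                     100)
  expect_equal(w4$has_n, c(TRUE, FALSE))
  expect_equal(nrow(tile_windows(character(0), 100)), 0L)
})

test_that("window stats equal a brute-force recount on random chromosomes", {
  set.seed(301)
  for (i in 1:100) {
    s <- random_seq(sample(150:600, 1),
                    alphabet = c("A", "C", "G", "T", if (i %% 3 == 0) "N"))
    w <- tile_windows(c(chrA = s), 100)
    ora <- oracle_windows(s, 100)
    expect_equal(w$start, ora$start)
    expect_equal(w$gc_fraction, ora$gc_fraction)
    expect_equal(w$cpg_count, ora$cpg_count)
    expect_equal(w$has_n, ora$has_n)
  }
})

test_that("block calls equal the explicit run-search oracle on random genomes", {
  set.seed(302)
  for (i in 1:100) {
    # genomes with composition drifting around the thresholds so that both
    # passing and failing windows are common
    gc_level <- runif(1, 0.3, 0.7)
    s <- random_seq(sample(800:3000, 1),
                    alphabet = c(rep("A", round(20 * (1 - gc_level))),
                                 rep("T", round(20 * (1 - gc_level))),
                                 rep("C", round(20 * gc_level)),
                                 rep("G", round(20 * gc_level)),
                                 if (i %% 5 == 0) "N"))
    crit <- scan_criteria(window_size = 100,
                          gc_min = if (i %% 2) gc_level else NULL,
                          cpg_min = sample(0:3, 1),
                          min_block_length = sample(c(100, 200, 500), 1))
    win <- tile_windows(c(chr1 = s), 100)
    got <- find_blocks(win, crit)
    pass <- !win$has_n & win$cpg_count >= crit$cpg_min
    if (!is.null(crit$gc_min)) pass <- pass & win$gc_fraction >= crit$gc_min
    ora <- oracle_blocks(win, pass, 100, crit$min_block_length)
    if (is.null(ora)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$start, ora$start)
      expect_equal(got$end, ora$end)
      expect_equal(got$n_windows, ora$n_windows)
    }
  }
})

test_that("planted blocks are recovered exactly with no spurious calls", {
  for (seed in 1:20) {
    start1 <- 100 * sample(5:20, 1)
    sg <- synth_genome(genome_plant_spec(
      c(chrA = 5000L, chrB = 4000L),
      background_gc = 0.40, background_cpg_per_100bp = 1,
      plants = data.frame(chrom = c("chrA", "chrB"),
                          start = c(start1, 800L),
                          length = c(1000L, 700L),
                          gc = 0.40, cpg_per_100bp = 10),
      seed = seed))
    got <- scan_at_rich_cpg_rich(sg$genome, min_block_length = 500)
    expect_equal(nrow(got), 2L)
    expect_equal(got$start[order(got$chrom)], sg$truth$start)
    expect_equal(got$end[order(got$chrom)], sg$truth$end)
    # the orthogonal scan finds nothing in this genome
    expect_equal(nrow(scan_gc_rich_cpg_poor(sg$genome)), 0L)
  }
})

test_that("scan wrappers behave on degenerate and designed inputs", {
  # all-A genome: no CpGs anywhere
  expect_equal(nrow(scan_at_rich_cpg_rich(c(chr1 = strrep("A", 2000)))), 0L)
  expect_equal(nrow(scan_at_rich_cpg_rich(character(0))), 0L)
  # a genome that is one designed GC-rich CpG-poor island with a flat
  # composition profile
  isl <- design_windowed(1000, 0.65, cpg_per_100bp = 1, seed = 5)
  b <- scan_gc_rich_cpg_poor(c(chr1 = as.character(isl)))
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$start, b$end), c(0L, 1000L))
  # 40%-GC background yields nothing under the GC-rich scan
  bg <- design_sequence(design_spec(3000, 0.40, cpg_per_100bp = 1, seed = 6))
  expect_equal(nrow(scan_gc_rich_cpg_poor(c(chr1 = as.character(bg)))), 0L)
})

test_that("relaxing the minimum block length only adds blocks", {
  set.seed(303)
  for (i in 1:10) {
    s <- random_seq(3000, alphabet = c("A", "T", "C", "G", "C", "G"))
    win <- tile_windows(c(chr1 = s), 100)
    strict <- find_blocks(win, scan_criteria(gc_min = 0.5,
                                             min_block_length = 1000))
    relaxed <- find_blocks(win, scan_criteria(gc_min = 0.5,
                                              min_block_length = 500))
    expect_gte(nrow(relaxed), nrow(strict))
    for (r in seq_len(nrow(strict)))
      expect_true(any(relaxed$start == strict$start[r] &
                      relaxed$end == strict$end[r]))
  }
})

test_that("blocks never merge across chromosome boundaries", {
  isl <- design_windowed(600, 0.70, cpg_per_100bp = 0, seed = 8)
  two <- c(chr1 = isl, chr2 = isl)
  b <- find_blocks(tile_windows(two, 100),
                   scan_criteria(gc_min = 0.6, min_block_length = 500))
  expect_equal(nrow(b), 2L)
  expect_equal(b$chrom, c("chr1", "chr2"))
  expect_true(all(b$end - b$start == 600))
})

test_that("random fragments are reproducible and composition-faithful", {
  g <- c(chr1 = as.character(design_sequence(
    design_spec(20000, 0.40, cpg_per_100bp = 1, seed = 12))))
  expect_equal(nrow(random_fragments(g, 0, 1000, seed = 1)), 0L)
  f1 <- random_fragments(g, 50, 1000, seed = 4)
  f2 <- random_fragments(g, 50, 1000, seed = 4)
  expect_identical(f1, f2)
  # fragments from a homogeneous 40%-GC genome cluster near 0.40: every
  # fragment's GC count is within a generous binomial-style band
  expect_true(all(abs(f1$gc_fraction - 0.40) < 0.1))
  expect_equal(mean(f1$gc_fraction), 0.40, tolerance = 0.01)
  expect_error(random_fragments(c(chr1 = "ACGT"), 5, 1000, seed = 1),
               "long enough")
})

test_that("BED output round-trips block coordinates", {
  isl <- design_windowed(1000, 0.65, cpg_per_100bp = 1, seed = 5)
  b <- scan_gc_rich_cpg_poor(c(myChr = as.character(isl)))
  path <- withr::local_tempfile(fileext = ".bed")
  write_blocks_bed(b, path)
  bed <- read_bed(path)
  expect_equal(bed$chrom, "myChr")
  expect_equal(bed$start, 0L)
  expect_equal(bed$end, 1000L)
  expect_equal(bed$V4, "gc_rich_cpg_poor")
})
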