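test_that("site location separates CpG and non-CpG cytosines", {
  amp <- locate_sites("ACGTACGT")
  expect_equal(amp$cpg_positions, c(1L, 5L))
  expect_length(amp$non_cpg_c_positions, 0L)
  amp2 <- locate_sites("CCGG")
  expect_equal(amp2$cpg_positions, 1L)
  expect_equal(amp2$non_cpg_c_positions, 0L)
  expect_error(locate_sites(""), "non-empty")
  # agreement with a regex-style scan on random sequences
  set.seed(401)
  for (i in 1:30) {
    s <- random_seq(sample(20:200, 1))
    amp <- locate_sites(s)
    rx_cpg <- as.integer(gregexpr("CG", s, fixed = TRUE)[[1]]) - 1L
    rx_cpg <- rx_cpg[rx_cpg >= 0]
    rx_c <- as.integer(gregexpr("C", s, fixed = TRUE)[[1]]) - 1L
    rx_c <- rx_c[rx_c >= 0]
    expect_equal(amp$cpg_positions, rx_cpg)
    expect_equal(sort(c(amp$cpg_positions, amp$non_cpg_c_positions)), rx_c)
  }
})

test_that("single-clone calls follow the C/T conversion rules", {
  amp <- locate_sites("ACGTACGT")  # no non-CpG C: conversion QC undefined
  expect_warning(full <- call_clone(amp, "ATGTATGT"), "undefined")
  expect_equal(full$calls, c("U", "U"))
  expect_warning(same <- call_clone(amp, "ACGTACGT"), "undefined")
  expect_equal(same$calls, c("M", "M"))
  expect_true(is.na(same$conversion_rate))
  mix <- suppressWarnings(call_clone(amp, "ACGTATGT"))
  expect_equal(mix$calls, c("M", "U"))
  # conversion QC from non-CpG Cs
  amp2 <- locate_sites("CACGTC")  # non-CpG Cs at 0 and 5, CpG at 2
  cl <- call_clone(amp2, "TACGTT")
  expect_equal(cl$calls, "M")
  expect_equal(cl$conversion_rate, 1.0)
  cl2 <- call_clone(amp2, "CATGTT")
  expect_equal(cl2$calls, "U")
  expect_equal(cl2$conversion_rate, 0.5)
  # ambiguous base at a CpG position
  expect_equal(suppressWarnings(call_clone(amp, "AAGTATGT"))$calls,
               c("X", "U"))
})

test_that("end-trimmed clones align gaplessly within tolerance", {
  ref <- as.character(design_sequence(design_spec(120, 0.55,
                                                  cpg_per_100bp = 5, seed = 21)))
  amp <- locate_sites(ref)
  conv <- chartr("C", "T", ref)  # fully converted, unmethylated everywhere
  # drop 3 leading bases: calls at uncovered sites become ambiguous,
  # covered sites still call U
  trimmed <- substr(conv, 4, 120)
  cl <- call_clone(amp, trimmed)
  covered <- amp$cpg_positions >= cl$offset
  expect_true(all(cl$calls[covered] == "U"))
  expect_equal(cl$conversion_rate, 1.0)
  expect_error(call_clone(amp, substr(conv, 10, 120)), "shorter")
})

test_that("summaries exclude low-conversion clones and ambiguous calls", {
  amp <- locate_sites("ACGTACGT")
  mm <- call_clones(amp, c(a = "ACGTACGT", b = "ACGTACGT"))
  sm <- summarize_methylation(mm)
  expect_equal(sm$overall_percent, 100)
  expect_equal(sm$n_clones, 2L)
  # ambiguous calls do not move the methylated/unmethylated ratio
  mm2 <- call_clones(amp, c(a = "ACGTATGT", b = "ACGTAAGT"))
  expect_equal(mm2$calls["b", 2], "X")
  sm2 <- summarize_methylation(mm2)
  expect_equal(sm2$overall_percent, 100 * 2 / 3)
  # a clone failing conversion QC is excluded and reported
  amp3 <- locate_sites(paste0(strrep("CA", 20), "CG", strrep("AC", 20)))
  good <- chartr("C", "T", paste0(strrep("CA", 20), "CG", strrep("AC", 20)))
  bad <- paste0(strrep("CA", 20), "CG", strrep("AC", 20))  # unconverted
  mm3 <- call_clones(amp3, c(good = good, bad = bad))
  sm3 <- summarize_methylation(mm3)
  expect_equal(sm3$n_clones, 1L)
  expect_equal(sm3$excluded_clones, "bad")
  expect_warning(summarize_methylation(call_clones(amp3, c(bad = bad))),
                 "no clone passes")
})

test_that("simulated clones recover their generating parameters", {
  ref <- as.character(design_sequence(design_spec(400, 0.55,
                                                  cpg_per_100bp = 8, seed = 22)))
  amp <- locate_sites(ref)
  k <- length(amp$cpg_positions)
  # degenerate cases are exact
  all1 <- synth_clones(clone_sim_spec(ref, 1, 1, n_clones = 5, seed = 23))
  sm1 <- summarize_methylation(call_clones(amp, all1$clones))
  expect_equal(sm1$overall_percent, 100)
  all0 <- synth_clones(clone_sim_spec(ref, 0, 1, n_clones = 5, seed = 24))
  mm0 <- call_clones(amp, all0$clones)
  expect_equal(summarize_methylation(mm0)$overall_percent, 0)
  expect_true(all(mm0$conversion_rate == 1))
  # stochastic case: estimate within the exact binomial 95% band of p = 0.8
  sim <- synth_clones(clone_sim_spec(ref, 0.8, 0.99, n_clones = 20,
                                     seed = 25))
  sm <- summarize_methylation(call_clones(amp, sim$clones))
  n_calls <- 20 * k
  band <- qbinom(c(0.025, 0.975), n_calls, 0.8) / n_calls
  expect_gte(sm$overall_percent / 100, band[1])
  expect_lte(sm$overall_percent / 100, band[2])
  # and the caller reproduces the simulation's own truth table closely
  expect_equal(sm$overall_percent, 100 * mean(sim$truth), tolerance = 0.05)
})

test_that("overall methylation is invariant to clone and site ordering", {
  ref <- as.character(design_sequence(design_spec(200, 0.6,
                                                  cpg_per_100bp = 6, seed = 26)))
  amp <- locate_sites(ref)
  sim <- synth_clones(clone_sim_spec(ref, 0.5, 0.99, n_clones = 10, seed = 27))
  mm <- call_clones(amp, sim$clones)
  mm_rev <- call_clones(amp, rev(sim$clones))
  expect_equal(summarize_methylation(mm)$overall_percent,
               summarize_methylation(mm_rev)$overall_percent)
  shuf <- mm
  set.seed(28)
  perm <- sample(ncol(mm$calls))
  shuf$calls <- mm$calls[, perm, drop = FALSE]
  expect_equal(summarize_methylation(shuf)$overall_percent,
               summarize_methylation(mm)$overall_percent)
})

test_that("GC-vs-methylation transition sits at the largest drop", {
  expect_equal(gc_vs_methylation(c(40, 65), c(95, 5))$transition_gc, 52.5)
  res <- gc_vs_methylation(c(40, 50, 55, 65, 70), c(98, 95, 50, 4, 2))
  expect_equal(res$transition_gc, 60)  # 50 -> 4 is the largest drop
  expect_equal(res$table$gc_percent, sort(c(40, 50, 55, 65, 70)))
  expect_true(is.na(gc_vs_methylation(c(40, 60), c(10, 90))$transition_gc))
  expect_error(gc_vs_methylation(50, 10), "at least two")
})
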