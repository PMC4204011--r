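# cgikit

Toolkit for studying how DNA base composition shapes CpG-island (CGI)
chromatin. CGIs differ from bulk vertebrate genomic DNA in two features
that usually co-occur but can be varied independently: G+C-rich base
composition (~65% vs ~40% genome-wide) and high CpG dinucleotide density
(up to 1 per ~10 bp vs ~1 per 100 bp). Experiments that integrate
promoter-less artificial CGI-like DNA into embryonic stem cell genomes
separate the two — and need, on the computational side, exactly what this
package provides:

- **Constrained sequence design** — random DNA with *exact* joint
  constraints on length, G+C base count and CpG count
  (`design_spec()`, `design_sequence()`, `design_windowed()`,
  `embed_with_flanks()`, `design_report()`).
- **Composition metrics** — G+C fraction, CpG counts and density, the
  observed/expected CpG ratio
  `o/e = n_CpG · L / (n_C · n_G)`, sliding-window profiles, and the
  classical length ≥ 200 bp / GC ≥ 0.5 / o/e ≥ 0.6 island rule
  (`gc_fraction()`, `count_cpg()`, `cpg_obs_exp()`, `sliding_profile()`,
  `classify_cgi()`).
- **Genome scanning** — 100-bp tiling with per-window composition and
  maximal blocks of adjoining windows passing criteria; packaged searches
  for A+T-rich/CpG-rich (GC < 50% and ≥ 5 CpGs per window) and
  G+C-rich/CpG-poor (GC ≥ 61%, ≤ 1 CpG per window) domains, plus random
  background fragment sampling (`tile_windows()`, `find_blocks()`,
  `scan_at_rich_cpg_rich()`, `scan_gc_rich_cpg_poor()`,
  `random_fragments()`).
- **Bisulfite clone calling** — per-CpG methylation calls from
  Sanger-style clone reads with conversion-efficiency QC from non-CpG
  cytosines, lollipop plots, and the construct-level G+C vs methylation
  transition (`locate_sites()`, `call_clones()`,
  `summarize_methylation()`, `gc_vs_methylation()`).
- **Interval statistics** — equal-count quartile binning of intervals by
  length or CpG density against a signal column, ≥ 1 bp overlap fractions
  between interval sets, Spearman rank correlation (`quartile_bin()`,
  `overlap_fraction()`, `rank_correlation()`).
- **Synthetic fixtures** — seeded, byte-reproducible generators of genomes
  with planted composition blocks, simulated bisulfite clones and
  feature–signal interval sets, each with ground-truth tables
  (`synth_genome()`, `synth_clones()`, `synth_signal_intervals()`).

All coordinates are 0-based half-open (BED convention). Every stochastic
function takes a mandatory seed and never touches the session RNG. See the
methods vignette (`vignettes/cgi-composition-methods.Rmd`) for the models,
conventions and design decisions.

## Worked example

Design an artificial CGI with the composition of a typical island —
1000 bp, 65% G+C, one CpG per 10 bp — and audit it:

```r
library(cgikit)

spec <- design_spec(1000, gc = 0.65, cpg_per_100bp = 10, seed = 1,
                    label = "artificial_cgi_1")
s <- design_sequence(spec)
design_report(s, spec)
#> design_spec 'artificial_cgi_1': 1000 bp, 65.0% G+C (650 strong bases), 100 CpGs (10.00 / 100 bp), seed 1
#> achieved: 1000 bp, 65.00% G+C, 100 CpGs (10.00 / 100 bp), o/e 1.00
#> deviations: length = 0, cpg_count = 0, gc_bases = 0
```

The constraints are met exactly: 650 of 1000 bases are G or C (65%), there
are exactly 100 CpGs (10 per 100 bp), and every deviation from the spec is
zero. The o/e ratio of ~1.0 says the sequence carries as many CpGs as
expected from its C and G frequencies — unlike bulk genomic DNA, which is
CpG-depleted (o/e ≈ 0.2–0.3). A planted copy of such an island is found by
the scanner at exact coordinates:

```r
sg <- synth_genome(genome_plant_spec(
  c(chr1 = 6000L), seed = 7,
  plants = data.frame(chrom = "chr1", start = 2000L, length = 1000L,
                      gc = 0.40, cpg_per_100bp = 10)))
scan_at_rich_cpg_rich(sg$genome)
#>   chrom start  end n_windows mean_gc mean_cpg_per_100bp
#> 1  chr1  2000 3000        10     0.4                 10
```

A command-line front end with `design`, `profile`, `scan`, `bisulfite`,
`bins` and `fixtures` subcommands is installed at
`inst/cli/cgikit.R` (run `Rscript cgikit.R` for usage).

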