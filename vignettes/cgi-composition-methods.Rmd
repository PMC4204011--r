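---
title: "Methods: constrained CGI design, composition scanning and bisulfite calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constrained CGI design, composition scanning and bisulfite calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgikit)
```

# The scientific setting

CpG islands (CGIs) differ from bulk vertebrate genomic DNA in two features
that usually co-occur but are logically independent: G+C-rich base
composition (about 65% vs ~40% genome-wide) and a high density of the CpG
dinucleotide (up to one per ~10 bp vs roughly one per 100 bp in bulk DNA).
Experiments that integrate promoter-less artificial CGI-like sequences into
embryonic stem cell genomes can vary these two features independently —
e.g. a 1000-bp construct at 65% G+C with 10 CpGs/100 bp, a "Low CpG / High
G+C" construct at 65% G+C with only 1 CpG/100 bp, and "High CpG / Low G+C"
constructs at 40% G+C with 10 CpGs/100 bp — and then read out chromatin
state (H3K4me3/H3K27me3 bivalency) and DNA methylation.  cgikit implements
the computational side of that experimental design: generating the
constrained random sequences, measuring and scanning composition, calling
bisulfite clone methylation, and relating interval features to chromatin
signal.

# Composition metrics

For a sequence with $n_{CG}$ CpG dinucleotides, $n_C$ cytosines, $n_G$
guanines and effective (non-N) length $L$:

* G+C fraction $= (n_C + n_G) / L$;
* CpG density $= 100\, n_{CG} / L$ per 100 bp;
* observed/expected CpG ratio, Gardiner-Garden & Frommer convention:
  $$ o/e = \frac{n_{CG} \cdot L}{n_C \cdot n_G}. $$

The o/e ratio corrects CpG density for overall base composition, which is
why A+T-rich constructs with CGI-level CpG density have a *high* o/e even
though their raw density matches an ordinary CGI.  Two conventions exist in
the CGI literature (Gardiner-Garden & Frommer's $n_C \cdot n_G$ and
Takai–Jones' $((n_C+n_G)/2)^2$ expectation); we use the former throughout,
as it is the convention behind the classical 200 bp / 50% GC / 0.6 o/e
island rule that `classify_cgi()` applies.  For near-equal C and G counts
the two differ negligibly.

Conventions applied everywhere:

* CpGs are counted on the plus strand only.  The CpG site is
  self-complementary in duplex DNA, so plus-strand counting covers the site
  exactly once; counting both strands would double every site.
* N bases never match C or G, never form part of a CpG, and are excluded
  from the effective length.  A scan window containing any N is flagged and
  excluded (and breaks block runs) — a conservative choice that prevents
  assembly gaps from being read as composition signal.
* All coordinates are 0-based half-open, so window and block tables can be
  written as BED without translation.
* In windowed profiles and tilings, a CpG whose C is a window's final base
  belongs to that window (the window containing the C).

# The constrained designer

`design_sequence()` produces a random sequence satisfying three *exact*
constraints: length $L$, CpG count $k$ (from a density target,
$k = \mathrm{round}(L \cdot d / 100)$), and G+C base count
$S = \mathrm{round}(gc \cdot L)$.  Published construct descriptions use
approximate language ("one CpG per ~10 bp"); we resolve this to exact
counts because exactness is testable and loses no generality — a scientist
wanting looseness can draw the target from a distribution.  Feasibility
requires $2k \le L$ and $2k \le S \le L$ (each CpG consumes one C and one
G); infeasible specs fail fast with the violated inequality named.

The algorithm:

1. Draw the $k$ CpG start positions uniformly at random among all position
   sets with pairwise spacing $\ge 2$ (non-overlap), using the standard
   bijection between spaced subsets of $\{1..L-1\}$ and unrestricted
   $k$-subsets of $\{1..L-k\}$.  Spacing 2 is the minimal non-overlap
   constraint; clustering beyond that is left to chance, matching the idea
   of a "random" island.
2. Write `CG` at each start; distribute the remaining $S - 2k$ strong bases
   uniformly among free positions; fill other free positions with A/T
   (uniform).
3. Assign each strong free position C or G at random, then run a repair
   pass: any *emergent* CpG (a C immediately followed by a G that is not a
   placed pair) has its C flipped to G.  A flip preserves the strong-base
   count and strictly decreases the number of Cs, so the pass terminates;
   because a CpG is exactly "C before G", eliminating all such Cs
   eliminates all unplaced CpGs.  The repair slightly biases the C:G split
   at positions left of a G — harmless, since no constraint involves the
   C:G split, only their sum.
4. Verify every constraint by recount; on failure (not observed in
   practice, but kept as a guard) restart from step 1 within the same
   seeded stream, up to 10 restarts, then raise a generation-failure error.

All randomness flows from the spec's mandatory seed through a local RNG
scope (`.Random.seed` is saved and restored), so identical specs reproduce
byte-identical sequences and package functions never disturb a session's
global RNG.

`design_windowed()` is a variant that applies the same generator
window-by-window (default 100 bp), regenerating a window when a CpG would
span a junction.  Whole-sequence constraints leave per-window composition
to fluctuate hypergeometrically (a 1000-bp, 65% G+C design will often
contain a window below 61%); the windowed variant pins *every* window to
the target, which is what a construct with a flat composition profile —
and any deterministic plant-and-recover scanner test — needs.

# Genome scanning

`tile_windows()` divides each chromosome into non-overlapping 100-bp
windows from coordinate 0 (trailing partial windows dropped) and computes
per-window G+C fraction and CpG count via cumulative sums.
`find_blocks()` reports maximal runs of adjoining passing windows whose
total length reaches `min_block_length`; runs break at chromosome
boundaries, coordinate gaps and N-flagged windows.  Two published searches
are packaged as wrappers:

* `scan_at_rich_cpg_rich()`: windows with $\ge$ 50% G+C or fewer than 5
  CpGs are subtracted; blocks of the surviving (A+T-rich, CpG-rich)
  windows are reported.  Applied genome-wide to mouse, domains of this
  composition at CGI-like dimensions are absent — consistent with de novo
  methylation of A+T-rich CpG-rich DNA and consequent CpG loss by
  deamination over evolutionary time.
* `scan_gc_rich_cpg_poor()`: windows pass at $\ge$ 61% G+C and $\le$ 1
  CpG.  The G+C-rich, CpG-deficient domains this finds in a real genome do
  not form bivalent chromatin.

Both searches use the same 100-bp tiling machinery; the published
description details windowing only for the A+T-rich search, so treating
the G+C-rich search identically is a design choice.  Whether the "$\le 1$
CpG per 100 bp" bound was originally evaluated per window or over whole
candidate regions is ambiguous; we evaluate it per window, the stricter
and simpler reading.  `min_block_length` defaults to 500 bp (the
approximate minimum CGI size, the documented "relaxed" setting), with
1000 bp for full CGI-like dimensions.  Real-genome block counts depend on
assembly version and are therefore not asserted by any test; the scanner
recomputes them from whatever FASTA it is given.

`random_fragments()` samples equal-sized fragments uniformly over valid
start positions (chromosomes weighted by valid-start count), giving the
bulk-genome background cloud for CpG-density vs %G+C scatter plots.

# Bisulfite clone calling

Bisulfite converts unmethylated cytosine to uracil (read as T); methylated
CpG cytosines resist conversion.  `locate_sites()` records the CpG and
non-CpG cytosine positions of the amplicon reference; `call_clone()` reads
each clone as a top-strand sequence, calling each CpG C as methylated (C),
unmethylated (T) or ambiguous (anything else), and estimates per-clone
conversion efficiency from the non-CpG cytosines, which are essentially
unmethylated in ESC DNA — a retained non-CpG C is a conversion failure.

Design choices where the published protocol is silent: clones are assumed
to be full-length top-strand reads; alignment is gapless with up to 5
bases of end-trimming tolerated (Sanger clone ends are ragged; indels in a
~400-bp amplicon are rare enough that an indel-tolerant aligner would be
over-engineering at this scale, and a mis-length beyond the tolerance is
an error, not a guess); clones converting below 95% of their non-CpG Cs
are excluded from summaries (a conventional QC threshold); ambiguous calls
are excluded from all denominators, so they cannot move a methylation
percentage.  `summarize_methylation()` reports per-site, per-clone and
overall percent methylation over the QC-passing clones.

`gc_vs_methylation()` sorts construct-level summaries by %G+C and reports
the midpoint of the largest methylation drop between adjacent G+C values —
an operational estimate of the composition at which constructs switch from
densely methylated to methylation-free (empirically a sharp transition in
the 50–60% G+C range, with a 55% G+C construct showing intermediate
methylation).

# Interval statistics

`quartile_bin()` ranks intervals by length or CpG density and splits them
into four equal-*count* bins (quartiles of the ranked list, not
equal-width feature ranges; tied features keep stable input order, lower
ranks filling lower bins), reporting mean and median signal per bin — the
display used to show that CGI length and CpG density correlate positively
with H3K4me3 and H3K27me3 read counts at bivalent islands.
`overlap_fraction()` reports the fraction of query intervals sharing at
least 1 bp with any subject interval ("coincidence" is operationalized as
$\ge$ 1 bp overlap; the interval engine is GenomicRanges, and the test
suite checks it against an all-pairs brute-force oracle).
`rank_correlation()` is Spearman's rank correlation with an explicit
zero-variance error.

# Synthetic fixtures and what they do (not) show

The generators in `synth_genome()`, `synth_clones()` and
`synth_signal_intervals()` are first-class, seeded, and byte-reproducible.

* `synth_genome()` builds chromosome backgrounds with the constrained
  designer itself (default 40% G+C, 1 CpG/100 bp — bulk-genome levels), so
  background composition is exact rather than merely expected, and plants
  blocks built with the windowed designer so that every planted window
  passes its scan criteria deterministically.  CpGs spanning a
  plant/background junction are removed by weakening the adjacent
  *background* base (the plant is the ground truth and is never altered).
  Chromosomes of 4–10 kb and ~100 replicate genomes keep the scanner
  oracle-equivalence sweep under a few seconds while still covering every
  run-boundary case; the generator does not emulate repeats, isochores or
  assembly gaps beyond explicit N injection, so passing tests demonstrate
  algorithmic correctness, not robustness to real-genome artifacts.
* `synth_clones()` draws per-site methylation Bernoulli($p_{site}$) and
  converts unmethylated and non-CpG cytosines with the stated efficiency
  (defaults 0.99 conversion, 20 clones — a typical Sanger bisulfite
  experiment).  It simulates neither sequencing error nor chimeric clones.
* `synth_signal_intervals()` draws interval lengths log-normally around
  ~700 bp and CpG densities around 8/100 bp (CGI-like scales), with a
  read-count-style signal equal to `dependence_strength` times a latent
  composition axis plus unit normal noise; dependence 0 gives pure noise,
  large values drive the rank correlation toward 1.  The default
  dependence of 2 yields an unmistakably monotone quartile pattern at
  n = 200 without being a noise-free caricature.

# Numerical and testing notes

Problem sizes in the test suite are chosen for coverage per second: 1000
random feasible design specs (lengths 100–2000, G+C 0.30–0.70, densities
0–12/100 bp), 100 random genomes of 3–8 kb for scanner/oracle equivalence,
20 plant-and-recover genomes, 400 Monte-Carlo sequences for the o/e ≈ 1
check (standard error ~0.006 against a 0.02 tolerance), and the exact
binomial 95% acceptance band for the simulated bisulfite recovery at
p = 0.8.  Degenerate inputs have defined behavior throughout: empty or
all-N sequences raise composition errors, o/e is an error without both C
and G, a window larger than its sequence yields an empty profile with a
warning, zero QC-passing clones yield an empty summary with a warning, and
an empty query set makes `overlap_fraction()` an error rather than a
silent NaN.

Known limitations: the designer's uniformity over sequences is
approximate (the repair pass is a conditional resampling, not exact
rejection sampling); the scanner assumes an assembled FASTA and has no
streaming mode for chromosomes that do not fit memory; the bisulfite
caller is deliberately gapless and top-strand only; and genome-scale
published counts (block tallies on a particular mouse assembly, the
fraction of bivalent promoters coinciding with CGIs) are functions of
external data versions — the pipeline recomputes them from supplied
inputs but the package asserts no fixed values for them.
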