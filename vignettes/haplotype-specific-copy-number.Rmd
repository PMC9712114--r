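---
title: "Haplotype-specific copy number inference and foreground structural variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-specific copy number inference and foreground structural variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapcells)
```

## Why haplotype-specific copy number

Shallow single-cell whole-genome sequencing measures, per cell, an integer
total copy number in fixed 500-kb bins. Total copy number cannot tell a
gain of the maternal homologue from a gain of the paternal one, yet
processes such as breakage–fusion–bridge cycles and homologous
recombination deficiency act on individual homologues, and independent
subpopulations of cells frequently alter *opposite* homologues of the same
region ("parallel" events). This package infers, per cell and bin, the
pair (a, b) of homologue copy numbers, and builds on it a set of
statistics for cell-to-cell structural variation: amplitude variance of
high-level amplifications, parallel allelic events, serrate breakpoints,
missegregation, whole-genome-doubling-aware copy number distances, and
parsimony event rates on single-cell phylogenies.

## The emission–transition model

Conditioned on the total state $t_i$ of bin $i$, the hidden state space is
$S_i = \{(a,b) : a+b = t_i\}$, parameterized by $b$. The observation is
the number of reads supporting the B haplotype among the bin's
allele-informative reads, aggregated from phased haplotype blocks
(each block is assigned to the bin containing its midpoint). Emissions are
Beta-Binomial:

$$ b_i^{obs} \sim \mathrm{BetaBin}\!\left(t_i^{obs},\ \mu = \mathrm{clamp}\!\left(\tfrac{b}{t_i},\ \varepsilon,\ 1-\varepsilon\right),\ s\right) $$

* $\varepsilon$ (default 0.01) shrinks the expected BAF away from $\{0,1\}$:
  sequencing and phasing errors make pure-allele observations imperfect, and
  without the clamp a single stray read would zero out an LOH state's
  likelihood.
* $s$ (default 50) is the Beta-Binomial concentration ($\alpha+\beta$).
  It is a free parameter of this implementation, estimable by method of
  moments from regions that are balanced in essentially all cells; 50
  corresponds to the mild overdispersion we observe in simulated
  nanowell-style data and is deliberately conservative.
* Bins with $t_i = 0$ carry the single state (0,0) and emit nothing; reads
  observed there are counted and reported as discordant. Bins with no
  reads emit likelihood 1 for every state.
* Totals above `t_max` (default 12) are clamped: the state space is built
  on `t_max` while keeping the BAF grid, bounding state-space growth at
  high-level amplifications.

Transitions along a chromosome keep the current phase with probability $e$
(default 0.95): the self-transition mass goes to the state of the next bin
whose BAF is nearest the current state's BAF (ties to the smaller $b$;
the (0,0) state takes BAF 0.5 for this purpose), and the remaining
$1-e$ is uniform over the other states. This generalizes a diagonal
self-transition to neighbouring bins with *different* totals, which the
model must handle constantly at copy number breakpoints. $e = 0.999$ is
the documented alternative for unusually noisy samples. The initial
distribution is uniform over the first bin's states. Decoding is exact
Viterbi per cell and chromosome; the posterior of each assigned state is
computed by forward–backward and reported alongside.

Raising $e$ can only reduce the number of state changes along a decoded
path; the test suite asserts this monotonicity and checks the decoder
against exhaustive path enumeration (with an independently integrated
Beta-Binomial likelihood) on small chromosomes.

## Phasing across the population

Haplotype blocks arrive with per-block orientation: which allele the
caller labelled "B" is arbitrary per block unless upstream statistical
phasing already aligned them. Two operations address this:

* `phase_blocks()` applies the population-aggregate rule: every block
  whose aggregate BAF across cells exceeds 0.5 is flipped, so aggregate B
  becomes the chromosome-level minor allele. Ties at exactly 0.5 keep the
  current orientation. This is the right initializer when input
  orientations are arbitrary.
* `infer_population_hscn()` by default *trusts* the input orientations
  (statistically phased data is mostly consistent, with occasional switch
  errors) and only repairs them: each round, every block is compared with
  a local reference — the count-weighted mean signed BAF deviation of each
  cell over the block's neighbours within `phase_window` (10) blocks — and
  flipped when its own per-cell deviations anticorrelate with that
  reference. Using *which* cells deviate rather than the population mean
  is essential: when two cell subsets carry events on opposite
  homologues, the aggregate BAF is balanced and carries no orientation
  signal, but the cross-cell pattern does. Iteration stops at convergence
  or `max_phase_iters` (10).

A design point worth stating explicitly: the relative phase of two genome
regions whose cross-cell imbalance patterns are uncorrelated is not
identifiable from allele counts alone — both labellings have identical
likelihood and identical path parsimony. Identifiability of long-range
phase comes from the upstream phasing, which is why the default preserves
input orientations and why the simulator models phased input (below).
After decoding, labels are made canonical per chromosome: the aggregate
BAF of allele B is at most 0.5. Quantities that do not depend on the
labelling at all — LOH, total states, minor-allele copy, distances —
are unaffected by any of this.

## Downstream statistics and their rules

All cutoffs follow the field's printed conventions and are exercised at,
below and above the boundary in the test suite:

* Bin filter: mappability ≤ 0.99 removed, plus blacklist overlap. Cell
  filter: quality ≥ 0.75, not S-phase, contamination ≤ 5% (upstream
  classifier outputs; inputs here).
* Cell ploidy = modal state over unmasked bins; modal ties resolve to the
  smaller value everywhere in the package, making every consensus
  deterministic.
* Gain/loss segments relative to ploidy; segments spanning ≤ 1.5 Mb
  (three bins) are discarded as state noise. Span is the sum of unmasked
  bin widths, so calls are invariant to masked bins inside a run.
* Missegregation: cells whose ploidy differs from the clone consensus are
  rescaled (`state × clone_ploidy / cell_ploidy`, rounded half away from
  zero — the rounding rule is our choice, no convention exists), and a
  chromosome is flagged when one exact nonzero offset covers ≥ 75% of its
  bins. A clean genome doubling therefore yields no events.
* HLAMP: raw copy ≥ 10 in ≥ 10 cells per bin; variance after dividing by
  cell ploidy and centering on the clone mean; gene-level clone max/min
  ratio with the inclusive boundary (ratio ≥ 2 is "variable" — the
  literature uses both ≥ and >; we chose inclusive and test the boundary).
* Serration: clone consensus profiles are segmented into maximal
  constant-state runs (the full piecewise-constant segmentation, not only
  gain/loss runs — breakpoint matching needs the neighbours' states);
  cell segments are matched under the local-min/local-max/intermediate
  compatibility rule with one-sided comparisons at chromosome ends; the
  noise filter removes cells whose mean |raw − state| over ±5 bins around
  their breakpoint exceeds the stable-cell mean; a position is rare if
  carried by strictly < 5% of the event's cells; eligibility needs ≥ 100
  cells and ≥ 20 Mbp of adjacent consensus segments.
* Parallel events: per disjoint genotyped segment (GenomicRanges::disjoin
  of the clone segmentations; per-cell modal genotypes), both alleles
  altered in > 1% of cells on a span > 4 Mbp; CCF from total states with
  classes clonal (> 0.8), subclonal (0.2, 0.8], rare (≤ 0.2].
* Copy number transformation distance: minimum number of contiguous ±1
  events turning one profile into another, zeros absorbing. The
  implementation is an exact dynamic program over per-position event
  coverage counts (deletions scheduled before amplifications; a position
  deleted to zero becomes transparent to later events, which can merge
  strokes across it), run-length compressed, and is verified against a
  breadth-first-search oracle over operation sequences. Distances are
  summed per chromosome and haplotype; whole-genome doubling of either
  profile is allowed at the cost of one extra event, with ties favouring
  the undoubled comparison. Pairwise matrices symmetrize each pair by the
  cheaper direction and summarize over feasible pairs (an infeasible
  direction arises when a zero position would need to regain copies).
* Event rates: per segment, binary gained/not and lost/not states relative
  to the modal state across cells; Sankoff ancestral reconstruction with
  unit costs on the cell phylogeny (exact for multifurcating trees; checked
  against exhaustive labellings and against phangorn's Fitch
  implementation); rates = summed parsimony score / number of cells,
  stratified by scale (whole chromosome / arm / segmental at 95% coverage
  — the tolerance is our choice) and copy number background.
* scRNA allelic imbalance: segments ≥ 10 Mbp, cells with < 200 SNP counts
  removed, BAF as summed ratios; the neighbourhood enrichment score is
  `log2(observed/expected)` so that 0 means a perfectly mixed
  neighbourhood (the ratio and the zero-centred reading of the score are
  reconciled by the log).

## What the simulator emulates — and what it does not

`simulate_population()` draws a clone tree, applies haplotype-specific
gains and losses at whole-chromosome, arm and segment scale along its
edges, optionally doubles clone genomes, and plants HLAMP loci (amplitude
jittered per cell by a lognormal factor), non-overlapping parallel events
with stated per-allele cell fractions, serrate breakpoints (per-cell
offsets geometric around the modal position; smaller p = heavier serration)
and private per-cell events. Readouts: bin reads are negative-binomial with
mean proportional to the true total copy; allele-informative totals are a
binomial thinning of bin reads; B counts are Beta-Binomial around the true
haplotype fraction; raw copies are reads rescaled so each cell's mean
equals its modal ploidy (the "cell mean = ploidy" convention, chosen
because HLAMP thresholds are expressed on the copy scale).

Block orientations model statistically phased input: one arbitrary
reference flip per chromosome plus block-level switch errors at
`phase_switch_prob` (a property of the block shared by all cells, as real
phasing errors are). `scramble_orientation = TRUE` randomizes every block
instead; as discussed above, under full scrambling only
relabelling-invariant quantities remain identifiable, and the test suite
uses this mode precisely for the relabelling-invariance property.

The generator does not emulate: GC and mappability bias (off by default to
keep fixtures interpretable), doublets and contamination (QC flags are
inputs), read-level artefacts, replication-timing structure, or SV
breakpoint sequences (the SV table consumed by the HLAMP feature vectors
is an input). Passing tests therefore demonstrate correctness of the
inference and statistics under the stated generative assumptions, not
robustness to every artefact of real libraries.

## Numerical and engineering choices

* All likelihood computations are in log space; forward–backward uses
  log-sum-exp.
* Every modal tie resolves to the smaller value (lexicographic for (a,b)
  pairs); even-count medians use the lower middle for integer fields and
  the arithmetic mean for real fields. Re-running any stage on identical
  input yields identical output; a single seed controls all stochastic
  stages.
* Problem sizes in the test and acceptance runs — 200–500 cells, 100–200
  bins, depth 20, 60-cell distance subsamples — were chosen as the
  smallest populations at which the stochastic recovery statistics are
  stable; the simulator and all algorithms scale to thousands of cells.
* Coordinates are 1-based inclusive throughout; BED conversion happens
  only in `read_blacklist_bed()`/`write_blacklist_bed()`.

## Known limitations

* Total copy number is conditioned on, not re-estimated: errors in the
  upstream integer states propagate to (a, b).
* The Beta-Binomial concentration is global; amplicon-specific
  overdispersion is not modelled.
* Long-range phase between imbalance-uncorrelated regions is taken from
  the input phasing; the package can repair block-level switch errors but
  cannot create phase information that the input does not contain.
* Serration scores are computed per clone-level breakpoint; cells are
  matched only within their own clone, and events whose clone has no
  stable (modal-position) cell are skipped rather than scored.

```{r example}
cfg <- sim_config(n_cells = 40, bins_per_chrom = 30, seed = 5,
                  events_per_edge = c(whole_chromosome = 1, arm = 1,
                                      segment = 1))
sim <- simulate_population(cfg)
hscn <- infer_population_hscn(sim$cn, sim$alleles, sim$grid)
unlist(truth_metrics(hscn, sim))
```
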