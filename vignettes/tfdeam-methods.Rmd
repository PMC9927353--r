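---
title: "Profiling TF-guided deamination SNPs: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling TF-guided deamination SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfdeam)
```

## The experiment being modelled

A cytidine deaminase fused to a transcription factor (TF) deaminates
cytosines near the TF's binding sites when the local DNA is transiently
single-stranded (chiefly in the transcription open complex). In a strain
lacking uracil-DNA glycosylase the resulting U:G lesions are not repaired,
and replication converts them to C→T substitutions — or G→A in
reference-strand notation when the edited cytosine lay on the minus strand.
Cells are induced at high density and serially passaged (two 12-h rounds
with 5× dilution, roughly `G = 24` generations), which gives the deaminase
several generations to act while limiting the number of generations over
which slow-growing mutants are purged. Whole-genome sequencing of the
population then reads each mutation out as an allele frequency
(alt reads / total reads).

The analysis problem is pure set discrimination: which of the called SNPs
were guided by the TF? `tfdeam` answers it with the screening cascade
described below, and ships a generative simulator of the whole experiment
so that every screening stage can be tested against ground truth.

## The screening cascade

Each sample is a `snp_set`, keyed by the identity tuple
(contig, 0-based position, ref, alt). Requiring the identical alternate
base prevents conflating different substitutions at one position; depths
and frequencies never enter membership tests.

1. **Wild-type stock exclusion.** SNPs already fixed in the lab stock are
   removed from every replicate before anything else.
2. **Replicate consensus** (`intersect_replicates`). A stochastic mutation
   present in one replicate recurs in all `k` with probability `p0^k`, so
   the expected leak-through is `N * p0^k` (`expected_shared_stochastic`).
   At `N = 6.3e6`, `p0 = 1e-4`, `k = 3` that is `6.3e-6` shared SNPs — the
   consensus is, for practical purposes, background-free. The retained
   records carry every replicate's frequency (`freq_rep1..k`) for
   reproducibility statistics.
3. **Background subtraction** (`build_background`, `subtract_background`).
   The union of the void-vector consensus, the deaminase-only consensus
   and the stock set removes reproducible but TF-independent mutations
   (deaminase sequence bias, hypermutable loci, media effects).
4. **Region exclusion** (`filter_excluded_regions`). Known hypermutable
   spans — in *Pseudomonas aeruginosa* PAO1, the pf4 prophage region — are
   configured as intervals and dropped. This filter commutes with
   subtraction (both are key/locus filters); the pipeline applies
   subtraction first and the test suite asserts the equivalence.
5. **Cross-TF recurrence** (`filter_recurrent_cross_tf`). A SNP appearing
   in more than `cross_tf_max_occurrences = 2` different TFs' experiments
   is discarded: three unrelated TFs regulating one site is much less
   likely than weak-nonspecific binding. Whether the focal TF's own
   experiment counts toward the tally is not uniquely determined by the
   rule's phrasing; both modes are supported
   (`recurrence_includes_focal`, default `TRUE`, so "more than twice"
   means occurrences ≥ 3 including the focal set).
6. **Attribution** (`classify_region`). A SNP inside any gene body is
   `nonpromoter` even if it is also upstream of a neighbouring gene — the
   promoter-like class is *intergenic* by definition. An intergenic SNP is
   `promoter_like` when its intergenic interval lies 5′ of at least one
   flanking gene: the right-flanking gene on `+`, the left-flanking gene
   on `-`, both for a divergent pair. No maximum upstream distance is
   imposed: the definition is positional, not metric, so a long intergenic
   region is promoter-like throughout. The complement (gene bodies,
   convergent gaps) is `nonpromoter`.
7. **Flank retrieval** (`extract_flanks`). 100 bp on each side of the SNP
   (201 bp in all) on the reference strand, written as FASTA for motif
   discovery. Windows at contig ends are truncated, never N-padded —
   padding would invent sequence, and motif tools accept ragged lengths —
   with a `flank_truncated` flag.

Coordinates are 0-based half-open everywhere inside the package; VCF
(1-based) and GFF3 (1-based closed) are converted at the I/O boundary only,
and reports print 1-based positions. Records lacking depth information get
`frequency = NA` ("unknown"), which is excluded from frequency statistics
rather than treated as 0.

## The simulator

`simulate_experiment` builds, deterministically under one seed:

* a uniform-composition random contig with non-overlapping gene bodies
  (`generate_genome`; lengths ~ Normal(600, 120) bp truncated at 90, gaps
  ≥ 80 bp — compact, bacterial-like spacing at test scale);
* `n_boxes` copies of a 20-bp dyad consensus written into randomly chosen
  promoter-like intergenic regions (`plant_boxes`), each with an occupancy
  drawn from U(0.5, 1) by default — occupancy is the probability the box
  is TF-bound, `[TF]/([TF]+Kd)` under first-order binding, so 0.5
  corresponds to expression at the dissociation constant;
* sequenced replicates (`simulate_replicate`) for the TF strain, a
  deaminase-only control (same boxes, occupancy forced to 0) and a
  void-vector control.

### Directed editing model

The per-generation editing probability of a site at distance `d` from a
box is

```
mu(d) = mu0 * occupancy * exp(-d / window_scale)   for d <= window_max,
```

with `d` clipped to 0 inside the box and `mu = 0` for bases other than C/G
(`site_edit_prob`). On top of this closed form the replicate engine applies
the deaminase's sequence-context preference: sites in a WRC context
(W = A/T, R = A/G, reading the edited C; GYW on the minus strand) edit at
the full rate, all other C/G sites at `cold_factor = 0.05` of it. Without
this heterogeneity every C/G in a window would cross the detection
threshold together — population frequencies are deterministic per site — and
simulated boxes would light up as solid runs of SNPs rather than the few
discrete sites real experiments show. The context factor is switchable
(`wrc_hotspot = FALSE`) for studies of the pure distance model.

Defaults: `mu0 = 0.03`, `window_scale = 10` bp, `window_max = 100` bp.
With occupancy ≥ 0.5 a hotspot inside the box reaches a population
frequency of `1 - (1 - 0.015)^24 ≈ 0.30`, comfortably above caller
thresholds, while hotspots beyond ~20 bp fall below them — so detected
SNPs concentrate within a few tens of bp of the box, most sites near a box
stay silent, and the planted consensus (which contains two symmetric
WRC/GYW hotspots of its own) guarantees that every occupied box is
recoverable. Under these defaults a box typically yields ~4–8 surviving
SNPs; exactly-one-SNP-per-box behaviour cannot emerge from deterministic
per-site frequencies and a palindromic box, and is not claimed.

### Frequency dynamics

`freq_after_generations` iterates, per generation, conversion
`f <- f + (1 - f) * mu` then selection `f <- f (1 - s) / (1 - f s)`.
With `s = 0` this closes to `1 - (1 - mu)^G`. The test suite checks the
recursion against an agent-based Monte-Carlo population (explicit cells,
binomial mutation, selection-weighted resampling) within three standard
errors. Selection is off by default (`s = 0`): the serial-passage protocol
is designed to limit purging of slow-growing mutants, and the package makes
no claim about fitness effects of individual lesions.

### Background model

Each bp mutates per experiment with probability `1 - (1 - p_bg)^G`
(compounded rather than trajectory-simulated; the agent-based oracle, not
the engine, carries full lineages). The default `p_bg = 4.2e-6` per
generation compounds to ≈ 1e-4 per experiment — the stochastic rate bound
the screening argument assumes. A background lesion arises in a single
cell at a uniformly drawn generation `g` and drifts neutrally, so its
final population share is approximated as `2^-g`; most such lesions sit
below caller thresholds, which is why the *detected* background rate is a
few-fold lower than the mutated-position rate, as in real data.

### Sequencing and caller emulation

`alt_depth ~ Binomial(depth = 100, f)`; a record is emitted only when the
alternate fraction reaches `detect_min_frac = 0.1` and the alternate count
reaches `detect_min_alt = 3`. These thresholds are ordinary variant-caller
behaviour, not published constants; both are configurable, and the
profiler itself trusts the caller (`min_frequency = 0`) unless told
otherwise.

### What the simulator does not model

Read-level artefacts (sequencing error, PCR duplicates, mapping bias),
transcription-rate-dependent single-strand exposure, deaminase expression
variability, fitness effects of specific lesions, and real genome
composition (the synthetic contig is uniform-random, so hotspot density is
uniform too). Passing tests on simulated data therefore demonstrate the
*set algebra, attribution geometry and statistical machinery* of the
pipeline — not robustness to caller artefacts or to biological
false-negative modes (fusion-impaired TFs, silent promoters), which are
properties of the wet protocol, not of this software.

## Summary statistics

* `distance_to_box`: signed distance to the nearest box base; adjacent
  base = 1, in-box sites are negative, `-(1 + offset to the nearer edge)`,
  so the first/last box base is −1. Only in-box SNPs are negative. The
  in-box magnitude convention is this package's; only the sign convention
  is standard.
* `strand_class`: returns the strand carrying the deaminated C relative to
  a gene — a reference C>T is `CS` (coding strand) for a `+` gene and `TS`
  (template strand) for a `-` gene; G>A is the reverse; anything else is
  not a deamination signature and errors. Under the simulator's
  strand-symmetric editing the TS:CS ratio is ~1, which the tests check
  with a binomial test.
* `replicate_r2`: pairwise ordinary-least-squares R² of replicate
  frequencies over the consensus set — three values for three replicates,
  regressing replicate *j* on *i* for *i* < *j*, intercept included
  (computed as `cor(x, y)^2`, which is identical for the OLS fit with
  intercept). Pairwise rather than replicate-vs-mean because exactly one
  R² per replicate pair is the natural readout of three samples. Constant
  vectors give `NA` — undefined, never 0.
* `promoter_peak_frequency`: per promoter, the maximum SNP frequency (the
  site with the highest frequency represents the promoter's degree of
  mutation).
* `snps_per_box`: per-box SNP counts within a window, and their histogram.
* `venn_compare`: overlap / new targets / not detected against a reference
  target list, with the identities `overlap + new = |detected|` and
  `overlap + not_detected = |reference|`. Divergent promoter regions carry
  comma-composite ids (`g1,g2`); components are matched on both sides, so
  either gene id counts as the same target (which can make one detected
  region cover two single-gene reference entries).

## Numerical and degenerate-input choices

* SNP frequencies with zero or unknown total depth are `NA`, propagated as
  "unknown" and excluded from statistics.
* Empty final SNP sets are valid results, reported prominently rather than
  raised as errors; `run_profile` is total on empty inputs.
* `distance_to_box` tie-breaks equidistant boxes toward the lower start
  coordinate; an enclosing box always wins.
* Multiallelic VCF rows are split into per-alt records by default
  (skippable); indels and MNVs are dropped at read time — the method's
  signal is single-nucleotide deamination.
* Seeds: every stochastic stage takes an explicit seed and restores the
  caller's RNG state (`withr::with_seed`); replicate streams derive from
  `(experiment seed, replicate seed)` so replicates are independent but
  jointly reproducible.

## Problem sizes used in the tests

The default simulated scenario is a 100-kb genome with 40 genes and 10
boxes at 100× depth — large enough for every pipeline stage to see
realistic multiplicity (tens of SNPs, divergent and convergent gene pairs,
composite promoters) while a full experiment simulates in a few seconds.
The stochastic-sharing validation runs 200 seeds of background-only
replicates on gene-free contigs (1e5–2e5 bp), comparing shared-position
counts to `N * p0^k` under a Poisson band; the genome-scale bound itself is
checked analytically and by rescaled Monte-Carlo.

## Known limitations

* Promoter-likeness is purely positional; without transcription-start or
  operon information, leaderless genes and internal promoters are
  misclassified by construction.
* The recurrence filter needs the other TFs' SNP sets to exist; profiling
  a single TF leaves that filter inert.
* Benchmarking against literature target lists inherits the curation of
  those lists; `venn_compare` counts identities, it does not judge them.
* The simulator's directed-editing scale (`mu0`) is a free parameter: the
  experimental literature constrains the *shape* of the footprint (tight
  concentration within tens of bp of the box) and the detectability of
  sensitive promoters, not an absolute per-generation rate.
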