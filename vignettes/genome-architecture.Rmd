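---
title: "Methods: repeat landscapes, telomeres and two-speed compartments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat landscapes, telomeres and two-speed compartments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genarch)
```

This vignette is the package's own account of what it computes, the
assumptions baked into each statistic, the numerical choices made where the
underlying conventions are genuinely open, and what the synthetic-data tests
do and do not establish about real genomes.

## Coordinates and input contracts

All internal coordinates are 0-based half-open, so `end - start` is a length
everywhere and flanking-distance arithmetic needs no ±1 corrections.
Conversion happens only at file boundaries: GFF3 (1-based inclusive) is
converted on read and reconverted on write; BED output is natively 0-based
half-open. Soft-masked (lowercase) bases are uppercased and not treated
specially — masking state carries no information for any statistic computed
here. Characters outside `{A,C,G,T,N}` are mapped to `N` with a warning:
ambiguity codes are rare in polished assemblies and treating them as
missing is conservative for every downstream count.

Gene-category labels (effector / CAZyme / core) are consumed from upstream
predictors as a closed vocabulary. A gene labelled both effector and CAZyme
contributes to both category summaries but is treated as an effector — the
rarer, more informative class — wherever a single label per gene is needed
(plots, enrichment resolution).

## SSR detection

The scanner reports every **maximal perfect tandem run** with motif length
`min_len`–`max_len` (default 2–10 bp) and at least `min_repeats` (default 5)
complete units. Perfect means exact: no mismatches or indels, which is the
defensible contract when only length and repeat-count thresholds are
specified. The mechanism compares the sequence with itself shifted by each
candidate period `p`; a run of `L` consecutive matching positions is a
perfectly periodic region of length `L + p`. Consequences of the contract:

- **Mononucleotide runs are excluded** by `min_len = 2`; a poly-A run is
  never reported as an "AA" dinucleotide because motifs must be
  period-minimal (not a repetition of a shorter unit).
- **Partial trailing units extend the span** but do not increment the unit
  count, so a 11-bp `(AT)5A` region is one locus of 5 units spanning 11 bp.
- **Runs are split at `N`** and loci never contain `N`.
- **Both strands are covered by canonicalisation** rather than double
  scanning: each locus is reported once, on forward-strand coordinates,
  under the lexicographically smallest motif among all rotations of the
  motif and of its reverse complement. Scanning a reverse-complemented
  scaffold therefore yields mirrored coordinates and identical canonical
  motifs — a tested invariant.
- **Overlapping candidates of different periods** are resolved greedily:
  longer span wins, ties go to the smaller period, then to the leftmost
  start. One visible consequence: two abutting arrays whose periodicities
  chain across the junction (e.g. `...ATAT` + `ACG...`, where the leading
  `A` of the second array continues the dinucleotide phase) can resolve to
  a single locus; arrays separated by even one phase-breaking base stay
  separate.

Published per-genome totals depend on the counting conventions of whichever
detection tool produced them (compound-repeat merging in particular), so
summaries report both the raw locus count and the count after merging
book-ended/overlapping spans, and coverage is always computed on the span
union. Correctness is established against an independent brute-force oracle
(regex backreference matching plus manual extension) over thousands of
random sequences, not against any external tool's output files.

## Telomere end-calling

A scaffold end is telomeric when at least `min_copies` (default 5)
*consecutive* units occur within the terminal `window` (default 200 bp);
the forward unit (default `TTAGGG`, the common fungal repeat) is expected
at the 3′ end and its reverse complement at the 5′ end, reflecting the
G-rich strand running towards each terminus. A single interruption breaks a
run — the simplest defensible contract given that published thresholds for
this call are rarely stated; unit, copies and window are all configurable.
Reverse-complementing a scaffold swaps the two ends and their copy counts
exactly (tested). Interstitial telomeric repeats are out of scope.

## Flanking intergenic regions and compartments

For consecutive genes `a`, `b` on a scaffold the gap is
`max(0, b.start − a.end)`; overlapping or nested genes share a gap of 0.
Gaps are assigned to each gene's 5′/3′ sides by its own strand (the
convention is declared because published FIR plots rarely define it; a
strand flip swaps the two slots, which is tested). Scaffold-terminal genes
receive the distance to the scaffold end with a boundary flag and are
**excluded** from densities, summaries and classification by default:
assembly breaks truncate the true intergenic distance, so boundary FIRs are
lower bounds, not measurements.

The 2-D density surface bins `(fir5, fir3)` pairs on `n_bins` (default 30)
log10-spaced edges over 1–100,000 bp. Zero-length FIRs enter through a
+1 bp pseudo-count; values beyond the range are clamped into the terminal
bins, so the matrix total always equals the number of genes binned.

Compartment assignment formalises what two-speed contour plots show
visually: a gene is *sparse* iff **both** FIRs reach a threshold. The
default threshold is the 75th percentile of pooled non-boundary FIR values
(`"q75"`). With a bipartite architecture whose sparse compartment is a
minority, the pooled upper quartile falls in the trough between the short-
and long-gap modes, making the rule robust to the exact quantile; a fixed
bp threshold can be supplied when an external calibration exists. Because
no quantitative threshold accompanies published two-speed figures,
classification accuracy is validated on synthetic genomes with known
compartments (≥ 90 % required, ~99.8 % observed at the default
configuration) rather than against a published gene list.

Enrichment of a category in the sparse compartment uses the 2×2 table
(category/other × sparse/dense), a two-sided Fisher exact test, and BH
correction across the categories tested in one call, judged at q < 0.05.

## Fisher's exact test and BH

The two-sided p-value follows the probability-mass rule — the sum of
hypergeometric probabilities of all tables with the observed margins whose
probability does not exceed the observed table's (absolute slack 1e-12 for
floating-point ties) — the dominant convention for 2×2 tables, and the one
`stats::fisher.test()` implements; the test suite checks both agreement
with that reference and exact agreement with a `choose()`-arithmetic
enumeration oracle for every table with n ≤ 30. The odds ratio is the
*sample* OR `(a·d)/(b·c)` (Haldane +0.5 on every cell iff some cell is
zero), not the conditional MLE, because the sample OR is what tabulated
comparative summaries print. BH q-values delegate to
`stats::p.adjust(method = "BH")` behind a validating wrapper. Percent
outputs that mirror printed tables (coding fraction, singleton share) round
half-up to two decimals to match table formatting.

## The synthetic-assembly generator

`simulate_assembly()` emulates exactly the structures the analyses assume:

- **Layout.** Each scaffold carries alternating blocks of dense and sparse
  genes (default 30/10 per cycle, 5 scaffolds × 100 genes). Intergenic
  gaps are log-normal: dense `LogNormal(ln 200, 0.5)`, sparse
  `LogNormal(ln 5000, 0.5)` bp. Gaps at block transitions are drawn from
  the sparse law — compartment boundaries are repeat-rich in real genomes —
  so each gene's two flanking gaps match its own block and the planted
  compartment label is well-defined. Scaffold length is emergent (margins +
  genes + drawn gaps) rather than fixed, since fixing both the gap
  distributions and a total length would over-constrain the layout.
- **Genes** are `N(1500, 300)` bp (clipped at 300), uniform random strand,
  gene bodies plain background sequence: no analysis here reads coding
  content. Background is i.i.d. at the target GC (default 0.525, a typical
  Sordariomycete value); there is no transposon or RIP model, which is out
  of scope.
- **Categories.** Per-gene conditional probabilities: effector 0.75 in
  sparse vs 0.05 in dense blocks (CAZyme 0.25 vs 0.10, drawn after the
  effector label, categories mutually exclusive). These are deliberately
  strong effects: they test the machinery's direction and calibration, not
  the marginal detectability of weak compartmentalisation.
- **Planted repeats.** Default `(AT)10 ×15`, `(AAG)7 ×10`, `(ACAT)6 ×8`,
  placed in intergenic gaps with a 2 bp guard, never overlapping genes or
  each other; the flanking bases are set to break the periodicity so each
  array is maximal at exactly its planted span, making exact-span recovery
  a fair test. Planted telomeres (default `TTAGGG` ×8; scaffold 1 both
  ends, middle scaffolds 3′ only, last scaffold none) are likewise
  flank-broken. Telomere arrays are themselves genuine tandem repeats, so
  SSR *precision* against the planted-SSR list counts them with the random
  background; recovery tests therefore assert recall.

All randomness flows from one seed; identical configurations produce
byte-identical files (hash-tested). What passing these tests shows: the
statistics recover planted structure of the stated effect sizes
essentially perfectly. What they do not show: behaviour on imperfect
repeats, nested gene models from real annotation pipelines, fragmented
assemblies dominated by boundary genes, or compartments defined by
transposon content rather than gene spacing — on real data those features
deserve inspection of the density surface, not just the classifier output.

## Problem sizes and runtime choices

The default simulated assembly is ~1.5 Mb × 500 genes, which a scan
completes in about two seconds; oracle-equivalence sweeps use 1,000 random
sequences up to 10 kb; the Fisher sweep is exhaustive to n = 30; enrichment
calibration uses 100 replicate simulations. These sizes make the whole
suite run in a few minutes while leaving every assertion at full strength;
full-genome runs (tens of Mb) use the identical code paths and scale
linearly in sequence length.

## Known limitations

- Perfect-repeat detection only; imperfect/approximate microsatellites are
  a different problem with tuning parameters this package does not expose.
- The q75 compartment rule assumes a minority sparse compartment; genomes
  without bipartite structure will still be split at the quantile, so the
  density surface (bimodality) should be checked before interpreting the
  classification.
- Enrichment treats genes as exchangeable; spatial autocorrelation along
  scaffolds (effector clustering) is not modelled in the test's null.
- The simulator's i.i.d. background underestimates the repeat content of
  real fungal genomes; background SSR counts from simulations are reported
  but are not a calibration target.
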