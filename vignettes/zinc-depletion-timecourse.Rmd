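---
title: "Methods: time-course transcriptomics of zinc depletion in the fish gill"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-course transcriptomics of zinc depletion in the fish gill}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gillzinc)
```

## The experiment this package models

gillzinc analyses two-channel microarray time courses in which fish gill
RNA from a treatment group (zinc-depleted water and diet) and a time-matched
control group is hybridised against a common reference, at five sampling
points (0.3, 1, 4, 7 and 14 days) with five biological replicates per
group — 49 arrays in the emulated design, because one control replicate at
day 4 fails quality control. The scientific questions are: which genes are
regulated at which time point, is regulation predominantly up or down, which
functional annotations are over-represented among regulated genes, whether
the promoters of regulated genes are enriched for binding sites of
particular transcription factors, and how regulated products interconnect in
a curated interaction network.

## Preprocessing model

Each spot yields two channel intensities, transformed to
`M = log2(R/G)` and `A = (log2 R + log2 G)/2`. Dye chemistry makes `M`
depend systematically on `A`; we remove this trend per array by subtracting
the lowess fit of `M` on `A` (`stats::lowess`, span 0.3, 3 robustness
iterations — the span used by standard within-array loess normalization in
the microarray literature; the original analysis names no parameters).
Normalization is global per array rather than per print-tip group, because
no print-tip structure is modelled or required by the inputs. Spots flagged
low-confidence by the image quantification are treated as a pre-computed
flag column and set to missing; we do not re-derive spot quality. A reporter
enters the comparison at a time point only when both groups retain at least
three non-missing replicates there, so a reporter can be testable at one
time point and not another.

Numerical conventions: non-positive or missing intensities become `NA` in
both `M` and `A` and propagate; normalization never changes the missingness
pattern; the lowess fit is interpolated back to the observed `A` values
(ties averaged, ends extended flat) so that `sum(input - output)` equals the
summed fitted trend.

## Differential-expression calling

Within each time point, depleted and control log ratios are compared per
reporter by the Welch unequal-variance t-test. The pooled-variance Student
test is available (`var_equal = TRUE`) because the commercial software used
originally does not document its variant; Welch is the default as the more
robust choice under unequal group variances. Zero-variance degeneracies are
resolved by convention: equal constant groups give p = 1, unequal constant
groups give p = 0 and are flagged. P-values are adjusted by
Benjamini-Hochberg **within each time point**, because each time point is a
separate two-group comparison. The effect size is the signed fold change of
the geometric-mean ratio: `r = 2^(mean(depleted) - mean(control))`,
reported as `+r` when `r >= 1` and `-1/r` otherwise. A reporter is called
regulated when `|FC| > 1.8` **and** `q < 0.1`, both strict inequalities.
Reporters, not genes, are the test unit.

The temporal summary treats each called (reporter, time point) pair as one
event, reports per-time-point up/down counts and overall percentages, and
lists persistent-direction genes — called with the same sign at every
sampled time point.

## Term enrichment

Enrichment of a gene list against a background population is the one-sided
upper-tail hypergeometric probability of the observed list-term overlap.
The default mode is the conservative EASE variant, which decrements the
observed overlap by one before taking the tail (an overlap of one gene then
scores p = 1); the plain Fisher tail is available as `mode = "fisher"`.
Terms with zero overlap are omitted from the output and from the
multiple-testing family; adjustment across terms is Benjamini-Hochberg. The
background is an explicit input — the natural choice is the set of
reporters passing the expression filter — never a hard-coded genome.

## Promoter TFBS analysis

Promoters are the 2000 bp upstream of the **translation** start (the ATG),
extracted with 1-based inclusive coordinates: `[s-2000, s-1]` on the plus
strand, `[s+1, s+2000]` reverse-complemented on the minus strand, truncated
(and flagged) at contig edges. Motifs are IUPAC consensus strings; scanning
counts every exact IUPAC-compatible match including overlapping ones, on
both strands by default (minus-strand hits are found by scanning the
reverse-complemented motif, positions reported 1-based on the stored
promoter). An `N` in the promoter sequence never matches any pattern
symbol, including pattern `N` — an ambiguous base is evidence of nothing.

The tested quantity is presence/absence per gene (at least one site on
either strand), matching "percentage of genes with a site", not site
counts; raw counts are still reported. The percentage among regulated genes
is compared with that in a control cohort of 198 genes sampled uniformly
from the never-regulated pool, using the pooled two-proportion z-test
without continuity correction, two-sided — two-sided because depletion of a
site class below the background rate is as informative as enrichment. A
pooled proportion of exactly 0 or 1 is degenerate and scores z = 0, p = 1.
Motif patterns are user inputs; the packaged motif file contains synthetic
demonstration patterns only (including an MRE-like consensus labelled
fixture-only), since curated databases are proprietary.

Where several supplied patterns share a factor name they are scanned
independently; a factor-level union can be formed from the per-gene
presence table.

## Interaction network

The direct-interaction network is the induced subgraph of a curated edge
table on the regulated genes plus declared seed nodes (by default the
metal-ion node `Zn` and `MTF1`, included for its established regulatory
role even when its own transcript is unchanged). Edges are typed (binding,
expression, regulation, metabolism, promoter binding) and optionally
directed; duplicate (source, target, type) triples collapse; members
without edges stay in the node table flagged isolated. Hub ranking counts
unique neighbours, collapsing types and direction, with ties broken by node
id — so "interacting with 55 nodes" is a degree, not an edge count.

## Physiological calculations

Unidirectional ion influx is `J_in = cpm / (SA * bw * t)` in
pmol g^-1 h^-1, with the specific activity `SA` the labelled counts per
total ion content (cpm pmol^-1). qPCR quantification reads relative copies
off a per-gene standard curve, `copies = 10^((Ct - intercept)/slope)`, and
normalizes by the relative copies of the 18S rRNA reference. Standard-curve
fitting is deliberately plain ordinary least squares of Ct on log10
dilution, with the amplification efficiency `10^(-1/slope) - 1` reported
for curve quality control. Group comparisons of such measurements use the
two-sided unpaired pooled-variance t-test at alpha 0.05
(`welch_t_test(..., var_equal = TRUE)`).

## The synthetic-data generator

Every stage is verifiable offline because `simulate_expression_dataset()`
and its companions generate data with planted, enumerable ground truth.
The expression model is

```
M = baseline(reporter) + effect(reporter, condition, time) + b(A) + noise
```

with reporter baselines shared between conditions, intensity `A` drawn
normal(10, 1.7) in log2 units (log-normal intensities spanning roughly
three orders of magnitude, so the lowess fit is exercised over a realistic
MA range), a cubic dye-bias polynomial in centred `A` bounded by about 0.5
log2 units over the bulk of the intensity range, and Gaussian noise.
Defaults encode the emulated study conditions: 16000 reporters; 3% of
reporters regulated at one or more time points; planted effect magnitude
1.5 log2 units with noise SD 0.4; activity mostly at a single time point
(little temporal continuity), with time-point weights peaking at day 7 and
nearly vanishing by day 14; down-regulation probability 0.75 from day 4
onwards and 0.5 earlier, encoding the three-to-one late dominance of
down-regulation; 5% of spots flagged low-confidence. All randomness flows
from one master seed through named sub-streams, so identical configurations
are byte-identical and partial re-runs are stable.

What the generator does **not** emulate: probe sequences, print-tip or
batch structure (none is stated for the emulated experiment),
spatial/image artifacts, correlated noise between reporters, and real
biological pathway dynamics. Passing recovery tests therefore demonstrates
the correctness and calibration of the statistical chain, not performance
on any real dataset.

The promoter generator plants concrete realizations of IUPAC motifs into
`round(fraction * cohort size)` genes per cohort at uniform positions and
records every insertion; the annotation generator forces exact planted
list-term overlaps; the interaction generator draws Bernoulli edges per
node pair. Each emits the plain-text formats the readers consume, so every
file format is round-trip tested.

## Test design and problem sizes

The statistical engines are tested against independent oracles: BH against
a from-definition step-up on all 120 permutations of five p-values; the
hypergeometric tails against explicit binomial-coefficient sums for every
2x2 table with a universe up to 25; the IUPAC scanner against a naive
expand-and-slide oracle on 1000 random sequence/motif pairs (sequences up
to 200 bp including N, motifs up to 10 symbols, both strands); the
two-proportion z against the Pearson chi-square identity `z^2 = X^2` at
1e-10; Welch against `stats::t.test` and a hand-evaluated example.

Calibration and power are checked by simulation at sizes chosen to keep the
suite fast while leaving clear statistical margins: the null
false-discovery proportion uses 200 replicates of 2000 reporters at 5v5
(realized FDP must stay within three Monte-Carlo standard errors of 0.1);
the recovery check is a single-comparison power study with 2000 reporters
and 10% non-null at effect 1.5 / noise 0.4 — a standard FDR power-design
in which BH multiplicity is representative; sensitivity must reach 0.8
with all recovered directions correct, and the noise-free limit must
recover the planted set exactly. Under the full study conditions (3%
regulated, effects mostly at a single time point, per-time-point BH across
16000 reporters) the same chain is necessarily less sensitive (~0.3-0.5);
the acceptance script reports that number honestly alongside the power
study. The TFBS comparison is validated over 200 seeded replicates at the
study's cohort sizes (80 vs 198): presence 0.5 vs 0.05 must be flagged in
at least 95% of replicates, equal presence in at most 7.5%. The
normalization property (all per-A-decile medians of normalized control
log-ratios below 0.02 in absolute value) is checked on the study-scale
simulation by pooling the 24 control arrays, which isolates the dye-bias
trend from replicate-level noise.

## Known limitations

* No empirical-Bayes variance moderation or longitudinal modelling across
  time points; each time point is tested marginally, exactly as in the
  emulated analysis.
* The EASE/Fisher statistic is implemented, but term databases and their
  clustering heuristics are not; enrichment output depends entirely on the
  supplied term table.
* Motif scanning is consensus-based; no position-weight-matrix scoring.
* The interaction stage assembles and summarises a supplied edge table; it
  has no curated interaction content of its own.
* Dye-swap designs, background subtraction and between-array normalization
  are out of scope.
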