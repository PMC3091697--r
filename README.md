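# gillzinc

Analysis pipeline for two-channel microarray **time courses** of ion
depletion in the fish gill — the model system in which a treatment group
(zinc-depleted water and diet) and a time-matched control are profiled
against a common reference at several sampling points with biological
replication. The package is for researchers who want the complete
statistical chain of such a study as tested, reusable functions: from raw
channel intensities to per-time-point regulation calls, temporal
summaries, annotation enrichment, promoter binding-site statistics, an
interaction network, and the accompanying physiological calculations.

## What it computes

* **Preprocessing** — MA transform (`M = log2(R/G)`,
  `A = (log2 R + log2 G)/2`), per-array lowess normalization of `M` on
  `A`, confidence masking, and a ≥3-replicates-per-group filter applied
  per (time point, comparison).
* **Differential expression** — per time point, Welch t-test per reporter,
  Benjamini–Hochberg adjustment within the time point, signed fold change
  `FC = +r` (`r ≥ 1`) or `−1/r` (`r < 1`) with
  `r = 2^(mean_depleted − mean_control)`; a reporter is called regulated
  when `|FC| > 1.8` and `q < 0.1` (strict). Temporal summaries count each
  called (reporter, time point) pair as one event and report
  persistent-direction genes.
* **Term enrichment** — one-sided hypergeometric tail of the list–term
  overlap against an explicit background, in plain Fisher or conservative
  EASE mode (overlap decremented by one), BH-adjusted across terms.
* **Promoter TFBS analysis** — extraction of 2000 bp upstream of the
  translation start (strand-aware, truncation-flagged), IUPAC consensus
  scanning on both strands (overlapping matches counted; subject `N`
  matches nothing), and the pooled two-proportion z-test comparing the
  percentage of genes carrying ≥1 site between regulated genes and a
  seeded cohort of 198 never-regulated controls.
* **Network** — induced subgraph of a curated edge table on regulated
  genes plus seed nodes (`Zn`, `MTF1`), with unique-neighbour hub ranking.
* **Physiology** — unidirectional influx `J_in = cpm/(SA·bw·t)` and qPCR
  standard-curve quantification normalized to 18S.
* **Synthetic data** — generators for every input, with planted,
  enumerable ground truth (`simulate_expression_dataset()`,
  `simulate_promoter_set()`, `simulate_annotation_table()`,
  `simulate_interaction_table()`, `simulate_study()`), so the whole chain
  is verifiable without downloads.

## Worked example

```r
library(gillzinc)

cfg   <- sim_config(n_reporters = 4000, seed = 1)   # 2 x 5 x 5 design, 49 arrays
sim   <- simulate_expression_dataset(cfg)
ds    <- filter_expressed(normalize_dataset(sim$dataset), min_replicates = 3)
calls <- call_regulated(ds, fc_threshold = 1.8, fdr_threshold = 0.1)
s     <- temporal_summary(calls)
s$per_time
#>   time n_up n_down n_total
#> 1  0.3    0      2       2
#> 2  1.0    2      1       3
#> 3  4.0    0      0       0
#> 4  7.0    6     16      22
#> 5 14.0    1      0       1
sprintf("%.1f%% of events up, %.1f%% down (%d events)", s$pct_up, s$pct_down, s$n_events)
#> "32.1% of events up, 67.9% down (28 events)"
head(calls[calls$called, ], 3)
#>      reporter time        fc            p          q direction called
#> 1438   R01444  0.3 -3.580801 2.250014e-05 0.08280902      down   TRUE
#> 3034   R03044  0.3 -3.108267 4.152910e-05 0.08280902      down   TRUE
#> 5107   R01121  1.0  2.681075 1.289744e-05 0.03324108        up   TRUE
```

The summary shows the simulated study's signature: regulation peaks at day
7, down-regulation dominates after day 1, and each row of `calls` carries
the signed fold change, raw p, within-time-point q, and the call flag. The
individual statistics are available directly:

```r
welch_t_test(c(1, 2, 3), c(2, 4, 6))       # t = -1.549, df = 2.941, p = 0.221
zinc_influx(cpm = 1500, SA = 12, bw = 0.45, t = 3)  # 92.6 pmol g^-1 h^-1
```

`simulate_study()` writes a complete demo input directory (expression
TSVs, genome FASTA + coordinates, motif file, GMT term table, edge table)
and `run_pipeline(pipeline_config(...))` drives all stages end to end into
a report bundle (`de_calls.tsv`, `temporal_summary.json`,
`enrichment.tsv`, `tfbs_comparison.tsv`, network files, run log).

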