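# aluhsf

Heat shock factor (HSF) binding sites inside Alu repeats: motif modelling,
genome-region scanning, strand-aware classification, density statistics,
repeat-consensus positional mapping, and antisense-transcript proximity
analysis — with a seeded synthetic-data generator so the whole pipeline is
testable end to end without external downloads.

## The problem

Alu elements (~300-base primate SINE retroelements, >1 million copies)
harbour transcription factor binding sites, among them a 13-base heat shock
element variant of the form `nCAGAAAGCTCCG`. The analysis this package
implements asks whether such Alu-internal HSF sites are non-randomly placed
around heat-shock-responsive transcripts: whether Alu density is enriched
near down-regulated genes, whether sites concentrate in *antisense*-oriented
Alus (an Alu whose strand opposes its host transcript), whether they sit at
conserved Alu consensus positions (221 in both orientations, 175 sense-only,
91 antisense-only), and whether antisense transcription signals cluster
within ~2 kb of Alu-harboured sites — the geometry expected if HSF binding
in an antisense Alu drives a cis-natural antisense transcript that represses
its host.

It is aimed at regulatory-genomics analysts working with gene models
(BED12/refFlat), repeat annotations (RepeatMasker `.out`/BED6), sequences
(FASTA) and probe tables (BED/TSV).

## The model

Sites are scored by a position weight matrix over columns $i=1..13$: with
pseudocounted frequencies $f_{b,i} = (c_{b,i}+p)/(n+4p)$ and background
$q_b$, a window $x$ scores

$$s(x) = \sum_i \log_2\!\left(f_{x_i,i} / q_{x_i}\right) \ \text{bits},$$

and windows with $s \ge 8.7$ (the operating point at which the documented
HSPA1A promoter site, scoring 8.9, is retained) are hits, on both strands.
A classic Gibbs site sampler (`gibbsSampleMotif`) discovers the motif de
novo from unaligned sequences. Hits are classified Alu/non-Alu by a
midpoint rule, Alus sense/antisense by strand comparison with the host
transcript; per-gene densities (counts/kb upstream, counts/10 kb genic) are
compared between expression classes by Welch's two-tailed t-test; in-Alu
hits are projected onto subfamily consensus coordinates through
Smith–Waterman local alignment; and each antisense probe signal is related
to its nearest antisense-Alu site under a 5-kb flanking rule.

## Worked example

The orientation-bias summary on a published genome-wide count table of
Alus and Alu-internal HSF sites (bundled as
`inst/extdata/orientation_counts_example.tsv`; four rows = up/down
regulated × upstream/genic):

```r
library(aluhsf)
tab <- readOrientationCounts(system.file("extdata",
    "orientation_counts_example.tsv", package = "aluhsf"))
bias <- summarizeOrientationBias(tab)
round(bias$aggregate, 2)
#>   sense_percent antisense_percent fold
#> 1          4.22              20.7  4.9
round(bias$perRow$fold, 2)
#> [1] 4.13 4.78 4.90 4.99
```

So ~4% of sense Alus versus ~21% of antisense Alus carry a site — a four-
to five-fold per-row over-representation in antisense copies.

A fully synthetic run (50 genes per expression class, default planted
structure), recovering the same qualitative picture plus the positional and
proximity geometry:

```r
res <- runPipeline(pipelineConfig(synthetic = syntheticConfig(seed = 1)))
round(res$biasSummary$aggregate, 2)
#>   sense_percent antisense_percent fold
#> 1          5.92             24.16 4.08
res$positional$modes
#>   orientation position count
#> 1   antisense       91    73
#> 2   antisense      221    40
#> 3       sense      175    11
#> 4       sense      221    16
res$proximitySummary[c("n_signals", "n_within", "n_upstream", "modal_bin")]
#> $n_signals
#> [1] 19
#> $n_within
#> [1] 19
#> $n_upstream
#> [1] 19
#> $modal_bin
#> [1] 2000
```

Every planted antisense signal has an Alu-harboured HSF site within 5 kb,
all upstream of the antisense transcript, with the distance mode in the
2-kb bin; the preferred consensus positions 221/175 (sense) and 221/91
(antisense) are recovered. `writeSyntheticDataset()` emits the same data as
FASTA/BED12/BED6/RepeatMasker-`.out`/TSV for running the pipeline from
files, and `runPipeline(..., outputDir =)` writes all stage tables plus a
seed-recording manifest.

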