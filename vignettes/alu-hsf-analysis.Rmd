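---
title: "Mapping heat shock factor binding sites in Alu repeats"
author: "aluhsf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping heat shock factor binding sites in Alu repeats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aluhsf)
```

## The biological question

Alu elements are ~300-base primate SINE retroelements present in over a
million genomic copies. Beyond their RNA polymerase III transcription, many
copies carry RNA polymerase II transcription factor binding sites, and Alu
RNA levels rise under heat stress. A 13-base heat shock element variant —
a motif of the nCAGAAAGCTCCG type bound by heat shock factor (HSF) — occurs
inside Alu copies at conserved consensus positions. This package implements
the computational side of asking whether such Alu-internal HSF sites are
non-randomly distributed around heat-shock-responsive transcripts: more Alus
(and more Alu-internal HSF sites) near down-regulated genes, a strong excess
of sites in *antisense*-oriented Alus, and antisense transcription signals
clustered within a few kilobases of those sites — the geometry expected if
HSF binding in an antisense Alu can fire a cis-natural antisense transcript
that represses its host gene.

## The motif model

The HSF site is modelled as a position weight matrix over columns
$i = 1..w$ (default $w = 13$). From an aligned site set of $n$ sequences,
with per-column base counts $c_{b,i}$, pseudocount $p$ and background
$q_b$:

$$f_{b,i} = \frac{c_{b,i} + p}{n + 4p}, \qquad
  s(x) = \sum_{i=1}^{w} \log_2 \frac{f_{x_i,i}}{q_{x_i}}.$$

Scores are in bits. A window is a hit when $s(x)$ reaches the threshold;
both strands are scanned and minus-strand hits are reported in plus-strand
coordinates of the region with the matched word read 5'→3' on its own
strand. Overlapping hits are all retained — sites are counted as
occurrences, matching the count-style tabulation this analysis feeds.

Key defaults, and why:

* **threshold = 8.7 bits.** The operating point used for "biologically
  significant" sites; the documented HSPA1A promoter site scores 8.9 under
  the original matrix, and 8.7 retains it with a small margin. The original
  training matrix is unpublished, so the threshold is configurable and
  honoured as a default rather than re-derived.
* **pseudocount = 0.25 per base.** Keeps log-odds finite for the very small
  site sets (including a single site) the synthetic studies use.
* **background = uniform (0.25 each).** Makes scores input-independent; a
  composition-based background can be supplied instead.
* **Ambiguous bases:** any window containing an N is skipped rather than
  scored — no fabricated scores for unsequenced bases.

`consensusString()` renders the model the way motif logos are summarised: a
column prints its majority base when that base's frequency reaches the
degeneracy cutoff (default 0.5) and lowercase `n` otherwise, which is how a
13-column model with one degenerate flank column prints as
`nCAGAAAGCTCCG`.

## Gibbs site sampling

`gibbsSampleMotif()` is the classic single-site sampler: one occurrence per
sequence; each update holds one sequence out, rebuilds the pseudocounted
model from the rest, and samples a new site offset with probability
proportional to the model's odds over the background. `nIterations` counts
these single-sequence updates (sequences are cycled deterministically), and
the best-information-content solution over `nRestarts` restarts is kept.
Two deterministic polish steps follow the stochastic phase: a column-phase
shift search (all sites moved together by up to ±3 columns) to fix the
classic phase-shift local optimum, and one argmax reassignment sweep. The
background is the pooled base composition floored at 0.05, so
near-monomorphic inputs cannot produce unbounded log-odds. The sampler is a
pure function of (input, seed).

## Regions, orientation and classification

Analysis regions are the 5-kb window upstream of the transcript start (on
the gene's own strand, truncated at contig edges) and the genic interval.
Gene models on `chr*_random` / `chr*_hap` assemblies are dropped at load
time to avoid location ambiguity. An Alu is *sense* when its strand matches
the host transcript's, *antisense* otherwise.

Two deterministic midpoint rules avoid boundary double-counting:

* an Alu belongs to the gene region containing its midpoint (so per-region
  Alu counts partition);
* a hit is in-Alu iff the hit's midpoint base lies inside the Alu interval;
  among overlapping Alus the larger hit overlap wins, ties to the smaller
  start.

Genomic containers are standard Bioconductor `GRanges` (1-based closed);
the scanner's and classifier's tabular outputs use 0-based half-open
coordinates like the BED files they are written to. Conversions happen only
at that boundary.

Orientation tabulation reports *both* site-occurrence counts (the
count-table convention: "HSF sites in sense/antisense Alus") and the
per-Alu presence view ("Alus harbouring at least one site"), because the
two readings differ and the published percentages — about 4% of sense Alus
versus about 21% of antisense Alus — are recovered from the occurrence
ratio, as `summarizeOrientationBias()` on the bundled worked-example table
shows.

## Density statistics

Densities are per gene (the gene is the sampling unit): counts per kb in
the upstream window and counts per 10 kb in the genic region — the 10×
genic scaling brings the two magnitudes onto comparable scales since genic
stretches dwarf the 5-kb windows. Group comparisons use Welch's
unequal-variance two-tailed t-test: the analysis tradition here says only
"two-tailed t-test", and Welch is the safer default when class variances
differ. No multiple-testing correction is applied to the three planned
class contrasts, matching the raw-p-value reporting convention;
`p.adjust()` can be applied downstream if desired.

## Positional mapping onto the consensus

Each in-Alu hit is projected onto its subfamily consensus coordinate: the
Alu copy (reverse-complemented first when on the minus strand, so all
alignments run consensus-forward) is locally aligned to the consensus by
Smith–Waterman with affine gaps via `Biostrings::pairwiseAlignment`
(defaults match +2, mismatch −3, gap open 8, gap extend 1 — ordinary
DNA-vs-close-consensus settings, all configurable). The hit's Alu-local
offset (measured from the 3' genomic end for minus-strand copies) is looked
up in the alignment's match/mismatch columns; an offset falling in a gap
uses the nearest aligned column to the right, and `mapped_fraction` records
how much of the 13-mer the alignment covers. Consensus positions are
1-based, the convention in which the conserved sites sit at 221 (both
orientations), 175 (sense only) and 91 (antisense only). Histogram modes
are local maxima (±5 positions) above a minimum count; the pipeline
requires a mode to carry at least 5% of all mappings, because at 5% copy
divergence a handful of borderline windows in mutated copies cross the
score threshold and would otherwise register as single-count "preferred
positions".

## Antisense proximity

Probe signals with detection p strictly below α (default 0.05) count as
antisense transcription. For each signal the nearest in-Alu HSF site in an
antisense-oriented Alu of the same gene's genic region is selected by
edge-to-edge interval gap (0 for overlap; ties to the smaller start), and
the 5-kb flanking rule flags proximal pairs. *Upstream of the antisense
signal* is interpreted in the antisense transcript's frame — the transcript
runs opposite the host gene, so for a plus-strand host a site at higher
coordinates is upstream. This frame is the one in which the mechanistic
model (HSF binding firing the antisense transcript) is meaningful; a
host-frame reading would simply swap the labels, and the summary counts by
side so either reading is recoverable.

## The synthetic-data generator

`generateDataset()` builds one contig per gene — a 5-kb upstream pad plus a
genic body of 4–10 kb, on the side the gene's strand dictates — which
removes inter-gene interval ambiguity from every downstream test. Into each
region it drops non-overlapping copies of a 300-base consensus at a
per-class Poisson rate per kb, each copy substituted at 5% per base by
default (a typical young-subfamily divergence; indels optional and off by
default — full-length copies only). The bundled consensus is a synthetic
stand-in, not RepBase material: GC-rich arms around an A-rich linker with a
B-box-like interior, constructed so that no window on either strand
resembles the default planted motif (best chance window 5.6 bits, far below
the 8.7 threshold) — scans of unplanted copies are therefore clean by
construction. All three bundled subfamily labels share this consensus so
that the property holds for every label.

The planted structure mirrors the study's observed effects, and these
defaults are the generator's study conditions:

| parameter | default | emulates |
|---|---|---|
| genic Alu rate, down vs up vs random (per kb) | 0.6 / 0.4 / 0.3 | Alu enrichment in down-regulated transcripts |
| plant probability, antisense vs sense Alus | 0.21 / 0.04 | ~21% vs ~4% orientation-biased site load |
| plant positions, sense / antisense | 221, 175 / 221, 91 | positional conservation on the consensus |
| antisense signal offset | 2 kb | signal enrichment ~2 kb from the site |

Planted motif windows are protected from mutation by default (the copy is
mutated first, then the motif written in), which makes positional-recovery
expectations deterministic; disable `protectMotifs` to study degraded
sites. Antisense probe signals (100-base intervals, detection p drawn below
0.04) are emitted for each planted antisense-Alu site in the genic region
of a down-regulated gene, offset 2 kb in the antisense transcript's
downstream direction and clamped into the genic region. A truth table
records every planted instance, and object validity verifies each recorded
13-mer is retrievable from the genome.

What the generator does **not** emulate: array intensities or probe-level
noise, retrotranspositional phylogeny, truncated Alu insertions, isoform
structure, overlapping genes, or a shared chromosome. Passing tests
therefore demonstrate the correctness of the pipeline's bookkeeping and the
recoverability of planted structure under the stated noise — not
performance on real hg18 annotation, whose scale-dependent quantities
(genome-wide p-values, raw transcript counts) are outside desk scale.

## Numerical and degenerate-input choices

* Frequency columns are validated to sum to 1 within 1e-9; log-odds are
  validated against frequencies/background within 1e-6.
* Pseudocount 0 is allowed; zero-frequency bases then score −Inf and such
  windows simply never pass a finite threshold.
* Sequences shorter than the motif width scan to an empty hit list;
  zero-length regions are an error in density computation.
* Signal/site gap is 0 for overlapping or abutting intervals under the
  half-open convention; the side of an overlapping pair is decided by
  midpoint comparison (ties upstream).
* The detection filter is strictly `p < alpha`, so `p == alpha` is dropped.
* Pipeline outputs are a pure function of (inputs, config, seed); the run
  manifest records seed, parameters and input checksums, and contains no
  timestamps so repeated runs are byte-identical.

## Problem sizes used by the checks

The shipped checks run at sizes chosen to make their statistical
expectations sharp: the scanner oracle compares all windows on 100 random
1-kb sequences exactly; Gibbs recovery uses 50 trials of 20×200-base
sequences with an exactly planted 13-mer (5 restarts × 300 updates per
trial — ample for exact plants; the 25×500 defaults are sized for noisier
sites); positional recovery plants every Alu (probability 1) in 60 genes at
2% mutation; the density power study uses 100 seeded runs of 300 genes per
class at a genic rate ratio of 1.5; the proximity check uses the default
sparse planting probabilities so that each signal's nearest antisense site
is almost surely its planted 2-kb partner — under saturated planting the
nearest-site statistic is confounded by unrelated sites, which is a
property of the geometry, not of the implementation.

## Known limitations

* The original scanning matrix and its training sites are unpublished; the
  8.7/8.9 scores are honoured as calibration constants, not reproduced.
* RepBase subfamily consensus sequences are licence-restricted and not
  bundled; positional claims about real AluY coordinates require
  user-supplied consensus FASTA files.
* One interval per gene is assumed; collapse isoforms before loading.
* The Gibbs sampler assumes exactly one site per sequence (the classic
  site-sampler model), not zero-or-more.

## A minimal run

```{r, eval = FALSE}
cfg <- pipelineConfig(synthetic = syntheticConfig(seed = 1))
res <- runPipeline(cfg)
res$biasSummary$aggregate      # orientation-biased site load
res$positional$modes           # recovered consensus positions
res$proximitySummary$modal_bin # signal-to-site distance mode
```
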