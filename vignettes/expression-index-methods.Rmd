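---
title: "Methods: Expression-Index analysis of barcoded AAV promoter screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Expression-Index analysis of barcoded AAV promoter screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promEI)
```

## The assay and its statistical model

A barcoded promoter kit is a pool of AAV vectors identical except for the
promoter and a short identifying barcode placed between the eGFP coding
sequence and the WPRE element. After pooled (competitive) transduction,
three amplicon libraries are sequenced per experiment: the pre-transduction
mix, genomic DNA (vector genomes that entered cells) and cDNA (transcripts).
Because capsid-mediated entry is promoter-independent, the ratio of a
barcode's expression share to its entry share isolates promoter activity
from everything upstream of transcription.

`promEI` commits to the following normalisation chain for each
(model, capsid, replicate):

1. pseudocounted proportions per library,
   $p_i = (c_i + a) / \sum_j (c_j + a)$;
2. premix normalisation with renormalisation to shares,
   $R_i = (p_i / p^{pre}_i) / \sum_j (p_j / p^{pre}_j)$, applied separately
   to the gDNA and cDNA libraries against that capsid batch's premix
   library;
3. the Expression Index per barcode, $EI_i = R^{rna}_i / R^{dna}_i$;
4. promoter aggregation, then within-replicate EI proportions
   $EI_k / \sum_k EI_k$ over the kit's promoters.

Step 2's renormalisation makes $EI$ a dimensionless ratio of shares, so
$EI = 1$ always means "expression tracks entry" regardless of library
depth or premix imbalance. The chain is exactly invariant to rescaling any
library's counts when $a = 0$ and invariant in the limit otherwise.

Two aggregation modes are provided because barcode-level and count-level
pooling are both defensible: `barcode_mean` (default) computes EI per
barcode and averages within promoter, preserving between-barcode agreement
as a QC signal; `count_pooled` sums counts across a promoter's barcodes
(premix likewise) before the whole chain. With one barcode per promoter and
$a = 0$ they coincide, which the test suite asserts.

## Inference

Replicate-level EI proportions are compared nonparametrically — EI
proportions are bounded shares with heavy-tailed replicate scatter, so rank
tests are the defensible default and a Shapiro–Wilk annotation (computed,
never branched on) records the normality evidence per scope.

* The omnibus test is the tie-corrected Kruskal–Wallis statistic
  $H = \left[\frac{12}{N(N+1)}\sum_i R_i^2/n_i - 3(N+1)\right] /
  \left[1 - \sum(t^3-t)/(N^3-N)\right]$, referred to $\chi^2_{k-1}$.
* Post-hoc pairwise comparisons use Dunn's z on pooled midranks with the
  tie-corrected variance and two-sided Bonferroni adjustment over all
  $k(k-1)/2$ pairs of one comparison family; families are never pooled
  across scopes.
* Two families are fitted per (model, capsid): promoter classes, with all
  cardiac-specific promoters pooled into one CSP group against CMV and LSP
  (each replicate contributes one value per promoter, so CSP holds
  $6 \times n$ values); and the six cardiac-specific promoters
  individually. Pooling rather than per-promoter averaging at class level
  is a committed choice: it weights every promoter's replicate evidence
  equally and keeps the test's observation unit consistent across levels.
* Scopes with a single replicate (single large-animal subjects) cannot
  support rank tests; they are skipped with a notice and surface only in
  rankings, heat maps and the bubble summary.

Both tests are verified against independent brute-force rank-table
implementations on random small instances, and Kruskal–Wallis additionally
against the standard base-R implementation, to $10^{-10}$.

## The simulator: what it emulates

`ground_truth()` + `simulate_experiment()` generate the entire experiment
with recorded truth:

* **Premix**: a symmetric Dirichlet draw around the equimolar pool.
  Default concentration 200 per component (~7% coefficient of variation)
  represents careful equimolar pooling; `Inf` disables jitter.
* **Entry**: per-replicate barcode shares are the premix distorted by
  promoter-independent lognormal noise (`entry_sd`, natural-log scale,
  default 0.3 ≈ 30% CV — the scale of between-well transduction
  variability in pooled AAV assays). The same realised entry vector feeds
  that replicate's gDNA and cDNA draws, as in the real assay where both
  fractions come from one well or animal.
* **Expression**: entry shares weighted by the promoter × model activity
  matrix plus lognormal expression noise (`expr_sd`, default 0.3).
* **Sequencing**: multinomial sampling at `depth` (default 1e5) and, in
  read synthesis, independent per-base substitutions at `error_rate`
  (default 0.01) uniform over the three alternatives, on single-end
  150-nt reads. Substitution-only is deliberate: the barcode is
  position-anchored between constant regions in this amplicon design, so
  indels are rare relative to substitutions and an indel-free channel
  keeps the extraction oracle exact.

The default activity matrix encodes the qualitative biology the screen
targets — in cardiac models CMV ≫ NCX ≈ cTnT > αMHC ≈ MLC-2v > α1c > cTnI
with LSP near-silent, in hepatic models LSP ≫ the cardiac set with cTnT
lowest — spanning 50-fold, with αMHC fixed at exactly twice α1c so a known
2× pair is available for calibration. These values are configuration, not
biological claims.

Not emulated: PCR amplification bias and chimeras, UMIs, paired-end reads,
indels, quality-score structure, batch effects between sequencing runs.
Passing recovery tests therefore demonstrates correctness of the analysis
chain under this generative model, not robustness to every artefact of
real libraries; with real data the extraction statistics
(`extraction_stats.tsv`) are the first place such artefacts would show.

## Barcode extraction

The default whitelist is generated deterministically (greedy lexicographic
scan over all 4^6 6-mers) with pairwise Hamming distance ≥ 3, so a single
substitution can never move one whitelist barcode within distance 1 of
another and 1-mismatch assignment is unambiguous by construction. The
synthetic constant regions are built deterministically against the
whitelist with two guarantees: no barcode-length window of either anchor
is within distance 1 of any whitelist barcode, and no window of any
amplicon other than the true site is within 4 mismatches of the left
anchor — the mismatch-tolerant scan cannot lock onto a spurious site.

Extraction defaults (anchor ≤ 2 mismatches, barcode ≤ 1, exact-match
priority, ambiguous → discard, forward strand with optional
reverse-complement rescue) are all exposed on `anchor_spec()`. Excision
requires only the left anchor, tolerating 3'-quality decay.

## Numerical and design choices

* **Pseudocount** $a = 0.5$ on every library. It exists to keep premix and
  gDNA denominators finite under dropout; at the depths the assay uses
  (≥ 1e4) its bias is negligible, which the null calibration confirms.
* **RNG substreams**: every stochastic stage draws under a seed derived by
  hashing the run seed with a stage/replicate key (kept below $2^{31}$).
  This makes whole directory trees byte-reproducible from one seed while
  letting a replicate's cDNA draw reuse its own realised entry vector.
* **Ranking ties** share the minimum rank and list alphabetically;
  heat-map columns for single-subject scopes carry that subject's values
  directly.
* **Degenerate inputs** are hard errors at the boundary (all-zero library
  with $a = 0$, constant vectors in the normality screen, empty groups,
  cDNA without a gDNA partner, duplicate barcodes or sample ids), never
  silent repairs.

## Problem sizes used in the checks

The package's own verification uses: 1000 equal-activity simulations
(n = 5 replicates, depth 1e4) for type-I calibration of the class-level
omnibus test and for mean-EI bias; 100 seeded simulations (hiPSC-CM
n = 4 and mouse-liver n = 8, the study-design replicate numbers for those
scopes) for the CSP/LSP discrimination rates; depth 1e5 with n = 5 for
Spearman recovery of the 50-fold activity span; depth 1e6 noise-free for
the 2× pair; and one full read-level run over cardiac, liver and
single-subject scopes at depth 1e4 for the qualitative pattern. Repeated
calibration and power sweeps run at the count level — the read channel is
validated separately as lossless at zero error and enumeration-calibrated
at 1% error — so the sweeps measure the statistics, not file I/O.

## Limitations

The Expression Index is relative within a kit and capsid batch: it cannot
give absolute expression per vector genome, compare across capsids (each
batch is self-contained, normalised to its own premix), or separate
transcription from transcript stability. Class-level inference inherits
the compositional coupling of EI proportions (they sum to 1 within a
replicate); under the null this leaves the tests exchangeable and, as the
calibration shows, close to nominal, but strong single-promoter effects
necessarily depress the measured shares of the others.
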