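---
title: "Methods: screening an endosymbiont genome for feminization candidate genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening an endosymbiont genome for feminization candidate genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(femscreen)
```

## The problem

*Wolbachia* are maternally inherited intracellular bacteria that can convert
genetic males of the pillbug *Armadillidium vulgare* into functional
phenotypic females. The feminizing strain (wVulC) offers no obvious effector
candidates from sequence annotation alone, so the screen implemented here
combines two orthogonal sources of evidence:

1. **Comparative genomics.** Genes shared with non-feminizing relatives are
   unlikely to explain feminization. An ordered filter cascade removes, in
   turn: repeats (transposable elements, prophage genes and other repeated
   genes, which also defeat specific PCR assays), pseudogenes, genes under
   150 bp, small CDS of genes split in two CDS, members of the core genome
   of five arthropod-infecting *Wolbachia* strains, and genes 100% identical
   over at least 90% of their length to their homolog in the closely
   related, CI-inducing (non-feminizing) strain wCon.
2. **Developmental expression profiling.** Feminization acts during gonad
   differentiation (intermolt stages 3–6 in *A. vulgare*), so surviving
   candidates are profiled by efficiency-corrected qRT-PCR across stages,
   in two successive samplings of the native host and one of the
   heterologous host *Cylisticus convexus*, which differentiates one stage
   earlier.

Finally, candidates are searched against the *f* element — a fragment of a
feminizing *Wolbachia* genome horizontally transferred into the
*A. vulgare* nuclear genome and associated with female sex determination —
since genes driving feminization from either genetic context are expected
to overlap.

The package is organized so each stage is a reusable function with an
explicit contract, and a synthetic-data module can plant any funnel of
category counts (the default preset reproduces the published funnel:
1888 genes, 792 + 26 + 52 + 16 removed by annotation, 721 core, 16
identical to wCon, 265 candidates, 216 amplifiable, 139 expressed, 13 + 29
differentially expressed, 35 consistent, 29 regulated in both hosts, 3
cross-correlated of which 2 with a one-stage shift, 27 in the f element of
which 20 with identical copies).

## Sequence comparison

All alignments are exact dynamic programming (Needleman–Wunsch or
Smith–Waterman via `Biostrings::pairwiseAlignment`) with BLOSUM62, gap open
11, gap extension 1. A heuristic search engine is deliberately not used:
the synthetic proteomes are desk-scale, and the downstream filters depend
only on identity, coverage and e-value. Bit scores use fixed gapped
BLOSUM62 Karlin–Altschul constants (λ = 0.267, K = 0.041) and
`E = m n 2^(-S')`; e-values only gate thresholds here, so the constants'
exact values are immaterial as long as they are fixed.

Two scale decisions matter:

* **Pair preselection.** The all-vs-all hit table behind ortholog
  clustering only aligns sequence pairs sharing at least one exact 10-mer
  (the word-hit idea underlying BLAST seeding, applied as a pair filter in
  front of an exact aligner). Unrelated random 60-mers share a 10-mer with
  probability ~2.5e-10, while the synthetic ortholog families carry a
  conserved 12-residue anchor block, so the screen is lossless for every
  planted relationship. Query-vs-database searches (conservation filter,
  f-element search) align all pairs with no preselection.
* **Clustering.** Ortholog groups are connected components over reciprocal
  hits passing 70% identity and e-value 1e-6, with group ids ordered by
  smallest member (so output is independent of input row order). Markov
  clustering is not needed: the screen uses groups only as a core/non-core
  oracle, and at the identity separations simulated (~85% within families,
  background at random-alignment levels) component recovery is exact.
  The core genome is the set of groups with at least one member in every
  reference genome.
* **Identity convention.** The 70% clustering floor is applied to the
  aligned region (matches / alignment columns), not the full protein; the
  conservation filter demands identity 1.0 with query coverage ≥ 0.90.

## qPCR model

Raw amplification curves are processed by a windowed log-linear fit:
baseline = mean of the first five cycles, detection threshold = 10 baseline
standard deviations (1% of the maximal baseline-subtracted signal when the
baseline has zero spread, as noiseless synthetic curves do), and the
exponential window (≥ 4 cycles above threshold) is chosen to maximize the
R² of `log F` against cycle, giving `E = exp(slope) - 1` and the fractional
threshold-crossing cycle as Ct. This replaces the original iterative
curve-analysis tool, whose full algorithm is not public; the downstream
arithmetic needs only (E, Ct). Efficiencies use the `[0, 1]` convention
with amplification factor `1 + E`.

Relative expression follows the efficiency-corrected ΔΔCt model,
generalized over several reference genes:

$$
\mathrm{ratio}_s \;=\;
\frac{(1+E_t)^{\,Ct_{t,\mathrm{cal}}-Ct_{t,s}}}
     {\mathrm{geomean}_r\,(1+E_r)^{\,Ct_{r,\mathrm{cal}}-Ct_{r,s}}}
$$

with the calibrator Ct the mean over stage-2 samples of the same host and
campaign (stage 2 is the earliest stage amplified in all samplings). With
all efficiencies equal to 1 this reduces exactly to `2^-ΔΔCt`. Technical
replicates are averaged at the Ct level before any ratio computation; a
missing pool leaves the stage mean to the remaining pools.

Reference genes are selected BestKeeper-style from a 15-gene housekeeping
panel: the stability index is the per-sample geometric mean of Ct across
the panel, genes correlated with the index at Pearson r > 0.95 are kept,
and each kept gene must additionally be stage-invariant relative to the
endosymbiont single-copy marker *wsp* (one-way ANOVA on
`Ct_gene - Ct_wsp` by stage, dropped when p ≤ 0.05). The ANOVA is a
stand-in: the original verification statistic is not stated. Note that on
synthetic data this check is an exact null test, so each truly stable gene
still carries the nominal α risk of being dropped; the p > 0.05 rule is
kept because it is the natural reading of "verified that expression
remained constant", not because it optimizes recovery.

Differential expression uses inclusive thresholds (ratio ≥ 2 or ≤ 0.5 at
one or more stages of interest; the source states "thresholds of 0.5 and
2" without strictness, and inclusivity is configurable). Sampling-1 calls
use per-stage means over pools; the sampling-2 consistency rule demands at
least one individual replicate crossing in the same direction ("for all
replicates" governs only the failures). Stages of interest are 3–6 in the
native host and 2–5 in the heterologous host, matching its one-stage
earlier sexual differentiation.

## Cross-host comparison

Per-gene stage series are per-stage means of log2 ratios (stages 1–7).
The cross-correlation uses overall-mean centering, full-series standard
deviations and n in the denominator (values shrink at large lags; this is
the convention of R's `ccf`, stated explicitly because conventions
differ), scanning lags −2…2 — a 7-point grid supports little more. A lag
is significant when `|ccf| > 1.96/sqrt(n)`; the best lag maximizes |ccf|
with ties broken toward smaller then positive lags. The autocorrelation
pre-check (same conventions) only flags genes, since the source uses it as
verification, and η² (between-stage over total sum of squares) is reported
per gene and host with an informational flag below 0.5 — no pass/fail
threshold is applied because none is stated.

A consequence of the n-denominator convention worth knowing: for strongly
autocorrelated series (e.g. monotone ramps) a shifted copy is *not*
detected at the shift, because lag 0 already correlates almost perfectly —
this is exactly the situation the autocorrelation pre-check exists to
expose. Peaked developmental profiles, the relevant case here, are
detected at the planted lag.

## What the synthetic data emulate — and what they do not

The generators work in log2 template units:
`Ct = base - (log2 fold + λ_sample)/log2(1+E) + N(0, ct_sd)` per technical
replicate, where λ ~ N(0, 2.5 cycles-equivalent) is a shared per-sample
loading signal. The six planted-stable housekeeping genes track λ; the
other nine (including *wsp*) fluctuate independently with SD 1 log2 unit.
These magnitudes make the planted stable panel separate cleanly
(r ≈ 0.97 vs ≈ 0.1 against the index) at the study's sample counts. The
published work states no noise magnitudes; `ct_sd = 0.1` cycles,
efficiencies uniform in [0.8, 1.0] and zero dropout are this package's
choices, exposed in `noise_model()`.

Planted effects keep wide margins: regulated profiles cross the fold
thresholds at log2 magnitudes ≥ 1.4 while unregulated profiles stay within
±0.5, so planted counts are recovered exactly under the default noise —
by design. Passing tests therefore demonstrate that the pipeline's
arithmetic and bookkeeping are correct, *not* that the screen would be
robust on borderline real data, where effects sit near thresholds and
noise is not Gaussian.

Two generator constructions deserve explanation:

* **Family anchors and interior substitutions.** Ortholog family members
  and planted f-element copies are mutated only at interior positions
  (conserved 12-residue anchor, intact termini). Local alignment trims
  terminal mismatches, which would otherwise turn a planted 98%-identity
  copy into a reported 100%-identity one over a shorter region; interior
  placement makes the reported identity equal the planted identity.
* **Cross-host profile pairs.** With seven stages and lags to ±2, almost
  any two single-peak profiles correlate strongly at some lag. Genes
  planted as "regulated in both hosts but not cross-correlated" therefore
  get a native-host profile with two well-separated peaks and a
  heterologous profile with a moderate crossing (log2 1.4–1.8) plus
  spread-out secondary variation; pairs are rejection-sampled until the
  noiseless |ccf| ≤ 0.50 at every lag, safely under the 0.74 significance
  bound. This is construction of the planted truth, not tuning of the
  detector.

Not emulated at all: read-level sequencing, assembly, annotation errors,
prophage architecture, nucleotide-level structure, non-Gaussian qPCR
artifacts (inhibition, primer dimers), and any correlation between a
gene's sequence and its expression role.

## Numerical and design choices

* Enrichment fold of the DNA-enrichment protocol is defined as the odds
  ratio of the endosymbiont base-pair proportion — the source reports a
  ">300-fold enrichment" without defining the ratio; the definition is
  recorded in output.
* `fisher_exact` sums hypergeometric probabilities of tables at most as
  probable as the observed one (with the customary 1 + 1e-7 relative
  tolerance). The published p = 0.22 is not reproducible because the
  background set behind it is not printed; the function is instead
  verified against full enumeration, and the enrichment helper requires an
  explicit background.
* Filter precedence is fixed (repeat → pseudogene → short → split chunk →
  core → identical-to-nonfeminizer) and each gene is counted once, under
  its first matching filter — the published per-category counts sum
  exactly, implying disjoint accounting.
* The 150 bp length cut is applied on nucleotide length; "< 50 amino
  acids" is the same cut at 3 bp per residue.
* Reference-gene correlation is gene-vs-index by default; a pairwise mode
  is available (`pairwise = TRUE`).
* Significance bounds for acf/ccf use n, not n − |lag|; configurable in
  principle, fixed here for determinism of the planted counts.
* Problem sizes: the default end-to-end run aligns ~11,000 preselected
  pairs for clustering, ~30,000 pairs for the conservation filter and
  ~4,500 for the f-element search, and simulates ~34,500 qPCR wells for
  sampling 1 — about half a minute in total. The test suite exercises the
  full default funnel once and otherwise uses a 60-gene preset with the
  same structure.

## Limitations

* The screen reports planted-truth recovery on synthetic data; no claim is
  made about sensitivity or specificity on real genomes and real qPCR.
* Six-frame translated search of nucleotide scaffolds is out of scope; the
  f element is consumed as a protein set.
* No multiple-testing correction is applied across genes in the
  cross-correlation test (none was applied in the original design), and
  the η² check is informational only.
* The e-value model uses fixed Karlin–Altschul constants and a
  whole-set database length; absolute e-values should not be compared with
  those of other software.
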