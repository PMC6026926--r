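# femscreen

Screening an endosymbiont genome for feminization candidate genes.

Inherited *Wolbachia* bacteria can convert genetic males of the pillbug
*Armadillidium vulgare* into functional females. Which *Wolbachia* genes do
this is unknown: the feminizing strain wVulC carries ~1900 annotated genes
and no effector stands out from annotation alone. `femscreen` implements,
as a tested and reusable R pipeline, the screen that narrows this gene set
by combining comparative genomics with developmental expression profiling,
and maps the survivors onto the *f* element — the fragment of a feminizing
*Wolbachia* genome horizontally transferred into the host nuclear genome
and associated with female sex determination. It is written for
researchers working on endosymbiont–host interactions who want each stage
of such a screen as an auditable function, and for anyone needing its
building blocks: exact protein alignment statistics, ortholog clustering
and core genomes, efficiency-corrected qPCR quantification, reference-gene
stability selection, lagged cross-correlation of stage series, and exact
2×2 enrichment tests.

## The method in brief

**Filter cascade** (comparative genomics). From the annotated focal genome
remove, in order: repeats, pseudogenes, genes < 150 bp, split-CDS chunks;
then genes in the core genome of five reference *Wolbachia* strains
(ortholog groups = connected components over reciprocal alignments with
identity ≥ 70% and E ≤ 10⁻⁶, groups spanning all five genomes); then genes
100% identical over ≥ 90% of their length to the non-feminizing sister
strain. Every filter returns a partition of its input, so the funnel
counts always sum exactly.

**Expression screen** (qRT-PCR). Ratios are efficiency-corrected and
calibrated to stage 2:

```
ratio = (1+E_t)^(Ct_t,cal − Ct_t,s)  /  geomean_r (1+E_r)^(Ct_r,cal − Ct_r,s)
```

with reference genes selected BestKeeper-style (Pearson r > 0.95 against
the per-sample geometric-mean Ct index, then stage-invariance relative to
the single-copy marker *wsp*). A gene is differentially expressed when its
per-stage mean ratio crosses 0.5 or 2 in the gonad differentiation window
(stages 3–6); calls must be confirmed by at least one same-direction
replicate crossing in a second sampling, and are compared across hosts
with a lagged cross-correlation test (`|ccf(l)| > 1.96/√n`, lags ±2) that
accommodates the heterologous host's one-stage shift in sexual
differentiation.

**f element.** Final candidates are searched against the f-element protein
set by exact local alignment (E ≤ 0.001, identity ≥ 90%), counting copies
and flagging 100%-identity copies; enrichment is testable with an exact
Fisher test against an explicit background.

A first-class synthetic-data module generates every input with planted
truth — annotation categories, ortholog families at controlled identity,
Ct values with a known fold table and housekeeping correlation structure,
stage-lagged two-host profiles, and an f element with planted copies — so
the whole screen can be exercised end to end against known answers. The
default preset plants the published funnel.

## Worked example

```r
library(femscreen)

cfg <- make_paper_fixture("study", seed = 42)  # writes the synthetic dataset
report <- run_screen(cfg)                      # runs the full screen (~30 s)
print(report)
```

```
Candidate screen funnel
  annotated genes                      1888
  after annotation filters             1002
  candidates (after cascade)            265
  amplifiable                           216
  expressed (stages 3-6)                139
  under-expressed, sampling 1            13
  over-expressed, sampling 1             29
  final candidates (consistent)          35
  regulated in both hosts                29
  cross-correlation significant           3
    of which one-stage shift              2
  in f element                           27
    of which identical copies            20
  reference genes: gltA, L2, L20, S4, fabF, purF
```

Reading the funnel: of 1888 annotated genes, 886 are dropped by the
annotation filters (repeats, pseudogenes, short and split CDS), 721 as
core-genome orthologs and 16 as identical to the non-feminizing strain,
leaving 265 candidates. Of these, 216 amplify and 139 are expressed during
gonad differentiation; 42 cross the 2-fold thresholds in sampling 1 and 35
do so consistently in sampling 2 — the final candidate set. 29 of the 35
are also regulated in the heterologous host, and three share their whole
developmental profile across hosts (two with exactly the one-stage shift
that separates the hosts' sexual differentiation). 27 of the 35 lie in the
f element, 20 of them with amino-acid-identical copies. Per-stage
artifacts (filter audit, expression tables, cross-correlation table,
f-element hits) are written to `cfg$output_dir`.

The individual stages are ordinary functions — e.g.
`align(a, b, mode = "local")`, `cluster_orthologs(hits)`,
`select_reference_genes(ct)`, `cross_correlation(a, b, max_lag = 2)`,
`fisher_exact(a, b, c, d)` — see the methods vignette
(`vignettes/candidate-screen-methods.Rmd`) for the model behind each and
the choices made where the original description was open.

A thin CLI wraps the pipeline: `exec/femscreen run --config cfg.yaml`,
`exec/femscreen fixture --out dir --seed 42`, plus `qpcr`, `filter` and
`felement` subcommands.

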