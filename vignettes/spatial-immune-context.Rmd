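---
title: "Methods: quantifying the spatial immune context of mIHC tissue cores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the spatial immune context of mIHC tissue cores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunocontext)
```

## The analysis

Multiplex immunohistochemistry (mIHC) stains several protein markers on one
tissue section; image processing (outside this package's scope) yields a
table of segmented cells with nucleus-centroid coordinates, a tissue
compartment per cell — epithelial (`EPI`, the tumour-cell compartment) or
stromal (`TME`) — and a 0–3 intensity score per marker. `immunocontext`
takes these tables and produces the downstream science:

1. **Marker quantification.** Per core and compartment, the H-score
   $100\,(1 p_1 + 2 p_2 + 3 p_3)$ over the score-level proportions
   (range 0–300); marker positivity (score $\ge$ 1 by default); tumour
   purity as the epithelial cell fraction; densities as positive cells per
   mm² of the *compartment's own* segmented area.
2. **Phenotyping.** Fourteen phenotypes over three panels (myeloid M, T-cell
   T, "other" O) assigned by priority-ordered marker gates with negative
   screening: each cell gets the first gate it satisfies, or `UNASSIGNED`.
3. **Spatial context.** Every immune cell's Euclidean distance to its
   nearest tumour cell (all EPI-compartment cells by default), half-open
   radius bins (0,10], (10,20], (20,30], (30,∞) µm, and "effective" immune
   cells — those with at least one tumour cell within 10/20/30 µm.
4. **Immune subtyping.** Ward (`ward.D2`) hierarchical clustering of
   z-scored patient density profiles with the cluster number chosen by
   average silhouette width (elbow sums reported as a diagnostic);
   phenotype–phenotype Spearman correlations; differential densities
   flagged at |log2FC| > 1 and p < 0.05.
5. **Outcome statistics.** Kaplan–Meier/log-rank, univariate and clinically
   adjusted Cox proportional-hazards models of densities (cohort median
   split), distance-stratified prognosis of effective-cell counts, baseline
   chi-squared tables (Yates-corrected iff 2×2) and Wilcoxon/Kruskal–Wallis
   rank tests.

Standard statistical machinery is delegated: `survival` for KM/log-rank/Cox,
`stats::hclust`/`cluster::silhouette` for clustering, `stats` for the
chi-squared and rank tests. The domain-specific computations — gating,
H-scores, purities, densities, nearest-tumour distances, effective-cell
counts, the subtype pipeline and the cohort generator — are implemented
here.

## Gating rules and their open choices

The T panel gates, in priority order: Treg (CD3+FOXP3+), CD8T (CD3+CD8A+,
FOXP3−), Tex (CD3+TIM3+, FOXP3−), then the negative-screening residual
CD4Tcon (CD3+ CD8A−TIM3−FOXP3−). Because assignment is first-match,
CD8A+TIM3+ cells resolve to CD8T; `default_panels(tex_before_cd8t = TRUE)`
selects the alternative reading. CD3T is reported as the pan-CD3+ tally
alongside its subsets (the documented exception to label exclusivity);
`cd3t_mode = "leftover"` instead counts CD3+ cells matched by no exclusive
gate. The M panel resolves multi-positive macrophages by the configurable
priority TAM2 > TAM1 > TAM3 (TAM2 — CD68+IDO1+ — is the focal, rarest
subtype; the order is explicit in the config). O-panel phenotypes are
exclusively single-marker-positive; Ki-67+ cells count as cycling cancer
cells only in the epithelial compartment, and O-panel multi-positives stay
`UNASSIGNED`.

Positivity uses score ≥ 1. Raw-intensity binning into 0–3 scores has no
standard cutpoints, so it is deliberately out of the data path: the
generator emits scores directly and real inForm exports already carry them;
a pluggable threshold config would sit at ingest if ever needed.

## Spatial conventions

Cells are points (nucleus centroids). The tumour reference set is, per the
stated proxy, *every* epithelial-compartment cell (`tumor_mode = "literal"`);
`"exclude_immune"` drops phenotype-assigned cells from the reference.
Immune cells inside the epithelium are measured like any other — to their
nearest *other* tumour cell, never to themselves (distance 0 happens only
for genuinely coincident centroids). Cores without tumour cells yield
flagged missing distances, never zeros. Bins are half-open `(a, b]` so the
printed 10/20/30 µm thresholds are inclusive upper bounds. Cohort summaries
aggregate per-core medians first (one value per tissue sample), then take
the cohort median. Nearest distances are computed by blockwise vectorised
cross-distance minimisation — exact, with no grid approximation; the test
suite holds it to within 1e-9 of a per-cell brute-force loop. At the
hundreds-of-cells-per-core scale of TMA data a tree index would buy
nothing.

## Subtyping choices

Densities are heavy-tailed, so Spearman is the default correlation and
columns are z-scored before clustering (both switchable). When the elbow
and silhouette disagree, silhouette wins and the elbow curve is reported.
Cluster labels are canonicalised by size so they are stable under row
permutation. The differential cut-off (|log2FC| > 1, p < 0.05, rank-sum
p-values, no multiplicity correction) mirrors the screening convention it
reproduces and is flagged in the output as exactly that — a screen, not
FDR-controlled inference. Zero group means take a pseudocount of half the
smallest nonzero density. Both compartments' columns enter clustering by
default; pass a column subset to restrict.

## The synthetic cohort generator

No public per-cell data exist for this design, so the generator is a
first-class module that emulates the data structure the analyses assume:

* **Geometry.** A circular core (radius 600 µm ≈ a TMA punch) with 2–4
  non-overlapping disc-shaped tumour nests (radius 90–170 µm). EPI = the
  nests, TME = the complement; compartment areas are exact from the disc
  geometry. Non-overlap keeps the areas closed-form and the
  boundary-distance structure intact.
* **Cells.** Tumour cells are a homogeneous Poisson process inside nests at
  2500 cells/mm² (epithelium is dense; sparser settings inflate
  nearest-cell distances beyond the 10–25 µm medians typical of these
  data). Each phenotype has an expected per-core count, an epithelial
  preference π<sub>EPI</sub>, and an exponential proximity kernel: TME
  cells sit at distance d ~ Exp(scale) from a nest boundary. Defaults place
  myeloid lineages nearest and densest (TAM2 rarest and closest), T/B and
  stromal lineages farther out, and B cells at ~55 cells per sample.
* **Scores.** Each phenotype's true markers emit scores 1–3
  (probabilities 0.15/0.35/0.5); a flip rate (default 0.02) zeroes a true
  positive or adds a weak false positive, giving gating a small, known
  confusion rate. Note one realistic consequence: a weak false stain on a
  tumour cell creates a false *single-positive* cell, and because the
  epithelium is dense these accumulate there (~0.02 × tumour count per
  marker per core), inflating epithelial densities of single-marker
  phenotypes — the synthetic analogue of a well-known mIHC artifact. Zero
  noise makes gating recovery exact — used when an experiment must isolate
  a downstream estimator.
* **Patients.** One geometry per patient shared by all three panel cores
  (so cross-panel purity consistency emerges rather than being asserted);
  clinical covariates drawn from two-array study-like marginals; per-panel
  QC attrition at the study's pass rates (141/164/160 of 190). Overall
  survival follows an exponential proportional-hazards model on z-scores of
  the *realised* outcome covariate (density, or an effective-within-radius
  count), with administrative uniform censoring on [0, 400] months — ≈20%
  censoring at the default baseline hazard of 0.012/month. Everything is a
  deterministic function of one seed.

What it does **not** emulate: irregular nest shapes, cell-size exclusion
effects, spatial clustering of immune cells beyond the boundary kernel,
marker intensity continua, panel-specific segmentation error. Passing
recovery tests therefore demonstrates the pipeline's correctness on data
with the assumed structure, not robustness to every pathology of real
slides.

## Validation studies and their design

Each `validate_*()` function runs one recovery experiment end to end (the
acceptance script reports their outputs):

* **Spatial oracle / bin conservation** — exact checks against a
  brute-force loop and exact count conservation on simulated cohorts.
* **Proximity recovery** — seven phenotypes at kernel scales 4–58 µm,
  50 patients, ten seeds; Spearman correlation between planted scales and
  recovered cohort medians.
* **Gating fidelity** — noiseless emission must recover 100% of planted
  labels with order-invariant assignments.
* **Subtype recovery** — 120 patients, three groups (47/31/22%) with
  multipliers 1/0.3/1.7. This scenario is deliberately *controlled*:
  geometry is held constant across patients (shared compartment-area
  variation otherwise elongates clusters along the infiltration gradient),
  counts are raised and π<sub>EPI</sub> balanced so every density column
  separates adjacent groups by more than 2 SD of its within-group
  variation, and the multipliers are equally spaced on the density scale.
  With unequal spacing or sub-2-SD columns, silhouette merges or overcuts
  — a genuine property of silhouette selection on infiltration gradients,
  worth knowing when interpreting real-data k choices.
* **Survival recovery** — planted log-HR −0.7 per SD of the TME CD8 T-cell
  density, 200 patients, ~20% censoring, noiseless emission (the gated
  density then *equals* the planted covariate, so the experiment measures
  the Cox estimator, not gating noise). Coverage of the Wald 95% CI is
  estimated over 400 replicates so that the Monte Carlo standard error
  (≈1.1%) is small against the 93–97% acceptance band; the null rejection
  rate comes from 200 zero-log-HR cohorts. Null rejection is measured on
  null *cohorts* because in an effect cohort every density shares the
  TME-area denominator with the causal density and is legitimately
  outcome-correlated.
* **Distance mechanism** — CD8 T cells planted as two independent
  subpopulations (proximal kernel 6 µm, distal 100 µm) with the hazard
  driven only by the realised ≤20 µm effective count; 150 patients, low
  geometry variability so the >30 µm stratum is a true null. Success =
  significant HR < 1 in the 0–20 µm stratum and a non-significant >30 µm
  stratum.

## Numerical and degenerate-input conventions

H-score on zero cells or unscored markers is an error, never 0. Densities
with zero area error out unless the count is also zero. Contingency tables
with an all-zero margin are rejected (undefined expected counts) — this is
why structurally zero rows (e.g. a location that one array cannot have) are
not tested. All-tied rank tests return p = 1 by convention, with a message.
Cox non-convergence is flagged in the result, never silent. Strata with
fewer than two patients per arm are skipped and marked, not dropped.
Clustering requires a complete matrix; patients missing a panel are
excluded by the caller (the analysis scripts use the all-panels-passing
subset, mirroring the common-core design).

## Problem sizes

The bundled studies use 50–200 patients per cohort and a few hundred cells
per core — enough that every Monte Carlo interval in the acceptance studies
is decisively inside its band, and chosen as the package's own default
experiment sizes.
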