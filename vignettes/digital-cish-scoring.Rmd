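---
title: "Digital scoring of chromogenic RNA in situ hybridization slides"
author: "cishscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital scoring of chromogenic RNA in situ hybridization slides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cishscore)
```

## The scoring problem

Branched-amplification chromogenic in situ hybridization (CISH, of the
RNAscope family) renders each detected RNA molecule as a discrete red
punctum over a hematoxylin counterstain. Expression of a target gene in a
tumor section is summarized by binning every evaluable tumor cell by its
dot count — negative (0 dots), low (1–3), medium (4–9), high (10+) — and
weighting the bin percentages:

$$H = 3\,\%_{\text{high}} + 2\,\%_{\text{medium}} + 1\,\%_{\text{low}},
\qquad H \in [0, 300].$$

Percentages are taken over **all** evaluable tumor cells in the annotated
region of analysis (ROA), negatives included. This denominator choice is
deliberate and prominent: exhaustive digital counting includes every
negative cell, whereas a human scorer of a large resection tends to
under-count negatives and so inflates $H$ (the "denominator effect").
An H-score is only reported when control probes pass: a PPIB-like
housekeeping probe must average at least 4 dots/cell (RNA integrity), a
dapB-like bacterial probe must stay below a background limit, and the ROA
must hold at least 100 evaluable tumor cells. For downstream use the
H-score maps to expression bins: negative ($H = 0$), low ($0 < H < 35$)
and high ($H \ge 35$), the 35 cutoff being the clinically anchored upper
tertile for the assay this design follows.

## Pipeline

`score_slide()` chains six stages, each independently exposed:

1. **Stain separation** (`separate_stains`). Each 8-bit pixel is converted
   to optical density, $OD = -\log_{10}((p + \varepsilon)/255)$ with
   $\varepsilon = 1/255$ guarding $\log 0$, and projected onto a 3x3 unit
   absorbance basis (hematoxylin, red chromogen, residual). Beer–Lambert
   linearity makes the projection an exact inverse of composition on
   noiseless images; real Fast Red spectra vary by lot, so the matrix is
   a per-assay configuration, not a constant.
2. **Dot intensity threshold** (`estimate_dot_threshold`). Dots must
   exceed an OD threshold established above background. With a dapB
   control channel available the threshold is its 99.5th percentile plus
   a margin; otherwise Otsu's method on the target channel. Both
   estimates are floored at OD 0.1 so a near-blank slide cannot
   hallucinate a threshold inside background noise. How the original
   commercial system derived its threshold is unpublished; this choice is
   ours and is echoed into every report for audit.
3. **Nucleus detection** (`detect_nuclei`). Otsu threshold on the
   hematoxylin channel, hole filling, watershed on the distance transform
   to split touching nuclei, and an area gate (default 6–200 µm²). A
   classical detector replaces the proprietary learned detector the
   workflow it mirrors used; what validation exercises is the contract —
   one object per true cell — not the detector family.
4. **Tumor/stroma separation** (`train_compartment_classifier`,
   `classify_compartments`). Mirrors the analyst-seeded protocol: small
   circled example regions of tumor and stroma label training cells; a
   shallow supervised model (linear discriminant by default, random
   forest as a config option) over six per-cell features (area,
   eccentricity, solidity, mean hematoxylin OD, mean red OD, local cell
   density) labels the rest. The model refuses to train below 10 seed
   cells per class and records stratified cross-validated accuracy.
   Stromal cells are detected, labeled and excluded from scoring — they
   are never silently dropped, which keeps per-cell specificity
   evaluation possible.
5. **Dot detection and assignment** (`detect_dots`,
   `assign_dots_to_cells`). Connected components above the threshold,
   shape-gated by area (0.15–40 µm²) and circularity (≥ 0.2 — merged
   clusters of true puncta are elongated, so the area gate, not shape,
   is what rejects background blotches). Merged blobs are declumped by
   area quantization: molecule-equivalents = blob area / single-dot
   reference area, rounded, floored at 1. Scoring needs exact counts only
   up to bin boundaries (10+ is one bin), so approximate, auditable
   declumping suffices. Each dot goes to the nearest nucleus centroid
   within 6.5 µm (a nucleus radius plus a 3 µm cytoplasmic margin,
   matched to the renderer's placement disk); exact ties break to the
   lower cell id, and molecule-equivalents are conserved between cells
   and the unassigned pool.
6. **Artifact flag and QC** (`flag_ap_artifact`, `qc_gate`). Endogenous
   alkaline phosphatase produces a diffuse red wash that mimics signal
   and is the known specificity-failure mode. Two metrics operationalize
   the pathologist's "visibly distinct" judgment: the fraction of all
   pixels above threshold outside any accepted dot (limit 0.05) and the
   fraction of above-threshold pixels in shape-rejected blobs (limit
   0.30). A flagged slide keeps its score but is marked *requires manual
   review* and is recorded as a specificity failure in validation. The
   limits are deployment-tunable and reported, not universal constants.

## Validation harness

`evaluate_specificity` / `evaluate_sensitivity` compute per-sample FP/FN
rates over truly negative / truly positive cells with a 20% pass bound;
an artifact-flagged slide fails specificity outright.
`evaluate_accuracy` wraps a Spearman or Pearson correlation against an
orthogonal measurement and passes on a positive coefficient with
$p \le 0.05$; the Spearman $p$ is exact (full permutation distribution)
for $n < 10$ without ties and uses the t approximation otherwise.
`evaluate_precision` applies the three-staining-day rule: all replicate
H-scores in the same expression bin, or, if bins are discordant, a
replicate range of at most 20 points. For three values the range reading
and the pairwise ±20 reading coincide, and it is the reading consistent
with a 32-to-75 replicate spread being a failure. `cohort_rollup`
applies the cohort thresholds — 90% of samples for the staining-assay
profile, 85% for the digital-algorithm profile, 80% for precision — and
emits a machine-readable report mirroring the usual validation-table
layout, with excluded samples listed by reason.

## The synthetic renderer

`render_slide()` exists so that every stage above is testable against
exhaustive ground truth without clinical material. It composes images in
OD space with the same Beer–Lambert model the separator inverts: nuclei
are hematoxylin disks (radius ~ N(3.5, 0.4) µm, clipped to [0.6, 1.6] x
mean, ±15% stain jitter) placed by dart-throwing with a minimum center
spacing (default 10 µm; a retry budget turns infeasible layouts into a
geometry error rather than an infinite loop); dots are solid disks
(radius 0.5 µm, peak OD 0.9) placed uniformly in each cell's assignment
disk; a pale eosinophilic background closes the model. Defaults assume
0.25 µm/pixel — the common 40x scan convention; the source workflow
never states its scanner scale, so this is a convention, not a derived
value. Bin compositions come from `bin_fraction_spec` (within-bin counts
uniform over the bin support, high bin capped at 25 dots to keep
rendering tractable), and the analytic true H-score is computed from the
realized counts. Degradation (a multiplicative OD attenuation of dots)
emulates partial RNA loss; `ap_background_level` adds the diffuse wash
plus irregular blotches, recorded as artifact pixels and never as dots.
Control slides (`render_control_pair`) reuse the nucleus layout with
Poisson per-cell counts. Everything is a pure function of the seed:
re-rendering is bit-identical.

What the renderer deliberately omits: tissue texture, scanner noise and
chromatic aberration, necrosis/folds, nuclear pleomorphism, pyramidal
WSI formats, and real Fast Red spectral variation. Passing tests
therefore demonstrate correctness of the *algorithmic contracts* —
counting, binning, gating, flagging, validation arithmetic — on images
whose generative model matches the pipeline's assumptions. They do not
certify segmentation or threshold performance on real tissue, where the
stain matrix, shape gates and artifact limits must be re-tuned and
verified by a pathologist.

## Numerical and design choices

- **Coordinates** are 0-based (row, col) with pixel centers on integer
  grid points; polygons (GeoJSON, x = col, y = row) are in pixel units
  and cells enter the ROA by the centroid rule — unambiguous for cells
  straddling the boundary.
- **The 34–35 gap.** The conventional printed bin labels ("< 34" /
  "≥ 35") leave $34 \le H < 35$ unassigned. The low bin here is the open
  interval (0, 35), making the clinically anchored 35 the single
  boundary. `assign_expression_bin(34.5)` is therefore "low".
- **dapB limit.** The conventional "< 1–3 dots/cell" background phrase is
  ambiguous; the default is the strict reading (mean < 1 dot/cell),
  configurable up to 3, and echoed in reports.
- **PPIB aggregation.** The ≥ 4 dots/cell criterion is applied to the
  mean over cells in the ROA (median available by configuration); the
  source workflow does not state its aggregation and the mean is the
  stabler of the two on synthetic data.
- **Degenerate inputs** are first-class: blank channels yield zero cells
  or dots (not errors), a constant channel under Otsu is an error
  advising the fixed method, zero evaluable cells is an
  "undefined score" error distinct from $H = 0$, and a one-class seed
  set is a training error naming the missing class.

## Problem sizes in the test suite

The shipped tests render slides of 256–1024 px (64–256 µm of synthetic
tissue, 8–200 cells). The end-to-end recovery check runs twenty 1024²
slides spanning true H-scores 0–300 and requires the pipeline H within
15 points of truth on at least 90% of them — a property of this
renderer's regime, not a clinical claim. The rendered precision study
uses 12 samples x 3 replicates at 384². The law-of-large-numbers check
on bin fractions uses 100 000 sampled cells.

## Known limitations

- Declumping by area quantization under-counts heavily overlapped
  puncta; cells near the 10-dot boundary can slip one bin on dense
  slides.
- Dense tissue with assignment disks wider than half the cell spacing
  will occasionally swap dots between neighboring cells; counts are
  conserved but individual cells can gain or lose a dot.
- The compartment classifier is only as good as its seeds; it refuses to
  extrapolate from fewer than `min_seeds` cells per class but cannot
  detect unrepresentative seeds.
- The artifact flag is a screen, not a diagnosis: it routes slides to
  manual review and is tuned to the renderer's artifact model.
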