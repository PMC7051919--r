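---
title: "Methods: automated PD-L1 tumor-cell scoring and assay concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated PD-L1 tumor-cell scoring and assay concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcscore)
```

## The problem

Tumor PD-L1 expression, reported as the percentage of tumor cells with
positive membrane staining (the tumor proportion score, TPS), decides
eligibility for several anti-PD-1/PD-L1 therapies. Four commercial
immunohistochemistry assays (Ventana SP263 and SP142, Dako 22C3 and 28-8)
stain the same antigen with different antibodies, protocols and
sensitivities, and the pathologists who read them disagree with one another
appreciably — often more than the assays themselves differ. `ihcscore`
implements an automated scoring chain that applies *one* assay-independent
positivity rule to every cell of every assay, plus the statistical machinery
to quantify agreement between any two raters (assay × {image analysis,
pathologist}) over the full range of clinical cutoffs, and a
threshold-refitting workflow that aligns a less sensitive assay to a
reference assay.

Everything is exercised end to end on synthetic slides with planted ground
truth, so the pipeline's accuracy claims are checked against quantities that
are known exactly.

## The scoring model

### Stain separation

Brightfield H-DAB images follow the Beer–Lambert model: per channel
$c \in \{R,G,B\}$,

$$\mathrm{OD}_c = -\log_{10}\frac{I_c + 1}{256}
  = a_H v_{H,c} + a_D v_{D,c},$$

where $v_H, v_D$ are the unit stain vectors of hematoxylin and DAB
(Ruifrok–Johnston values) and $a_H, a_D \ge 0$ are the per-pixel stain
densities. `deconvolve_stains()` recovers $a_H, a_D$ by least squares,
clips negative loadings, and rescales onto a `[0, 255]` working scale with
the declared convention **OD 1.0 = 85 units**. Feature thresholds in this
package are only meaningful on that declared scale; published DAB
thresholds from other systems implicitly assume their own (usually
unstated) scale and must be re-fitted with `optimize_thresholds()` before
use elsewhere. The synthetic renderer uses the same stain vectors and the
same forward model, which deliberately removes stain-estimation error as a
confounder so that segmentation and scoring errors can be isolated.

### Segmentation and compartments

Nuclei are segmented from the hematoxylin channel regardless of DAB stain:
Gaussian smoothing (sigma 1 px at a 20×-like resolution), a global Otsu
threshold, a distance-transform watershed to split touching nuclei, and a
minimum-area filter (20 px²) for debris. All settings live in
`segmentation_params()`.

The membrane compartment of a cell is a ring 2–5 px outside its nucleus
boundary (offset 2 px, width 3 px). Between neighbouring cells, membrane
pixels belong to whichever nucleus is nearer, with ties resolved to the
lower label, so compartments are disjoint and deterministic. Two features
are extracted per cell as plain mask means over the DAB map:

* `feat_mem_dab` — mean DAB over the membrane ring;
* `feat_cell_dab` — mean DAB over the whole cell (nucleus + ring interior);
* `feat_ratio = feat_mem_dab / feat_cell_dab`.

"Overall" DAB intensity is interpreted as the whole-cell mean. This is the
reading under which the ratio behaves as a membrane-pattern detector: a
uniformly stained cell has ratio exactly 1, and only stain concentrated on
the membrane pushes the ratio above 1, which is what a threshold slightly
above 1 discriminates. A membrane-local background denominator would be an
alternative reading; it is not implemented.

### Cell classification and the sample score

Immune cells (lymphocyte-like) are recognised by a morphology gate: nucleus
area below 80 px² *and* circularity above 0.6. Tumor cells are everything
else. This is deliberately simple; it suffices for the synthetic morphology
(immune nuclei are rendered at half the tumor nucleus radius) and is fully
configurable for other material. Macrophages are not modelled at all.

A cell is **positive** when

$$\texttt{feat\_ratio} > t_r \quad\text{and}\quad
  \texttt{feat\_mem\_dab} > t_m,$$

with strict inequalities and defaults $t_r = 1.02$, $t_m = 17.72$ — values
fitted by correlation-maximising search against a reference assay, exposed
as configuration rather than constants. Immune cells never count as
positive. The sample score is

$$\mathrm{TPS} = 100 \cdot
  \frac{\#\{\text{positive tumor cells}\}}{\#\{\text{tumor cells}\}},$$

computed over cells whose nucleus centroid lies in the comparable region.
Samples with fewer than `min_cells` tumor cells (default 100, the usual
clinical floor for a stable percentage; no authoritative value exists)
are flagged invalid and their score withheld rather than reported noisily.

## Serial-section registration

Consecutive sections are modelled as rigidly displaced views: rotation
about the image centre plus translation. `register_images()` estimates
rotation by phase correlation of log-polar resampled Fourier magnitudes
(rotation becomes a shift along the angle axis; the 180° magnitude
ambiguity is resolved by trying both signed candidates and keeping the one
with the stronger translation peak), refines the angle by maximising the
phase-correlation peak over a local bracket, and then estimates translation
at full resolution with sub-pixel (parabolic) peak interpolation. The
guaranteed capture range is ±45°; synthetic serial sections refuse to plant
rotations beyond it.

The translation peak height doubles as a confidence score. Because the
expected peak for incoherent images decays like $1/N$ with image size, the
failure floor defaults to $\max(0.05,\, 12/\min(H, W))$ — about three times
the pure-noise peak at the working resolution. Pairs below the floor raise
a `registration_failed` condition and the sample is excluded as lacking
comparable tissue, mirroring how unregistrable scans are handled in
practice. Elastic deformation is out of scope: the generator's jitter field
emulates small local tissue displacement, and the rigid model's recovery
under it is a measured property, not an assumption.

Annotations (tumor-center and exclusion polygons) are transferred through
the estimated transform, clipped to the target image, and combined into the
**comparable region**: the intersection of all assays' tumor polygons minus
the union of all exclusion polygons. A cell is in the region iff its
nucleus centroid is — a resolution-robust rule with no partial-overlap
ambiguity. An empty intersection raises `no_comparable_tissue` and excludes
the sample.

## Concordance statistics

For two raters and a cutoff pair $(c_A, c_B)$, a sample is called positive
by rater $r$ when its score is $\ge c_r$. The cutoff is *inclusive* because
the clinical cutoffs these grids sweep (TC ≥ 1%, ≥ 25%, ≥ 50%) are
inclusive; a strict variant is available via `inclusive = FALSE`. From the
confusion counts,

$$\mathrm{OPA} = \frac{TP + TN}{\text{all samples}}, \qquad
  \mathrm{F1} = \frac{2\,TP}{2\,TP + FN + FP}.$$

F1 is symmetric in FP and FN, hence invariant under swapping the raters.
`concordance_grid()` evaluates either metric on the full 99 × 99 grid of
cutoff pairs (1–99% in 1% steps). Cells with $TP = FP = FN = 0$ — no
positives under either rater — are undefined and stay `NA`: 0/0 is not
evidence of discordance. Samples invalid under either rater are dropped
pairwise, so each comparison uses its own evaluable-sample count. On a
negative-heavy cohort (the default synthetic mixture) OPA is dominated by
concordant negatives and exceeds F1 at high matched cutoffs; F1 isolates
the positive calls, which is why both are reported.

## Threshold optimization

`optimize_thresholds()` re-implements the dynamic rescoring workflow:
features are extracted once per cell and frozen; every candidate pair on an
exhaustive grid ($t_r \in \{0.90, 0.92, \dots, 1.30\}$,
$t_m \in \{0, 2, \dots, 80\}$; ~900 evaluations, trivial at these sizes)
rescans the feature table and correlates the resulting sample scores with a
reference assay's scores on a training split. Pearson correlation on
untransformed percentages is the default objective — the diagnostic of
interest is the linear fit between the two score scales — with Spearman
available. The cohort is split 50/50 by a seeded draw; the held-out half
reports `objective_test` but never influences selection, which makes
over-fitting directly measurable (with two parameters it is negligible, a
measured gap around 10⁻³). Objective ties break toward larger $t_m$, then
larger $t_r$: the most conservative of the equally good rules. A constant
reference is rejected (`degenerate reference`) since correlation is then
undefined.

`skewness_check()` quantifies what optimization is supposed to fix: for
each cutoff of rater A it locates the cutoff of rater B with maximal F1 and
reports the mean signed offset of that ridge from the diagonal. Two
conventions matter. F1 is piecewise constant in the cutoffs, so maxima come
in plateaus; within a plateau the cutoff nearest the diagonal is taken,
which makes identical raters score an offset of exactly 0. Rows whose best
F1 is 0 or undefined (rater A has no positives there) carry no ridge
information and are excluded. A less sensitive assay scored with the
reference's thresholds shows a large negative offset; after refitting
against the reference the offset collapses toward 0, at the usual price of
thresholds that are no longer comparable across assays.

## The synthetic cohort generator

The generator emulates exactly the features the pipeline must be sensitive
to, and nothing more:

* **Layouts.** Non-overlapping round nuclei placed by dart throwing with a
  hard minimum spacing (default keeps whole cells, ring included,
  disjoint). Tumor nuclei ~7 px radius; immune nuclei at 0.5× radius.
  Overcrowded requests fail with an explicit error instead of degrading.
* **Expression.** Each sample draws a target prevalence from a
  zero-inflated mixture: point mass at 0 with weight 0.35 plus
  $100 \cdot \mathrm{Beta}(0.6, 1.6)$. This is a stand-in chosen to make
  negatives outnumber positives at most cutoffs — the regime real PD-L1
  cohorts sit in — not a calibration to any particular cohort. Tumor cells
  are then planted bimodally: positives draw latent expression uniformly
  above the staining threshold plus a 0.05 margin, negatives below minus
  the margin. The margin reflects that PD-L1 expression is substantially
  bimodal at the cell level; cells sitting exactly at threshold would make
  "the" true score ill-defined. 30% of immune cells are planted
  DAB-positive so the exclusion rule has something to exclude.
* **Assays.** An `assay_profile` maps latent expression to staining: a
  cell stains when latent + offset exceeds the threshold, and its membrane
  ring gets DAB OD `gain × latent + background`. The default set has three
  concordant profiles and one low-titration profile (gain 0.35, offset
  −0.10) whose faint membranes fall below the default DAB threshold — an
  SP142-like divergence by construction.
* **Readers.** Simulated pathologist reads are truth + bias + Gaussian
  noise (optionally heteroscedastic, shrinking at 0 and 100), snapped to a
  reporting grid and clipped to [0, 100].
* **Artifacts and sections.** Pen-mark rectangles and blur patches are
  planted with polygon records for exclusion handling; serial sections are
  rigid transforms (±45°) plus an optional smooth jitter field, with the
  re-aligning transform recorded for recovery tests.

What it does **not** emulate: tissue texture and stromal background,
nucleus clumping and overlap, macrophages, staining gradients, pyramidal
whole-slide formats. Passing tests therefore demonstrate correctness of the
algorithms under clean, known conditions — fidelity of stain separation,
geometry, counting, agreement statistics and optimization — not robustness
to the full messiness of clinical material.

## Numerical choices and problem sizes

All randomness flows from one root seed through named substreams (layout,
latent, render, reader, split, ...), so each stage's draws are independent
of the others and every table is exactly reproducible. The test suite and
the acceptance script use: a 50-sample single-assay cohort at 1024² px with
500 cells per field for end-to-end recovery (measured: cell counts within
0.2%, score MAE well under 1 percentage point, Pearson r vs truth > 0.99);
100 planted rigid transforms at 512² px (|rotation| ≤ 10°, |t| ≤ 50 px; ≥
95 must land within 2 px and 0.5°); 20 replicates of 100-sample
feature-level cohorts for threshold recovery. These sizes were chosen as
the smallest at which the measured properties are stable; all of them are
configurable upward.

Degenerate inputs are contracts, not crashes: blank fields segment to zero
cells; samples with no tumor cells are invalid, not division errors;
flat or incoherent image pairs fail registration with a classed condition;
empty comparable regions flag the sample. Watershed and Voronoi ties are
deterministic (lower label wins), so repeated runs are bit-identical.

## Known limitations

* The rigid registration model cannot represent true elastic section
  distortion; on heavily deformed pairs it will either fail the confidence
  floor or return the best rigid approximation.
* The immune gate is morphology-only and tuned to the synthetic rendering;
  real lymphocyte/tumor discrimination needs either re-tuned cutoffs or a
  richer feature set.
* The default positivity thresholds travel with the declared intensity
  scale; any change to stain vectors, scanner or scale invalidates them
  until refitted.
* `feat_ratio`'s denominator choice (whole-cell mean) is one of two
  defensible readings of "overall" intensity; results near the ratio
  threshold depend on it.
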