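---
title: "Methods: dementia-informed IDPs, staged QC, and hierarchical FDR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dementia-informed IDPs, staged QC, and hierarchical FDR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpscreen)
```

`idpscreen` covers the layer between a preprocessed brain-MRI pipeline and
a clinical research question: extracting dementia-relevant scalar
phenotypes from registered maps, triaging scan quality, and screening the
phenotypes against age, cognition and ordered diagnosis with
within-modality false-discovery-rate control. This vignette records the
models, the parameter choices, and the places where the design was
genuinely open.

## Inputs and assumptions

Every voxel-space input is a `volume_grid`: a 3D array plus voxel
dimensions in mm. The package assumes all maps for a subject — GM partial
volume, WMH mask, CSF map, subcortical structure masks, MD/MO, skeleton,
streamline densities — and all atlas masks live on one common grid.
Registration is deliberately out of scope: the operators act after it, and
no resampling is performed. Masks are strictly binary; partial-volume maps
live in [0, 1]; MD is in mm²/s (typical grey/white values around
0.7–1.0 × 10⁻³); MO is dimensionless in [−1, 1].

## Segmentation corrections

Atrophic, lesion-heavy brains break tissue segmentations in two
characteristic ways, and two corrections run before any volume is
measured:

* **Lesion masking**: WMHs are segmented as grey matter often enough to
  bias GM volumes upward, so the GM partial-volume estimate is zeroed
  inside the WMH mask (`gm × (1 − wmh)`), elementwise and nowhere else.
* **CSF masking**: subcortical surface fits leak into enlarged
  ventricles; voxels whose CSF value exceeds `csf_threshold` (default
  0.5) are removed from structure masks. The threshold is exposed because
  the appropriate value depends on how the upstream CSF map was produced;
  with a binary CSF map any threshold in (0, 1) reduces to set removal.
* **Mislocalisation**: a structure whose overlap with thresholded CSF
  reaches `mislocalised_threshold` (default 1, i.e. complete overlap) is
  considered misplaced rather than correctable, and its downstream IDPs
  are emitted as missing. The default encodes "full overlap"; it is
  configurable because stricter screening (e.g. 0.9) may suit noisier
  segmentations.

Missing is never conflated with zero: a zero volume is a legitimate
measurement (an empty WMH–tract overlap), whereas a mislocalised
hippocampus has no defensible MD value at all, so it yields `NA`.

## The supplementary IDP set

With the default atlas configuration `extract_all()` emits exactly 110
IDPs: 4 lobar GM volumes + 48 tract-wise WMH volumes + 2 NBM volumes +
1 PSMD + 27 tractography tract volumes + 28 regional diffusion metrics
(14 regions × {MD, MO}). Two compositional choices deserve a note, since
the total is better attested than its decomposition:

* the tractography set is fixed at 27 bundles, which is what makes the
  total come out at 110 with the other counts as given; commonly used
  tractography atlases carry different bundle counts, so the 27-bundle
  set is a configuration default, not a claim about any particular atlas;
* the five cortical ROIs are treated bilaterally (10 regions), joining
  the four corrected subcortical structures to give 14 diffusion ROIs.

All volume IDPs are partial-volume-weighted sums (`Σ gm·mask × voxel
volume`), not binary counts, for consistency: the NBM definition is
explicitly GM-weighted, and treating lobar volumes the same way makes
every GM-derived volume respond identically to the lesion correction.

Numerical conventions, each declared once and used by both the
implementation and the test oracles:

* **Percentiles** (PSMD, quartiles): linear interpolation between closest
  order statistics — quantile type 7, `h = (n−1)p + 1`. PSMD is then
  `P95 − P5` of MD on the skeleton, which makes it translation-invariant
  and positively homogeneous; both properties are tested.
* **Tract binarisation**: strict inequality `density > 0.005`. "At the
  threshold" is a genuine edge case; strictness is asserted by a boundary
  test (a map equal to 0.005 everywhere has zero volume).
* **CSF removal**: strict inequality `csf > threshold`, same reasoning.

## Staged quality control

Image-quality metrics (IQMs) arrive as a long table (scan, modality,
metric, value); the package does not compute IQMs from raw images. For
each metric *within each modality*, scans outside
`[Q1 − k·IQR, Q3 + k·IQR]` (k = 1.5) are flagged; a scan is flagged
overall if any metric flags it. Grouping per metric within modality is the
natural reading when metrics are incommensurable across sequences; it also
makes flagging invariant under affine rescaling of any single metric,
which is tested as a property. A constant metric has zero IQR and flags
nothing. At least 5 scans per modality are required — below that,
quartiles are not meaningful.

Flagging is deliberately only a triage signal. Exclusion is a separate
input (`summarize_flags(reports, exclusions = ...)`) because the decisive
step is visual inspection, which cannot be automated here; the summary
table reports % flagged and % excluded per modality in the conventional
N/total form.

The DSE decomposition splits each voxel's mean-centred time series into
half-differences `(y_{t+1} − y_t)/2` (fast, D), half-sums (slow, S) and
endpoint terms `y_1²/2, y_T²/2` (edge, E). Averaged over voxels these
satisfy `Σ_t A_t = Σ D + Σ S + E` *exactly*, and that conservation
identity — tested at 10⁻⁶ relative tolerance — is what pins down the
normalisation choices the formulation leaves open (variance of the
centred series, whole-brain averaging after squaring). Per-timepoint
percentages are expressed relative to the whole-series mean A-var, so
white noise puts both D and S near 50%; global percentages are relative
to total A-var and sum to 100. The S-var criterion flags transitions with
slow share above 75%, the conventional threshold for residual structured
noise; the threshold is a parameter because its appropriateness for
clinical populations is an open question.

## The association screen

All numeric variables — every IDP, age, ACE-III total, head size — are
rank-based Gaussian normalised: `Φ⁻¹((r − ½)/n)` with average ranks for
ties, missing kept missing. Whether such a transform centres ranks at
`(r − ½)/n` or `r/(n + 1)` is immaterial for rank-based inference (the
two differ by a monotone reindexing that vanishes in the model fits); the
offset-rank form is fixed here for reproducibility and asserted by a
direct numeric test. Sex stays a raw binary indicator. The payoff is that
linear slopes are SD-per-SD effects, the ordinal slope is a log-odds per
SD, and every estimate is invariant to affine rescaling of the raw
inputs — also tested as a property.

Per IDP, three models: OLS of age on IDP + sex + head size + ACE; OLS of
ACE on IDP + age + sex + head size; proportional-odds logistic of the
ordered diagnosis on IDP + age + sex + head size. Cognition enters the
age model as a covariate so that "age effects" are not merely relabelled
impairment effects in a population where the two are tightly coupled. The
covariate set is deliberately small — with ~200 subjects, a big-cohort
confound set would consume the degrees of freedom the screen needs.
Ordinal p-values are Wald by default; a likelihood-ratio option exists
(`p_type = "lr"`) since neither choice is canonical. When the outcome has
only two observed levels, the proportional-odds model *is* ordinary
logistic regression, and the implementation fits it as such (the
equivalence is tested). Each fit is complete-case; IDPs falling below
`min_n` complete cases are skipped and logged in the result rather than
silently dropped. An optional mapping of IDPs to matched ROI/tract-volume
IDPs adds that volume as an extra covariate — the sensitivity variant that
separates microstructural signal from plain atrophy.

Multiplicity is controlled per outcome with a two-stage hierarchical FDR.
Stage 1: Simes omnibus p-value per modality family
(`min_i m·p_(i)/i`), then BH across the m family p-values at level q.
Stage 2: within each of the R selected families, BH at level `q·R/m`;
unselected families reject nothing. The source of the stage-2 level is
the one genuinely open reading in the procedure: "a more stringent
threshold according to the number of significant omnibus p-values" is
implemented as the proportional `q·R/m` rule — the canonical
selection-adjusted choice, stricter exactly when R < m and reducing to
plain BH when every family is selected. Reported within-family adjusted
p-values are stage-2 BH-adjusted values scaled by `m/R`, so
`p_adj ≤ q ⇔ rejected`; they are not compounded with the stage-1
adjustment, which matches reporting corrected p-values per modality
hierarchy.

## What the synthetic data does and does not emulate

The generators exist to give every stage an exact oracle, not to imitate
MR physics:

* `make_phantom()` builds axis-aligned box regions at fixed coordinates
  (fitting the minimum 16³ grid), so every volume, overlap and weighted
  mean is known by counting voxels. Lesions are sampled inside deep WM
  and the temporal lobe so both lesion-masking and WMH–tract overlap are
  exercised; the left hippocampus partially overlaps a high-CSF block so
  CSF-masking removes a known set. There is no MR contrast, noise
  texture, artefact structure, or anatomical realism.
* `make_cohort()` plants standardised effects by construction:
  `IDP = β_age·z_age + β_ace·z_ace + s·ε` with `s` the unit-variance
  completion, so planted βs are the population standardised slopes the
  screen estimates; diagnosis comes from a proportional-odds latent
  `Σ β_diag·IDP + logistic noise` with cutpoints (−1.1, 1.1), giving all
  three classes mass (roughly 25/50/25 under the null). Age is
  78 ± 6.2 years and ACE-III centred near 74 (SD 17, clamped to 0–100),
  emulating a memory-clinic population; the default cohort size used by
  the pipeline is 213. Planted effect sizes have no empirical
  distribution to draw on, so they are explicit arguments everywhere.
* `make_iqm_table()` guarantees each designated scan one value beyond the
  1.5-IQR fences of the *remaining* scans; `make_bold()` adds a constant
  to every voxel at spike timepoints atop i.i.d. Gaussian noise.

Consequently, green tests certify the *arithmetic and the statistics* —
operators equal their brute-force oracles, the FDR procedure controls
what it claims, planted effects are recovered — not performance on real
scans, where registration error, segmentation failure modes and
non-Gaussian IDP distributions all enter.

## Problem sizes and runtime choices

The test-suite and acceptance simulations are sized to give stable Monte
Carlo answers on a single CPU: phantoms at 16³–32³ voxels; FDR control at
2000 replicates of 6 families × 50 tests (Monte-Carlo SE of the empirical
FDR ≈ 0.2 percentage points); linear and ordinal parameter recovery at
n = 2000 with 200 replicates; the global-null uniformity check at
n = 5000 subjects × 60 IDPs. The FDR simulation plants 10 non-null tests
in each of 2 of the 6 families with non-null z ~ N(3, 1), which puts
per-test power near one half at the stage-2 working threshold — enough
signal that family selection actually engages, the regime in which the
procedure's selection adjustment matters.

## Known limitations

* IQM tables are consumed, not produced; no MRIQC/QUAD-style metric
  computation, FIX denoising, or visual-report rendering.
* The proportional-odds model assumes proportionality; no test of that
  assumption is built in, and separation is reported as an error rather
  than resolved by penalisation.
* The hierarchical procedure's FDR guarantee is within selected families
  under independence/positive dependence; the simulation checks
  independence only.
* Phantom geometry cannot surface resampling/partial-volume interactions
  that arise from real registration, by design.
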