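---
title: "Methods: CT latent-trait phenotyping of humidifier-disinfectant-exposed lungs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT latent-trait phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, parameters,
numerical choices and limitations. The pipeline characterizes lungs of
subjects exposed to aerosolized humidifier disinfectants (HD) whose CT and
lung function look normal: it searches for *latent* tissue-pattern traits in
paired inspiratory (TLC) / expiratory (RV) CT and uses them to cluster
subjects, profile the clusters, and probe the aerodynamic consequences of
the airway geometry associated with them.

## The two-channel image

Let `u(x)` be the displacement (mm) mapping TLC voxel coordinates to RV
coordinates. The Jacobian determinant `J = det(I + ∇u)` is the local RV/TLC
volume ratio: `J < 1` marks tissue that is larger at TLC than RV (normal
deflation), `1/J` is the local expansion. `jacobian_determinant()` evaluates
`∇u` by second-order central differences (one-sided at grid boundaries) with
spacing in mm, and clips the result to a configurable positive floor
(default `1e-3`) so folded or noisy voxels cannot inject non-physical
non-positive volume ratios into the second channel. On affine fields the
finite differences are exact; the test suite asserts agreement with
`det(I + A)` to `1e-12`.

Channel 1 is the TLC attenuation mapped linearly from [-1024, 200] HU (air
to soft tissue) to [0, 1] and clamped. The window is a declared choice — it
spans the full parenchymal range while keeping normalized densities of
aerated lung in the 0.05–0.3 region where pattern contrast lives. Outside
the lung mask the channels take the fill value (0, 1).

## Patch extraction

Tissue patterns live at the scale of the secondary pulmonary lobule
(~20 mm), so the unit of analysis is a cubic two-channel patch. Training
patches are drawn uniformly over all positions whose patch lies inside the
volume and covers at least `min_lung_fraction` (default 0.5) lung;
quantification uses a deterministic sliding-window raster (default stride
half the patch edge, i.e. 50 % overlap) with the same lung filter.
Extraction requires isotropic spacing so a physical cube is a voxel cube.
The 20 mm default edge targets real-size CT; the desk-scale tests use 12 mm
patches on the 64³ × 1 mm phantom, whose lungs (~45 mL) are far smaller than
human lungs — at 12 mm the phantom hosts enough windows per lung for stable
histograms, and the full suite (including ten end-to-end replicates) runs in
minutes on one CPU.

## The CAE-FC pattern-cluster model

The encoder applies two stride-2 3×3×3 convolution blocks (2→16→32
channels, ReLU) followed by a full-extent convolution that collapses the
patch to a C-channel *global* embedding (one activation per channel). The
feature constructor (FC) scores each channel by the sum of its positive
activations, keeps the arg-max channel (ties to the lowest index), zeroes
the rest, and the mirrored transposed-convolution decoder reconstructs the
patch from that single channel. The surviving channel index is the patch's
pattern cluster.

Three design choices deserve justification, because the naive formulation
fails in reproducible ways:

* **Global embedding.** With a spatial (3³) embedding, one channel has
  enough code capacity to reconstruct *every* patch and the arg-max
  partition collapses onto a single channel (observed purity 0.25 on a
  4-class fixture). Collapsing the embedding to one activation per channel
  makes each channel essentially a learned template with an amplitude, so
  hoarding classes on one channel costs reconstruction error.
* **Per-channel normalization.** The embedding pre-activations are
  batch-normalized per channel (training: batch statistics; inference:
  statistics accumulated over the training set). Without it the channel
  scores live on incomparable scales and the competition dies; with it every
  channel stays in play.
* **Self-labelled alignment (default on).** Reconstruction gradients alone
  do not re-route a patch from one channel to another, so similar classes
  merge and strong classes split (purity plateaued at 0.75). Training
  therefore adds (i) an auxiliary reconstruction of the *full* embedding
  (weight 0.3) — which also guarantees that decoding all channels is never
  worse than decoding one — and (ii) a cross-entropy (weight 1) between the
  softmax of the channel scores and fixed pseudo-labels from a seeded
  k-means (20 restarts) on each patch's (mean density, mean J) pair, the
  same two axes on which tissue-pattern clusters are characterized
  downstream. Pseudo-classes are mapped to channels once, greedily by mean
  score at the first batch, and the masks are teacher-forced during
  training. Inference is untouched: a pure forward pass with arg-max channel
  selection. With alignment the 4-class fixture is recovered at purity 1.0
  across seeds.

  The pseudo-label teacher clusters first-order patch statistics; texture
  classes that differ only in higher-order structure (same mean density and
  deformation) would not be separated by the teacher and would have to be
  resolved by the reconstruction objective alone. `align = FALSE` restores
  the plain objective.

The optimizer is Adam (learning rate `1e-3`, batch 32) under a fixed seed;
identical seeds give bit-identical weights. The cluster count C is selected
by training one model per candidate under an identical budget and taking the
lowest final reconstruction loss (`select_cluster_count()`); the desk-scale
default grid is {2, 4, 8, 16}, and cohort-scale values (e.g. 80) are reached
by configuration.

## Histograms, factors, scores

Per subject, sliding-window assignments are tabulated into a length-C
frequency histogram (sums to 1; all windows weighted equally over the whole
lung). Exploratory factor analysis of the subjects × C matrix uses
principal-axis factoring with iterated communalities (initialized at squared
multiple correlations, tolerance `1e-4`, 200 iterations) and varimax
rotation by default — orthogonal rotation keeps the factor-score geometry
interpretable for the k-means stage; promax is available. Because histogram
rows sum to 1, the correlation matrix is rank-deficient by one; all solves
go through a tolerance-based eigenvalue pseudo-inverse. Factor scores are
Thomson regression scores `S = Z R⁻ Λ` (mean 0 over the fitting sample).
The factor count is fixed when given; `"auto"` uses Horn-style parallel
analysis (95th percentile of seeded random-data eigenvalues). A factor's
associated pattern clusters are those with |loading| ≥ 0.4 (the conventional
salient-loading cutoff, configurable); a factor with salient loadings of
both signs is flagged *bi-polar* and interpreted through its positive and
negative cluster sets. Correlations of scores with clinical/imaging
variables use Pearson for continuous and point-biserial for binary
variables; the reported table masks entries with p ≥ 0.05 but the full
table is always written.

## Quantitative CT metrics

* `LAA%`: fraction of masked voxels below a threshold; -950 HU at TLC
  (emphysema-like) and -856 HU at RV (gas trapping) — the field-standard
  values, exposed as arguments.
* `Tissue%`: mean of `clamp((HU + 1000) / 1055, 0, 1)` — a linear air
  (-1000 HU) to soft-tissue (55 HU) mixture model.
* `fSAD%`: joint parametric-response-map rule — non-emphysematous at TLC
  (≥ -950) but trapping at RV (< -856) on co-registered grids. The four PRM
  classes (normal / fSAD / emphysema-like / high-attenuation above -250 HU)
  partition the mask exactly.
* `RV/TLC` from mask volumes; `AWV%` from the airway-tree cylinder volume
  when no airway mask exists. Lobe-resolved variants use the 5-label lobe
  mask; in-lung voxels without a lobe label count only in the total.

## Cohort statistics

Welch's t (from raw samples or published mean/SD/n summaries, two-sided,
Welch–Satterthwaite df), Welch's heteroscedastic ANOVA (reduces to Welch's t
at k = 2), Games–Howell pairwise tests (per-pair Welch df, p from the
studentized range with k groups), and Pearson chi-square with expected
counts. Yates continuity correction defaults to on for 2×2 tables and off
otherwise — on reconstructed 2×2 gender-by-exposure counts of the reference
cohort the corrected test reproduces the published p = 0.013, while the
uncorrected statistic is anticonservative. α = 0.05 throughout; no
multiple-testing correction beyond Games–Howell is applied.

## Subject clusters and the decision tree

K-means runs with 20 seeded restarts (best inertia kept); `"auto"` picks the
cluster count maximizing the Calinski–Harabasz variance ratio over 2..10 —
a declared reading of "inter- vs intra-cluster variability" (silhouette is a
drop-in alternative). Clusters are relabelled C0, C1, … by descending size;
clusters with fewer than 5 members are flagged minor and excluded from mean
contrasts, mirroring the exclusion of 1- and 4-member clusters in the
reference cohort. Factor scores enter k-means unstandardized (regression
scores already share a scale). Representative subjects minimize Euclidean
distance to the centroid, ties broken lexicographically. The decision tree
is CART (Gini, depth ≤ 3) on variables passing a Welch-ANOVA screen at
α = 0.05, evaluated by stratified 3-fold cross-validation accuracy.

## 1D airway resistance and deposition surrogate

The full 3D computational fluid and particle dynamics stage is out of scope;
the package implements the 1D conducting-airway surrogate. Inhalation is a
half-sine: tidal volume 7 mL/kg body weight, inspiratory phase
`T_insp = 2.4 s` (peak at 1.2 s, breath period 4.8 s read as the full cycle
— the period statement is ambiguous and this reading is flagged in the
configuration), peak flow `Q_p = π V_T / (2 T_insp)`. Branch flows descend
from the inlet by symmetric (default) or area-weighted splits. Per branch:

* resistance: laminar Poiseuille `ΔP = 128 μ L Q / (π D_h⁴)` with
  `μ = 1.81e-5 Pa·s` and hydraulic diameter `D_h = 4A/P`;
* impaction: a Stokes-number bend fit
  `η_I = 1 − (2/π) arccos(θ Stk) + (1/π) sin(2 arccos(θ Stk))`
  (branch angle θ default 45°, zero for the root which has no upstream
  bifurcation);
* sedimentation: the exact laminar parabolic-profile solution
  `η_S = (2/π)[2κ√(1−κ^{2/3}) − κ^{1/3}√(1−κ^{2/3}) + arcsin(κ^{1/3})]`,
  `κ = 3 v_s L cos φ / (8 R ū)` clipped at 1, gravity angle φ default 45°;
  the suite checks it against a 10⁵-particle tracking simulation (within
  2 %);
* diffusion: Ingham's laminar solution in `Δ = π D_B L / (4Q)`; slip
  correction and Brownian diffusivity from standard aerosol mechanics
  (λ = 66 nm, T = 293 K).

Mechanisms combine as `η = 1 − Π(1 − η_i)`; the entering aerosol fraction is
propagated root→leaves with flow-split weights, each branch retains
`entering × η`, and the leaf outflow is the escape fraction — branch
fractions plus escape sum to 1 exactly by construction. Efficiencies are
evaluated quasi-steadily at peak inspiratory flow.

## The synthetic cohort generator

The generator exists to give every stage testable ground truth, not to be
anatomically faithful:

* **Phantom**: two ellipsoids (left/right lung) inside a soft-tissue body
  ellipsoid on a 64³ × 1 mm grid by default; fixed fractional planes along
  the inferior–superior axis split the left lung at 0.5 (LUL/LLL) and the
  right at 0.45/0.70 (RLL/RML/RUL).
* **Patterns**: one Gaussian-smoothed noise field per subject is
  quantile-sliced so the planted mixture proportions are realized almost
  exactly while staying spatially coherent at the blob scale (default 8 mm).
  Four default classes span the (attenuation, J) plane: normal (-889 HU,
  J 0.55), air-trapping (-916, 0.77), hypoinflation/fibrosis-like (-697,
  1.40), hyperdeflation (-833, 0.45), SDs 35–60 HU / 0.05–0.08. No
  published HU distribution per tissue state exists; these values were
  chosen once for separability, loosely calibrated to the normalized
  densities (~0.09–0.27) typical of reported pattern-cluster summaries.
* **Deformation**: the target Jacobian field J\* assigns each blob its
  pattern's J with smooth noise, is smoothed by normalized (mask-weighted)
  convolution — so lung values are never contaminated by the outside-lung
  value 1 — and blended to 1 beyond the lung surface. The displacement is
  single-axis, `u_z(x,y,z) = ∫₀^z (J*(x,y,t) − 1) dt`: `I + ∇u` is then
  triangular with diagonal (1, 1, J\*), so the *analytic* Jacobian equals
  J\* exactly, giving an exact oracle for the finite-difference operator.
  (A sum of cosine modes was considered and rejected: its Jacobian only
  approximates the per-blob targets, which weakens the oracle.) Per-blob
  agreement is asserted on blob interiors (eroded by the smoothing radius);
  pattern interfaces are intentionally smooth.
* **EX image**: attenuation transforms mass-conservingly,
  `HU_RV = −1000 + (HU_TLC + 1000)/J*`, and the EX volume/mask are obtained
  by inverting the monotone per-column warp; `ex_warped` stores the RV
  attenuation on the TLC frame for PRM metrics.
* **Cohort**: groups differ through their pattern mixtures (the default
  "exposed" mixture is shifted toward hypoinflation/hyperdeflation) plus
  configurable covariate shifts (gender proportion, height, airway calibre);
  subjects add logistic-normal mixture jitter (SD 0.15). All randomness
  descends from one master seed via fixed offsets.
* **Airway trees**: binary trees; child diameter = parent × ratio ×
  (1 ± asymmetry/2), length = 3 diameters, circular lumens; the five lobar
  bronchi are labelled on the anatomical layout (LUL/LLL off the left main
  bronchus, RUL and the intermedius off the right, RML/RLL off the
  intermedius — full labelling therefore needs ≥ 4 levels), and sub-lobar
  subsets are a lobar bronchus's children and grandchildren.

What the phantom does **not** emulate: reconstruction-kernel noise and CT
artefacts, realistic lung and lobe shapes, airway lumens inside the image
volume, vascular structures, or realistic spatial covariance of disease.
Tests passing on the phantom therefore demonstrate the correctness and
internal consistency of the pipeline, not clinical performance on patient
CT.

## Problem sizes and runtime choices

Unit fixtures use 12³ patches (200 patches, 20 epochs ≈ 20 s); the
end-to-end recovery suite runs ten seeded replicates of a 2 × 8-subject
cohort at 64³ (≈ 25 s each); Monte-Carlo suites use 10⁴ ANOVA null
replicates, 5 × 10³ Games–Howell families and 10⁵ tracked particles. These
sizes keep the whole suite within minutes on one CPU while leaving each
statistical check adequately powered.

## Known limitations

* The CAE-FC teacher aligns channels with first-order patch statistics (see
  above); purely textural pattern classes are out of reach of the default
  alignment.
* The EFA retention default (parallel analysis) and the varimax rotation are
  conventional but not canonical; both are switchable.
* The 1D deposition surrogate assumes fully developed laminar flow, a fixed
  45° geometry angle absent per-branch orientation, and inspiration only; it
  captures monotone effects of calibre (narrower airways → higher resistance
  and deposition), not secondary-flow hotspots.
* Published cohort-level means for real subjects are not reproducible
  without the (unreleased) imaging data; the shipped reference tables allow
  re-deriving only the aggregate statistics.
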