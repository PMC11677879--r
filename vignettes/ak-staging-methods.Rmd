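---
title: "Methods: multimodal staging of actinic keratosis from HFUS and dermatoscopy phantoms"
author: "akstage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal staging of actinic keratosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Actinic keratosis (AK) is a pre-malignant keratinocyte lesion of
sun-exposed skin, graded clinically on the three-point Zalaudek scale:
grade 1 shows a pink pseudonetwork with discrete scales, grade 2 the
"strawberry pattern" of keratotic follicles on an erythematous background,
and grade 3 thick white-yellow keratotic masses. Two non-invasive imaging
modalities carry complementary staging information: dermatoscopy (surface
color and texture) and 20 MHz high-frequency ultrasound (HFUS), whose
B-scans resolve the *entry echo* (the bright superficial band produced by
the dead epidermal layers) and, beneath it, the *subepidermal low echogenic
band* (SLEB) associated with elastosis, inflammation and tumour
infiltration.

`akstage` implements a complete machine-learning pipeline for three-class
AK staging from paired HFUS and dermatoscopy images: skin-layer
segmentation, handcrafted and CNN feature extraction, feature-selective SVM
classification under patient-grouped validation, and rank-based group
statistics. Because clinical AK image collections are not publicly
deposited, the package also ships a first-class synthetic-data module that
generates seeded phantoms with the statistical structure the method is
designed to detect; every claim the test suite makes is a claim about those
phantoms.

## The phantom generators as study conditions

`phantom_params()` fixes the simulated study conditions. The HFUS phantom
is a layered speckle image: a dark coupling-gel band, a bright entry echo
whose per-column thickness is a smooth profile around a stage-dependent
mean (8, 12, 16 px for stages 1-3, sd 2 px) with stage-increasing boundary
roughness (sinusoid plus smoothed noise, amplitude 1, 2.5, 4 px), an
optional SLEB (presence probability 0.85, mean thickness 22 px), and dermis
below. Speckle is multiplicative: each pixel is its layer mean times
`1 + s (X - 1)` with `X` a unit-mean Rayleigh draw and `s` the layer's
speckle fraction; `s = 0` reduces the image to exact layer means, which the
tests exploit. Mean intensities (background 8, entry echo 190, SLEB
55/45/35 by stage, dermis 120) encode the defining contrast of the SLEB as
a low echogenic band referenced to dermis. SLEB speckle *decreases* with
stage (0.35, 0.27, 0.20): stage-1 lesions show the most SLEB texture
contrast, the direction reported for clinical scans, which makes GLCM
contrast stage-decreasing and homogeneity stage-increasing. The entry-echo
speckle rises with stage, so intensity entropy rises too.

The default cohort mirrors a published clinical AK series: class counts
92/42/27. Those printed per-class counts sum to 161 while the series'
printed total is 162; the generator keeps the per-class counts and logs the
one-pair discrepancy rather than silently resolving it. Lesions are
distributed round-robin over patients after a seeded shuffle, so single
patients hold several stages — the property that makes patient-grouped
validation non-trivial.

The dermatoscopy phantom composes a clean stage-textured lesion (stage
colors run from pink toward white-yellow, scale-texture amplitude 6/12/18,
keratotic follicle count 0/25/40) over skin with fine grain noise (sd 2.5),
then injects the acquisition artifacts the preprocessing stage must remove:
a dark round-corner frame, 3-9 px wide dark and light hairs drawn as
quadratic Bezier strokes, and ruler tick marks. Ground-truth masks cover
the artifacts exactly. Default canvases are 256 x 128 px (HFUS) and
512 x 512 px (dermatoscopy) — desk-scale stand-ins for the clinical
1024 x 224 (cropped to 512) and 3024 x 4032 formats, selectable via
parameters.

What the phantoms do *not* model: acoustic physics (attenuation, shadows
behind keratotic scale, probe frequency response), device-dependent
intensity calibration, lesion-boundary irregularity, and the full
variability of real hair, illumination and skin color. Passing tests
therefore demonstrate that the pipeline recovers structure it is pointed
at, with no leakage and correct statistical calibration — not clinical
performance.

## Skin-layer segmentation

`build_model()` constructs a compact contextual-feature-pyramid
encoder-decoder, a reduced variant of the CFPNet-M family: a full-resolution
stem, two stride-2 encoder stages, and at each encoder stage a pyramid
block of three parallel 3 x 3 convolutions with dilation rates 1, 2 and 4
whose outputs are concatenated, fused by a 1 x 1 convolution and added back
residually — the mechanism that lets the network combine local boundary
detail with wider context. The decoder restores resolution with nearest
up-sampling, 1 x 1 convolutions and skip additions, and a 1 x 1 head emits
per-pixel class scores (background / entry echo / SLEB by default; a
four-class variant adds a predicted dermis band). Channel widths default to
6/12/24 (about 15k parameters): on the phantom task wider variants (8/16/32)
raise held-out Dice by under 0.03 while costing ~60% more compute, so the
smaller network is the default and widths stay configurable. Training
minimizes cross-entropy plus soft Dice — a standard pairing for thin-layer
segmentation where foreground pixels are rare — with Adam (lr 3e-3), 20
epochs by default, single-image batches, and full seeding of
initialization and shuffling. The convolution primitives are compiled
(RcppArmadillo im2col/GEMM with cached patch matrices for backprop).

`train_segmentation()` splits *patients* (never lesions) into folds,
asserts the split, trains one model per fold and reports per-lesion,
per-layer Dice on the held-out patients. `segment_layers()` takes the
argmax map, keeps the largest connected component per layer, derives the
dermis reference as the 50 px band directly below the deepest segmented
boundary (the clinical analyses reference SLEB echogenicity to dermis, but
only entry echo and SLEB are segmented), and flags an empty entry-echo
prediction as degenerate instead of failing silently. The Dice convention
for two empty masks is 1 (agreement on absence), which matters for
SLEB-absent phantoms.

At the packaged study scale — 40 phantoms, 4 folds, 20 epochs, 256 x 128
inputs — held-out Dice runs about 0.96 for the entry echo and 0.98 for the
SLEB. These phantoms are much cleaner than clinical scans; the numbers
validate the training machinery, not clinical segmentation quality.

## Handcrafted HFUS descriptors

Features are named `hfus.<family>.<region>.<stat>` over regions
`entry_echo`, `sleb`, `dermis` and `combined` (entry echo plus SLEB):

* **Morphology** — per-column thickness statistics (mean, sd, min,
  quartiles), perimeter-to-area ratio, boundary roughness (sd of the lower
  boundary depth) and boundary length ratio, SLEB depth descriptors. The
  perimeter counts background-facing pixel edges at 4-connectivity, so a
  solid n x n square scores 4n/n² and a single pixel 4 — a convention fixed
  by an enumeration oracle in the tests.
* **Echogenicity** — fractions of low/medium/high echogenic pixels
  (LEP/MEP/HEP) with default cuts at 30 and 150 on the 8-bit scale
  (configurable; conventional HFUS banding), plus mean intensity; SLEB
  values are additionally divided by the dermis-band values (`_rel`
  features). The three fractions partition to 1 exactly by construction.
* **Histogram** — mean, sd, skewness, kurtosis, 256-bin Shannon entropy
  (bits).
* **GLCM** — contrast, homogeneity, correlation, energy from a symmetric
  normalized co-occurrence matrix at distance 1, four orientations,
  averaged, with 32 fixed-width intensity bins. Pairs are restricted to
  pixels that are both inside the mask. Fixed-range (not min-max)
  quantization keeps codes comparable across regions and lesions.
* **LBP** — rotation-invariant uniform 8-neighbour codes at radius 1
  (ties count as "greater or equal", so flat regions map to the all-ones
  code), normalized 10-bin histogram, computed only where the full
  neighbourhood lies inside the mask.
* **Scattering wavelets** — order-0/1/2 coefficients of a Gabor filter
  bank (2 dyadic scales, 6 orientations) applied to the mask bounding box
  with background replaced by the in-mask mean, spatially averaged per
  path (49 features). Modulus-based, hence non-negative, and stable under
  small translations; regions with a bounding box under 16 px per side are
  reported missing.

Texture computed on raw (not dermis-normalized) SLEB intensities; the
dermis referencing enters through the explicit `_rel` echogenicity
features. SLEB-absent lesions carry explicit `NA`s that are imputed only
inside classifier training folds.

## Dermatoscopic preprocessing and features

`remove_frame_and_background()` follows intensity adjustment (1-99%
contrast stretch), dark thresholding (6% of the stretched range) for the
round-corner frame, and 2-cluster fuzzy c-means on (intensity, local
sharpness). Local sharpness is a 5 x 5 local standard deviation, capped at
five times its median so hair and frame edges cannot dominate the
clustering; the low-sharpness cluster is discarded only when its raw
sharpness center falls below 0.35 times the median sharpness of the
candidate region — optical blur suppresses fine grain by an order of
magnitude, while smooth-but-focused skin stays near the median, so plain
skin is never discarded. The component containing the image center is kept
and hole-filled. Clustering runs on a fixed-seed subsample, making the
result deterministic.

`remove_hairs()` generalizes morphological hair removal to both
polarities: grayscale closing (dark hairs) and opening (light hairs) with
15 px linear structuring elements at 0/45/90/135 degrees, taking the
maximal filtered-minus-original response. Pixels outside the valid region
are first replaced by the median valid intensity so the dark frame cannot
respond to the line elements. Candidates above the 10-unit threshold are
grouped; a component is kept when it is thin (major/minor axis ratio >= 4)
or spans a long bounding-box diagonal (>= 2 structuring-element lengths —
crossing hairs merge into networks whose covariance is isotropic), *and*
its mean response exceeds twice the pixel threshold (a hysteresis check
that rejects chains of faint texture blobs). The kept mask is dilated by a
5 px disc and inpainted: inverse-distance-weighted directional fill from
the four axis directions (frame pixels never seed the fill) followed by
ten 3 x 3 diffusion iterations. On phantoms this removes hairs with pixel
recall above 0.9 and reduces the mean absolute error to the clean image
several-fold; a second pass changes under 1% of pixels.

Channels are decomposed as R, G, B plus H, S, V (hue circular on 0-255),
and the full texture family set is computed per channel over the valid
mask (`derm.<channel>.<family>.<stat>`).

The CNN feature interface mirrors transfer learning from AK/non-AK
classification: any checkpoint exposing the compact classification
architecture (two strided 3 x 3 convolutions, global average pooling, one
hidden fully connected layer whose activations are the features) plugs in
via `load_extractor_checkpoint()`; `train_derm_extractor()` trains the
bundled desk-scale instance on phantom AK-vs-plain-skin images (it reaches
~1.0 held-out phantom accuracy in seconds). Reproducing a full
EfficientNet trained on public archives is deliberately out of scope; the
interface is the contract, and `derm.nn.f###` features flow into the
classifier identically either way.

## Staging classifier

`select_and_classify()` runs, for one feature-set combination (HFUS
handcrafted, dermatoscopy handcrafted, dermatoscopy CNN, and their
unions):

1. outer leave-one-patient-out folds;
2. inside each training fold only: median imputation, z-score
   normalization (sample sd; constant features zeroed with a warning),
   MRMR ranking, and a joint grid search over the feature-count cutoff
   (default 5-40) and SVM cost/gamma (RBF; cost 0.1-100, gamma as
   multiples 0.1/1/10 of the 1/p heuristic) scored by patient-grouped
   5-fold inner cross-validation;
3. SMOTE oversampling of the minority stages to the majority count
   (k = 5 neighbours, reduced to class size minus one; synthetic samples
   are convex combinations of same-class neighbours; originals preserved);
4. an SVM fit on the balanced fold and prediction of the held-out
   patient.

MRMR uses the difference (MID) criterion with one-way ANOVA relevance
expressed on the eta-squared scale `ssb/(ssb+ssw)` — a bounded, monotone
transform of the F statistic — against mean absolute Pearson correlation
redundancy. The bounded scale is deliberate: with raw F values in the
hundreds, a [0,1] correlation penalty could never influence the ranking
and the redundancy term would be decorative. Even so, a perfect duplicate
of the top feature ranks by `relevance - 1`, which for a near-perfect
feature still exceeds weak-feature scores: redundancy penalizes, it does
not annihilate.

Ties in model selection resolve to the smallest feature count, then the
smallest cost and gamma — reproducibility over an unstated original rule.
Per-fold selected feature counts vary; the report records them all plus
their mode as the headline count. When every inner split of a tiny cohort
loses a class, the fold falls back to the most regularized grid corner
with a warning instead of aborting. Determinism: every stochastic step
(folds, SMOTE, inner splits) derives from the call's seed.

Leakage control is tested operationally: a feature that equals the stage
label only on rows of one held-out patient leaves accuracy at chance,
while a genuinely informative feature drives it above 0.9; permuted labels
give kappa within 0.15 of zero. Agreement is summarized by accuracy and
unweighted Cohen's kappa `(p_o - p_e)/(1 - p_e)` with the standard
qualitative bands (below 0 none, up to 0.2 slight, 0.4 fair, 0.6 moderate,
0.8 substantial, 1.0 almost perfect). The degenerate `p_e = 1` branch is
handled defensively, though a valid confusion matrix can only reach it
with all mass in one diagonal cell (kappa 1).

## Group statistics

`feature_screen()` applies, per interpretable feature (morphology,
echogenicity, histogram, GLCM families by default), the tie-corrected
Kruskal-Wallis test at alpha 0.05, the H-based effect size
`eta^2 = (H - k + 1)/(n - k)` floored at zero (bands: 0.01 small, 0.06
medium, 0.14 large), and Dunn's post hoc z tests with Bonferroni
correction over the three stage pairs. No multiplicity correction is
applied *across* features — each feature is reported as its own test, with
Bonferroni only inside the pairwise family; screen-wide significance
counts should be read accordingly. Implementations are pinned to
`stats::kruskal.test` and a direct evaluation of the mean-rank formula on
random tied datasets, and the chi-squared calibration is verified by
permutation (type-I rate within [0.03, 0.07] at alpha 0.05).

## Numerical and engineering choices

* Images are numeric matrices/arrays on the 8-bit 0-255 scale; masks are
  logical matrices; phantoms are rounded to integers so PNG round-trips
  are exact. Masks serialize as indexed PNG (0 background, 1 entry echo,
  2 SLEB, 3 dermis reference).
* All seeded entry points save and restore the caller's RNG state;
  sub-seeds derive from the master seed by a single `sample.int` draw.
* Problem sizes in the packaged experiments (40-phantom segmentation
  study, 90-lesion staging cohort, 4 preprocessing phantoms, 1000-replicate
  calibration loops) were chosen as the smallest sizes at which the
  respective effects are unambiguous; all are parameters, not constants.
* Degenerate inputs are contracts, not surprises: empty masks yield
  missing features; empty entry-echo predictions raise a flag; a
  single-member class in SMOTE errors with an explicit fallback flag;
  invalid manifests report every offending row at once.

## Known limitations

The phantom generators encode strong, clean stage effects: staging
accuracy near 1.0 on phantoms says nothing about the much weaker clinical
separability (the clinical analogue of the HFUS-handcrafted combination
reports accuracy near 0.48). Intensity-based features are not calibrated
across ultrasound devices. The scattering transform uses periodic
convolution on the mask bounding box, so elongated regions with strong
non-periodic gradients see mild boundary effects. The CNN extractor
bundled for tests is deliberately small; it demonstrates the interface and
phantom-scale learnability, not transfer performance.
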