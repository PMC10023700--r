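---
title: "Ventilation mapping and functional classification for paired-phase micro-CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ventilation mapping and functional classification for paired-phase micro-CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Longitudinal micro-CT of free-breathing mice can be reconstructed into
end-inspiratory and end-expiratory volumes by retrospective gating. Static
density readouts (mean lung density, hyperdense volume) describe structure
but say nothing about function: a dense region may still exchange gas, and
an aerated region may be functionally silent. Subtracting the specific gas
volume of spatially matched voxels across the two breathing phases yields a
voxel-wise surrogate of regional ventilation, and combining it with
absolute gas content separates truly fibrotic tissue from tissue that is
aerated but poorly ventilated. `microvent` implements that chain for the
bleomycin mouse model of pulmonary fibrosis: calibration, deformable
registration, ventilation mapping, percentile-threshold classification,
regional biomarkers, and histology area-fraction morphometry, together with
a synthetic phantom that makes every stage testable without animal data.

## The measurement model

A CT voxel value in Hounsfield Units (standard convention: air = −1000 HU,
water = 0 HU) determines the specific volume of its tissue-plus-gas
mixture:

$$SV_\text{tissue+gas} = \frac{1000}{HU + 1000} \;\text{ml/g}.$$

Subtracting the specific volume of gas-free soft tissue,
$SV_\text{tissue} = 1/1.065 = 0.939$ ml/g, leaves the specific gas volume
$SVg$ — millilitres of gas per gram of tissue in the voxel. The
ventilation surrogate is the phase difference on the inspiratory grid:

$$\Delta SVg = SVg_\text{insp} - SVg_\text{exp,warped}.$$

Scanner grey levels are mapped to HU by the affine transformation fixed by
two anchors (the grey levels of air and water); the anchors are
acquisition-specific inputs, never defaults.

Two numerical guards matter here. First, $1000/(HU+1000)$ is singular at
−1000 HU, so HU values are clamped at a floor (default −990 HU,
configurable) before conversion, and the number of clamped voxels is
reported. Second, negative $\Delta SVg$ values (expiration locally denser
than inspiration, e.g. from noise) are preserved rather than clipped;
clipping would bias regional medians upward.

## Registration

The expiratory volume is registered onto the inspiratory one with
symmetric-forces Thirion Demons and a four-level multiresolution pyramid
(downsampling by two per level after Gaussian anti-aliasing). Because lung
intensity changes globally with inflation, the similarity is driven by
Laplacian-filtered images: the discrete 7-point Laplacian responds to
structural boundaries (vessels, airways, lesion edges, parenchymal
texture) rather than absolute intensity. The filter is applied once at
full resolution before pyramid construction; coarser levels see its
smoothed versions. Each filtered image is normalized to unit standard
deviation so the force balance does not depend on global contrast. The
resulting displacement field lives on the fixed (inspiratory) grid in
micrometres and is applied to the *unfiltered* HU volume with trilinear
interpolation — interpolating in HU avoids interpolating across the
strongly nonlinear SVg scale near −1000 HU. Masks are warped with nearest
neighbour only.

Defaults: iterations (100, 100, 50, 25) coarse to fine, field smoothing
sigma 1.5 voxels after every iteration, Thirion step normalization capping
each per-iteration update at half a voxel. Registration quality is
summarized by the landmark target registration error (TRE): the Euclidean
distance between a fixed landmark mapped through the field and its paired
moving landmark, with the displacement interpolated trilinearly at the
landmark's physical position. Out-of-domain samples during warping take
the moving image's edge value and are counted in the report.

## Classification

Thresholds are percentiles of the pooled in-mask voxel values of
saline-treated control animals — never shipped constants: `alpha_I` and
`alpha_E` are the 5th percentiles of the inspiratory and expiratory SVg
pools and `beta` is the 25th percentile of the ΔSVg pool. All percentiles
use linear interpolation between order statistics (R's type 7), recorded in
the threshold provenance. Each in-mask voxel is then labelled:

* **F** (fibrosis): $SVg_\text{insp} < \alpha_I$ **and**
  $SVg_\text{exp} < \alpha_E$ — low gas content in both phases;
* **LV** (low ventilation): otherwise, $\Delta SVg < \beta$;
* **NV** (normal ventilation): otherwise ($\Delta SVg \ge \beta$; the
  boundary belongs to NV).

Voxels with exactly one SVg value below its alpha threshold do not meet the
F definition; they are assigned by the ΔSVg rule so that the three classes
always partition the lung, and their fraction is logged for QC. By
construction, a healthy cohort classified with its own thresholds shows
roughly 25% of voxels below `beta` and 5% below each alpha — percentile
thresholds measure *relative* abnormality, which is also why they must be
recomputed per study rather than reused.

## Regional biomarkers

Density metrics (median, 75th percentile, IQR of inspiratory HU),
ventilation metrics (the same for ΔSVg) and per-class volume percentages
are computed over the whole lung and over regions of equal vertical size:
upper/lower halves along the cranio-caudal axis, and ventral/intermediate/
dorsal thirds along the dorsoventral axis to match dorsal-plane histology
sectioning. The bounding extent of the mask along the chosen axis is cut
into equal slab counts with any remainder given to the first slabs; the
axis is an explicit argument because "vertical" differs between the two
schemes. The 75th percentile tracks the histogram tail (densification for
HU; the well-ventilated tail for ΔSVg) and the IQR heterogeneity. Density
histograms default to 25-HU bins over [−1000, 500] HU, per-subject
frequency-normalized; group curves are per-bin medians across subjects and
therefore need not sum to one. Structure–function association uses
Spearman rank correlation with midranks, a t-approximation p-value on
n − 2 degrees of freedom, and an exact full-enumeration permutation
p-value for n ≤ 10.

## The phantom: what it emulates and what it does not

The generator builds a chest analytically: two ellipsoidal lungs in a
soft-tissue torso (+40 HU), vessel-like markers (0 HU, radius 2 voxels)
whose centres double as landmark pairs, and — in lesioned modes —
fibrotic (−100 HU in both phases) and low-ventilation (−450/−420 HU)
lesions. The default grid is 128³ at 50 µm isotropic. Ventilated
parenchyma defaults to −550 HU at inspiration and −400 HU at expiration,
i.e. a tidal gas turnover of 0.15 ml gas per ml lung and a ΔSVg of
1000/450 − 1000/600 ≈ 0.556 ml/g, compatible with healthy-control values
above 0.4 ml/g.

The expiratory phase is produced by evaluating the same analytic anatomy
through the exact inverse of a smooth deformation: a cranio-caudal
raised-cosine compression (zero at the apex, maximal at the diaphragm,
default peak 6 voxels) plus a small lateral expansion. Because the anatomy
is analytic, the inverse is exact and the ground-truth field, landmark
pairs and class map are free of discretization error. Parenchymal
heterogeneity is modelled as a spatially correlated density texture
(Gaussian field, default 18 HU shared between phases — the same tissue
seen twice — plus 8 HU per phase, correlation scale 2.5 voxels);
acquisition noise is optional additive Gaussian HU noise. Raw volumes are
an affine re-encoding of HU through a known calibration so the calibration
stage is exercised end to end.

**Compensatory redistribution.** In lesion-bearing phantoms the spared
parenchyma inflates more at inspiration: the tidal gas volume is conserved
at the animal level, so the share of non-ventilating lesion volume
(weighting low-ventilation lesions at 80% of a fibrotic lesion's deficit)
is redistributed to the spared compartment. With the default 10% F + 15%
LV load this deepens spared-parenchyma inspiratory HU to about −594 HU and
raises its ΔSVg to about 0.78 ml/g. This choice is physiological —
regional compensation is a recognized feature of the bleomycin model — and
it is also what makes phantom-truth recovery a meaningful test: if the
spared compartment's ΔSVg distribution were *identical* to the healthy
cohort's, the 25th-percentile threshold would, by definition, mislabel a
quarter of it, and no pipeline could recover the compartment map. The
`fibrotic` preset instead models severe late-timepoint disease as a
confluent dorsal consolidation (about 40% F with a 20% peri-lesional LV
band), the configuration used for direction checks of the density and
ventilation biomarkers.

What the phantom does **not** emulate: projection-domain physics (gating
artifacts, beam hardening, streaks), cardiac motion, airway trees,
sliding-lung discontinuities at the pleura, and real biological
variability in lesion morphology. Passing the phantom suite therefore
demonstrates the correctness and internal consistency of the algorithms —
not scanner-grade robustness on real animals.

## Noise control

Quantitative maps are optionally denoised with a Gaussian filter before
SVg conversion. Plain smoothing would mix the dense chest wall into the
parenchymal rim and corrupt thresholds, so the quantitative path uses
mask-normalized smoothing (normalized convolution): each in-lung voxel
averages only in-lung neighbours. Registration, which benefits from
whole-field structure, sees the plainly smoothed volumes. The default is
no smoothing; analyses of data with appreciable noise (e.g. the 20-HU
phantom setting) use sigma = 1 voxel, matched to the point-spread scale.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles
(hand-computed stencils, closed-form resampling of ramps, brute-force
percentile and rank computations, exact landmark geometry) on small grids
(40–48³), and the full chain at study scale (128³): threshold
self-consistency on a three-phantom control cohort, landmark TRE of the
four-level registration at or below the 50 µm voxel size, per-class Dice
against phantom truth of at least 0.90 noise-free and 0.80 at 20 HU noise,
and the expected biomarker directions between fibrotic and healthy
phantoms. Control-cohort thresholds in these study-scale checks are
computed through the phantom's analytic reference deformation: threshold
construction is a percentile property of the voxel pools, and registration
accuracy is validated separately by the TRE criterion. Sampling designs
(three control subjects, one evaluated subject per condition) keep the
full suite practical on a single CPU.

## Design choices that were genuinely open

* **HU convention.** Micro-CT workflows occasionally state the
  calibration with the opposite assignment (water = 1000, air = 0), which
  is inconsistent with the SVg formula: only the standard convention
  (water = 0, air = −1000) gives water a specific volume of 1 ml/g. The
  package defaults to the standard convention; the calibration object can
  express any other affine assignment.
* **Laplacian once vs per level.** The structure filter is applied once at
  full resolution; pyramid smoothing then provides the coarse-scale
  versions. Re-filtering each level would re-amplify the highest surviving
  frequency per level and couple the similarity metric to the pyramid
  depth.
* **Warp-then-convert.** The field is applied to HU volumes and SVg is
  computed afterwards, avoiding interpolation across the hyperbolic SVg
  scale.
* **Threshold cohort pooling.** Voxels are pooled across control animals
  without per-animal weighting, so larger lungs contribute more voxels;
  per-animal percentile medians remain available as a sensitivity mode via
  per-subject pools.
* **Histology colour rules.** Stain-threshold settings are inherently
  protocol-specific; the defaults (green hue band
  80–160° with minimum saturation/value; white = all channels ≥ 0.85)
  are explicit, configurable, and documented as requiring calibration to
  the staining protocol.

## Known limitations

Registration offers no diffeomorphic guarantee; field invertibility is
only verified on the phantom, where the truth is invertible by
construction. The Demons variant assumes roughly matched structural
contrast after Laplacian normalization; strong phase-dependent contrast
changes beyond a global scale are not modelled. The phantom's lesions are
spheres or smooth caps, which underestimates the boundary complexity of
real fibrotic consolidation, and its deformation family is separable and
smooth — it cannot represent sliding at the pleural interface. Percentile
thresholds inherit cohort composition: a control pool that itself contains
pathology shifts all three thresholds.
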