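# microvent

Ventilation mapping and functional tissue classification for paired
inspiratory/expiratory micro-CT of the mouse lung.

Longitudinal micro-CT of free-breathing mice, retrospectively gated into
end-inspiratory and end-expiratory reconstructions, carries functional
information that single-phase density readouts miss. `microvent` turns such
paired volumes into voxel-wise ventilation maps and a three-class
functional segmentation, for researchers quantifying fibrosis progression
and antifibrotic response (e.g. in the bleomycin model) without terminal
lung-function measurements.

The core quantities, per voxel:

- specific volume of tissue + gas, `SV = 1000 / (HU + 1000)` ml/g
  (standard HU convention, water = 0, air = −1000);
- specific gas volume, `SVg = SV − SV_tissue` with
  `SV_tissue = 1/1.065 = 0.939` ml/g;
- ventilation, `ΔSVg = SVg_insp − SVg_exp` after deformable registration of
  the expiratory onto the inspiratory volume (symmetric-forces Demons,
  four-level multiresolution, similarity driven by Laplacian-filtered
  images so structure dominates over inflation-dependent intensity).

Each lung voxel is classified against percentile thresholds derived from a
healthy control cohort — `α_I`, `α_E` (5th percentiles of inspiratory and
expiratory SVg) and `β` (25th percentile of ΔSVg):

- **fibrosis (F)**: `SVg_insp < α_I` and `SVg_exp < α_E`;
- **low ventilation (LV)**: otherwise `ΔSVg < β`;
- **normal ventilation (NV)**: otherwise (`ΔSVg ≥ β`).

Regional biomarkers (median, 75th percentile and IQR of inspiratory HU and
of ΔSVg; class volume percentages) are reported for the whole lung, for
upper/lower halves and for ventral/intermediate/dorsal thirds, plus
histology collagen and alveolar-air area fractions and Spearman
structure–function correlation.

A synthetic paired-phase phantom — ellipsoidal lungs in a soft-tissue
torso, vessel-like landmarks, fibrotic and low-ventilation lesions, an
analytically invertible breathing deformation, and a known grey-level
calibration — makes every stage verifiable; see the methods vignette
(`vignettes/microvent-methods.Rmd`) for the model, parameter choices and
limitations.

## Worked example

Derive control thresholds from three healthy phantoms, then run the full
chain — calibration, Demons registration, ventilation mapping,
classification — on a lesioned subject (64³ grids keep this a couple of
minutes on one CPU; the validation suite uses 128³):

```r
library(microvent)

# healthy control cohort
cohort <- lapply(1:3, function(i) {
  ph <- generate_phantom(phantom_spec("saline", shape = c(64, 64, 64), seed = i))
  analyze_pair_with_field(ph$insp_raw, ph$exp_raw, ph$mask_insp, ph$truth$field,
                          mask_exp = ph$mask_exp, calibration = ph$calibration)
})
th <- derive_thresholds(pool_values(cohort, "svg_insp"),
                        pool_values(cohort, "svg_exp"),
                        pool_values(cohort, "dsvg"))
th
#> <functional_thresholds> alpha_I = 1.1410, alpha_E = 0.5902, beta = 0.5234 ml/g (p5/p25, cohort saline)

# diseased subject, full chain from raw grey levels
ph <- generate_phantom(phantom_spec("lesioned", shape = c(64, 64, 64), seed = 7))
res <- analyze_pair(ph$insp_raw, ph$exp_raw, ph$mask_insp, ph$mask_exp,
                    calibration = ph$calibration, landmarks = ph$truth$landmarks)
sprintf("TRE: %.0f um before, %.0f um after registration",
        res$report$tre_before$mean, res$report$tre_after$mean)
#> "TRE: 154 um before, 8 um after registration"

fmap <- classify_voxels(res$svg_insp, res$svg_exp, res$dsvg, th, res$domain)
round(class_percentages(fmap), 1)
#>  pctF pctLV pctNV
#>  10.1  15.8  74.2
round(evaluate_recovery(ph$truth, fmap)$dice, 3)
#>     F    LV    NV
#> 0.989 0.993 1.000
```

The thresholds sit where percentile construction puts them (`β` just below
the healthy ΔSVg mode of ≈ 0.56 ml/g); registration reduces the mean
landmark error from 154 µm to 8 µm (well under the 50 µm voxel); the
recovered class percentages match the phantom's 10% fibrosis / 15%
low-ventilation design, with per-class Dice ≥ 0.99 against ground truth.

File-based studies are driven by a YAML manifest through `run_pipeline()`
or the thin CLI (`inst/cli/microvent.R`) with subcommands `phantom`,
`calibrate`, `register`, `ventilate`, `thresholds`, `classify`, `run-all`
and `validate`.

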