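# mtvseg

Fully automated delineation and classification of metabolically active
lesions — primary tumor and lymph-node (LN) metastases — in paired
FDG-PET/CT volumes of head-and-neck cancer, in R.

PET-derived metabolic tumor volume (MTV) and the total tumor burden (TTB,
the union of primary and nodal volumes) are prognostic of overall survival,
but manual lesion delineation is slow and observer-dependent, and
threshold-based tools fail at the low lesion-to-background contrast typical
of nodal disease. `mtvseg` implements the complete pipeline for a CNN-based
alternative and everything needed to evaluate one:

* **Preprocessing** — resampling to a 2.5 mm isotropic grid, central
  transaxial cropping, axial cropping, CT windowing to [−150, 150] HU,
  per-volume min–max normalization, one-hot targets, and overlapping
  128×128×32 patch extraction with ≥ 75% axial overlap.
* **Network** — a residual 3D U-Net with a multi-head self-attention
  bottleneck (flattened bottleneck voxels as tokens, learned positional
  embedding), trained with a Dice + cross-entropy loss by Adadelta under
  5-fold patient-level cross-validation (64/16/20 train/validation/test)
  with early stopping on the validation soft DSC. Forward and backward
  passes are implemented in the package (compiled im2col + GEMM
  convolutions; gradients verified against finite differences).
* **Inference** — sliding-window prediction fused with 3D Gaussian weights
  whose FWHM equals the patch side length, optional model ensembling,
  argmax class assignment (ties to background), and exclusion of regions
  under 0.1 ml.
* **Evaluation** — cohort and per-patient Dice (DSC = 2|A∩B|/(|A|+|B|)),
  voxel-level classification rates
  (TPR_PT = T_PT/(T_PT+F_LN), TPR_LN = T_LN/(T_LN+F_PT), ACC), lesion-level
  detection by 50% coverage matching (TPR_str, PPV_str), and TTB agreement
  (OLS with top-1% outlier rejection, R², 95% prediction band).
* **Survival** — median-TTB risk stratification, a from-scratch univariate
  Cox proportional-hazards fit (Newton–Raphson on the partial likelihood,
  Breslow or Efron ties) and Kaplan–Meier curves.
* **Phantoms** — a synthetic PET/CT generator emulating the clinical lesion
  regime (log-normal lesion volumes matched to published mean/median values,
  SUV 3–22 over a 1–2 background, physiological confounder hot spots,
  necrotic cores), so the whole pipeline is testable without patient data.

## Worked example

Generate a small phantom cohort, train a tiny model, and evaluate it:

```r
library(mtvseg)

geom  <- grid_geometry(c(64, 64, 16), rep(2.5, 3))
specs <- sample_cohort(25, seed = 101, geometry = geom, noise_sd = 0.05,
                       suv_range = c(10, 22), max_ln = 2)
prep <- lapply(specs, function(sp) {
  ph <- generate_phantom(sp)
  c(window_and_normalize(ph$pet, ph$ct), list(labels = ph$labels))
})
samples <- function(p) {
  extract_patches(list(pet = p$pet$values, ct = p$ct$values,
                       target = one_hot_encode(p$labels)),
                  patch_shape = c(64, 64, 16))
}

cfg <- network_config(levels = 3, base_channels = 4, attention_heads = 8,
                      patch_shape = c(64, 64, 16), seed = 7)
fit <- train_fold(build_model(cfg),
                  unlist(lapply(prep[1:16], samples), recursive = FALSE),
                  unlist(lapply(prep[17:20], samples), recursive = FALSE),
                  max_epochs = 15, patience = 30, batch_size = 1, seed = 11)

refs  <- lapply(prep[21:25], `[[`, "labels")
preds <- lapply(prep[21:25],
                function(p) predict_volume(fit$model, p$pet, p$ct)$labels)
dsc_report(refs, preds)
```

On one CPU this trains in about 8 minutes and prints:

```
Target      cohort   mean  median  50% CI          failed
primary      0.843  0.766   0.896  [0.763, 0.961]  0
ln           0.330  0.337   0.337  [0.169, 0.506]  1
union        0.891  0.892   0.901  [0.869, 0.961]  0
```

Reading: pooled over the five held-out phantoms, the delineation of all
malignant tissue (union row) overlaps the ground truth with a Dice
coefficient of 0.89, and no phantom's delineation failed outright;
separating the classes, primaries are delineated well while LN metastases —
small, low-contrast, and easily confused with confounder uptake at this
tiny training scale — remain the hard part, mirroring where the difficulty
lies at clinical scale. Lesion-level detection and burden agreement follow
the same pattern:

```r
structure_match(refs, preds, target = "primary")$tpr_str  # 1.0: all primaries found
ttb(filter_small_rois(preds[[1]]))                        # burden of one phantom, ml
```

A thin command-line interface over the same functions is installed at
`inst/cli/mtvseg.R` (subcommands `simulate`, `train`, `predict`, `evaluate`,
`survive`, `describe-model`).

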