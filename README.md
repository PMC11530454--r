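# stainshift

Mitotic figures (MFs) are counted in hematoxylin & eosin (H&E) stained tumor
sections as a proliferation marker, but their identification from morphology
alone shows poor inter-rater agreement. Overlaying a co-registered slide
stained against phospho-histone H3 (PHH3) — an immunohistochemical marker
specific to mitotic nuclei — makes annotators far more consistent, which has
made *PHH3-assisted annotation* popular for building MF detection datasets.
The assistance has a hidden cost: PHH3 highlights early-prophase cells that
carry **no recognizable mitotic morphology in the H&E image** (while some
H&E-obvious telophases are weakly labeled), and seeing the marker biases
raters toward calling such cells identifiable anyway. Labels produced this
way embed an *information mismatch*: for any detector that only sees H&E
pixels they act as asymmetric label noise, depressing measured recall in
evaluation and shifting the decision boundary in training — an
*interpretation shift*. A dual-stain detector that receives both images is
immune and can exploit the cleaner labels.

`stainshift` makes this whole study design reproducible at desk scale on
purely synthetic data, for methodologists studying annotation protocols and
label noise in computational pathology. It provides:

* a **synthetic study generator**: co-registered H&E/PHH3 image pairs with
  known cell-level ground truth (five mitotic phases, lookalikes, a
  controllable mismatch fraction, residual registration deformation) and a
  simulated 13-expert, two-phase annotation study with per-rater
  sensitivity, false-positive, jitter and hindsight-bias parameters;
* **consensus building**: greedy distance clustering of point annotations
  within a 7.5 µm radius (one nucleus diameter), support thresholds
  (≥ 6 of 13 experts), leave-one-out consensus, derived H&E-only /
  PHH3-assisted / post-hoc-cleaned label sets;
* **agreement statistics**: per-rater precision/recall/F1 against the
  leave-one-out consensus, the intraclass correlation of mitotic counts in
  its average-of-k fixed-panel form `ICC(3,k) = (MS_T − MS_E)/MS_T`
  (equivalently the Spearman–Brown adjusted single-rater reliability),
  Fleiss' κ for categorical panel verdicts, and paired t-tests with
  Shapiro–Wilk checks and Bonferroni correction;
* **detectors**: a compact anchor-free one-stage detector (three-level
  feature pyramid, per-location class/centerness/box-regression heads) and
  its dual-input variant with per-level mid-fusion
  `F = ReLU(Conv₁ₓ₁(LayerNorm(Cat(H, P))))`, trained with AdamW, ≥ 50 %
  MF-containing patches, a four-operation augmentation pipeline and early
  stopping on validation AP — implemented from scratch in R/C++ with
  hand-derived backpropagation;
* **evaluation**: tiled whole-image inference (512 px tiles, 50 px overlap,
  global non-maximum suppression), distance-matched average precision, and
  the cross-validated train-label × eval-label experiment grid;
* **latent analysis**: a mapping-network embedding of the consensus cells
  with test-time augmentation, a single UMAP projection, majority-vote
  detected/missed flags per labeling condition, and 75 % highest-density
  regions whose centroid shift quantifies the decision-boundary movement
  per mitotic phase group.

## Worked example

```r
library(stainshift)

cfg   <- study_config(rng_seed = 1)      # 13 raters, 20 ROIs, mismatch 0.56
study <- generate_study(cfg)
study
#> <study_dataset> 20 images, 13 raters, 2472 cells, 15647 annotations

glance(rater_agreement(study))
#> # A tibble: 2 × 7
#>   study_phase precision_mean precision_sd recall_mean recall_sd f1_mean  f1_sd
#>   <chr>                <dbl>        <dbl>       <dbl>     <dbl>   <dbl>  <dbl>
#> 1 P1                   0.518       0.0712       0.774    0.126    0.614 0.0637
#> 2 P2                   0.847       0.0352       0.850    0.0402   0.848 0.0265

icc_avg_fixed_raters(mitotic_count_matrix(study, "P1"))
#> ICC(3,13) = 0.8700  [single-rater ICC(3,1) = 0.3399; n = 20 targets]
icc_avg_fixed_raters(mitotic_count_matrix(study, "P2"))
#> ICC(3,13) = 0.9342  [single-rater ICC(3,1) = 0.5218; n = 20 targets]

label_sets <- derive_label_sets(study)
cat(sprintf("consensus MFs: %d (H&E-only) -> %d (PHH3-assisted)\n",
            nrow(label_sets$he_only_labels),
            nrow(label_sets$phh3_assisted_labels)))
#> consensus MFs: 358 (H&E-only) -> 646 (PHH3-assisted)

ag <- rater_agreement(study)
paired_metric_test(ag$f1[ag$study_phase == "P1"],
                   ag$f1[ag$study_phase == "P2"], n_tests = 3)
#> paired t-test: t(12) = -19.037, p = 2.48e-10 (Shapiro-Wilk p = 0.972, alpha* = 0.0167) *
```

Reading the numbers: PHH3 assistance lifts every rater's object-level
agreement with the panel consensus (mean F1 0.61 → 0.85, driven mostly by
precision 0.52 → 0.85, and highly significant at the Bonferroni-corrected
level), raises the count reliability (ICC 0.87 → 0.93), and nearly doubles
the consensus set — the newly found points mix marker-positive cells
without any H&E morphology with borderline-faint figures, which is exactly
the label noise the detection experiments then quantify. A detection
experiment and the latent-space analysis run the same way from these
objects via `run_experiment_grid()` and `run_latent_analysis()`; see the
vignette in `vignettes/interpretation-shift.Rmd` for the model details.

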