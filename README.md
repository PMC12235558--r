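# cordparc

Data-driven parcellation of cervical spinal cord resting-state fMRI into
**functional levels** — the neuron-pool compartments that give rise to one
pair of nerve roots each — together with the evaluation framework needed to
trust such a parcellation.

The package is aimed at spinal cord fMRI researchers who want to (a) extract
rostro-caudally organized resting-state networks from cord BOLD runs, (b)
quantify how well those networks align with anatomically defined segmental
levels, and (c) measure how robust, replicable and temporally stable the
parcellation is — at the group and single-participant scales. Because public
cord data are scarce, the package also ships a synthetic cohort generator
with full ground truth, so every part of the machinery can be validated end
to end.

## What it computes

Two extraction streams operate on denoised runs:

**Hierarchical group ICA.** Per-subject spatial PCA (20 components) →
generalized canonical correlation analysis across subjects (SVD of the
stacked orthonormal bases; directions shared by the group have singular
value near √n) → fixed-point spatial ICA (log-cosh contrast) on the group
subspace. At the participant scope only the ICA step applies.

**iCAPs (innovation-driven co-activation patterns).** Per voxel, Total
Activation deconvolution solves

```
min_s  ½ ‖y − A s‖² + λ ‖s‖₁ ,    A = H C,
```

where `C` integrates the innovation signal `s` into an activity-inducing
signal and `H` convolves with the canonical HRF; the ℓ1 penalty on `s` is
the generalized total-variation penalty matched to the HRF. Innovations
that exceed per-voxel two-sided thresholds from phase-randomized surrogates
(α = 0.05) mark *significant frames*; frames with > 5 % active voxels are
k-means clustered (cosine distance, sign folding) into K co-activation
patterns.

Denoising (before either stream) removes, by a single orthogonal projection
applied jointly with a 0.01 Hz cosine high-pass: 5 CSF CompCor components,
18 RETROICOR regressors (3 cardiac + 4 respiratory harmonics + 1
interaction order), 5 DCT detrending functions, motion parameters and
DVARS-flagged outlier volumes.

Evaluation: Z > 1.6 thresholding and binarization, Dice and cosine
similarity, maximum-weight bipartite matching of components to segmental
levels (and across methods), per-level percent overlap, bootstrap
model-order stability (median [IQR] Dice across participant subsets for
K ± 2), split-run temporal stability, center-of-mass statistics,
individual-level heatmaps, and Benjamini–Hochberg FDR adjustment.

## Worked example

```r
library(cordparc)

geo <- make_geometry(n_levels = 5, level_height_vox = 6, radius_vox = 3)
sim <- simulate_cohort(n_subjects = 10, geometry = geo, t = 200,
                       tr = 2.5, seed = 11)
cfg <- pipeline_config(K = 5, seed = 11)
rep <- run_pipeline(cfg, sim$runs, geo$cord, geo$csf, geo$atlas,
                    sim$confounds)
rep
#> <parcellation_report> K=5, 10 subjects
#>   cross-method mean matched Dice: 0.999
#>   ica: mean atlas Dice 0.844, mean matched overlap 100.0%
#>   icap: mean atlas Dice 0.843, mean matched overlap 100.0%
```

Reading: both streams recover the five planted levels — the mean Dice
between each (binarized, Z > 1.6) component and its maximum-weight-matched
atlas level is ≈ 0.84, every retained component voxel falls inside the
matched segmental level, and the two methods agree with each other almost
exactly (cross-method matched Dice 0.999). Model-order stability then
confirms the planted K:

```r
coh <- rep$cohort
bs <- bootstrap_stability(coh, "icap", K_target = 5, n_subsets = 20,
                          subset_size = 10, seed = 42)
bs$summary[, c("K", "median", "iqr")]
#>   K    median        iqr
#> 1 3 0.6207192 0.68259888
#> 2 4 0.9710216 0.45168685
#> 3 5 0.9956710 0.03150382
#> 4 6 0.9806795 0.11739888
#> 5 7 0.9426052 0.20143492
```

The subset-vs-full-cohort Dice distribution is highest and much tightest at
the true K = 5 (median 0.996, IQR 0.03; neighbouring orders have IQRs an
order of magnitude wider). Numbers are from the seed shown; a different
seed shifts them by a few hundredths.

A command-line front end for the same steps is installed with the package
(`inst/cli/cordparc`): `cordparc simulate|denoise|ica|icap|evaluate|run`,
with `--config` (YAML overrides of the defaults), `--seed`, `--out-dir`.

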