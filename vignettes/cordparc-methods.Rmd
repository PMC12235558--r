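---
title: "Methods: data-driven parcellation of spinal cord fMRI into functional levels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: data-driven parcellation of spinal cord fMRI into functional levels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

The cervical spinal cord is organized in rostro-caudally stacked *segmental
levels*: pools of motor and sensory neurons that give rise to one pair of
nerve roots each. Resting-state fMRI of the cord shows spatially organized
spontaneous fluctuations, and the working hypothesis of this package is
that data-driven network extraction can recover one *functional level* per
segmental level. `cordparc` implements two extraction streams plus the
evaluation framework needed to ask whether the recovered networks are
anatomically aligned, robust across methods, stable over time, and
detectable in single participants.

Everything runs on three inputs sharing one voxel grid: a 4D BOLD run per
participant, binary cord and CSF masks, and an integer-labeled segmental
atlas whose labels are rostro-caudally ordered. All spatial maps are dense
arrays that are defined (and Z-scored) only over in-mask voxels; voxels
outside the mask are exact zeros. Voxel indices are 0-based in all
coordinate computations and the rostro-caudal axis is the array's +z axis
unless the atlas says otherwise.

# Denoising model

Spinal cord fMRI is dominated by structured physiological noise, so the
cleaning stage removes a rich nuisance design by a single orthogonal
projection:

* **CompCor** — the first 5 principal component time courses of the CSF
  voxel-by-time matrix (per-voxel mean removed; a config switch adds
  variance normalization, off by default because plain mean removal keeps
  the components interpretable as raw CSF fluctuation modes).
* **RETROICOR** — a Fourier expansion of the cardiac and respiratory phase
  traces: 3 cardiac and 4 respiratory harmonics (cosine and sine each)
  plus one multiplicative interaction order contributing the four
  sum/difference products, 18 columns in total. The sum/difference
  convention is the standard extension for the interaction term and is the
  one that reproduces the 18-column count.
* **Detrending** — the first 5 non-constant type-II DCT basis vectors.
* **Motion** — any `motion_*` columns supplied in the confound table (two
  are typical for cord acquisitions: in-plane x and y).
* **Outliers** — one indicator column per DVARS-flagged volume. DVARS is
  the in-mask RMS intensity difference of consecutive volumes; the flag
  rule is the box-plot fence (75th percentile + 1.5 IQR of the DVARS
  series), and both members of an offending volume pair are flagged. The
  fence is recorded in the output so the rule is auditable.

The high-pass filter (0.01 Hz) is implemented as a cosine *stop band* —
the constant plus every DCT vector with frequency below the edge — and the
nuisance columns are first projected onto the orthogonal complement of
that band, after which data are residualized against the augmented
stop-band + orthogonalized-nuisance design in one projection. Doing the
filter and the regression jointly (rather than serially) means removing
nuisance can never reintroduce the low frequencies the filter already
removed, and it makes the result invariant to the order in which nuisance
families are listed. Collinear columns (e.g. the detrending DCTs, which
live inside the stop band) are dropped with a warning.

A consequence worth stating plainly: a joint projection removes an
r-dimensional subspace from a t-dimensional time series, so a fraction of
*signal* energy is lost along with the noise — roughly r/t for signal
uncorrelated with the design. Cleaning improves recovery of the underlying
block signal whenever the structured confounds cost more correlation than
that subspace loss, which is the regime spinal data (and the default
generator, below) live in.

# The ICA stream

The group decomposition is hierarchical:

1. **Subject PCA** — each participant's cleaned voxel-by-time matrix is
   reduced to its top 20 spatial principal components, so every subject
   contributes an equal-dimensional, orthonormal basis.
2. **Group subspace** — the subject bases are stacked column-wise and the
   left singular vectors of the stack are retained (a MAXVAR-style
   generalized canonical correlation analysis). A direction present in
   every subject's basis has singular value near sqrt(n_subjects); the
   basis is ordered by this cross-subject consistency. The construction is
   closed-form and deterministic and reduces to ordinary CCA for two
   subjects. It requires at least two subjects — single-participant
   analyses use the subject scope instead.
3. **Spatial ICA** — fixed-point ICA with the log-cosh contrast rotates
   the first K group directions into spatially independent maps (500
   iteration cap, symmetric decorrelation, 10 seeded restarts). The
   fixed-point iteration has spurious local optima at which it converges
   cleanly, so restarts are compared by the contrast objective itself —
   the converged run with the highest total log-cosh negentropy is kept,
   not merely the one with the smallest convergence residual. The
   algorithm and contrast are package choices; only the iteration budget
   is inherited from the reference configuration.

At the participant scope only step 3 applies, on the subject's own
PCA-whitened data. Component sign is fixed by positive skewness (maps are
read by their positive tail after thresholding), each map is Z-scored over
the mask, and components are ordered by rostro-caudal center of mass for
readability — no evaluation step depends on that order.

# The iCAP stream

The innovation-driven co-activation pattern stream models each voxel's
cleaned series y as the HRF-convolution of a piecewise-constant
activity-inducing signal u, and works on the *innovations* s = diff(u),
which are nonzero only at activity transitions.

**Total Activation.** Writing A = H C, where C is the discrete integrator
(cumulative sum, mapping s to u) and H the Toeplitz convolution with the
HRF kernel sampled at TR, the deconvolution solves, per voxel,

    min_s  0.5 * || y - A s ||^2  +  lambda * || s ||_1 .

This is the innovation-domain parameterization of the generalized
total-variation problem: the l1 penalty on s is exactly the penalty on the
differential operator that annihilates HRF responses to piecewise-constant
drive. The kernel is the canonical two-gamma HRF (peak near 6 s,
undershoot near 16 s, ratio 1/6, unit peak); its leading zero samples are
dropped when building H since they would make the convolution matrix
singular while carrying no information. The simulator and the solver share
this kernel by default, and both accept a custom kernel for mismatch
experiments.

The solver is cyclic coordinate descent on the Gram matrix G = A'A (shared
by all voxels of a run), with an active-set refinement: each outer sweep
visits all coordinates, then inner sweeps iterate the nonzero set until
progress stalls. Convergence is certified by the lasso duality gap,
computed from Gram quantities only, with stopping rule gap <= 1e-3
relative to the primal objective (config `ta_tol`) and a cap of 2000
outer sweeps; non-converged voxels are flagged and the best iterate kept.
Coordinate descent was chosen over proximal-gradient methods because, at
cord-sized problems (t of a few hundred), the explicit Gram matrix makes
each sweep cheap and the active-set structure of innovation signals (tens
of transitions per run) makes convergence fast; the optimality
certificate is identical. The default gap of 1e-3 is deliberate: on
cord-sized problems the estimated activity is numerically indistinguishable
from the 1e-5 solution (recovery correlations agree to three decimals)
at an order of magnitude less compute, and the certificate still bounds
suboptimality explicitly. Tighter gaps are a config change away and are
exercised in the solver-verification tests.

**lambda strategy.** Per voxel, lambda is rescaled iteratively (4 rounds,
warm-started, descending from a sparse solution) so the residual energy
matches t times a robust noise variance estimate — the squared MAD of the
finest-scale Haar detail coefficients of y. This follows the convention of
the deconvolution literature the stream builds on; nothing in the
reference configuration pins lambda, so the strategy is recorded here as
a package choice, with a fixed-lambda override in the API.

**Thresholding and clustering.** Significance of innovations is assessed
against surrogates: each voxel's series is phase-randomized (amplitude
spectrum preserved exactly) and deconvolved with the full Total Activation
procedure — including the noise-matched lambda strategy, so the null model
receives the same adaptive treatment as the data — at a relaxed duality
gap (surrogates feed quantile estimates only), and the
pooled surrogate innovations give per-voxel two-sided thresholds at
alpha = 0.05 (2.5% per tail — innovations are signed, so the "5%
confidence interval" is read two-sided). Eight surrogates per run are the
default, giving about 1600 samples per voxel for the tail quantiles;
thresholds are per voxel by default because noise is heterogeneous
across the cord, with a pooled option in the config. Frames whose
active-voxel fraction exceeds 5% are retained with their signed active
values, then clustered by k-means with cosine distance and sign folding: a
frame and its negation belong to the same cluster, because a level's
activation onset and offset are transitions of one network. Sign folding
assigns each frame the sign of its correlation with its nearest centroid;
cosine distance is used because frame amplitude scales with event size
while orientation carries the pattern (Euclidean is available as a config
switch). The best of 5 seeded restarts by within-cluster dispersion is
kept. Cluster map k is the voxelwise mean of its folded member frames,
Z-scored over the mask.

# Evaluation framework

* **Thresholding** — Z-scored maps are binarized at Z > 1.6 (about the
  upper 5% of a Gaussian map); 2 and 2.3 are accepted alternatives.
* **Dice** — 2|A∩B| / (|A|+|B|). Two empty maps have undefined Dice; the
  value is reported as missing and *excluded* from summaries rather than
  scored 0, because an empty thresholded map signals extraction failure
  and is recorded separately.
* **Matching** — components are paired with atlas levels (or with each
  other) by maximum-weight bipartite matching on the Dice (or overlap)
  matrix; with unequal set sizes, min(nA, nB) pairs are returned. Weights
  are shifted to be strictly positive before matching, which forces
  maximal cardinality without changing the optimal assignment.
* **Level overlap** — the percentage of a binarized component's voxels in
  each atlas level plus an outside bin, summing to 100.
* **Model-order stability** — for each K in K_target ± 2, components are
  extracted on the full cohort and on bootstrap subsets of participants
  (100 subsets of 10 by default; drawn with replacement), binarized,
  matched to the full-cohort maps *at the same K* by maximum-weight
  matching on Dice (the pairing rule is a package decision; the reference
  protocol leaves it open), and the matched Dice values pooled per K.
  Summaries report median and IQR, plus mean and SD.
* **Temporal stability** — runs are split into contiguous equal parts
  (the final split absorbs any remainder, since published split lengths
  are approximate); each split is re-analyzed from scratch — including
  deconvolution and fresh surrogate thresholds for iCAP — and compared to
  full-run components by matched Dice.
* **Individual maps** — per-subject component sets are binarized, sorted
  by the rostro-caudal center of mass of their largest 26-connected
  cluster, and summed slot-wise across subjects into heatmap volumes.
  Centers of mass use 0-based slice indices times the z voxel size, in mm.
* **Inference** — group comparisons in this package reduce to paired
  two-sided comparisons with Benjamini–Hochberg FDR adjustment. The
  reference analyses' linear mixed models, Wald tests and effect sizes are
  routine statistics outside this package's scope.

# The synthetic cohort

Because the real acquisitions are gated or private, validation runs on a
generator with full ground truth. It emulates:

* a cylindrical cord of K stacked level compartments inside a disjoint
  CSF sheath (default 5 levels, 6 slices each, radius 3 voxels on an
  11 x 11 x 30 grid with 1 x 1 x 3 mm voxels);
* per-level transient activity: binary block trains (default 8 blocks per
  level per run, 4–8 volumes long, amplitude 1, separated by at least 2
  volumes) convolved with the canonical HRF — the transient structure the
  iCAP stream presumes;
* per-subject level boundaries jittered by rounded Gaussian shifts
  (SD 1 slice), emulating inter-participant variability in level
  positions;
* a shared rank-2 CSF noise process (amplitude 1), 10% of which leaks
  into the cord — what CompCor is for;
* cardiac (~1 Hz) and respiratory (~0.25 Hz) oscillations with slow phase
  wander, written into both tissues with random voxel weights and
  amplitude 1 — what RETROICOR is for; the generating phases are exported
  as the confound table;
* a slow cosine drift below 0.01 Hz (amplitude 1) and 2 motion-spike
  volumes per run (global intensity jump of 3) — what detrending, the
  high-pass and DVARS scrubbing are for;
* Gaussian thermal noise (SD 0.5).

With unit block amplitude, these defaults put the generator in the
physiological-noise-dominated regime that characterizes cervical cord
fMRI — structured confounds carry more energy than thermal noise, which
is precisely why the denoising stack exists. Default runs are 200 volumes
at TR 2.5 s for 10 participants; that grid (~870 cord voxels) keeps a full
two-method analysis with bootstrap and split protocols in the minutes
range on one CPU, and the problem sizes are stated alongside every result
the package reports.

What the generator does *not* emulate: MR physics (field inhomogeneity,
slice leakage), actual head/cord motion beyond spike volumes, and any
lateral (ventral/dorsal) substructure within a level — the reference
coverage gives no quantitative basis for simulating sub-level structure,
so passing tests say nothing about resolving dorsal versus ventral horns.
Synthetic results validate the machinery (recovery of planted structure
under realistic noise), not the biological findings themselves.

# Numerical choices and degenerate inputs

* Collinear design columns are dropped with a logged warning; the
  projection uses the QR rank.
* Zero-variance maps cannot be Z-scored or thresholded and raise errors;
  empty thresholded maps make Dice undefined (excluded, warned) and
  level-overlap an error.
* k-means ties in assignment break toward the lower cluster index; empty
  clusters are re-seeded at the worst-fit frame.
* The bootstrap draws, ICA restarts, k-means restarts and surrogate phase
  draws are all derived from the configured seed; a fixed seed reproduces
  every reported table bit-for-bit.
* Splits that do not divide the run length place the remainder in the
  final split.
* A cohort of one participant cannot enter the group subspace stage; the
  pipeline raises a stage-labeled error directing to subject scope.

# Known limitations

* The Total Activation implementation is purely temporal; the spatial
  regularization present in some deconvolution variants is out of scope.
* iCAP time courses are not back-projected and transient-duration
  statistics are not computed.
* Group analyses require a shared voxel grid; template registration is
  assumed done upstream.
* Model order K is chosen by the user; the stability protocol evaluates
  candidate K values but deliberately does not auto-select one. On real
  cervical data the reference configuration expects K = 5 (C5–T1
  coverage) or K = 9 (C1–T1 coverage).
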