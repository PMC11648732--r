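---
title: "Benchmarking federated against local lesion segmentation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking federated against local lesion segmentation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fedsegbench)
```

## The problem

Hospitals that want a shared lesion-segmentation model usually cannot pool
their CT scans. Federated learning (FL) sidesteps this: every site trains
locally and only model weights travel. The open question for a site is
whether joining such a federation actually buys it anything over (a) its own
locally trained model, (b) a post-hoc ensemble of several sites' local
models, or (c) a federated model trained *without* it. `fedsegbench`
implements the full benchmarking machinery for that question at desk scale:
a synthetic multi-site data generator, fingerprint-synchronized model
configuration, in-process federated training with non-weighted weight
averaging, the comparator model families, a four-metric segmentation
evaluation with explicit degenerate-case conventions, and rank aggregation
across sites and metrics.

Three voxel classes are segmented on chest-like phantoms: consolidation
(label 1), ground-glass opacity (GGO, label 2) and pleural effusion (PE,
label 3), with PE the least prevalent class.

## The synthetic multi-site generator

Real multi-centre CT cohorts differ between sites in scanner geometry and in
annotation procedure far more than in normalized intensity. The generator
reproduces exactly that structure. Each `site_profile()` fixes:

* **voxel spacing** — the default six sites span voxel volumes from
  0.15 mm^3 to 4.84 mm^3, the dominant inter-site difference;
* **intensity shift and noise** — small (shifts of ±0.01 in normalized
  units), because intensity distributions are made similar by normalization;
  scan-to-scan variability is instead injected *per case* as a
  multiplicative gain (sd 0.06) and additive offset (sd 0.02) on the tissue
  levels, emulating reconstruction and contrast differences between scans.
  This per-case jitter is what keeps an 8-case training site genuinely
  under-sampled, the regime in which collaboration can pay off;
* **class prevalence** — Bernoulli per class and case, PE lowest
  (0.40-0.50 versus 0.85-0.90); a case that would be lesion-free has one
  class forced in, because the cohort design assumes every scan shows
  pathology;
* **annotation style** — `"manual"`, or `"auto"` with a
  `fragmentation_level` that scatters extra small connected components per
  present class, mimicking automatically pre-processed annotations whose
  connected-component (CC) counts exceed manually drawn ones.

Anatomy is deliberately schematic: an ellipsoidal "lung", lesions as
Gaussian-smoothed thresholded random blobs (white noise at ~10 mm
correlation length, trilinearly upsampled and thresholded inside the lung),
and PE as a contiguous layer at the dependent (bottom) part of the lung,
which is physically how free effusion pools. Tissue intensity levels are
0.25 (lung), 0.45 (GGO), 0.65 (consolidation), 0.85 (PE) in normalized
units. Default volumes are 48^3 voxels so that a full federation trains in
CPU minutes.

What the phantom does **not** emulate: airway/vascular anatomy, lesion
texture, partial lung collapse, scanner artefacts, or demographic structure.
Passing benchmarks here shows the *machinery* is correct and that the
collaborative-versus-local comparison behaves as expected in a controlled
regime; it says nothing quantitative about clinical data.

Everything is reproducible: all randomness derives from integer seeds via a
hash-based stream-splitting scheme (`derive_seed()`), so one site, one case
and one federation round each get an isolated, deterministic RNG stream.

## Fingerprint synchronization

Each site computes a `compute_fingerprint()` of its **training split only**:
median spacing, median shape, and mean/sd plus (0.5, 99.5) percentiles of
foreground intensity (voxels with any lesion label). The server pools the
fingerprints case-count-weighted (`aggregate_fingerprints()`, sorted by site
id first, so the result is order-invariant), and every site derives the same
`configure_model()` from the pooled fingerprint — serialized configurations
are byte-equal, which the tests assert. The percentile pair (0.5, 99.5)
follows the convention of self-configuring segmentation pipelines; the exact
pooling rule (weighted means of per-site summaries rather than re-pooling
raw voxels) is an approximation, chosen because raw voxels must not leave a
site. The "low-resolution" regime is realized by doubling the pooled median
spacing.

Preprocessing resamples each case to the target spacing (trilinear for
images, nearest for labels), clips to the configured percentile window and
standardizes by the configured mean/sd.

## The learner

A deliberately small two-level 3D U-Net-style encoder-decoder
(`n_channels_base = 4` at desk scale): conv 3^3 → pool 2× → conv 3^3 →
nearest upsample → skip concatenation → conv 3^3 → 1^3 output conv →
softmax over 4 classes. The benchmark logic is architecture-agnostic, and a
clinical-scale network would add nothing but hours.

Training samples patches (8^3 at desk scale) with foreground oversampling:
with probability 0.5 a patch is centred on a random voxel of a random class
present in the case, so rare PE is seen regularly. The loss is cross-entropy
plus soft Dice, the Dice term averaged over the classes present in the
patch — averaging over absent classes makes every lesion-free patch actively
suppress rare-class logits, which at desk scale prevented the intermediate
GGO class from ever being learned.

The optimizer is SGD with momentum 0.8 and global gradient-norm clipping at
1.0, learning rate 0.05. Plain fixed-rate SGD was tried first and could not
learn the GGO class at all within desk budgets (a per-voxel intensity
threshold oracle reaches Dice ~0.94 on the same inputs, so the failure was
optimization, not information); momentum plus clipping resolves it. The
momentum velocity is reset at each epoch start, so a local epoch is
self-contained: no optimizer state crosses a federation round, which also
settles what would otherwise be an ambiguity about carrying optimizer state
between rounds.

At `scale = "paper"` the configuration switches to the full training
schedule (1000 epochs of 250 batches); at `scale = "desk"` it is 5 epochs of
100 batches of 2 patches. Full-volume prediction tiles the volume with
half-patch stride and renormalizes accumulated softmax maps, so per-voxel
probabilities always sum to 1.

## Federated training

`run_federated_training()` implements synchronous rounds: every
participating site trains `epochs_per_round = 1` local epoch from the
current global weights, then the server replaces the global weights with the
**non-weighted** block-wise mean — equal weight per site regardless of
dataset size, so the aggregate optimizes all sites' objectives equally. The
orchestrator only ever moves `fsb_model_weights` across the site boundary;
every (site, case, phase, round) read is appended to an access log that the
tests audit for data locality (no test-split reads during training, no
cross-site reads, excluded sites absent from leave-one-out runs).

Checkpoints (`save_checkpoint()` / `resume_run()`) carry the round index,
weights and traces plus an FNV-1a content digest; corruption raises an
integrity error, and because per-round seeds are pure functions of the
federation seed, a resumed run reproduces the uninterrupted trajectory
byte-for-byte. After the final round the global model is distributed once
more so every site holds it.

## Comparator models and scenarios

For evaluation site $i$: the local model $L_i$; the ensemble $E$ averaging
the softmax maps of all sites' local models; the federated model $FL$; their
leave-$i$-out variants $E(-i)$ and $FL(-i)$ trained/combined without site
$i$; and specializations $Spec(\cdot)$, the equal-weight softmax average of
a collaborative model with $L_i$. Averaging is done in probability space,
after the softmax, with equal weights (1/2 for specialization). Three
scenarios are benchmarked, each evaluated on site $i$'s test split only:

| scenario | methods |
|---|---|
| personalization | $L_i$, $E$, $FL$, $Spec(E)$, $Spec(FL)$ |
| generalization without local training | $L_j$ for every $j \ne i$, $E(-i)$, $FL(-i)$ |
| generalization with local training | $L_i$, $E$, $FL(-i)$, $Spec(E)$, $Spec(FL(-i))$ |

In the second scenario each other site's local model is ranked as its own
method; since $L_j$ is never evaluated at site $j$ itself, its overall rank
averages the columns where it appears.

## Evaluation metrics and conventions

Per (case, class) pair, independently per class:

* **DSC** — Dice similarity $2|A \cap B| / (|A| + |B|)$;
* **NSD** — normalized surface Dice: the fraction of surface voxels of each
  mask within 1 mm (default tolerance) of the other mask's surface;
* **HSD** — Hausdorff surface distance in mm; the default is the symmetric
  maximum over directed surface distances (a 95th-percentile mode is
  available), matching a worst-case reading of the 260 mm cap below;
* **NAVE** — normalized volume error $|V_{pred} - V_{gt}| / V_{gt}$; the
  exact normalization is not canonical, so a mean-of-volumes denominator is
  selectable, and the choice is echoed in every report header.

Surface voxels are foreground voxels with at least one background
face-neighbour (array boundaries count as background); distances are
Euclidean between surface-voxel centres scaled by the voxel spacing.

Degenerate cases follow fixed conventions: an **empty ground truth** (a
false positive opportunity) is excluded from all aggregates, and the tests
prove inertness by mutation; an **empty prediction** against non-empty
ground truth (false negative) scores DSC 0.0, NSD 0.0, HSD 260.0 mm
(roughly the craniocaudal height of a lung, i.e. a worst case) and NAVE
20.0. Per-site means average exactly the non-excluded (case, class) records.

## Rank aggregation

All methods are ranked within each (site, metric) column — rank 1 is best;
DSC/NSD higher-better, HSD/NAVE lower-better — and a method's overall rank
$r$ is the mean of its $N_{sites} \times N_{metrics}$ ranks. Ties get
fractional mid-ranks, which preserves the per-column rank sum
$N(N{+}1)/2$ under any tie pattern (the tests check this invariant and an
independent counting oracle). Reports render the rank heatmap with the
final average-rank column.

## Numerical and design notes

* Tie-break in `predict_segmentation()`: exact probability ties decode to
  the **lower** class index, so a perfectly uniform voxel is background.
* `aggregate_fingerprints()` sorts by site id before any floating-point
  arithmetic, making permutation invariance exact rather than approximate.
* Weight aggregation divides by the number of entries; with one site this
  is division by 1, so a one-site federation is byte-identical to local
  training.
* Site RNG streams are keyed by (seed, site, round); two sites holding
  identical data therefore still draw different patches, as independent
  hospitals would.
* Content digests use FNV-1a 64-bit over a canonical serialization;
  configuration hashes additionally canonicalize through sorted-key JSON so
  byte equality is meaningful across processes.
* Problem sizes in tests and the acceptance run are the package's desk
  defaults: 3 sites × 10 cases of 48^3 voxels, 80/20 split, 5 rounds;
  module tests use 16^3 phantoms. The headline collaborative-versus-local
  comparison is a stochastic property of this configuration: with 2 test
  cases per site individual seeds can favour the local models, so it is
  asserted at the fixed default seed, not as a per-seed guarantee.

## Known limitations

* The phantom's lesion appearance is far simpler than clinical CT; absolute
  metric values are not comparable to clinical studies.
* Federation is simulated in one process; no transport, scheduling,
  privacy mechanism or client dropout beyond checkpoint/resume.
* The learner is a minimal stand-in for a self-configuring clinical
  segmentation network; only the configuration-synchronization idea is
  carried over, not the full rule set.
* Bootstrap confidence intervals for the metric means are not produced;
  with 2 test cases per site at desk scale they would be vacuous.
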