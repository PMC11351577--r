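---
title: "Methods: a hybrid quantum-classical lung-lesion classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a hybrid quantum-classical lung-lesion classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qlung)
```

## The model

`qlung` classifies subjects into *normal*, *benign* or *malignant* from a
paired chest radiograph (CXR) and CT image. The pipeline is a chain of
fitted stages:

| stage | operator | output |
|---|---|---|
| feature extraction | CNN forward pass to a named layer, per modality | `F^cxr`, `F^ct` |
| fusion | concatenation, CXR first | `F = F^cxr || F^ct` |
| compression | truncated SVD, `q = Vᵀ(F − μ)` | 5 quantum features |
| embedding | min–max scaling to `[0, π]`, one RY angle per qubit | 5 angles |
| quantum layer | H wall → RY embed → 2 × (RY + CNOT chain) → ⟨Z⟩ | 5 expectations |
| head | dense 100/50/20/3, ReLU + softmax | 3 class probabilities |

The quantum layer and head are trained jointly by minibatch Adam on softmax
cross-entropy. Circuit gradients use the parameter-shift rule, which is
exact for RY parameters: `∂f/∂θ = [f(θ + π/2) − f(θ − π/2)]/2`. The head's
input gradient chains the two: `∂L/∂θ_j = Σ_k (∂L/∂z_k)(∂z_k/∂θ_j)`. All
measurement outputs are deterministic Pauli-Z *expectations*, not sampled
collapses — training stays differentiable and reproducible; a sampling mode
(`sample_measurements()`) exists for demonstration only.

Assumptions worth making explicit:

* **Paired modalities.** Fusion concatenates per-subject CXR and CT feature
  vectors, so every subject must be imaged in both modalities. The phantom
  generator provides genuinely paired images; real cohorts assembled from
  unrelated CXR and CT archives would not satisfy this contract, and
  `merge_dataset()` refuses unpaired subjects rather than dropping them.
* **Frozen upstream stages.** The backbone is a fixed (or separately
  fine-tuned) feature extractor during hybrid training; the SVD projector
  and the angle scaler are fitted on the training split only and then held
  fixed. Anything else leaks test data into the representation.
* **Expectations feed the head.** The head consumes the five raw ⟨Z⟩ values
  in `[-1, 1]`; no binarization happens anywhere in the trained path.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| resize target | 1024 | px/side | standard preprocessing resolution of the architecture; phantom studies use 64 px directly |
| SVD components | 5 | features | one per qubit; the circuit width fixes it |
| qubits | 5 | — | one per quantum feature |
| variational layers | 2 | — | smallest depth whose CNOT chains entangle all five qubits twice; configurable |
| embedding range | [0, π] | radians | keeps angles within one RY half-turn; see the note below |
| head sizes | 100/50/20/3 | neurons | the architecture's published classifier head |
| optimizer | Adam, lr 1e-3, batch 16 | — | standard small-network defaults (β₁ 0.9, β₂ 0.999, ε 1e-8) |
| epochs | 30 | — | desk-scale phantom schedule; real-data schedules are much longer |
| split | 70/15/15 | fraction | stratified at subject level, seeded |

A note on the embedding range: after the Hadamard wall, an RY(θ) embedding
gives ⟨Z⟩ = −sin θ, which is *not* injective over [0, π] (θ and π − θ
collide at the measurement). The underlying state is still unique in θ, and
the variational layers that follow can rotate the distinguishing X
component back into the measurement basis, so the range is kept at [0, π]
for its symmetric treatment of the feature midpoint; the identity-stage
baseline receives the same scaled angles, keeping the two training modes
comparable input-for-input.

## What the phantom generator emulates — and what it does not

`phantom_config()` draws, per subject, one *lesion latent*: lesion count,
centres, radii (px) and intensity offsets (gray levels), with ranges
ordered by class (normal: none; benign: 1–3 lesions of radius 3–5;
malignant: 2–5 lesions of radius 8–12 with higher intensity). The same
latent is rendered twice:

* **CT**: sharp-edged disks on a quiet dark background (low noise),
* **CXR**: the same lesions as Gaussian-softened blobs (projection-like
  blur, σ = r/1.3) over a brighter sinusoidal rib-stripe background with
  higher noise.

The default draw is 300 subjects at 64×64 px in proportions
0.5/0.25/0.25 (malignant/benign/normal), mirroring a 1000/500/500 class
split at desk scale, with pixel noise of 8 gray levels. These defaults are
the package's reference study conditions; the latent record is persisted
as JSON next to the manifest so tests can verify cross-modality pairing.

What the phantom deliberately is *not*: anatomically realistic. There are
no lung fields, no occlusion, no scanner physics, no inter-reader label
noise, and class separation is by construction strong. Passing the phantom
study therefore demonstrates that the pipeline's stages compose, train and
reproduce correctly — it says nothing about accuracy on clinical images,
and the clinical accuracy figures reported for this architecture are not
reproducible from this package.

## Numerical choices

* **Gray range.** Images live on integer gray levels 1–255; a stored 0 is
  clamped to 1 rather than rejected, so arbitrary 8-bit PNGs remain
  loadable, and in-range values round-trip exactly.
* **Resize filter.** Bilinear (via EBImage), chosen for determinism; a
  same-size resize is an exact identity.
* **SVD conventions.** The training matrix is mean-centered before the SVD
  (configurable off); each basis column's largest-magnitude entry is made
  nonnegative so fits are reproducible across linear-algebra backends;
  singular values are stored nonincreasing.
* **Qubit ordering.** Little-endian: qubit 0 is the least significant bit
  of the basis index. Stated once here, asserted in tests.
* **Degenerate inputs.** A constant quantum feature maps to the midpoint
  angle π/2; inference values outside the training range are clamped;
  0/0 metric ratios are reported as 0 with a `zero_division` flag instead
  of erroring.
* **Weight initialization.** He-style seeded normal draws for conv/dense
  weights; variational angles start uniform in (−0.1, 0.1) to break the
  symmetry of an all-zero start.
* **Loss reporting.** History rows report loss as
  `100 · CE / log 3` percent so an uninformative classifier sits at 100.
* **Determinism.** Every stage draws from a stream derived from one root
  seed; the same configuration and seed reproduce histories, weights and
  written files bit-for-bit. Serialized models store doubles at 17
  significant digits, which round-trips IEEE doubles exactly.
* **Tolerances.** Gate unitarity is asserted at 1e-12, state norms at
  1e-10 (1e-9 over 50-gate sequences), parameter-shift vs finite
  differences at 1e-5, SVD orthonormality at 1e-8.

## Open design choices

Several aspects of the architecture are under-specified in its published
description; the package fixes them as follows and exposes each as
configuration where it is a genuine knob:

* **Ansatz.** The published circuit diagram shows Hadamard and phase gates
  but not the parameterized family or entangler layout. The package uses
  RY angle embedding, RY variational rotations and a linear CNOT chain
  (0→1→…→4); the S gate is available in the gate library but not placed in
  the default ansatz.
* **Binary counts for a 3-class task.** Published misclassification tables
  give a single TP/TN/FP/FN per model. The package reads this as
  one-vs-rest with *malignant* positive, exposed as `positive_class` so no
  interpretation is hard-coded. (Worked through the published hybrid
  RepVGG counts — TP 4400, TN 200, FP 300, FN 100 — the standard formulas
  give accuracy 92.00% and sensitivity 97.78%; the small discrepancies
  between such derived values and the separately tabulated headline
  metrics in the source material are documented here as inconsistencies of
  the source, not reconciled by the package.)
* **Fine-tuning depth.** "Fine-tuned" backbones are implemented as
  frozen-body, trainable-head — the cheapest faithful reading — with the
  regime configurable.
* **Ablation contract.** The no-quantum baseline replaces the circuit by
  an identity pass-through of the same five scaled features into the same
  head, so hybrid and traditional runs share one code path differing only
  in that stage.
* **Early stopping.** Provided (patience on training loss) but off by
  default, since the reference training schedule does not state one.

## Problem sizes

The reference phantom study — 300 subjects, 64×64 px, 30 epochs — was
chosen so a full hybrid + baseline + reproducibility run completes in well
under a minute on one CPU while leaving a wide margin above the 85%
training-accuracy smoke threshold; the test suite uses 24–60 subjects for
contract tests. Larger images or deeper circuits scale as
`O(n_px²)` per conv layer and `O(2^n_qubits)` per gate respectively; the
simulator caps registers at 12 qubits.

## Known limitations

* Dense statevector simulation only: no noise models, density matrices or
  hardware backends.
* The built-in CNN is a two-block network for desk-scale studies; the six
  large pretrained backbones enter only through the adapter contract with
  externally supplied weights.
* No DICOM ingestion, windowing, lung segmentation or augmentation (the
  augmentation section of the config is a disabled stub).
* Phantom results do not transfer to clinical performance claims (see
  above).
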