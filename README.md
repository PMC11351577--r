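# qlung

Hybrid quantum–classical classification of lung lesions from paired chest
radiograph (CXR) and CT images.

Early lung-cancer screening pipelines increasingly combine convolutional
feature extraction with alternative classifier heads. `qlung` implements one
such architecture end-to-end in R, for researchers who want to study — on
controlled synthetic data — how a small variational quantum circuit behaves
as the classification stage of a multimodal imaging pipeline:

1. **Imaging** — 8-bit grayscale images clamped to gray levels 1–255,
   bilinear square resize (default 1024×1024), and a synthetic paired
   CXR/CT *phantom* generator with class-dependent lesion structure
   (normal / benign / malignant), so the whole pipeline runs without any
   clinical data.
2. **Feature extraction** — a small trainable CNN behind a named-layer
   backbone contract (`F = TL(I)` per modality); the published pretrained
   backbones (VGG16 … RepVGG) are reachable through a declared-dimension
   adapter.
3. **Fusion** — per-subject concatenation `F_total = F^cxr || F^ct`
   (CXR block first, split index recorded): 512+512 → 1024, 2048+2048 → 4096.
4. **SVD compression** — mean-centered truncated SVD of the fused training
   matrix; the top five right singular vectors map every subject to five
   *quantum features* (`q = Vᵀ(x − μ)`).
5. **Quantum layer** — a from-scratch dense statevector simulator (H, S,
   RY, RZ, CNOT; ≤12 qubits). The classifier circuit puts a Hadamard wall
   on five qubits, embeds the five features as RY angles scaled to [0, π],
   applies two variational RY+CNOT-chain layers, and measures ⟨Z⟩ per qubit.
   Gradients are exact via the parameter-shift rule
   (∂f/∂θ = [f(θ+π/2) − f(θ−π/2)]/2).
6. **Dense head** — fully connected 100/50/20/3 ReLU layers with softmax,
   trained jointly with the circuit parameters by Adam; an *identity-stage*
   baseline (`train_traditional()`) ablates the quantum layer for
   like-for-like comparisons.
7. **Evaluation** — 3×3 confusion matrices, one-vs-rest collapse, accuracy /
   sensitivity / specificity / precision / F1 / MCC, and ROC–AUC by
   threshold sweep.

## Worked example

```r
library(qlung)

# a seeded paired-modality phantom dataset: 60 subjects, 64x64 images
dir <- file.path(tempdir(), "phantoms")
cfg <- phantom_config(n_subjects = 60, seed = 7)
manifest <- generate_phantom_dataset(cfg, dir)

# per-modality CNN features, fused and compressed inside the trainer
bb    <- tiny_cnn_backbone(seed = 2)
feats <- extract_dataset_features(bb, manifest)

model <- train_hybrid(feats$CXR, feats$CT, train_config(epochs = 10, seed = 5))
tail(model$history, 3)
#> # A tibble: 3 × 3
#>   epoch accuracy_pct loss_pct
#>   <int>        <dbl>    <dbl>
#> 1     8         90.9     59.7
#> 2     9         88.6     56.3
#> 3    10         86.4     53.5

ev <- evaluate_model(model, feats$CXR, feats$CT)
glance(ev)
autoplot(model)      # training curves
autoplot(ev$roc)     # malignant-vs-rest ROC
```

The history rows are training accuracy (percent of subjects whose argmax
class is correct) and loss (cross-entropy as a percentage of the
uninformative `log 3` baseline). `evaluate_model()` reports the full metric
set; with `positive_class = "malignant"` the collapsed counts treat
malignant-vs-rest as the binary task.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/qlung.R generate --config run.yaml --out data/
Rscript inst/cli/qlung.R train    --config run.yaml --manifest data/manifest.csv --out model/ --mode hybrid
Rscript inst/cli/qlung.R evaluate --bundle model/ --manifest data/manifest.csv --out report/
```

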