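# FewShotSynergy

Few-shot meta-learning for drug-synergy prediction in data-scarce cancer
cell lines.

Drug-combination screens label some cell lines with thousands of synergy
measurements and most with almost none. FewShotSynergy treats every cell
line as a *task*: from K labeled drug pairs (the support set) of a new
line, it adapts and predicts the synergy scores of that line's remaining
pairs (the query set). It is aimed at computational researchers studying
cross-cell-line generalization of synergy predictors and at anyone who
needs a fully testable, downloads-free implementation of the mechanism.

## Model and training strategy

Two encoders feed a regression head:

* a **3-layer graph convolutional network** over the heavy-atom molecular
  graph of each drug (78-dimensional atom descriptors: element, heavy
  degree, implicit valence, hydrogen count, aromaticity), with
  symmetrically normalized aggregation
  *h′ᵤ = ReLU(W Σ_{v∈N(u)∪{u}} e₍ᵥᵤ₎/√(D̂ᵥD̂ᵤ) hᵥ)* and a max-pool readout;
* a **CNN** over each cell line's 900 marker-gene expression values
  arranged as a 30×30 grid (conv → batch-norm → ReLU → max-pool per
  layer);
* a shared FC transform per drug plus an FC cell transform, concatenated
  into a joint embedding *z*, and a two-layer head
  *ŷ = ReLU(zW₁+b₁)W₂+b₂*.

Parameters are partitioned into embedding parameters θ_E and head
parameters θ_p. Training is stage-wise:

1. **Pretraining** of all parameters on data-rich cell lines
   (½Σ(ŷ−y)² objective);
2. **Cross-tier meta-optimization**: episodes of N tasks; the inner tier
   adapts *only the head*, θ′ = (θ_E, θ_p − α∇_{θ_p}L_support); the outer
   tier updates the shared initialization with the gradient of
   Σ_j L_query(f_{θ′_j}), differentiated through the inner step
   (second order, with a first-order switch);
3. **Fine-tuning**: the same head-only update on a new line's K support
   samples, then query prediction.

Zero-shot mode disables adaptation everywhere; ablation flags switch off
meta-learning, fine-tuning, selective (head-only) adaptation, or
pretraining.

The package also ships a synthetic benchmark generator (drug library,
cell-line profiles with controllable similarity, synergy landscapes with a
controllable shared-structure fraction and per-line dispersion), the
evaluation protocols (random and low-similarity clustering splits,
repeated few-shot/zero-shot harnesses, per-cell-line analysis, ablation
orchestration), and a config-driven pipeline with checkpoints and a run
manifest (`runPipeline()`, CLI wrapper in `inst/scripts/fewshot-synergy.R`).

## Worked example

```r
library(FewShotSynergy)

## a small synthetic world: 20 drugs, 10 cell lines, strong shared structure
world <- generateWorld(syntheticWorldConfig(
  nDrugs = 20, nCellLines = 10, samplesPerCellLine = 40,
  sharedWeight = 0.8, seed = 42))
split <- splitRandom(names(world@profiles), fraction = 0.8, seed = 42)

cfg <- benchmarkConfig(model = modelConfig(
  gcnDims = c(16, 16, 16), convChannels = c(2, 4), fdHidden = 32,
  fdOut = 16, fcOut = 16, headHidden = 32),
  pretrainEpochs = 15, episodes = 200, N = 4, K = 10, Q = 10, seed = 42)

model <- trainVariant(world, split, cfg, variant = "none")
entities <- buildEntityCache(world@drugs, world@profiles)

evaluateFewShot(model, worldSamples(world), entities, split,
                K = 10, Q = 10, nTasks = 10, repeats = 5, seed = 42)
```

prints

```
Few-shot evaluation (fewshot): 5 repeats x 10 tasks (K = 10, Q = 10)
  mse   0.2494 +/- 0.0415
  scc   0.8829 +/- 0.0191
  r2    0.7169 +/- 0.0309
  auc   0.9698 +/- 0.0151
  aupr  0.9879 +/- 0.0062
```

i.e. after fifteen pretraining epochs and two hundred meta-episodes,
adapting the head on 10 support samples per unseen cell line explains
~72% of query score variance (scores are standardized, so an uninformed
predictor sits near MSE 1). The same call with `mode = "zeroshot"` gives
the unadapted model: MSE 0.3535, SCC 0.8477 — the gap between 0.3535 and
0.2494 is the value of few-shot adaptation on this world.

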