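# histomamba

Binary classification of H&E histopathology tiles (normal vs. abnormal
tissue) with an uncertainty-driven global–local state-space network, in
pure R (+ two small C++ kernels). The package is self-contained: it ships
Macenko stain standardization, patient-independent data handling, a
synthetic Beer–Lambert H&E tile simulator, and a reproducible
training/evaluation/ablation harness, so the full pipeline runs end to end
on one CPU with no external data.

## The model

A UNet-style encoder–decoder whose building block fuses two branches
computed from a pre-normalized feature map:

* a **local branch**: depthwise separable convolution,
  `F_local = PW(DW(F_in, k=3) + b_dw) + b_pw`;
* a **global branch**: the map is flattened row-wise into a token sequence
  `X ∈ R^{L×C}` (`L = H·W`) and run through a bank of per-channel diagonal
  linear state-space recurrences

  `s_t = a ⊙ s_{t−1} + b x_t`, `y_t = c·s_t + d x_t`

  in both directions (`O(L)` per direction), concatenated and projected
  back to `C` channels;
* a **convex fusion** `F = α·F_local + (1−α)·F_global`. Encoder blocks
  compute a per-channel `α = sigmoid(GAP(F_local ⊕ F_global)·W_att +
  b_att)`; decoder blocks use a spatial weight driven by feature
  uncertainty: with `U(i,j)` the entropy of the normalized squared channel
  intensities of the encoder bottleneck,

  `α′(i,j) = α₀ · exp(−λ·U(i,j))`, `α₀` learnable (init 0.5), `λ = 1`.

Training minimizes `L = L_CE + γ·L_UAL` (`γ = 0.1`): class-weighted,
label-smoothed cross-entropy plus an uncertainty-calibration term
`L_UAL = 1 − ρ(U, E)`, the Pearson correlation between the upsampled
uncertainty map and the pixel-wise error map `E(i,j) = |ŷ(i,j) − y|` of an
auxiliary local-probability head. For a default 224×224×3 input the
encoder bottleneck is 14×14×512 and the classifier pools the 224×224×64
decoder output into a 64-vector.

## Worked example

Desk-scale end-to-end run: 60 synthetic patients × 10 tiles at 64 px,
patient-independent 70/15/15 split, tiny model profile (8 base channels,
state size 8), ≤15 epochs.

```r
library(histomamba)

co    <- generate_cohort(cohort_spec(60, 10, seed = 11))
split <- patient_independent_split(co$manifest, seed = 11)
man   <- apply_split(co$manifest, split)

model <- build_model(tiny_config(), seed = 101)
rec   <- train_model(model, co$tiles, man, desk_train_config(seed = 11),
                     verbose = TRUE)
ev    <- evaluate_model(rec$model, co$tiles, man, subset = "test")
cat("acc", ev$accuracy, " f1", ev$f1, " auc", ev$auc,
    " mean rho(U,E)", round(ev$mean_rho, 3), "\n")
```

Output from this exact run (about 2 minutes on one CPU):

```
epoch   1  lr 1.50e-03  loss 0.8083  val F1 0.2000
epoch   2  lr 3.00e-03  loss 0.7472  val F1 0.2000
epoch   3  lr 2.96e-03  loss 0.6128  val F1 0.5714
epoch   4  lr 2.83e-03  loss 0.4618  val F1 0.9474
epoch   5  lr 2.64e-03  loss 0.3153  val F1 1.0000
...
acc 1  f1 1  auc 1  mean rho(U,E) 0.629
```

The held-out patients are classified perfectly (the synthetic task is
separable by design — see the methods vignette for what this does and does
not establish), and the mean per-tile Pearson correlation between the
uncertainty map and the actual error map is strongly positive: the
calibration loss has taught the network to be uncertain where it is wrong.

Stain standardization works on any tile in `[0,1]`:

```r
tile <- generate_tile(1, jitter_stain_matrix(sd_deg = 4), seed = 9)
std  <- normalize_stains(tile)          # Macenko, default H&E profile
```

## Command line

```sh
Rscript -e 'histomamba::histomamba_cli()' generate-data \
    --out-dir tiles --n-patients 60 --tiles-per-patient 10 --seed 1
Rscript -e 'histomamba::histomamba_cli()' normalize-stains \
    --input-dir tiles --output-dir tiles_std --target profile.json
Rscript -e 'histomamba::histomamba_cli()' train \
    --config run.yaml --variant 1 --seed 1 --out runs/full
Rscript -e 'histomamba::histomamba_cli()' ablate \
    --config run.yaml --variants 1,5 --seeds 1,2,3 --out ablation.csv
```

`run.yaml` holds `model:` (tile_size, base_channels, `gmamba:` kernel /
state_dim, `ud:` lambda / eps), `train:` (lr, epochs, batch_size, seed,
...), `loss:` (gamma, ual_metric, label_smoothing, class_weighting),
`augment:` and `data: {dir: ...}`; ablation variants are 1 = full, 2 = no
uncertainty adjustment, 3 = no local branch, 4 = no skip connections,
5 = 2+3 combined.

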