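# daresunet

Binary segmentation of clinical targets — fetal crown-rump length and
foot in ultrasound, polyps in colonoscopy, prostate in MRI — with a
**double attention residual U-Net**: two consecutive attention-gated
residual U-Nets in which the second network re-segments the input after
it has been re-weighted by the first network's *salient map*, and whose
decoder receives attention-gated skip features from **both** encoders.
The package is aimed at medical-image-analysis researchers who want a
fully inspectable, dependency-light reference implementation of this
architecture family that runs and is testable entirely on synthetic
data, on one CPU.

The numerical core — stride-2 convolutions, transposed convolutions,
batch normalization, additive attention gates, and reverse-mode
gradients for all of them — is implemented in the package itself
(R + BLAS with C++ patch extraction), so every stage of the model is
open to inspection and exact unit testing.

## The model

Let $E_i, R_i, D_i, AG_i$ be the encoder, residual bottleneck, decoder
and attention gates of network $i$. With input $x$:

$$
y_1 = \mathrm{head}\big(D_1(\mathrm{Concat}(AG_1),\ R_1(E_1(x)))\big), \qquad
y_2 = \mathrm{head}\big(D_2(\mathrm{Concat}(AG_1, AG_2),\ R_2(E_2(y_1 \odot x)))\big)
$$

* **Encoder**: five blocks of 5×5 conv (stride 2, same padding) →
  batch-norm → leaky ReLU (slope 0.2); filters 20/40/80/160/320.
* **Bottleneck**: four residual blocks $H_k = F(H_{k-1}) + H_{k-1}$,
  $F$ = conv → BN → conv → BN (320 filters, stride 1, no ReLU after the
  second conv).
* **Attention gates** (per decoder scale): with skip $x^l$ and
  upsampled gating signal $g$,
  $\alpha = \sigma_2(\psi^\top\sigma_1(W_x^\top x^l + W_g^\top g + b_g) + b_\psi)
  \in (0,1)$, and the skip is rescaled as $x^l \odot \alpha$.
* **Decoder**: four blocks of 5×5 transposed conv (stride 2) → BN →
  dropout 0.3 → concat gated skips → ReLU; filters 160/80/40/20, then a
  transposed-conv sigmoid head.
* **Training**: Adam (lr 1e-4) at batch size 1 on the minus-Dice loss
  $\mathcal{L} = -\mathrm{softDice}(y_2, t) - \lambda\,\mathrm{softDice}(y_1, t)$
  (default $\lambda = 0.5$).
* **Evaluation**: Dice, Jaccard and symmetric Hausdorff distance on
  binarized predictions; Feret-diameter lengths with Bland–Altman and
  correlation agreement analysis.

The methods vignette
(`vignettes/double-attention-res-unet.Rmd`) documents every formula,
default and design decision.

## Worked example: overfitting eight synthetic phantoms

The generator produces ultrasound-like phantoms (deformed-ellipse
target, multiplicative Gamma speckle, attenuation, blur) with exact
ground truth, so the whole pipeline runs without any downloads:

```r
library(daresunet)

dir <- file.path(tempdir(), "phantoms")
generateDataset(synthConfig(n_samples = 8, seed = 7), dir)
samples <- readManifest(file.path(dir, "manifest.tsv"))

cfg <- networkConfig(encoder_filters = c(4, 8, 16, 32, 64),   # reduced width
                     decoder_filters = c(32, 16, 8, 4))
model <- assembleDoubleNet(cfg, seed = 7)
fit <- trainModel(model, samples, trainConfig(epochs = 200, seed = 7))

print(metricSummary(evaluateModel(fit$model, samples)))
```

After about six minutes on one CPU this prints

```
  metric      mean         sd
1    dsc 0.9784876 0.02123369
2    jsc 0.9585997 0.03950990
3     hd 1.0517767 0.14644661
```

i.e. the reduced-width double network overfits the eight phantoms to a
mean Dice of 0.98, Jaccard 0.96, and a Hausdorff distance of about one
pixel. The first network's output behaves as a salient map:

```r
s <- samples[[1]]
sal <- salientMap(predictSegmentation(fit$model, sampleImage(s))$pred)
mean(sal[sampleMask(s) == 1])   # 0.932  (inside the true target)
mean(sal[sampleMask(s) == 0])   # 0.092  (outside)
```

The same pipeline is scriptable from a shell via the bundled CLI
(`inst/scripts/daresunet`): `synth`, `train`, `predict`, `evaluate` and
`agree` subcommands driven by a flat `key: value` config file with
flag > file > default precedence; every run writes its resolved
configuration, a log, and its outputs (train log CSV, checkpoint,
metric CSV, predicted masks) into the chosen directory.

```sh
Rscript inst/scripts/daresunet synth --out data --n_samples 8 --seed 7
Rscript inst/scripts/daresunet train --manifest data/manifest.tsv --out fit \
    --encoder_filters 4,8,16,32,64 --decoder_filters 32,16,8,4 \
    --resize false --epochs 200 --seed 7
Rscript inst/scripts/daresunet evaluate --checkpoint fit/checkpoint.bin \
    --manifest data/manifest.tsv --out eval --resize false \
    --encoder_filters 4,8,16,32,64 --decoder_filters 32,16,8,4
```

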