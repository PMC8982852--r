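# bindsignal

Base-resolution modeling of transcription-factor binding signal from DNA
sequence, in R.

ChIP-seq and ATAC-seq pipelines produce, for every base of a called peak, a
significance signal (a −log10 p-value track). `bindsignal` trains a
symmetric fully convolutional encoder–decoder network that regresses this
per-base signal directly from the 1000-bp one-hot sequence, and then derives
four downstream tasks from the single predicted track **z**:

* **Signal regression** — minimize the base-resolution penalized MSE
  (Eq. below) between predicted and measured `log10(1 + p)` signal,

  `loss = (1/NL) Σᵢ Σⱼ (z_ij − ẑ_ij)² + α‖w‖²`

* **Classification** — binding probability `σ(max z)` with
  `σ(x) = 1/(1+e^−x)`;
* **Localization** — the binding site is at `argmax z`; a 60-bp region
  around it is reported, and whole chromosomes are scanned in 1000-bp
  windows against a threshold (default 1.5);
* **Motif discovery** — 100-bp regions around the argmax are scored by the
  trained first-layer convolution filters; per-sample maximal-activation
  k-mers are stacked into a position frequency matrix (PFM) and written in
  MEME format;
* plus **variant effect scores** `|z_alt[i] − z_ref[i]|` at a SNP's offset
  `i`, and a chromatin **openness** statistic
  `log10(1 + overlapping reads)`.

The architecture is U-net-like: three conv/ReLU/maxpool/dropout encoder
blocks (default desk-scale channels 32/48/64, pools 5/5/5; the GPU-scale
64/96/128 profile is one `model_config()` call away), a bidirectional GRU
bottleneck
whose directions are summed and whose global-average-pooled context is
broadcast back, and four bilinear-upsampling decoder stages with skip
connections and a linear 1-channel head. Any input length divisible by 125
works; other lengths are N-padded and trimmed. The network, its backward
pass and Adam training are implemented in the package (R + a few C++
kernels); no deep-learning runtime is required.

A synthetic-data module (`generator_spec()`, `simulate_dataset()`,
`shift_experiment_set()`, `insertion_experiment_set()`) generates
motif-planted sequences with Gaussian signal bumps so that the entire
pipeline — data preparation, training, classification, localization,
scanning, motif extraction and SNP scoring — is trainable and testable on a
desk CPU. See `vignettes/methods.Rmd` for the model, its assumptions, and
the design decisions.

## Worked example

Train on the packaged synthetic world and run every downstream task
(about 5 minutes on one CPU; shrink `n_pos`/`max_epochs` for a faster
smoke run):

```r
library(bindsignal)

spec  <- generator_spec(seed = 1)         # 2000 pos + 2000 neg, 1000 bp
sim   <- simulate_dataset(spec)
split <- split_random(sim$samples, seed = 1)
fit   <- train_model(split, train_config(seed = 1))   # Adam, early stopping

te   <- stack_samples(split$test)
pred <- sapply(split$test, function(s) predict_signal(s$seq, fit))
metric_report(pred, te$y,
              scores = apply(pred, 2, classify_sequence),
              labels = te$labels)
#> <metric_report> n=800  MSE 0.10669  Pearson r 0.8391  AUC 0.9417  PRAUC 0.9466

# localization: argmax within +/-50 bp of the planted center
pos     <- which(te$labels == 1)
centers <- sapply(split$test[pos], function(s) s$source$summit)
mean(abs(apply(pred[, pos], 2, which.max) - 1 - centers) <= 50)
#> [1] 0.857513

# motif recovery vs the planted 12-bp matrix
motif <- extract_motif(Filter(function(s) s$label == 1, split$train)[1:500],
                       fit)
align_pfm(motif, spec$pwm)$mean_r
#> [1] 0.9998481
write_meme_motif(motif, "synthetic_motif", "motif.meme")
```

The interpretation: on held-out synthetic windows the model explains most
of the per-base signal (r ≈ 0.84), separates binding from non-binding
windows well via `σ(max z)` (AUC ≈ 0.94), places the signal argmax within
±50 bp of the planted site for ~86% of positives, and the PFM extracted
from the first conv layer matches the generating motif almost exactly
(mean per-position r ≈ 0.9998 at the best alignment offset).

A command-line interface wraps the same steps:

```sh
Rscript -e 'bindsignal::run_cli()' simulate --out data/ --seed 1
Rscript -e 'bindsignal::run_cli()' train --data data/ --out model.ckpt --seed 1
Rscript -e 'bindsignal::run_cli()' scan --model model.ckpt --fasta chr.fa \
    --out hits.bed --threshold 1.5 --width 60
Rscript -e 'bindsignal::run_cli()' motif --model model.ckpt --data data/ \
    --out motifs.meme
```

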