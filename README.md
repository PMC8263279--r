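# fnirsdbn

Deep-belief-network classification of lateralized motor signals in
functional near-infrared spectroscopy (fNIRS), with a full synthetic-data
generator for the underlying experimental protocol.

## What this is for

fNIRS measures cortical hemodynamics through the scalp: over activated
motor cortex, oxygenated hemoglobin (HbO) rises, more strongly in the
hemisphere contralateral to the moving — or merely imagined — limb. A
brain-computer interface can exploit this to decode *which arm* a person
moves or imagines moving. This package implements that analysis end to end
for a 16-channel, 20 Hz montage and a four-task protocol (left/right arm
flexion-extension, executed and imagined; 8 s task + 17 s rest; three
sessions of 30 trials per task), for researchers who want a tested,
reproducible reference implementation of the method:

* **Synthetic study generator** — trial-structured HbO/HbR sessions with a
  double-gamma hemodynamic response (boxcar-convolved peak at 16–20 s),
  contralateral-dominant and execution-dominant amplitudes, physiological
  noise (cardiac, respiratory, Mayer waves), and per-subject idiosyncrasy
  (focal activation topography, channel noise profiles). Writes/reads
  delimited text (channel CSV + events TSV).
* **Preprocessing** — zero-phase 0.01–0.2 Hz Butterworth band-pass, 0–8 s
  epoch extraction (160 samples/trial), per-channel min–max normalization
  fitted on training sessions only; every time point becomes one
  16-dimensional sample.
* **The classifier** — a deep belief network: two restricted Boltzmann
  machines trained by one-step contrastive divergence,

  $$E(v,h) = -a^\top v - b^\top h - v^\top W h, \qquad
    \Delta w_{ij} = \varepsilon(\langle v_i h_j\rangle_\text{data}
                   - \langle v_i h_j\rangle_\text{recon}),$$

  stacked with a softmax layer and fine-tuned in two phases (softmax-only,
  then full backpropagation) by Polak–Ribière conjugate gradients with
  momentum. Hidden sizes are selected from the grid {10,20,30,40,50}² by
  trial-blocked 2-fold cross-validation.
* **Evaluation** — sample- and trial-level (majority-vote) accuracy,
  group mean ± population SD, and the 10 × 10 cross-subject transfer grid
  (every subject's model scored on every subject's held-out session).
* **Exact small-model oracles** — enumeration of the RBM's
  product-of-experts marginal and of the exact likelihood gradient, used to
  verify the sampling-based training.

See `vignettes/fnirsdbn-methods.Rmd` for the model, its assumptions, and
every calibration decision.

## Worked example

One subject, imagery problem, at the reduced study scale (10 trials per
task per session; sessions 1–2 train, session 3 test):

```r
library(fnirsdbn)

cfg <- run_config(seed = 1,
                  sim = sim_config(n_subjects = 1,
                                   trials_per_task_per_session = 10))
study <- simulate_study(cfg$sim)
ds <- build_subject_samples(study[[1]], "MI", cfg$bandpass)
dim(ds$train$x)   # 6400   16   (at the full protocol: 19200 x 16)
dim(ds$test$x)    # 3200   16   (full protocol: 9600 x 16)

fit <- train_dbn(ds$train, cfg$grid, cfg$cd, cfg$ft)
fit$history[c("h1", "h2")]   # $h1 50, $h2 30  (selected by 2-fold CV)

score_model(fit$model, ds$test)
```

which prints

```
held-out session: sample accuracy 85.38%, trial accuracy 95.00%
confusion (true x predicted):
       0    1
  0 1499  101
  1  367 1233
```

so the left/right imagery decision is correct for 85% of individual time
points and 19 of 20 held-out trials. Label 0 is the left-arm task, 1 the
right-arm task.

## The analysis workflow

The numbered drivers under `analysis/` run the study as a narrative:

```sh
Rscript analysis/01_simulate.R      # simulate the 10-subject study
Rscript analysis/02_preprocess.R    # dataset geometry per subject
Rscript analysis/03_train_models.R  # select + pretrain + fine-tune (slow)
Rscript analysis/04_evaluate.R      # group table vs published accuracies
Rscript analysis/05_transfer.R      # 10 x 10 cross-subject transfer grid
```

Each step prints what it found and writes a small table under `results/`.
`analysis/_settings.R` holds the shared configuration (seed, scale); one
flag switches to the full 30-trials-per-session protocol.

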