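# qrseg

Single-pass QRS detection and beat classification for single-lead Holter
ECG, in R.

Ambulatory (Holter) ECG recorded by wearable devices during daily
activities is heavily disturbed by movement noise, which breaks the
classical detect-then-classify processing chain. `qrseg` implements the
one-inference-step alternative: a 1D residual network (five blocks) with a
gated recurrent layer segments the signal per sample into four channels —
no-QRS, normal beat (N), premature ventricular contraction (PVC),
premature atrial contraction (PAC) — and deterministic post-processing
converts the segmentation mask into time-stamped, classified beat
annotations:

```
ECG (any fs >= 100 Hz)
  -> resample to 100 Hz, standardize (zero mean, unit variance)
  -> network: 5 residual conv blocks -> GRU -> FC -> softmax, shape (4, L)
  -> argmax per sample -> same-class segments (>= 2 samples)
  -> segment centers = candidate peaks (strength = mean class probability)
  -> remove weaker of any two peaks closer than 0.15 s
  -> beat list (time, class, strength) at the native sampling rate
```

Training follows the published recipe: per-batch augmentation (random 30 s
crop, polarity inversion with p = 0.5, weighted oversampling to balance
beat classes), per-sample cross-entropy, AdamW (lr 0.001), gradient L2
norm clipped to 1.0, no weight decay. Targets widen each beat fiducial to
a 10-sample run of its class. Evaluation is tolerance-matched: a predicted
beat within 0.1 s (inclusive) of a reference annotation is a true
positive under a maximum-cardinality one-to-one matching, and the package
reports detection F1 = 2TP/(2TP+FP+FN) plus per-class / micro / macro
classification F1.

Because the original training data are private, the package bundles a
synthetic Holter ECG generator (45 s @ 200 Hz records, Gaussian-mixture
beat morphologies, RR-interval rhythm model with premature beats and
compensatory pauses, movement-noise bursts) so the entire pipeline —
simulate, train, detect, evaluate — runs end-to-end with no external data.
The compiled core (Rcpp/RcppArmadillo) implements the network forward and
backward passes in float32; gradients are verified against finite
differences in the test suite.

## Worked example

```r
library(qrseg)

# 1. simulate a small synthetic Holter dataset (30 s records @ 200 Hz)
cfg <- synthesis_config(duration_s = 30, fs = 200,
                        pac_fraction = 0.1, pvc_fraction = 0.1)
tr <- make_dataset(60, cfg, seed = 101)
va <- make_dataset(10, cfg, seed = 202, id_prefix = "val")
te <- make_dataset(20, cfg, seed = 303, id_prefix = "test")

# 2. train a reduced model for a few epochs
model <- build_model(model_config(channels = c(8, 16, 16, 32, 32),
                                  gru_hidden = 32), seed = 7)
fit <- train(model, tr$records, va$records,
             train_config(epochs = 8, seed = 7, validate_every = 2),
             verbose = TRUE)
#> epoch   2  train_loss 1.2296  val_loss 1.3575  val_F1 0.4409  val_macro 0.1351
#> epoch   4  train_loss 1.0187  val_loss 1.2327  val_F1 0.5779  val_macro 0.2057
#> epoch   6  train_loss 0.8557  val_loss 1.0822  val_F1 0.8443  val_macro 0.2601
#> epoch   8  train_loss 0.7164  val_loss 0.9217  val_F1 0.9519  val_macro 0.2815

# 3. detect beats on held-out records and score them
dets <- lapply(te$records, function(a) detect(fit$model, a))
names(dets) <- vapply(te$records, function(a) a$record$record_id, "")
refs <- te$records; names(refs) <- names(dets)
print(evaluate_dataset(dets, refs)$report)
#> Detection: TP 711  FP 80  FN 11  F1 0.9399
#> Classification F1: N 0.8347  PVC 0.0000  PAC 0.0000  micro 0.7574  macro 0.2782
```

Eight epochs (8 gradient steps here) already give detection F1 0.94:
beats are found, but the rarer beat classes need a longer schedule. The
acceptance suite (`tests/testthat/test-acceptance.R`, criterion 6) runs
the same experiment at 200 training records, a bidirectional GRU and 55
epochs with AdamW warm restarts, printing on this machine:

```
[criterion 6] noisy held-out: detection F1 0.9785 | class F1 N 0.972 PVC 0.981 PAC 0.921 | macro 0.9580
[criterion 6] clean held-out: detection F1 1.0000
```

that is, with moderate movement noise the detector finds 97.9% of beats
(harmonic mean of precision/recall) and classifies them with macro F1
0.96 across N/PVC/PAC; on noise-free records detection is perfect.

`detect()` accepts any `ecg_record` — including WFDB recordings read with
`read_wfdb_record()`, which selects lead I when present, maps detailed
beat symbols to the closest of {N, PAC, PVC}, and drops non-beat marks.

## Command line

```sh
Rscript inst/cli/qrseg.R simulate --out data/ --n 100 --seed 1
Rscript inst/cli/qrseg.R train    --data data/ --out run/ --config train.json
Rscript inst/cli/qrseg.R detect   --model run/model.json --record data/syn0001.json --out pred.csv
Rscript inst/cli/qrseg.R evaluate --pred pred.csv --ref data/syn0001.csv --fs 200
```

## Scope

Reimplementations of the seven comparison detectors, the annotation GUI,
reproduction of the published per-database score tables, and GPU inference
are out of scope. See `vignettes/qrseg-methods.Rmd` for the model details,
the synthetic world and its limitations, and the design decisions taken
where the source is silent.
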