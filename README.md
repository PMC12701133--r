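# facesurv

Multimodal seven-day survival prediction for clinical patients: a facial
feature detector plus a recurrent tabular classifier, fused into one
pipeline, with the evaluation metrics and survival-factor statistics that
go with it.

## The problem

Short-horizon prognosis in emergency and general medicine draws on two
heterogeneous sources: a table of physiological indicators (vital signs,
blood gas, coagulation and liver panels, Glasgow Coma Scale, chronic
health evaluation, ...) and visible facial signs. This package implements
a complete framework that

1. localizes **eyes and lips** in patient images with a bespoke
   convolutional detector (**FRegNet**): a residual stem whose side branch
   is modulated by a global-average-pooled projection under a Softplus
   (`stem(x) = softplus((relu(conv_c x) + conv_d x) · k_GAP)`), a staged
   residual body, and a path-aggregated feature pyramid (**FPAFPN**,
   `P_i = Con(C_i) + H(P_{i+1})`, second pass
   `F_i = Con(P_i) + Down(F_{i-1})`) whose upsampling `H` is separable
   cubic-convolution interpolation with factors 2 and 3;
2. classifies 36 physiological indicators (optionally fused with facial
   features) with **ETED**, an LSTM
   (`f,i,o = σ(W h + U x + b)`, `C^t = f C^{t-1} + i tanh(·)`,
   `h^t = o tanh(C^t)`) under a per-timestep affine dense map
   (`z = x·w + α`), adaptive attention (`softmax(tanh(score))`), a sigmoid
   gate (`σ(R · f(z))`) and a batch-normalized residual branch
   (`BN(relu(f(Z))) + B`), ending in the probability of death within seven
   days;
3. evaluates detection with COCO-style AP / AR / mAP over an IoU grid and
   classification with accuracy / precision / recall / F1 / AUC;
4. analyses survival factors with Welch group comparisons, dichotomous
   logistic regression (IRLS; B, SE, standardized Beta, Wald t, 95% CI,
   OR) and permutation feature-impact ranking.

Because cohorts of this kind are private, the package ships a first-class
synthetic-data module: face-like images with geometric eye/lip targets and
exactly known boxes, and a cohort drawn from a stated logistic model with
a latent facial signal linking the two modalities. Everything — both
neural models included — runs in plain R with an in-package reverse-mode
autodiff; no deep-learning framework is required.

## Worked example

```r
library(facesurv)

# images with known eye/lip boxes; train the detector on 40, inspect one
d <- generate_face_images(synthetic_image_spec(n_images = 50, seed = 1))
det <- train_detector(d$images[1:40],
                      detector_config(epochs = 10, seed = 1))
print(det)
dets <- do.call(rbind, lapply(d$images[41:50], function(im)
  detect(im$image, det, image_id = im$id)))
gt <- do.call(rbind, lapply(d$images[41:50], function(im) im$boxes))
print(summarize_detection(dets, gt))

# a synthetic cohort with strong coefficients; train and evaluate ETED
co  <- generate_clinical_cohort(
  synthetic_cohort_spec(600, beta = 4 * default_beta(), gamma = 0, seed = 1))
x <- as.matrix(co[, clinical_indicator_names()])
fit <- train_eted(x[1:500, ], co$label[1:500],
                  eted_config(epochs = 40, learning_rate = 3e-3, seed = 1))
print(classification_metrics(co$label[501:600], predict(fit, x[501:600, ])))
```

Output from this exact script:

```
FRegNet facial-feature detector
  classes: eye, lip 
  parameters: 55270 
  anchors: 1701 over 3 pyramid levels
  epochs trained: 10 (final loss 0.1726)
Detection metrics over IoU 0.50-0.95:
  AP 0.353  AR 0.402  mAP 0.353  AP@0.5 0.848  precision 0.727
  eye    AP 0.393  AR 0.465
  lip    AP 0.312  AR 0.340
Classification at threshold 0.50: accuracy 0.920, precision 0.860, recall 0.977, F1 0.915, AUC 0.976
  confusion: TP 43  FP 7  TN 49  FN 1
```

Reading it: after ten epochs on forty images the detector already finds
nearly all targets at IoU 0.5 (AP@0.5 0.848 — the strict COCO average over
IoU 0.50–0.95 is much lower because the boxes are only a few pixels
tight), and the tabular classifier separates the strong synthetic cohort
with AUC 0.976 on held-out patients. The longer schedule used by the
acceptance script (below) reached AP@0.5 of 0.996 on this machine
(individual seeds range roughly 0.77-1.00).

A command-line wrapper is installed under `inst/cli/facesurv` with
subcommands (`synth-images`, `synth-cohort`, `train-detector`, `detect`,
`train-eted`, `evaluate`, `stats`, `pipeline`), all driven by one YAML
configuration; repeated runs with the same config and seed are
byte-identical.

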