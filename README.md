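# ecgdann

Domain-adversarial classification of printed 12-lead ECG images, in R.

## The problem

Most 12-lead electrocardiograms exist only as printed pages, and the
practical way to digitise a page in a clinic is to photograph it with a
phone. A convolutional classifier trained on clean page scans collapses on
such photographs — tilt, crumple, shadows, occlusions and sensor noise put
the images far outside the training distribution — and no labeled corpus of
phone-captured pages exists to retrain on.

`ecgdann` is for researchers studying this unsupervised domain-adaptation
setting. It implements a domain-adversarial neural network (DANN) over
printed ECG page images together with a fully synthetic data path (signal
generator → page renderer → capture-artifact simulator), so the complete
training protocol can be built, tested and benchmarked on a laptop with no
external data.

## The method

Two networks share one convolutional feature extractor `G_f` (stacked
`conv 7x7 → batch norm → ReLU → dropout` blocks):

* **ECG-Vanilla** — `G_f` plus a sigmoid label head `G_y`, a plain binary
  classifier for one cardiac condition, trained on labeled clean pages.
* **ECG-Adversarial** — adds a domain head `G_d` (clean = 0, captured = 1)
  behind a **gradient reversal layer**: identity forward, gradient
  `g ↦ -λ g` backward. Minimizing the domain loss w.r.t. `G_d` while the
  extractor receives the *reversed* gradient forces `G_f` toward features
  that classify the disease but cannot distinguish the domain.

The reversal strength ramps with training progress `p ∈ [0, 1]`:

```
λ = 0.85 · exp(5.5 · p),   p = (b + E · N_B) / (N_B · N_E)
```

(`b` batch index, `E` epoch index, `N_B` batches/epoch, `N_E` the epoch
horizon). Training alternates labeled source batches with 50/50
source/target mixed batches after a warm-up; a model state is checkpointed
only when the source-validation ROC-AUC is a new best **and** the domain
classifier's accuracy on a held-out mixed validation set lies in
[40%, 60%] — near chance, meaning the features are domain-agnostic.
Evaluation uses the standard panel: sensitivity, specificity, PPV, NPV,
accuracy, F1, Mann-Whitney ROC-AUC and Youden-threshold selection.

## Worked example

```r
library(ecgdann)

# 1. synthetic labeled records: sinus bradycardia vs normal rhythm
recs <- generate_dataset(6, c(sinus_bradycardia = 0.5, normal = 0.5), seed = 7)
measure_heart_rate(recs[[1]])   # this record drew the bradycardia label
#> # A tibble: 1 × 3
#>   hr_bpm  rr_cv n_beats
#>    <dbl>  <dbl>   <int>
#> 1   55.3 0.0487       9

# 2. render a printed page (3x4 layout + lead II rhythm strip) and
#    simulate a phone capture of it
page <- render_page(recs[[1]], format_spec(), out_h = 220, out_w = 412)
frame <- simulate_capture(page, capture_config(), seed = 1)
page
#> <ecg_image 220x412x3 domain=clean format=default record=sinus_bradycardia_2002728244>
frame$domain
#> [1] "captured"

# 3. the adaptive reversal coefficient
sch <- lambda_schedule(n_batches = 25, n_epochs = 60)
adaptive_lambda(0, 0, sch)     # first batch of first epoch
#> [1] 0.85
adaptive_lambda(0, 30, sch)    # halfway through the horizon (p = 0.5)
#> [1] 13.29624

# 4. metrics
roc_auc(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE))
#> [1] 0.75
classification_metrics(confusion(c(TRUE, TRUE, FALSE, FALSE),
                                 c(TRUE, FALSE, FALSE, FALSE)))
#> # A tibble: 1 × 6
#>     tpr   tnr   ppv   npv   acc    f1
#>   <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1   0.5     1     1 0.667  0.75 0.667
```

A full two-arm experiment — generate data, train ECG-Vanilla and
ECG-Adversarial at matched seeds, evaluate on clean and captured test
pages — is one call:

```r
bm <- run_benchmark(benchmark_config(conditions = "sinus_bradycardia",
                                     seeds = 1:3))
glance(bm)    # per-condition median adaptation gap AUC_adv - AUC_vanilla
tidy(bm)      # per (condition, arm, domain, format, seed) AUC/ACC/F1
autoplot(bm)
```

Fitted models are `ecg_fit` objects with `tidy()` (per-epoch history),
`glance()`, `autoplot()` (training curves with the 40-60% checkpoint
window) and `predict()` methods. A thin command-line interface over the
same functions lives at `inst/cli/ecgdann.R`
(`synth | render | distort | train | evaluate | benchmark`).

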