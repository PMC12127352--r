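# fascal

Training-free layer selection and feature calibration for few-shot image
classification, aimed at plant disease recognition on frozen backbone
features.

Rare plant diseases are documented by a handful of images, so classifiers
must solve *N-way-K-shot* episodes: N classes, K labeled support examples
each, queries assigned to the nearest class prototype
(`ŷ = argmin_k d(q, c_k)`, with `c_k` the mean support embedding). No
gradient step is ever taken; everything operates on embeddings extracted by
a frozen backbone. The package is for researchers and practitioners who
already have (or can extract) labeled embedding banks and want to answer
two questions quantitatively:

**Which backbone layer transfers best?** The *Feature Adaptation Score*
ranks a backbone's intermediate layers from the labeled pool alone:

    FAS_l = σ²_between,l / σ²_within,l + D̄_l / √n_l

where `σ²_within` is the mean squared distance of samples to their class
mean, `σ²_between` the mean squared distance of class means to the global
mean, `D̄` the mean (unsquared) pairwise distance between class means, and
`n_l` the layer's embedding dimension. Higher FAS predicts higher few-shot
accuracy; `fas_layers()` scores a whole bank and selects the argmax layer.

**Can a source-domain feature bank help?** *Plant Disease Feature
Calibration* (PDFC) shifts each episode's support prototype `s_i` toward
the reference bank: average the `m` bank vectors nearest `s_i` into a
centroid `c_i`; find the prototype's two nearest centroids `c_a`, `c_b`;
set `T = (1−λ)c_a + λc_b`; move `γ` units toward `T`:

    s_i_cal = s_i + γ (T − s_i) / ‖T − s_i‖

`(λ, γ)` are tuned by exhaustive grid search or by Gaussian-process
Bayesian optimization with Expected Improvement (`grid_search()`,
`bayes_search()`).

The package also ships the complete evaluation harness (1000-episode ×
20-run protocol with accuracy and pooled macro precision/recall/F1), HDF5
and TSV feature-bank storage, a deterministic toy backbone for image
folders, synthetic Gaussian generators with known ground truth, and a
`fascal` command line (`simulate`, `extract`, `fas`, `eval`, `tune`).

## Worked example

Score a synthetic 7-layer bank whose separability peaks at layer 6, then
evaluate the selected layer and calibrate under covariate shift:

```r
library(fascal)

bank   <- make_layer_series(gaussian_class_spec(seed = 1))
report <- fas_layers(bank)
report
#> Feature Adaptation Score report (7 layers)
#> # A tibble: 7 × 6
#>   layer_id within_var between_var mean_between_dist   dim   fas
#>      <int>      <dbl>       <dbl>             <dbl> <int> <dbl>
#> 1        1       3.86       0.180             0.632    64 0.126
#> 2        2       3.95       0.222             0.699    64 0.144
#> 3        3       3.89       0.342             0.869    64 0.197
#> 4        4       3.83       0.527             1.08     64 0.273
#> 5        5       3.83       0.716             1.26     64 0.344
#> 6        6       3.82       1.45              1.79     64 0.603
#> 7        7       3.86       0.385             0.924    64 0.215
#> best layer: 6
```

FAS picks layer 6: its between/within ratio (0.38) and scaled centroid
distance both dominate the other layers. Evaluating that layer:

```r
ev <- run_evaluation(bank_layer(bank, report$best_layer),
                     episode_spec(5, 1, 15),
                     episodes_per_run = 200, runs = 2, seed = 1)
ev
#> 5-way 1-shot evaluation: 200 episodes x 2 runs
#>   mean accuracy 0.7965 (sd 0.0724)
#>   macro P/R/F1  0.7966 / 0.7965 / 0.7965
```

Calibration against a clean source bank when the target domain is shifted
and noisy:

```r
pair <- make_shift_pair(shift_spec(seed = 8))
cal  <- pdfc_calibrator(pair$reference, calibration_params(m = 10, lam = 0, gamma = 1))
base <- run_evaluation(pair$target, episode_spec(5, 1, 15), 200, 1, seed = 2)
pdfc <- run_evaluation(pair$target, episode_spec(5, 1, 15), 200, 1,
                       calibrator = cal, seed = 2)
c(baseline = base$summary$mean_accuracy, calibrated = pdfc$summary$mean_accuracy)
#>   baseline calibrated
#>     0.5900     0.8175
```

Moving one-shot prototypes toward the reference centroids lifts mean
accuracy by about 23 points here: the shift direction removes most of the
support-side noise and the global domain offset at once. All result
objects have broom-style `tidy()`/`glance()` methods and `autoplot()`
figures. The same pipeline runs from a shell:

```sh
fascal simulate layers --out bank.h5 --seed 1
fascal fas --bank bank.h5 --out report.json
fascal eval --bank bank.h5 --layer 6 --out summary.json --episodes 200 --runs 2
```

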