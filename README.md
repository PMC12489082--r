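# mwibelt

Synthetic microwave-belt imaging and machine learning for lung tumor
screening, end to end and fully reproducible.

Malignant lung tissue has a much higher permittivity and conductivity than
healthy lung, so a tumor leaves a measurable imprint on the multistatic
scattering matrix recorded by a wearable belt of `Na = 8` antennas sweeping
`Nf = 500` frequency points over 0.5-3.5 GHz. `mwibelt` implements the full
processing and learning chain around that sensor concept:

* a **Born-approximation forward model** on parametric torso phantoms that
  generates paired body/empty S-parameter sweeps (Touchstone `.s8p` I/O),
  with clutter, a common-mode skin reflection, and a tumor term whose
  energy grows with tumor volume and decays with belt offset;
* **two-step calibration** — empty-domain subtraction, then per-frequency
  removal of the cross-channel complex mean
  (`S_cal = (S_body - S_empty) - mean_ij(...)`) — which cancels clutter and
  skin exactly on the generator;
* **multistatic frequency-domain backprojection**
  `I(p) = | Σ_i Σ_j Σ_q S_ij(f_q) e^{+jk(f_q)(|p-r_i|+|p-r_j|)} |`,
  healthy-reference normalization and 3-channel rendering;
* **band-averaged spectral features**: amplitude and phase of all 64
  channels averaged over 1.5-3 GHz → 128 features per case;
* **ADASYN oversampling** (from scratch, largest-remainder allocation),
  flip/rotation image augmentation, and leakage-safe splitting;
* **four learners** — gradient-boosted detector (10 trees, depth 3) and
  size regressor (1000 trees, depth 4) on features; a compact CNN detector
  and size regressor (15,825 parameters, implemented in the package's
  compiled code) on images — plus noise-robust fine-tuning (1/5/10%
  multiplicative perturbations, training continuation);
* **decision fusion** across belt positions (OR for detection, maximum for
  size) and size-based early-stage assignment
  (IA ≤ 30 mm < IB ≤ 40 < IIA ≤ 50 < IIB).

## Worked example

Balance the canonical 26-vs-134 detection set and inspect the size ladder
of reconstructed images:

```r
library(mwibelt)

# ADASYN: 26 minority vs 134 majority, beta = 1
set.seed(0)
syn <- adasyn(matrix(rnorm(26 * 128), 26),
              matrix(rnorm(134 * 128, 2), 134), k = 5, beta = 1, seed = 0)
nrow(syn)
#> [1] 108          # 26 + 108 = 134: the balanced set has 268 instances

# miniature fixture study: 12 cases, 6 diameters per lung
fx <- make_fixtures(seed = 1)
sapply(fx$images[1:6], function(im) max(normalized_intensity(im)))
#>  A-left-d04.00-o+000  A-left-d08.00-o+000  A-left-d12.00-o+000
#>                0.006                0.046                0.154
#>  A-left-d20.00-o+000  A-left-d36.00-o+000  A-left-d48.00-o+000
#>                0.715                4.170                9.884
```

The normalized peak (relative to the tumor-free reference image) rises
strictly with diameter — the monotone response the size models exploit.

The whole study — 170 cases in three simulation sets, calibration, imaging,
balancing, four learners, fine-tuning, evaluation — runs in about two
minutes in the default smoke profile:

```r
res <- run_all(run_config("smoke", seed = 0))
res$report$metrics
#>          model       section   metric      value  n
#> 1 xgb_detector     in_domain accuracy  1.0000000 32
#> 2     xgb_size     in_domain  mse_mm2  0.3697606 10
#> 3 cnn_detector     in_domain accuracy  0.8125000 32
#> 4     cnn_size     in_domain  mse_mm2  1.8643585 10
#> 5 xgb_detector cross_phantom accuracy  1.0000000 10
#> 6     xgb_size cross_phantom  mse_mm2 81.1533223 10
#> 7 cnn_detector cross_phantom accuracy  1.0000000 10
#> 8     cnn_size cross_phantom  mse_mm2 56.7964977 10
res$noisy_eval
#>          model   metric    naive finetuned  n
#> 1 xgb_detector accuracy 1.000000  1.000000 20
#> 2     cnn_size  mse_mm2 1.752634  0.849845 20
```

Detection separates cleanly in-domain and transfers to the second phantom;
size regression is accurate in-domain (MSE well below the ~71 mm² target
variance) but does not transfer across phantoms without adaptation, and
fine-tuning on noise-infused data halves the size error on 10%-noise test
cases. The methods vignette (`vignettes/mwibelt-methods.Rmd`) documents the
model, every tunable parameter, and what these synthetic results do and do
not show.

A thin CLI sits over the same functions:

```sh
Rscript inst/cli/mwibelt run-all --out runs/demo --seed 0
Rscript inst/cli/mwibelt simulate --out data/synthetic --seed 1
```

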