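# finsexer

Automated phenotypic sexing of zebrafish (*Danio rerio*) from lateral RGB
photographs, for fish-facility and eco-devo workflows where manual sexing is
subjective and gonadal inspection is terminal.

Adult zebrafish are mildly sexually dichromatic — males carry a more intense
yellow caudal-fin pigmentation, females a rounder body — and embryonic heat
exposure both skews the sex ratio toward males and washes out male fin color
(putative neomales). `finsexer` implements two machine-learning sexing routes
and the statistics used to interpret them:

* **Color route.** Caudal-fin ROI → CIE L\*a\*b\* → per-channel histograms
  (3 × 64 bins, normalized) → soft-margin SVM with Gaussian kernel
  `k(x, y) = exp(−γ‖x − y‖²)`. The signed decision value
  `f(x) = Σᵢ wᵢ k(xᵢ, x) + b` gives the per-sex score pair
  (s_male = f/2, s_female = −f/2, difference d = f) and, z-transformed
  across the cohort, a per-fish **color-intensity score**
  `z = (d − d̄)/sd(d)`.
* **Shape route.** Whole-body image → residual convolutional network
  (3×3 stem, stages widening 96→384 filters — 16/32/64 at desk scale —
  identity/projection shortcuts, batch norm, global mean pooling, 2-unit
  softmax), implemented from scratch on BLAS matrix products and trained
  with Adam.
* **Statistics.** φ (mean square contingency) coefficient of classifier-vs-
  truth 2×2 tables; logit-link Bernoulli GLM for sex ratios with
  back-transformed LS-means `π = e^η/(1+e^η)`; polynomial ANCOVA of z on
  treatment × sex with body weight/length covariates up to degree 3,
  backward elimination by partial F tests under marginality, externally
  studentized residual screening (|r| > 3), and Tukey–Kramer adjusted
  LS-means with compact letters.

A synthetic cohort generator (`simulate_cohort()`) renders fish-like images
with the study's structure — male-yellow fins, attenuated treated males,
male-only size–color coupling, rounder females — so the entire pipeline is
testable without photographs. See the methods vignette
(`vignettes/finsexer-methods.Rmd`) for the model details and the reasoning
behind every default.

## Worked example

```r
library(finsexer)

# a 200-fish synthetic cohort: 50 per treatment x sex cell
cohort <- simulate_cohort(sim_config(n_per_cell = 50, seed = 11))
feats  <- fin_features(cohort)               # 192 histogram features per fish

cv <- svm_cv(feats, folds = 5, seed = 2)     # stratified cross-validation
cv$accuracy
#> [1] 0.955

model  <- svm_train(feats)
scores <- add_intensity(svm_score(model, feats))
agreement_report(scores)$treatment[c("phi", "pct_male_true", "pct_male_predicted")]
#> $phi
#> [1] 0.8643325
#>
#> $pct_male_true
#> [1] 50
#>
#> $pct_male_predicted
#> [1] 45

fit_sex_ratio(c(treatment = 158, control = 125), c(198, 249))
#> <sex_ratio_fit> logit-link Bernoulli GLM
#>       group n_male   n      eta     se    pi  pct
#> 1 treatment    158 198 1.373716 0.1770 0.798 79.8
#> 2   control    125 249 0.008032 0.1267 0.502 50.2
#> contrasts (logit scale, Tukey-Kramer adjusted):
#>              contrast estimate     se     p_adj
#> 1 treatment - control    1.366 0.2177 3.537e-10
```

The cross-validated accuracy (0.955) is the color route's performance when
fin yellowness separates the sexes by three times the pixel noise; the
treated-group φ of 0.86 is lower than the control group's because attenuated
treated males are called female from color alone — the mechanism the
intensity analysis then quantifies. The GLM reproduces the observed male
percentages (79.80% heat-treated vs. 50.20% control) with their logit-scale
LS-means and a strongly significant treatment contrast.

```r
dat <- dplyr::inner_join(scores[, c("id", "z")], truth_table(cohort), by = "id") |>
  dplyr::transmute(id, z, group, sex = true_sex, body_weight_g, total_length_mm)
fit <- backward_eliminate(fit_ancova(dat, ancova_spec()))
sex_slopes(fit)
#> # A tibble: 2 × 5
#>   sex   slope    se  lower upper
#>   <chr> <dbl> <dbl>  <dbl> <dbl>
#> 1 F     0.303 0.411 -0.507  1.11
#> 2 M     2.36  0.526  1.32   3.40
```

Color intensity rises with body weight in males (about 2.4 z-units per
gram, CI excluding zero) and not in females — the generator's male-only
size–color coupling, recovered through the full image → histogram → SVM →
z → ANCOVA chain.

## Command line

A thin CLI over the same functions lives at `inst/cli/finsexer`:

```sh
Rscript inst/cli/finsexer run --out-dir runs/demo --seed 1
Rscript inst/cli/finsexer ancova --out-dir runs/demo
```

Stages (`simulate`, `features`, `train-svm`, `predict`, `agreement`,
`intensity`, `ancova`, `report`) write CSV/JSON artifacts with a manifest;
completed stages are skipped unless `--force`.
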