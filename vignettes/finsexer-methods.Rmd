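---
title: "Methods: automated phenotypic sexing from fin coloration and body shape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated phenotypic sexing from fin coloration and body shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Adult zebrafish are sexually dichromatic: males carry a more intense yellow
pigmentation, most visibly in the caudal fin, while females tend to a rounder
body. Neither cue is reliable for a human observer, and definitive sexing by
gonadal inspection kills the animal. `finsexer` implements two automated
classifiers of phenotypic sex from a lateral photograph, plus the statistics
used to interpret them: agreement with gonadally determined sex, sex-ratio
modelling, a per-fish color-intensity score, and the association between that
score and body size. Because embryonic heat exposure both masculinizes
genotypic females and attenuates male fin color, the package's synthetic
cohort generator builds in a treatment arm whose males are yellower than
females but paler than control males — the structure every downstream test
exercises.

## The color route: Lab histograms and a Gaussian-kernel SVM

Images are converted from sRGB to CIE L\*a\*b\* (D65 white point, 2 degree
observer) with the standard closed-form transform, implemented in the package
and verified against an independently coded per-pixel reference; the b\* axis
(blue to yellow) carries the dichromatism signal. The caudal-fin rectangle
given in the metadata is cropped and summarized as three per-channel
histograms over fixed ranges (L\* in [0, 100], a\* and b\* in [-128, 127]),
concatenated into one feature vector. Defaults: 64 bins per channel
(dimension 192) and normalization by pixel count, which removes fin-area
dependence and makes the feature invariant to image scale. The bin count is a
design choice, not a published value: full 8-bit resolution is supported but
adds nothing at these sample sizes.

A soft-margin SVM with Gaussian kernel
$k(x, y) = \exp(-\gamma \lVert x - y \rVert^2)$ separates male from female
histograms; the solver is libsvm (via e1071) and the decision value is
verified in the tests against an explicit sum over support vectors,
$f(x) = \sum_i w_i\, k(x_i, x) + b$.

Two defaults deserve explanation:

* **Score convention.** A binary SVM produces one signed decision value
  $f(x)$. The per-sex score pair is defined as $s_\mathrm{male} = f/2$,
  $s_\mathrm{female} = -f/2$, so the male-minus-female difference
  $d = s_\mathrm{male} - s_\mathrm{female} = f$ is exactly the decision
  value. Predicted sex is male when $d > 0$; an exact tie is called female
  and logged.
* **Kernel bandwidth.** The default is $\gamma = 0.01 / (p \cdot
  \mathrm{var})$, with $p$ the feature dimension and var the overall feature
  variance — deliberately wider than the common $1/(p \cdot \mathrm{var})$
  heuristic. Classification accuracy is flat in $\gamma$ over several orders
  of magnitude on these features, but the intensity statistic below is not:
  normalized fin histograms are sparse, so with a narrow kernel the decision
  value saturates for any fish far from the margin and the within-sex
  ordering of scores collapses, while a wide kernel keeps $f$ nearly linear
  in the histogram and the scores graded. Both $\gamma$ and the cost $C$
  (default 1) are overridable, and stratified cross-validation is the
  default evaluation protocol since no train/test split is published for
  the original data.

## The intensity statistic

The spread of $d$ across a cohort reflects how strongly each fish expresses
the male color phenotype. The package standardizes it,
$z_i = (d_i - \bar d)/\mathrm{sd}(d)$, with the population ($n$) denominator
by default ($n-1$ by flag). $z$ is location- and scale-free, has mean 0 and
SD 1 on every scored cohort by construction, and preserves the ordering of
$d$. One caveat is documented and tested at its honest strength: a kernel
machine's decision value compresses far from the margin, so the within-male
rank correlation between $z$ and true fin yellowness is strongly positive
(about 0.7 on the generator at defaults) but not 1; across the whole cohort,
where the sex gap dominates, it exceeds 0.85.

## The shape route: a residual convolutional network

The whole-body classifier is a small residual network: a 3x3 convolution
stem, three stages of residual blocks that widen the representation
(96 to 384 filters in the full geometry; 16/32/64 in the desk-scale one),
stride-2 transitions with 1x1 projection shortcuts, batch normalization and
ReLU, global mean pooling, and a 2-unit softmax head. Unpublished details —
block counts, the downsampling schedule, the normalization scheme, the
optimizer — are configuration with documented defaults: two blocks per stage
in the full geometry, batch normalization (selectable off), Adam at
learning rate 1e-3 (1e-2 desk-scale) with a step decay to a tenth after 60%
and a hundredth after 85% of the epochs, decoupled weight decay 1e-3 on
weight matrices, and seeded initialization and data order. Everything —
im2col convolution, batch-norm forward/backward, residual blocks, the
optimizer — is implemented in the package on BLAS matrix products, and the
backward pass is verified against finite differences in the tests.

The desk-scale geometry (`cnn_config_small()`: 64x64 inputs, stride-2 stem,
widths 16/32/64, one block per stage, about 78k parameters) is what the test
suite trains. Inputs are standardized per channel with moments computed from
the training cohort. Training on the default synthetic cohort is genuinely
slow to converge — the generator's pixel noise (SD 8 in Lab units) is large,
and the network must average it away before the shape cue emerges — so the
held-out benchmark trains for up to 120 epochs (about 7 minutes on one CPU
core at n = 140 training images). Optional fresh-noise augmentation
(`augment_noise`) exists but is off by default, matching a training protocol
without augmentation.

## Agreement and sex-ratio statistics

Classifier-versus-truth agreement uses the phi (mean square contingency)
coefficient of the 2x2 table,
$\varphi = (n_{11} n_{22} - n_{12} n_{21}) / \sqrt{r_1 r_2 c_1 c_2}$,
identical to the Pearson correlation of the binary indicators (the tests
check this equivalence on random tables). A zero margin raises an error
rather than returning 0, because a silent zero corrupts agreement summaries.

Sex ratios are modelled as Bernoulli outcomes with a logit link,
$\mathrm{logit}(\pi_i) = \mu + \alpha_i$ with treatment as the single fixed
factor, fitted by maximum likelihood (`stats::glm`); least-squares means are
estimated on the logit scale and back-transformed with
$\pi = e^\eta / (1 + e^\eta)$. For this saturated one-factor model the
back-transformed LS-mean equals the observed group proportion and
$\mathrm{SE}(\hat\eta_i) = \sqrt{1/(n_i \hat p_i (1 - \hat p_i))}$ — both
verified against a hand-rolled Newton-Raphson IRLS oracle in the tests.
Pairwise contrasts are Tukey-Kramer adjusted, which with two groups
coincides with the unadjusted test. No random effects enter any model here,
so plain GLM/OLS machinery suffices throughout.

## The association model

The link between fin-color intensity and body size is estimated by
polynomial analysis of covariance on $z$: fixed factors treatment, sex and
their interaction; the covariate (body weight in g or total length in mm)
centered at its mean and entered as powers up to degree 3, alone and in
interaction with each factor. Centering before raising to powers tames the
collinearity of raw polynomial columns; reported per-sex slopes are returned
on the raw scale. Factors are coded sum-to-zero internally so LS-means are
estimable functions; the coding never surfaces in output.

Backward elimination repeatedly removes the least significant removable term
(partial F test, threshold `alpha_stay = 0.05` by default — the threshold is
a package default, not a published value) and refits, until every removable
term is significant. Marginality is enforced in both senses: no interaction
without its main effects, and no power $x^q$ without $x^p$ for $p < q$
(including within factor-by-power interactions). Ties in p-values break
deterministically by term order. Two consequences are worth knowing when
reading elimination results: terms contained in retained terms survive
regardless of their own p-value, and with seven removable nuisance terms at
threshold 0.05 roughly one run in three keeps something spurious — exact
recovery of a generating model is therefore not the right success measure;
retention of the true terms is, and that is what the tests assert.

Outliers are screened with externally studentized (leave-one-out) residuals;
observations with $|r| > 3$ are flagged, removed in a single pass, and the
model refitted once. An exactly interpolating fit (residuals at rounding
level) flags nothing. On clean Gaussian data at n = 448 the expected flag
count is about 1.2; a much larger count on real data reflects heavy tails,
not a software property.

LS-means for every treatment-by-sex cell are computed at the covariate grand
mean by default (all centered powers at zero) or at caller-supplied
covariate values, with Tukey-Kramer adjusted pairwise tests and a compact
letter display (implemented in-package by the standard insert-and-absorb
sweep). The same machinery, without covariates, serves the two-way ANOVA of
body weight and length.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` renders each fish as an ellipsoidal body plus a
triangular caudal fin on a light background, composited in Lab space and
quantized to 8-bit sRGB, so the generator's truth is recorded in exactly the
units the feature extractor measures (the stored `true_fin_b` is the
quantized round trip of the fin paint; a noiseless measurement reproduces it
bit-exactly). The two classifiers get two separable cues: fin b\* for the
color route and the body depth/length ratio for the shape route (0.30 for
males, 0.42 for females, echoing the rounder female form).

The default conditions are the study conditions: per-cell body weight and
length means from the published growth table; male probabilities 0.798
(treated) and 0.502 (control) in ratio mode; fin yellowness 40 (male) versus
16 (female) b\* units with pixel noise SD 8, so the sex separation is three
times the pixel noise; between-individual yellowness SD 5, chosen so that
control-group color classification lands near the published agreement
(phi about 0.96) rather than at an arbitrary difficulty; treated males
attenuated by 7 b\* units, which reproduces the published one-in-six rate of
treated males misread as female from color alone; and a male-only
size-color slope of 60 b\* per gram, which on the z scale is the few-units-
per-gram association the ANCOVA route is meant to detect. Between-individual
color variation is Gaussian — an assumption, since no distributional form is
published. Fixed per-cell counts are the default (reproducible contingency
tables); Bernoulli sex draws are the `ratio` mode.

The generator deliberately omits: stripes and per-pixel pigment pattern,
iridophore shininess and post-mortem paling, lighting gradients, camera
profiles other than sRGB, fin-shape variation, and any fin damage. Passing
tests on this generator therefore demonstrate that the pipeline's inference
machinery is correct under its stated model, not that the classifiers reach
any particular accuracy on real photographs.

## Numerical and protocol choices

* Lab conversion: sRGB primaries, D65, 2 degree observer; round trip within
  one 8-bit level on the sRGB gamut. A camera profile other than sRGB is
  possible for the original study but unstated; sRGB is assumed.
* ROIs are metadata rectangles (0-based, half-open), mirroring a manual
  cropping step; there is no automatic fin detector.
* Histograms clamp out-of-range Lab values into the edge bins.
* The SVM route never resizes images (normalized histograms are
  area-invariant); the CNN route resizes bilinearly to its input size.
* Desk-scale problem sizes used by the tests: cohorts of 40-400 fish at
  64x64 or 96x96 pixels, 100-replicate simulation suites for the ANCOVA
  properties, 500-replicate null suites for outlier and retention rates.
* Serialization is plain JSON for both classifiers; a reloaded SVM scores
  through the explicit kernel sum and needs no solver state.

## Known limitations

The full 255x255x3, 96-384-filter CNN geometry is available but impractical
to train in pure R at realistic sample sizes; the desk geometry is the
supported scale. The intensity statistic inherits the decision-value
compression discussed above. Backward elimination inherits the usual
stepwise-selection caveats; it is faithful to the described procedure, not a
recommendation. Real-data quantities from the study (agreement coefficients,
intensity LS-means, growth-table values, the 20-of-448 outlier count) are
not reproducible without the photographs and enter this package only as
generator defaults and reconstruction inputs.
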