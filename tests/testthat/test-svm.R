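test_that("gaussian kernel has the closed form, symmetry and identity", {
  expect_equal(gaussian_kernel(c(0, 0), c(1, 1), 0.5), exp(-1))
  set.seed(3)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(6); g <- runif(1, 0.1, 3)
    expect_equal(gaussian_kernel(x, x, g), 1)
    expect_equal(gaussian_kernel(x, y, g), gaussian_kernel(y, x, g))
    expect_gt(gaussian_kernel(x, y, g), 0)
    expect_lte(gaussian_kernel(x, y, g), 1)
  }
  expect_error(gaussian_kernel(1:3, 1:4, 1), "equal length")
  expect_error(gaussian_kernel(1:3, 1:3, 0), "gamma")
})

test_that("well-separated single-bin classes are classified perfectly", {
  feats <- make_toy_features(n_per_class = 5)
  model <- svm_train(feats, gamma = 1, cost = 10)
  sc <- svm_score(model, feats)
  expect_equal(sc$predicted_sex, feats$true_sex)
  expect_true(all(sc$d[feats$true_sex == "M"] > 0))
  expect_true(all(sc$d[feats$true_sex == "F"] < 0))
  expect_equal(sc$d, sc$s_male - sc$s_female)
})

test_that("training rejects degenerate label sets", {
  feats <- make_toy_features(n_per_class = 4)
  expect_error(svm_train(feats, labels = rep("M", 8)), "both sexes")
  expect_error(svm_train(feats, labels = c("M", rep("F", 7))), "2 samples per class")
})

test_that("decision values equal the brute-force kernel sum over support vectors", {
  co <- make_tiny_cohort(n_per_cell = 8)
  feats <- fin_features(co, bins = 16)
  model <- svm_train(feats)
  X <- finsexer:::.feature_matrix(feats)
  sc <- svm_score(model, feats)
  want <- vapply(seq_len(nrow(X)),
                 function(i) oracle_svm_decision(model, X[i, ]), numeric(1))
  expect_equal(sc$d, want, tolerance = 1e-8)
  # and the same through the solver-free JSON round trip
  path <- withr::local_tempfile(fileext = ".json")
  svm_save(model, path)
  reloaded <- svm_load(path)
  expect_null(reloaded$fit)
  sc2 <- svm_score(reloaded, feats)
  expect_equal(sc2$d, sc$d, tolerance = 1e-8)
})

test_that("a feature at the midpoint of two symmetric classes ties to F with a warning", {
  feats <- make_toy_features(n_per_class = 3, bins = 8, bin_m = 2, bin_f = 6)
  model <- svm_train(feats, gamma = 1, cost = 1)
  mid <- feats[1, ]
  fcols <- finsexer:::.feature_columns(feats)
  mid[, fcols] <- as.list((as.numeric(feats[1, fcols]) + as.numeric(feats[4, fcols])) / 2)
  expect_warning(sc <- svm_score(model, mid), "tie")
  expect_equal(sc$d, 0)
  expect_equal(sc$predicted_sex, "F")
})

test_that("shuffled labels give chance-level cross-validated accuracy", {
  co <- simulate_cohort(sim_config(n_per_cell = 25, image_size = c(64, 64), seed = 31))
  feats <- fin_features(co, bins = 16)
  set.seed(99)
  accs <- vapply(1:20, function(r) {
    shuffled <- feats
    shuffled$true_sex <- sample(feats$true_sex)
    svm_cv(shuffled, folds = 5, seed = r)$accuracy
  }, numeric(1))
  # binomial SE at p = 0.5, n = 100, averaged over 20 repeats
  se <- sqrt(0.25 / 100) / sqrt(20)
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.02)
})

test_that("z-transform matches the closed form with the population denominator", {
  sc <- tibble::tibble(id = c("a", "b", "c"), s_male = 0, s_female = 0,
                       d = c(1, 2, 3), predicted_sex = "M")
  class(sc) <- c("sex_scores", class(sc))
  z <- add_intensity(sc)$z
  expect_equal(z, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
})

test_that("z is location-invariant, order-preserving and fails on zero variance", {
  set.seed(12)
  sc <- tibble::tibble(id = letters[1:10], s_male = 0, s_female = 0,
                       d = rnorm(10), predicted_sex = "M")
  class(sc) <- c("sex_scores", class(sc))
  z1 <- add_intensity(sc)$z
  sc2 <- sc; sc2$d <- sc$d + 7
  expect_equal(add_intensity(sc2)$z, z1, tolerance = 1e-12)
  expect_identical(order(z1), order(sc$d))
  sc3 <- sc; sc3$d <- rep(1, 10)
  expect_error(add_intensity(sc3), "zero variance")
  # sample denominator flag
  zs <- add_intensity(sc, denominator = "sample")$z
  expect_equal(sd(zs), 1, tolerance = 1e-12)
})

test_that("intensity drops in attenuated treated males and drives misclassification", {
  # train on controls, score cohorts of increasing attenuation
  co <- simulate_cohort(sim_config(n_per_cell = 40, image_size = c(64, 64), seed = 41))
  feats <- fin_features(co, bins = 32)
  model <- svm_train(feats[co$group == "control", ])
  sc <- add_intensity(svm_score(model, feats))
  z_tm <- mean(sc$z[sc$group == "treatment" & sc$true_sex == "M"])
  z_cm <- mean(sc$z[sc$group == "control" & sc$true_sex == "M"])
  expect_lt(z_tm, z_cm)
  miss <- vapply(c(0, 7, 14, 21), function(a) {
    ct <- simulate_cohort(sim_config(n_per_cell = 40, image_size = c(64, 64),
                                     treatment_male_attenuation = a, seed = 43))
    st <- svm_score(model, fin_features(ct, bins = 32))
    tm <- st$group == "treatment" & st$true_sex == "M"
    mean(st$predicted_sex[tm] == "F")
  }, numeric(1))
  expect_true(all(diff(miss) >= 0))
  expect_gt(miss[4], miss[1])
})

test_that("z preserves the yellowness ordering among males under the default kernel", {
  # The decision value of a kernel machine compresses far from the margin,
  # so the within-sex ordering is preserved strongly but not perfectly;
  # the wide default kernel keeps the link monotone.
  co <- simulate_cohort(sim_config(n_per_cell = 50, image_size = c(64, 64),
                                   seed = 47))
  feats <- fin_features(co)
  model <- svm_train(feats)
  sc <- add_intensity(svm_score(model, feats))
  males <- co$true_sex == "M"
  rho <- cor(sc$z[males], co$true_fin_b[males], method = "spearman")
  expect_gt(rho, 0.55)
  # and across the whole cohort the link is very strong (sex gap included)
  rho_all <- cor(sc$z, co$true_fin_b, method = "spearman")
  expect_gt(rho_all, 0.85)
})
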