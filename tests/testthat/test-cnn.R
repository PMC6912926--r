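# Unit properties of the network machinery on small geometries; the
# training-performance checks live in the acceptance suite.

test_that("configurations are validated", {
  expect_error(cnn_config(input_size = c(16, 64)), ">= 32")
  expect_error(cnn_config(kernel_size = 4), "odd")
  expect_error(cnn_config(stem_filters = 64, stages = list(c(32L, 1L))), "widths")
  expect_error(cnn_config(stages = list(c(64L, 1L), c(32L, 1L))), "widths")
})

test_that("forward pass emits a probability vector and is seed-deterministic", {
  cfg <- cnn_config(input_size = c(32, 32), stem_filters = 4,
                    stages = list(c(4L, 1L), c(8L, 1L)), seed = 11)
  m1 <- cnn_build(cfg)
  m2 <- cnn_build(cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$head, m2$head)
  set.seed(1)
  x <- array(runif(32 * 32 * 3 * 3), c(32, 32, 3, 3))
  fw <- finsexer:::.cnn_forward(m1, x, training = FALSE, keep = FALSE)
  expect_equal(rowSums(fw$probs), rep(1, 3), tolerance = 1e-6)
  expect_true(all(fw$probs >= 0))
  m3 <- cnn_build(cnn_config(input_size = c(32, 32), stem_filters = 4,
                             stages = list(c(4L, 1L), c(8L, 1L)), seed = 12))
  expect_false(identical(m1$params, m3$params))
})

test_that("parameter count matches a layer-by-layer hand count", {
  cfg <- cnn_config(input_size = c(32, 32), stem_filters = 4,
                    stages = list(c(4L, 1L), c(8L, 1L)), normalization = "batch")
  m <- cnn_build(cfg)
  # stem: 3x3x3 -> 4 conv (+bias) + bn scale/offset
  stem <- 3 * 3 * 3 * 4 + 4 + 2 * 4
  # stage-1 block: two 3x3x4 -> 4 convs + 2 bn, identity shortcut
  blk1 <- 2 * (3 * 3 * 4 * 4 + 4 + 2 * 4)
  # stage-2 block: conv1 3x3x4 -> 8 (stride 2), conv2 3x3x8 -> 8, 2 bn,
  # projection 1x1x4 -> 8 + bn
  blk2 <- (3 * 3 * 4 * 8 + 8 + 2 * 8) + (3 * 3 * 8 * 8 + 8 + 2 * 8) +
    (1 * 1 * 4 * 8 + 8 + 2 * 8)
  head <- 8 * 2 + 2
  expect_identical(cnn_n_params(m), stem + blk1 + blk2 + head)
})

test_that("a residual block with zero weights is the identity on nonnegative input", {
  cfg <- cnn_config(input_size = c(32, 32), stem_filters = 4,
                    stages = list(c(4L, 2L)), normalization = "none", seed = 2)
  m <- cnn_build(cfg)
  # unit 3 is the second stage-1 block: same width, stride 1, no projection
  unit <- m$units[[3]]
  expect_false(unit$project)
  par <- m$params[[3]]
  par$conv1$W[] <- 0; par$conv1$b[] <- 0
  par$conv2$W[] <- 0; par$conv2$b[] <- 0
  set.seed(3)
  x <- array(abs(rnorm(32 * 32 * 4 * 2)), c(32, 32, 4, 2))
  out <- finsexer:::.unit_forward(unit, par, m$stats[[3]], x, training = FALSE,
                                  keep = FALSE)$out
  expect_equal(out, x, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences through every layer type", {
  cfg <- cnn_config(input_size = c(32, 32), stem_filters = 3,
                    stages = list(c(3L, 1L), c(6L, 1L)), normalization = "batch",
                    seed = 31)
  m <- cnn_build(cfg)
  set.seed(32)
  x <- array(rnorm(32 * 32 * 3 * 4, 0, 0.3), c(32, 32, 3, 4))
  onehot <- cbind(c(1, 0, 1, 0), c(0, 1, 0, 1))
  lossfn <- function(model) {
    fw <- finsexer:::.cnn_forward(model, x, training = TRUE)
    -sum(log(rowSums(fw$probs * onehot) + 1e-12)) / 4
  }
  fw <- finsexer:::.cnn_forward(m, x, training = TRUE)
  bw <- finsexer:::.cnn_backward(m, fw, (fw$probs - onehot) / 4)
  eps <- 1e-5
  cases <- list(
    list(path = c(1, "conv", "W"), grad = bw$grads[[1]]$conv$W),
    list(path = c(2, "conv2", "W"), grad = bw$grads[[2]]$conv2$W),
    list(path = c(2, "bn1", "gamma"), grad = bw$grads[[2]]$bn1$gamma),
    list(path = c(3, "proj", "W"), grad = bw$grads[[3]]$proj$W),
    list(path = c(3, "bn2", "beta"), grad = bw$grads[[3]]$bn2$beta)
  )
  for (case in cases) {
    i <- as.integer(case$path[1]); a <- case$path[2]; b <- case$path[3]
    for (j in c(1L, 2L)) {
      m2 <- m
      m2$params[[i]][[a]][[b]][j] <- m2$params[[i]][[a]][[b]][j] + eps
      up <- lossfn(m2)
      m2$params[[i]][[a]][[b]][j] <- m2$params[[i]][[a]][[b]][j] - 2 * eps
      dn <- lossfn(m2)
      num <- (up - dn) / (2 * eps)
      # finite differences can straddle ReLU kinks; allow a few percent
      expect_lt(abs(case$grad[j] - num), 0.05 * abs(num) + 1e-6)
    }
  }
  # head (kink-free: the head is linear in its weights)
  m2 <- m; m2$head$W[1] <- m2$head$W[1] + eps; up <- lossfn(m2)
  m2$head$W[1] <- m2$head$W[1] - 2 * eps; dn <- lossfn(m2)
  expect_equal(bw$head$W[1], (up - dn) / (2 * eps), tolerance = 1e-4)
})

test_that("logits are invariant to whole-stride translation on constant background", {
  cfg <- cnn_config(input_size = c(64, 64), stem_filters = 4, stem_stride = 2,
                    stages = list(c(4L, 1L), c(8L, 1L)), normalization = "none",
                    seed = 41)
  m <- cnn_build(cfg)
  base <- array(0.2, c(64, 64, 3))
  blob <- array(0.9, c(10, 12, 3))
  img1 <- base; img1[21:30, 17:28, ] <- blob
  img2 <- base; img2[21:30, 25:36, ] <- blob  # shifted by 8 = total stride
  x <- array(c(img1, img2), c(64, 64, 3, 2)) - 0.5
  fw <- finsexer:::.cnn_forward(m, x, training = FALSE, keep = FALSE)
  # invariance is exact except for border cells whose receptive fields
  # reach the pattern; their contribution to the pooled logits is tiny
  expect_lt(max(abs(fw$logits[1, ] - fw$logits[2, ])), 1e-3)
  expect_gt(max(abs(fw$logits)), 1e-2)  # the comparison is not vacuous
})

test_that("training is reproducible, logged, and rejects single-class data", {
  co <- make_tiny_cohort(n_per_cell = 2, image_size = c(64, 64))
  cfg <- cnn_config(input_size = c(32, 32), stem_filters = 4, stem_stride = 2,
                    stages = list(c(4L, 1L)), epochs = 2, batch_size = 4,
                    seed = 51)
  m1 <- cnn_train(cnn_build(cfg), co)
  m2 <- cnn_train(cnn_build(cfg), co)
  expect_identical(m1$params, m2$params)
  expect_equal(nrow(m1$training_log), 2)
  males <- co[co$true_sex == "M", ]
  expect_error(cnn_train(cnn_build(cfg), males), "both sexes")
})

test_that("predictions are probabilities and survive a serialization round trip", {
  co <- make_tiny_cohort(n_per_cell = 2, image_size = c(64, 64))
  cfg <- cnn_config(input_size = c(32, 32), stem_filters = 4, stem_stride = 2,
                    stages = list(c(4L, 1L)), epochs = 2, batch_size = 4,
                    seed = 61)
  m <- cnn_train(cnn_build(cfg), co)
  p1 <- cnn_predict(m, co)
  expect_equal(p1$prob_male + p1$prob_female, rep(1, nrow(co)), tolerance = 1e-9)
  path <- withr::local_tempfile(fileext = ".json")
  cnn_save(m, path)
  m2 <- cnn_load(path)
  p2 <- cnn_predict(m2, co)
  expect_equal(p2$prob_male, p1$prob_male, tolerance = 1e-9)
  expect_identical(p2$predicted_sex, p1$predicted_sex)
  expect_equal(as.data.frame(m2$training_log), as.data.frame(m$training_log))
})
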