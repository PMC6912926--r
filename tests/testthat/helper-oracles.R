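# Independent reference implementations used as oracles. These are written
# deliberately naively (scalar loops, direct formulas) and share no code
# with the package internals they check.

# Scalar sRGB (D65) -> CIE L*a*b*, one pixel at a time, straight from the
# standard: gamma expansion, 3x3 XYZ matrix, f() cube-root transform.
oracle_rgb_to_lab <- function(r, g, b) {
  dec <- function(u) if (u <= 0.04045) u / 12.92 else ((u + 0.055) / 1.055)^2.4
  rl <- dec(r); gl <- dec(g); bl <- dec(b)
  X <- 0.4124564 * rl + 0.3575761 * gl + 0.1804375 * bl
  Y <- 0.2126729 * rl + 0.7151522 * gl + 0.0721750 * bl
  Z <- 0.0193339 * rl + 0.1191920 * gl + 0.9503041 * bl
  f <- function(t) {
    d <- 6 / 29
    if (t > d^3) t^(1 / 3) else t / (3 * d^2) + 4 / 29
  }
  fx <- f(X / 0.95047); fy <- f(Y / 1.00000); fz <- f(Z / 1.08883)
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# Brute-force per-channel histogram by looping over every pixel.
oracle_histogram <- function(lab, bins) {
  ranges <- list(c(0, 100), c(-128, 127), c(-128, 127))
  counts <- matrix(0, bins, 3)
  for (k in 1:3) {
    lo <- ranges[[k]][1]; hi <- ranges[[k]][2]
    width <- (hi - lo) / bins
    for (v in c(lab[, , k])) {
      v <- min(max(v, lo), hi)
      bin <- min(floor((v - lo) / width) + 1, bins)
      counts[bin, k] <- counts[bin, k] + 1
    }
  }
  counts
}

# Kernel-sum SVM decision value evaluated support vector by support vector.
oracle_svm_decision <- function(model, x) {
  total <- model$bias
  for (i in seq_len(nrow(model$support_vectors))) {
    sv <- model$support_vectors[i, ]
    total <- total + model$dual_weights[i] * exp(-model$gamma * sum((x - sv)^2))
  }
  total
}

# phi via the Pearson correlation of indicator vectors.
oracle_phi_cor <- function(n11, n12, n21, n22) {
  truth <- c(rep(1, n11 + n12), rep(0, n21 + n22))
  pred <- c(rep(1, n11), rep(0, n12), rep(1, n21), rep(0, n22))
  stats::cor(truth, pred)
}

# One-factor logit GLM by hand-rolled Newton-Raphson IRLS on the
# group-indicator design (intercept + dummy for group 2).
oracle_logit_irls <- function(successes, totals) {
  stopifnot(length(successes) == 2)
  X <- cbind(1, c(0, 1))
  y <- successes
  n <- totals
  beta <- c(0, 0)
  for (iter in 1:50) {
    eta <- as.vector(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- n * p * (1 - p)
    grad <- t(X) %*% (y - n * p)
    H <- t(X) %*% (X * W)
    step <- solve(H, grad)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < 1e-12) break
  }
  eta <- as.vector(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  V <- solve(t(X) %*% (X * (n * p * (1 - p))))
  # per-group logit means and their SEs via contrast vectors
  L <- rbind(c(1, 0), c(1, 1))
  list(eta = as.vector(L %*% beta),
       se = sqrt(diag(L %*% V %*% t(L))),
       pi = 1 / (1 + exp(-as.vector(L %*% beta))))
}

# LS-mean and SE for a contrast vector L on an lm fit: L b, sqrt(L V L').
oracle_lsmean_contrast <- function(fit, L) {
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  c(est = sum(L * b), se = sqrt(as.numeric(t(L) %*% V %*% L)))
}

# Deterministic little cohort for I/O tests.
make_tiny_cohort <- function(n_per_cell = 2, seed = 42, ...) {
  simulate_cohort(sim_config(n_per_cell = n_per_cell, seed = seed, ...))
}

# Well-separated single-bin histogram features for SVM toy cases:
# class M concentrated in bin `bin_m`, class F in bin `bin_f`.
make_toy_features <- function(n_per_class = 5, bins = 8, bin_m = 2, bin_f = 6) {
  mk <- function(bin) {
    f <- numeric(3 * bins)
    f[bin] <- 1; f[bins + bin] <- 1; f[2 * bins + bin] <- 1
    f
  }
  mat <- rbind(matrix(rep(mk(bin_m), n_per_class), nrow = n_per_class, byrow = TRUE),
               matrix(rep(mk(bin_f), n_per_class), nrow = n_per_class, byrow = TRUE))
  colnames(mat) <- paste0(rep(c("L", "a", "b"), each = bins), rep(seq_len(bins), 3))
  out <- tibble::tibble(id = sprintf("t%02d", seq_len(2 * n_per_class)),
                        true_sex = rep(c("M", "F"), each = n_per_class))
  dplyr::bind_cols(out, tibble::as_tibble(mat))
}

# Draw data from the final intensity model
#   z = mu + a[group] + b[sex] + ab + b1 * xc + b2 * male * xc + noise
# for ANCOVA recovery tests; xc is the centered covariate.
gen_ancova_data <- function(n_per_cell, mu = 0, a_trt = -0.4, b_male = 0.9,
                            ab = -0.6, b1 = 1, b2 = 5, sigma = 0.6,
                            x_mean = 0.4, x_sd = 0.07) {
  cells <- expand.grid(group = c("control", "treatment"), sex = c("F", "M"),
                       stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(group = cells$group[i], sex = cells$sex[i],
               body_weight_g = stats::rnorm(n_per_cell, x_mean, x_sd))
  }))
  xc <- rows$body_weight_g - mean(rows$body_weight_g)
  male <- as.numeric(rows$sex == "M")
  trt <- as.numeric(rows$group == "treatment")
  rows$z <- mu + a_trt * (trt - 0.5) + b_male * (male - 0.5) +
    ab * (trt - 0.5) * (male - 0.5) +
    b1 * xc + b2 * male * xc + stats::rnorm(nrow(rows), 0, sigma)
  rows$id <- sprintf("s%04d", seq_len(nrow(rows)))
  rows
}
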