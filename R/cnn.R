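# Residual convolutional network for whole-body sex classification,
# implemented directly on BLAS matrix products: im2col convolution, batch
# normalization, ReLU, residual blocks with identity shortcuts (1x1
# strided projections where widths change), global mean pooling and a
# 2-unit softmax head, trained with Adam on the cross-entropy.
#
# Tensor layout: activations are [H, W, C, N] arrays; convolution weights
# are [k*k*Cin, Cout] matrices whose rows follow (di fastest, dj, channel),
# matching the precomputed im2col index matrices cached per layer.

#' CNN configuration
#'
#' The default geometry is a 255 x 255 x 3 input, a 96-filter 3 x 3 stem,
#' and three residual stages widening 96 -> 192 -> 384 with stride-2
#' transitions, global mean pooling and a 2-unit softmax. [cnn_config_small()]
#' gives the desk-scale geometry used throughout the test-suite examples.
#'
#' @param input_size `(height, width)`, each >= 32.
#' @param stem_filters Filters in the stem convolution.
#' @param stem_stride Stride of the stem convolution (1 keeps full
#'   resolution; 2 halves it before the residual stages, the desk-scale
#'   default).
#' @param stages List of `c(filters, blocks)` per residual stage; stages
#'   after the first open with a stride-2 downsampling block. Filters must
#'   be nondecreasing.
#' @param kernel_size Odd convolution kernel size (default 3).
#' @param normalization `"batch"` or `"none"`.
#' @param epochs,batch_size,learning_rate Training hyperparameters (Adam).
#' @param weight_decay Decoupled L2 penalty applied to convolution and
#'   dense weight matrices at each update (normalization scales and biases
#'   are exempt).
#' @param augment_noise SD of fresh Gaussian pixel noise (standardized
#'   input units) added to each training presentation; 0 disables. Noise
#'   augmentation stops the network from memorizing the pixel noise of
#'   individual training images.
#' @param seed Seed for weight initialization and data order.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(input_size = c(255L, 255L),
                       stem_filters = 96L,
                       stem_stride = 1L,
                       stages = list(c(96L, 2L), c(192L, 2L), c(384L, 2L)),
                       kernel_size = 3L,
                       normalization = c("batch", "none"),
                       epochs = 20L, batch_size = 32L, learning_rate = 1e-3,
                       weight_decay = 1e-3, augment_noise = 0, seed = 1L) {
  normalization <- match.arg(normalization)
  input_size <- as.integer(input_size)
  if (length(input_size) != 2L || any(input_size < 32L)) {
    stop("`input_size` must be (height, width), both >= 32", call. = FALSE)
  }
  if (kernel_size %% 2L != 1L) stop("`kernel_size` must be odd", call. = FALSE)
  widths <- vapply(stages, function(s) as.integer(s[1]), integer(1))
  if (any(diff(widths) < 0L) || stem_filters > widths[1]) {
    stop("stage widths must be nondecreasing and >= stem_filters", call. = FALSE)
  }
  structure(list(input_size = input_size, channels = 3L,
                 stem_filters = as.integer(stem_filters),
                 stem_stride = as.integer(stem_stride),
                 stages = lapply(stages, as.integer),
                 kernel_size = as.integer(kernel_size),
                 normalization = normalization,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 augment_noise = augment_noise, seed = as.integer(seed)),
            class = "cnn_config")
}

#' @rdname cnn_config
#' @param ... Overrides passed to [cnn_config()].
#' @export
cnn_config_small <- function(...) {
  defaults <- list(input_size = c(64L, 64L), stem_filters = 16L,
                   stem_stride = 2L,
                   stages = list(c(16L, 1L), c(32L, 1L), c(64L, 1L)),
                   epochs = 20L, batch_size = 20L, learning_rate = 1e-2)
  do.call(cnn_config, utils::modifyList(defaults, list(...)))
}

# ---- im2col geometry -------------------------------------------------------

# Patch-gather indices for one image are computed once per layer; the
# batch-expanded gather and (ordered, run-length grouped) scatter indices
# are derived lazily per batch size and memoized in the geometry's
# environment, so convolution is a single BLAS product per chunk of images
# and its backward scatter is a cumsum over a presorted index run.

.conv_chunk_elems <- 8e6  # cap on gather-matrix elements per chunk

.conv_geom <- function(Hin, Win, Cin, k, stride) {
  pad <- if (k > 1L) (k - 1L) %/% 2L else 0L
  Hp <- Hin + 2L * pad
  Wp <- Win + 2L * pad
  Hout <- (Hp - k) %/% stride + 1L
  Wout <- (Wp - k) %/% stride + 1L
  oi <- seq.int(1L, by = stride, length.out = Hout)
  oj <- seq.int(1L, by = stride, length.out = Wout)
  base <- rep(oi, times = Wout) + (rep(oj, each = Hout) - 1L) * Hp
  di <- rep(0:(k - 1L), times = k * Cin)
  dj <- rep(rep(0:(k - 1L), each = k), times = Cin)
  ch <- rep(0:(Cin - 1L), each = k * k)
  offs <- di + dj * Hp + ch * Hp * Wp
  idx <- outer(as.integer(base), as.integer(offs), "+")
  storage.mode(idx) <- "integer"
  kk <- k * k * Cin
  chunk <- max(1L, as.integer(.conv_chunk_elems / (Hout * Wout * kk)))
  list(Hin = Hin, Win = Win, Cin = Cin, k = k, stride = stride, pad = pad,
       Hp = Hp, Wp = Wp, Hout = Hout, Wout = Wout, idx = idx,
       chunk = chunk, cache = new.env(parent = emptyenv()))
}

# batch-expanded indices for g images: gather matrix plus scatter grouping
.batch_idx <- function(geom, g) {
  key <- as.character(g)
  hit <- geom$cache[[key]]
  if (!is.null(hit)) return(hit)
  hw <- geom$Hout * geom$Wout
  npad <- geom$Hp * geom$Wp * geom$Cin
  idx_b <- geom$idx[rep(seq_len(hw), times = g), , drop = FALSE] +
    rep.int((seq_len(g) - 1L) * npad, rep.int(hw, g))
  v <- as.vector(idx_b)
  ord <- order(v)
  sv <- v[ord]
  ge <- which(c(sv[-1L] != sv[-length(sv)], TRUE))
  uidx <- sv[ge]
  out <- list(idx_b = idx_b, ord = ord, ge = ge, uidx = uidx)
  geom$cache[[key]] <- out
  out
}

.conv_init <- function(geom, Cout) {
  fan_in <- geom$k * geom$k * geom$Cin
  list(W = matrix(stats::rnorm(fan_in * Cout, 0, sqrt(2 / fan_in)), fan_in, Cout),
       b = numeric(Cout))
}

.pad_batch <- function(x, geom) {
  if (geom$pad == 0L) return(x)
  g <- dim(x)[4]
  xp <- array(0, c(geom$Hp, geom$Wp, geom$Cin, g))
  xp[geom$pad + seq_len(geom$Hin), geom$pad + seq_len(geom$Win), , ] <- x
  xp
}

# x: [H, W, C, N] -> list(out = [Hout, Wout, Cout, N], cols = per-chunk gather)
.conv_fw <- function(x, par, geom, keep_cols = TRUE) {
  n <- dim(x)[4]
  Cout <- ncol(par$W)
  hw <- geom$Hout * geom$Wout
  out <- array(0, c(geom$Hout, geom$Wout, Cout, n))
  starts <- seq(1L, n, by = geom$chunk)
  cols <- if (keep_cols) vector("list", length(starts)) else NULL
  for (ci in seq_along(starts)) {
    imgs <- starts[ci]:min(starts[ci] + geom$chunk - 1L, n)
    g <- length(imgs)
    xp <- .pad_batch(x[, , , imgs, drop = FALSE], geom)
    bi <- .batch_idx(geom, g)
    Xcol <- matrix(xp[as.vector(bi$idx_b)], nrow = hw * g)
    y <- Xcol %*% par$W
    y <- y + rep(par$b, each = hw * g)
    out[, , , imgs] <- aperm(array(y, c(hw, g, Cout)), c(1, 3, 2))
    if (keep_cols) cols[[ci]] <- Xcol
  }
  list(out = out, cols = cols)
}

.conv_bw <- function(dout, cache_cols, par, geom) {
  n <- dim(dout)[4]
  Cout <- ncol(par$W)
  hw <- geom$Hout * geom$Wout
  dW <- matrix(0, nrow(par$W), Cout)
  db <- numeric(Cout)
  dx <- array(0, c(geom$Hin, geom$Win, geom$Cin, n))
  npad <- geom$Hp * geom$Wp * geom$Cin
  starts <- seq(1L, n, by = geom$chunk)
  keep_rows <- if (geom$pad > 0L) {
    outer(geom$pad + seq_len(geom$Hin), (geom$pad + seq_len(geom$Win) - 1L) * geom$Hp, "+")
  } else NULL
  for (ci in seq_along(starts)) {
    imgs <- starts[ci]:min(starts[ci] + geom$chunk - 1L, n)
    g <- length(imgs)
    # rows: output pixel fastest, then image; columns: filter
    dy <- matrix(aperm(dout[, , , imgs, drop = FALSE], c(1, 2, 4, 3)),
                 nrow = hw * g, ncol = Cout)
    Xcol <- cache_cols[[ci]]
    dW <- dW + crossprod(Xcol, dy)
    db <- db + colSums(dy)
    dXcol <- dy %*% t(par$W)
    bi <- .batch_idx(geom, g)
    s <- cumsum(as.vector(dXcol)[bi$ord])
    sums <- s[bi$ge] - c(0, s[bi$ge[-length(bi$ge)]])
    dxp <- numeric(npad * g)
    dxp[bi$uidx] <- sums
    if (geom$pad > 0L) {
      dxp <- array(dxp, c(geom$Hp * geom$Wp, geom$Cin, g))
      dx[, , , imgs] <- array(dxp[as.vector(keep_rows), , ],
                              c(geom$Hin, geom$Win, geom$Cin, g))
    } else {
      dx[, , , imgs] <- array(dxp, c(geom$Hin, geom$Win, geom$Cin, g))
    }
  }
  list(dx = dx, dW = dW, db = db)
}

# ---- batch normalization ---------------------------------------------------

.bn_init <- function(C) {
  list(par = list(gamma = rep(1, C), beta = numeric(C)),
       stats = list(mean = numeric(C), var = rep(1, C), n = 0))
}

.bn_eps <- 1e-5

# Channel statistics without transposes: an [H, W, C, N] array viewed as an
# (H*W) x (C*N) matrix has channel varying fastest over columns, so
# per-(channel, image) column sums collapse to per-channel sums with one
# rowSums over a C x N matrix, and per-channel parameters broadcast with
# rep(par, times = N).

.bn_colstat <- function(m, C, N) {
  rowSums(matrix(colSums(m), C, N))
}

.bn_fw <- function(x, par, stats, training) {
  d <- dim(x)
  C <- d[3]; N <- d[4]
  hw <- d[1] * d[2]
  m <- matrix(x, hw, C * N)
  nr <- hw * N
  if (training) {
    mu <- .bn_colstat(m, C, N) / nr
    v <- .bn_colstat(m^2, C, N) / nr - mu^2
    momentum <- 0.9
    stats$mean <- momentum * stats$mean + (1 - momentum) * mu
    stats$var <- momentum * stats$var + (1 - momentum) * v
    stats$n <- stats$n + 1
  } else {
    denom <- if (stats$n > 0) 1 - 0.9^stats$n else 1
    mu <- stats$mean / denom
    v <- stats$var / denom
  }
  inv_sd <- 1 / sqrt(v + .bn_eps)
  bc <- function(vals) rep(rep(vals, times = N), each = hw)
  xhat <- (m - bc(mu)) * bc(inv_sd)
  y <- xhat * bc(par$gamma) + bc(par$beta)
  list(out = array(y, d),
       cache = list(xhat = xhat, inv_sd = inv_sd, d = d),
       stats = stats)
}

.bn_bw <- function(dout, cache, par) {
  d <- cache$d
  C <- d[3]; N <- d[4]
  hw <- d[1] * d[2]
  nr <- hw * N
  dy <- matrix(dout, hw, C * N)
  xhat <- cache$xhat
  bc <- function(vals) rep(rep(vals, times = N), each = hw)
  dgamma <- .bn_colstat(dy * xhat, C, N)
  dbeta <- .bn_colstat(dy, C, N)
  dxhat <- dy * bc(par$gamma)
  t1 <- dxhat - bc(.bn_colstat(dxhat, C, N) / nr)
  t2 <- xhat * bc(.bn_colstat(dxhat * xhat, C, N) / nr)
  dx_m <- (t1 - t2) * bc(cache$inv_sd)
  list(dx = array(dx_m, d), dgamma = dgamma, dbeta = dbeta)
}

# ---- units -----------------------------------------------------------------

# A "stem" unit: conv -> (bn) -> relu.
# A "block" unit: conv1 -> (bn1) -> relu -> conv2 -> (bn2); shortcut is the
# identity or a 1x1 strided projection (+ bn); output relu(main + shortcut).

.build_units <- function(config) {
  H <- config$input_size[1]; W <- config$input_size[2]; C <- config$channels
  k <- config$kernel_size
  units <- list()
  params <- list()
  stats <- list()
  add <- function(u, p, s) {
    units[[length(units) + 1L]] <<- u
    params[[length(params) + 1L]] <<- p
    stats[[length(stats) + 1L]] <<- s
  }
  use_bn <- config$normalization == "batch"

  g <- .conv_geom(H, W, C, k, if (is.null(config$stem_stride)) 1L else config$stem_stride)
  p <- list(conv = .conv_init(g, config$stem_filters))
  s <- list()
  if (use_bn) { b <- .bn_init(config$stem_filters); p$bn <- b$par; s$bn <- b$stats }
  add(list(type = "stem", geom = g, use_bn = use_bn), p, s)
  H <- g$Hout; W <- g$Wout
  C <- config$stem_filters

  for (si in seq_along(config$stages)) {
    width <- config$stages[[si]][1]
    blocks <- config$stages[[si]][2]
    for (bi in seq_len(blocks)) {
      stride <- if (si > 1L && bi == 1L) 2L else 1L
      project <- stride != 1L || width != C
      g1 <- .conv_geom(H, W, C, k, stride)
      g2 <- .conv_geom(g1$Hout, g1$Wout, width, k, 1L)
      p <- list(conv1 = .conv_init(g1, width), conv2 = .conv_init(g2, width))
      s <- list()
      if (use_bn) {
        b1 <- .bn_init(width); b2 <- .bn_init(width)
        p$bn1 <- b1$par; p$bn2 <- b2$par
        s$bn1 <- b1$stats; s$bn2 <- b2$stats
      }
      gp <- NULL
      if (project) {
        gp <- .conv_geom(H, W, C, 1L, stride)
        p$proj <- .conv_init(gp, width)
        if (use_bn) { bp <- .bn_init(width); p$proj_bn <- bp$par; s$proj_bn <- bp$stats }
      }
      add(list(type = "block", geom1 = g1, geom2 = g2, geom_proj = gp,
               project = project, use_bn = use_bn), p, s)
      H <- g1$Hout; W <- g1$Wout; C <- width
    }
  }
  list(units = units, params = params, stats = stats,
       out_dim = c(H, W, C))
}

#' Build a residual CNN sexer
#'
#' Instantiates the network of a [cnn_config()] with He-normal seeded
#' initialization. The same seed always gives identical initial weights.
#'
#' @param config A `cnn_config`.
#' @return An untrained `cnn_sexer`.
#' @export
cnn_build <- function(config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  old_seed <- .hold_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(config$seed)
  built <- .build_units(config)
  C <- built$out_dim[3]
  head <- list(W = matrix(stats::rnorm(C * 2L, 0, sqrt(2 / C)), C, 2L),
               b = numeric(2L))
  structure(list(config = config, units = built$units,
                 params = built$params, stats = built$stats,
                 head = head, out_dim = built$out_dim,
                 training_log = tibble::tibble(epoch = integer(), loss = numeric(),
                                               accuracy = numeric()),
                 trained = FALSE),
            class = "cnn_sexer")
}

.unit_forward <- function(unit, par, stats, x, training, keep = TRUE) {
  cache <- list()
  if (unit$type == "stem") {
    cv <- .conv_fw(x, par$conv, unit$geom, keep_cols = keep)
    z <- cv$out
    cache$cols <- cv$cols
    if (unit$use_bn) {
      bn <- .bn_fw(z, par$bn, stats$bn, training)
      z <- bn$out; cache$bn <- bn$cache; stats$bn <- bn$stats
    }
    cache$mask <- z > 0
    out <- z * cache$mask
  } else {
    cv1 <- .conv_fw(x, par$conv1, unit$geom1, keep_cols = keep)
    z1 <- cv1$out
    cache$cols1 <- cv1$cols
    if (unit$use_bn) {
      bn1 <- .bn_fw(z1, par$bn1, stats$bn1, training)
      z1 <- bn1$out; cache$bn1 <- bn1$cache; stats$bn1 <- bn1$stats
    }
    cache$mask1 <- z1 > 0
    a1 <- z1 * cache$mask1
    cv2 <- .conv_fw(a1, par$conv2, unit$geom2, keep_cols = keep)
    z2 <- cv2$out
    cache$cols2 <- cv2$cols
    if (unit$use_bn) {
      bn2 <- .bn_fw(z2, par$bn2, stats$bn2, training)
      z2 <- bn2$out; cache$bn2 <- bn2$cache; stats$bn2 <- bn2$stats
    }
    if (unit$project) {
      cvp <- .conv_fw(x, par$proj, unit$geom_proj, keep_cols = keep)
      sc <- cvp$out
      cache$colsp <- cvp$cols
      if (unit$use_bn) {
        bnp <- .bn_fw(sc, par$proj_bn, stats$proj_bn, training)
        sc <- bnp$out; cache$bnp <- bnp$cache; stats$proj_bn <- bnp$stats
      }
    } else {
      sc <- x
    }
    pre <- z2 + sc
    cache$mask <- pre > 0
    out <- pre * cache$mask
  }
  list(out = out, cache = cache, stats = stats)
}

.unit_backward <- function(unit, par, cache, dout) {
  grad <- list()
  if (unit$type == "stem") {
    dz <- dout * cache$mask
    if (unit$use_bn) {
      bw <- .bn_bw(dz, cache$bn, par$bn)
      grad$bn <- list(gamma = bw$dgamma, beta = bw$dbeta)
      dz <- bw$dx
    }
    cb <- .conv_bw(dz, cache$cols, par$conv, unit$geom)
    grad$conv <- list(W = cb$dW, b = cb$db)
    dx <- cb$dx
  } else {
    dpre <- dout * cache$mask
    # shortcut branch
    if (unit$project) {
      dsc <- dpre
      if (unit$use_bn) {
        bwp <- .bn_bw(dsc, cache$bnp, par$proj_bn)
        grad$proj_bn <- list(gamma = bwp$dgamma, beta = bwp$dbeta)
        dsc <- bwp$dx
      }
      cbp <- .conv_bw(dsc, cache$colsp, par$proj, unit$geom_proj)
      grad$proj <- list(W = cbp$dW, b = cbp$db)
      dx_short <- cbp$dx
    } else {
      dx_short <- dpre
    }
    # main branch
    dz2 <- dpre
    if (unit$use_bn) {
      bw2 <- .bn_bw(dz2, cache$bn2, par$bn2)
      grad$bn2 <- list(gamma = bw2$dgamma, beta = bw2$dbeta)
      dz2 <- bw2$dx
    }
    cb2 <- .conv_bw(dz2, cache$cols2, par$conv2, unit$geom2)
    grad$conv2 <- list(W = cb2$dW, b = cb2$db)
    da1 <- cb2$dx
    dz1 <- da1 * cache$mask1
    if (unit$use_bn) {
      bw1 <- .bn_bw(dz1, cache$bn1, par$bn1)
      grad$bn1 <- list(gamma = bw1$dgamma, beta = bw1$dbeta)
      dz1 <- bw1$dx
    }
    cb1 <- .conv_bw(dz1, cache$cols1, par$conv1, unit$geom1)
    grad$conv1 <- list(W = cb1$dW, b = cb1$db)
    dx <- cb1$dx + dx_short
  }
  list(dx = dx, grad = grad)
}

# Full forward pass. Returns probabilities, logits, per-unit caches and
# (possibly updated) BN statistics.
.cnn_forward <- function(model, x, training = FALSE, keep = training) {
  caches <- vector("list", length(model$units))
  for (i in seq_along(model$units)) {
    step <- .unit_forward(model$units[[i]], model$params[[i]], model$stats[[i]],
                          x, training, keep = keep)
    x <- step$out
    caches[[i]] <- step$cache
    model$stats[[i]] <- step$stats
  }
  d <- dim(x)
  hw <- d[1] * d[2]
  gap <- t(matrix(colSums(matrix(x, hw, d[3] * d[4])) / hw, d[3], d[4]))  # N x C
  logits <- sweep(gap %*% model$head$W, 2L, model$head$b, "+")
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  list(probs = probs, logits = logits, gap = gap, feat_dim = d,
       caches = caches, stats = model$stats, last = x)
}

.cnn_backward <- function(model, fw, dlogits) {
  grads <- vector("list", length(model$units))
  head_grad <- list(W = crossprod(fw$gap, dlogits), b = colSums(dlogits))
  dgap <- dlogits %*% t(model$head$W)          # N x C
  d <- fw$feat_dim
  dx <- array(rep(as.vector(t(dgap)), each = d[1] * d[2]) / (d[1] * d[2]), d)
  for (i in rev(seq_along(model$units))) {
    bw <- .unit_backward(model$units[[i]], model$params[[i]], fw$caches[[i]], dx)
    dx <- bw$dx
    grads[[i]] <- bw$grad
  }
  list(grads = grads, head = head_grad)
}

# Adam over nested parameter lists, with decoupled weight decay on the
# weight matrices (biases and normalization parameters are vectors and
# stay unpenalized).
.adam_update <- function(par, grad, m, v, lr, t, wd = 0,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.list(par)) {
    for (nm in names(grad)) {
      upd <- .adam_update(par[[nm]], grad[[nm]], m[[nm]], v[[nm]], lr, t, wd,
                          beta1, beta2, eps)
      par[[nm]] <- upd$par; m[[nm]] <- upd$m; v[[nm]] <- upd$v
    }
    list(par = par, m = m, v = v)
  } else {
    m <- beta1 * m + (1 - beta1) * grad
    v <- beta2 * v + (1 - beta2) * grad^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    new_par <- par - lr * mhat / (sqrt(vhat) + eps)
    if (wd > 0 && is.matrix(par)) new_par <- new_par - lr * wd * par
    list(par = new_par, m = m, v = v)
  }
}

.zeros_like <- function(x) {
  if (is.list(x)) lapply(x, .zeros_like) else x * 0
}

# Cohort images -> list of resized arrays, standardized per channel with
# the moments stored on the model (computed from the training cohort).
.cnn_inputs <- function(model, cohort) {
  size <- model$config$input_size
  raw <- lapply(cohort$image, function(img) resize_image(img / 255, size))
  norm <- model$input_norm
  if (is.null(norm)) norm <- list(mean = c(0.5, 0.5, 0.5), sd = c(1, 1, 1))
  lapply(raw, function(x) {
    for (k in 1:3) x[, , k] <- (x[, , k] - norm$mean[k]) / norm$sd[k]
    x
  })
}

.channel_moments <- function(cohort, size) {
  sums <- numeric(3); sqs <- numeric(3); n_px <- 0
  for (img in cohort$image) {
    x <- resize_image(img / 255, size)
    n_px <- n_px + prod(dim(x)[1:2])
    for (k in 1:3) {
      sums[k] <- sums[k] + sum(x[, , k])
      sqs[k] <- sqs[k] + sum(x[, , k]^2)
    }
  }
  m <- sums / n_px
  list(mean = m, sd = pmax(sqrt(sqs / n_px - m^2), 1e-6))
}

.assemble_batch <- function(inputs, idx) {
  d <- dim(inputs[[idx[1]]])
  x <- array(0, c(d, length(idx)))
  for (j in seq_along(idx)) x[, , , j] <- inputs[[idx[j]]]
  x
}

#' Train the CNN sexer
#'
#' Minibatch Adam on the softmax cross-entropy. Data order and weight
#' initialization are controlled by the config seed, so a training run is
#' reproducible on one machine.
#'
#' @param model A `cnn_sexer` from [cnn_build()].
#' @param cohort A `fish_cohort`; images are resized to the configured
#'   input size.
#' @param labels True sexes (`"M"`/`"F"`); defaults to `cohort$true_sex`.
#' @param verbose Print per-epoch loss/accuracy.
#' @param stop_accuracy Optional early stop: finish once the training
#'   accuracy reaches this value for three consecutive epochs (the grace
#'   period lets the normalization running statistics settle before
#'   inference).
#' @return The trained model; `$training_log` holds per-epoch loss and
#'   training accuracy.
#' @export
cnn_train <- function(model, cohort, labels = NULL, verbose = FALSE,
                      stop_accuracy = NULL) {
  stopifnot(inherits(model, "cnn_sexer"))
  if (is.null(labels)) labels <- cohort$true_sex
  y <- factor(as.character(labels), levels = c("M", "F"))
  if (nlevels(droplevels(y)) < 2L) {
    stop("both sexes must be present in the training labels", call. = FALSE)
  }
  cfg <- model$config
  if (is.null(model$input_norm)) {
    model$input_norm <- .channel_moments(cohort, cfg$input_size)
  }
  inputs <- .cnn_inputs(model, cohort)
  n <- length(inputs)
  onehot <- cbind(as.numeric(y == "M"), as.numeric(y == "F"))

  old_seed <- .hold_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(cfg$seed + 1L)

  opt <- list(m = .zeros_like(model$params), v = .zeros_like(model$params),
              mh = .zeros_like(model$head), vh = .zeros_like(model$head), t = 0L)
  # two-step decay: lr / 10 after 60% of the epochs, lr / 100 after 85%
  hits_in_a_row <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cfg$learning_rate *
      if (epoch > 0.85 * cfg$epochs) 0.01 else if (epoch > 0.6 * cfg$epochs) 0.1 else 1
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    tot_loss <- 0; tot_correct <- 0
    for (bidx in batches) {
      x <- .assemble_batch(inputs, bidx)
      aug <- if (is.null(cfg$augment_noise)) 0 else cfg$augment_noise
      if (aug > 0) x <- x + array(stats::rnorm(length(x), 0, aug), dim(x))
      fw <- .cnn_forward(model, x, training = TRUE)
      model$stats <- fw$stats
      p <- fw$probs
      yb <- onehot[bidx, , drop = FALSE]
      tot_loss <- tot_loss - sum(log(rowSums(p * yb) + 1e-12))
      tot_correct <- tot_correct + sum(max.col(p) == max.col(yb))
      dlogits <- (p - yb) / length(bidx)
      bw <- .cnn_backward(model, fw, dlogits)
      opt$t <- opt$t + 1L
      wd <- if (is.null(cfg$weight_decay)) 0 else cfg$weight_decay
      upd <- .adam_update(model$params, bw$grads, opt$m, opt$v, lr, opt$t, wd)
      model$params <- upd$par; opt$m <- upd$m; opt$v <- upd$v
      updh <- .adam_update(model$head, bw$head, opt$mh, opt$vh, lr, opt$t, wd)
      model$head <- updh$par; opt$mh <- updh$m; opt$vh <- updh$v
    }
    log_row <- tibble::tibble(epoch = epoch, loss = tot_loss / n,
                              accuracy = tot_correct / n)
    model$training_log <- dplyr::bind_rows(model$training_log, log_row)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  acc %.3f", epoch,
                      log_row$loss, log_row$accuracy))
    }
    if (!is.null(stop_accuracy)) {
      hits_in_a_row <- if (log_row$accuracy >= stop_accuracy) hits_in_a_row + 1L else 0L
      if (hits_in_a_row >= 3L) break
    }
  }
  model$trained <- TRUE
  model
}

#' Predict sex with a trained CNN
#'
#' @param model A trained `cnn_sexer`.
#' @param cohort A `fish_cohort`.
#' @return Tibble `id`, `prob_male`, `prob_female`, `predicted_sex`
#'   (plus `group`/`true_sex` passthrough). `prob_male` and `prob_female`
#'   sum to one; an exact tie is called `F` with a warning.
#' @export
cnn_predict <- function(model, cohort) {
  stopifnot(inherits(model, "cnn_sexer"))
  inputs <- .cnn_inputs(model, cohort)
  n <- length(inputs)
  probs <- matrix(0, n, 2L)
  batch <- max(model$config$batch_size, 1L)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    x <- .assemble_batch(inputs, idx)
    fw <- .cnn_forward(model, x, training = FALSE, keep = FALSE)
    probs[idx, ] <- fw$probs
  }
  if (any(probs[, 1] == probs[, 2])) {
    warning(sum(probs[, 1] == probs[, 2]), " tie(s) at p = 0.5 classified as F",
            call. = FALSE)
  }
  out <- tibble::tibble(id = cohort$id,
                        prob_male = probs[, 1], prob_female = probs[, 2],
                        predicted_sex = ifelse(probs[, 1] > probs[, 2], "M", "F"))
  for (col in c("group", "true_sex")) {
    if (col %in% names(cohort)) out[[col]] <- cohort[[col]]
  }
  out
}

#' Number of trainable parameters
#'
#' @param model A `cnn_sexer`.
#' @return Integer parameter count over all convolutions, normalization
#'   scales/offsets and the dense head.
#' @export
cnn_n_params <- function(model) {
  count <- function(x) if (is.list(x)) sum(vapply(x, count, numeric(1))) else length(x)
  count(model$params) + count(model$head)
}

# ---- persistence -----------------------------------------------------------

.pack_tensors <- function(x) {
  if (is.list(x)) {
    lapply(x, .pack_tensors)
  } else if (is.matrix(x)) {
    list(.dim = dim(x), .data = as.vector(x))
  } else {
    list(.dim = length(x), .data = as.vector(x))
  }
}

.unpack_tensors <- function(x) {
  if (is.list(x) && identical(sort(names(x)), c(".data", ".dim"))) {
    d <- unlist(x$.dim)
    v <- as.numeric(unlist(x$.data))
    if (length(d) == 2L) matrix(v, d[1], d[2]) else v
  } else if (is.list(x)) {
    lapply(x, .unpack_tensors)
  } else {
    x
  }
}

#' Save / load a CNN sexer as JSON
#'
#' Weights, normalization statistics and the configuration are stored in
#' one self-contained JSON document (practical for desk-scale models).
#'
#' @param model A `cnn_sexer`.
#' @param path JSON file path.
#' @return `path` invisibly (save); a `cnn_sexer` (load).
#' @export
cnn_save <- function(model, path) {
  stopifnot(inherits(model, "cnn_sexer"))
  cfg <- unclass(model$config)
  doc <- list(type = "finsexer_cnn", config = cfg,
              params = .pack_tensors(model$params),
              head = .pack_tensors(model$head),
              stats = .pack_tensors(model$stats),
              input_norm = if (!is.null(model$input_norm)) .pack_tensors(model$input_norm),
              trained = model$trained,
              training_log = as.data.frame(model$training_log))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname cnn_save
#' @export
cnn_load <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$type, "finsexer_cnn")) stop("not a finsexer CNN file", call. = FALSE)
  cfg <- doc$config
  config <- cnn_config(input_size = unlist(cfg$input_size),
                       stem_filters = cfg$stem_filters,
                       stem_stride = if (is.null(cfg$stem_stride)) 1L else cfg$stem_stride,
                       stages = lapply(cfg$stages, unlist),
                       kernel_size = cfg$kernel_size,
                       normalization = cfg$normalization,
                       epochs = cfg$epochs, batch_size = cfg$batch_size,
                       learning_rate = cfg$learning_rate,
                       weight_decay = if (is.null(cfg$weight_decay)) 0 else cfg$weight_decay,
                       augment_noise = if (is.null(cfg$augment_noise)) 0 else cfg$augment_noise,
                       seed = cfg$seed)
  model <- cnn_build(config)
  model$params <- .unpack_tensors(doc$params)
  model$head <- .unpack_tensors(doc$head)
  model$stats <- .unpack_tensors(doc$stats)
  if (!is.null(doc$input_norm)) model$input_norm <- .unpack_tensors(doc$input_norm)
  model$trained <- isTRUE(doc$trained)
  lg <- doc$training_log
  if (length(lg) > 0) {
    model$training_log <- tibble::tibble(
      epoch = vapply(lg, function(r) as.integer(r$epoch), integer(1)),
      loss = vapply(lg, function(r) as.numeric(r$loss), numeric(1)),
      accuracy = vapply(lg, function(r) as.numeric(r$accuracy), numeric(1)))
  }
  model
}

#' @export
print.cnn_sexer <- function(x, ...) {
  cfg <- x$config
  cat("<cnn_sexer> residual CNN\n")
  cat(sprintf("  input %d x %d x 3, stem %d, stages %s, normalization: %s\n",
              cfg$input_size[1], cfg$input_size[2], cfg$stem_filters,
              paste(vapply(cfg$stages, function(s) paste0(s[1], "x", s[2]),
                           character(1)), collapse = " -> "),
              cfg$normalization))
  cat(sprintf("  parameters: %d   trained: %s\n", cnn_n_params(x), x$trained))
  invisible(x)
}
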