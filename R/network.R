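# Convolutional depth regressor: three conv/max-pool pairs (16/32/64 maps),
# a scaled dot-product self-attention block over the 64 final feature maps,
# a residual fully connected block, and a scalar head mapped to the 0-100
# depth range. Forward and backward passes are implemented directly on
# matrix operations (im2col convolutions); training is plain SGD.

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(S) {
  E <- exp(S - apply(S, 1L, max))
  E / rowSums(E)
}

# -- geometry helpers ---------------------------------------------------------

conv_out_side <- function(side, k, stride, pad) {
  num <- side + 2L * pad - k
  if (num %% stride != 0L)
    stopf("conv geometry: (%d + 2*%d - %d) not divisible by stride %d",
          side, pad, k, stride)
  num %/% stride + 1L
}

# linear indices of an im2col patch matrix into the zero-padded input vector
# (layout: row fastest, then column, then channel)
im2col_geometry <- function(H, W, C, k, stride = 1L, pad = 0L) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- conv_out_side(H, k, stride, pad)
  Wo <- conv_out_side(W, k, stride, pad)
  idx <- matrix(0L, Ho * Wo, k * k * C)
  pos <- 1L
  for (ch in seq_len(C)) for (cc in seq_len(k)) for (rr in seq_len(k)) {
    rows <- (seq_len(Ho) - 1L) * stride + rr
    cols <- (seq_len(Wo) - 1L) * stride + cc
    idx[, pos] <- as.vector(outer(rows, (cols - 1L) * Hp, "+")) +
      (ch - 1L) * Hp * Wp
    pos <- pos + 1L
  }
  # positions of the unpadded entries inside the padded vector
  pp <- as.vector(outer(seq_len(H) + pad,
                        (seq_len(W) + pad - 1L) * Hp, "+"))
  pad_pos <- as.vector(outer(pp, (seq_len(C) - 1L) * Hp * Wp, "+"))
  list(idx = idx, pad_pos = pad_pos, H = H, W = W, C = C,
       Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp, k = k)
}

# 2x2 (or m x m) pooling block rows: (Ho*Wo) x m^2 indices into (H*W)
pool_geometry <- function(H, W, m = 2L, stride = m) {
  Ho <- conv_out_side(H, m, stride, 0L)
  Wo <- conv_out_side(W, m, stride, 0L)
  idx <- matrix(0L, Ho * Wo, m * m)
  pos <- 1L
  for (cc in seq_len(m)) for (rr in seq_len(m)) {
    rows <- (seq_len(Ho) - 1L) * stride + rr
    cols <- (seq_len(Wo) - 1L) * stride + cc
    idx[, pos] <- as.vector(outer(rows, (cols - 1L) * H, "+"))
    pos <- pos + 1L
  }
  list(idx = idx, Ho = Ho, Wo = Wo, m = m)
}

# -- public layer operations --------------------------------------------------

#' 2-D convolution layer forward pass
#'
#' Cross-correlation of the input feature maps with a kernel bank, plus bias
#' and activation: each output value is `f(w . patch + d)`. The output
#' spatial side is `(in + 2*padding - k)/stride + 1` (error if not an
#' integer).
#'
#' @param input `H x W` matrix or `H x W x C` array of feature maps.
#' @param kernel `k x k` matrix (single input/output map) or
#'   `k x k x C_in x C_out` array.
#' @param bias per-output-map bias (recycled).
#' @param activation `"relu"` or `"linear"`.
#' @param stride,padding integers.
#' @return `H' x W'` matrix (single map) or `H' x W' x C_out` array.
#' @export
conv_forward <- function(input, kernel, bias = 0,
                         activation = c("relu", "linear"),
                         stride = 1L, padding = 0L) {
  activation <- match.arg(activation)
  if (is.matrix(input)) input <- array(input, c(dim(input), 1L))
  if (is.matrix(kernel)) kernel <- array(kernel, c(dim(kernel), 1L, 1L))
  dk <- dim(kernel)
  if (dk[1L] != dk[2L]) stopf("kernel must be square")
  if (dk[3L] != dim(input)[3L])
    stopf("kernel expects %d input maps, input has %d", dk[3L], dim(input)[3L])
  g <- im2col_geometry(dim(input)[1L], dim(input)[2L], dim(input)[3L],
                       dk[1L], as.integer(stride), as.integer(padding))
  Wm <- matrix(kernel, dk[1L] * dk[2L] * dk[3L], dk[4L])
  xp <- numeric(g$Hp * g$Wp * g$C)
  xp[g$pad_pos] <- as.vector(input)
  cols <- matrix(xp[g$idx], nrow(g$idx), ncol(g$idx))
  z <- sweep(cols %*% Wm, 2L, rep_len(bias, dk[4L]), "+")
  a <- if (activation == "relu") relu(z) else z
  out <- array(a, c(g$Ho, g$Wo, dk[4L]))
  if (dk[4L] == 1L) out[, , 1L] else out
}

#' Max-pooling layer
#'
#' Maximum over each `m x m` block; the default 2x2 window with stride 2
#' halves each spatial side.
#'
#' @param input `H x W` matrix or `H x W x C` array.
#' @param m pooling window side.
#' @param stride step between windows (defaults to `m`).
#' @return pooled matrix/array.
#' @export
max_pool <- function(input, m = 2L, stride = m) {
  if (is.matrix(input)) input <- array(input, c(dim(input), 1L))
  d <- dim(input)
  g <- pool_geometry(d[1L], d[2L], as.integer(m), as.integer(stride))
  A <- matrix(input, d[1L] * d[2L], d[3L])
  vals <- array(A[as.vector(g$idx), , drop = FALSE],
                c(nrow(g$idx), ncol(g$idx), d[3L]))
  out <- apply(vals, c(1L, 3L), max)
  out <- array(out, c(g$Ho, g$Wo, d[3L]))
  if (d[3L] == 1L) out[, , 1L] else out
}

#' Scaled dot-product self-attention
#'
#' Builds queries, keys and values as `Q = X W_q`, `K = X W_k`, `V = X W_v`,
#' forms row-stochastic weights `softmax(Q K^T / sqrt(d_k))` and returns
#' their convex combinations of the value vectors. With a single token the
#' output is exactly its value vector; with identical keys the weights are
#' uniform and the output is the mean value vector.
#'
#' @param X token matrix (`n_tokens x dim`).
#' @param W_q,W_k,W_v projection matrices (`dim x d_k`, `dim x d_k`,
#'   `dim x d_v`).
#' @param d_k key dimension used in the scaling (defaults to `ncol(W_k)`).
#' @return output token matrix (`n_tokens x d_v`) with the attention-weight
#'   matrix in `attr(, "weights")`.
#' @export
self_attention <- function(X, W_q, W_k, W_v, d_k = ncol(W_k)) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(W_q) || ncol(X) != nrow(W_k) || ncol(X) != nrow(W_v))
    stopf("projection matrices must have %d rows to match the tokens", ncol(X))
  if (ncol(W_q) != ncol(W_k))
    stopf("W_q and W_k must project to the same dimension")
  if (d_k <= 0) stopf("d_k must be positive")
  Q <- X %*% W_q; K <- X %*% W_k; V <- X %*% W_v
  A <- softmax_rows(Q %*% t(K) / sqrt(d_k))
  out <- A %*% V
  attr(out, "weights") <- A
  out
}

#' Residual (shortcut) block
#'
#' `H(x) = F(x) + x`: the identity path is added to the learned residual, so
#' a zero residual reproduces the input exactly.
#'
#' @param x input (vector, matrix or array).
#' @param f the residual transform, a function preserving `x`'s shape.
#' @return `f(x) + x`.
#' @export
residual_block <- function(x, f) {
  fx <- f(x)
  if (!identical(dim(fx) %||% length(fx), dim(x) %||% length(x)))
    stopf("residual transform changed the shape; a projection is required")
  fx + x
}

#' Linear autoencoder pretraining
#'
#' Fits encoder/decoder maps `y = f(x) = W_e^T x`, `x' = g(y)` by
#' alternating least squares on centered data: each half-step solves its
#' least-squares problem exactly, so the reconstruction error is
#' non-increasing and converges to the best rank-`code_dim` linear
#' reconstruction. Data lying exactly on a `code_dim`-dimensional linear
#' subspace is recovered with (numerically) zero error.
#'
#' @param x data matrix (`n x d`).
#' @param code_dim bottleneck width, `< d`.
#' @param epochs maximum alternations.
#' @param seed seed for the encoder initialization.
#' @return list with `encoder` (`d x code_dim`), `decoder`
#'   (`code_dim x d`), `center`, and the per-epoch `loss` curve.
#' @export
autoencoder_pretrain <- function(x, code_dim, epochs = 30L, seed = 1L) {
  x <- as.matrix(x)
  d <- ncol(x)
  if (code_dim >= d)
    stopf("code_dim (%d) must be smaller than the input dimension (%d)",
          code_dim, d)
  if (code_dim < 1L) stopf("code_dim must be >= 1")
  mu <- colMeans(x)
  Xc <- sweep(x, 2L, mu)
  W <- with_seed(seed, matrix(stats::rnorm(d * code_dim, 0, 1 / sqrt(d)),
                              d, code_dim))
  eps <- diag(1e-10, code_dim)
  loss <- numeric(0)
  D <- NULL
  for (e in seq_len(epochs)) {
    Z <- Xc %*% W
    D <- solve(crossprod(Z) + eps, crossprod(Z, Xc))   # decoder, k x d
    loss <- c(loss, mean((Xc - Z %*% D)^2))
    W <- t(D) %*% solve(tcrossprod(D) + eps)           # encoder given decoder
    if (e > 1L && loss[e - 1L] - loss[e] < 1e-14) break
  }
  Z <- Xc %*% W
  D <- solve(crossprod(Z) + eps, crossprod(Z, Xc))
  loss <- c(loss, mean((Xc - Z %*% D)^2))
  list(encoder = W, decoder = D, center = mu, loss = loss)
}

# -- network assembly ---------------------------------------------------------

#' Network configuration
#'
#' Defaults reproduce the reference architecture: three 3x3 stride-1
#' pad-1 convolutions with 16/32/64 maps, each followed by 2x2 stride-2 max
#' pooling (24 -> 12 -> 6 -> 3 spatial), then self-attention over the 64
#' three-by-three maps (each map one 9-d token), one residual fully
#' connected block on the 576-d flattened vector, and a scalar head scaled
#' to \[0, 100\] by `100 * sigmoid`. ReLU activations, mean squared error on
#' the 0-1 depth scale, minibatch SGD at learning rate 0.01 with momentum
#' 0.9 and light L2 weight decay (plain SGD is recovered with
#' `momentum = 0, weight_decay = 0`).
#'
#' @param lr learning rate (> 0).
#' @param momentum SGD momentum coefficient in \[0, 1); 0 gives plain SGD.
#' @param weight_decay L2 penalty coefficient added to every weight
#'   gradient (0 disables).
#' @param clip_norm global gradient-norm ceiling per update (0 disables).
#' @param d_k attention key dimension.
#' @param attention,residual logical switches for the two blocks.
#' @param head `"linear"` (sigmoid-scaled scalar) or `"softmax"` (softmax
#'   over `n_classes` discretized depth bins, prediction = probability-
#'   weighted bin center).
#' @param n_classes bins for the softmax head.
#' @param batch_size minibatch size for SGD.
#' @param checkpoint_every validation cadence in iterations.
#' @param accuracy_tol depth-unit tolerance defining prediction accuracy.
#' @param seed initialization / shuffling seed.
#' @return a `NetworkConfig` list.
#' @export
network_config <- function(lr = 0.01, momentum = 0.9, weight_decay = 0.003,
                           clip_norm = 5, d_k = 9L,
                           attention = TRUE, residual = TRUE,
                           head = c("linear", "softmax"),
                           n_classes = 20L, batch_size = 16L,
                           checkpoint_every = 30L, accuracy_tol = 10,
                           seed = 1L) {
  head <- match.arg(head)
  if (lr <= 0) stopf("learning rate must be > 0")
  if (momentum < 0 || momentum >= 1) stopf("momentum must be in [0, 1)")
  if (weight_decay < 0) stopf("weight_decay must be >= 0")
  if (clip_norm < 0) stopf("clip_norm must be >= 0")
  layers <- list(
    list(type = "conv", k = 3L, stride = 1L, pad = 1L, maps = 16L),
    list(type = "pool", k = 2L, stride = 2L),
    list(type = "conv", k = 3L, stride = 1L, pad = 1L, maps = 32L),
    list(type = "pool", k = 2L, stride = 2L),
    list(type = "conv", k = 3L, stride = 1L, pad = 1L, maps = 64L),
    list(type = "pool", k = 2L, stride = 2L)
  )
  structure(list(lr = lr, momentum = momentum,
                 weight_decay = weight_decay, clip_norm = clip_norm,
                 d_k = as.integer(d_k), attention = attention,
                 residual = residual, head = head,
                 n_classes = as.integer(n_classes),
                 batch_size = as.integer(batch_size),
                 checkpoint_every = as.integer(checkpoint_every),
                 accuracy_tol = accuracy_tol, seed = as.integer(seed),
                 layers = layers, input_side = 24L),
            class = "NetworkConfig")
}

#' Forward shape trace of the convolutional stack
#'
#' Propagates the spatial size and map count through the configured layers;
#' errors name the offending layer if sizes fail to propagate.
#'
#' @param config a [network_config()].
#' @return data frame with `layer`, `type`, `out_side`, `maps`, plus the
#'   flattened width as attribute `"flatten"`.
#' @export
forward_shapes <- function(config = network_config()) {
  side <- config$input_side; maps <- 1L
  rows <- list()
  for (i in seq_along(config$layers)) {
    ly <- config$layers[[i]]
    side <- tryCatch(
      if (ly$type == "conv") conv_out_side(side, ly$k, ly$stride, ly$pad)
      else conv_out_side(side, ly$k, ly$stride, 0L),
      error = function(e) stopf("layer %d (%s): %s", i, ly$type,
                                conditionMessage(e)))
    if (ly$type == "conv") maps <- ly$maps
    rows[[i]] <- data.frame(layer = i, type = ly$type,
                            out_side = side, maps = maps)
  }
  out <- do.call(rbind, rows)
  attr(out, "flatten") <- side * side * maps
  out
}

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

#' Build a depth-regression network
#'
#' Initializes all weights (He-scaled Gaussian, seeded from
#' `config$seed`) and precomputes the convolution/pooling index maps.
#'
#' @param config a [network_config()].
#' @return a `DepthNet` model object.
#' @export
build_network <- function(config = network_config()) {
  stopifnot(inherits(config, "NetworkConfig"))
  sh <- forward_shapes(config)
  flat <- attr(sh, "flatten")
  side <- config$input_side
  geom <- list(); params <- list()
  cur_side <- side; cur_maps <- 1L
  with_seed(config$seed, {
    for (i in seq_along(config$layers)) {
      ly <- config$layers[[i]]
      if (ly$type == "conv") {
        g <- im2col_geometry(cur_side, cur_side, cur_maps, ly$k,
                             ly$stride, ly$pad)
        geom[[i]] <- g
        fan_in <- ly$k * ly$k * cur_maps
        params[[paste0("W", i)]] <- he_init(fan_in, ly$maps, fan_in)
        params[[paste0("b", i)]] <- numeric(ly$maps)
        cur_side <- g$Ho; cur_maps <- ly$maps
      } else {
        geom[[i]] <- pool_geometry(cur_side, cur_side, ly$k, ly$stride)
        cur_side <- geom[[i]]$Ho
      }
    }
    tok_dim <- cur_side * cur_side            # 9: one token per feature map
    if (config$attention) {
      params$Wq <- he_init(tok_dim, config$d_k, tok_dim)
      params$Wk <- he_init(tok_dim, config$d_k, tok_dim)
      params$Wv <- he_init(tok_dim, tok_dim, tok_dim)
    }
    if (config$residual) {
      # small-gain residual start: the block begins near the identity
      params$Wr <- he_init(flat, flat, flat) * 0.1
      params$br <- numeric(flat)
    }
    out_dim <- if (config$head == "softmax") config$n_classes else 1L
    # small-gain head keeps the initial pre-activation near 0 (output at
    # mid-range) so the sigmoid/softmax never starts saturated
    params$Wo <- he_init(flat, out_dim, flat) * 0.1
    params$bo <- numeric(out_dim)
  })
  structure(list(config = config, params = params, geom = geom,
                 flat = flat, tok_dim = cur_side * cur_side,
                 n_tokens = cur_maps, side = side),
            class = "DepthNet")
}

#' @export
print.DepthNet <- function(x, ...) {
  cat(sprintf(paste0("<DepthNet> %dx%d input, conv 16/32/64, attention=%s, ",
                     "residual=%s, head=%s, flatten=%d\n"),
              x$side, x$side, x$config$attention, x$config$residual,
              x$config$head, x$flat))
  invisible(x)
}

bin_centers <- function(config) (seq_len(config$n_classes) - 0.5) *
  (100 / config$n_classes)

# forward pass of the conv/attention stack for one sample
# x_cols: spatial column-major vector of the 24x24 image
forward_single <- function(model, xvec, keep = FALSE) {
  cfg <- model$config; p <- model$params
  A <- matrix(xvec, ncol = 1L)              # (H*W) x C
  cache <- list()
  for (i in seq_along(cfg$layers)) {
    ly <- cfg$layers[[i]]; g <- model$geom[[i]]
    if (ly$type == "conv") {
      xp <- numeric(g$Hp * g$Wp * g$C)
      xp[g$pad_pos] <- as.vector(A)
      cols <- matrix(xp[g$idx], nrow(g$idx), ncol(g$idx))
      z <- sweep(cols %*% p[[paste0("W", i)]], 2L, p[[paste0("b", i)]], "+")
      A <- relu(z)
      if (keep) cache[[i]] <- list(cols = cols, mask = z > 0)
    } else {
      nIn <- nrow(A)
      vals <- array(A[as.vector(g$idx), , drop = FALSE],
                    c(nrow(g$idx), ncol(g$idx), ncol(A)))
      mx <- vals[, 1L, , drop = FALSE][, 1L, ]
      am <- matrix(1L, nrow(g$idx), ncol(A))
      for (jj in 2:ncol(g$idx)) {
        vj <- vals[, jj, , drop = FALSE][, 1L, ]
        upd <- vj > mx
        mx[upd] <- vj[upd]; am[upd] <- jj
      }
      mx <- matrix(mx, nrow(g$idx), ncol(A))
      if (keep) {
        rows_abs <- matrix(g$idx[cbind(rep(seq_len(nrow(g$idx)), ncol(A)),
                                       as.vector(am))],
                           nrow(g$idx), ncol(A))
        cache[[i]] <- list(argmax = rows_abs, n_in = nIn)
      }
      A <- mx
    }
  }
  X_tok <- t(A)                              # n_tokens x tok_dim
  if (cfg$attention) {
    Q <- X_tok %*% p$Wq; K <- X_tok %*% p$Wk; V <- X_tok %*% p$Wv
    Aw <- softmax_rows(Q %*% t(K) / sqrt(cfg$d_k))
    O <- Aw %*% V
    if (keep) cache$att <- list(X = X_tok, Q = Q, K = K, V = V, Aw = Aw)
  } else {
    O <- X_tok
  }
  h <- as.vector(t(O))                       # token-major flatten, length 576
  list(h = h, cache = cache)
}

# backward pass through attention + conv stack for one sample
backward_single <- function(model, dh, cache, grads) {
  cfg <- model$config; p <- model$params
  dO <- matrix(dh, model$n_tokens, model$tok_dim, byrow = TRUE)
  if (cfg$attention) {
    at <- cache$att
    dAw <- dO %*% t(at$V)
    dV <- t(at$Aw) %*% dO
    dS <- at$Aw * (dAw - rowSums(dAw * at$Aw))
    sc <- 1 / sqrt(cfg$d_k)
    dQ <- (dS %*% at$K) * sc
    dK <- (t(dS) %*% at$Q) * sc
    grads$Wq <- grads$Wq + t(at$X) %*% dQ
    grads$Wk <- grads$Wk + t(at$X) %*% dK
    grads$Wv <- grads$Wv + t(at$X) %*% dV
    dX <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  } else {
    dX <- dO
  }
  dA <- t(dX)                                # (H*W) x C at the stack top
  for (i in rev(seq_along(cfg$layers))) {
    ly <- cfg$layers[[i]]; g <- model$geom[[i]]
    if (ly$type == "pool") {
      cc <- cache[[i]]
      dIn <- matrix(0, cc$n_in, ncol(dA))
      dIn[cbind(as.vector(cc$argmax),
                rep(seq_len(ncol(dA)), each = nrow(dA)))] <- as.vector(dA)
      dA <- dIn
    } else {
      cc <- cache[[i]]
      dZ <- dA * cc$mask
      wi <- paste0("W", i); bi <- paste0("b", i)
      grads[[wi]] <- grads[[wi]] + crossprod(cc$cols, dZ)
      grads[[bi]] <- grads[[bi]] + colSums(dZ)
      dcols <- dZ %*% t(p[[wi]])
      sums <- rowsum(as.vector(dcols), group = as.vector(g$idx))
      dxp <- numeric(g$Hp * g$Wp * g$C)
      dxp[as.integer(rownames(sums))] <- sums
      dA <- matrix(dxp[g$pad_pos], ncol = g$C)
    }
  }
  grads
}

rowmajor_to_colmajor <- function(v, side) as.vector(matrix(v, side, side,
                                                           byrow = TRUE))

# full forward to flattened features for a batch (rows of x are row-major
# flattened images); returns B x flat matrix and per-sample caches
stack_forward <- function(model, x, keep = FALSE) {
  B <- nrow(x)
  H <- matrix(0, B, model$flat)
  caches <- if (keep) vector("list", B) else NULL
  for (b in seq_len(B)) {
    fs <- forward_single(model, rowmajor_to_colmajor(x[b, ], model$side),
                         keep = keep)
    H[b, ] <- fs$h
    if (keep) caches[[b]] <- fs$cache
  }
  list(H = H, caches = caches)
}

head_forward <- function(model, H, keep = FALSE) {
  cfg <- model$config; p <- model$params
  cache <- list(H_in = H)
  if (cfg$residual) {
    Zr <- sweep(H %*% p$Wr, 2L, p$br, "+")
    Fr <- relu(Zr)
    H2 <- H + Fr
    cache$mask_r <- Zr > 0
  } else H2 <- H
  cache$H2 <- H2
  Z <- sweep(H2 %*% p$Wo, 2L, p$bo, "+")
  if (cfg$head == "linear") {
    Pr <- sigmoid(Z)
    yhat <- 100 * as.vector(Pr)
    cache$P <- Pr
  } else {
    Pr <- softmax_rows(Z)
    yhat <- as.vector(Pr %*% bin_centers(cfg))
    cache$P <- Pr
  }
  if (keep) list(yhat = yhat, cache = cache) else list(yhat = yhat)
}

#' Predict depth for flattened samples
#'
#' @param model a [build_network()] model.
#' @param x matrix (`n x 576`) of row-major flattened 24x24 samples (a
#'   `SampleSet$x`).
#' @return numeric vector of depth predictions in \[0, 100\].
#' @export
predict_network <- function(model, x) {
  stopifnot(inherits(model, "DepthNet"))
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$flat)
    stopf("expected %d columns (flattened 24x24 samples)", model$flat)
  out <- numeric(nrow(x))
  bs <- 256L
  for (s in seq(1L, nrow(x), by = bs)) {
    e <- min(nrow(x), s + bs - 1L)
    H <- stack_forward(model, x[s:e, , drop = FALSE])$H
    out[s:e] <- head_forward(model, H)$yhat
  }
  out
}

zero_grads <- function(params) lapply(params, function(p)
  if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p)))

# loss and full gradient on a minibatch (rows of x row-major flattened)
network_loss_grad <- function(model, x, y) {
  cfg <- model$config
  B <- nrow(x)
  sf <- stack_forward(model, x, keep = TRUE)
  hf <- head_forward(model, sf$H, keep = TRUE)
  ca <- hf$cache
  y01 <- y / 100
  grads <- zero_grads(model$params)
  if (cfg$head == "linear") {
    P <- as.vector(ca$P)
    loss <- mean((P - y01)^2)
    dZ <- matrix(2 * (P - y01) * P * (1 - P) / B, ncol = 1L)
  } else {
    ctr <- bin_centers(cfg)
    cls <- pmin(cfg$n_classes, pmax(1L, ceiling(y / (100 / cfg$n_classes))))
    loss <- -mean(log(pmax(ca$P[cbind(seq_len(B), cls)], 1e-12)))
    dZ <- ca$P
    dZ[cbind(seq_len(B), cls)] <- dZ[cbind(seq_len(B), cls)] - 1
    dZ <- dZ / B
  }
  grads$Wo <- crossprod(ca$H2, dZ)
  grads$bo <- colSums(dZ)
  dH2 <- dZ %*% t(model$params$Wo)
  if (cfg$residual) {
    dZr <- dH2 * ca$mask_r
    grads$Wr <- crossprod(ca$H_in, dZr)
    grads$br <- colSums(dZr)
    dH <- dH2 + dZr %*% t(model$params$Wr)
  } else dH <- dH2
  for (b in seq_len(B))
    grads <- backward_single(model, dH[b, ], sf$caches[[b]], grads)
  list(loss = loss, grads = grads, yhat = hf$yhat)
}

sgd_update <- function(model, grads, velocity) {
  lr <- model$config$lr
  mu <- model$config$momentum %||% 0
  wd <- model$config$weight_decay %||% 0
  clip <- model$config$clip_norm %||% 0
  if (clip > 0) {
    gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
    if (is.finite(gnorm) && gnorm > clip)
      grads <- lapply(grads, function(g) g * (clip / gnorm))
  }
  for (nm in names(model$params)) {
    g <- grads[[nm]]
    if (wd > 0 && is.matrix(model$params[[nm]]))   # decay weights, not biases
      g <- g + wd * model$params[[nm]]
    velocity[[nm]] <- mu * velocity[[nm]] + g
    model$params[[nm]] <- model$params[[nm]] - lr * velocity[[nm]]
  }
  list(model = model, velocity = velocity)
}

#' Train a depth network by minibatch SGD
#'
#' Momentum SGD at the configured learning rate over
#' `schedule$periods x schedule$iters_per_period` iterations. When a
#' validation set is supplied, accuracy (within `accuracy_tol` depth units)
#' and RMSE are recorded every `checkpoint_every` iterations. Fully
#' deterministic for a fixed `config$seed`.
#'
#' @param train a `SampleSet` (see [build_samples()]).
#' @param config a [network_config()].
#' @param val optional validation `SampleSet`.
#' @param schedule list with `periods` and `iters_per_period`.
#' @param model optional pre-built/pre-trained model to continue from.
#' @return a `TrainResult`: list with `model`, `log` (one row per iteration:
#'   `iteration`, `period`, `loss`, and at checkpoints `val_accuracy`,
#'   `val_error`), and `checkpoints` (iteration numbers).
#' @export
train_network <- function(train, config = network_config(), val = NULL,
                          schedule = list(periods = 3L,
                                          iters_per_period = 200L),
                          model = NULL) {
  stopifnot(inherits(train, "SampleSet"))
  if (is.null(schedule$periods) || is.null(schedule$iters_per_period) ||
      schedule$periods < 1L || schedule$iters_per_period < 1L)
    stopf("schedule must give positive periods and iters_per_period")
  if (is.null(model)) model <- build_network(config)
  config <- model$config
  total <- schedule$periods * schedule$iters_per_period
  n <- nrow(train$x)
  B <- min(config$batch_size, n)
  log <- data.frame(iteration = seq_len(total),
                    period = rep(seq_len(schedule$periods),
                                 each = schedule$iters_per_period),
                    loss = NA_real_, val_accuracy = NA_real_,
                    val_error = NA_real_)
  checkpoints <- integer(0)
  velocity <- zero_grads(model$params)
  with_seed(child_seed(config$seed, 101L), {
    for (it in seq_len(total)) {
      idx <- sample.int(n, B)
      lg <- network_loss_grad(model, train$x[idx, , drop = FALSE],
                              train$y[idx])
      if (!is.finite(lg$loss))
        stopf("non-finite loss at iteration %d", it)
      upd <- sgd_update(model, lg$grads, velocity)
      model <- upd$model; velocity <- upd$velocity
      log$loss[it] <- lg$loss
      if (!is.null(val) && it %% config$checkpoint_every == 0L) {
        pv <- predict_network(model, val$x)
        log$val_accuracy[it] <- accuracy_within(val$y, pv,
                                                config$accuracy_tol)
        log$val_error[it] <- rmse(val$y, pv)
        checkpoints <- c(checkpoints, it)
      }
    }
  })
  structure(list(model = model, log = log, checkpoints = checkpoints,
                 schedule = schedule), class = "TrainResult")
}

#' Subject-level k-fold cross-validated training
#'
#' Splits subjects (never individual samples) into `folds` folds, trains one
#' network per fold on the remaining subjects and validates on the held-out
#' fold; the best and worst folds by final validation accuracy are
#' identified.
#'
#' @param samples a `SampleSet` covering all subjects.
#' @param config a [network_config()].
#' @param folds number of folds (default 5); must not exceed the number of
#'   subjects.
#' @param schedule as in [train_network()].
#' @return a `CVResult`: list of per-fold `TrainResult`s plus `best`,
#'   `worst` (fold indices) and `fold_subjects`.
#' @export
train_model <- function(samples, config = network_config(), folds = 5L,
                        schedule = list(periods = 3L,
                                        iters_per_period = 200L)) {
  subs <- unique(samples$subject_id)
  if (length(subs) < folds)
    stopf("%d subjects cannot form %d folds", length(subs), folds)
  assign_f <- with_seed(child_seed(config$seed, 55L),
                        sample(rep_len(seq_len(folds), length(subs))))
  names(assign_f) <- subs
  results <- vector("list", folds)
  final_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    hold <- subs[assign_f == f]
    tr <- subset_samples(samples, !(samples$subject_id %in% hold))
    va <- subset_samples(samples, samples$subject_id %in% hold)
    cfg_f <- config; cfg_f$seed <- child_seed(config$seed, 1000L + f)
    res <- train_network(tr, cfg_f, val = va, schedule = schedule)
    res$fold <- f
    pv <- predict_network(res$model, va$x)
    res$final_accuracy <- accuracy_within(va$y, pv, config$accuracy_tol)
    res$final_rmse <- rmse(va$y, pv)
    final_acc[f] <- res$final_accuracy
    results[[f]] <- res
  }
  structure(list(folds = results, best = which.max(final_acc),
                 worst = which.min(final_acc),
                 fold_subjects = split(subs, assign_f)),
            class = "CVResult")
}
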