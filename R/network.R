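#' Convolutional network configuration
#'
#' The feature extractor is a stack of blocks, each
#' `conv(kernel x kernel, stride s_i, same padding) -> batch norm -> ReLU ->
#' dropout`, followed by flattening to a per-sample feature vector consumed
#' by the fully connected label and domain heads. The full-scale
#' architecture uses 7 blocks with channels `[8,16,32,64,128,256,512]`,
#' strides `[1,2,2,2,2,2,2]` and a 7 x 7 kernel on 880 x 1650 x 3 inputs;
#' [desk_network_config()] provides a 5-block variant sized for CPU runs.
#'
#' @param input_h,input_w Input image size in pixels.
#' @param channels Integer vector of output channels per block.
#' @param strides Integer vector of strides per block (same length).
#' @param kernel Square kernel size.
#' @param dropout_p Dropout probability in `[0, 1)`.
#' @param seed Seed used by [init_params()] for weight initialization.
#' @return An object of class `network_config`; element `feature_dim` gives
#'   the flattened feature dimension F.
#' @export
#' @examples
#' network_config(880, 1650)$feature_dim  # 14 * 26 * 512
network_config <- function(input_h = 880, input_w = 1650,
                           channels = c(8, 16, 32, 64, 128, 256, 512),
                           strides = c(1, 2, 2, 2, 2, 2, 2),
                           kernel = 7L, dropout_p = 0.25, seed = 1L) {
  if (length(channels) != length(strides)) {
    abort("`channels` and `strides` must have equal length.")
  }
  if (any(strides < 1)) abort("`strides` must be >= 1.")
  if (dropout_p < 0 || dropout_p >= 1) abort("`dropout_p` must be in [0, 1).")
  h <- input_h; w <- input_w
  for (s in strides) { h <- ceiling(h / s); w <- ceiling(w / s) }
  structure(
    list(input_h = as.integer(input_h), input_w = as.integer(input_w),
         channels = as.integer(channels), strides = as.integer(strides),
         kernel = as.integer(kernel), dropout_p = dropout_p,
         seed = as.integer(seed),
         out_h = as.integer(h), out_w = as.integer(w),
         feature_dim = as.integer(h * w * channels[length(channels)])),
    class = "network_config"
  )
}

#' @rdname network_config
#' @export
desk_network_config <- function(input_h = 220, input_w = 412,
                                channels = c(8, 16, 32, 64),
                                strides = c(4, 2, 2, 2),
                                dropout_p = 0.25, seed = 1L) {
  network_config(input_h, input_w, channels = channels, strides = strides,
                 kernel = 7L, dropout_p = dropout_p, seed = seed)
}

#' Initialize model parameters
#'
#' Fan-in-scaled (He) random initialization for conv kernels, unit/zero
#' batch-norm affine parameters, zero-initialized running statistics, and
#' small random fully connected heads. Deterministic given `config$seed`.
#'
#' @param config A [network_config()].
#' @param seed Optional override of `config$seed`.
#' @return Nested parameter list (class `model_params`): `blocks` (conv `W`,
#'   `b`, batch-norm `gamma`, `beta`, `rm`, `rv`), `label` and `domain` heads
#'   (`w`, `b`).
#' @export
init_params <- function(config, seed = NULL) {
  k <- config$kernel
  with_seed(seed %||% config$seed, {
    cin <- 3L
    blocks <- vector("list", length(config$channels))
    for (i in seq_along(config$channels)) {
      cout <- config$channels[i]
      blocks[[i]] <- list(
        W = array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
                  dim = c(k, k, cin, cout)),
        b = numeric(cout),
        gamma = rep(1, cout), beta = numeric(cout),
        rm = numeric(cout), rv = rep(1, cout)
      )
      cin <- cout
    }
    f <- config$feature_dim
    structure(
      list(blocks = blocks,
           label = list(w = rnorm(f, sd = sqrt(1 / f)), b = 0),
           domain = list(w = rnorm(f, sd = sqrt(1 / f)), b = 0)),
      class = "model_params"
    )
  })
}

# ---- layer primitives --------------------------------------------------
# Activations are stored as (H, W, B, C) arrays so that matrix(x, ncol = C)
# exposes channels as columns; convolution is computed as a sum over the
# k x k kernel offsets of strided-slab x weight-slice matrix products
# (GEMM does the heavy lifting via BLAS).

same_pad <- function(len, k, s) {
  out <- ceiling(len / s)
  total <- max((out - 1L) * s + k - len, 0L)
  list(out = as.integer(out), before = as.integer(total %/% 2L),
       total = as.integer(total))
}

# The padded activation is kept as a 2D matrix (Hp, Wp*B*Cin): because R
# arrays are column-major, the strided k x k slab needed for each kernel
# offset is then a plain 2D row/column subset, which indexes far faster
# than generic 4D slicing. `colsel` enumerates, for one horizontal offset,
# the matrix columns of every (w_out, batch, channel) combination.
conv_forward <- function(x, W, b, stride) {
  d <- dim(x); h <- d[1]; w <- d[2]; bb <- d[3]; cin <- d[4]
  k <- dim(W)[1]; cout <- dim(W)[4]
  ph <- same_pad(h, k, stride); pw <- same_pad(w, k, stride)
  hp <- h + ph$total; wp <- w + pw$total
  xp <- matrix(0, hp, wp * bb * cin)
  src_cols <- as.vector(outer(pw$before + seq_len(w),
                              (seq_len(bb * cin) - 1L) * wp, `+`))
  xp[ph$before + seq_len(h), src_cols] <- x
  ho <- ph$out; wo <- pw$out
  n <- ho * wo * bb
  out <- matrix(0, n, cout)
  rows0 <- (seq_len(ho) - 1L) * stride
  cols0 <- (seq_len(wo) - 1L) * stride
  colsel0 <- as.vector(outer(cols0, (seq_len(bb * cin) - 1L) * wp, `+`))
  # All k horizontal offsets of one vertical offset are gathered in a single
  # subset + GEMM. The grouped slab's columns are ordered (wo, bb, cin, j),
  # i.e. flattened trailing dims (cin, j) with cin fastest; `wmat` is
  # permuted to match that row order.
  colsel_all <- as.vector(outer(colsel0, seq_len(k), `+`))
  wmat <- aperm(W, c(3, 2, 4, 1))          # (cin, j, cout, i)
  dim(wmat) <- c(cin * k, cout, k)
  for (i in seq_len(k)) {
    slab <- xp[i + rows0, colsel_all]
    dim(slab) <- c(n, cin * k)
    out <- out + slab %*% wmat[, , i]
  }
  out <- out + rep(b, each = n)
  dim(out) <- c(ho, wo, bb, cout)
  list(out = out, cache = list(xp = xp, dims = d, stride = stride, k = k,
                               ph = ph, pw = pw, W = W, wmat = wmat,
                               colsel0 = colsel0, colsel_all = colsel_all,
                               src_cols = src_cols, hp = hp, wp = wp))
}

conv_backward <- function(dout, cache) {
  xp <- cache$xp; W <- cache$W; k <- cache$k; stride <- cache$stride
  d <- cache$dims; h <- d[1]; w <- d[2]; bb <- d[3]; cin <- d[4]
  cout <- dim(W)[4]
  do_dim <- dim(dout); ho <- do_dim[1]; wo <- do_dim[2]
  n <- ho * wo * bb
  m <- dout; dim(m) <- c(n, cout)
  dW <- array(0, dim(W)); db <- colSums(m)
  dxp <- matrix(0, cache$hp, cache$wp * bb * cin)
  rows0 <- (seq_len(ho) - 1L) * stride
  colsel0 <- cache$colsel0
  for (i in seq_len(k)) {
    ri <- i + rows0
    slab <- xp[ri, cache$colsel_all]
    dim(slab) <- c(n, cin * k)
    dwi <- crossprod(slab, m)              # rows ordered (cin, j)
    dim(dwi) <- c(cin, k, cout)
    dW[i, , , ] <- aperm(dwi, c(2, 1, 3))
    dsl <- m %*% t(cache$wmat[, , i])      # (n, cin * k), j slowest
    dim(dsl) <- c(n * cin, k)
    # scatter-add per horizontal offset; offsets overlap when stride < k,
    # so they cannot be fused into one subassignment
    for (j in seq_len(k)) {
      cj <- colsel0 + j
      part <- dsl[, j]
      dim(part) <- c(ho, length(cj))
      dxp[ri, cj] <- dxp[ri, cj] + part
    }
  }
  dx <- dxp[cache$ph$before + seq_len(h), cache$src_cols]
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

bn_forward <- function(x, block, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); cc <- d[4]
  m <- x; dim(m) <- c(prod(d[1:3]), cc)
  if (training) {
    mu <- colMeans(m)
    xc <- sweep(m, 2L, mu)
    va <- colMeans(xc * xc)
    inv <- 1 / sqrt(va + eps)
    xhat <- sweep(xc, 2L, inv, `*`)
    rm <- (1 - momentum) * block$rm + momentum * mu
    rv <- (1 - momentum) * block$rv + momentum * va
  } else {
    inv <- 1 / sqrt(block$rv + eps)
    xhat <- sweep(sweep(m, 2L, block$rm), 2L, inv, `*`)
    rm <- block$rm; rv <- block$rv
  }
  out <- sweep(sweep(xhat, 2L, block$gamma, `*`), 2L, block$beta, `+`)
  dim(out) <- d
  list(out = out, rm = rm, rv = rv,
       cache = list(xhat = xhat, inv = inv, gamma = block$gamma, d = d,
                    training = training))
}

bn_backward <- function(dout, cache) {
  d <- cache$d; cc <- d[4]; n <- prod(d[1:3])
  m <- dout; dim(m) <- c(n, cc)
  dgamma <- colSums(m * cache$xhat)
  dbeta <- colSums(m)
  dxhat <- sweep(m, 2L, cache$gamma, `*`)
  if (cache$training) {
    t1 <- sweep(dxhat, 2L, colSums(dxhat) / n)
    t2 <- sweep(cache$xhat, 2L, colSums(dxhat * cache$xhat) / n, `*`)
    dx <- sweep(t1 - t2, 2L, cache$inv, `*`)
  } else {
    # evaluation mode: running statistics are constants, so the
    # normalization is a fixed per-channel affine map
    dx <- sweep(dxhat, 2L, cache$inv, `*`)
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' Feature extractor forward pass
#'
#' Runs the conv / batch-norm / ReLU / dropout stack and flattens the result
#' to one feature row per sample. Deterministic when `training = FALSE`
#' (dropout disabled, batch norm uses running statistics).
#'
#' @param x Input batch: `H x W x B x 3` array, or a list of `ecg_image`s /
#'   `H x W x 3` arrays (converted via [batch_array()]).
#' @param config A [network_config()].
#' @param params A [init_params()] parameter set.
#' @param training Logical; enables dropout and batch statistics.
#' @return A `B x F` feature matrix.
#' @export
feature_extractor_forward <- function(x, config, params, training = FALSE) {
  if (is.list(x)) x <- batch_array(x)
  fwd <- extractor_forward_internal(x, config, params, training)
  fwd$features
}

extractor_forward_internal <- function(x, config, params, training) {
  d <- dim(x)
  if (length(d) != 4L || d[1] != config$input_h || d[2] != config$input_w ||
      d[4] != 3L) {
    abort("input batch shape does not match the network configuration.")
  }
  caches <- vector("list", length(params$blocks))
  new_stats <- vector("list", length(params$blocks))
  for (i in seq_along(params$blocks)) {
    blk <- params$blocks[[i]]
    cf <- conv_forward(x, blk$W, blk$b, config$strides[i])
    bf <- bn_forward(cf$out, blk, training)
    relu_mask <- bf$out > 0
    out <- bf$out * relu_mask
    drop_mask <- NULL
    if (training && config$dropout_p > 0) {
      keep <- 1 - config$dropout_p
      drop_mask <- array((runif(length(out)) < keep) / keep, dim(out))
      out <- out * drop_mask
    }
    caches[[i]] <- list(conv = cf$cache, bn = bf$cache, relu = relu_mask,
                        drop = drop_mask)
    new_stats[[i]] <- list(rm = bf$rm, rv = bf$rv)
    x <- out
  }
  b <- d[3]
  feats <- aperm(x, c(3, 1, 2, 4))
  dim(feats) <- c(b, config$feature_dim)
  list(features = feats, caches = caches, new_stats = new_stats,
       out_dim = dim(x))
}

extractor_backward_internal <- function(dfeat, config, params, fwd) {
  od <- fwd$out_dim
  b <- od[3]
  dx <- array(dfeat, c(b, od[1], od[2], od[4]))
  dx <- aperm(dx, c(2, 3, 1, 4))
  grads <- vector("list", length(params$blocks))
  for (i in rev(seq_along(params$blocks))) {
    cch <- fwd$caches[[i]]
    if (!is.null(cch$drop)) dx <- dx * cch$drop
    dx <- dx * cch$relu
    bnb <- bn_backward(dx, cch$bn)
    cvb <- conv_backward(bnb$dx, cch$conv)
    grads[[i]] <- list(W = cvb$dW, b = cvb$db,
                       gamma = bnb$dgamma, beta = bnb$dbeta)
    dx <- cvb$dx
  }
  grads
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Fully connected heads
#'
#' Single linear layer `F -> 1` with a sigmoid, producing one probability
#' per sample. `label_head_forward()` scores disease presence;
#' `domain_head_forward()` scores which domain (clean = 0, captured = 1) an
#' image came from, operating on features routed through the gradient
#' reversal layer during training.
#'
#' @param features `B x F` feature matrix.
#' @param params A `model_params` set (the relevant head is used).
#' @return Numeric vector of B probabilities, strictly inside (0, 1).
#' @export
label_head_forward <- function(features, params) {
  p <- sigmoid(as.numeric(features %*% params$label$w + params$label$b))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' @rdname label_head_forward
#' @export
domain_head_forward <- function(features, params) {
  p <- sigmoid(as.numeric(features %*% params$domain$w + params$domain$b))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Gradient reversal layer
#'
#' `grad_reverse()` is the identity in the forward pass;
#' `grad_reverse_backward()` implements its custom backward rule, mapping an
#' upstream gradient `g` to `-lam * g`. During adversarial training the
#' reversal sits between the feature extractor and the domain head, so the
#' extractor is pushed to *erase* domain-discriminative information while
#' the domain head itself still learns normally.
#'
#' @param x Numeric array (passed through unchanged).
#' @param lam Non-negative reversal scale.
#' @return `grad_reverse()`: `x` exactly. `grad_reverse_backward()`:
#'   `-lam * grad`.
#' @export
grad_reverse <- function(x, lam) {
  check_number(lam, "lam", lower = 0)
  x
}

#' @rdname grad_reverse
#' @param grad Upstream gradient array.
#' @export
grad_reverse_backward <- function(grad, lam) {
  check_number(lam, "lam", lower = 0)
  -lam * grad
}

#' Adaptive gradient-reversal schedule
#'
#' The reversal coefficient ramps exponentially with training progress
#' `p = (b + E * N_Batches) / (N_Batches * N_Epoch)` (clipped to `[0, 1]`):
#' `lambda = a * exp(k * p)` with defaults `a = 0.85`, `k = 5.5`. At the
#' first batch of the first epoch `lambda = 0.85`; at the end of training it
#' reaches `0.85 * exp(5.5)`. The ramp compensates for label-relevant
#' features being less prominent than domain-relevant ones early on.
#'
#' @param n_batches Batches per epoch (>= 1).
#' @param n_epochs Total epochs the schedule spans (>= 1).
#' @param a,k Schedule coefficients.
#' @return A `lambda_schedule` object.
#' @export
#' @examples
#' sch <- lambda_schedule(10, 10)
#' adaptive_lambda(0, 0, sch)   # 0.85
lambda_schedule <- function(n_batches, n_epochs, a = 0.85, k = 5.5) {
  check_number(n_batches, "n_batches", lower = 1)
  check_number(n_epochs, "n_epochs", lower = 1)
  check_number(a, "a", lower = 1e-12)
  check_number(k, "k", lower = 1e-12)
  structure(list(n_batches = as.integer(n_batches),
                 n_epochs = as.integer(n_epochs), a = a, k = k),
            class = "lambda_schedule")
}

#' @rdname lambda_schedule
#' @param b 0-based batch index within the epoch.
#' @param E 0-based epoch index.
#' @param schedule A [lambda_schedule()].
#' @export
adaptive_lambda <- function(b, E, schedule) {
  check_number(b, "b", lower = 0)
  check_number(E, "E", lower = 0)
  p <- (b + E * schedule$n_batches) / (schedule$n_batches * schedule$n_epochs)
  p <- min(max(p, 0), 1)
  schedule$a * exp(schedule$k * p)
}

#' Stack images into a network input batch
#'
#' @param images List of `ecg_image`s or `H x W x 3` arrays.
#' @return `H x W x B x 3` array.
#' @export
batch_array <- function(images) {
  arrs <- purrr::map(images, function(im) {
    if (inherits(im, "ecg_image")) im$pixels else im
  })
  d <- dim(arrs[[1]])
  b <- length(arrs)
  out <- array(0, dim = c(d[1], d[2], b, 3L))
  for (i in seq_len(b)) out[, , i, ] <- arrs[[i]]
  out
}
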