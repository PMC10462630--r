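test_that("spatial dimensions follow the ceil(dim/stride) recursion", {
  full <- network_config(880, 1650)
  expect_equal(full$out_h, 14)
  expect_equal(full$out_w, 26)
  expect_equal(full$feature_dim, 14 * 26 * 512)
  five <- network_config(220, 412, channels = c(8, 16, 32, 64, 128),
                         strides = c(2, 2, 2, 2, 2))
  expect_equal(c(five$out_h, five$out_w), c(7, 13))
  expect_equal(five$feature_dim, 7 * 13 * 128)
  expect_error(network_config(64, 64, channels = c(4, 8), strides = c(2)),
               "equal length")
  expect_error(network_config(64, 64, dropout_p = 1), "dropout_p")
})

test_that("extractor forward output is per-sample, finite and eval-deterministic", {
  cfg <- tiny_net()
  p <- init_params(cfg)
  set.seed(1)
  x <- array(runif(64 * 120 * 3 * 3), c(64, 120, 3, 3))
  f1 <- feature_extractor_forward(x, cfg, p, training = FALSE)
  expect_equal(dim(f1), c(3, cfg$feature_dim))
  expect_true(all(is.finite(f1)))
  f2 <- feature_extractor_forward(x, cfg, p, training = FALSE)
  expect_identical(f1, f2)
  # batch permutation permutes rows
  xp <- x[, , c(3, 1, 2), , drop = FALSE]
  fp <- feature_extractor_forward(xp, cfg, p, training = FALSE)
  expect_equal(fp, f1[c(3, 1, 2), ], tolerance = 1e-12)
  expect_error(feature_extractor_forward(x[1:32, , , , drop = FALSE], cfg, p),
               "shape")
})

test_that("initialization is seeded and reproducible", {
  cfg <- tiny_net()
  expect_identical(init_params(cfg, seed = 5), init_params(cfg, seed = 5))
  expect_false(identical(init_params(cfg, seed = 5)$label$w,
                         init_params(cfg, seed = 6)$label$w))
})

test_that("heads map zero parameters to 0.5 and saturate correctly", {
  cfg <- tiny_net()
  p <- init_params(cfg)
  p$label$w[] <- 0; p$label$b <- 0
  p$domain$w[] <- 0; p$domain$b <- 0
  f <- matrix(rnorm(4 * cfg$feature_dim), 4)
  expect_equal(label_head_forward(f, p), rep(0.5, 4))
  expect_equal(domain_head_forward(f, p), rep(0.5, 4))
  p$label$b <- 50
  p_big <- label_head_forward(f, p)
  expect_true(all(p_big > 1 - 1e-6))
  expect_true(all(p_big < 1))  # strictly inside (0, 1)
  # per-sample independence: permuting rows permutes outputs
  p$label$w <- rnorm(cfg$feature_dim); p$label$b <- 0
  expect_equal(label_head_forward(f[4:1, ], p), label_head_forward(f, p)[4:1])
})

test_that("gradient reversal is a forward identity with reversed scaled backward", {
  x <- array(rnorm(10), c(2, 5))
  expect_identical(grad_reverse(x, 2.5), x)
  g <- c(1, -2)
  expect_equal(grad_reverse_backward(g, 2), c(-2, 4))
  expect_equal(grad_reverse_backward(g, 0), c(0, 0))
  expect_error(grad_reverse(x, -1), "lam")
})

test_that("GRL analytic gradient matches central finite differences", {
  # scalar loss L(grad_reverse(x, lam)) = sum(w * grl(x))^2 / 2
  set.seed(42)
  for (lam in c(0.5, 2)) {
    x <- rnorm(10)
    w <- rnorm(10)
    loss <- function(xx) sum(w * grad_reverse(xx, lam))^2 / 2
    upstream <- sum(w * x) * w          # dL/d(grl output)
    analytic <- grad_reverse_backward(upstream, lam)
    eps <- 1e-6
    numeric_grad <- vapply(seq_along(x), function(i) {
      xp <- x; xm <- x
      xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
      # reversal applies to the backward path; the induced input gradient
      # is -lam times the plain loss derivative
      -lam * (loss(xp) - loss(xm)) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(analytic - numeric_grad)) /
                max(abs(numeric_grad)), 1e-4)
  }
})

test_that("adaptive lambda follows the exponential ramp exactly", {
  sch <- lambda_schedule(10, 10)
  expect_identical(adaptive_lambda(0, 0, sch), 0.85)
  expect_equal(adaptive_lambda(0, 5, sch), 0.85 * exp(2.75), tolerance = 1e-12)
  expect_equal(adaptive_lambda(0, 10, sch), 0.85 * exp(5.5), tolerance = 1e-12)
  # clipping at p = 1
  expect_equal(adaptive_lambda(9, 20, sch), 0.85 * exp(5.5), tolerance = 1e-12)
  # monotone in b and E
  vals <- vapply(0:9, function(b) adaptive_lambda(b, 3, sch), numeric(1))
  expect_true(all(diff(vals) > 0))
  epochs <- vapply(0:9, function(E) adaptive_lambda(4, E, sch), numeric(1))
  expect_true(all(diff(epochs) > 0))
  expect_error(lambda_schedule(0, 5), "n_batches")
})

test_that("evaluation-mode backward (fixed-statistics batch norm) is exact", {
  # the domain path backpropagates through evaluation-mode batch norm,
  # where running statistics are constants
  cfg <- network_config(12, 16, channels = c(3, 4), strides = c(2, 2),
                        dropout_p = 0)
  p <- init_params(cfg, seed = 4)
  # non-trivial running stats
  for (i in 1:2) {
    p$blocks[[i]]$rm <- rnorm(length(p$blocks[[i]]$rm), sd = 0.2)
    p$blocks[[i]]$rv <- runif(length(p$blocks[[i]]$rv), 0.5, 2)
  }
  set.seed(5)
  x <- array(runif(12 * 16 * 2 * 3), c(12, 16, 2, 3))
  y <- c(1, 0)
  loss_of <- function(pp, xx = x) {
    f <- ecgdann:::extractor_forward_internal(xx, cfg, pp, training = FALSE)
    pr <- domain_head_forward(f$features, pp)
    -mean(y * log(pr) + (1 - y) * log(1 - pr))
  }
  fwd <- ecgdann:::extractor_forward_internal(x, cfg, p, training = FALSE)
  pr <- domain_head_forward(fwd$features, p)
  dfeat <- outer((pr - y) / 2, p$domain$w)
  gb <- ecgdann:::extractor_backward_internal(dfeat, cfg, p, fwd)
  eps <- 1e-6
  for (bi in 1:2) {
    for (t in 1:4) {
      i <- sample(length(p$blocks[[bi]]$W), 1)
      pp <- p; pp$blocks[[bi]]$W[i] <- pp$blocks[[bi]]$W[i] + eps
      pm <- p; pm$blocks[[bi]]$W[i] <- pm$blocks[[bi]]$W[i] - eps
      expect_equal(gb[[bi]]$W[i], (loss_of(pp) - loss_of(pm)) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
  # gamma gradient under fixed statistics
  i <- sample(length(p$blocks[[1]]$gamma), 1)
  pp <- p; pp$blocks[[1]]$gamma[i] <- pp$blocks[[1]]$gamma[i] + eps
  pm <- p; pm$blocks[[1]]$gamma[i] <- pm$blocks[[1]]$gamma[i] - eps
  expect_equal(gb[[1]]$gamma[i], (loss_of(pp) - loss_of(pm)) / (2 * eps),
               tolerance = 1e-4)
})

test_that("whole-model analytic gradients match finite differences", {
  # end-to-end check through conv, batch-norm, ReLU and the label head
  cfg <- network_config(12, 16, channels = c(3, 4), strides = c(2, 2),
                        dropout_p = 0)
  p <- init_params(cfg, seed = 2)
  set.seed(3)
  x <- array(runif(12 * 16 * 2 * 3), c(12, 16, 2, 3))
  y <- c(1, 0)
  loss_of <- function(pp) {
    f <- ecgdann:::extractor_forward_internal(x, cfg, pp, training = TRUE)
    pr <- label_head_forward(f$features, pp)
    -mean(y * log(pr) + (1 - y) * log(1 - pr))
  }
  fwd <- ecgdann:::extractor_forward_internal(x, cfg, p, training = TRUE)
  pr <- label_head_forward(fwd$features, p)
  dlogit <- (pr - y) / 2
  dfeat <- outer(dlogit, p$label$w)
  gb <- ecgdann:::extractor_backward_internal(dfeat, cfg, p, fwd)
  eps <- 1e-6
  # spot-check a few weights in each block
  for (bi in 1:2) {
    for (t in 1:4) {
      i <- sample(length(p$blocks[[bi]]$W), 1)
      pp <- p; pp$blocks[[bi]]$W[i] <- pp$blocks[[bi]]$W[i] + eps
      pm <- p; pm$blocks[[bi]]$W[i] <- pm$blocks[[bi]]$W[i] - eps
      num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      expect_equal(gb[[bi]]$W[i], num, tolerance = 1e-4)
    }
    i <- sample(length(p$blocks[[bi]]$gamma), 1)
    pp <- p; pp$blocks[[bi]]$gamma[i] <- pp$blocks[[bi]]$gamma[i] + eps
    pm <- p; pm$blocks[[bi]]$gamma[i] <- pm$blocks[[bi]]$gamma[i] - eps
    expect_equal(gb[[bi]]$gamma[i],
                 (loss_of(pp) - loss_of(pm)) / (2 * eps), tolerance = 1e-4)
  }
})
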