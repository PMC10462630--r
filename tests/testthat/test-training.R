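test_that("train_config validates its invariants", {
  expect_error(train_config(lr = 0), "lr")
  expect_error(train_config(batch_size = 1), "batch_size")
  expect_error(train_config(domain_start_epoch = 60, max_epochs = 60),
               "domain_start_epoch")
})

test_that("oversampling reaches the target balance while keeping originals", {
  man <- tibble::tibble(i = 1:100, label = c(rep(TRUE, 10), rep(FALSE, 90)))
  res <- oversample(man, 0.5, seed = 1)
  expect_true(all(man$i %in% res$i))
  n_pos <- sum(res$label)
  expect_true(abs(n_pos - 90) <= 1)
  expect_equal(sum(!res$label), 90)
  expect_lte(abs(mean(res$label) - 0.5), 1 / nrow(res))
  # already balanced: unchanged
  bal <- tibble::tibble(i = 1:10, label = rep(c(TRUE, FALSE), 5))
  expect_identical(oversample(bal, 0.5)$i, bal$i)
  expect_error(oversample(man, 0), "strictly between")
  expect_error(oversample(man, 1), "strictly between")
  single <- tibble::tibble(i = 1:5, label = rep(TRUE, 5))
  expect_error(oversample(single, 0.5), "positive and one negative")
})

test_that("the dual checkpoint rule implements best-metric AND 40-60% window", {
  expect_true(should_checkpoint(0.91, 0.52, best_so_far = 0.88))
  expect_false(should_checkpoint(0.91, 0.70, best_so_far = 0.88))
  expect_false(should_checkpoint(0.85, 0.50, best_so_far = 0.88))
  expect_false(should_checkpoint(0.88, 0.50, best_so_far = 0.88))  # strict
  expect_true(should_checkpoint(0.40, 0.40))                        # boundary
  expect_true(should_checkpoint(0.40, 0.60))
  expect_false(should_checkpoint(0.40, 0.399))
})

test_that("optimizer steps reach every trainable tensor", {
  cfg <- tiny_net(dropout_p = 0)
  p0 <- init_params(cfg, seed = 1)
  imgs <- blob_set(8, 0)
  y <- vapply(imgs, function(x) x$labels[["blob"]], TRUE)
  tc <- tiny_tc()
  set.seed(2)
  st <- ecgdann:::label_step(imgs, as.numeric(y), p0, cfg, NULL, tc)
  for (i in seq_along(p0$blocks)) {
    for (leaf in c("W", "b", "gamma", "beta")) {
      expect_false(identical(st$params$blocks[[i]][[leaf]],
                             p0$blocks[[i]][[leaf]]),
                   info = sprintf("block %d %s unchanged", i, leaf))
    }
  }
  expect_false(identical(st$params$label$w, p0$label$w))
  # domain path updates extractor and domain head, not the label head
  set.seed(3)
  std <- ecgdann:::domain_step(imgs, rep(c(0, 1), 4), 1.5, p0, cfg, NULL, tc)
  expect_false(identical(std$params$blocks[[1]]$W, p0$blocks[[1]]$W))
  expect_false(identical(std$params$domain$w, p0$domain$w))
  expect_identical(std$params$label$w, p0$label$w)
})

test_that("vanilla training learns separable classes and snapshots the best epoch", {
  tr <- blob_set(40, 0)
  va <- blob_set(20, 500)
  fit <- train_vanilla(tr, va, "blob", tiny_net(), tiny_tc(max_epochs = 5, seed = 3))
  h <- tidy(fit)
  expect_equal(nrow(h), 5)
  expect_gte(max(h$val_auc), 0.95)
  expect_equal(h$val_auc[h$epoch == fit$checkpoint_epoch], max(h$val_auc))
  # training accuracy on the training set itself
  scores <- predict(fit, tr)
  y <- vapply(tr, function(x) x$labels[["blob"]], TRUE)
  expect_gte(mean((scores >= 0.5) == y), 0.95)
  g <- glance(fit)
  expect_equal(g$mode, "vanilla")
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("training is deterministic given the seed", {
  tr <- blob_set(24, 0)
  va <- blob_set(12, 500)
  tc <- tiny_tc(max_epochs = 3, seed = 11,
                augmentation = list(distortion = 0.15, prob = 0.8,
                                    enabled = TRUE))
  f1 <- train_vanilla(tr, va, "blob", tiny_net(), tc)
  f2 <- train_vanilla(tr, va, "blob", tiny_net(), tc)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$params, f2$params)
})

test_that("early stopping halts after patience stagnant epochs", {
  # force stagnation with validation labels uncorrelated with the blob
  # side: training loss falls while validation loss cannot improve
  tr <- blob_set(24, 0)
  va_noise <- lapply(seq_len(12), function(i) {
    im <- blob_image(i %% 2 == 0, 700 + i)
    im$labels <- c(blob = i %% 3 == 0)
    im
  })
  fit <- train_vanilla(tr, va_noise, "blob", tiny_net(),
                       tiny_tc(max_epochs = 30, early_stop_patience = 3,
                               seed = 5))
  expect_lt(nrow(tidy(fit)), 30)
})

test_that("warm-up epochs train the label path only", {
  src <- blob_set(24, 0)
  tgt <- blob_set(24, 900, domain = "captured", shade = 0.6)
  val <- blob_set(12, 500)
  mix <- c(blob_set(6, 600), blob_set(6, 650, domain = "captured", shade = 0.6))
  cfg <- tiny_net()
  tc <- tiny_tc(max_epochs = 3, domain_start_epoch = 2, seed = 7)
  fit <- train_adversarial(src, tgt, val, mix, "blob", cfg, tc)
  h <- tidy(fit)
  expect_equal(h$n_domain_updates[h$epoch < 2], c(0L, 0L))
  expect_gt(h$n_domain_updates[h$epoch == 2], 0L)
  expect_true(all(is.na(h$lambda_end[h$epoch < 2])))
  # warm-up epochs are unaffected by the target data: swapping the target
  # set changes nothing before domain_start_epoch
  tgt_other <- blob_set(24, 2000, domain = "captured", shade = 0.3)
  fit2 <- train_adversarial(src, tgt_other, val, mix, "blob", cfg, tc)
  h2 <- tidy(fit2)
  expect_identical(h$train_loss[h$epoch < 2], h2$train_loss[h2$epoch < 2])
  expect_identical(h$val_auc[h$epoch < 2], h2$val_auc[h2$epoch < 2])
})

test_that("the lambda trace equals the closed-form schedule at each (b, E)", {
  src <- blob_set(16, 0)
  tgt <- blob_set(16, 900, domain = "captured", shade = 0.6)
  val <- blob_set(8, 500)
  mix <- c(blob_set(4, 600), blob_set(4, 650, domain = "captured", shade = 0.6))
  tc <- tiny_tc(max_epochs = 4, domain_start_epoch = 1, seed = 9)
  fit <- train_adversarial(src, tgt, val, mix, "blob", tiny_net(), tc)
  n_batches <- 16L %/% tc$batch_size
  sch <- lambda_schedule(n_batches, tc$max_epochs)
  expected <- unlist(lapply(1:(tc$max_epochs - 1), function(E) {
    vapply(0:(n_batches - 1), adaptive_lambda, numeric(1), E = E,
           schedule = sch)
  }))
  n_done <- length(fit$lambda_trace)
  expect_gt(n_done, 0)
  expect_identical(fit$lambda_trace, expected[seq_len(n_done)])
})

test_that("indistinguishable domains keep the domain classifier near chance", {
  src <- blob_set(24, 0)
  tgt <- lapply(blob_set(24, 0), function(im) { im$domain <- "captured"; im })
  val <- blob_set(12, 500)
  mix <- c(blob_set(6, 600),
           lapply(blob_set(6, 600), function(im) { im$domain <- "captured"; im }))
  fit <- train_adversarial(src, tgt, val, mix, "blob", tiny_net(),
                           tiny_tc(max_epochs = 4, domain_start_epoch = 1,
                                   seed = 13))
  h <- tidy(fit)
  expect_true(all(abs(h$domain_acc - 0.5) <= 0.25))
})

test_that("accepted checkpoints always sit inside the domain-accuracy window", {
  src <- blob_set(24, 0)
  tgt <- blob_set(24, 900, domain = "captured", shade = 0.6)
  val <- blob_set(12, 500)
  mix <- c(blob_set(6, 600), blob_set(6, 650, domain = "captured", shade = 0.6))
  fit <- train_adversarial(src, tgt, val, mix, "blob", tiny_net(),
                           tiny_tc(max_epochs = 5, domain_start_epoch = 2,
                                   seed = 15))
  h <- tidy(fit)
  taken <- h[h$checkpoint, ]
  if (nrow(taken) > 0) {
    expect_true(all(taken$domain_acc >= 0.40 & taken$domain_acc <= 0.60))
    # label metric strictly improves across successive accepted checkpoints
    expect_true(all(diff(taken$val_auc) > 0))
    expect_false(fit$no_checkpoint)
    # returned parameters reproduce the recorded domain accuracy exactly
    d_val <- vapply(mix, function(x) x$domain == "captured", TRUE)
    dp <- predict_scores(fit$params, fit$config, mix, head = "domain")
    expect_identical(mean((dp >= 0.5) == d_val),
                     h$domain_acc[h$epoch == fit$checkpoint_epoch])
  } else {
    expect_true(fit$no_checkpoint)
  }
})

test_that("checkpoints survive a save/load round-trip", {
  dir <- withr::local_tempdir()
  tr <- blob_set(16, 0)
  va <- blob_set(8, 500)
  fit <- train_vanilla(tr, va, "blob", tiny_net(), tiny_tc(max_epochs = 2))
  p <- file.path(dir, "fit.rds")
  save_checkpoint(fit, p)
  back <- load_checkpoint(p)
  expect_identical(back$params, fit$params)
  expect_identical(predict(back, va), predict(fit, va))
})
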