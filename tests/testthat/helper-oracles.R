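# Independent oracles used to validate package output. These deliberately
# reimplement the quantities with different algorithms than the package.

# R-peak oracle: runs of samples above a mid-range threshold; one peak per
# run (argmax); runs closer than 250 ms merged.
oracle_rpeaks <- function(x, fs) {
  z <- x - stats::median(x)
  th <- 0.5 * max(z)
  above <- z > th
  if (!any(above)) return(integer())
  idx <- which(above)
  run_start <- c(TRUE, diff(idx) > 1)
  run_id <- cumsum(run_start)
  peaks <- vapply(split(idx, run_id),
                  function(ix) ix[which.max(z[ix])], integer(1))
  peaks <- unname(peaks)
  merged <- peaks[1]
  for (p in peaks[-1]) {
    if (p - merged[length(merged)] < 0.25 * fs) {
      if (z[p] > z[merged[length(merged)]]) merged[length(merged)] <- p
    } else {
      merged <- c(merged, p)
    }
  }
  merged
}

oracle_hr <- function(record) {
  pk <- oracle_rpeaks(record$leads$II, record$fs)
  rr <- diff(pk) / record$fs
  list(hr = 60 / mean(rr), cv = stats::sd(rr) / mean(rr), n = length(pk))
}

# brute-force confusion counting (element-by-element loop)
oracle_counts <- function(y_true, y_pred) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(y_true)) {
    if (y_true[i] && y_pred[i]) tp <- tp + 1L
    else if (y_true[i] && !y_pred[i]) fn <- fn + 1L
    else if (!y_true[i] && y_pred[i]) fp <- fp + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

oracle_metrics <- function(y_true, y_pred) {
  ct <- oracle_counts(y_true, y_pred)
  with(ct, list(
    tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    tnr = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    acc = (tp + tn) / (tp + tn + fp + fn),
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  ))
}

# explicit pairwise Mann-Whitney AUC (quadratic loop)
oracle_auc <- function(scores, y_true) {
  pos <- scores[y_true]; neg <- scores[!y_true]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

# flat synthetic "page" with a dark blob whose side encodes the label;
# cheap stand-in inputs for training-loop mechanics tests
blob_image <- function(label, seed, h = 64, w = 120, domain = "clean",
                       noise = 0.05, shade = 1) {
  set.seed(seed)
  px <- array(1, c(h, w, 3))
  rs <- (h %/% 3):(2 * h %/% 3)
  cs <- if (label) (w %/% 6):(w %/% 3) else (2 * w %/% 3):(5 * w %/% 6)
  px[rs, cs, ] <- 0
  px <- px * shade + array(rnorm(h * w * 3, sd = noise), c(h, w, 3))
  px <- pmin(pmax(px, 0), 1)
  img <- ecg_image(px, "clean", labels = c(blob = label),
                   source_record_id = sprintf("blob_%d", seed))
  img$domain <- domain
  img
}

blob_set <- function(n, seed0, domain = "clean", shade = 1) {
  lapply(seq_len(n), function(i) {
    blob_image(i %% 2 == 0, seed0 + i, domain = domain, shade = shade)
  })
}

tiny_net <- function(h = 64, w = 120, dropout_p = 0.1) {
  network_config(h, w, channels = c(4, 8), strides = c(4, 4),
                 dropout_p = dropout_p)
}

tiny_tc <- function(max_epochs = 4, domain_start_epoch = 1, seed = 1L,
                    augmentation = list(distortion = 0.15, prob = 0.8,
                                        enabled = FALSE), ...) {
  train_config(lr = 1e-3, batch_size = 8, max_epochs = max_epochs,
               domain_start_epoch = domain_start_epoch, seed = seed,
               augmentation = augmentation, ...)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
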