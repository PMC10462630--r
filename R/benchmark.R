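#' Generate the synthetic two-domain benchmark data for one condition
#'
#' Builds the full data path at desk scale: labeled ECG records (a 50/50 mix
#' of the condition and normal sinus rhythm), clean page renders (source
#' domain), simulated mobile captures of the training and test pages (target
#' domain), a held-out 50/50 mixed clean/captured validation set for the
#' domain-accuracy window, and optionally test pages in unseen formats.
#' Splits are per record: every image derived from one record stays on one
#' side of every split.
#'
#' @param condition Condition name from [ecg_conditions()].
#' @param n_train,n_val,n_test Records per split.
#' @param image_h,image_w Rendered page size in pixels.
#' @param spec Training page [format_spec()].
#' @param capture A [capture_config()].
#' @param seed Master seed; everything is derived from it.
#' @param frames_per_image Capture frames per training page.
#' @param n_unseen Number of unseen-format variants (0 disables that arm).
#' @return A list of image sets (`source_train`, `target_train`,
#'   `source_val`, `mixed_val`, `clean_test`, `captured_test`,
#'   `unseen_captured_test`) plus the records per split and the mix used.
#' @export
generate_benchmark_data <- function(condition, n_train = 400, n_val = 100,
                                    n_test = 200, image_h = 220,
                                    image_w = 412, spec = format_spec(),
                                    capture = capture_config(), seed = 1L,
                                    frames_per_image = 1L, n_unseen = 0L) {
  mix <- stats::setNames(c(0.5, 0.5), c(condition, "normal"))
  s <- derive_seeds(seed, 8L)
  recs <- list(
    train = generate_dataset(n_train, mix, seed = s[1]),
    val = generate_dataset(n_val, mix, seed = s[2]),
    test = if (n_test > 0) generate_dataset(n_test, mix, seed = s[3]) else list()
  )
  render_all <- function(rs, fmt = spec) {
    purrr::map(rs, render_page, spec = fmt, out_h = image_h, out_w = image_w)
  }
  source_train <- render_all(recs$train)
  target_train <- capture_dataset(source_train, capture,
                                  frames_per_image = frames_per_image,
                                  seed = s[4])
  source_val <- render_all(recs$val)
  mixed_val <- c(source_val, capture_dataset(source_val, capture, 1L,
                                             seed = s[5]))
  clean_test <- render_all(recs$test)
  captured_test <- if (n_test > 0) {
    capture_dataset(clean_test, capture, 1L, seed = s[6])
  } else {
    list()
  }
  unseen_captured_test <- NULL
  if (n_unseen > 0L && n_test > 0) {
    variants <- make_format_variants(spec, n_unseen, seed = s[7])
    unseen_clean <- purrr::imap(recs$test, function(r, i) {
      render_page(r, variants[[((i - 1L) %% n_unseen) + 1L]],
                  out_h = image_h, out_w = image_w)
    })
    unseen_captured_test <- capture_dataset(unseen_clean, capture, 1L,
                                            seed = s[8])
  }
  list(condition = condition, mix = mix, records = recs,
       source_train = source_train, target_train = target_train,
       source_val = source_val, mixed_val = mixed_val,
       clean_test = clean_test, captured_test = captured_test,
       unseen_captured_test = unseen_captured_test)
}

#' Benchmark configuration
#'
#' Desk-scale defaults: one or more rate-based conditions, 220 x 412 pages,
#' the 5-block network, and a few seeds. `n_unseen > 0` adds the
#' unseen-format evaluation arm; `resume_unseen = TRUE` additionally resumes
#' adversarial training with the unseen-format captures added (unlabeled) to
#' the target set.
#'
#' @param conditions Character vector of condition names.
#' @param n_train,n_val,n_test Records per split and domain.
#' @param image_h,image_w Page size in pixels.
#' @param spec Training [format_spec()].
#' @param capture A [capture_config()]; zero all strengths for the
#'   no-domain-shift control.
#' @param net A [network_config()] matching the image size.
#' @param tc A [train_config()].
#' @param seeds Integer vector of run seeds.
#' @param n_unseen Unseen-format variants for the extra test arm.
#' @param resume_unseen Resume training with unseen-format target data?
#' @return A `benchmark_config` object.
#' @export
benchmark_config <- function(conditions = c("sinus_bradycardia",
                                            "sinus_tachycardia",
                                            "atrial_fibrillation"),
                             n_train = 400, n_val = 100, n_test = 200,
                             image_h = 220, image_w = 412,
                             spec = format_spec(),
                             capture = capture_config(),
                             net = desk_network_config(image_h, image_w),
                             tc = desk_train_config(),
                             seeds = 1:3, n_unseen = 0L,
                             resume_unseen = FALSE) {
  stopifnot(length(conditions) >= 1L, length(seeds) >= 1L)
  if (net$input_h != image_h || net$input_w != image_w) {
    abort("network input size must match the rendered image size.")
  }
  structure(
    list(conditions = conditions, n_train = n_train, n_val = n_val,
         n_test = n_test, image_h = image_h, image_w = image_w,
         spec = spec, capture = capture, net = net, tc = tc,
         seeds = as.integer(seeds), n_unseen = as.integer(n_unseen),
         resume_unseen = isTRUE(resume_unseen)),
    class = "benchmark_config"
  )
}

eval_arm <- function(fit, images, condition, arm, domain, fmt, seed) {
  ev <- evaluate_model(fit, images)
  tibble::tibble(condition = condition, arm = arm, domain = domain,
                 format = fmt, seed = seed, auc = ev$roc_auc, acc = ev$acc,
                 f1 = ev$f1)
}

#' Run the vanilla-versus-adversarial benchmark
#'
#' For each condition and seed: generates signals, renders the clean source
#' sets, simulates the captured target sets (labels hidden from training,
#' kept for testing), trains both arms at matched seed / epochs /
#' architecture, and evaluates on clean test, captured test and (optionally)
#' captured test in unseen formats. The adaptation gap is
#' `delta = AUC_adversarial - AUC_vanilla` on the captured test set.
#'
#' @param config A [benchmark_config()].
#' @param verbose Print stage progress?
#' @return An `ecg_benchmark`: list with `results` (one row per
#'   condition/arm/domain/seed), `gaps` (per-condition median adaptation
#'   gap), `fits` and `splits` (record ids per role, for contamination
#'   checks).
#' @export
run_benchmark <- function(config = benchmark_config(), verbose = interactive()) {
  stopifnot(inherits(config, "benchmark_config"))
  rows <- list(); fits <- list(); splits <- list()
  for (cond in config$conditions) {
    for (sd in config$seeds) {
      say <- function(...) if (verbose) message(sprintf(...))
      say("[%s seed %d] generating data", cond, sd)
      dat <- generate_benchmark_data(
        cond, config$n_train, config$n_val, config$n_test,
        config$image_h, config$image_w, config$spec, config$capture,
        seed = sd, n_unseen = config$n_unseen
      )
      splits[[length(splits) + 1L]] <- tibble::tibble(
        condition = cond, seed = sd,
        role = rep(c("train", "val", "test"),
                   vapply(dat$records, length, 1L)),
        record_id = unlist(purrr::map(dat$records,
                                      ~ purrr::map_chr(.x, "record_id")),
                           use.names = FALSE)
      )
      tc <- config$tc; tc$seed <- as.integer(sd)
      say("[%s seed %d] training vanilla", cond, sd)
      van <- train_vanilla(dat$source_train, dat$source_val, cond,
                           config$net, tc)
      say("[%s seed %d] training adversarial", cond, sd)
      adv <- train_adversarial(dat$source_train, dat$target_train,
                               dat$source_val, dat$mixed_val, cond,
                               config$net, tc)
      fits[[sprintf("%s_seed%d_vanilla", cond, sd)]] <- van
      fits[[sprintf("%s_seed%d_adversarial", cond, sd)]] <- adv
      for (arm in list(list(fit = van, name = "vanilla"),
                       list(fit = adv, name = "adversarial"))) {
        rows[[length(rows) + 1L]] <-
          eval_arm(arm$fit, dat$clean_test, cond, arm$name, "clean", "seen", sd)
        rows[[length(rows) + 1L]] <-
          eval_arm(arm$fit, dat$captured_test, cond, arm$name, "captured",
                   "seen", sd)
        if (!is.null(dat$unseen_captured_test)) {
          rows[[length(rows) + 1L]] <-
            eval_arm(arm$fit, dat$unseen_captured_test, cond, arm$name,
                     "captured", "unseen", sd)
        }
      }
      if (config$resume_unseen && !is.null(dat$unseen_captured_test)) {
        say("[%s seed %d] resuming with unseen-format target data", cond, sd)
        s_extra <- derive_seeds(sd + 7L, 2L)
        variants <- make_format_variants(config$spec, max(config$n_unseen, 1L),
                                         seed = s_extra[1])
        extra_clean <- purrr::imap(dat$records$train, function(r, i) {
          render_page(r, variants[[((i - 1L) %% length(variants)) + 1L]],
                      out_h = config$image_h, out_w = config$image_w)
        })
        extra_tgt <- capture_dataset(extra_clean, config$capture, 1L,
                                     seed = s_extra[2])
        res <- train_adversarial(dat$source_train,
                                 c(dat$target_train, extra_tgt),
                                 dat$source_val, dat$mixed_val, cond,
                                 config$net, tc, init = adv$params)
        fits[[sprintf("%s_seed%d_resumed", cond, sd)]] <- res
        rows[[length(rows) + 1L]] <-
          eval_arm(res, dat$unseen_captured_test, cond, "adversarial_resumed",
                   "captured", "unseen", sd)
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  gaps <- results |>
    dplyr::filter(.data$domain == "captured", .data$format == "seen",
                  .data$arm %in% c("vanilla", "adversarial")) |>
    dplyr::select("condition", "arm", "seed", "auc") |>
    tidyr::pivot_wider(names_from = "arm", values_from = "auc") |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      median_gap = median(.data$adversarial - .data$vanilla),
      median_vanilla_auc = median(.data$vanilla),
      median_adversarial_auc = median(.data$adversarial),
      n_seeds = dplyr::n(), .groups = "drop"
    )
  structure(list(results = results, gaps = gaps, fits = fits,
                 splits = dplyr::bind_rows(splits), config = config),
            class = "ecg_benchmark")
}

#' @export
print.ecg_benchmark <- function(x, ...) {
  cat("<ecg_benchmark>\n")
  print(x$gaps)
  invisible(x)
}

#' @export
tidy.ecg_benchmark <- function(x, ...) x$results

#' @export
glance.ecg_benchmark <- function(x, ...) x$gaps

#' Plot benchmark AUCs by arm and domain
#'
#' @param object An `ecg_benchmark`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecg_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$domain, y = .data$auc,
                               colour = .data$arm)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_grid(.data$condition ~ .data$format) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "ROC-AUC") +
    ggplot2::theme_minimal()
}

#' Write benchmark results as CSV, JSON and a markdown summary
#'
#' @param bench An `ecg_benchmark` (or its `results` tibble).
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_benchmark_report <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  results <- if (inherits(bench, "ecg_benchmark")) bench$results else bench
  paths <- file.path(dir, c("results.csv", "results.json", "summary.md"))
  readr::write_csv(results, paths[1])
  jsonlite::write_json(results, paths[2], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  md <- c("# Benchmark summary", "",
          "| condition | arm | domain | format | median AUC |",
          "|---|---|---|---|---|")
  if (nrow(results) > 0) {
    agg <- results |>
      dplyr::group_by(.data$condition, .data$arm, .data$domain,
                      .data$format) |>
      dplyr::summarise(median_auc = median(.data$auc), .groups = "drop")
    md <- c(md, sprintf("| %s | %s | %s | %s | %.3f |", agg$condition,
                        agg$arm, agg$domain, agg$format, agg$median_auc))
  }
  writeLines(md, paths[3])
  invisible(paths)
}
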