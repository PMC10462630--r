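#' Describe a parametric cardiac condition
#'
#' A condition spec drives the synthetic 12-lead generator: it fixes the
#' heart-rate range, the beat-to-beat variability of the RR interval, scaling
#' of the QT interval and QRS width, and whether P waves are present. The
#' presets in [ecg_conditions()] define separable but non-trivial classes:
#' sinus bradycardia and tachycardia differ from normal only in rate, atrial
#' fibrillation has irregular RR intervals and no P wave, prolonged QT and
#' wide QRS are morphological.
#'
#' @param name Condition name (used as the label column).
#' @param hr_range Heart-rate range in bpm; the record's mean rate is drawn
#'   uniformly from it.
#' @param rr_cv_range Range for the coefficient of variation of RR intervals.
#' @param qt_scale_range Multiplicative scale range for the QT interval
#'   (T-wave latency and width).
#' @param qrs_scale_range Multiplicative scale range for QRS width.
#' @param p_wave Logical; are P waves present?
#' @param irregular Logical; if `TRUE` RR intervals are drawn i.i.d. (atrial
#'   fibrillation style) rather than jittered around the mean.
#'
#' @return An object of class `condition_spec`.
#' @export
#' @examples
#' condition_spec("sinus_bradycardia", hr_range = c(40, 55))
condition_spec <- function(name,
                           hr_range = c(60, 95),
                           rr_cv_range = c(0.02, 0.05),
                           qt_scale_range = c(1, 1),
                           qrs_scale_range = c(1, 1),
                           p_wave = TRUE,
                           irregular = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_range <- function(r, nm) {
    if (!is.numeric(r) || length(r) != 2L || any(is.na(r)) || r[1] > r[2]) {
      abort(sprintf("`%s` must be a non-empty numeric range.", nm))
    }
    if (nm == "hr_range" && any(r <= 0)) abort("heart-rate bounds must be positive.")
    r
  }
  structure(
    list(
      name = name,
      hr_range = check_range(hr_range, "hr_range"),
      rr_cv_range = check_range(rr_cv_range, "rr_cv_range"),
      qt_scale_range = check_range(qt_scale_range, "qt_scale_range"),
      qrs_scale_range = check_range(qrs_scale_range, "qrs_scale_range"),
      p_wave = isTRUE(p_wave),
      irregular = isTRUE(irregular)
    ),
    class = "condition_spec"
  )
}

#' Preset condition specifications
#'
#' @return Named list of [condition_spec()] objects covering the six built-in
#'   classes: normal, sinus bradycardia, sinus tachycardia, atrial
#'   fibrillation, prolonged QT and wide QRS.
#' @export
ecg_conditions <- function() {
  list(
    normal = condition_spec("normal", hr_range = c(60, 95)),
    sinus_bradycardia = condition_spec("sinus_bradycardia", hr_range = c(40, 55)),
    sinus_tachycardia = condition_spec("sinus_tachycardia", hr_range = c(105, 140)),
    atrial_fibrillation = condition_spec("atrial_fibrillation",
                                         hr_range = c(70, 120),
                                         rr_cv_range = c(0.2, 0.3),
                                         p_wave = FALSE, irregular = TRUE),
    prolonged_qt = condition_spec("prolonged_qt", qt_scale_range = c(1.3, 1.5)),
    wide_qrs = condition_spec("wide_qrs", qrs_scale_range = c(1.6, 2.0))
  )
}

# Per-wave amplitude projection onto the 12 leads, relative to lead II.
# Columns: P, Q, R, S, T. Values are stylised clinical polarities (aVR
# inverted, rS pattern in V1 growing to qR in V6), not a fitted dipole model.
lead_projection_matrix <- function() {
  m <- rbind(
    I   = c(0.55,  0.60, 0.70, 0.55, 0.60),
    II  = c(1.00,  1.00, 1.00, 1.00, 1.00),
    III = c(0.50,  0.55, 0.55, 0.70, 0.45),
    aVR = c(-0.75, -0.70, -0.85, -0.75, -0.70),
    aVL = c(0.20,  0.35, 0.25, 0.15, 0.25),
    aVF = c(0.75,  0.80, 0.80, 0.85, 0.70),
    V1  = c(0.35, -0.20, 0.18, 1.30, -0.30),
    V2  = c(0.40, -0.10, 0.40, 1.45, 0.55),
    V3  = c(0.45,  0.15, 0.65, 1.10, 0.80),
    V4  = c(0.50,  0.40, 0.95, 0.70, 0.85),
    V5  = c(0.52,  0.55, 0.90, 0.45, 0.75),
    V6  = c(0.55,  0.65, 0.80, 0.30, 0.65)
  )
  colnames(m) <- c("P", "Q", "R", "S", "T")
  m
}

# Gaussian-bump beat morphology on the reference lead (II), in mV and
# seconds. Centers are offsets from the R peak; QT scaling moves/widens the
# T wave, QRS scaling widens Q/R/S.
wave_table <- function(qt_scale, qrs_scale, p_wave) {
  tab <- data.frame(
    wave   = c("P", "Q", "R", "S", "T"),
    center = c(-0.165, -0.033 * qrs_scale, 0, 0.033 * qrs_scale, 0.30 * qt_scale),
    width  = c(0.026, 0.011 * qrs_scale, 0.013 * qrs_scale,
               0.013 * qrs_scale, 0.065 * qt_scale),
    amp    = c(0.15, -0.12, 1.20, -0.30, 0.35)
  )
  if (!p_wave) tab$amp[tab$wave == "P"] <- 0
  tab
}

#' Generate one synthetic 12-lead ECG record
#'
#' Builds a beat train (regular with mild jitter, or i.i.d. RR intervals for
#' irregular rhythms), places Gaussian P/Q/R/S/T components per beat on a
#' reference lead, projects them onto the 12 standard leads through a fixed
#' per-wave projection matrix, and adds baseline wander plus Gaussian sensor
#' noise. Deterministic given `(spec, fs, duration_s, seed)`.
#'
#' @param spec A [condition_spec()].
#' @param fs Sampling rate in Hz (>= 100).
#' @param duration_s Duration in seconds (>= 10; the page renderer consumes
#'   the first 10 s).
#' @param seed Integer seed for this record.
#' @param condition_set Character vector of condition names the label map
#'   must cover; defaults to the built-in presets.
#'
#' @return An `ecg_record`: list with `record_id`, `leads` (named list of 12
#'   numeric vectors in mV), `fs`, `duration_s`, `labels` (named logical) and
#'   `seed`.
#' @export
#' @examples
#' rec <- generate_record(ecg_conditions()$sinus_bradycardia, seed = 1)
#' length(rec$leads$II)
generate_record <- function(spec, fs = 500, duration_s = 10, seed = 1L,
                            condition_set = names(ecg_conditions())) {
  if (!inherits(spec, "condition_spec")) abort("`spec` must be a condition_spec.")
  check_number(fs, "fs", lower = 100)
  check_number(duration_s, "duration_s", lower = 10)
  n <- round(fs * duration_s)
  proj <- lead_projection_matrix()

  with_seed(seed, {
    hr <- runif(1, spec$hr_range[1], spec$hr_range[2])
    cv <- runif(1, spec$rr_cv_range[1], spec$rr_cv_range[2])
    qt_scale <- runif(1, spec$qt_scale_range[1], spec$qt_scale_range[2])
    qrs_scale <- runif(1, spec$qrs_scale_range[1], spec$qrs_scale_range[2])
    mean_rr <- 60 / hr

    # beat train covering the record with margin for edge waves
    n_beats <- ceiling((duration_s + 2) / mean_rr) + 2
    rr <- if (spec$irregular) {
      shape <- 1 / cv^2
      mean_rr * rgamma(n_beats, shape = shape, rate = shape)
    } else {
      pmax(mean_rr * (1 + cv * rnorm(n_beats)), 0.25)
    }
    r_times <- runif(1, 0.2, 0.2 + mean_rr) + cumsum(c(0, rr[-length(rr)]))
    r_times <- r_times[r_times > -0.5 & r_times < duration_s + 0.5]

    tt <- (seq_len(n) - 1L) / fs
    waves <- wave_table(qt_scale, qrs_scale, spec$p_wave)

    # one train per wave type, built on local windows for speed
    trains <- matrix(0, nrow = n, ncol = nrow(waves))
    colnames(trains) <- waves$wave
    amp_jitter <- matrix(1 + 0.03 * rnorm(length(r_times) * nrow(waves)),
                         nrow = length(r_times))
    for (w in seq_len(nrow(waves))) {
      sigma <- waves$width[w]
      for (b in seq_along(r_times)) {
        ctr <- r_times[b] + waves$center[w]
        i0 <- max(1L, floor((ctr - 4 * sigma) * fs) + 1L)
        i1 <- min(n, ceiling((ctr + 4 * sigma) * fs) + 1L)
        if (i0 > i1) next
        idx <- i0:i1
        trains[idx, w] <- trains[idx, w] +
          waves$amp[w] * amp_jitter[b, w] * exp(-((tt[idx] - ctr)^2) / (2 * sigma^2))
      }
    }

    leads <- vector("list", 12L)
    names(leads) <- ECG_LEADS
    for (ld in ECG_LEADS) {
      base <- as.numeric(trains %*% proj[ld, ])
      wander <- 0.05 * sin(2 * pi * runif(1, 0.15, 0.45) * tt + runif(1, 0, 2 * pi))
      leads[[ld]] <- base + wander + rnorm(n, sd = 0.02)
    }

    labels <- stats::setNames(condition_set == spec$name, condition_set)
    structure(
      list(
        record_id = sprintf("%s_%010d", spec$name, as.integer(seed)),
        leads = leads,
        fs = fs,
        duration_s = duration_s,
        labels = labels,
        seed = as.integer(seed)
      ),
      class = "ecg_record"
    )
  })
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s: 12 leads x %d samples @ %g Hz, labels: %s>\n",
              x$record_id, length(x$leads[[1]]), x$fs,
              paste(names(x$labels)[x$labels], collapse = ",") %||% ""))
  invisible(x)
}

#' Generate a labeled dataset of synthetic ECG records
#'
#' Draws each record's condition from `condition_mix` and generates it with a
#' seed derived deterministically from `seed`.
#'
#' @param n Number of records (>= 1).
#' @param condition_mix Named numeric vector of class fractions summing to 1.
#' @param fs,duration_s Passed to [generate_record()].
#' @param seed Master seed.
#' @param conditions Named list of [condition_spec()]s; must cover the names
#'   in `condition_mix`.
#'
#' @return A list of `ecg_record`s.
#' @export
#' @examples
#' recs <- generate_dataset(4, c(normal = 0.5, sinus_bradycardia = 0.5), seed = 7)
generate_dataset <- function(n, condition_mix, fs = 500, duration_s = 10,
                             seed = 1L, conditions = ecg_conditions()) {
  check_number(n, "n", lower = 1)
  if (length(conditions) == 0L) abort("`conditions` must be a non-empty list.")
  if (is.null(names(condition_mix)) ||
      !all(names(condition_mix) %in% names(conditions))) {
    abort("`condition_mix` names must match `conditions`.")
  }
  if (abs(sum(condition_mix) - 1) > 1e-9) {
    abort("`condition_mix` fractions must sum to 1.")
  }
  draws <- with_seed(seed, sample(names(condition_mix), n, replace = TRUE,
                                  prob = condition_mix))
  seeds <- derive_seeds(seed + 1L, n)
  purrr::map2(draws, seeds, function(cond, s) {
    generate_record(conditions[[cond]], fs = fs, duration_s = duration_s,
                    seed = s, condition_set = names(conditions))
  })
}

#' Dataset manifest as a tibble
#'
#' One row per record: `record_id`, optional file `path`, and one logical
#' column per condition label.
#'
#' @param records List of `ecg_record`s.
#' @param paths Optional character vector of file paths.
#' @return A tibble.
#' @export
dataset_manifest <- function(records, paths = NA_character_) {
  labs <- purrr::map(records, "labels")
  tibble::tibble(
    record_id = purrr::map_chr(records, "record_id"),
    path = rep_len(paths, length(records))
  ) |>
    dplyr::bind_cols(purrr::map_dfr(labs, ~ tibble::as_tibble(as.list(.x))))
}

#' Detect R peaks with a simple threshold rule
#'
#' Local maxima exceeding `thresh_frac` of the demeaned signal's maximum,
#' separated by at least `min_rr_s`. Intended for validating generated
#' records (rate and rhythm-regularity measurements), not as a clinical
#' detector.
#'
#' @param x Numeric signal (typically lead II) in mV.
#' @param fs Sampling rate in Hz.
#' @param thresh_frac Fraction of the maximum used as detection threshold.
#' @param min_rr_s Minimum separation between peaks in seconds.
#' @return Integer vector of peak sample indices (1-based).
#' @export
detect_rpeaks <- function(x, fs, thresh_frac = 0.55, min_rr_s = 0.25) {
  z <- x - median(x)
  th <- thresh_frac * max(z)
  cand <- which(z > th)
  cand <- cand[cand > 1 & cand < length(z)]
  cand <- cand[z[cand] >= z[cand - 1] & z[cand] >= z[cand + 1]]
  if (length(cand) == 0L) return(integer())
  keep <- cand[1]
  for (i in cand[-1]) {
    if ((i - keep[length(keep)]) >= min_rr_s * fs) {
      keep <- c(keep, i)
    } else if (z[i] > z[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  keep
}

#' Measure heart rate and RR variability of a record
#'
#' @param record An `ecg_record`.
#' @param lead Lead used for detection (default "II").
#' @return A tibble with `hr_bpm` (mean rate), `rr_cv` (coefficient of
#'   variation of RR intervals) and `n_beats`.
#' @export
measure_heart_rate <- function(record, lead = "II") {
  pk <- detect_rpeaks(record$leads[[lead]], record$fs)
  rr <- diff(pk) / record$fs
  tibble::tibble(
    hr_bpm = if (length(rr)) 60 / mean(rr) else NA_real_,
    rr_cv = if (length(rr) > 1) stats::sd(rr) / mean(rr) else NA_real_,
    n_beats = length(pk)
  )
}
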