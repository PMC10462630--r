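#' Render the full-resolution page canvas for a record
#'
#' Draws calibrated ECG paper (1 mm minor / 5 mm major grid at
#' `px_per_mm`), an optional 1 mV calibration pulse per row, the short-lead
#' panels (each showing `seconds_per_panel` of its lead at the paper speed
#' and gain, consecutive panels in a row showing consecutive time windows),
#' and the rhythm strip along the bottom. Returns the pre-resample canvas;
#' [render_page()] wraps it with resampling to the network input size.
#'
#' @param record An `ecg_record`.
#' @param spec A [format_spec()].
#' @return Numeric array `H x W x 3` in `[0,1]` with a `geom` attribute
#'   (pixel geometry: trace origin, px per second/mV, row baselines,
#'   calibration-pulse columns) used by geometry checks.
#' @export
render_canvas <- function(record, spec) {
  if (!inherits(record, "ecg_record")) abort("`record` must be an ecg_record.")
  if (!inherits(spec, "format_spec")) abort("`spec` must be a format_spec.")
  need_s <- max(spec$seconds_per_panel * spec$panel_grid[2],
                if (!is.null(spec$rhythm_lead)) spec$rhythm_seconds else 0)
  if (record$duration_s < need_s - 1e-9) {
    abort("record shorter than the window required by the format.")
  }
  if (!all(spec$lead_order %in% names(record$leads))) {
    abort("record is missing leads named in the format.")
  }

  ppm <- spec$px_per_mm
  margin <- round(spec$margins_mm * ppm)
  cal_px <- if (spec$calibration_pulse) round(8 * ppm) else 0L
  pps <- spec$mm_per_s * ppm                    # px per second
  ppmv <- spec$mm_per_mV * ppm                  # px per mV
  rows <- spec$panel_grid[1]; cols <- spec$panel_grid[2]
  rh <- round(spec$row_height_mm * ppm)
  has_rhythm <- !is.null(spec$rhythm_lead)
  panel_w <- round(cols * spec$seconds_per_panel * pps)
  rhythm_w <- if (has_rhythm) round(spec$rhythm_seconds * pps) else 0L
  W <- 2L * margin + cal_px + max(panel_w, rhythm_w)
  n_rows_tot <- rows + as.integer(has_rhythm)
  H <- 2L * margin + n_rows_tot * rh

  canvas <- array(1, dim = c(H, W, 3L))

  # grid: minor 1 mm, major 5 mm
  minor_x <- seq(1L, W, by = max(1L, round(ppm)))
  minor_y <- seq(1L, H, by = max(1L, round(ppm)))
  major_x <- seq(1L, W, by = max(1L, round(5 * ppm)))
  major_y <- seq(1L, H, by = max(1L, round(5 * ppm)))
  for (ch in 1:3) {
    canvas[, minor_x, ch] <- spec$grid_minor[ch]
    canvas[minor_y, , ch] <- spec$grid_minor[ch]
  }
  for (ch in 1:3) {
    canvas[, major_x, ch] <- spec$grid_major[ch]
    canvas[major_y, , ch] <- spec$grid_major[ch]
  }

  x0 <- margin + cal_px + 1L                    # column of t = 0
  baselines <- margin + (seq_len(n_rows_tot) - 0.5) * rh
  baselines <- round(baselines)
  fs <- record$fs

  # Drawing collects linear (row + (col-1)*H) indices; ink is painted once
  # at the end so the canvas is never copied per stroke.
  seg_idx <- function(rws, cls) {
    ok <- rws >= 1 & rws <= H & cls >= 1 & cls <= W
    rws[ok] + (cls[ok] - 1L) * H
  }

  # trace polyline: per canvas column take the y-range of its samples and
  # connect to the previous column's last sample so the curve is continuous
  trace_idx <- function(x_px, y_px, y_top, y_bot, lw = 2L) {
    ci <- as.integer(round(x_px))
    yi <- as.integer(round(pmin(pmax(y_px, y_top), y_bot)))
    lo <- tapply(yi, ci, min); hi <- tapply(yi, ci, max)
    ylast <- tapply(yi, ci, function(v) v[length(v)])
    cls <- as.integer(names(lo))
    nc <- length(cls)
    prev <- c(NA_integer_, ylast[-nc])
    l <- as.integer(ifelse(is.na(prev), lo, pmin(lo, prev)))
    h <- as.integer(ifelse(is.na(prev), hi, pmax(hi, prev)))
    lens <- h - l + 1L
    rws <- sequence(lens, from = l)
    cl1 <- rep(cls, lens)
    unlist(lapply(0:(lw - 1L), function(off) seg_idx(rws, cl1 + off)),
           use.names = FALSE)
  }

  ink <- list()
  cal_rise_x <- integer(0)
  if (spec$calibration_pulse) {
    for (r in seq_len(n_rows_tot)) {
      yb <- baselines[r]
      yt <- yb - round(ppmv)                    # 1 mV pulse top
      xa <- margin + round(1.5 * ppm)           # rising edge column
      xb <- margin + round(6.5 * ppm)           # falling edge column
      ink[[length(ink) + 1L]] <- c(
        seg_idx(rep(yb, xa - margin), margin + seq_len(xa - margin)),
        seg_idx(yt:yb, rep(xa, length(yt:yb))),
        seg_idx(rep(yt, xb - xa + 1L), xa:xb),
        seg_idx(yt:yb, rep(xb, length(yt:yb))),
        seg_idx(rep(yb, margin + cal_px - xb + 1L), xb:(margin + cal_px))
      )
      cal_rise_x <- c(cal_rise_x, xa)
    }
  }

  sp <- spec$seconds_per_panel
  for (r in seq_len(rows)) {
    y_top <- margin + (r - 1L) * rh + 1L
    y_bot <- margin + r * rh
    for (cc in seq_len(cols)) {
      lead <- spec$lead_order[(r - 1L) * cols + cc]
      t0 <- (cc - 1L) * sp; t1 <- cc * sp
      i0 <- floor(t0 * fs) + 1L
      i1 <- min(floor(t1 * fs), length(record$leads[[lead]]))
      idx <- i0:i1
      tt <- (idx - 1L) / fs
      x_px <- x0 + tt * pps
      y_px <- baselines[r] - record$leads[[lead]][idx] * ppmv
      ink[[length(ink) + 1L]] <- trace_idx(x_px, y_px, y_top, y_bot)
    }
  }
  if (has_rhythm) {
    r <- n_rows_tot
    idx <- seq_len(min(floor(spec$rhythm_seconds * fs), length(record$leads[[spec$rhythm_lead]])))
    tt <- (idx - 1L) / fs
    ink[[length(ink) + 1L]] <- trace_idx(
      x0 + tt * pps,
      baselines[r] - record$leads[[spec$rhythm_lead]][idx] * ppmv,
      margin + (r - 1L) * rh + 1L, margin + r * rh
    )
  }
  all_ink <- unlist(ink, use.names = FALSE)
  np <- H * W
  for (ch in 1:3) canvas[all_ink + (ch - 1L) * np] <- 0

  attr(canvas, "geom") <- list(
    px_per_mm = ppm, px_per_s = pps, px_per_mV = ppmv,
    margin_px = margin, cal_px = cal_px, trace_x0 = x0,
    row_height_px = rh, baselines = baselines, cal_rise_x = cal_rise_x,
    n_rows = n_rows_tot
  )
  canvas
}

#' Render a record to a page image at the network input size
#'
#' Renders the full-resolution canvas via [render_canvas()] then resamples
#' bilinearly to `out_h x out_w`. The result carries domain `"clean"` and the
#' record's labels. Deterministic.
#'
#' @inheritParams render_canvas
#' @param out_h,out_w Output size in pixels. The default 220 x 412 is a
#'   quarter-scale version of the full-page 880 x 1650 input, which remains
#'   available by passing those dimensions.
#' @return An [ecg_image()] with domain `"clean"`.
#' @export
#' @examples
#' rec <- generate_record(ecg_conditions()$normal, seed = 2)
#' img <- render_page(rec, format_spec(), out_h = 110, out_w = 206)
#' dim(img$pixels)
render_page <- function(record, spec = format_spec(), out_h = 220, out_w = 412) {
  check_number(out_h, "out_h", lower = 1)
  check_number(out_w, "out_w", lower = 1)
  canvas <- render_canvas(record, spec)
  px <- resample_bilinear(canvas, out_h, out_w)
  ecg_image(px, domain = "clean", format_id = spec$format_id,
            labels = record$labels, source_record_id = record$record_id)
}
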