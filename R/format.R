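#' Describe a printed 12-lead page format
#'
#' A format spec fixes everything about how a vendor lays a 12-lead recording
#' out on calibrated ECG paper: the short-lead panel grid, which lead goes in
#' which panel, the optional full-width rhythm strip, paper speed and gain,
#' grid colours and rendering density. The default is the common clinical
#' 3 x 4 layout (columns I/II/III, aVR/aVL/aVF, V1-V3, V4-V6 read
#' column-wise) with a 10 s lead II rhythm strip, 25 mm/s and 10 mm/mV.
#'
#' @param format_id Identifier string.
#' @param panel_grid Integer `c(rows, cols)` for the short leads; must
#'   multiply to 12.
#' @param lead_order The 12 lead names in row-major panel order.
#' @param rhythm_lead Lead plotted as the full-width strip, or `NULL`.
#' @param seconds_per_panel Seconds of signal per short-lead panel.
#' @param rhythm_seconds Seconds shown on the rhythm strip.
#' @param mm_per_s Paper speed.
#' @param mm_per_mV Gain.
#' @param px_per_mm Rendering density of the pre-resample canvas.
#' @param row_height_mm Vertical extent allotted to each panel row.
#' @param margins_mm Page margin.
#' @param grid_minor,grid_major RGB colours (length-3 in `[0,1]`) of the 1 mm
#'   and 5 mm grid lines.
#' @param calibration_pulse Draw a 1 mV calibration pulse at the start of
#'   each row?
#' @return An object of class `format_spec`.
#' @export
format_spec <- function(format_id = "default",
                        panel_grid = c(3L, 4L),
                        lead_order = c("I", "aVR", "V1", "V4",
                                       "II", "aVL", "V2", "V5",
                                       "III", "aVF", "V3", "V6"),
                        rhythm_lead = "II",
                        seconds_per_panel = 2.5,
                        rhythm_seconds = 10,
                        mm_per_s = 25,
                        mm_per_mV = 10,
                        px_per_mm = 4,
                        row_height_mm = 30,
                        margins_mm = 5,
                        grid_minor = c(1, 0.82, 0.82),
                        grid_major = c(1, 0.60, 0.60),
                        calibration_pulse = TRUE) {
  if (length(panel_grid) != 2L || prod(panel_grid) != 12L) {
    abort("`panel_grid` rows x cols must equal 12.")
  }
  if (length(lead_order) != 12L || !setequal(lead_order, ECG_LEADS)) {
    abort("`lead_order` must be a permutation of the 12 standard leads.")
  }
  if (!is.null(rhythm_lead)) {
    if (!rhythm_lead %in% ECG_LEADS) abort("unknown `rhythm_lead`.")
    if (seconds_per_panel * panel_grid[2] > rhythm_seconds + 1e-9) {
      abort("seconds_per_panel * cols must not exceed rhythm_seconds.")
    }
  }
  check_number(seconds_per_panel, "seconds_per_panel", lower = 0.5)
  check_number(px_per_mm, "px_per_mm", lower = 1)
  structure(
    list(format_id = format_id,
         panel_grid = as.integer(panel_grid),
         lead_order = lead_order, rhythm_lead = rhythm_lead,
         seconds_per_panel = seconds_per_panel,
         rhythm_seconds = rhythm_seconds,
         mm_per_s = mm_per_s, mm_per_mV = mm_per_mV,
         px_per_mm = px_per_mm, row_height_mm = row_height_mm,
         margins_mm = margins_mm,
         grid_minor = grid_minor, grid_major = grid_major,
         calibration_pulse = calibration_pulse),
    class = "format_spec"
  )
}

#' Generate distinct format variants ("unseen formats")
#'
#' Emulates pages from other vendors: random permutations of the panel
#' placement, rhythm strip present or absent (and on a different lead), grid
#' colour and margin jitter. Variants are pairwise distinct in their
#' `(lead_order, rhythm_lead)` tuple and differ from `base`.
#'
#' @param base A [format_spec()] to perturb.
#' @param n Number of variants (>= 1).
#' @param seed Integer seed; the variant list is deterministic given it.
#' @return List of `format_spec`s.
#' @export
make_format_variants <- function(base, n, seed = 1L) {
  check_number(n, "n", lower = 1)
  key <- function(lo, rl) paste(paste(lo, collapse = ","), rl %||% "none")
  with_seed(seed, {
    out <- vector("list", n)
    seen <- key(base$lead_order, base$rhythm_lead)
    for (i in seq_len(n)) {
      repeat {
        lo <- sample(ECG_LEADS)
        rl <- if (runif(1) < 0.5) NULL else sample(c("II", "V1", "V5"), 1)
        if (!key(lo, rl) %in% seen) break
      }
      seen <- c(seen, key(lo, rl))
      tint <- runif(1, 0.6, 1)
      out[[i]] <- format_spec(
        format_id = sprintf("%s_var%02d", base$format_id, i),
        panel_grid = base$panel_grid,
        lead_order = lo, rhythm_lead = rl,
        seconds_per_panel = base$seconds_per_panel,
        rhythm_seconds = base$rhythm_seconds,
        mm_per_s = base$mm_per_s, mm_per_mV = base$mm_per_mV,
        px_per_mm = base$px_per_mm, row_height_mm = base$row_height_mm,
        margins_mm = runif(1, 3, 8),
        grid_minor = pmin(1, base$grid_minor * c(1, tint, tint)),
        grid_major = pmin(1, base$grid_major * c(1, tint, tint)),
        calibration_pulse = runif(1) < 0.7
      )
    }
    out
  })
}
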