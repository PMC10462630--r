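test_that("format specs validate their invariants", {
  expect_error(format_spec(panel_grid = c(2, 4)), "12")
  expect_error(format_spec(lead_order = rep("II", 12)), "permutation")
  expect_error(format_spec(seconds_per_panel = 3), "rhythm_seconds")
  expect_silent(format_spec(seconds_per_panel = 3, rhythm_lead = NULL))
  expect_error(format_spec(rhythm_lead = "X1"), "rhythm_lead")
})

test_that("rendered pages have the requested size, range and metadata", {
  rec <- generate_record(ecg_conditions()$normal, seed = 4)
  img <- render_page(rec, format_spec(), out_h = 220, out_w = 412)
  expect_equal(dim(img$pixels), c(220, 412, 3))
  expect_true(min(img$pixels) >= 0 && max(img$pixels) <= 1)
  expect_identical(img$domain, "clean")
  expect_identical(img$labels, rec$labels)
  expect_identical(img$source_record_id, rec$record_id)
  # full-scale network input size remains available by configuration
  big <- render_page(rec, format_spec(), out_h = 880, out_w = 1650)
  expect_equal(dim(big$pixels), c(880, 1650, 3))
  # determinism
  expect_identical(img$pixels, render_page(rec, format_spec(),
                                           out_h = 220, out_w = 412)$pixels)
})

flat_record <- function(value = 0) {
  rec <- generate_record(ecg_conditions()$normal, seed = 1)
  rec$leads <- lapply(rec$leads, function(x) rep(value, length(x)))
  rec
}

test_that("an all-zero record draws flat baselines confined to one row band", {
  spec <- format_spec(calibration_pulse = FALSE)
  cv <- render_canvas(flat_record(), spec)
  g <- attr(cv, "geom")
  dark <- which(cv[, , 1] < 0.5, arr.ind = TRUE)
  expect_gt(nrow(dark), 0)
  # every dark pixel sits within 2 px (line thickness) of a row baseline
  dist <- vapply(dark[, 1], function(r) min(abs(r - g$baselines)), numeric(1))
  expect_lte(max(dist), 2)
})

test_that("the 1 mV calibration pulse is 10 mm tall at the canvas density", {
  rec <- flat_record()
  for (ppm in c(3, 4)) {
    spec <- format_spec(px_per_mm = ppm)
    cv <- render_canvas(rec, spec)
    g <- attr(cv, "geom")
    col <- cv[, g$cal_rise_x[1], 1]
    dark_rows <- which(col < 0.5)
    # rows belonging to the first panel row's pulse
    band <- dark_rows[abs(dark_rows - g$baselines[1]) <= g$px_per_mV + 2]
    expect_equal(max(band) - min(band), round(spec$mm_per_mV * ppm))
  }
})

test_that("a spike at t = 1 s lands at the expected rhythm-strip column", {
  rec <- flat_record()
  spec <- format_spec(calibration_pulse = FALSE)
  i_spike <- round(1.0 * rec$fs) + 1L
  rec$leads$II[i_spike] <- 1.0   # 1 mV instant spike
  cv <- render_canvas(rec, spec)
  g <- attr(cv, "geom")
  rhythm_band <- (g$baselines[4] - g$px_per_mV - 3):(g$baselines[4] - 3)
  dark_cols <- which(apply(cv[rhythm_band, , 1] < 0.5, 2, any))
  expected <- g$trace_x0 + 1.0 * g$px_per_s
  expect_true(any(abs(dark_cols - expected) <= 2))
  expect_true(all(abs(dark_cols - expected) <= 3))
})

test_that("trace ink does not decrease when amplitudes double", {
  rec <- generate_record(ecg_conditions()$normal, seed = 6)
  rec$leads <- lapply(rec$leads, function(x) x * 0.4)  # stay in panel bounds
  spec <- format_spec(calibration_pulse = FALSE)
  ink <- function(r) sum(render_canvas(r, spec)[, , 1] < 0.5)
  rec2 <- rec
  rec2$leads <- lapply(rec$leads, function(x) x * 2)
  expect_gte(ink(rec2), ink(rec))
})

test_that("rendering errors on short records and missing leads", {
  rec <- generate_record(ecg_conditions()$normal, seed = 1)
  short <- rec
  short$duration_s <- 6
  expect_error(render_canvas(short, format_spec()), "shorter")
  broken <- rec
  names(broken$leads)[2] <- "XX"
  expect_error(render_canvas(broken, format_spec()), "missing leads")
})

test_that("format variants are distinct, valid and deterministic", {
  base <- format_spec()
  vars <- make_format_variants(base, 6, seed = 9)
  expect_length(vars, 6)
  keys <- vapply(vars, function(v) {
    paste(paste(v$lead_order, collapse = ","), v$rhythm_lead %||% "none")
  }, character(1))
  base_key <- paste(paste(base$lead_order, collapse = ","), base$rhythm_lead)
  expect_equal(anyDuplicated(keys), 0L)
  expect_false(base_key %in% keys)
  for (v in vars) expect_s3_class(v, "format_spec")
  expect_equal(make_format_variants(base, 6, seed = 9)[[3]], vars[[3]])
  one <- make_format_variants(base, 1, seed = 2)
  expect_false(identical(one[[1]]$lead_order, base$lead_order) &&
                 identical(one[[1]]$rhythm_lead, base$rhythm_lead))
})

test_that("PNG round-trip preserves pixels to 8-bit precision and metadata", {
  dir <- withr::local_tempdir()
  rec <- generate_record(ecg_conditions()$normal, seed = 8)
  img <- render_page(rec, out_h = 64, out_w = 120)
  p <- file.path(dir, "img.png")
  write_image_png(img, p)
  back <- read_image_png(p)
  expect_lte(max(abs(back$pixels - img$pixels)), 1 / 255)
  expect_identical(back$domain, "clean")
  expect_identical(unlist(back$labels), img$labels)
  man <- image_manifest(list(img, back), c("a.png", "b.png"))
  expect_equal(nrow(man), 2)
  expect_true("sinus_bradycardia" %in% names(man))
})
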