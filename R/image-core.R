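#' Construct a rendered ECG page image object
#'
#' Wraps an H x W x 3 pixel array in `[0, 1]` with its domain tag
#' (`"clean"` for rendered pages, `"captured"` for simulated mobile-device
#' frames), the page format id, and the labels inherited from the source
#' record.
#'
#' @param pixels Numeric array `H x W x 3` with values in `[0, 1]`.
#' @param domain `"clean"` or `"captured"`.
#' @param format_id Page format identifier.
#' @param labels Named logical vector of condition labels.
#' @param source_record_id Id of the `ecg_record` the page was rendered from.
#' @return An object of class `ecg_image`.
#' @export
ecg_image <- function(pixels, domain = c("clean", "captured"),
                      format_id = "default", labels = logical(),
                      source_record_id = NA_character_) {
  domain <- match.arg(domain)
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L || d[1] < 1L || d[2] < 1L) {
    abort("`pixels` must be an H x W x 3 array.")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    abort("`pixels` must be finite and within [0, 1].")
  }
  structure(
    list(pixels = pixels, domain = domain, format_id = format_id,
         labels = labels, source_record_id = source_record_id),
    class = "ecg_image"
  )
}

#' @export
print.ecg_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<ecg_image %dx%dx3 domain=%s format=%s record=%s>\n",
              d[1], d[2], x$domain, x$format_id, x$source_record_id))
  invisible(x)
}

# Bilinear sampling of an H x W x 3 array at fractional (row, col)
# coordinates (1-based, matrices of equal dim). Out-of-range samples get
# `fill`. The workhorse behind resampling, perspective and crumple warps.
bilinear_sample <- function(pixels, rows, cols, fill = 1) {
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  out_dim <- dim(rows)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  inside <- rows >= 1 & rows <= h & cols >= 1 & cols <= w
  # clamp corner indices so indexing is always valid; fill applied after
  r0c <- pmin(pmax(r0, 1L), h); r1c <- pmin(r0c + 1L, h)
  c0c <- pmin(pmax(c0, 1L), w); c1c <- pmin(c0c + 1L, w)
  w00 <- (1 - fr) * (1 - fc); w01 <- (1 - fr) * fc
  w10 <- fr * (1 - fc); w11 <- fr * fc
  out <- array(fill, dim = c(out_dim, 3L))
  np <- h * w
  i00 <- r0c + (c0c - 1L) * h; i01 <- r0c + (c1c - 1L) * h
  i10 <- r1c + (c0c - 1L) * h; i11 <- r1c + (c1c - 1L) * h
  for (ch in 1:3) {
    off <- (ch - 1L) * np
    v <- w00 * pixels[i00 + off] + w01 * pixels[i01 + off] +
      w10 * pixels[i10 + off] + w11 * pixels[i11 + off]
    v[!inside] <- fill
    out[, , ch] <- v
  }
  out
}

# Bilinear resize to (out_h, out_w), mapping pixel centers.
resample_bilinear <- function(pixels, out_h, out_w) {
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  rr <- ((seq_len(out_h) - 0.5) * h / out_h) + 0.5 - 1e-9
  cc <- ((seq_len(out_w) - 0.5) * w / out_w) + 0.5 - 1e-9
  rows <- matrix(rr, nrow = out_h, ncol = out_w)
  cols <- matrix(cc, nrow = out_h, ncol = out_w, byrow = TRUE)
  out <- bilinear_sample(pixels, rows, cols, fill = 1)
  pmin(pmax(out, 0), 1)
}

#' Write / read a rendered image as PNG with JSON sidecar
#'
#' Pixels are quantised to 8-bit RGB by rounding; the sidecar stores domain,
#' format id, labels and source record id.
#'
#' @param image An `ecg_image`.
#' @param path PNG output path (sidecar written next to it as `.json`).
#' @return Invisibly, `path`.
#' @export
write_image_png <- function(image, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(image$pixels, path)
  side <- list(domain = image$domain, format_id = image$format_id,
               labels = as.list(image$labels),
               source_record_id = image$source_record_id)
  jsonlite::write_json(side, sub("\\.png$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), dim = c(dim(px), 3L))
  px <- px[, , 1:3, drop = FALSE]
  side <- jsonlite::read_json(sub("\\.png$", ".json", path),
                              simplifyVector = TRUE)
  ecg_image(px, domain = side$domain, format_id = side$format_id,
            labels = unlist(side$labels),
            source_record_id = side$source_record_id)
}

#' Manifest for a set of page images
#'
#' @param images List of `ecg_image`s.
#' @param paths Optional file paths.
#' @return Tibble with image_id, path, domain, format_id and label columns.
#' @export
image_manifest <- function(images, paths = NA_character_) {
  tibble::tibble(
    image_id = seq_along(images),
    path = rep_len(paths, length(images)),
    source_record_id = purrr::map_chr(images, "source_record_id"),
    domain = purrr::map_chr(images, "domain"),
    format_id = purrr::map_chr(images, "format_id")
  ) |>
    dplyr::bind_cols(purrr::map_dfr(images,
                                    ~ tibble::as_tibble(as.list(.x$labels))))
}
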