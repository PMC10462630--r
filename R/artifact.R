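#' Configuration for simulated mobile-device capture
#'
#' Software emulation of the artifacts a phone camera introduces when filming
#' a printed page: page crumple (smooth sinusoidal warp), perspective tilt,
#' uneven illumination, cast shadows/occlusions, defocus blur and sensor
#' noise. Strengths are tunable; the defaults produce a clearly shifted but
#' still legible target domain.
#'
#' @param perspective_strength Corner displacement bound as a fraction of the
#'   image dimension (see [random_perspective()]).
#' @param illumination_amp Multiplicative shading amplitude in `[0, 1)`.
#' @param occlusion_count Number of dark soft-edged patches.
#' @param occlusion_max_frac Maximum area fraction per patch (< 0.25).
#' @param wave_amp_px Crumple displacement amplitude in pixels.
#' @param blur_sigma_px Gaussian blur sigma in pixels.
#' @param noise_std Additive Gaussian noise sd in pixel units.
#' @param seed Default seed used by [simulate_capture()] when none is given.
#' @return An object of class `capture_config`.
#' @export
capture_config <- function(perspective_strength = 0.12,
                           illumination_amp = 0.35,
                           occlusion_count = 2L,
                           occlusion_max_frac = 0.08,
                           wave_amp_px = 3,
                           blur_sigma_px = 0.8,
                           noise_std = 0.02,
                           seed = 1L) {
  for (nm in c("perspective_strength", "illumination_amp", "occlusion_count",
               "occlusion_max_frac", "wave_amp_px", "blur_sigma_px",
               "noise_std")) {
    check_number(get(nm), nm, lower = 0)
  }
  if (illumination_amp >= 1) abort("`illumination_amp` must be < 1.")
  if (occlusion_max_frac >= 0.25) abort("`occlusion_max_frac` must be < 0.25.")
  structure(
    list(perspective_strength = perspective_strength,
         illumination_amp = illumination_amp,
         occlusion_count = as.integer(occlusion_count),
         occlusion_max_frac = occlusion_max_frac,
         wave_amp_px = wave_amp_px, blur_sigma_px = blur_sigma_px,
         noise_std = noise_std, seed = as.integer(seed)),
    class = "capture_config"
  )
}

# Projective transform (x_src, y_src) <- M (x_dst, y_dst) from 4 point
# correspondences; x = column, y = row. Solves the standard 8x8 system with
# m33 = 1.
solve_homography <- function(src_xy, dst_xy) {
  a <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    xd <- dst_xy[i, 1]; yd <- dst_xy[i, 2]
    xs <- src_xy[i, 1]; ys <- src_xy[i, 2]
    a[2 * i - 1, ] <- c(xd, yd, 1, 0, 0, 0, -xd * xs, -yd * xs)
    a[2 * i, ]     <- c(0, 0, 0, xd, yd, 1, -xd * ys, -yd * ys)
    b[2 * i - 1] <- xs; b[2 * i] <- ys
  }
  p <- solve(a, b)
  matrix(c(p, 1), 3, 3, byrow = TRUE)
}

apply_homography <- function(pixels, m, fill = 1) {
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  cols <- matrix(seq_len(w), nrow = h, ncol = w, byrow = TRUE)
  rows <- matrix(seq_len(h), nrow = h, ncol = w)
  den <- m[3, 1] * cols + m[3, 2] * rows + m[3, 3]
  xs <- (m[1, 1] * cols + m[1, 2] * rows + m[1, 3]) / den
  ys <- (m[2, 1] * cols + m[2, 2] * rows + m[2, 3]) / den
  bilinear_sample(pixels, ys, xs, fill = fill)
}

#' Random perspective transformation
#'
#' With probability `prob`, each of the four image corners is displaced
#' inward, independently and uniformly, by at most
#' `distortion * dimension / 2` in each axis; the induced projective
#' homography is applied with bilinear sampling and white fill. Otherwise the
#' image is returned unchanged. This is both the training-time augmentation
#' (defaults 0.15 / 0.8) and the tilt component of [simulate_capture()].
#'
#' @param pixels `H x W x 3` array in `[0,1]`.
#' @param distortion Corner displacement bound as a fraction (in `[0, 0.5]`).
#' @param prob Probability of applying the transform.
#' @return Transformed array, same shape; the sampled corner positions are
#'   attached as attribute `"corners"` (`NULL` when the identity was taken).
#' @export
random_perspective <- function(pixels, distortion = 0.15, prob = 0.8) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) abort("input must be an H x W x 3 array.")
  check_number(distortion, "distortion", lower = 0, upper = 0.5)
  check_number(prob, "prob", lower = 0, upper = 1)
  if (prob <= 0 || runif(1) >= prob) return(pixels)
  if (distortion == 0) return(pixels)
  h <- d[1]; w <- d[2]
  dx <- runif(4, 0, distortion * w / 2)
  dy <- runif(4, 0, distortion * h / 2)
  # corners in (x, y) = (col, row): TL, TR, BR, BL; displacement inward
  src <- rbind(c(1, 1), c(w, 1), c(w, h), c(1, h))
  dst <- rbind(c(1 + dx[1], 1 + dy[1]),
               c(w - dx[2], 1 + dy[2]),
               c(w - dx[3], h - dy[3]),
               c(1 + dx[4], h - dy[4]))
  m <- solve_homography(src, dst)  # dst -> src for inverse sampling
  out <- apply_homography(pixels, solve(m), fill = 1)
  out <- pmin(pmax(out, 0), 1)
  attr(out, "corners") <- list(src = src, dst = dst)
  out
}

# separable Gaussian blur with edge replication
blur_gaussian <- function(pixels, sigma) {
  if (sigma <= 0) return(pixels)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  out <- array(0, dim(pixels))
  tmp <- array(0, dim(pixels))
  for (ch in 1:3) {
    x <- pixels[, , ch]
    acc <- matrix(0, h, w)
    for (j in seq_along(k)) {
      cc <- pmin(pmax(seq_len(w) + (j - r - 1L), 1L), w)
      acc <- acc + k[j] * x[, cc]
    }
    tmp[, , ch] <- acc
  }
  for (ch in 1:3) {
    x <- tmp[, , ch]
    acc <- matrix(0, h, w)
    for (j in seq_along(k)) {
      rr <- pmin(pmax(seq_len(h) + (j - r - 1L), 1L), h)
      acc <- acc + k[j] * x[rr, ]
    }
    out[, , ch] <- acc
  }
  out
}

#' Simulate one mobile-device capture of a clean page image
#'
#' Applies, in order: crumple warp, perspective tilt, multiplicative smooth
#' illumination, dark soft-edged occlusion patches, Gaussian blur, additive
#' sensor noise, and a final clamp to `[0,1]`. The order mimics physical
#' image formation (page deformation, camera pose, lighting, optics, sensor).
#' With all strengths zero the pixels pass through unchanged. Labels and
#' format id are preserved; the domain tag flips to `"captured"`.
#'
#' @param image An [ecg_image()] with domain `"clean"`.
#' @param config A [capture_config()].
#' @param seed Seed for this frame; defaults to `config$seed`.
#' @return An [ecg_image()] with domain `"captured"`.
#' @export
simulate_capture <- function(image, config = capture_config(), seed = NULL) {
  if (!inherits(image, "ecg_image")) abort("`image` must be an ecg_image.")
  if (!inherits(config, "capture_config")) abort("`config` must be a capture_config.")
  if (image$domain != "clean") abort("`image` must be a clean-domain page.")
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  with_seed(seed %||% config$seed, {
    if (config$wave_amp_px > 0) {
      fx <- runif(1, 1, 3); fy <- runif(1, 1, 3)
      p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
      cols <- matrix(seq_len(w), nrow = h, ncol = w, byrow = TRUE)
      rows <- matrix(seq_len(h), nrow = h, ncol = w)
      src_r <- rows + config$wave_amp_px * sin(2 * pi * fx * cols / w + p1)
      src_c <- cols + config$wave_amp_px * sin(2 * pi * fy * rows / h + p2)
      px <- bilinear_sample(px, src_r, src_c, fill = 1)
    }
    if (config$perspective_strength > 0) {
      px <- random_perspective(px, distortion = config$perspective_strength,
                               prob = 1)
      attr(px, "corners") <- NULL
    }
    if (config$illumination_amp > 0) {
      ax <- runif(1, 0.3, 1); ay <- runif(1, 0.3, 1); ph <- runif(1, 0, 2 * pi)
      cols <- matrix(seq_len(w), nrow = h, ncol = w, byrow = TRUE)
      rows <- matrix(seq_len(h), nrow = h, ncol = w)
      field <- 1 + config$illumination_amp *
        sin(2 * pi * (ax * cols / w + ay * rows / h) + ph)
      for (ch in 1:3) px[, , ch] <- px[, , ch] * field
    }
    if (config$occlusion_count > 0 && config$occlusion_max_frac > 0) {
      cols <- matrix(seq_len(w), nrow = h, ncol = w, byrow = TRUE)
      rows <- matrix(seq_len(h), nrow = h, ncol = w)
      for (k in seq_len(config$occlusion_count)) {
        frac <- runif(1, 0.25, 1) * config$occlusion_max_frac
        aspect <- runif(1, 0.4, 2.5)
        # ellipse with area frac * H * W: pi * ra * rb = frac * h * w
        rb <- sqrt(frac * h * w / (pi * aspect))
        ra <- aspect * rb
        cy <- runif(1, 1, h); cx <- runif(1, 1, w)
        d <- sqrt(((rows - cy) / ra)^2 + ((cols - cx) / rb)^2)
        shade <- 0.2 + 0.8 * pmin(pmax((d - 1) / 0.25, 0), 1)  # soft edge
        for (ch in 1:3) px[, , ch] <- px[, , ch] * shade
      }
    }
    if (config$blur_sigma_px > 0) px <- blur_gaussian(px, config$blur_sigma_px)
    if (config$noise_std > 0) {
      px <- px + array(rnorm(length(px), sd = config$noise_std), dim(px))
    }
    px <- pmin(pmax(px, 0), 1)
  })
  ecg_image(px, domain = "captured", format_id = image$format_id,
            labels = image$labels, source_record_id = image$source_record_id)
}

#' Simulate several capture frames per page
#'
#' Emits `frames_per_image` independently perturbed captures of each input
#' page, mirroring how consecutive video frames of the same printed page all
#' differ. Frame seeds are derived deterministically from `seed`.
#'
#' @param images List of clean [ecg_image()]s.
#' @param config A [capture_config()].
#' @param frames_per_image Frames per input page (>= 1).
#' @param seed Master seed.
#' @return List of captured `ecg_image`s (length `n * frames_per_image`).
#' @export
capture_dataset <- function(images, config = capture_config(),
                            frames_per_image = 1L, seed = 1L) {
  check_number(frames_per_image, "frames_per_image", lower = 1)
  n <- length(images) * frames_per_image
  seeds <- derive_seeds(seed, n)
  out <- vector("list", n)
  k <- 0L
  for (img in images) {
    for (f in seq_len(frames_per_image)) {
      k <- k + 1L
      out[[k]] <- simulate_capture(img, config, seed = seeds[k])
    }
  }
  out
}
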