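# Pixel convention: internal movie arrays are [row, col, frame] with row 1 at
# y = 0 (origin at the field's lower-left corner); pixel (r, c) is centred at
# x = (c - 0.5) * pixel_size_um, y = (r - 0.5) * pixel_size_um. The TIFF
# writer flips rows so files follow the usual top-left image convention.

um_to_px <- function(um, pixel_size_um) um / pixel_size_um + 0.5

px_to_um <- function(px, pixel_size_um) (px - 0.5) * pixel_size_um

add_gaussian_spot <- function(img, cx_px, cy_px, amplitude, sigma_px) {
  h <- nrow(img); w <- ncol(img)
  half <- ceiling(4 * sigma_px)
  c0 <- max(1L, floor(cx_px) - half); c1 <- min(w, floor(cx_px) + half)
  r0 <- max(1L, floor(cy_px) - half); r1 <- min(h, floor(cy_px) + half)
  if (c0 > c1 || r0 > r1) return(img)
  cc <- c0:c1; rr <- r0:r1
  gx <- exp(-(cc - cx_px)^2 / (2 * sigma_px^2))
  gy <- exp(-(rr - cy_px)^2 / (2 * sigma_px^2))
  img[rr, cc] <- img[rr, cc] + amplitude * outer(gy, gx)
  img
}

apply_shot_noise <- function(img, seed_offset_rng_active = TRUE) {
  # additive normal noise with variance matched to the (Poisson-like)
  # expected signal; background sd is sqrt(background)
  noisy <- img + stats::rnorm(length(img), 0, sqrt(pmax(img, 1)))
  noisy[noisy < 0] <- 0
  noisy
}

#' Render a track set into a single-channel movie stack
#'
#' Produces a synthetic fluorescence movie: each organelle is drawn as an
#' isotropic Gaussian intensity profile at its position in every frame where
#' its track is observed, on a constant background with signal-dependent
#' (variance-matched normal) noise. Spot peak amplitude is
#' `snr * sqrt(background)`, so the peak-to-background-noise ratio is
#' approximately `snr`. Positions outside the field are clipped (not drawn).
#'
#' @param ts A `trackset` whose frame indices fit in the geometry.
#' @param geometry An `acquisition_geometry`; frames beyond
#'   `geometry$n_frames` are ignored.
#' @param psf_sigma_px Gaussian point-spread sigma in pixels.
#' @param snr Peak signal over background noise, > 0.
#' @param seed Integer seed for the noise.
#' @param background Mean background level (camera counts).
#' @return A numeric array `[height_px, width_px, n_frames]` of class
#'   `movie_stack` with the geometry attached as attribute `geometry`.
#' @export
render_movie <- function(ts, geometry = acquisition_geometry(),
                         psf_sigma_px = 1.3, snr = 10, seed = 1L,
                         background = 100) {
  stopifnot(inherits(ts, "trackset"))
  if (psf_sigma_px <= 0) stop("psf_sigma_px must be > 0")
  if (snr <= 0) stop("snr must be > 0")
  tr <- ts$tracks
  if (nrow(tr) > 0) {
    span <- geometry$field_length_um
    if (any(tr$x_um < -span | tr$x_um > 2 * span |
            tr$y_um < -span | tr$y_um > 2 * span)) {
      stop("track positions exceed the field by more than one field length; ",
           "geometry/track unit mismatch?")
    }
  }
  nf <- geometry$n_frames
  h <- geometry$height_px; w <- geometry$width_px
  px <- geometry$pixel_size_um
  amp <- snr * sqrt(background)

  withr::with_seed(seed, {
    stack <- array(background, dim = c(h, w, nf))
    tr <- tr[tr$frame >= 0L & tr$frame < nf, , drop = FALSE]
    if (nrow(tr) > 0) {
      rel_int <- if ("intensity" %in% names(tr)) tr$intensity else 1
      by_frame <- split(seq_len(nrow(tr)), tr$frame)
      for (key in names(by_frame)) {
        f <- as.integer(key) + 1L
        img <- stack[, , f]
        for (i in by_frame[[key]]) {
          cx <- um_to_px(tr$x_um[i], px); cy <- um_to_px(tr$y_um[i], px)
          if (cx < 0.5 || cx > w + 0.5 || cy < 0.5 || cy > h + 0.5) next
          img <- add_gaussian_spot(img, cx, cy, amp * rel_int[i], psf_sigma_px)
        }
        stack[, , f] <- img
      }
    }
    for (f in seq_len(nf)) stack[, , f] <- apply_shot_noise(stack[, , f])
    structure(stack, geometry = geometry, class = c("movie_stack", "array"))
  })
}
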