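#' Simulate an immunofluorescence field of nuclei with foci
#'
#' Places `n_nuclei` non-overlapping elliptical nuclei in a 2-D field,
#' draws a Poisson number of foci per nucleus and channel at the given
#' rates, and renders each focus as a bright Gaussian blob inside its
#' nucleus on a noisy background. `truth_counts` records exactly the number
#' of rendered blobs per nucleus and channel, so downstream counting can be
#' scored against ground truth. Foci within one nucleus are placed with a
#' minimum mutual separation of six focus radii so that distinct truth
#' foci stay resolvable after thresholding; in the rare event that a crowded nucleus cannot
#' accommodate another focus after bounded retries, the focus is dropped and
#' the truth count reflects what was actually rendered.
#'
#' @param n_nuclei Number of nuclei (>= 1).
#' @param mean_foci_per_nucleus Per-channel Poisson rates (numeric vector,
#'   one entry per channel; names become channel names).
#' @param focus_radius_px Gaussian sigma of a rendered focus (px).
#' @param snr Focus peak over background noise.
#' @param seed Integer seed.
#' @param width_px,height_px Field size in pixels.
#' @param nucleus_radii_px Range of nucleus semi-axes (px).
#' @param background Mean background level.
#' @param max_retries Placement retries per nucleus before giving up.
#' @return An object of class `foci_field`: list with `nucleus_mask`
#'   (labelled integer matrix; 0 = background), `channels` (list of
#'   intensity matrices), `truth_counts` (tibble: `nucleus`, `channel`,
#'   `count`), `seed`.
#' @examples
#' ff <- simulate_foci_field(4, c(dsb = 3), seed = 1, width_px = 160,
#'                           height_px = 160)
#' sum(ff$truth_counts$count)
#' @export
simulate_foci_field <- function(n_nuclei,
                                mean_foci_per_nucleus = c(foci = 5),
                                focus_radius_px = 1.5,
                                snr = 10,
                                seed = 1L,
                                width_px = 512L,
                                height_px = 512L,
                                nucleus_radii_px = c(16, 22),
                                background = 100,
                                max_retries = 1000L) {
  if (n_nuclei < 1) stop("n_nuclei must be >= 1")
  if (any(mean_foci_per_nucleus < 0)) stop("foci rates must be >= 0")
  channels <- names(mean_foci_per_nucleus)
  if (is.null(channels)) {
    channels <- paste0("channel", seq_along(mean_foci_per_nucleus))
  }

  withr::with_seed(seed, {
    # place non-overlapping ellipses by rejection sampling
    margin <- max(nucleus_radii_px)
    placed <- matrix(numeric(0), ncol = 4)  # cx, cy, a, b
    tries <- 0L
    while (nrow(placed) < n_nuclei) {
      tries <- tries + 1L
      if (tries > max_retries * n_nuclei) {
        stop("field too small to place ", n_nuclei,
             " nuclei without overlap")
      }
      a <- stats::runif(1, nucleus_radii_px[1], nucleus_radii_px[2])
      b <- stats::runif(1, nucleus_radii_px[1], nucleus_radii_px[2])
      cx <- stats::runif(1, margin + 1, width_px - margin)
      cy <- stats::runif(1, margin + 1, height_px - margin)
      if (nrow(placed) > 0) {
        d <- sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2)
        if (any(d < placed[, 3] + a + 2)) next
      }
      placed <- rbind(placed, c(cx, cy, a, b))
    }

    cols <- matrix(rep(seq_len(width_px), each = height_px), nrow = height_px)
    rows <- matrix(rep(seq_len(height_px), width_px), nrow = height_px)
    mask <- matrix(0L, height_px, width_px)
    for (k in seq_len(n_nuclei)) {
      inside <- ((cols - placed[k, 1]) / placed[k, 3])^2 +
                ((rows - placed[k, 2]) / placed[k, 4])^2 <= 1
      mask[inside] <- k
    }

    amp <- snr * sqrt(background)
    min_sep <- 6 * focus_radius_px
    truth <- list()
    imgs <- list()
    for (ci in seq_along(channels)) {
      img <- matrix(background, height_px, width_px)
      counts <- integer(n_nuclei)
      for (k in seq_len(n_nuclei)) {
        target <- stats::rpois(1, mean_foci_per_nucleus[ci])
        pts <- matrix(numeric(0), ncol = 2)
        fails <- 0L
        while (nrow(pts) < target && fails < 200L) {
          # uniform inside the ellipse, with margin for the blob itself
          u <- stats::runif(1); th <- stats::runif(1, 0, 2 * pi)
          r <- sqrt(u)
          fx <- placed[k, 1] + r * cos(th) * (placed[k, 3] - focus_radius_px)
          fy <- placed[k, 2] + r * sin(th) * (placed[k, 4] - focus_radius_px)
          if (nrow(pts) > 0 &&
              any(sqrt((pts[, 1] - fx)^2 + (pts[, 2] - fy)^2) < min_sep)) {
            fails <- fails + 1L
            next
          }
          pts <- rbind(pts, c(fx, fy))
        }
        for (j in seq_len(nrow(pts))) {
          img <- add_gaussian_spot(img, pts[j, 1], pts[j, 2], amp,
                                   focus_radius_px)
        }
        counts[k] <- nrow(pts)
      }
      imgs[[channels[ci]]] <- apply_shot_noise(img)
      truth[[ci]] <- tibble::tibble(nucleus = seq_len(n_nuclei),
                                    channel = channels[ci], count = counts)
    }

    structure(list(nucleus_mask = mask,
                   channels = imgs,
                   truth_counts = dplyr::bind_rows(truth),
                   seed = seed),
              class = "foci_field")
  })
}

#' @export
print.foci_field <- function(x, ...) {
  cat("<foci_field> ", max(x$nucleus_mask), " nuclei, ",
      length(x$channels), " channel(s), ",
      sum(x$truth_counts$count), " foci\n", sep = "")
  invisible(x)
}
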