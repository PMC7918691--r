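log_kernel <- function(sigma_px) {
  half <- ceiling(4 * sigma_px)
  ax <- -half:half
  g <- exp(-ax^2 / (2 * sigma_px^2))
  G <- outer(g, g)
  G <- G / sum(G)
  r2 <- outer(ax^2, ax^2, "+")
  # negative Laplacian of Gaussian: positive response at bright blobs,
  # scale-normalized by sigma^2
  K <- -G * (r2 - 2 * sigma_px^2) / sigma_px^4
  K - mean(K)  # zero-sum: flat background gives zero response
}

local_maxima <- function(resp) {
  h <- nrow(resp); w <- ncol(resp)
  keep <- matrix(TRUE, h, w)
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  padded <- matrix(-Inf, h + 2, w + 2)
  padded[2:(h + 1), 2:(w + 1)] <- resp
  for (i in seq_len(nrow(shifts))) {
    nb <- padded[2:(h + 1) + shifts$dr[i], 2:(w + 1) + shifts$dc[i]]
    keep <- keep & (resp >= nb)
  }
  keep
}

#' Detect organelle spots in one movie frame
#'
#' Laplacian-of-Gaussian blob detection at a single scale: the frame is
#' convolved with a scale-normalized LoG kernel of width `sigma_px`, local
#' maxima of the (sign-inverted) response above the quality threshold are
#' kept, and each detection is refined to sub-pixel precision by an
#' intensity-weighted centroid in a `(2 * ceiling(2 * sigma) + 1)^2` window
#' of the background-subtracted frame. Two spots closer than about one
#' sigma merge into a single detection. Positions are returned in um using
#' the lower-left-origin pixel convention; the estimated diameter is
#' `2 * sigma * sqrt(2)` pixels.
#'
#' @param frame_image A 2-D numeric matrix (one frame, `[row, col]`).
#' @param sigma_px Detection scale in pixels (> 0).
#' @param threshold Quality cut-off on the scale-normalized LoG response;
#'   `NULL` chooses `5 * mad(response)` automatically.
#' @param pixel_size_um Pixel size in um.
#' @return A tibble of spots: `x_um`, `y_um`, `intensity` (window-summed,
#'   background-subtracted), `diameter_um`, `quality`.
#' @export
detect_spots <- function(frame_image, sigma_px = 1.3, threshold = NULL,
                         pixel_size_um = 0.22955) {
  if (length(dim(frame_image)) != 2L || !is.numeric(frame_image)) {
    stop("frame_image must be a 2-D numeric matrix")
  }
  if (sigma_px <= 0) stop("sigma_px must be > 0")
  K <- log_kernel(sigma_px)
  resp <- EBImage::filter2(frame_image, K, boundary = "replicate")
  if (is.null(threshold)) threshold <- 5 * stats::mad(resp)
  cand <- which(local_maxima(resp) & resp > threshold, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(tibble::tibble(x_um = numeric(), y_um = numeric(),
                          intensity = numeric(), diameter_um = numeric(),
                          quality = numeric()))
  }
  h <- nrow(frame_image); w <- ncol(frame_image)
  half <- ceiling(2 * sigma_px)
  out <- lapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]
    rr <- max(1L, r - half):min(h, r + half)
    cc <- max(1L, c - half):min(w, c + half)
    win <- frame_image[rr, cc, drop = FALSE]
    wgt <- win - min(win)
    s <- sum(wgt)
    if (s <= 0) {
      cy <- r; cx <- c
    } else {
      cy <- sum(rowSums(wgt) * rr) / s
      cx <- sum(colSums(wgt) * cc) / s
    }
    tibble::tibble(x_um = px_to_um(cx, pixel_size_um),
                   y_um = px_to_um(cy, pixel_size_um),
                   intensity = s,
                   diameter_um = 2 * sigma_px * sqrt(2) * pixel_size_um,
                   quality = resp[r, c])
  })
  dplyr::bind_rows(out)
}

#' Detect spots in every frame of a movie stack
#'
#' @param movie A `[height, width, frames]` array (e.g. from
#'   [render_movie()]).
#' @inheritParams detect_spots
#' @return A list of per-frame spot tibbles (frame f at index f, 0-based
#'   frame `f - 1`).
#' @export
detect_movie <- function(movie, sigma_px = 1.3, threshold = NULL,
                         pixel_size_um = 0.22955) {
  stopifnot(length(dim(movie)) == 3L)
  lapply(seq_len(dim(movie)[3]), function(f) {
    detect_spots(movie[, , f], sigma_px, threshold, pixel_size_um)
  })
}

#' Link per-frame spots into tracks
#'
#' Greedy nearest-neighbour frame-to-frame assignment: candidate links
#' between open track ends and current-frame spots are accepted in order of
#' increasing Euclidean distance (ties broken by smaller spot index, then
#' smaller track index), gated at `max_link_dist_um` per bridged frame — a
#' track end that has been unmatched for `g` frames may link within
#' `(g + 1) * max_link_dist_um`, up to `max_gap_frames` missing frames.
#' Tracks with fewer than 2 points are discarded.
#'
#' @param spots_per_frame List of per-frame spot tibbles (as from
#'   [detect_movie()]); index f holds 0-based frame `f - 1`.
#' @param max_link_dist_um Gating radius per frame step (um).
#' @param max_gap_frames Maximum number of missing frames to bridge.
#' @param frame_interval_s Frame interval used to time-stamp points (s).
#' @param metadata Metadata list passed to the resulting `trackset`.
#' @return A `trackset`.
#' @export
link_tracks <- function(spots_per_frame, max_link_dist_um = 2,
                        max_gap_frames = 2L, frame_interval_s = 0.3,
                        metadata = list()) {
  if (length(spots_per_frame) == 0L) stop("no frames to link")
  if (max_link_dist_um <= 0) stop("max_link_dist_um must be > 0")
  if (max_gap_frames < 0) stop("max_gap_frames must be >= 0")

  tracks <- list()   # each: list(rows = tibble, last_frame)
  active <- integer(0)

  for (f in seq_along(spots_per_frame)) {
    frame0 <- f - 1L
    spots <- spots_per_frame[[f]]
    n_spots <- if (is.null(spots)) 0L else nrow(spots)
    assigned_spot <- rep(FALSE, n_spots)

    if (length(active) && n_spots) {
      last_xy <- t(vapply(tracks[active], function(t) {
        rows <- t$rows
        c(rows$x_um[nrow(rows)], rows$y_um[nrow(rows)])
      }, numeric(2)))
      gaps <- vapply(tracks[active], function(t) frame0 - t$last_frame - 1L,
                     integer(1))
      d <- sqrt(outer(last_xy[, 1], spots$x_um, "-")^2 +
                outer(last_xy[, 2], spots$y_um, "-")^2)
      gate <- (gaps + 1) * max_link_dist_um
      ok <- d <= matrix(gate, nrow = length(active), ncol = n_spots)
      cand <- which(ok, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(d[cand], cand[, 2], cand[, 1])
        used_track <- rep(FALSE, length(active))
        for (i in ord) {
          ti <- cand[i, 1]; si <- cand[i, 2]
          if (used_track[ti] || assigned_spot[si]) next
          used_track[ti] <- TRUE
          assigned_spot[si] <- TRUE
          id <- active[ti]
          row <- spots[si, , drop = FALSE]
          row$frame <- frame0
          tracks[[id]]$rows <- dplyr::bind_rows(tracks[[id]]$rows, row)
          tracks[[id]]$last_frame <- frame0
        }
      }
    }

    if (n_spots) {
      for (si in which(!assigned_spot)) {
        row <- spots[si, , drop = FALSE]
        row$frame <- frame0
        tracks[[length(tracks) + 1L]] <- list(rows = row, last_frame = frame0)
      }
    }
    active <- which(vapply(tracks, function(t) {
      frame0 - t$last_frame <= max_gap_frames
    }, logical(1)))
  }

  keep <- which(vapply(tracks, function(t) nrow(t$rows) >= 2L, logical(1)))
  if (!length(keep)) {
    return(trackset(tibble::tibble(track_id = integer(), frame = integer(),
                                   t_s = numeric(), x_um = numeric(),
                                   y_um = numeric(), intensity = numeric()),
                    metadata))
  }
  rows <- dplyr::bind_rows(lapply(seq_along(keep), function(i) {
    r <- tracks[[keep[i]]]$rows
    r$track_id <- i
    r$t_s <- r$frame * frame_interval_s
    r
  }))
  cols <- intersect(c("track_id", "frame", "t_s", "x_um", "y_um",
                      "intensity", "diameter_um", "quality"), names(rows))
  trackset(rows[, cols], metadata)
}
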