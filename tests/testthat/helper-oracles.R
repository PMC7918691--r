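# Independent oracles used across the suite. These deliberately re-derive
# results from first principles (naive loops, enumeration, textbook
# formulas) so they share no code with the implementation they check.

small_geometry <- function(px = 128L, frames = 60L) {
  acquisition_geometry(width_px = px, height_px = px, n_frames = frames)
}

# Ward hierarchical clustering by explicit Lance-Williams recursion on
# squared Euclidean distances (heights on the distance scale).
ward_oracle_heights <- function(m) {
  n <- nrow(m)
  D2 <- as.matrix(stats::dist(m))^2
  size <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  for (it in seq_len(n - 1L)) {
    best <- c(Inf, 0, 0)
    for (i in active) {
      for (j in active) {
        if (i < j && D2[i, j] < best[1]) best <- c(D2[i, j], i, j)
      }
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, sqrt(best[1]))
    for (k in setdiff(active, c(i, j))) {
      D2[i, k] <- D2[k, i] <-
        ((size[i] + size[k]) * D2[i, k] + (size[j] + size[k]) * D2[j, k] -
         size[k] * D2[i, j]) / (size[i] + size[j] + size[k])
    }
    size[i] <- size[i] + size[j]
    active <- setdiff(active, j)
  }
  heights
}

# Minimal-total-distance one-to-one assignment by explicit enumeration
# (n <= 7), with gating: pairs beyond the gate stay unmatched.
assignment_oracle_cost <- function(from_xy, to_xy, gate) {
  n_from <- nrow(from_xy); n_to <- nrow(to_xy)
  d <- sqrt(outer(from_xy[, 1], to_xy[, 1], "-")^2 +
            outer(from_xy[, 2], to_xy[, 2], "-")^2)
  d[d > gate] <- NA
  best <- list(cost = Inf, links = -1L)
  recurse <- function(i, used, cost, links) {
    if (i > n_from) {
      if (links > best$links ||
          (links == best$links && cost < best$cost)) {
        best <<- list(cost = cost, links = links)
      }
      return()
    }
    for (j in seq_len(n_to)) {
      if (!used[j] && !is.na(d[i, j])) {
        used[j] <- TRUE
        recurse(i + 1L, used, cost + d[i, j], links + 1L)
        used[j] <- FALSE
      }
    }
    recurse(i + 1L, used, cost, links)  # leave i unmatched
  }
  recurse(1L, rep(FALSE, n_to), 0, 0L)
  best
}

# Triangle threshold re-derived with a naive per-bin loop and the
# point-to-line distance formula |a x + b y + c| / sqrt(a^2 + b^2).
triangle_oracle <- function(v, n_bins = 256L) {
  v <- as.numeric(v)
  breaks <- seq(min(v), max(v), length.out = n_bins + 1L)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  h <- counts / max(counts)
  peak <- which.max(counts)
  nz <- range(which(counts > 0))
  far <- if ((nz[2] - peak) >= (peak - nz[1])) nz[2] else nz[1]
  # line through (peak, h[peak]) and (far, h[far]): a x + b y + c = 0
  a <- h[far] - h[peak]
  b <- -(far - peak)
  cc <- -(a * peak + b * h[peak])
  rng <- if (far > peak) peak:far else far:peak
  dist <- abs(a * rng + b * h[rng] + cc) / sqrt(a^2 + b^2)
  best <- rng[which.max(dist)]
  (breaks[best] + breaks[best + 1L]) / 2
}

# Textbook one-way ANOVA + pooled-variance pairwise t with Bonferroni.
anova_oracle <- function(groups) {
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  grand <- mean(unlist(groups))
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- k - 1L; dfw <- N - k
  F_stat <- (ssb / dfb) / (ssw / dfw)
  p <- stats::pf(F_stat, dfb, dfw, lower.tail = FALSE)
  s2p <- ssw / dfw
  m <- k * (k - 1) / 2
  pair <- list()
  idx <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      idx <- idx + 1L
      t_stat <- unname((means[i] - means[j]) /
                       sqrt(s2p * (1 / n[i] + 1 / n[j])))
      p_raw <- 2 * stats::pt(-abs(t_stat), dfw)
      pair[[idx]] <- c(i = i, j = j, p_raw = p_raw,
                       p_adj = min(1, p_raw * m))
    }
  }
  list(F = F_stat, p = p, pairwise = do.call(rbind, pair))
}

# Fraction of ground-truth tracks recovered by majority overlap: a truth
# track counts as recovered when one predicted track matches more than half
# of its points (same frame, position within tol_um).
track_recovery_fraction <- function(truth_ts, pred_ts, tol_um = 0.5) {
  t_tr <- truth_ts$tracks
  p_tr <- pred_ts$tracks
  ids <- unique(t_tr$track_id)
  recovered <- 0L
  for (id in ids) {
    g <- t_tr[t_tr$track_id == id, ]
    best <- 0
    for (pid in unique(p_tr$track_id)) {
      p <- p_tr[p_tr$track_id == pid, ]
      m <- merge(g[, c("frame", "x_um", "y_um")],
                 p[, c("frame", "x_um", "y_um")], by = "frame")
      if (!nrow(m)) next
      ok <- sqrt((m$x_um.x - m$x_um.y)^2 + (m$y_um.x - m$y_um.y)^2) < tol_um
      best <- max(best, sum(ok) / nrow(g))
    }
    if (best > 0.5) recovered <- recovered + 1L
  }
  recovered / length(ids)
}

# Track set laid out for imaging tests: lanes in y, starts centred in x so
# tracks stay inside a small field.
laned_trackset <- function(n_lanes, geometry, seed = 5, duration_s = 18,
                           state = "mobile", organelle = "mito",
                           lane_gap_um = 3.2) {
  ts <- simulate_tracks(state, organelle, n_tracks = n_lanes, seed = seed,
                        duration_s = duration_s, dt_s = 0.3,
                        geometry = geometry)
  tr <- ts$tracks
  for (id in unique(tr$track_id)) {
    i <- tr$track_id == id
    tr$y_um[i] <- tr$y_um[i] - tr$y_um[i][1] + 3 + (id - 1) * lane_gap_um
    tr$x_um[i] <- tr$x_um[i] - tr$x_um[i][1] + geometry$field_length_um / 2
  }
  ts$tracks <- tr
  ts
}

stationary_trackset <- function(x_um, y_um, n_frames = 10L, dt = 0.3) {
  trackset(tibble::tibble(track_id = 1L, frame = 0:(n_frames - 1L),
                          t_s = (0:(n_frames - 1L)) * dt,
                          x_um = x_um, y_um = y_um, intensity = 1),
           list())
}
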