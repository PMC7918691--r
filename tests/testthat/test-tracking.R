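test_that("a blank noise frame yields no detections above threshold", {
  withr::with_seed(1, {
    img <- matrix(100 + rnorm(64 * 64, 0, 10), 64, 64)
  })
  spots <- detect_spots(img, sigma_px = 1.3, threshold = 100)
  expect_equal(nrow(spots), 0L)
  expect_error(detect_spots(array(0, c(4, 4, 4))), "2-D")
})

test_that("well-separated rendered spots are each recovered within 0.5 px", {
  g <- small_geometry(px = 128L, frames = 1L)
  px <- g$pixel_size_um
  xs <- c(5, 12, 19, 26, 8); ys <- c(5, 10, 15, 20, 25)
  ts <- trackset(tibble::tibble(track_id = 1:5, frame = 0L, t_s = 0,
                                x_um = xs, y_um = ys, intensity = 1), list())
  mv <- render_movie(ts, g, psf_sigma_px = 1.3, snr = 10, seed = 3)
  spots <- detect_spots(mv[, , 1], sigma_px = 1.3, pixel_size_um = px)
  expect_equal(nrow(spots), 5L)
  for (i in 1:5) {
    d <- sqrt((spots$x_um - xs[i])^2 + (spots$y_um - ys[i])^2) / px
    expect_lt(min(d), 0.5)
  }
  expect_true(all(spots$diameter_um > 0))
})

test_that("two spots one sigma apart merge into a single detection", {
  g <- small_geometry(px = 64L, frames = 1L)
  px <- g$pixel_size_um
  sep <- 1.3 * px  # 1 sigma
  ts <- trackset(tibble::tibble(track_id = 1:2, frame = 0L, t_s = 0,
                                x_um = c(7, 7 + sep), y_um = 7,
                                intensity = 1), list())
  mv <- render_movie(ts, g, psf_sigma_px = 1.3, snr = 20, seed = 4)
  spots <- detect_spots(mv[, , 1], sigma_px = 1.3, pixel_size_um = px)
  expect_equal(nrow(spots), 1L)
})

test_that("unambiguous chains link into single tracks", {
  # one spot drifting slowly: a single track spanning all frames
  frames <- lapply(0:9, function(f) {
    tibble::tibble(x_um = 5 + 0.1 * f, y_um = 3, intensity = 1)
  })
  ts <- link_tracks(frames, max_link_dist_um = 2, max_gap_frames = 0,
                    frame_interval_s = 0.3)
  expect_equal(n_tracks(ts), 1L)
  expect_equal(nrow(ts$tracks), 10L)
  expect_equal(ts$tracks$t_s, (0:9) * 0.3)
  expect_error(link_tracks(list()), "no frames")
})

test_that("distant spots never swap identities", {
  # two tracks always > 2 * gate apart -> 2 tracks, no switches
  frames <- lapply(0:7, function(f) {
    tibble::tibble(x_um = c(2 + 0.2 * f, 20 - 0.2 * f), y_um = c(2, 20),
                   intensity = 1)
  })
  ts <- link_tracks(frames, max_link_dist_um = 2, max_gap_frames = 1)
  expect_equal(n_tracks(ts), 2L)
  tr <- ts$tracks
  for (id in unique(tr$track_id)) {
    y <- tr$y_um[tr$track_id == id]
    expect_equal(length(unique(y)), 1L)  # no identity switch across lanes
  }
})

test_that("gap closing bridges a missing frame without inventing points", {
  frames <- lapply(0:6, function(f) {
    if (f == 3) return(tibble::tibble(x_um = numeric(), y_um = numeric(),
                                      intensity = numeric()))
    tibble::tibble(x_um = 5 + 0.15 * f, y_um = 4, intensity = 1)
  })
  ts <- link_tracks(frames, max_link_dist_um = 1, max_gap_frames = 1)
  expect_equal(n_tracks(ts), 1L)
  expect_equal(sort(ts$tracks$frame), c(0:2, 4:6))  # no interpolated point
  # with no gap closing the chain breaks in two
  ts0 <- link_tracks(frames, max_link_dist_um = 1, max_gap_frames = 0)
  expect_equal(n_tracks(ts0), 2L)
})

test_that("every link respects its gating radius and no spot is reused", {
  withr::with_seed(11, {
    frames <- lapply(0:9, function(f) {
      tibble::tibble(x_um = runif(6, 0, 15), y_um = runif(6, 0, 15),
                     intensity = 1)
    })
  })
  gate <- 2.5
  ts <- link_tracks(frames, max_link_dist_um = gate, max_gap_frames = 2)
  tr <- ts$tracks
  # no spot in two tracks: (frame, x, y) combinations unique
  expect_false(any(duplicated(tr[, c("frame", "x_um", "y_um")])))
  for (id in unique(tr$track_id)) {
    g <- tr[tr$track_id == id, ]
    g <- g[order(g$frame), ]
    if (nrow(g) < 2) next
    step <- sqrt(diff(g$x_um)^2 + diff(g$y_um)^2)
    gaps <- diff(g$frame)
    expect_true(all(step <= gaps * gate + 1e-9))
    expect_true(all(gaps <= 3))
  }
})

test_that("greedy linking stays within 10% of brute-force optimal cost", {
  gate <- 3
  excess <- c()
  for (seed in 1:8) {
    withr::with_seed(seed, {
      a <- cbind(runif(5, 0, 10), runif(5, 0, 10))
      b <- a + matrix(rnorm(10, 0, 0.8), ncol = 2)
    })
    frames <- list(tibble::tibble(x_um = a[, 1], y_um = a[, 2], intensity = 1),
                   tibble::tibble(x_um = b[, 1], y_um = b[, 2], intensity = 1))
    ts <- link_tracks(frames, max_link_dist_um = gate, max_gap_frames = 0)
    tr <- ts$tracks
    greedy_cost <- 0; greedy_links <- 0L
    for (id in unique(tr$track_id)) {
      g <- tr[tr$track_id == id, ]
      if (nrow(g) == 2L) {
        greedy_cost <- greedy_cost + sqrt(diff(g$x_um)^2 + diff(g$y_um)^2)
        greedy_links <- greedy_links + 1L
      }
    }
    opt <- assignment_oracle_cost(a, b, gate)
    expect_gte(greedy_links, opt$links - 1L)
    if (opt$links > 0 && greedy_links == opt$links) {
      excess <- c(excess, (greedy_cost - opt$cost) / opt$cost)
    }
  }
  expect_lt(mean(excess), 0.10)
})

test_that("detect + link recovers simulated tracks end to end", {
  g <- small_geometry(px = 128L, frames = 60L)
  ts <- laned_trackset(8, g, seed = 5, duration_s = 18)
  mv <- render_movie(ts, g, psf_sigma_px = 1.3, snr = 10, seed = 9)
  spots <- detect_movie(mv, sigma_px = 1.3, pixel_size_um = g$pixel_size_um)
  lt <- link_tracks(spots, max_link_dist_um = 2, max_gap_frames = 2,
                    frame_interval_s = 0.3)
  expect_gte(track_recovery_fraction(ts, lt), 0.9)
})
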