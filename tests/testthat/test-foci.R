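test_that("triangle threshold matches an independent reference", {
  withr::with_seed(1, {
    bg <- rnorm(20000, 10, 2)
    fg <- rnorm(600, 200, 10)
  })
  v <- c(bg, fg)
  thr <- triangle_threshold(matrix(v, ncol = 100))
  oracle <- triangle_oracle(v)
  bin_w <- diff(range(v)) / 256
  expect_lt(abs(thr - oracle), bin_w + 1e-9)
  expect_gt(thr, 10)
  expect_lt(thr, 200)
  expect_error(triangle_threshold(matrix(5, 3, 3)), "constant")
})

test_that("triangle threshold shifts exactly with a constant offset", {
  withr::with_seed(2, {
    v <- round(c(rnorm(5000, 50, 6), rnorm(300, 210, 12)))
  })
  t0 <- triangle_threshold(v)
  for (offset in c(17, 140)) {
    expect_equal(triangle_threshold(v + offset), t0 + offset,
                 tolerance = 1e-9)
  }
})

test_that("count_foci recovers ground truth on simulated fields", {
  ff <- simulate_foci_field(30, c(dsb = 5), seed = 4, snr = 10,
                            width_px = 480, height_px = 480)
  thr <- triangle_threshold(ff$channels$dsb)
  counts <- count_foci(ff$channels$dsb, ff$nucleus_mask, thr,
                       min_size_px = 4)
  truth <- ff$truth_counts$count
  expect_gte(mean(counts$count == truth), 0.95)
  expect_error(count_foci(ff$channels$dsb, ff$nucleus_mask[1:10, ], thr),
               "shape")
})

test_that("counting is monotone in threshold and min size", {
  ff <- simulate_foci_field(12, c(f = 4), seed = 6, snr = 10,
                            width_px = 320, height_px = 320)
  img <- ff$channels$f
  thr0 <- triangle_threshold(img)
  total <- function(thr, ms) sum(count_foci(img, ff$nucleus_mask, thr,
                                            min_size_px = ms)$count)
  counts_thr <- vapply(c(thr0, thr0 * 1.5, thr0 * 2.5), total,
                       numeric(1), ms = 4)
  expect_true(all(diff(counts_thr) <= 0))
  counts_ms <- vapply(c(1, 4, 12, 40), function(ms) total(thr0, ms),
                      numeric(1))
  expect_true(all(diff(counts_ms) <= 0))
  # empty binarization -> all zero
  zero <- count_foci(img, ff$nucleus_mask, max(img) + 1)
  expect_true(all(zero$count == 0))
})

test_that("generator bookkeeping and Poisson statistics are exact", {
  ff0 <- simulate_foci_field(6, c(a = 0, b = 0), seed = 3,
                             width_px = 256, height_px = 256)
  expect_true(all(ff0$truth_counts$count == 0))
  expect_equal(nrow(ff0$truth_counts), 12L)  # per nucleus per channel
  # labelled nuclei are disjoint by construction of a single label matrix;
  # check each label occupies a plausible contiguous area
  areas <- tabulate(ff0$nucleus_mask[ff0$nucleus_mask > 0])
  expect_length(areas, 6L)
  expect_true(all(areas > 200))
  # determinism
  ff1 <- simulate_foci_field(5, c(x = 3), seed = 11, width_px = 256,
                             height_px = 256)
  ff2 <- simulate_foci_field(5, c(x = 3), seed = 11, width_px = 256,
                             height_px = 256)
  expect_identical(ff1$channels$x, ff2$channels$x)
  expect_identical(ff1$truth_counts, ff2$truth_counts)
  # empirical mean within 3 standard errors of the Poisson rate
  ff <- simulate_foci_field(200, c(f = 5), seed = 1,
                            width_px = 1400, height_px = 1400)
  expect_lt(abs(mean(ff$truth_counts$count) - 5), 3 * sqrt(5 / 200))
  # impossible packing is rejected
  expect_error(simulate_foci_field(50, c(f = 1), seed = 1, width_px = 96,
                                   height_px = 96, max_retries = 20),
               "too small")
})

test_that("GA/DSB co-occurrence classification follows the stated rule", {
  expect_equal(as.character(classify_ga_dsb(2, 0)), "A")
  expect_equal(as.character(classify_ga_dsb(1, 3)), "B")
  expect_equal(as.character(classify_ga_dsb(0, 5)), "unclassified")
  expect_equal(as.character(classify_ga_dsb(1, 2)), "unclassified")
  expect_equal(as.character(classify_ga_dsb(1, 1)), "unclassified")
  expect_equal(as.character(classify_ga_dsb(0, 0)), "unclassified")
  expect_error(classify_ga_dsb(-1, 0), "non-negative")
  # the relaxed DSB-free reading is available as a flag
  expect_equal(as.character(classify_ga_dsb(1, 2, dsb_free_max = 2)), "A")
})

test_that("category fractions match analytic expectations on Poisson draws", {
  lambda_ga <- 1.5; lambda_dsb <- 2
  n <- 4000
  withr::with_seed(13, {
    ga <- rpois(n, lambda_ga); dsb <- rpois(n, lambda_dsb)
  })
  cls <- classify_ga_dsb(ga, dsb)
  p_ga <- 1 - exp(-lambda_ga)
  p_a <- p_ga * dpois(0, lambda_dsb)
  p_b <- p_ga * ppois(2, lambda_dsb, lower.tail = FALSE)
  se <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(cls == "A") - p_a), 3 * se(p_a))
  expect_lt(abs(mean(cls == "B") - p_b), 3 * se(p_b))
})

test_that("Pearson colocalization hits its endpoints and invariances", {
  withr::with_seed(21, {
    a <- matrix(runif(100 * 100), 100)
    b <- matrix(runif(100 * 100), 100)
  })
  expect_equal(pearson_colocalization(a, a), 1)
  expect_equal(pearson_colocalization(a, max(a) - a), -1)
  expect_lt(abs(pearson_colocalization(a, b)), 0.05)  # null bound, 1e4 px
  # invariant under positive affine rescaling
  expect_equal(pearson_colocalization(a, 3 + 2 * a), 1)
  r0 <- pearson_colocalization(a, b)
  expect_equal(pearson_colocalization(5 * a + 1, b), r0)
  # masked variant and degenerate inputs
  mask <- matrix(FALSE, 100, 100); mask[1:50, ] <- TRUE
  expect_equal(pearson_colocalization(a, 2 * a, mask), 1)
  expect_error(pearson_colocalization(a, matrix(1, 100, 100)), "variance")
  expect_error(pearson_colocalization(a, b[1:50, 1:50]), "shape")
})

test_that("per-100-cell normalization is exact arithmetic", {
  expect_equal(foci_per_100_cells(30, 60), 50)
  expect_equal(foci_per_100_cells(0, 10), 0)
  expect_equal(foci_per_100_cells(123, 100), 123)
  expect_error(foci_per_100_cells(5, 0), "n_cells")
})
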