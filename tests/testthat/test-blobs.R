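test_that("density map equals the brute-force per-pixel count", {
  withr::with_seed(10, {
    for (k in 1:5) {
      pts <- data.frame(x = runif(60), y = runif(60))
      g <- grid_spec(pts, n_px = 32)
      r <- runif(1, 0.05, 0.3)
      expect_identical(density_map(pts, g, r) + 0L, density_oracle(pts, g, r))
    }
  })
})

test_that("density of coincident points is additive", {
  g <- grid_spec(n_px = 32, x_min = 0, x_max = 1, y_min = 0, y_max = 1)
  one <- density_map(data.frame(x = 0.5, y = 0.5), g, 0.2)
  two <- density_map(data.frame(x = c(0.5, 0.5), y = c(0.5, 0.5)), g, 0.2)
  expect_equal(two, 2L * one)
  expect_true(all(one %in% c(0L, 1L)))
  # exactly the pixels whose centers lie within r
  cx <- g$x_min + (seq_len(32) - 0.5) * g$dx
  cy <- g$y_min + (seq_len(32) - 0.5) * g$dy
  expect_equal(one == 1L, outer((cx - 0.5)^2, (cy - 0.5)^2, "+") <= 0.04)
})

test_that("thresholded components are 8-connected and deterministically ordered", {
  m <- matrix(0L, 10, 10)
  m[2:4, 2:4] <- 5L
  m[7:9, 7:9] <- 5L
  expect_length(threshold_blobs(m, 1), 2)
  expect_length(threshold_blobs(m, 6), 0)
  # diagonal touch joins components under 8-connectivity
  m2 <- matrix(0L, 5, 5); m2[1, 1] <- 1L; m2[2, 2] <- 1L
  expect_length(threshold_blobs(m2, 1), 1)
  # larger component first; ties broken by first pixel
  m3 <- matrix(0L, 10, 10); m3[1:2, 1] <- 1L; m3[5:8, 5] <- 1L
  comps <- threshold_blobs(m3, 1)
  expect_equal(lengths(comps), c(4L, 2L))
})

test_that("components match an independent flood-fill oracle", {
  withr::with_seed(11, {
    for (k in 1:10) {
      dens <- matrix(rpois(40 * 40, 0.8), 40, 40)
      theta <- sample(1:3, 1)
      comps <- threshold_blobs(dens, theta)
      oracle <- components_oracle(dens >= theta)
      expect_equal(length(comps), max(oracle))
      got <- lapply(comps, sort)
      want <- lapply(split(which(oracle > 0), oracle[oracle > 0]), sort)
      # same partition regardless of label order
      expect_setequal(vapply(got, paste, character(1), collapse = ","),
                      vapply(want, paste, character(1), collapse = ","))
    }
  })
})

test_that("blob monotonicity in theta and r", {
  withr::with_seed(12, {
    pts <- data.frame(x = c(rnorm(50, 0, 0.05), rnorm(50, 1, 0.05)),
                      y = c(rnorm(50, 0, 0.05), rnorm(50, 1, 0.05)))
    g <- grid_spec(pts, n_px = 64)
    dens <- density_map(pts, g, 0.1)
    all_px <- function(comps) sort(unique(unlist(comps)))
    for (th in 1:4) {
      hi <- all_px(threshold_blobs(dens, th + 1))
      lo <- all_px(threshold_blobs(dens, th))
      expect_true(all(hi %in% lo))
    }
    # harvested sets grow with r at fixed theta
    h_r <- lapply(c(0.05, 0.1, 0.2), function(r) {
      comps <- threshold_blobs(density_map(pts, g, r), 1)
      sort(unique(unlist(lapply(comps, harvest_points, grid = g, emb = pts))))
    })
    expect_true(all(h_r[[1]] %in% h_r[[2]]))
    expect_true(all(h_r[[2]] %in% h_r[[3]]))
  })
})

test_that("harvesting is lag-oblivious and respects the grid", {
  withr::with_seed(13, {
    emb <- data.frame(x = runif(100), y = runif(100),
                      forward_lag = sample(1:20, 100, TRUE))
    emb$backward_lag <- emb$forward_lag - 21L
    g <- grid_spec(emb, n_px = 32)
    dens <- density_map(emb, g, 0.15)
    mask <- threshold_blobs(dens, 3)[[1]]
    h1 <- harvest_points(mask, g, emb)
    emb2 <- emb
    emb2$forward_lag <- sample(emb2$forward_lag)  # permute lags
    expect_identical(harvest_points(mask, g, emb2), h1)
    # full-grid mask harvests everything
    expect_equal(harvest_points(seq_len(32L * 32L), g, emb),
                 seq_len(100))
    # a point outside the grid is never harvested, with a warning
    emb3 <- rbind(emb, data.frame(x = 99, y = 99, forward_lag = 1L,
                                  backward_lag = -20L))
    expect_warning(h3 <- harvest_points(seq_len(32L * 32L), g, emb3),
                   "outside the grid")
    expect_equal(h3, seq_len(100))
  })
})

test_that("slice selection follows the two-lag rule", {
  emb <- data.frame(x = 0, y = 0, forward_lag = rep(1:10, 3))
  emb$backward_lag <- emb$forward_lag - 11L
  expect_equal(nrow(slice_points(emb, 1)), 6)    # lags 1 and 2, 3 intervals
  expect_equal(nrow(slice_points(emb, -1)), 6)   # lags -1 and -2
  expect_equal(nrow(slice_points(emb, 5)), 6)
  expect_equal(sort(unique(slice_points(emb, 5)$forward_lag)), c(5L, 6L))
  expect_equal(sort(unique(slice_points(emb, -3)$backward_lag)), c(-4L, -3L))
  expect_error(slice_points(emb, 0))
})

test_that("blob proposals sit on density modes with a deterministic order", {
  g <- grid_spec(n_px = 64, x_min = 0, x_max = 1, y_min = 0, y_max = 1)
  uni <- density_map(data.frame(x = rep(0.3, 5), y = rep(0.3, 5)), g, 0.1)
  p1 <- propose_blobs(uni)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$peak, 5L)
  two <- density_map(data.frame(x = c(rep(0.2, 4), rep(0.8, 4)),
                                y = c(rep(0.2, 4), rep(0.8, 4))), g, 0.08)
  p2 <- propose_blobs(two)
  expect_equal(nrow(p2), 2)
  expect_equal(p2$peak, c(4L, 4L))
  expect_true(p2$px[1] < p2$px[2])  # tie broken by position
})
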