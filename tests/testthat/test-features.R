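test_that("I-DT handles the stationary / jumping / two-step cases", {
  # 2 s perfectly stationary: one fixation covering everything
  f <- detect_fixations_idt(rep(0, 500), rep(0, 500))
  expect_equal(nrow(f), 1)
  expect_equal(f$duration_ms, 2000)
  expect_equal(f$dispersion, 0)

  # +/-5 deg alternation every sample: no fixation possible
  jump <- rep(c(-5, 5), 250)
  expect_equal(nrow(detect_fixations_idt(jump, jump)), 0)

  # 500 ms at (0,0), then 500 ms at (5,5): two fixations whose bounds
  # match the brute-force oracle
  x <- c(rep(0, 125), rep(5, 125))
  f <- detect_fixations_idt(x, x)
  expect_equal(nrow(f), 2)
  orc <- idt_oracle(x, x)
  expect_equal(cbind(f$start_idx, f$end_idx), orc, ignore_attr = TRUE)
})

test_that("I-DT matches the brute-force oracle on random walks", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(100:400, 1)
    x <- cumsum(rnorm(n, 0, 0.12))
    y <- cumsum(rnorm(n, 0, 0.12))
    f <- detect_fixations_idt(x, y)
    orc <- idt_oracle(x, y)
    if (is.null(orc)) {
      expect_equal(nrow(f), 0)
    } else {
      expect_equal(cbind(f$start_idx, f$end_idx), orc, ignore_attr = TRUE)
    }
    # every emitted fixation satisfies the bound and none overlap
    if (nrow(f) > 1) expect_true(all(diff(f$start_idx) > 0))
    if (nrow(f) > 0) {
      expect_true(all(f$dispersion <= 1))
      expect_true(all(f$duration_ms >= 100))
      if (nrow(f) > 1) expect_true(all(f$start_idx[-1] > f$end_idx[-nrow(f)]))
    }
  }
})

test_that("fixation ground truth is recovered on noise-free trials", {
  par <- condition_params(jitter_sd = 0, blink_rate = 1e-9)
  for (seed in 1:5) {
    trial <- generate_trial("external", par, duration = 12, seed = seed)
    f <- detect_fixations_idt(trial$data$lx, trial$data$ly)
    truth <- trial$events$fixations
    truth <- truth[truth$duration_ms >= 100, ]
    # event-level matching: a truth fixation is hit when a detection
    # overlaps more than half of it
    hit <- vapply(seq_len(nrow(truth)), function(i) {
      ov <- pmin(f$end_idx, truth$end_idx[i]) - pmax(f$start_idx, truth$start_idx[i]) + 1
      any(ov > 0.5 * (truth$end_idx[i] - truth$start_idx[i] + 1))
    }, logical(1))
    recall <- mean(hit)
    precision <- nrow(truth) / max(1, nrow(f))
    f1 <- 2 * recall * precision / (recall + precision)
    expect_gte(f1, 0.9)
  }
})

test_that("saccades connect consecutive fixation centroids", {
  x <- c(rep(0, 125), rep(5, 125))
  f <- detect_fixations_idt(x, x)
  s <- derive_saccades(f, x, x)
  expect_equal(nrow(s), 1)
  expect_equal(s$amplitude, sqrt(50), tolerance = 1e-12)

  expect_equal(nrow(derive_saccades(f[1, ], x, x)), 0)
  expect_equal(nrow(derive_saccades(f[0, ], x, x)), 0)
})

test_that("vergence is the per-sample horizontal disparity", {
  expect_equal(vergence_signal(1:10, 1:10), rep(0, 10))
  expect_equal(vergence_signal(rep(0, 5), rep(1, 5)), rep(1, 5))
  # sinusoidal disparity of amplitude A has sample SD -> A/sqrt(2)
  t <- seq(0, 100, by = 0.001)
  v <- vergence_signal(rep(0, length(t)), 0.8 * sin(2 * pi * t))
  expect_equal(sd(v), 0.8 / sqrt(2), tolerance = 1e-3)
})

test_that("summary statistics follow the documented conventions", {
  expect_equal(unname(summary_stats(rep(3, 10))), c(3, 0, 3, 3, 3, 0, 0, 0))
  expect_equal(unname(summary_stats(numeric(0))), rep(0, 8))

  # direct moment oracle on {1,2,3,4}
  s <- c(1, 2, 3, 4)
  m2 <- mean((s - mean(s))^2); m3 <- mean((s - mean(s))^3)
  m4 <- mean((s - mean(s))^4)
  expect_equal(unname(summary_stats(s)),
               c(2.5, sd(s), 2.5, 4, 1, 3, m4 / m2^2 - 3, m3 / m2^1.5),
               tolerance = 1e-12)
})

test_that("minimum enclosing circle handles degenerate cases", {
  c1 <- min_enclosing_circle(1, 2)
  expect_equal(c1$radius, 0)
  expect_equal(c1$center, c(1, 2))

  c2 <- min_enclosing_circle(c(0, 4), c(0, 0))
  expect_equal(c2$radius, 2)
  expect_equal(c2$center, c(2, 0))

  expect_error(min_enclosing_circle(numeric(0), numeric(0)), "empty")
})

test_that("minimum enclosing circle matches the exhaustive support oracle", {
  set.seed(7)
  for (rep in 1:100) {
    n <- sample(3:25, 1)
    px <- runif(n, -5, 5); py <- runif(n, -5, 5)
    got <- min_enclosing_circle(px, py)
    want <- mec_oracle(px, py)
    expect_equal(got$radius, want$radius, tolerance = 1e-9)
    # every point inside
    expect_true(all(sqrt((px - got$center[1])^2 + (py - got$center[2])^2) <=
                      got$radius + 1e-9))
  }
})

test_that("the explicit feature vector has the frozen 75-value layout", {
  nms <- gaze_feature_names()
  expect_length(nms, 75)
  expect_equal(nms[1:3], c("n_fixations", "n_saccades", "n_blinks"))

  trial <- generate_trial("internal", preset_params("internal"), 12, seed = 3)
  w <- extract_window(trial, 0, 8)
  v <- build_feature_vector(w)
  expect_length(v, 75)
  expect_named(v, nms)
  expect_true(all(is.finite(v)))
  expect_identical(v, build_feature_vector(w))

  # a window with zero blinks has zero count and all-zero blink stats
  clean <- make_window(lx = rep(0, 2000))
  v0 <- build_feature_vector(clean)
  expect_equal(unname(v0["n_blinks"]), 0)
  expect_equal(unname(v0[grep("^blink_duration", names(v0))]), rep(0, 8))
  expect_true(all(is.finite(v0)))
})

test_that("appending trailing invalid samples that form no blink leaves the vector unchanged", {
  set.seed(21)
  lx <- c(rep(0, 300), rep(3, 300)) + rnorm(600, 0, 0.05)
  ly <- rnorm(600, 0, 0.05)
  w <- make_window(lx = lx, ly = ly, rx = lx + 0.3, ry = ly,
                   lp = 4 + rnorm(600, 0, 0.1), rp = 4 + rnorm(600, 0, 0.1))
  v1 <- build_feature_vector(w)
  # append 6 invalid samples (24 ms < blink threshold)
  pad <- function(v, fill) c(v, rep(fill, 6))
  w2 <- make_window(lx = pad(lx, 0), ly = pad(ly, 0),
                    rx = pad(lx + 0.3, 0), ry = pad(ly, 0),
                    lp = pad(w$data$lp, 0), rp = pad(w$data$rp, 0),
                    valid_l = pad(w$data$valid_l, FALSE),
                    valid_r = pad(w$data$valid_r, FALSE))
  v2 <- build_feature_vector(w2)
  expect_equal(v2, v1)
})
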