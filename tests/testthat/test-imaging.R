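test_that("unit rescaling maps extremes to -1/1 and constants to 0", {
  expect_equal(rescale_unit(c(0, 5, 10)), c(-1, 0, 1))
  expect_equal(rescale_unit(rep(7, 20)), rep(0, 20))
  set.seed(1)
  s <- rescale_unit(rnorm(100))
  expect_equal(min(s), -1)
  expect_equal(max(s), 1)
})

test_that("PAA computes weighted segment means and conserves the mean", {
  expect_equal(paa(c(1, 2, 3, 4), 2), c(1.5, 3.5))
  s <- rnorm(100)
  expect_equal(paa(s, 100), s)
  expect_error(paa(s, 0), "positive")
  expect_error(paa(s, 101), "exceeds")

  set.seed(2)
  for (n in c(750, 2000)) {
    s <- rnorm(n)
    expect_equal(mean(paa(s, 48)), mean(s), tolerance = 1e-9)
  }
  # fractional boundaries: 5 -> 2 splits the middle sample half-half
  expect_equal(paa(c(1, 1, 4, 2, 2), 2), c((1 + 1 + 0.5 * 4) / 2.5,
                                           (0.5 * 4 + 2 + 2) / 2.5))
})

test_that("Gramian fields equal their closed trigonometric forms", {
  # angle-space oracle evaluated independently via acos
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(4:64, 1)
    s <- rescale_unit(rnorm(n))
    phi <- acos(s)
    expect_equal(gasf(s), outer(phi, phi, function(a, b) cos(a + b)),
                 tolerance = 1e-9)
    expect_equal(gadf(s), outer(phi, phi, function(a, b) sin(a - b)),
                 tolerance = 1e-9)
    # structural identities
    g <- gasf(s); d <- gadf(s)
    expect_equal(g, t(g), tolerance = 1e-12)
    expect_equal(diag(d), rep(0, n))
    expect_equal(d, -t(d), tolerance = 1e-12)
    expect_equal(diag(g), 2 * s^2 - 1, tolerance = 1e-9)
    expect_true(all(abs(g) <= 1 + 1e-12) && all(abs(d) <= 1 + 1e-12))
  }
})

test_that("Gramian fields of the canonical small series match hand values", {
  s <- c(-1, -0.5, 0.5, 1)
  sq <- sqrt(1 - s^2)
  expect_equal(gasf(s), outer(s, s) - outer(sq, sq), tolerance = 1e-12)
  expect_equal(gadf(s), outer(sq, s) - outer(s, sq), tolerance = 1e-12)
  # constant series rescales to zeros: GASF all -1, GADF all 0
  z <- rescale_unit(rep(2, 5))
  expect_equal(gasf(z), matrix(-1, 5, 5))
  expect_equal(gadf(z), matrix(0, 5, 5))
  expect_error(gasf(c(0, 1.5)), "outside")
})

test_that("MTF matches a brute-force transition-count oracle", {
  mtf_oracle <- function(s, bins) {
    k <- max(bins)
    W <- matrix(0, k, k)
    for (i in seq_len(length(s) - 1)) {
      W[bins[i], bins[i + 1]] <- W[bins[i], bins[i + 1]] + 1
    }
    for (r in seq_len(k)) if (sum(W[r, ]) > 0) W[r, ] <- W[r, ] / sum(W[r, ])
    n <- length(s)
    M <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) M[i, j] <- W[bins[i], bins[j]]
    M
  }
  set.seed(4)
  for (rep in 1:20) {
    s <- rnorm(16)
    got <- mtf(s, n_bins = 4)
    expect_equal(got$field, mtf_oracle(s, got$bins))
    # occupied rows of the transition matrix sum to 1
    rs <- rowSums(got$transition)
    expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
  }

  # strictly alternating two-level series: deterministic checkerboard
  s <- rep(c(0, 1), 8)
  got <- mtf(s, n_bins = 2)
  expect_equal(got$transition, matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(got$field, mtf_oracle(s, got$bins))

  # constant series collapses to one bin, field all ones
  got <- mtf(rep(5, 10), n_bins = 8)
  expect_equal(got$field, matrix(1, 10, 10))
})

test_that("image reduction block-pools then min-max normalises", {
  set.seed(5)
  M <- matrix(rnorm(96 * 96), 96, 96)
  raw <- to_image(M, 48, normalize = FALSE)
  # each output pixel equals the mean of its 2x2 block
  blk <- matrix(0, 48, 48)
  for (i in 1:48) for (j in 1:48) {
    blk[i, j] <- mean(M[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  }
  expect_equal(raw, blk, tolerance = 1e-12)

  img <- to_image(M, 48)
  expect_equal(min(img), -1)
  expect_equal(max(img), 1)

  # 48x48 input: pooling is identity, only normalisation applies
  M48 <- matrix(rnorm(48 * 48), 48, 48)
  expect_equal(to_image(M48, 48, normalize = FALSE), M48)
  expect_error(to_image(matrix(0, 10, 10), 48), "smaller")
  expect_equal(to_image(matrix(3, 48, 48), 48), matrix(0, 48, 48))
})

test_that("the image stack has 18 channels of 48x48 in [-1, 1]", {
  for (len in c(3, 8)) {
    trial <- generate_trial("internal", preset_params("internal"), 12, seed = 5)
    w <- extract_window(trial, 0, len)
    st <- build_image_stack(w)
    expect_equal(dim(st), c(48, 48, 18))
    expect_true(all(st >= -1 & st <= 1))
    expect_length(attr(st, "channels"), 18)
  }
})

test_that("stack construction is deterministic and eye-symmetric", {
  trial <- generate_trial("external", preset_params("external"), 11, seed = 8)
  w <- extract_window(trial, 0, 8)
  s1 <- build_image_stack(w)
  s2 <- build_image_stack(w)
  expect_identical(s1, s2)

  # swapping the eyes swaps the L and R channel groups
  w_sw <- w
  w_sw$data[, c("lx", "ly", "lp", "rx", "ry", "rp")] <-
    w$data[, c("rx", "ry", "rp", "lx", "ly", "lp")]
  s_sw <- build_image_stack(w_sw)
  chn <- attr(s1, "channels")
  for (ch in seq_along(chn)) {
    sw_name <- chartr("LR", "RL", chn[ch])
    expect_equal(s_sw[, , ch], s1[, , which(chn == sw_name)],
                 info = chn[ch])
  }
})

test_that("stacks for a fixed seeded trial are stable across runs", {
  trial <- generate_trial("internal", preset_params("internal"), 12, seed = 123)
  w <- extract_window(trial, 0, 3)
  st <- build_image_stack(w)
  # frozen fingerprint of the full stack (golden values)
  expect_equal(dim(st), c(48, 48, 18))
  fp <- c(mean(st), sd(as.vector(st)), st[1, 1, 1], st[24, 24, 9], st[48, 48, 18])
  expect_equal(fp, attr(stack_fingerprint_golden, "values"), tolerance = 1e-10)
})
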