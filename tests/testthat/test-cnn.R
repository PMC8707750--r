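test_that("parameter counts match the published architecture exactly", {
  p_impl <- count_parameters(build_network(combined = FALSE))
  p_comb <- count_parameters(build_network(combined = TRUE))
  expect_equal(attr(p_impl, "total"), 5256562)
  expect_equal(attr(p_comb, "total"), 5279212)

  get <- function(tab, layer) tab$params[tab$layer == layer]
  expect_equal(get(p_impl, "conv1"), 27060)
  expect_equal(get(p_impl, "conv2"), 180120)
  expect_equal(get(p_impl, "fc1"), 4860500)
  expect_equal(get(p_impl, "fc2"), 150300)
  expect_equal(get(p_impl, "fc3"), 36120)
  expect_equal(get(p_impl, "fc4"), 2420)
  expect_equal(get(p_impl, "fc5"), 42)
  expect_equal(get(p_comb, "bn_explicit"), 150)
  expect_equal(get(p_comb, "fc2"), 172800)
  expect_equal(attr(p_comb, "total") - attr(p_impl, "total"), 22650)
})

test_that("forward pass realises the published intermediate shapes", {
  net <- build_network(FALSE, seed = 1)
  x <- array(runif(48 * 48 * 18 * 2, -1, 1), c(48, 48, 18, 2))
  a1 <- gazeits:::.conv_fwd(x, net$params$conv1_w, net$params$conv1_b, 5L, 1L)
  expect_equal(dim(a1), c(44, 44, 60, 2))
  a2 <- gazeits:::.conv_fwd(a1, net$params$conv2_w, net$params$conv2_b, 5L, 2L)
  expect_equal(dim(a2), c(20, 20, 120, 2))
  mp1 <- gazeits:::.maxpool_fwd(a2, 3L, 1L)
  expect_equal(dim(mp1$y), c(18, 18, 120, 2))
  mp2 <- gazeits:::.maxpool_fwd(mp1$y, 2L, 2L)
  expect_equal(prod(dim(mp2$y)[1:3]), 9720)

  fwd <- gazeits:::.cnn_forward(net, x)
  expect_equal(dim(fwd$logits), c(2, 2))
})

test_that("convolution and pooling kernels pass a finite-difference check", {
  set.seed(11)
  x <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  w <- matrix(rnorm(3 * 3 * 2 * 4) * 0.1, 18, 4)
  b <- rnorm(4) * 0.1
  dy <- array(rnorm(4 * 4 * 4 * 2), c(3, 3, 4, 2))
  dy <- array(rnorm(length(gazeits:::.conv_fwd(x, w, b, 3L, 2L))),
              dim(gazeits:::.conv_fwd(x, w, b, 3L, 2L)))
  bwd <- gazeits:::.conv_bwd(x, w, dy, 3L, 2L)
  loss <- function(xx, ww, bb) sum(gazeits:::.conv_fwd(xx, ww, bb, 3L, 2L) * dy)
  eps <- 1e-6
  for (i in sample(length(x), 5)) {
    x2 <- x; x2[i] <- x2[i] + eps
    expect_equal((loss(x2, w, b) - loss(x, w, b)) / eps, bwd$dx[i],
                 tolerance = 1e-4)
  }
  for (i in sample(length(w), 5)) {
    w2 <- w; w2[i] <- w2[i] + eps
    expect_equal((loss(x, w2, b) - loss(x, w, b)) / eps, bwd$dw[i],
                 tolerance = 1e-4)
  }

  mp <- gazeits:::.maxpool_fwd(x, 2L, 2L)
  dym <- array(rnorm(length(mp$y)), dim(mp$y))
  dxm <- gazeits:::.maxpool_bwd(dym, mp$argmax, length(x))
  lossm <- function(xx) sum(gazeits:::.maxpool_fwd(xx, 2L, 2L)$y * dym)
  for (i in sample(length(x), 5)) {
    x2 <- x; x2[i] <- x2[i] + eps
    expect_equal((lossm(x2) - lossm(x)) / eps, dxm[i], tolerance = 1e-4)
  }
})

test_that("the full network gradient matches finite differences", {
  set.seed(12)
  B <- 2
  x <- array(runif(48 * 48 * 18 * B, -1, 1), c(48, 48, 18, B))
  E <- matrix(rnorm(75 * B), 75, B)
  y01 <- c(1L, 2L)
  net <- build_network(TRUE, seed = 3)
  fwd <- gazeits:::.cnn_forward(net, x, E, training = FALSE, keep_cache = TRUE)
  bwd <- gazeits:::.cnn_backward(net, fwd, y01)
  lossfn <- function(n2) {
    f <- gazeits:::.cnn_forward(n2, x, E, training = FALSE)
    p <- gazeits:::.softmax_cols(f$logits)
    -mean(log(p[cbind(y01, 1:B)]))
  }
  eps <- 1e-6
  for (nm in c("conv1_w", "conv2_w", "fc1_w", "bn_gamma", "fc2_w", "fc5_b")) {
    i <- sample(length(net$params[[nm]]), 1)
    n2 <- net
    n2$params[[nm]][i] <- n2$params[[nm]][i] + eps
    fd <- (lossfn(n2) - bwd$loss) / eps
    expect_equal(bwd$grads[[nm]][i], fd, tolerance = 1e-3,
                 info = nm)
  }
})

test_that("combined network demands the explicit branch input", {
  net <- build_network(TRUE, seed = 1)
  x <- array(0, c(48, 48, 18, 1))
  expect_error(predict_network(net, x), "explicit")
  # an all-zero explicit vector still yields finite outputs
  out <- predict_network(net, x, explicit = matrix(0, 1, 75))
  expect_true(all(is.finite(out$scores)))
})

test_that("prediction is deterministic with argmax ties to the first class", {
  net <- build_network(FALSE, seed = 2)
  net$classes <- c("external", "internal")
  # zero the output layer: logits are exactly tied
  net$params$fc5_w[] <- 0
  net$params$fc5_b[] <- 0
  x <- array(runif(48 * 48 * 18 * 3, -1, 1), c(48, 48, 18, 3))
  out <- predict_network(net, x)
  expect_equal(out$labels, rep("external", 3))
  expect_equal(unname(out$scores[, 1]), rep(0.5, 3))
  # inference has no stochastic elements
  expect_identical(predict_network(net, x), predict_network(net, x))
})

test_that("training is reproducible and rejects single-class data", {
  set.seed(33)
  x <- array(runif(48 * 48 * 18 * 8, -1, 1), c(48, 48, 18, 8))
  labs <- rep(c("internal", "external"), 4)
  cfg <- train_config(epochs = 2, batch_size = 4, val_fraction = 0)
  n1 <- train_network(build_network(FALSE, seed = 7), x, labs, config = cfg)
  n2 <- train_network(build_network(FALSE, seed = 7), x, labs, config = cfg)
  expect_identical(n1$params, n2$params)
  expect_equal(nrow(n1$history), 2)

  expect_error(
    train_network(build_network(FALSE, seed = 7), x, rep("internal", 8),
                  config = cfg),
    "two classes")
})
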