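#' Build the heterogeneous two-stage gaze CNN
#'
#' Constructs the two-branch convolutional classifier. The implicit
#' branch processes the 18 x 48 x 48 image stack: two 5 x 5
#' convolutions (18 to 60 channels at stride 1, then 60 to 120 at
#' stride 2), a 3 x 3 stride-1 max pool to 120 x 18 x 18, 2-D channel
#' dropout (p = 0.5), a 2 x 2 stride-2 max pool, and a 9720-to-500
#' linear layer, all with ReLU activations. In the combined variant the
#' 75-dimensional explicit feature vector is batch-normalised (momentum
#' 0.1) and concatenated after the 500-unit layer. The fused signal then
#' passes linear layers 300, 120, dropout, 20 and 2, with tanh
#' activations after the injection point; the 2-unit output matches the
#' two attention labels.
#'
#' Weights use fan-in uniform initialisation; the construction is a pure
#' function of `(combined, seed)`.
#'
#' @param combined Logical: include the explicit-feature branch?
#' @param seed Integer seed for weight initialisation.
#' @return A `hetero_cnn` object (list of parameter tensors plus the
#'   architecture description).
#' @export
build_network <- function(combined = FALSE, seed = 1) {
  dims <- .cnn_dims(combined)
  init <- function(nr, nc) {
    s <- 1 / sqrt(nc)
    matrix(runif(nr * nc, -s, s), nr, nc)
  }
  params <- withr::with_seed(as.integer(seed), {
    p <- list(
      conv1_w = init(25 * 18, 60), conv1_b = runif(60, -1, 1) / sqrt(25 * 18),
      conv2_w = init(25 * 60, 120), conv2_b = runif(120, -1, 1) / sqrt(25 * 60),
      fc1_w = init(500, 9720), fc1_b = runif(500, -1, 1) / sqrt(9720),
      fc2_w = init(300, dims$fc2_in), fc2_b = runif(300, -1, 1) / sqrt(dims$fc2_in),
      fc3_w = init(120, 300), fc3_b = runif(120, -1, 1) / sqrt(300),
      fc4_w = init(20, 120), fc4_b = runif(20, -1, 1) / sqrt(120),
      fc5_w = init(2, 20), fc5_b = runif(2, -1, 1) / sqrt(20)
    )
    if (combined) {
      p$bn_gamma <- rep(1, 75)
      p$bn_beta <- rep(0, 75)
    }
    p
  })
  structure(
    list(
      combined = combined, seed = seed, params = params,
      bn_running_mean = if (combined) rep(0, 75),
      bn_running_var = if (combined) rep(1, 75),
      bn_momentum = 0.1, dropout_p = 0.5, classes = NULL
    ),
    class = "hetero_cnn"
  )
}

.cnn_dims <- function(combined) {
  list(fc2_in = if (combined) 575L else 500L, flat = 9720L)
}

#' @export
print.hetero_cnn <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf("<hetero_cnn> %s feature set, %s learnable parameters%s\n",
              if (x$combined) "combined" else "implicit-only",
              format(attr(pc, "total"), big.mark = ","),
              if (is.null(x$classes)) " (untrained)" else " (trained)"))
  invisible(x)
}

#' Per-layer learnable parameter counts
#'
#' @param net A `hetero_cnn`.
#' @return Data frame with columns `layer`, `output_shape`, `params`;
#'   the `total` attribute holds the sum.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "hetero_cnn"))
  p <- net$params
  sz <- function(nm) if (is.null(p[[nm]])) 0L else length(p[[nm]])
  rows <- list(
    c("conv1", "[60, 44, 44]", sz("conv1_w") + sz("conv1_b")),
    c("conv2", "[120, 20, 20]", sz("conv2_w") + sz("conv2_b")),
    c("maxpool1", "[120, 18, 18]", 0L),
    c("dropout2d", "[120, 18, 18]", 0L),
    c("maxpool2", "[120, 9, 9]", 0L),
    c("fc1", "[500]", sz("fc1_w") + sz("fc1_b"))
  )
  if (net$combined) {
    rows <- c(rows, list(c("bn_explicit", "[75]",
                           sz("bn_gamma") + sz("bn_beta"))))
  }
  rows <- c(rows, list(
    c("fc2", "[300]", sz("fc2_w") + sz("fc2_b")),
    c("fc3", "[120]", sz("fc3_w") + sz("fc3_b")),
    c("dropout", "[120]", 0L),
    c("fc4", "[20]", sz("fc4_w") + sz("fc4_b")),
    c("fc5", "[2]", sz("fc5_w") + sz("fc5_b"))
  ))
  out <- data.frame(
    layer = vapply(rows, `[`, "", 1),
    output_shape = vapply(rows, `[`, "", 2),
    params = as.integer(vapply(rows, `[`, "", 3))
  )
  attr(out, "total") <- sum(out$params)
  out
}

.relu <- function(z) pmax(z, 0)

.softmax_cols <- function(logits) {
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  sweep(e, 2, colSums(e), "/")
}

# Forward pass. x: [48,48,18,B]; explicit: 75 x B matrix or NULL.
# Returns logits plus (when keep_cache) every intermediate needed for
# backprop and the updated batch-norm running statistics.
.cnn_forward <- function(net, x, explicit = NULL, training = FALSE,
                         keep_cache = FALSE) {
  p <- net$params
  B <- dim(x)[4]
  if (net$combined) {
    if (is.null(explicit)) stop("combined network requires the explicit feature matrix")
    stopifnot(nrow(explicit) == 75, ncol(explicit) == B)
  }

  a1 <- .conv_fwd(x, p$conv1_w, p$conv1_b, 5L, 1L)
  h1 <- .relu(a1)
  a2 <- .conv_fwd(h1, p$conv2_w, p$conv2_b, 5L, 2L)
  h2 <- .relu(a2)
  mp1 <- .maxpool_fwd(h2, 3L, 1L)
  z1 <- mp1$y
  if (training) {
    # 2-D dropout: zero whole channels per image, inverted scaling
    cmask <- matrix(rbinom(120 * B, 1, 1 - net$dropout_p), 120, B) /
      (1 - net$dropout_p)
    z1 <- z1 * aperm(array(cmask, dim = c(120, B, 18, 18)), c(3, 4, 1, 2))
  } else {
    cmask <- NULL
  }
  mp2 <- .maxpool_fwd(z1, 2L, 2L)
  flat <- mp2$y
  dim(flat) <- c(9720L, B)
  f1 <- p$fc1_w %*% flat + p$fc1_b
  h3 <- .relu(f1)

  bn_cache <- NULL
  if (net$combined) {
    eps <- 1e-5
    if (training) {
      mu <- rowMeans(explicit)
      v <- rowMeans((explicit - mu)^2)
      xhat <- (explicit - mu) / sqrt(v + eps)
      vu <- if (B > 1) v * B / (B - 1) else v
      net$bn_running_mean <- (1 - net$bn_momentum) * net$bn_running_mean +
        net$bn_momentum * mu
      net$bn_running_var <- (1 - net$bn_momentum) * net$bn_running_var +
        net$bn_momentum * vu
      bn_cache <- list(xhat = xhat, inv_sd = 1 / sqrt(v + eps),
                       fixed = FALSE)
    } else {
      xhat <- (explicit - net$bn_running_mean) /
        sqrt(net$bn_running_var + eps)
      bn_cache <- list(xhat = xhat,
                       inv_sd = 1 / sqrt(net$bn_running_var + eps),
                       fixed = TRUE)
    }
    eb <- p$bn_gamma * xhat + p$bn_beta
    z2 <- rbind(h3, eb)
  } else {
    z2 <- h3
  }

  f2 <- p$fc2_w %*% z2 + p$fc2_b
  h4 <- tanh(f2)
  f3 <- p$fc3_w %*% h4 + p$fc3_b
  h5 <- tanh(f3)
  if (training) {
    dmask <- matrix(rbinom(120 * B, 1, 1 - net$dropout_p), 120, B) /
      (1 - net$dropout_p)
    h5d <- h5 * dmask
  } else {
    dmask <- NULL
    h5d <- h5
  }
  f4 <- p$fc4_w %*% h5d + p$fc4_b
  h6 <- tanh(f4)
  logits <- p$fc5_w %*% h6 + p$fc5_b

  out <- list(logits = logits, net = net)
  if (keep_cache) {
    out$cache <- list(x = x, a1 = a1, h1 = h1, a2 = a2, h2 = h2, mp1 = mp1,
                      z1 = z1, cmask = cmask, mp2 = mp2, flat = flat,
                      f1 = f1, h3 = h3, explicit = explicit,
                      bn_cache = bn_cache, z2 = z2, h4 = h4, h5 = h5,
                      dmask = dmask, h5d = h5d, h6 = h6)
  }
  out
}

# Backward pass: cross-entropy gradient through the whole network.
# y01: integer vector in {1, 2} (class index per column).
.cnn_backward <- function(net, fwd, y01) {
  p <- net$params
  cache <- fwd$cache
  B <- ncol(fwd$logits)
  probs <- .softmax_cols(fwd$logits)
  dlogits <- probs
  dlogits[cbind(y01, seq_len(B))] <- dlogits[cbind(y01, seq_len(B))] - 1
  dlogits <- dlogits / B

  g <- list()
  g$fc5_w <- dlogits %*% t(cache$h6); g$fc5_b <- rowSums(dlogits)
  dh6 <- t(p$fc5_w) %*% dlogits
  df4 <- dh6 * (1 - cache$h6^2)
  g$fc4_w <- df4 %*% t(cache$h5d); g$fc4_b <- rowSums(df4)
  dh5d <- t(p$fc4_w) %*% df4
  dh5 <- if (is.null(cache$dmask)) dh5d else dh5d * cache$dmask
  df3 <- dh5 * (1 - cache$h5^2)
  g$fc3_w <- df3 %*% t(cache$h4); g$fc3_b <- rowSums(df3)
  dh4 <- t(p$fc3_w) %*% df3
  df2 <- dh4 * (1 - cache$h4^2)
  g$fc2_w <- df2 %*% t(cache$z2); g$fc2_b <- rowSums(df2)
  dz2 <- t(p$fc2_w) %*% df2

  if (net$combined) {
    dh3 <- dz2[1:500, , drop = FALSE]
    deb <- dz2[501:575, , drop = FALSE]
    bc <- cache$bn_cache
    g$bn_gamma <- rowSums(deb * bc$xhat)
    g$bn_beta <- rowSums(deb)
    dxhat <- deb * p$bn_gamma
    if (isTRUE(bc$fixed)) {
      # inference statistics are constants
      dE <- dxhat * bc$inv_sd
    } else {
      # batch-norm input gradient (biased-variance formulation)
      dE <- bc$inv_sd * (dxhat - rowMeans(dxhat) -
                           bc$xhat * rowMeans(dxhat * bc$xhat))
    }
    g$explicit <- dE
  } else {
    dh3 <- dz2
  }

  df1 <- dh3 * (cache$f1 > 0)
  g$fc1_w <- df1 %*% t(cache$flat); g$fc1_b <- rowSums(df1)
  dflat <- t(p$fc1_w) %*% df1
  dmp2 <- dflat
  dim(dmp2) <- c(9L, 9L, 120L, B)
  dz1 <- .maxpool_bwd(dmp2, cache$mp2$argmax, length(cache$z1))
  dim(dz1) <- c(18L, 18L, 120L, B)
  if (!is.null(cache$cmask)) {
    dz1 <- dz1 * aperm(array(cache$cmask, dim = c(120, B, 18, 18)),
                       c(3, 4, 1, 2))
  }
  dh2 <- .maxpool_bwd(dz1, cache$mp1$argmax, length(cache$h2))
  dim(dh2) <- dim(cache$h2)
  da2 <- dh2 * (cache$a2 > 0)
  cb2 <- .conv_bwd(cache$h1, p$conv2_w, da2, 5L, 2L)
  g$conv2_w <- cb2$dw; g$conv2_b <- cb2$db
  dh1 <- cb2$dx * (cache$a1 > 0)
  cb1 <- .conv_bwd(cache$x, p$conv1_w, dh1, 5L, 1L)
  g$conv1_w <- cb1$dw; g$conv1_b <- cb1$db

  loss <- -mean(log(pmax(probs[cbind(y01, seq_len(B))], 1e-300)))
  list(grads = g, loss = loss)
}

#' Training configuration
#'
#' @param optimizer Only `"adam"` is implemented.
#' @param lr Learning rate (default 5e-4; larger rates can drive the
#'   tanh stages into saturation under mini-batch dropout noise).
#' @param batch_size Mini-batch size (default 16).
#' @param epochs Maximum epochs (default 30).
#' @param patience Early-stopping patience in epochs on the validation
#'   split; ignored when `val_fraction = 0`.
#' @param val_fraction Fraction of trials held out for early stopping
#'   (default 0.1).
#' @param max_grad_norm Global gradient-norm clip (default 10).
#' @param restarts Maximum number of re-initialisations when training
#'   ends in the collapsed regime (final epoch loss above
#'   `restart_loss`); each restart derives a fresh deterministic seed
#'   (default 2).
#' @param restart_loss Training-loss level above which the fit is
#'   considered collapsed to the class prior (default 0.6, just below
#'   log 2).
#' @param seed Seed controlling shuffling, dropout and the validation
#'   split.
#' @return A `train_config` list, serialised into every trained network.
#' @export
train_config <- function(optimizer = "adam", lr = 5e-4, batch_size = 16,
                         epochs = 30, patience = 5, val_fraction = 0.1,
                         max_grad_norm = 10, restarts = 2, restart_loss = 0.6,
                         seed = 1) {
  stopifnot(optimizer == "adam", lr > 0, batch_size >= 1, epochs >= 1,
            max_grad_norm > 0, restarts >= 0)
  structure(list(optimizer = optimizer, lr = lr, batch_size = batch_size,
                 epochs = epochs, patience = patience,
                 val_fraction = val_fraction, max_grad_norm = max_grad_norm,
                 restarts = restarts, restart_loss = restart_loss,
                 seed = as.integer(seed)),
            class = "train_config")
}

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    if (is.null(gnm)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gnm
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gnm^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the gaze CNN
#'
#' Minimises softmax cross-entropy with Adam. Given the same data,
#' network and configuration seed, training is bit-reproducible. With
#' `val_fraction > 0`, a stratified validation split monitors accuracy
#' and training stops after `patience` epochs without improvement,
#' restoring the best weights.
#'
#' @param net A `hetero_cnn` from [build_network()].
#' @param x Image stacks, array `[48, 48, 18, N]`.
#' @param labels Factor or character vector of length `N` with exactly
#'   two classes.
#' @param explicit Optional `N x 75` matrix of explicit features
#'   (required for combined networks).
#' @param config A [train_config()].
#' @return The trained network, with a `history` element (per-epoch loss
#'   and accuracies) and the serialised `config`.
#' @export
train_network <- function(net, x, labels, explicit = NULL,
                          config = train_config()) {
  stopifnot(inherits(net, "hetero_cnn"), inherits(config, "train_config"))
  N <- dim(x)[4]
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L) {
    stop("training data must contain exactly two classes")
  }
  labels <- droplevels(labels)
  y01 <- as.integer(labels)
  if (net$combined) {
    if (is.null(explicit)) stop("combined network requires explicit features")
    stopifnot(nrow(explicit) == N, ncol(explicit) == 75)
    Emat <- t(explicit)
  } else {
    Emat <- NULL
  }

  net0 <- net
  for (attempt in 0:config$restarts) {
    seed_a <- config$seed + 104729L * attempt
    if (attempt > 0) {
      # fresh deterministic re-initialisation after a collapsed fit
      net <- build_network(net0$combined, seed = net0$seed + 7919L * attempt)
      net$dropout_p <- net0$dropout_p
      net$bn_momentum <- net0$bn_momentum
    }
    net <- .train_once(net, x, Emat, y01, config, seed_a)
    final_loss <- utils::tail(net$history$loss, 1)
    if (is.finite(final_loss) && final_loss <= config$restart_loss) break
  }
  net$classes <- levels(labels)
  net$config <- config
  net
}

.train_once <- function(net, x, Emat, y01, config, seed) {
  N <- dim(x)[4]
  withr::with_seed(as.integer(seed %% .Machine$integer.max), {
    # stratified validation split for early stopping
    val_idx <- integer(0)
    if (config$val_fraction > 0 && N >= 10) {
      for (k in 1:2) {
        idx <- which(y01 == k)
        n_val <- max(1L, floor(length(idx) * config$val_fraction))
        val_idx <- c(val_idx, sample(idx, n_val))
      }
    }
    tr_idx <- setdiff(seq_len(N), val_idx)
    if (length(unique(y01[tr_idx])) < 2L) {
      val_idx <- integer(0)
      tr_idx <- seq_len(N)
    }

    state <- .adam_init(net$params)
    best <- list(acc = -Inf, params = net$params,
                 bn = list(net$bn_running_mean, net$bn_running_var))
    wait <- 0
    history <- list()

    for (epoch in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0; ep_n <- 0; ep_correct <- 0
      for (b0 in seq(1, length(ord), by = config$batch_size)) {
        bi <- ord[b0:min(b0 + config$batch_size - 1, length(ord))]
        xb <- x[, , , bi, drop = FALSE]
        eb <- if (net$combined) Emat[, bi, drop = FALSE]
        fwd <- .cnn_forward(net, xb, eb, training = TRUE, keep_cache = TRUE)
        net <- fwd$net  # batch-norm running statistics
        bwd <- .cnn_backward(net, fwd, y01[bi])
        if (!is.finite(bwd$loss)) {
          stop(sprintf("non-finite loss at epoch %d; aborting training", epoch))
        }
        gnorm <- sqrt(sum(vapply(bwd$grads[names(net$params)],
                                 function(g) sum(g^2), numeric(1))))
        if (is.finite(gnorm) && gnorm > config$max_grad_norm) {
          bwd$grads <- lapply(bwd$grads, function(g) {
            g * config$max_grad_norm / gnorm
          })
        }
        upd <- .adam_step(net$params, bwd$grads, state, config$lr)
        net$params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + bwd$loss * length(bi)
        ep_n <- ep_n + length(bi)
        ep_correct <- ep_correct +
          sum(apply(fwd$logits, 2, which.max) == y01[bi])
      }
      train_acc <- ep_correct / ep_n
      val_acc <- NA_real_
      if (length(val_idx)) {
        vf <- .cnn_forward(net, x[, , , val_idx, drop = FALSE],
                           if (net$combined) Emat[, val_idx, drop = FALSE],
                           training = FALSE)
        val_acc <- mean(apply(vf$logits, 2, which.max) == y01[val_idx])
        if (val_acc > best$acc) {
          best <- list(acc = val_acc, params = net$params,
                       bn = list(net$bn_running_mean, net$bn_running_var))
          wait <- 0
        } else {
          wait <- wait + 1
        }
      }
      history[[epoch]] <- data.frame(epoch = epoch, loss = ep_loss / ep_n,
                                     train_acc = train_acc, val_acc = val_acc)
      if (length(val_idx) && wait >= config$patience) break
      if (train_acc == 1 && ep_loss / ep_n < 0.05) break
    }
    if (length(val_idx) && is.finite(best$acc)) {
      net$params <- best$params
      net$bn_running_mean <- best$bn[[1]]
      net$bn_running_var <- best$bn[[2]]
    }
    net$history <- do.call(rbind, history)
  })
  net
}

#' Predict attention labels with a trained network
#'
#' Runs the network in inference mode (dropout disabled, batch
#' normalisation using running statistics) and takes the argmax of the
#' two class scores; an exact tie resolves to the first class.
#'
#' @param net A trained `hetero_cnn`.
#' @param x Image stacks `[48, 48, 18, N]` (a single stack is accepted).
#' @param explicit Optional `N x 75` explicit feature matrix.
#' @return List with `labels` (character) and `scores` (`N x 2` softmax
#'   probability matrix, columns named by class).
#' @export
predict_network <- function(net, x, explicit = NULL) {
  stopifnot(inherits(net, "hetero_cnn"))
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (dim(x)[1] != 48 || dim(x)[2] != 48 || dim(x)[3] != 18) {
    stop("expected stacks of shape [48, 48, 18, N]")
  }
  Emat <- NULL
  if (net$combined) {
    if (is.null(explicit)) stop("combined network requires explicit features")
    if (is.vector(explicit)) explicit <- matrix(explicit, nrow = 1)
    stopifnot(ncol(explicit) == 75, nrow(explicit) == dim(x)[4])
    Emat <- t(explicit)
  }
  fwd <- .cnn_forward(net, x, Emat, training = FALSE)
  probs <- t(.softmax_cols(fwd$logits))
  classes <- if (is.null(net$classes)) c("class1", "class2") else net$classes
  colnames(probs) <- classes
  idx <- apply(probs, 1, which.max)
  list(labels = classes[idx], scores = probs)
}
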