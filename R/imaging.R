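#' Rescale a series to [-1, 1]
#'
#' Affine min-max map sending the minimum to -1 and the maximum to 1.
#' A constant series has no scale and maps to all zeros.
#'
#' @param series Non-empty numeric vector.
#' @return Numeric vector in `[-1, 1]`.
#' @export
rescale_unit <- function(series) {
  if (length(series) == 0L) stop("empty series")
  lo <- min(series); hi <- max(series)
  if (hi == lo) return(rep(0, length(series)))
  2 * (series - lo) / (hi - lo) - 1
}

# PAA aggregation matrix: out_len x n, row i averages the index interval
# [ (i-1) n/out, i n/out ) with fractional boundary samples weighted by
# their overlap. Rows sum to 1 and columns to out_len/n, so segment means
# are proper averages and the global mean is conserved exactly.
.paa_matrix <- function(n, out_len) {
  seg <- n / out_len
  P <- matrix(0, out_len, n)
  for (i in seq_len(out_len)) {
    a <- (i - 1) * seg
    b <- i * seg
    j0 <- floor(a) + 1
    j1 <- ceiling(b)
    for (j in j0:min(j1, n)) {
      w <- min(b, j) - max(a, j - 1)
      if (w > 0) P[i, j] <- w
    }
  }
  P / seg
}

#' Piecewise aggregate approximation
#'
#' Downsamples a series to `out_len` segment means over a balanced
#' partition of the index range; when `n` is not a multiple of `out_len`,
#' boundary samples are split between adjacent segments with fractional
#' weights, so the global mean is preserved exactly.
#'
#' @param series Numeric vector.
#' @param out_len Target length, `1 <= out_len <= length(series)`.
#' @return Numeric vector of length `out_len`.
#' @export
paa <- function(series, out_len) {
  n <- length(series)
  if (out_len <= 0) stop("out_len must be positive")
  if (out_len > n) stop("out_len exceeds series length")
  if (out_len == n) return(series)
  as.vector(.paa_matrix(n, out_len) %*% series)
}

#' Gramian angular fields
#'
#' A series rescaled to `[-1, 1]` is encoded in polar coordinates as
#' `phi_i = arccos(x_i)`; the summation field is the pairwise
#' trigonometric sum and the difference field the pairwise difference:
#' \deqn{GASF_{ij} = \cos(\phi_i + \phi_j) = x_i x_j -
#'   \sqrt{1 - x_i^2}\sqrt{1 - x_j^2}}
#' \deqn{GADF_{ij} = \sin(\phi_i - \phi_j) =
#'   \sqrt{1 - x_i^2}\, x_j - x_i \sqrt{1 - x_j^2}}
#' The GASF is symmetric with diagonal `2 x^2 - 1` (which carries the
#' original values); the GADF is antisymmetric with a zero diagonal. The
#' GADF sign convention is row minus column angle.
#'
#' @param series Numeric vector with values in `[-1, 1]` (tolerance
#'   1e-12; use [rescale_unit()] first).
#' @return An `n x n` matrix.
#' @export
gasf <- function(series) {
  x <- .check_unit(series)
  s <- sqrt(pmax(0, 1 - x^2))
  outer(x, x) - outer(s, s)
}

#' @rdname gasf
#' @export
gadf <- function(series) {
  x <- .check_unit(series)
  s <- sqrt(pmax(0, 1 - x^2))
  outer(s, x) - outer(x, s)
}

.check_unit <- function(series) {
  if (length(series) == 0L) stop("empty series")
  if (any(series < -1 - 1e-12 | series > 1 + 1e-12)) {
    stop("series values outside [-1, 1]; rescale first")
  }
  pmin(1, pmax(-1, series))
}

#' Markov transition field
#'
#' The series is discretised into `n_bins` quantile bins; first-order
#' transitions between consecutive samples are counted and row-normalised
#' into a Markov transition matrix `W`, which is then spread over the
#' time axis: `MTF[i, j] = W[bin(i), bin(j)]`. The main diagonal holds
#' the self-transition probability of each time step. When the series
#' has fewer distinct quantile edges than requested, the bin count is
#' reduced accordingly (a constant series yields a single bin and an
#' all-ones field).
#'
#' @param series Numeric vector, length >= 2.
#' @param n_bins Number of quantile bins (default 8).
#' @return List with `field` (`n x n` matrix), `transition` (the
#'   row-normalised bin transition matrix) and `bins` (per-sample bin
#'   index).
#' @export
mtf <- function(series, n_bins = 8) {
  n <- length(series)
  if (n < 2L) stop("series must have length >= 2")
  edges <- unique(quantile(series, probs = seq(0, 1, length.out = n_bins + 1),
                           names = FALSE, type = 7))
  if (length(edges) < 2L) {
    bins <- rep(1L, n)
    k <- 1L
  } else {
    k <- length(edges) - 1L
    bins <- findInterval(series, edges, rightmost.closed = TRUE,
                         all.inside = TRUE)
  }
  W <- matrix(0, k, k)
  for (i in seq_len(n - 1L)) W[bins[i], bins[i + 1L]] <- W[bins[i], bins[i + 1L]] + 1
  rs <- rowSums(W)
  occ <- rs > 0
  W[occ, ] <- W[occ, , drop = FALSE] / rs[occ]
  list(field = matrix(W[cbind(rep(bins, times = n), rep(bins, each = n))],
                      n, n),
       transition = W, bins = bins)
}

#' Reduce a square field to a fixed-size image in [-1, 1]
#'
#' Reduces an `n x n` matrix to `size x size` by two-dimensional block
#' mean pooling (fractional block boundaries weighted, the 2-D analogue
#' of [paa()]), then min-max normalises the pixels to `[-1, 1]`. A
#' constant field normalises to all zeros.
#'
#' @param mat Square numeric matrix with side >= `size`.
#' @param size Output side length (default 48).
#' @param normalize Min-max normalise to `[-1, 1]` (default TRUE).
#' @return A `size x size` matrix.
#' @export
to_image <- function(mat, size = 48, normalize = TRUE) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  n <- nrow(mat)
  if (n < size) stop("matrix side smaller than requested image size")
  img <- if (n == size) mat else {
    P <- .paa_matrix(n, size)
    P %*% mat %*% t(P)
  }
  if (normalize) {
    lo <- min(img); hi <- max(img)
    img <- if (hi == lo) matrix(0, size, size) else
      2 * (img - lo) / (hi - lo) - 1
  }
  img
}

# canonical channel order: transform (MTF, GASF, GADF) x eye (L, R) x
# signal (X, Y, pupil)
.stack_channel_names <- function() {
  as.vector(t(outer(c("MTF", "GASF", "GADF"),
                    as.vector(t(outer(c("L", "R"), c("X", "Y", "pupil"),
                                      paste, sep = "_"))),
                    paste, sep = "_")))
}

#' Build the 18-channel image stack of a trial window
#'
#' Encodes the six per-eye series (X, Y, pupil for each eye) of a
#' blink-removed window with the three transforms (MTF, GASF, GADF) into
#' eighteen 48 x 48 images in `[-1, 1]`. Short sub-blink invalid runs
#' are linearly interpolated first (set `interpolate_short = FALSE` to
#' disable), then blink samples are removed and the valid segments
#' concatenated. The Gramian fields are computed on the series PAA-reduced
#' to `size` and rescaled to `[-1, 1]`; the MTF is computed at full
#' length and block-pooled down. Each image is min-max normalised
#' individually.
#'
#' @param window A `trial_window`.
#' @param size Image side length (default 48).
#' @param n_bins MTF quantile bin count (default 8).
#' @param interpolate_short Interpolate invalid runs shorter than the
#'   blink threshold before removal (default TRUE).
#' @return An `image_stack`: array of dim `c(size, size, 18)` with a
#'   `channels` attribute giving the canonical channel names.
#' @export
build_image_stack <- function(window, size = 48, n_bins = 8,
                              interpolate_short = TRUE) {
  stopifnot(inherits(window, "trial_window"))
  if (interpolate_short) window <- interpolate_short_gaps(window)
  cleaned <- remove_blink_samples(window)
  d <- cleaned$data
  if (nrow(d) < size) stop("fewer than ", size, " valid samples after blink removal")

  series <- list(L_X = d$lx, L_Y = d$ly, L_pupil = d$lp,
                 R_X = d$rx, R_Y = d$ry, R_pupil = d$rp)
  ord <- c("L_X", "L_Y", "L_pupil", "R_X", "R_Y", "R_pupil")
  stack <- array(0, dim = c(size, size, 18L))
  ch <- 0L
  for (tr in c("MTF", "GASF", "GADF")) {
    for (s in ord) {
      ch <- ch + 1L
      v <- series[[s]]
      stack[, , ch] <- switch(tr,
        MTF = to_image(mtf(v, n_bins = n_bins)$field, size),
        GASF = to_image(gasf(rescale_unit(paa(v, size))), size),
        GADF = to_image(gadf(rescale_unit(paa(v, size))), size)
      )
    }
  }
  attr(stack, "channels") <- .stack_channel_names()
  class(stack) <- c("image_stack", class(stack))
  stack
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %d channels of %dx%d in [%.2f, %.2f]\n",
              dim(x)[3], dim(x)[1], dim(x)[2], min(x), max(x)))
  cat("  channels:", paste(attr(x, "channels"), collapse = ", "), "\n")
  invisible(x)
}
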