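# Independent brute-force oracles shared by the unit and acceptance tests.

# I-DT oracle: at each start, find the longest window whose dispersion
# (recomputed from scratch) stays within the threshold; emit if it covers
# the minimum duration.
idt_oracle <- function(x, y, fs = 250, thr = 1, min_ms = 100) {
  n <- length(x)
  need <- max(2, ceiling(min_ms / 1000 * fs))
  disp <- function(i, j) (max(x[i:j]) - min(x[i:j])) + (max(y[i:j]) - min(y[i:j]))
  res <- NULL
  i <- 1
  while (i + need - 1 <= n) {
    if (disp(i, i + need - 1) <= thr) {
      j <- i + need - 1
      while (j < n && disp(i, j + 1) <= thr) j <- j + 1
      res <- rbind(res, c(i, j))
      i <- j + 1
    } else i <- i + 1
  }
  res
}

# smallest-circle oracle: exhaustive minimum over all 2-point (diameter)
# and 3-point (circumcircle) support sets that contain every point
mec_oracle <- function(px, py) {
  n <- length(px)
  best <- NULL
  consider <- function(cx, cy, r) {
    if (all(sqrt((px - cx)^2 + (py - cy)^2) <= r + 1e-10)) {
      if (is.null(best) || r < best$radius) {
        best <<- list(center = c(cx, cy), radius = r)
      }
    }
  }
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    consider((px[i] + px[j]) / 2, (py[i] + py[j]) / 2,
             sqrt((px[i] - px[j])^2 + (py[i] - py[j])^2) / 2)
  }
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      ax <- px[i]; ay <- py[i]; bx <- px[j]; by <- py[j]
      cx <- px[k]; cy <- py[k]
      d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
      if (abs(d) < 1e-12) next
      ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
               (cx^2 + cy^2) * (ay - by)) / d
      uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
               (cx^2 + cy^2) * (bx - ax)) / d
      consider(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
    }
  }
  best
}
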