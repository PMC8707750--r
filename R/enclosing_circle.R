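#' Smallest enclosing circle of a point set
#'
#' Exact minimum bounding circle via the incremental move-to-front
#' algorithm: points are added one at a time; whenever a point falls
#' outside the current circle, the circle is rebuilt with that point
#' constrained to the boundary, recursing over one- and two-point
#' boundary constraints (with the usual left/right circumcircle candidate
#' selection in the two-point case). Expected linear time on shuffled
#' input; exact up to floating point. Used to summarise the spatial
#' extent of gaze samples or fixation centroids.
#'
#' @param x,y Numeric coordinate vectors (degrees), at least one point.
#' @return List with `center` (length-2 numeric) and `radius`.
#' @export
min_enclosing_circle <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) == 0L) stop("empty point set")
  pts <- cbind(x, y)
  pts <- pts[!duplicated(pts), , drop = FALSE]
  n <- nrow(pts)
  # deterministic shuffle keeps expected-linear behaviour reproducible
  ord <- withr::with_seed(8191L, sample.int(n))
  pts <- pts[ord, , drop = FALSE]

  contains <- function(circ, p) {
    sqrt(sum((p - circ$center)^2)) <= circ$radius * (1 + 1e-12) + 1e-14
  }
  diam_circle <- function(p, q) {
    list(center = (p + q) / 2, radius = sqrt(sum((p - q)^2)) / 2)
  }
  cross <- function(p, q, r) {
    (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  }
  circumcircle <- function(p, q, r) {
    d <- 2 * (p[1] * (q[2] - r[2]) + q[1] * (r[2] - p[2]) + r[1] * (p[2] - q[2]))
    if (abs(d) < 1e-14) return(NULL)
    ux <- (sum(p^2) * (q[2] - r[2]) + sum(q^2) * (r[2] - p[2]) +
             sum(r^2) * (p[2] - q[2])) / d
    uy <- (sum(p^2) * (r[1] - q[1]) + sum(q^2) * (p[1] - r[1]) +
             sum(r^2) * (q[1] - p[1])) / d
    ctr <- c(ux, uy)
    list(center = ctr,
         radius = max(sqrt(sum((p - ctr)^2)), sqrt(sum((q - ctr)^2)),
                      sqrt(sum((r - ctr)^2))))
  }
  # smallest circle with p and q on the boundary enclosing pts[1:i, ]
  two_boundary <- function(i, p, q) {
    circ <- diam_circle(p, q)
    left <- NULL
    right <- NULL
    for (k in seq_len(i)) {
      r <- pts[k, ]
      if (contains(circ, r)) next
      cr <- cross(p, q, r)
      cc <- circumcircle(p, q, r)
      if (is.null(cc)) next
      if (cr > 0 && (is.null(left) ||
                     cross(p, q, cc$center) > cross(p, q, left$center))) {
        left <- cc
      } else if (cr < 0 && (is.null(right) ||
                            cross(p, q, cc$center) < cross(p, q, right$center))) {
        right <- cc
      }
    }
    if (is.null(left) && is.null(right)) return(circ)
    if (is.null(left)) return(right)
    if (is.null(right)) return(left)
    if (left$radius <= right$radius) left else right
  }
  # smallest circle with p on the boundary enclosing pts[1:i, ]
  one_boundary <- function(i, p) {
    circ <- list(center = p, radius = 0)
    for (j in seq_len(i)) {
      q <- pts[j, ]
      if (!contains(circ, q)) {
        circ <- if (circ$radius == 0) diam_circle(p, q) else
          two_boundary(j - 1L, p, q)
      }
    }
    circ
  }

  circ <- list(center = pts[1, ], radius = 0)
  if (n > 1) {
    for (i in 2:n) {
      p <- pts[i, ]
      if (!contains(circ, p)) circ <- one_boundary(i - 1L, p)
    }
  }
  list(center = unname(circ$center), radius = unname(circ$radius))
}
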