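#' Detect blinks in a trial window
#'
#' A blink is a maximal run of samples during which both eyes are invalid
#' (device invalidity flag or non-positive pupil diameter) lasting at
#' least `min_duration_ms`. Monocular dropouts are not blinks: no gaze
#' information is lost only when neither eye reports a valid sample.
#' Runs shorter than the threshold are ignored.
#'
#' @param window A `trial_window` (see [extract_window()]).
#' @param min_duration_ms Minimum blink duration in ms (default 50).
#' @return A data frame with one row per blink: `start`, `end` (seconds,
#'   window time), `duration_ms`, `start_idx`, `end_idx` (sample indices).
#'   Zero rows when no blink is present.
#' @export
detect_blinks <- function(window, min_duration_ms = 50) {
  stopifnot(inherits(window, "trial_window"))
  d <- window$data
  fs <- window$sampling_rate
  invalid <- (!d$valid_l | d$lp <= 0) & (!d$valid_r | d$rp <= 0)
  r <- rle(invalid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / fs * 1000 >= min_duration_ms)
  out <- data.frame(
    start = d$time[starts[keep]],
    end = d$time[starts[keep]] + r$lengths[keep] / fs,
    duration_ms = r$lengths[keep] / fs * 1000,
    start_idx = starts[keep],
    end_idx = ends[keep]
  )
  rownames(out) <- NULL
  out
}

#' Linearly interpolate short invalid runs
#'
#' Bridges isolated invalid runs shorter than `max_gap_ms` by linear
#' interpolation of all gaze and pupil channels, marking them valid. This
#' avoids spurious transitions in the image encodings when a couple of
#' samples drop out without a true blink; it is applied on the implicit
#' (image) path only, never before explicit event detection.
#'
#' @param window A `trial_window`.
#' @param max_gap_ms Runs shorter than this are interpolated (default 50,
#'   i.e. anything below the blink threshold).
#' @return The window with short gaps filled.
#' @export
interpolate_short_gaps <- function(window, max_gap_ms = 50) {
  stopifnot(inherits(window, "trial_window"))
  d <- window$data
  fs <- window$sampling_rate
  invalid <- (!d$valid_l | d$lp <= 0) & (!d$valid_r | d$rp <= 0)
  if (!any(invalid) || all(invalid)) return(window)
  r <- rle(invalid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  short <- r$values & (r$lengths / fs * 1000 < max_gap_ms)
  fill <- rep(FALSE, nrow(d))
  for (i in which(short)) fill[starts[i]:ends[i]] <- TRUE
  ok <- !invalid
  for (ch in c("lx", "ly", "rx", "ry", "lp", "rp")) {
    d[[ch]][fill] <- approx(d$time[ok], d[[ch]][ok], xout = d$time[fill],
                            rule = 2)$y
  }
  d$valid_l[fill] <- TRUE
  d$valid_r[fill] <- TRUE
  window$data <- d
  window
}

#' Remove blink and invalid samples from a window
#'
#' Drops every invalid sample (blinks and residual dropouts) and
#' concatenates the remaining valid segments, compressing the time axis.
#' Used on the implicit path before image encoding, where the transforms
#' require a gap-free series.
#'
#' @param window A `trial_window`.
#' @return The window restricted to valid samples; `n_removed` attribute
#'   records how many samples were dropped.
#' @export
remove_blink_samples <- function(window) {
  stopifnot(inherits(window, "trial_window"))
  d <- window$data
  invalid <- (!d$valid_l | d$lp <= 0) & (!d$valid_r | d$rp <= 0)
  if (all(invalid)) stop("window contains no valid samples")
  window$data <- d[!invalid, , drop = FALSE]
  rownames(window$data) <- NULL
  attr(window, "n_removed") <- sum(invalid)
  window
}
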