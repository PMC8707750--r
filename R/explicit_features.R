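#' Dispersion-threshold (I-DT) fixation detection
#'
#' Greedy left-to-right dispersion-threshold identification: a candidate
#' window covering the minimum duration is grown sample by sample while
#' its dispersion, `(max(x) - min(x)) + (max(y) - min(y))`, stays at or
#' below `dispersion_threshold`; when growth stops, the window is emitted
#' as a fixation and detection restarts after it. If the initial window
#' already exceeds the threshold, the window slides forward by one sample.
#'
#' @param x,y Equal-length gaze coordinate series in degrees (valid
#'   samples only).
#' @param sampling_rate Sampling rate in Hz.
#' @param dispersion_threshold Maximum dispersion in degrees (default 1).
#' @param min_duration_ms Minimum fixation duration in ms (default 100).
#' @return Data frame with one row per fixation: `start_idx`, `end_idx`
#'   (sample indices), `start`, `end` (seconds from series start),
#'   `duration_ms`, `centroid_x`, `centroid_y`, `dispersion`.
#' @export
detect_fixations_idt <- function(x, y, sampling_rate = 250,
                                 dispersion_threshold = 1.0,
                                 min_duration_ms = 100) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n == 0L) stop("empty input series")
  win <- max(2L, as.integer(ceiling(min_duration_ms / 1000 * sampling_rate)))
  out <- list()
  i <- 1L
  while (i + win - 1L <= n) {
    j <- i + win - 1L
    xs <- x[i:j]; ys <- y[i:j]
    disp <- (max(xs) - min(xs)) + (max(ys) - min(ys))
    if (disp <= dispersion_threshold) {
      xmin <- min(xs); xmax <- max(xs); ymin <- min(ys); ymax <- max(ys)
      while (j < n) {
        nx <- x[j + 1L]; ny <- y[j + 1L]
        d2 <- (max(xmax, nx) - min(xmin, nx)) + (max(ymax, ny) - min(ymin, ny))
        if (d2 > dispersion_threshold) break
        j <- j + 1L
        xmin <- min(xmin, nx); xmax <- max(xmax, nx)
        ymin <- min(ymin, ny); ymax <- max(ymax, ny)
      }
      out[[length(out) + 1L]] <- data.frame(
        start_idx = i, end_idx = j,
        start = (i - 1L) / sampling_rate, end = j / sampling_rate,
        duration_ms = (j - i + 1L) / sampling_rate * 1000,
        centroid_x = mean(x[i:j]), centroid_y = mean(y[i:j]),
        dispersion = (xmax - xmin) + (ymax - ymin)
      )
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start_idx = integer(), end_idx = integer(),
                      start = numeric(), end = numeric(),
                      duration_ms = numeric(), centroid_x = numeric(),
                      centroid_y = numeric(), dispersion = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Derive saccades from consecutive fixations
#'
#' One saccade per consecutive fixation pair: its amplitude is the
#' Euclidean distance between the two fixation centroids, its duration
#' the gap between the fixations, and its peak velocity the maximum
#' two-point (central-difference) speed within the gap at the native
#' sampling rate, without smoothing.
#'
#' @param fixations Fixation data frame from [detect_fixations_idt()],
#'   ordered in time.
#' @param x,y The gaze series the fixations were detected on.
#' @param sampling_rate Sampling rate in Hz.
#' @return Data frame with `start`, `end` (s), `duration_ms`, `amplitude`
#'   (deg), `peak_velocity` (deg/s); zero rows for fewer than two
#'   fixations.
#' @export
derive_saccades <- function(fixations, x, y, sampling_rate = 250) {
  empty <- data.frame(start = numeric(), end = numeric(),
                      duration_ms = numeric(), amplitude = numeric(),
                      peak_velocity = numeric())
  if (is.null(fixations) || nrow(fixations) < 2L) return(empty)
  n <- length(x)
  vx <- c(NA, (x[-(1:2)] - x[1:(n - 2)]) / 2, NA) * sampling_rate
  vy <- c(NA, (y[-(1:2)] - y[1:(n - 2)]) / 2, NA) * sampling_rate
  speed <- sqrt(vx^2 + vy^2)
  out <- lapply(seq_len(nrow(fixations) - 1L), function(i) {
    a <- fixations[i, ]; b <- fixations[i + 1L, ]
    gap <- seq(a$end_idx, min(b$start_idx, n))
    pv <- suppressWarnings(max(speed[gap], na.rm = TRUE))
    if (!is.finite(pv)) pv <- 0
    data.frame(
      start = a$end, end = b$start,
      duration_ms = (b$start_idx - a$end_idx - 1L) / sampling_rate * 1000,
      amplitude = sqrt((b$centroid_x - a$centroid_x)^2 +
                         (b$centroid_y - a$centroid_y)^2),
      peak_velocity = pv
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Horizontal vergence signal
#'
#' Per-sample horizontal disparity between the eyes, `right_x - left_x`
#' in degrees. Under parallel (distant) fixation the disparity is
#' constant; its variability increases when attention is directed
#' internally.
#'
#' @param left_x,right_x Equal-length horizontal gaze series (degrees).
#' @return Numeric disparity series.
#' @export
vergence_signal <- function(left_x, right_x) {
  stopifnot(length(left_x) == length(right_x))
  right_x - left_x
}

#' Eight summary statistics of a series
#'
#' Mean, standard deviation (sample, n-1), median, maximum, minimum,
#' range, excess kurtosis and skewness, in that order. Skewness and
#' kurtosis are standardized central moments (`m3 / m2^1.5` and
#' `m4 / m2^2 - 3`). Degenerate inputs are imputed to keep downstream
#' feature vectors finite: an empty series gives all zeros; constant or
#' shorter-than-3 series give zero spread, skewness and kurtosis.
#'
#' @param series Numeric vector (may be empty).
#' @return Named numeric vector of length 8.
#' @export
summary_stats <- function(series) {
  nm <- c("mean", "sd", "median", "max", "min", "range", "kurtosis", "skewness")
  series <- series[is.finite(series)]
  n <- length(series)
  if (n == 0L) return(stats::setNames(numeric(8), nm))
  s <- if (n > 1L) sd(series) else 0
  kurt <- skew <- 0
  if (n >= 3L && s > 0) {
    skew <- e1071::skewness(series, type = 1)
    kurt <- e1071::kurtosis(series, type = 1)
  }
  stats::setNames(
    c(mean(series), s, median(series), max(series), min(series),
      max(series) - min(series), kurt, skew), nm)
}

# signal blocks summarised by summary_stats(), in frozen order
.feature_signals <- c("fixation_duration", "fixation_dispersion",
                      "saccade_duration", "saccade_amplitude",
                      "saccade_peak_velocity", "blink_duration",
                      "left_pupil", "right_pupil", "vergence")

#' Canonical names of the 75 explicit gaze features
#'
#' Three event counts (fixations, saccades, blinks) followed by the eight
#' summary statistics of [summary_stats()] for each of nine signals:
#' fixation durations, fixation dispersions, saccade durations, saccade
#' amplitudes, saccade peak velocities, blink durations, left pupil
#' series, right pupil series, and the vergence (horizontal disparity)
#' signal. The order is frozen; feature vectors always follow it.
#'
#' @return Character vector of length 75.
#' @export
gaze_feature_names <- function() {
  stat_nm <- c("mean", "sd", "median", "max", "min", "range", "kurtosis",
               "skewness")
  c("n_fixations", "n_saccades", "n_blinks",
    as.vector(t(outer(.feature_signals, stat_nm, paste, sep = "_"))))
}

#' Build the 75-dimensional explicit feature vector of a trial window
#'
#' Detects blinks on the full window, then runs I-DT fixation detection
#' on the binocular-average gaze trace restricted to valid samples,
#' derives saccades between consecutive fixations, and assembles: the
#' three event counts plus [summary_stats()] of the nine signals listed
#' in [gaze_feature_names()]. Event streams that are empty in a window
#' (e.g. no blinks) contribute a zero count and all-zero statistics, so
#' the vector is always finite.
#'
#' @param window A `trial_window`.
#' @param dispersion_threshold I-DT dispersion threshold in degrees.
#' @param min_fixation_ms Minimum fixation duration in ms.
#' @param min_blink_ms Minimum blink duration in ms.
#' @return Named numeric vector of length 75 in the canonical order.
#' @export
build_feature_vector <- function(window, dispersion_threshold = 1.0,
                                 min_fixation_ms = 100, min_blink_ms = 50) {
  stopifnot(inherits(window, "trial_window"))
  d <- window$data
  fs <- window$sampling_rate
  blinks <- detect_blinks(window, min_duration_ms = min_blink_ms)

  valid <- (d$valid_l & d$lp > 0) | (d$valid_r & d$rp > 0)
  # binocular average trace; fall back to the valid eye when one drops out
  both <- d$valid_l & d$valid_r & d$lp > 0 & d$rp > 0
  ax <- ifelse(both, (d$lx + d$rx) / 2, ifelse(d$valid_l & d$lp > 0, d$lx, d$rx))
  ay <- ifelse(both, (d$ly + d$ry) / 2, ifelse(d$valid_l & d$lp > 0, d$ly, d$ry))
  ax <- ax[valid]; ay <- ay[valid]

  if (length(ax) >= 2L) {
    fix <- detect_fixations_idt(ax, ay, sampling_rate = fs,
                                dispersion_threshold = dispersion_threshold,
                                min_duration_ms = min_fixation_ms)
    sac <- derive_saccades(fix, ax, ay, sampling_rate = fs)
  } else {
    fix <- detect_fixations_idt(c(0, 0), c(0, 0), sampling_rate = fs)[0, ]
    sac <- derive_saccades(fix, 0, 0)
  }

  ok_both <- both
  signals <- list(
    fixation_duration = fix$duration_ms,
    fixation_dispersion = fix$dispersion,
    saccade_duration = sac$duration_ms,
    saccade_amplitude = sac$amplitude,
    saccade_peak_velocity = sac$peak_velocity,
    blink_duration = blinks$duration_ms,
    left_pupil = d$lp[d$valid_l & d$lp > 0],
    right_pupil = d$rp[d$valid_r & d$rp > 0],
    vergence = vergence_signal(d$lx[ok_both], d$rx[ok_both])
  )
  stats <- unlist(lapply(.feature_signals, function(s) summary_stats(signals[[s]])))
  v <- c(nrow(fix), nrow(sac), nrow(blinks), stats)
  v <- stats::setNames(as.numeric(v), gaze_feature_names())
  v[!is.finite(v)] <- 0
  v
}
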