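#' Construct a binocular gaze recording
#'
#' The core data container: a timestamped binocular gaze and pupil series
#' with per-eye validity flags. Gaze coordinates are stored in degrees of
#' visual angle relative to the screen centre; pixel data must be converted
#' with [px_to_degrees()] (the reader does this automatically when a screen
#' geometry is supplied). Invalid samples are flagged, never silently
#' imputed.
#'
#' Timestamps must be strictly increasing and compatible with the declared
#' sampling rate: spacing may jitter by up to 20% of a sample period.
#' Larger gaps are tolerated but the sample following a gap is marked
#' invalid, since the signal across the gap is unobserved.
#'
#' @param participant_id Character scalar identifying the participant.
#' @param time Numeric vector of timestamps in seconds, strictly increasing.
#' @param lx,ly,rx,ry Left/right eye gaze coordinates, degrees of visual
#'   angle relative to screen centre.
#' @param lp,rp Left/right pupil diameter (mm or device units; values
#'   `<= 0` are treated as invalid).
#' @param valid_l,valid_r Logical per-sample validity per eye. Defaults to
#'   all valid; non-positive pupil samples are flagged invalid regardless.
#' @param sampling_rate Sampling rate in Hz (default 250).
#' @param geometry Optional screen geometry, see [screen_geometry()].
#' @param trials Optional data frame of trial metadata with columns
#'   `task`, `condition` (`"internal"` or `"external"`) and `onset` (s).
#'
#' @return An object of class `gaze_recording`: a list with elements
#'   `participant_id`, `sampling_rate`, `data` (a data frame with columns
#'   `time, lx, ly, rx, ry, lp, rp, valid_l, valid_r`), `geometry`, and
#'   `trials`.
#' @export
gaze_recording <- function(participant_id, time, lx, ly, rx, ry, lp, rp,
                           valid_l = NULL, valid_r = NULL,
                           sampling_rate = 250, geometry = NULL,
                           trials = NULL) {
  n <- length(time)
  series <- list(lx = lx, ly = ly, rx = rx, ry = ry, lp = lp, rp = rp)
  lens <- vapply(series, length, integer(1))
  if (any(lens != n)) {
    stop("all channels must have the same length as `time`")
  }
  if (n == 0L) stop("empty recording")
  if (is.null(valid_l)) valid_l <- rep(TRUE, n)
  if (is.null(valid_r)) valid_r <- rep(TRUE, n)
  stopifnot(length(valid_l) == n, length(valid_r) == n)

  dt <- diff(time)
  period <- 1 / sampling_rate
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  if (any(dt < 0.8 * period)) {
    stop("timestamp spacing more than 20% below the sample period")
  }
  # samples right after a gap carry no information about the gap interval
  after_gap <- c(FALSE, dt > 1.2 * period)
  valid_l <- valid_l & !after_gap & !is.na(lp) & lp > 0
  valid_r <- valid_r & !after_gap & !is.na(rp) & rp > 0

  structure(
    list(
      participant_id = as.character(participant_id),
      sampling_rate = sampling_rate,
      data = data.frame(time = time, lx = lx, ly = ly, rx = rx, ry = ry,
                        lp = lp, rp = rp, valid_l = valid_l,
                        valid_r = valid_r),
      geometry = geometry,
      trials = trials
    ),
    class = "gaze_recording"
  )
}

#' @export
print.gaze_recording <- function(x, ...) {
  dur <- nrow(x$data) / x$sampling_rate
  cat(sprintf(
    "<gaze_recording> participant %s: %d samples at %g Hz (%.2f s), %d trial(s)\n",
    x$participant_id, nrow(x$data), x$sampling_rate, dur,
    if (is.null(x$trials)) 0L else nrow(x$trials)
  ))
  invisible(x)
}

#' Screen geometry for pixel-to-degree conversion
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param width_cm,height_cm Physical screen size in cm.
#' @param distance_cm Viewing distance in cm (must be positive).
#' @return A `screen_geometry` list.
#' @export
screen_geometry <- function(width_px, height_px, width_cm, height_cm,
                            distance_cm) {
  vals <- c(width_px, height_px, width_cm, height_cm, distance_cm)
  if (anyNA(vals) || length(vals) != 5) stop("geometry must be fully specified")
  if (distance_cm <= 0) stop("viewing distance must be positive")
  structure(list(width_px = width_px, height_px = height_px,
                 width_cm = width_cm, height_cm = height_cm,
                 distance_cm = distance_cm),
            class = "screen_geometry")
}

#' Convert on-screen pixel coordinates to degrees of visual angle
#'
#' Visual angle is taken relative to the screen centre, via the arctangent
#' of the physical on-screen offset over the viewing distance. The screen
#' centre maps to (0, 0); y grows downwards in pixels and upwards in
#' degrees is not imposed -- the sign convention of the input is preserved.
#'
#' @param x_px,y_px Pixel coordinates (vectors).
#' @param geometry A [screen_geometry()].
#' @return A list with numeric vectors `x` and `y` in degrees.
#' @export
px_to_degrees <- function(x_px, y_px, geometry) {
  if (is.null(geometry) || !inherits(geometry, "screen_geometry")) {
    stop("missing or invalid screen geometry")
  }
  dx_cm <- (x_px - geometry$width_px / 2) * geometry$width_cm / geometry$width_px
  dy_cm <- (y_px - geometry$height_px / 2) * geometry$height_cm / geometry$height_px
  list(x = atan(dx_cm / geometry$distance_cm) * 180 / pi,
       y = atan(dy_cm / geometry$distance_cm) * 180 / pi)
}

# canonical CSV dialect for gaze recordings
.gaze_csv_cols <- c("time_s", "lx_deg", "ly_deg", "rx_deg", "ry_deg",
                    "lp", "rp", "valid_l", "valid_r")

#' Read a gaze recording from delimited text
#'
#' Reads the package's documented CSV dialect: columns `time_s, lx_deg,
#' ly_deg, rx_deg, ry_deg, lp, rp, valid_l, valid_r`, with a JSON sidecar
#' (`<path>.json`) carrying participant id, sampling rate, optional screen
#' geometry and trial metadata. Alternative column layouts (e.g. a device
#' export in pixels) are handled through `columns`, a named character
#' vector mapping dialect names to file column names; when gaze columns
#' are in pixels, supply `geometry` and set `units = "px"` to convert at
#' read time.
#'
#' @param path Path to the delimited-text file.
#' @param sampling_rate Sampling rate in Hz; overrides the sidecar value.
#' @param columns Optional named remapping of column names.
#' @param units `"deg"` (default) or `"px"` for the gaze columns.
#' @param geometry Optional [screen_geometry()]; required if `units = "px"`.
#' @param sep Field separator (default comma).
#' @return A [gaze_recording()].
#' @export
read_gaze_recording <- function(path, sampling_rate = NULL, columns = NULL,
                                units = c("deg", "px"), geometry = NULL,
                                sep = ",") {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty file: ", path)
  if (!is.null(columns)) {
    for (std in names(columns)) {
      if (!columns[[std]] %in% names(df)) {
        stop("mapped column not found: ", columns[[std]])
      }
      names(df)[names(df) == columns[[std]]] <- std
    }
  }
  missing_cols <- setdiff(.gaze_csv_cols[1:7], names(df))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"valid_l" %in% names(df)) df$valid_l <- TRUE
  if (!"valid_r" %in% names(df)) df$valid_r <- TRUE

  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(sampling_rate)) sampling_rate <- meta$sampling_rate
  if (is.null(sampling_rate)) stop("sampling rate not given and not in sidecar")
  if (is.null(geometry) && !is.null(meta$geometry)) {
    geometry <- do.call(screen_geometry, as.list(meta$geometry))
  }
  trials <- if (!is.null(meta$trials)) as.data.frame(meta$trials) else NULL
  pid <- if (!is.null(meta$participant)) meta$participant else basename(path)

  if (units == "px") {
    l <- px_to_degrees(df$lx_deg, df$ly_deg, geometry)
    r <- px_to_degrees(df$rx_deg, df$ry_deg, geometry)
    df$lx_deg <- l$x; df$ly_deg <- l$y
    df$rx_deg <- r$x; df$ry_deg <- r$y
  }

  gaze_recording(
    participant_id = pid, time = df$time_s,
    lx = df$lx_deg, ly = df$ly_deg, rx = df$rx_deg, ry = df$ry_deg,
    lp = df$lp, rp = df$rp,
    valid_l = as.logical(df$valid_l), valid_r = as.logical(df$valid_r),
    sampling_rate = sampling_rate, geometry = geometry, trials = trials
  )
}

#' Write a gaze recording in the package CSV dialect
#'
#' Writes `<path>` (CSV) and `<path>.json` (metadata sidecar). The
#' round-trip `read_gaze_recording(write_gaze_recording(rec))` reproduces
#' all channels up to the printed float precision.
#'
#' @param rec A [gaze_recording()].
#' @param path Output file path.
#' @param digits Significant digits for numeric columns (default 10).
#' @return `path`, invisibly.
#' @export
write_gaze_recording <- function(rec, path, digits = 10) {
  stopifnot(inherits(rec, "gaze_recording"))
  d <- rec$data
  out <- data.frame(
    time_s = signif(d$time, digits), lx_deg = signif(d$lx, digits),
    ly_deg = signif(d$ly, digits), rx_deg = signif(d$rx, digits),
    ry_deg = signif(d$ry, digits), lp = signif(d$lp, digits),
    rp = signif(d$rp, digits), valid_l = d$valid_l, valid_r = d$valid_r
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  meta <- list(participant = rec$participant_id,
               sampling_rate = rec$sampling_rate)
  if (!is.null(rec$geometry)) meta$geometry <- unclass(rec$geometry)
  if (!is.null(rec$trials)) meta$trials <- rec$trials
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Extract an analysis window from a recording
#'
#' Returns the samples in the half-open interval
#' `[onset + 1, onset + 1 + length)` seconds: the first second after trial
#' onset is always discarded to exclude task-onset contamination, and the
#' half-open convention guarantees exact sample counts (750 at 3 s,
#' 2000 at 8 s, for 250 Hz data).
#'
#' @param rec A [gaze_recording()].
#' @param onset Trial onset in seconds (recording time).
#' @param length Window length in seconds, 3 or 8.
#' @param task_id Optional task identifier carried into the window.
#' @param label Optional condition label, `"internal"` or `"external"`.
#' @return A `trial_window` object: list with `participant_id`, `task_id`,
#'   `label`, `window_length`, `sampling_rate` and `data` (same columns as
#'   the recording).
#' @export
extract_window <- function(rec, onset, length = c(8, 3), task_id = NA,
                           label = NA) {
  stopifnot(inherits(rec, "gaze_recording"))
  length <- match.arg(as.character(length[1]), c("8", "3"))
  length <- as.numeric(length)
  t0 <- onset + 1
  t1 <- t0 + length
  eps <- 1e-9
  keep <- rec$data$time >= t0 - eps & rec$data$time < t1 - eps
  expected <- as.integer(round(length * rec$sampling_rate))
  if (sum(keep) < expected) {
    stop(sprintf("recording does not cover [%g, %g) s (need %d samples, have %d)",
                 t0, t1, expected, sum(keep)))
  }
  data <- rec$data[keep, , drop = FALSE][seq_len(expected), , drop = FALSE]
  rownames(data) <- NULL
  if (!is.na(label)) label <- match.arg(label, c("internal", "external"))
  structure(
    list(participant_id = rec$participant_id, task_id = task_id,
         label = label, window_length = length,
         sampling_rate = rec$sampling_rate, data = data),
    class = "trial_window"
  )
}

#' @export
print.trial_window <- function(x, ...) {
  cat(sprintf(
    "<trial_window> participant %s, task %s, label %s: %g s (%d samples at %g Hz)\n",
    x$participant_id, as.character(x$task_id), as.character(x$label),
    x$window_length, nrow(x$data), x$sampling_rate
  ))
  invisible(x)
}
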