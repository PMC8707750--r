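# build a trial_window directly from channel vectors (250 Hz default)
make_window <- function(lx, ly = lx * 0, rx = lx, ry = ly, lp = NULL,
                        rp = NULL, valid_l = NULL, valid_r = NULL,
                        fs = 250, label = NA) {
  n <- length(lx)
  if (is.null(lp)) lp <- rep(4, n)
  if (is.null(rp)) rp <- rep(4, n)
  if (is.null(valid_l)) valid_l <- rep(TRUE, n)
  if (is.null(valid_r)) valid_r <- rep(TRUE, n)
  structure(
    list(participant_id = "T", task_id = NA, label = label,
         window_length = n / fs, sampling_rate = fs,
         data = data.frame(time = (seq_len(n) - 1) / fs, lx = lx, ly = ly,
                           rx = rx, ry = ry, lp = lp, rp = rp,
                           valid_l = valid_l, valid_r = valid_r)),
    class = "trial_window")
}

# a clean 250 Hz recording with slow sinusoidal gaze drift
make_recording <- function(duration = 10, fs = 250, pid = "P1") {
  n <- duration * fs
  t <- (seq_len(n) - 1) / fs
  gaze_recording(
    participant_id = pid, time = t,
    lx = 2 * sin(2 * pi * 0.2 * t), ly = 1.5 * cos(2 * pi * 0.15 * t),
    rx = 2 * sin(2 * pi * 0.2 * t) + 0.3, ry = 1.5 * cos(2 * pi * 0.15 * t),
    lp = 4 + 0.1 * sin(2 * pi * 0.1 * t), rp = 4 + 0.1 * sin(2 * pi * 0.1 * t),
    sampling_rate = fs)
}
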