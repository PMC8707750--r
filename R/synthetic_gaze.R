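#' Condition parameters for the synthetic gaze generator
#'
#' Bundles the event-level generative parameters of one attentional
#' condition. Durations are log-normal, saccade amplitudes gamma,
#' microsaccades and blinks Poisson processes; the pupil and the
#' vergence disparity are AR(1) processes. All rates and durations must
#' be positive.
#'
#' @param fixation_rate Nominal fixation rate in events/s implied by the
#'   duration parameters (documentation value; the realised rate emerges
#'   from the fixation/saccade alternation).
#' @param fixation_dur_meanlog,fixation_dur_sdlog Log-normal parameters
#'   of fixation duration in ms.
#' @param saccade_shape,saccade_scale Gamma parameters of saccade
#'   amplitude in degrees.
#' @param microsaccade_rate Microsaccade rate within fixations, events/s.
#' @param blink_rate Blink rate, events/min.
#' @param blink_dur_meanlog,blink_dur_sdlog Log-normal parameters of
#'   blink duration in ms.
#' @param pupil_base Baseline pupil diameter, mm.
#' @param pupil_sd Stationary SD of the AR(1) pupil process, mm.
#' @param vergence_sd Stationary SD of the AR(1) vergence disparity, deg.
#' @param jitter_sd Gaussian positional jitter within fixations, deg
#'   (set to 0 for noise-free event recovery tests).
#' @return A `condition_params` list.
#' @export
condition_params <- function(fixation_rate = 3,
                             fixation_dur_meanlog = log(250),
                             fixation_dur_sdlog = 0.4,
                             saccade_shape = 2, saccade_scale = 2,
                             microsaccade_rate = 1.5,
                             blink_rate = 15,
                             blink_dur_meanlog = log(150),
                             blink_dur_sdlog = 0.3,
                             pupil_base = 4, pupil_sd = 0.15,
                             vergence_sd = 0.3, jitter_sd = 0.05) {
  p <- list(fixation_rate = fixation_rate,
            fixation_dur_meanlog = fixation_dur_meanlog,
            fixation_dur_sdlog = fixation_dur_sdlog,
            saccade_shape = saccade_shape, saccade_scale = saccade_scale,
            microsaccade_rate = microsaccade_rate, blink_rate = blink_rate,
            blink_dur_meanlog = blink_dur_meanlog,
            blink_dur_sdlog = blink_dur_sdlog, pupil_base = pupil_base,
            pupil_sd = pupil_sd, vergence_sd = vergence_sd,
            jitter_sd = jitter_sd)
  pos <- c("fixation_rate", "fixation_dur_sdlog", "saccade_shape",
           "saccade_scale", "blink_rate", "blink_dur_sdlog", "pupil_base",
           "pupil_sd", "vergence_sd")
  for (nm in pos) if (p[[nm]] <= 0) stop("parameter must be positive: ", nm)
  if (p$microsaccade_rate < 0 || p$jitter_sd < 0) {
    stop("rates and spreads must be non-negative")
  }
  structure(p, class = "condition_params")
}

#' Condition presets encoding the internal/external class structure
#'
#' Returns the generator parameters of one condition. The external
#' preset is the [condition_params()] default; the internal preset
#' shifts it in the directions reported for internally directed
#' attention: fewer but longer fixations and blinks, increased vergence
#' and pupil-diameter variability, and fewer microsaccades. All offsets
#' scale with `effect_size`; at `effect_size = 0` the two presets are
#' identical, making class separability a controlled dial.
#'
#' With `channels = "explicit"` the internal offsets are restricted to
#' the blink parameters, confining most of the class signal to event
#' statistics that only the explicit feature vector summarises (blink
#' samples are removed before image encoding), which is useful to probe
#' the added value of the explicit branch.
#'
#' @param condition `"internal"` or `"external"`.
#' @param effect_size Non-negative scalar scaling all class offsets
#'   (default 1).
#' @param channels `"all"` (default) or `"explicit"`.
#' @return A `condition_params` object.
#' @export
preset_params <- function(condition = c("external", "internal"),
                          effect_size = 1, channels = c("all", "explicit")) {
  condition <- match.arg(condition)
  channels <- match.arg(channels)
  if (effect_size < 0) stop("effect_size must be non-negative")
  p <- condition_params()
  if (condition == "internal") {
    e <- effect_size
    p$blink_rate <- p$blink_rate * exp(-0.35 * e)
    p$blink_dur_meanlog <- p$blink_dur_meanlog + 0.30 * e
    if (channels == "all") {
      p$fixation_dur_meanlog <- p$fixation_dur_meanlog + 0.35 * e
      p$microsaccade_rate <- p$microsaccade_rate * exp(-0.5 * e)
      p$vergence_sd <- p$vergence_sd * (1 + 0.6 * e)
      p$pupil_sd <- p$pupil_sd * (1 + 0.8 * e)
      p$fixation_rate <- p$fixation_rate * exp(-0.35 * e)
    }
  }
  p
}

# minimum-jerk displacement profile on [0, 1]
.min_jerk <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)

# stationary AR(1) with autocorrelation phi and stationary sd
.ar1 <- function(n, phi, sd_stat) {
  if (sd_stat == 0 || n == 0L) return(numeric(n))
  innov_sd <- sd_stat * sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd_stat)
  if (n > 1) {
    e <- rnorm(n - 1, 0, innov_sd)
    for (i in 2:n) x[i] <- phi * x[i - 1] + e[i - 1]
  }
  x
}

#' Generate one synthetic trial
#'
#' Simulates a binocular recording of one trial as a piecewise
#' trajectory: fixations (stationary position plus Gaussian jitter and
#' Poisson microsaccadic shifts bounded within the dispersion limit)
#' alternating with ballistic saccades following a minimum-jerk profile
#' toward gamma-distributed amplitudes, with direction biased back
#' toward the screen centre. Blinks arrive as a Poisson process and mark
#' both eyes invalid. The right eye equals the left eye plus an AR(1)
#' vergence disparity; both pupils follow a common AR(1) process around
#' the baseline. The ground-truth event list is returned for oracle
#' tests.
#'
#' @param condition `"internal"` or `"external"` (label only; the
#'   statistics are set by `params`).
#' @param params A [condition_params()].
#' @param duration Trial duration in seconds, in `[10, 14]`.
#' @param sampling_rate Sampling rate in Hz (default 250).
#' @param seed Integer seed; the trial is a pure function of
#'   `(condition, params, duration, seed)`.
#' @return A [gaze_recording()] with an extra `events` element: list of
#'   data frames `fixations` (start/end s, x, y, duration_ms),
#'   `saccades`, `blinks` and `microsaccades`.
#' @export
generate_trial <- function(condition = c("external", "internal"),
                           params = preset_params(), duration = 12,
                           sampling_rate = 250, seed = 1) {
  condition <- match.arg(condition)
  stopifnot(inherits(params, "condition_params"))
  if (duration < 10 || duration > 14) stop("duration must lie in [10, 14] s")
  fs <- sampling_rate
  n <- as.integer(round(duration * fs))

  rec <- withr::with_seed(as.integer(seed), {
    x <- numeric(n); y <- numeric(n)
    fix_events <- list(); sac_events <- list(); micro_events <- list()

    pos <- runif(2, -6, 6)
    i <- 1L
    while (i <= n) {
      # fixation
      dur_ms <- rlnorm(1, params$fixation_dur_meanlog, params$fixation_dur_sdlog)
      len <- max(2L, as.integer(round(dur_ms / 1000 * fs)))
      j <- min(n, i + len - 1L)
      fx <- rep(pos[1], j - i + 1L)
      fy <- rep(pos[2], j - i + 1L)
      n_micro <- rpois(1, params$microsaccade_rate * (j - i + 1L) / fs)
      if (n_micro > 0) {
        at <- sort(sample.int(j - i + 1L, min(n_micro, j - i + 1L)))
        off <- c(0, 0)
        for (m in at) {
          ang <- runif(1, 0, 2 * pi)
          off <- off + 0.2 * c(cos(ang), sin(ang))
          r <- sqrt(sum(off^2))
          if (r > 0.2) off <- off * 0.2 / r  # stay inside the dispersion bound
          fx[m:(j - i + 1L)] <- pos[1] + off[1]
          fy[m:(j - i + 1L)] <- pos[2] + off[2]
          micro_events[[length(micro_events) + 1L]] <-
            data.frame(time = (i + m - 2L) / fs)
        }
      }
      if (params$jitter_sd > 0) {
        fx <- fx + rnorm(j - i + 1L, 0, params$jitter_sd)
        fy <- fy + rnorm(j - i + 1L, 0, params$jitter_sd)
      }
      x[i:j] <- fx; y[i:j] <- fy
      fix_events[[length(fix_events) + 1L]] <- data.frame(
        start = (i - 1L) / fs, end = j / fs, x = pos[1], y = pos[2],
        duration_ms = (j - i + 1L) / fs * 1000,
        start_idx = i, end_idx = j)
      i <- j + 1L
      if (i > n) break

      # saccade toward a new target, direction biased to recentre
      amp <- rgamma(1, shape = params$saccade_shape, scale = params$saccade_scale)
      to_center <- atan2(-pos[2], -pos[1])
      ang <- to_center + rnorm(1, 0, pi / 3)
      target <- pos + amp * c(cos(ang), sin(ang))
      target <- pmin(12, pmax(-12, target))
      sdur_ms <- 21 + 2.2 * amp  # main-sequence-like duration
      slen <- max(2L, as.integer(round(sdur_ms / 1000 * fs)))
      k <- min(n, i + slen - 1L)
      tau <- seq_len(k - i + 1L) / (slen + 1L)
      x[i:k] <- pos[1] + (target[1] - pos[1]) * .min_jerk(tau)
      y[i:k] <- pos[2] + (target[2] - pos[2]) * .min_jerk(tau)
      sac_events[[length(sac_events) + 1L]] <- data.frame(
        start = (i - 1L) / fs, end = k / fs,
        amplitude = sqrt(sum((target - pos)^2)),
        duration_ms = (k - i + 1L) / fs * 1000)
      pos <- target
      i <- k + 1L
    }

    # blinks: Poisson process, log-normal durations, non-overlapping
    valid <- rep(TRUE, n)
    blink_events <- list()
    n_blinks <- rpois(1, params$blink_rate * duration / 60)
    if (n_blinks > 0) {
      starts <- sort(runif(n_blinks, 0, duration))
      last_end <- -Inf
      for (b in seq_len(n_blinks)) {
        bdur_ms <- rlnorm(1, params$blink_dur_meanlog, params$blink_dur_sdlog)
        s_idx <- as.integer(floor(starts[b] * fs)) + 1L
        e_idx <- min(n, s_idx + max(1L, as.integer(round(bdur_ms / 1000 * fs))) - 1L)
        if (s_idx <= last_end + 1L || s_idx > n) next
        valid[s_idx:e_idx] <- FALSE
        blink_events[[length(blink_events) + 1L]] <- data.frame(
          start = (s_idx - 1L) / fs, end = e_idx / fs,
          duration_ms = (e_idx - s_idx + 1L) / fs * 1000,
          start_idx = s_idx, end_idx = e_idx)
        last_end <- e_idx
      }
    }

    verg <- .ar1(n, 0.97, params$vergence_sd)
    pupil <- params$pupil_base + .ar1(n, 0.97, params$pupil_sd)
    lp <- pmax(0.5, pupil + rnorm(n, 0, 0.01))
    rp <- pmax(0.5, pupil + rnorm(n, 0, 0.01))
    lp[!valid] <- 0
    rp[!valid] <- 0

    rec <- gaze_recording(
      participant_id = "synthetic", time = (seq_len(n) - 1L) / fs,
      lx = x, ly = y, rx = x + verg, ry = y + rnorm(n, 0, 0.02),
      lp = lp, rp = rp, valid_l = valid, valid_r = valid,
      sampling_rate = fs,
      trials = data.frame(task = NA, condition = condition, onset = 0)
    )
    rec$events <- list(
      fixations = .bind_or_empty(fix_events,
        c("start", "end", "x", "y", "duration_ms", "start_idx", "end_idx")),
      saccades = .bind_or_empty(sac_events,
        c("start", "end", "amplitude", "duration_ms")),
      blinks = .bind_or_empty(blink_events,
        c("start", "end", "duration_ms", "start_idx", "end_idx")),
      microsaccades = .bind_or_empty(micro_events, "time")
    )
    rec
  })
  rec
}

.bind_or_empty <- function(lst, cols) {
  if (length(lst) == 0L) {
    df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    return(df)
  }
  res <- do.call(rbind, lst)
  rownames(res) <- NULL
  res
}

#' Generate a synthetic multi-participant study
#'
#' Simulates a full study: each participant performs `trials_per_participant`
#' trials over 6 tasks (3 internal, 3 external; modalities numerical,
#' verbal, visuospatial), so labels are exactly balanced. Inter-individual
#' variability is modelled by per-participant log-normal multipliers on
#' the fixation-duration, blink-rate, pupil and vergence parameters,
#' drawn once per participant. Seeds are hierarchical (master seed gives
#' participant seeds, which give trial seeds), so any subset regenerates
#' identically.
#'
#' @param n_participants Number of participants (>= 1).
#' @param trials_per_participant Trials per participant, divisible by 6
#'   (default 96).
#' @param effect_size Class separation dial passed to [preset_params()].
#' @param channels Passed to [preset_params()].
#' @param duration_range Trial duration range in seconds (default 10-14).
#' @param sampling_rate Sampling rate in Hz.
#' @param seed Master seed.
#' @return A `gaze_study`: list with `participants` (list of per-trial
#'   [generate_trial()] recordings), `meta` (data frame: participant,
#'   task, modality, condition, trial index) and the generation settings.
#' @export
generate_study <- function(n_participants, trials_per_participant = 96,
                           effect_size = 1, channels = c("all", "explicit"),
                           duration_range = c(10, 14), sampling_rate = 250,
                           seed = 1) {
  channels <- match.arg(channels)
  if (n_participants < 1) stop("need at least one participant")
  if (trials_per_participant %% 6 != 0) {
    stop("trials_per_participant must be divisible by 6")
  }
  per_task <- trials_per_participant / 6
  tasks <- data.frame(
    task = paste0(rep(c("internal", "external"), each = 3), "_",
                  c("numerical", "verbal", "visuospatial")),
    modality = rep(c("numerical", "verbal", "visuospatial"), 2),
    condition = rep(c("internal", "external"), each = 3)
  )

  part_seeds <- withr::with_seed(as.integer(seed),
                                 sample.int(.Machine$integer.max, n_participants))
  participants <- vector("list", n_participants)
  meta <- list()
  for (p in seq_len(n_participants)) {
    pid <- sprintf("P%03d", p)
    draws <- withr::with_seed(part_seeds[p], list(
      mult = rlnorm(4, 0, 0.08),
      trial_seeds = sample.int(.Machine$integer.max, trials_per_participant),
      durations = runif(trials_per_participant, duration_range[1],
                        duration_range[2]),
      order = sample.int(trials_per_participant)
    ))
    trial_tasks <- tasks[rep(seq_len(6), each = per_task), ][draws$order, ]
    trials <- vector("list", trials_per_participant)
    for (tr in seq_len(trials_per_participant)) {
      cond <- trial_tasks$condition[tr]
      par <- preset_params(cond, effect_size = effect_size, channels = channels)
      par$fixation_dur_meanlog <- par$fixation_dur_meanlog + log(draws$mult[1])
      par$blink_rate <- par$blink_rate * draws$mult[2]
      par$pupil_base <- par$pupil_base * draws$mult[3]
      par$vergence_sd <- par$vergence_sd * draws$mult[4]
      recording <- generate_trial(cond, par, duration = draws$durations[tr],
                                  sampling_rate = sampling_rate,
                                  seed = draws$trial_seeds[tr])
      recording$participant_id <- pid
      recording$trials$task <- trial_tasks$task[tr]
      trials[[tr]] <- recording
      meta[[length(meta) + 1L]] <- data.frame(
        participant = pid, trial = tr, task = trial_tasks$task[tr],
        modality = trial_tasks$modality[tr], condition = cond)
    }
    participants[[p]] <- trials
  }
  structure(
    list(participants = participants, meta = do.call(rbind, meta),
         effect_size = effect_size, channels = channels, seed = seed,
         sampling_rate = sampling_rate),
    class = "gaze_study"
  )
}

#' @export
print.gaze_study <- function(x, ...) {
  cat(sprintf(
    "<gaze_study> %d participants x %d trials, effect size %g (%s channels), seed %d\n",
    length(x$participants), nrow(x$meta) / length(x$participants),
    x$effect_size, x$channels, x$seed
  ))
  invisible(x)
}

#' Write a synthetic study to disk in the gaze CSV dialect
#'
#' One CSV + JSON sidecar per trial, under `dir/<participant>/trial_<k>.csv`.
#'
#' @param study A `gaze_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "gaze_study"))
  for (p in seq_along(study$participants)) {
    trials <- study$participants[[p]]
    pid <- trials[[1]]$participant_id
    pdir <- file.path(dir, pid)
    dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
    for (tr in seq_along(trials)) {
      write_gaze_recording(trials[[tr]],
                           file.path(pdir, sprintf("trial_%03d.csv", tr)))
    }
  }
  invisible(dir)
}
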