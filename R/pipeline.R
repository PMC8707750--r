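#' Prepare a trial dataset for classification
#'
#' Extracts the analysis window of every trial of a synthetic (or
#' loaded) study and precomputes both feature representations: the
#' 18-channel image stack and the 75-dimensional explicit vector.
#' Computing the features once up front lets every evaluation protocol
#' reuse them across folds.
#'
#' @param study A `gaze_study` from [generate_study()], or a list of
#'   [gaze_recording()]s with trial metadata.
#' @param window_length Window length in seconds, 3 or 8.
#' @return A `trial_dataset`: list with `x` (array `[48, 48, 18, N]`),
#'   `explicit` (`N x 75` matrix), `meta` (data frame with `participant`,
#'   `task`, `condition`) and `window_length`.
#' @export
prepare_trials <- function(study, window_length = 3) {
  stopifnot(inherits(study, "gaze_study"))
  recs <- unlist(study$participants, recursive = FALSE)
  meta <- study$meta
  stopifnot(length(recs) == nrow(meta))
  N <- length(recs)
  x <- array(0, dim = c(48L, 48L, 18L, N))
  expl <- matrix(0, N, 75, dimnames = list(NULL, gaze_feature_names()))
  for (i in seq_len(N)) {
    w <- extract_window(recs[[i]], onset = 0, length = window_length,
                        task_id = meta$task[i], label = meta$condition[i])
    x[, , , i] <- build_image_stack(w)
    expl[i, ] <- build_feature_vector(w)
  }
  structure(list(x = x, explicit = expl, meta = meta,
                 window_length = window_length),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf(
    "<trial_dataset> %d trials, %d participant(s), %g s windows\n",
    nrow(x$meta), length(unique(x$meta$participant)), x$window_length))
  invisible(x)
}

# fit on train indices, return accuracy on test indices
.fit_and_score <- function(dataset, train_idx, test_idx,
                           features = c("implicit", "combined"),
                           config = train_config(), seed = config$seed) {
  features <- match.arg(features)
  combined <- features == "combined"
  config$seed <- as.integer(seed)
  net <- build_network(combined = combined, seed = seed)
  net <- train_network(
    net, dataset$x[, , , train_idx, drop = FALSE],
    labels = dataset$meta$condition[train_idx],
    explicit = if (combined) dataset$explicit[train_idx, , drop = FALSE],
    config = config)
  pred <- predict_network(
    net, dataset$x[, , , test_idx, drop = FALSE],
    explicit = if (combined) dataset$explicit[test_idx, , drop = FALSE])
  mean(pred$labels == dataset$meta$condition[test_idx])
}
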