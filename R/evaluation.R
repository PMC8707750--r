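#' Stratified shuffled k-fold assignment
#'
#' Shuffles the indices of each class independently and deals them round
#' robin over `k` folds, so per-fold class counts differ by at most one
#' and the folds partition the data.
#'
#' @param labels Vector of class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold assignment (1..k) per observation.
#' @export
stratified_folds <- function(labels, k = 5, seed = 1) {
  labels <- as.factor(labels)
  if (any(table(labels) < k)) stop("every class needs at least k observations")
  fold <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    # one round-robin deal continued across classes, so per-class counts
    # per fold differ by <= 1 and total fold sizes differ by <= 1 as well
    offset <- 0L
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- (offset + seq_along(idx) - 1L) %% k + 1L
      offset <- offset + length(idx)
    }
  })
  fold
}

#' Person-dependent five-fold cross-validation
#'
#' Evaluates one participant's trials with a shuffled, stratified k-fold
#' split: the network is trained on k-1 folds and tested on the held-out
#' fold; the per-fold test accuracies (whose average is the participant's
#' score) are returned.
#'
#' @param dataset A `trial_dataset` (see [prepare_trials()]); typically
#'   restricted to one participant via `participant`.
#' @param participant Participant id to evaluate (defaults to the first).
#' @param k Number of folds (default 5).
#' @param features `"implicit"` or `"combined"`.
#' @param config A [train_config()].
#' @param seed Seed for the fold assignment and training.
#' @return Data frame with `fold`, `n_test`, `accuracy`.
#' @export
person_dependent_cv <- function(dataset, participant = NULL, k = 5,
                                features = c("implicit", "combined"),
                                config = train_config(), seed = 1) {
  stopifnot(inherits(dataset, "trial_dataset"))
  features <- match.arg(features)
  if (is.null(participant)) participant <- dataset$meta$participant[1]
  idx <- which(dataset$meta$participant == participant)
  if (!length(idx)) stop("unknown participant: ", participant)
  fold <- stratified_folds(dataset$meta$condition[idx], k = k, seed = seed)
  out <- lapply(seq_len(k), function(f) {
    test_idx <- idx[fold == f]
    train_idx <- idx[fold != f]
    data.frame(fold = f, n_test = length(test_idx),
               accuracy = .fit_and_score(dataset, train_idx, test_idx,
                                         features = features, config = config,
                                         seed = seed + f))
  })
  do.call(rbind, out)
}

#' Person-independent (leave-one-participant-out) evaluation
#'
#' For each participant, trains one network on all other participants'
#' trials and tests on the held-out participant, yielding one accuracy
#' per participant. Each held-out participant uses a fixed, distinct
#' seed so the protocol is reproducible.
#'
#' @inheritParams person_dependent_cv
#' @return Data frame with `participant`, `n_test`, `accuracy`.
#' @export
person_independent_cv <- function(dataset,
                                  features = c("implicit", "combined"),
                                  config = train_config(), seed = 1) {
  stopifnot(inherits(dataset, "trial_dataset"))
  features <- match.arg(features)
  parts <- unique(dataset$meta$participant)
  if (length(parts) < 2L) stop("leave-one-participant-out needs >= 2 participants")
  out <- lapply(seq_along(parts), function(i) {
    test_idx <- which(dataset$meta$participant == parts[i])
    train_idx <- which(dataset$meta$participant != parts[i])
    data.frame(participant = parts[i], n_test = length(test_idx),
               accuracy = .fit_and_score(dataset, train_idx, test_idx,
                                         features = features, config = config,
                                         seed = seed + i))
  })
  do.call(rbind, out)
}

#' Task-independent train/test splits
#'
#' Builds the nine task-combination splits: the test set is one internal
#' task crossed with one external task; the training set is the
#' remaining four tasks (two internal, two external), pooled across
#' participants.
#'
#' @param meta Trial metadata data frame with columns `task` and
#'   `condition` (all six tasks must be present).
#' @return List of 9 splits, each with `internal_task`, `external_task`,
#'   `train_idx`, `test_idx`.
#' @export
task_independent_splits <- function(meta) {
  tasks_int <- sort(unique(meta$task[meta$condition == "internal"]))
  tasks_ext <- sort(unique(meta$task[meta$condition == "external"]))
  if (length(tasks_int) != 3L || length(tasks_ext) != 3L) {
    stop("expected 3 internal and 3 external tasks")
  }
  splits <- list()
  for (ti in tasks_int) {
    for (te in tasks_ext) {
      test_idx <- which(meta$task %in% c(ti, te))
      splits[[length(splits) + 1L]] <- list(
        internal_task = ti, external_task = te,
        train_idx = setdiff(seq_len(nrow(meta)), test_idx),
        test_idx = test_idx)
    }
  }
  splits
}

#' Task-independent evaluation
#'
#' Trains and tests the classifier on each of the nine
#' [task_independent_splits()].
#'
#' @inheritParams person_dependent_cv
#' @return Data frame with `internal_task`, `external_task`, `n_test`,
#'   `accuracy`.
#' @export
task_independent_cv <- function(dataset,
                                features = c("implicit", "combined"),
                                config = train_config(), seed = 1) {
  stopifnot(inherits(dataset, "trial_dataset"))
  features <- match.arg(features)
  splits <- task_independent_splits(dataset$meta)
  out <- lapply(seq_along(splits), function(i) {
    s <- splits[[i]]
    data.frame(internal_task = s$internal_task,
               external_task = s$external_task, n_test = length(s$test_idx),
               accuracy = .fit_and_score(dataset, s$train_idx, s$test_idx,
                                         features = features, config = config,
                                         seed = seed + i))
  })
  do.call(rbind, out)
}

#' Better-than-random accuracy threshold
#'
#' The smallest accuracy `k/n` such that a random classifier (binomial
#' with success probability `p0`) reaches at least `k` correct out of
#' `n` with probability at most `alpha`. Exact binomial upper tail, no
#' normal approximation; for 96 balanced trials at the 5% level the
#' threshold is 57/96.
#'
#' @param n_test Test-set size (>= 1).
#' @param alpha Confidence level complement (default 0.05).
#' @param p0 Chance success probability (default 0.5).
#' @return The accuracy threshold in (0, 1].
#' @export
random_threshold <- function(n_test, alpha = 0.05, p0 = 0.5) {
  if (length(n_test) > 1L) {
    return(vapply(n_test, random_threshold, numeric(1), alpha = alpha, p0 = p0))
  }
  stopifnot(n_test >= 1)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  k <- seq(0, n_test)
  tail_p <- pbinom(k - 1, n_test, p0, lower.tail = FALSE)  # P(X >= k)
  k_min <- k[match(TRUE, tail_p <= alpha)]
  if (is.na(k_min)) return(Inf)
  k_min / n_test
}

#' Paired comparison of two accuracy vectors
#'
#' Two-sided paired t-test and Pearson correlation between matched
#' per-unit accuracies of two feature sets or protocols. A
#' zero-variance difference vector is degenerate: the t-statistic is
#' undefined and `p` is reported as 1 with `degenerate = TRUE`.
#'
#' @param acc_a,acc_b Equal-length numeric vectors (length >= 3), paired
#'   per unit.
#' @return List with `mean_diff` (`mean(acc_a - acc_b)`), `t`, `df`,
#'   `p`, `r`, `degenerate`.
#' @export
compare_feature_sets <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b)) stop("paired vectors must have equal length")
  if (length(acc_a) < 3L) stop("need at least 3 paired observations")
  d <- acc_a - acc_b
  degenerate <- sd(d) == 0
  if (degenerate) {
    tt <- list(statistic = NA_real_, parameter = length(d) - 1, p.value = 1)
  } else {
    tt <- t.test(acc_a, acc_b, paired = TRUE)
  }
  r <- if (sd(acc_a) == 0 || sd(acc_b) == 0) NA_real_ else cor(acc_a, acc_b)
  list(mean_diff = mean(d), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, r = r,
       degenerate = degenerate)
}

#' Benjamini-Hochberg FDR decisions
#'
#' Step-up false-discovery-rate control: rejects the hypotheses whose
#' BH-adjusted p-value is at most `alpha`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return Logical rejection vector.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH") <= alpha
}

#' Summarise per-unit classification accuracies
#'
#' Computes the descriptive battery reported per protocol: mean, SD,
#' min, max, the t-based 95% confidence interval of the mean, the count
#' and fraction of units beating their exact-binomial better-than-random
#' threshold, and the counts above 0.75 and 0.90 accuracy.
#'
#' @param accuracies Numeric vector of per-unit accuracies.
#' @param n_test Test-set size per unit (scalar or vector), used for the
#'   per-unit [random_threshold()].
#' @param alpha Threshold confidence complement (default 0.05).
#' @param conf_level Confidence level of the CI of the mean (default 0.95).
#' @return An `evaluation_report` list.
#' @export
summarize_accuracies <- function(accuracies, n_test, alpha = 0.05,
                                 conf_level = 0.95) {
  stopifnot(length(accuracies) >= 1)
  n <- length(accuracies)
  n_test <- rep_len(n_test, n)
  m <- mean(accuracies)
  s <- if (n > 1) sd(accuracies) else 0
  half <- if (n > 1) qt(1 - (1 - conf_level) / 2, n - 1) * s / sqrt(n) else 0
  thr <- random_threshold(n_test, alpha = alpha)
  better <- sum(accuracies > thr)
  structure(
    list(n = n, mean = m, sd = s, min = min(accuracies),
         max = max(accuracies), ci = c(m - half, m + half),
         thresholds = thr, better_than_chance = better,
         better_than_chance_rel = better / n,
         above_75 = sum(accuracies > 0.75),
         above_90 = sum(accuracies > 0.90),
         accuracies = accuracies),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d units\n", x$n))
  cat(sprintf("  mean accuracy        %.3f (sd %.3f, range [%.3f, %.3f])\n",
              x$mean, x$sd, x$min, x$max))
  cat(sprintf("  95%% CI of the mean   [%.3f, %.3f]\n", x$ci[1], x$ci[2]))
  cat(sprintf("  better than chance   %d/%d (%.1f%%)\n",
              x$better_than_chance, x$n, 100 * x$better_than_chance_rel))
  cat(sprintf("  above 0.75 / 0.90    %d / %d\n", x$above_75, x$above_90))
  invisible(x)
}
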