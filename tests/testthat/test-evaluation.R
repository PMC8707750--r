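test_that("stratified folds partition 96 balanced trials as 20/19/19/19/19", {
  labels <- rep(c("internal", "external"), each = 48)
  fold <- stratified_folds(labels, k = 5, seed = 1)
  expect_equal(sort(as.integer(table(fold)), decreasing = TRUE),
               c(20L, 19L, 19L, 19L, 19L))
  # class counts within a fold differ by at most one
  tab <- table(fold, labels)
  expect_true(all(abs(tab[, 1] - tab[, 2]) <= 1))
  # folds are a partition and the assignment is seed-stable
  expect_equal(sum(table(fold)), 96)
  expect_identical(fold, stratified_folds(labels, k = 5, seed = 1))
  expect_false(identical(fold, stratified_folds(labels, k = 5, seed = 2)))
  expect_error(stratified_folds(rep(c("a", "b"), c(3, 60)), k = 5), "at least k")
})

test_that("task-independent splits enumerate the nine combinations", {
  meta <- expand.grid(participant = c("P1", "P2"),
                      task = paste0(rep(c("internal", "external"), each = 3),
                                    "_", c("num", "verb", "vis")),
                      rep = 1:4, stringsAsFactors = FALSE)
  meta$condition <- ifelse(grepl("^internal", meta$task), "internal", "external")
  splits <- task_independent_splits(meta)
  expect_length(splits, 9)
  for (s in splits) {
    # train has exactly 2 internal + 2 external tasks, none of them tested
    train_tasks <- unique(meta$task[s$train_idx])
    expect_length(train_tasks, 4)
    expect_equal(sum(grepl("^internal", train_tasks)), 2)
    expect_length(intersect(s$train_idx, s$test_idx), 0)
    expect_setequal(unique(meta$task[s$test_idx]),
                    c(s$internal_task, s$external_task))
    expect_setequal(c(s$train_idx, s$test_idx), seq_len(nrow(meta)))
  }
  expect_error(task_independent_splits(meta[meta$task != "internal_num", ]),
               "3 internal")
})

test_that("better-than-random thresholds match the exact binomial tail sum", {
  # independent oracle: direct summation of binomial point masses
  oracle <- function(n, alpha = 0.05, p0 = 0.5) {
    for (k in 0:n) {
      tail <- sum(choose(n, k:n) * p0^(k:n) * (1 - p0)^(n - (k:n)))
      if (tail <= alpha) return(k / n)
    }
    Inf
  }
  for (n in seq(10, 200, by = 5)) {
    expect_equal(random_threshold(n), oracle(n), info = n)
  }
  expect_equal(random_threshold(96), 57 / 96)
  # n = 1: even a perfect score has tail probability 0.5 > alpha, so no
  # attainable threshold exists (agrees with the oracle)
  expect_equal(random_threshold(1), oracle(1))
  expect_true(is.infinite(random_threshold(1)))
  # approaches chance level from above as n grows
  thr <- random_threshold(c(10, 50, 100, 500, 5000))
  expect_true(all(diff(thr) < 0))
  expect_lt(thr[5] - 0.5, 0.02)
  expect_error(random_threshold(10, alpha = 1.5), "alpha")
})

test_that("paired comparisons match the direct formulas", {
  a <- c(0.62, 0.71, 0.55, 0.68, 0.74)
  b <- a + c(0.03, 0.05, 0.01, 0.04, 0.02)
  res <- compare_feature_sets(b, a)
  d <- b - a
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * stats::pt(-abs(t_hand), 4), tolerance = 1e-12)
  expect_false(res$degenerate)

  same <- compare_feature_sets(a, a)
  expect_true(same$degenerate)
  expect_equal(same$p, 1)
  expect_equal(same$mean_diff, 0)

  lin <- compare_feature_sets(a, 2 * a + 1)
  expect_equal(lin$r, 1)
  expect_error(compare_feature_sets(a, a[1:3]), "equal length")
  expect_error(compare_feature_sets(a[1:2], a[1:2]), "at least 3")
})

test_that("BH-FDR matches the brute-force step-up definition", {
  stepup <- function(p, alpha) {
    m <- length(p)
    ord <- order(p)
    k <- 0
    for (i in seq_len(m)) if (p[ord[i]] <= i / m * alpha) k <- i
    rej <- logical(m)
    if (k > 0) rej[ord[seq_len(k)]] <- TRUE
    rej
  }
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.2)),
               c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(bh_fdr(rep(1, 6)), rep(FALSE, 6))
  expect_equal(bh_fdr(0.04), TRUE)
  set.seed(8)
  for (rep in 1:25) {
    p <- runif(sample(3:30, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), stepup(p, 0.05))
  }
  expect_error(bh_fdr(c(0.2, 1.4)), "0, 1")
})

test_that("accuracy summaries reproduce the closed-form CI and counts", {
  rep1 <- summarize_accuracies(rep(1, 7), n_test = 24)
  expect_equal(rep1$mean, 1)
  expect_equal(rep1$sd, 0)
  expect_equal(rep1$better_than_chance, 7)
  expect_equal(rep1$above_75, 7)
  expect_equal(rep1$above_90, 7)

  acc <- c(0.55, 0.62, 0.71, 0.49, 0.80)
  rep2 <- summarize_accuracies(acc, n_test = 96)
  half <- qt(0.975, 4) * sd(acc) / sqrt(5)
  expect_equal(rep2$ci, c(mean(acc) - half, mean(acc) + half))
  expect_true(rep2$ci[1] <= rep2$mean && rep2$mean <= rep2$ci[2])
  expect_equal(rep2$better_than_chance_rel * rep2$n, rep2$better_than_chance)
  expect_equal(rep2$better_than_chance, sum(acc > 57 / 96))
})
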