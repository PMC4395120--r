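# Exhaustive triplet resampling and paired t-tests.

test_that("triplet enumeration matches combinatorics", {
  expect_equal(nrow(enumerate_triplets(1:25)), 2300)
  expect_equal(nrow(enumerate_triplets(1:4)), 4)
  # brute-force count for n = 6
  ids <- c(4, 1, 6, 3, 2, 5)
  tr <- enumerate_triplets(ids)
  expect_equal(nrow(tr), 20)
  expect_false(any(duplicated(apply(tr, 1, paste, collapse = "-"))))
  expect_identical(tr, enumerate_triplets(sort(ids)))  # order-invariant
  expect_true(all(tr[, 1] < tr[, 2] & tr[, 2] < tr[, 3]))
  expect_error(enumerate_triplets(1:2), class = "archepsy_invalid_argument")
})

test_that("group evaluation makes 12 stratified predictions", {
  set.seed(20)
  lab <- rep(c("a", "b", "c", "d"), 3)
  x <- matrix(rnorm(12 * 5), 12) + 4 * matrix(as.numeric(factor(lab)), 12, 5)
  r <- evaluate_group(x, lab, seed = 1)
  expect_length(r$predicted, 12)
  expect_equal(r$accuracy, 1.0)
  # each fold holds exactly one sample per class
  for (f in 1:3)
    expect_equal(sort(lab[r$fold == f]), c("a", "b", "c", "d"))
  expect_error(evaluate_group(x[1:10, ], lab[1:10]),
               class = "archepsy_invalid_design")
})

test_that("group accuracies live on the k/12 grid and are chance-level under the null", {
  set.seed(21)
  lab <- rep(c("a", "b", "c", "d"), 3)
  x <- matrix(rnorm(12 * 6), 12)
  accs <- vapply(1:400, function(i)
    evaluate_group(x, sample(lab), seed = i)$accuracy, numeric(1))
  expect_true(all(abs(accs * 12 - round(accs * 12)) < 1e-9))
  # mean of 400 label shuffles within a generous binomial CI of 0.25
  half <- qnorm(0.995) * sqrt(0.25 * 0.75 / (400 * 12 / 4))
  expect_lt(abs(mean(accs) - 0.25), half + 0.02)
})

test_that("paired t statistics match the closed form", {
  r <- paired_t(c(1, 2, 3), c(0, 0, 0))
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(round(r$t, 4), 3.4641)
  expect_equal(r$df, 2)

  a <- c(0.3, 0.5, 0.4, 0.6)
  z <- paired_t(a, a)
  expect_equal(z$t, 0); expect_equal(z$p, 1)

  expect_error(paired_t(c(1, 2), c(0, 1)),
               class = "archepsy_degenerate_variance")
  expect_error(paired_t(1, 2), class = "archepsy_invalid_argument")

  # constant comparison: one-sample test against the chance level
  r2 <- paired_t(a, 0.25, "vs chance")
  d <- a - 0.25
  expect_equal(r2$t, mean(d) / (sd(d) / 2), tolerance = 1e-12)
})

test_that("paired t agrees with an independent loop reference to 1e-9", {
  ref_t <- function(a, b) {
    d <- a - b; n <- length(d)
    m <- sum(d) / n
    s <- sqrt(sum((d - m)^2) / (n - 1))
    tt <- m / (s / sqrt(n))
    list(t = tt, df = n - 1, p = 2 * stats::pt(-abs(tt), n - 1))
  }
  set.seed(22)
  for (i in 1:20) {
    n <- sample(5:400, 1)
    a <- runif(n); b <- runif(n)
    ours <- paired_t(a, b)
    ref <- ref_t(a, b)
    expect_equal(ours$t, ref$t, tolerance = 1e-9)
    expect_equal(ours$p, ref$p, tolerance = 1e-9)
    expect_equal(ours$df, ref$df)
  }
})

test_that("df equals the number of triplets minus one", {
  acc <- runif(2300, 0.2, 0.6)
  r <- paired_t(acc, 0.25)
  expect_equal(r$df, 2299)
})

synthetic_cohort_tables <- function(n_subjects, sep, seed) {
  # feature + SAM tables with controllable class separation, bypassing the
  # signal pipeline for speed
  set.seed(seed)
  classes <- study_classes()
  subj <- rep(seq_len(n_subjects), each = 8)
  cls <- rep(classes, n_subjects)
  x <- matrix(rnorm(length(cls) * 12), ncol = 12) +
    sep * matrix(as.numeric(factor(cls)), length(cls), 12)
  features <- cbind(data.frame(subject = subj, class = cls),
                    as.data.frame(x))
  sam <- data.frame(subject = subj, class = cls,
                    arousal = pmin(9, pmax(1, round(rnorm(length(cls), 5, 2)))),
                    valence = pmin(9, pmax(1, round(rnorm(length(cls), 5, 2)))),
                    dominance = pmin(9, pmax(1, round(rnorm(length(cls), 5, 2)))))
  list(features = features, sam = sam)
}

test_that("run_comparisons produces the five study tests over all triplets", {
  tabs <- synthetic_cohort_tables(n_subjects = 6, sep = 1.2, seed = 23)
  res <- run_comparisons(tabs$features, tabs$sam, n_components = 5, seed = 1)
  expect_equal(nrow(res$comparisons), 5)
  expect_true(all(res$comparisons$df == choose(6, 3) - 1))
  expect_equal(nrow(res$groups), 20)
  expect_equal(nrow(res$group_summary), 4)
  # physiological features are strongly separable here; SAM is pure noise
  cm <- res$comparisons
  expect_lt(cm$p[cm$comparison == "physiological archetypes vs chance"], 0.001)
  expect_lt(cm$p[cm$comparison == "physiological emotions vs chance"], 0.001)
  expect_gt(cm$t[cm$comparison == "physiological vs SAM (archetypes)"], 0)
  expect_equal(res$group_summary$se,
               res$group_summary$sd / sqrt(res$group_summary$n_groups))
})

test_that("mean group accuracy increases with class separation", {
  means <- vapply(c(0, 1.5, 3), function(sep) {
    tabs <- synthetic_cohort_tables(n_subjects = 5, sep = sep, seed = 24)
    f <- tabs$features[tabs$features$class %in% task_classes("archetypes"), ]
    fx <- as.matrix(f[, -(1:2)])
    mean(group_accuracies(fx, f$class, f$subject, seed = 2)$accuracy)
  }, numeric(1))
  expect_true(all(diff(means) > -0.02))
  expect_gt(means[3], means[1] + 0.2)
})

test_that("disjoint-partition diagnostic uses independent groups", {
  tabs <- synthetic_cohort_tables(n_subjects = 9, sep = 2.5, seed = 25)
  f <- tabs$features[tabs$features$class %in% task_classes("archetypes"), ]
  fx <- as.matrix(f[, -(1:2)])
  d <- disjoint_partition_t(fx, f$class, f$subject, seed = 3)
  trip <- attr(d, "triplets")
  expect_equal(dim(trip), c(3, 3))
  expect_false(any(duplicated(as.vector(trip))))
  expect_equal(d$df, 2)
})
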