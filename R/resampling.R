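# Exhaustive triplet resampling: every three-subject subset of the cohort
# yields a small 12-sample (3 subjects x 4 classes) classification problem
# evaluated with stratified 3-fold kNN, and the resulting per-group accuracy
# vectors feed paired t-tests against chance and between data modalities.
# Overlapping triplets share subjects, so the paired t-tests inherit the
# dependence of the original procedure; a disjoint-partition diagnostic is
# provided alongside.

#' Enumerate all three-subject subsets
#'
#' @param subjects vector of distinct subject ids (n >= 3).
#' @return matrix with `choose(n, 3)` rows and 3 columns, rows in
#'   lexicographic order of the sorted ids.
#' @examples
#' nrow(enumerate_triplets(1:25))  # 2300
#' @export
enumerate_triplets <- function(subjects) {
  subjects <- sort(unique(subjects))
  if (length(subjects) < 3) stop_invalid_argument("need at least 3 subjects")
  t(combn(subjects, 3))
}

# stratified fold assignment: each fold receives exactly one sample of each
# class; deterministic given the seed
stratified_folds <- function(labels, folds, seed) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cc in sort(unique(labels))) {
      idx <- which(labels == cc)
      if (length(idx) != folds)
        stop_invalid_design(sprintf(
          "class '%s' has %d samples; need exactly %d for %d stratified folds",
          cc, length(idx), folds, folds))
      fold[idx] <- sample(folds)
    }
  })
  fold
}

#' Evaluate one subject triplet
#'
#' Stratified k-fold cross-validation (each fold holds one sample per class)
#' with a kNN classifier on the group's rows.
#'
#' @param x numeric matrix of the group's feature rows
#'   (`3 subjects x n_classes`).
#' @param labels class label per row; each class must appear exactly
#'   `folds` times.
#' @param k kNN neighbors (default 3; training folds are small).
#' @param folds number of folds (default 3).
#' @param seed seed for the fold assignment.
#' @return list with `accuracy`, `predicted`, `fold`.
#' @export
evaluate_group <- function(x, labels, k = 3, folds = 3, seed = 1) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) stop_invalid_argument("labels must match rows")
  fold <- stratified_folds(labels, folds, seed)
  pred <- character(nrow(x))
  for (f in seq_len(folds)) {
    te <- fold == f
    pred[te] <- knn_predict(x[!te, , drop = FALSE], labels[!te],
                            x[te, , drop = FALSE], k)
  }
  list(accuracy = mean(pred == labels), predicted = pred, fold = fold)
}

#' Per-triplet accuracies over an exhaustive enumeration
#'
#' @param x feature matrix (rows = epochs) for one task.
#' @param labels class label per row.
#' @param subjects subject id per row.
#' @param triplets matrix from [enumerate_triplets()]; default enumerates
#'   all subsets of the subjects present.
#' @param k,folds passed to [evaluate_group()].
#' @param seed root seed; each group uses a derived substream.
#' @return data.frame: one row per triplet with the three subject ids and
#'   the group `accuracy`.
#' @export
group_accuracies <- function(x, labels, subjects, triplets = NULL, k = 3,
                             folds = 3, seed = 1) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (is.null(triplets)) triplets <- enumerate_triplets(subjects)
  acc <- numeric(nrow(triplets))
  for (g in seq_len(nrow(triplets))) {
    rows <- subjects %in% triplets[g, ]
    acc[g] <- evaluate_group(x[rows, , drop = FALSE], labels[rows], k = k,
                             folds = folds,
                             seed = substream_seed(seed, "group", g))$accuracy
  }
  data.frame(s1 = triplets[, 1], s2 = triplets[, 2], s3 = triplets[, 3],
             accuracy = acc)
}

#' Paired t-test on accuracy vectors
#'
#' Two-sided paired t-test; `b` may be a single constant (e.g. the 0.25
#' chance level of a balanced four-class task), in which case the test is
#' the one-sample t-test of `a - b`. If every difference is exactly zero
#' the degenerate `t = 0, p = 1` result is returned; constant non-zero
#' differences raise a degenerate-variance error.
#'
#' @param a numeric vector of accuracies.
#' @param b numeric vector of equal length, or a single constant.
#' @param comparison label carried on the result.
#' @return object of class `archepsy_ttest`: `t`, `df` (`n - 1`), `p`
#'   (two-sided), `mean_diff`, `n`.
#' @examples
#' paired_t(c(1, 2, 3), 0)  # t = sqrt(12), df = 2
#' @export
paired_t <- function(a, b, comparison = "") {
  if (length(b) == 1) b <- rep(b, length(a))
  if (length(a) != length(b)) stop_invalid_argument("lengths must match")
  if (length(a) < 2) stop_invalid_argument("need at least 2 pairs")
  d <- a - b
  if (all(d == 0)) {
    res <- list(comparison = comparison, t = 0, df = length(d) - 1, p = 1,
                mean_diff = 0, n = length(d))
    return(structure(res, class = "archepsy_ttest"))
  }
  if (sd(d) == 0)
    stop_degenerate_variance("zero-variance non-zero differences")
  tt <- t.test(d, mu = 0)
  structure(
    list(comparison = comparison, t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value,
         mean_diff = mean(d), n = length(d)),
    class = "archepsy_ttest")
}

#' @export
print.archepsy_ttest <- function(x, ...) {
  cat(sprintf("<paired t> %s: t(%d) = %.3f, p = %.3g, mean diff = %.4f\n",
              x$comparison, x$df, x$t, x$p, x$mean_diff))
  invisible(x)
}

#' Diagnostic t-test on a disjoint subject partition
#'
#' The exhaustive triplet enumeration reuses subjects across groups, which
#' violates the independence assumption of the paired t-test. This
#' diagnostic partitions the subjects into `floor(n/3)` disjoint triplets
#' (seeded random partition) and runs the same test on those independent
#' groups.
#'
#' @inheritParams group_accuracies
#' @param b comparison vector/constant aligned with the partition groups.
#' @param seed seed for the partition and fold assignments.
#' @return an `archepsy_ttest` plus attribute `triplets`.
#' @export
disjoint_partition_t <- function(x, labels, subjects, b = 0.25, k = 3,
                                 folds = 3, seed = 1,
                                 comparison = "disjoint vs chance") {
  ids <- sort(unique(subjects))
  ng <- floor(length(ids) / 3)
  if (ng < 2) return(NULL)  # diagnostic needs at least two disjoint groups
  perm <- with_seed(substream_seed(seed, "partition"), sample(ids))
  trip <- matrix(perm[seq_len(3 * ng)], ncol = 3, byrow = TRUE)
  trip <- t(apply(trip, 1, sort))
  acc <- group_accuracies(x, labels, subjects, triplets = trip, k = k,
                          folds = folds, seed = seed)
  out <- tryCatch(paired_t(acc$accuracy, b, comparison),
                  archepsy_degenerate_variance = function(e)
                    structure(list(comparison = comparison, t = NA_real_,
                                   df = nrow(trip) - 1, p = NA_real_,
                                   mean_diff = mean(acc$accuracy - b),
                                   n = nrow(trip)),
                              class = "archepsy_ttest"))
  attr(out, "triplets") <- trip
  out
}

#' Run the study's accuracy comparisons
#'
#' Evaluates every subject triplet for both four-class tasks (archetypes,
#' explicit emotions) and both data modalities (physiological features,
#' SAM reports), then runs the five paired t-tests of the analysis: each
#' task against the 25% chance level (physiological), archetypes versus
#' emotions (physiological), physiological versus SAM for archetypes, and
#' SAM versus physiological for emotions.
#'
#' Physiological group models use the pooled standardized PCA scores
#' (`n_components` components fitted on all rows); SAM group models use the
#' raw three ratings. Group models are stratified 3-fold kNN.
#'
#' @param features cohort feature data.frame
#'   ([cohort_feature_matrix()] layout: `subject`, `class`, features).
#' @param sam cohort SAM data.frame ([cohort_sam_table()] layout).
#' @param n_components pooled PCA components for the physiological
#'   modality (default 25).
#' @param k group-level kNN neighbors (default 3).
#' @param folds folds per group (default 3).
#' @param seed root seed for fold assignments.
#' @param chance chance-level accuracy (default 0.25).
#' @return list with `comparisons` (data.frame of the five tests),
#'   `group_summary` (mean/sd/se of group accuracy per task x modality),
#'   `groups` (per-triplet accuracies), and `disjoint` (diagnostic tests).
#' @export
run_comparisons <- function(features, sam, n_components = 25, k = 3,
                            folds = 3, seed = 1, chance = 0.25) {
  stopifnot(all(c("subject", "class") %in% names(features)))
  fx <- as.matrix(features[, setdiff(names(features), c("subject", "class"))])
  red <- reduce_dimensions(fx, min(n_components, min(nrow(fx) - 1, ncol(fx))))
  scores <- red$scores
  sx <- as.matrix(sam[, c("arousal", "valence", "dominance")])

  acc <- list()
  trip <- enumerate_triplets(features$subject)
  for (task in c("archetypes", "emotions")) {
    cls <- task_classes(task)
    frows <- features$class %in% cls
    srows <- sam$class %in% cls
    acc[[paste0("phys_", task)]] <- group_accuracies(
      scores[frows, , drop = FALSE], features$class[frows],
      features$subject[frows], trip, k = k, folds = folds,
      seed = substream_seed(seed, "phys", task))$accuracy
    acc[[paste0("sam_", task)]] <- group_accuracies(
      sx[srows, , drop = FALSE], sam$class[srows], sam$subject[srows],
      trip, k = k, folds = folds,
      seed = substream_seed(seed, "sam", task))$accuracy
  }

  tests <- list(
    paired_t(acc$phys_archetypes, chance, "physiological archetypes vs chance"),
    paired_t(acc$phys_emotions, chance, "physiological emotions vs chance"),
    paired_t(acc$phys_archetypes, acc$phys_emotions,
             "archetypes vs emotions (physiological)"),
    paired_t(acc$phys_archetypes, acc$sam_archetypes,
             "physiological vs SAM (archetypes)"),
    paired_t(acc$sam_emotions, acc$phys_emotions,
             "SAM vs physiological (emotions)"))
  comparisons <- do.call(rbind, lapply(tests, function(tt)
    data.frame(comparison = tt$comparison, t = tt$t, df = tt$df, p = tt$p,
               mean_diff = tt$mean_diff)))
  group_summary <- do.call(rbind, lapply(names(acc), function(nm)
    data.frame(condition = nm, mean = mean(acc[[nm]]), sd = sd(acc[[nm]]),
               se = sd(acc[[nm]]) / sqrt(length(acc[[nm]])),
               n_groups = length(acc[[nm]]))))
  disjoint <- lapply(c("archetypes", "emotions"), function(task) {
    cls <- task_classes(task)
    frows <- features$class %in% cls
    disjoint_partition_t(scores[frows, , drop = FALSE],
                         features$class[frows], features$subject[frows],
                         b = chance, k = k, folds = folds,
                         seed = substream_seed(seed, "disjoint", task),
                         comparison = paste("disjoint", task, "vs chance"))
  })
  names(disjoint) <- c("archetypes", "emotions")
  groups <- data.frame(s1 = trip[, 1], s2 = trip[, 2], s3 = trip[, 3],
                       as.data.frame(acc))
  list(comparisons = comparisons, group_summary = group_summary,
       groups = groups, disjoint = disjoint)
}
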