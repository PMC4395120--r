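# End-to-end orchestration: simulate -> process -> featurize -> classify ->
# compare as one seeded, logged run. Sessions are generated and processed
# one subject at a time so the raw traces of a full cohort are never held in
# memory simultaneously. When an output directory is given, results are
# written as plain tabular files plus a JSON manifest keyed by a hash of the
# configuration; re-running with an identical configuration reloads the
# cached results instead of recomputing.

#' Build and validate a study configuration
#'
#' @param n_subjects,classes,stimulus_duration,baseline_duration,effect_size
#'   cohort settings (see [cohort_config()]).
#' @param seed root seed for the whole run.
#' @param n_components principal components kept before classification.
#' @param k_archetypes,k_emotions kNN neighborhood sizes for the two
#'   four-class LOOCV tasks.
#' @param leakage `"strict"` (refit standardization + PCA per fold) or
#'   `"paper"` (single pooled fit).
#' @param pca_scope `"pooled"` (fit PCA on all eight classes, used in paper
#'   leakage mode) or `"task"` (fit per four-class task).
#' @param group_k,group_folds kNN neighbors and folds for the triplet
#'   resampling stage.
#' @return validated list of class `study_config`.
#' @export
study_config <- function(n_subjects = 25, classes = study_classes(),
                         stimulus_duration = 300, baseline_duration = 40,
                         effect_size = 1, seed = 1, n_components = 25,
                         k_archetypes = 20, k_emotions = 25,
                         leakage = c("strict", "paper"),
                         pca_scope = c("pooled", "task"),
                         group_k = 3, group_folds = 3) {
  leakage <- match.arg(leakage)
  pca_scope <- match.arg(pca_scope)
  cohort <- cohort_config(n_subjects, classes, stimulus_duration,
                          baseline_duration, effect_size, seed)
  for (nm in c("n_components", "k_archetypes", "k_emotions", "group_k",
               "group_folds")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v))
      stop_config(sprintf("`%s` must be a positive integer", nm))
  }
  n_rows_task <- n_subjects * 4
  if (n_components > min(n_rows_task - 2, 158))
    stop_config("`n_components` too large for the task fold sizes")
  if (k_archetypes >= n_rows_task - 1 || k_emotions >= n_rows_task - 1)
    stop_config("kNN `k` must be smaller than task rows - 1")
  structure(
    list(cohort = cohort, seed = as.integer(seed),
         n_components = as.integer(n_components),
         k_archetypes = as.integer(k_archetypes),
         k_emotions = as.integer(k_emotions),
         leakage = leakage, pca_scope = pca_scope,
         group_k = as.integer(group_k),
         group_folds = as.integer(group_folds)),
    class = "study_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full study pipeline
#'
#' Simulates a cohort, processes every epoch, assembles the feature matrix,
#' evaluates kNN / naive Bayes / LDA under leave-one-out cross-validation on
#' the physiological features for both four-class tasks, evaluates LDA on
#' the SAM reports, and runs the exhaustive triplet-resampling comparisons.
#'
#' @param config a [study_config()].
#' @param out_dir optional output directory; when given, all tables are
#'   written there and an identical re-run reloads the cached results.
#' @param verbose print stage progress.
#' @return object of class `archepsy_study`: `features`, `sam`,
#'   `cv` (list of `archepsy_cv`, physiological: 3 classifiers x 2 tasks;
#'   SAM: LDA x 2 tasks), `comparisons` (from [run_comparisons()]),
#'   `config`, `config_hash`, `log` (stage records incl. the design
#'   defaults in force), `timings`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  hash <- config_hash(config)
  if (!is.null(out_dir) && file.exists(file.path(out_dir, "manifest.json"))) {
    man <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
    if (identical(man$config_hash, hash)) {
      if (verbose) message("configuration unchanged; reloading cached run")
      return(read_study(out_dir))
    }
  }
  log <- list()
  timings <- c()
  note <- function(stage, msg) {
    log[[length(log) + 1]] <<- sprintf("[%s] %s", stage, msg)
    if (verbose) message(sprintf("[%s] %s", stage, msg))
  }
  tic <- function() proc.time()[["elapsed"]]
  note("config", sprintf("seed=%d hash=%s", config$seed, hash))
  note("config", sprintf(
    "defaults: eq1 scope=per-subject/per-signal, leakage=%s, pca_scope=%s, n_components=%d, k=(%d,%d), group kNN k=%d folds=%d",
    config$leakage, config$pca_scope, config$n_components,
    config$k_archetypes, config$k_emotions, config$group_k,
    config$group_folds))

  t0 <- tic()
  cc <- config$cohort
  feats <- list(); sams <- list()
  for (sid in seq_len(cc$n_subjects)) {
    session <- generate_session(cc, subject_id = sid)
    feats[[sid]] <- extract_session_features(session)
    sams[[sid]] <- data.frame(subject = sid, class = rownames(session$sam),
                              arousal = session$sam[, "arousal"],
                              valence = session$sam[, "valence"],
                              dominance = session$sam[, "dominance"],
                              row.names = NULL)
  }
  features <- do.call(rbind, feats)
  sam <- do.call(rbind, sams)
  timings["simulate_featurize"] <- tic() - t0
  note("featurize", sprintf("feature matrix %d x %d", nrow(features),
                            ncol(features) - 2))

  t0 <- tic()
  fx <- as.matrix(features[, setdiff(names(features), c("subject", "class"))])
  cv <- list()
  for (task in c("archetypes", "emotions")) {
    cls <- task_classes(task)
    rows <- features$class %in% cls
    labs <- features$class[rows]
    kk <- if (task == "archetypes") config$k_archetypes else config$k_emotions
    xm <- fx[rows, , drop = FALSE]
    if (config$leakage == "paper" && config$pca_scope == "pooled") {
      pooled <- reduce_dimensions(fx, config$n_components)
      cv_in <- pooled$scores[rows, , drop = FALSE]
      nc <- NULL
    } else {
      cv_in <- xm
      nc <- config$n_components
    }
    for (clf in c("knn", "naive_bayes", "lda")) {
      cv[[paste(task, clf, sep = "_")]] <- loocv_classify(
        cv_in, labs, classifier = clf, k = kk, n_components = nc,
        leakage = config$leakage)
    }
    srows <- sam$class %in% cls
    cv[[paste(task, "sam_lda", sep = "_")]] <- sam_classify(
      as.matrix(sam[srows, c("arousal", "valence", "dominance")]),
      sam$class[srows])
  }
  timings["classify"] <- tic() - t0
  note("classify", paste(vapply(names(cv), function(nm)
    sprintf("%s=%.1f%%", nm, 100 * cv[[nm]]$accuracy), character(1)),
    collapse = " "))

  t0 <- tic()
  comparisons <- run_comparisons(features, sam,
                                 n_components = config$n_components,
                                 k = config$group_k,
                                 folds = config$group_folds,
                                 seed = substream_seed(config$seed, "compare"))
  timings["compare"] <- tic() - t0
  note("compare", sprintf("%d triplets per condition",
                          nrow(comparisons$groups)))

  study <- structure(
    list(features = features, sam = sam, cv = cv, comparisons = comparisons,
         config = config, config_hash = hash, log = unlist(log),
         timings = timings),
    class = "archepsy_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' @export
print.archepsy_study <- function(x, ...) {
  cat(sprintf("<archepsy_study> %d subjects x %d classes, seed %d\n",
              x$config$cohort$n_subjects, length(x$config$cohort$classes),
              x$config$seed))
  cat("LOOCV accuracy:\n")
  for (nm in names(x$cv))
    cat(sprintf("  %-22s %.1f%%\n", nm, 100 * x$cv[[nm]]$accuracy))
  cat("Comparisons:\n")
  cm <- x$comparisons$comparisons
  for (i in seq_len(nrow(cm)))
    cat(sprintf("  %-40s t(%d) = %7.3f, p = %.3g\n", cm$comparison[i],
                cm$df[i], cm$t[i], cm$p[i]))
  invisible(x)
}

#' @export
summary.archepsy_study <- function(object, ...) {
  gs <- object$comparisons$group_summary
  cat("Triplet-group accuracy (mean +/- sd, se):\n")
  for (i in seq_len(nrow(gs)))
    cat(sprintf("  %-18s %.2f%% +/- %.2f (se %.4f), %d groups\n",
                gs$condition[i], 100 * gs$mean[i], 100 * gs$sd[i], gs$se[i],
                gs$n_groups[i]))
  print(object)
  invisible(object)
}

#' Persist / reload a study run
#'
#' Writes the feature matrix, SAM table, per-classifier confusion matrices
#' and predictions, group accuracies, the comparison table and a JSON
#' manifest (config, seed, config hash, timings, log) as plain text files.
#'
#' @param study an `archepsy_study`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_matrix(study$features, file.path(dir, "features.tsv"))
  write.table(study$sam, file.path(dir, "sam.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  for (nm in names(study$cv)) {
    cvr <- study$cv[[nm]]
    write.table(as.data.frame.matrix(cvr$confusion),
                file.path(dir, sprintf("confusion_%s.tsv", nm)), sep = "\t",
                quote = FALSE)
    write.table(data.frame(actual = cvr$actual, predicted = cvr$predicted),
                file.path(dir, sprintf("predictions_%s.tsv", nm)),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write.table(study$comparisons$comparisons,
              file.path(dir, "comparisons.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(study$comparisons$group_summary,
              file.path(dir, "group_summary.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(study$comparisons$groups, file.path(dir, "groups.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(study$log, file.path(dir, "log.txt"))
  accs <- lapply(study$cv, function(z) z$accuracy)
  manifest <- list(config = unclass(study$config),
                   config_hash = study$config_hash,
                   seed = study$config$seed,
                   accuracies = accs,
                   timings = as.list(study$timings))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(dir)
}

#' @rdname write_study
#' @param dir directory written by [write_study()].
#' @return `read_study`: an `archepsy_study` restored from disk (confusion
#'   matrices and accuracies recomputed from the stored predictions).
#' @export
read_study <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  features <- read_feature_matrix(file.path(dir, "features.tsv"))
  sam <- read.table(file.path(dir, "sam.tsv"), header = TRUE, sep = "\t")
  cv <- list()
  for (f in list.files(dir, pattern = "^predictions_")) {
    nm <- sub("^predictions_(.*)\\.tsv$", "\\1", f)
    pp <- read.table(file.path(dir, f), header = TRUE, sep = "\t")
    clf <- sub("^(archetypes|emotions)_", "", nm)
    cv[[nm]] <- cv_result(clf, pp$actual, pp$predicted)
  }
  comparisons <- list(
    comparisons = read.table(file.path(dir, "comparisons.tsv"),
                             header = TRUE, sep = "\t"),
    group_summary = read.table(file.path(dir, "group_summary.tsv"),
                               header = TRUE, sep = "\t"),
    groups = read.table(file.path(dir, "groups.tsv"), header = TRUE,
                        sep = "\t"))
  cfgl <- man$config
  config <- study_config(
    n_subjects = cfgl$cohort$n_subjects,
    classes = unlist(cfgl$cohort$classes),
    stimulus_duration = cfgl$cohort$stimulus_duration,
    baseline_duration = cfgl$cohort$baseline_duration,
    effect_size = cfgl$cohort$effect_size, seed = cfgl$seed,
    n_components = cfgl$n_components, k_archetypes = cfgl$k_archetypes,
    k_emotions = cfgl$k_emotions, leakage = cfgl$leakage,
    pca_scope = cfgl$pca_scope, group_k = cfgl$group_k,
    group_folds = cfgl$group_folds)
  structure(
    list(features = features, sam = sam, cv = cv, comparisons = comparisons,
         config = config, config_hash = man$config_hash,
         log = readLines(file.path(dir, "log.txt")),
         timings = unlist(man$timings)),
    class = "archepsy_study")
}
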