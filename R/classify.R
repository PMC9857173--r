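# Screening-classifier evaluation: three feature sets (30 geometric
# measurements, 30 + CVI, 38 kernel principal components of the phonetic
# set), three classifiers (Random Forest, discrete AdaBoost, Gaussian Naive
# Bayes), stratified k-fold cross-validation with predictions pooled over
# folds, and a better-than-chance comparison against a fixed accuracy bar.

CHANCE_THRESHOLD <- 0.646  # accuracy a classifier must strictly exceed to beat random guessing

#' Construct a labeled feature table
#'
#' @param X Numeric matrix, rows = subjects.
#' @param labels Factor or character, `"control"` / `"positive"`.
#' @param name Feature-set name (`"geometric30"`, `"geometric_cvi31"`,
#'   `"phonetic38"`, or any descriptive label for intermediate stages).
#' @param subject_ids Subject identifiers; default rownames of `X`.
#' @return A `feature_table` object.
#' @export
feature_table <- function(X, labels, name, subject_ids = rownames(X)) {
  X <- as.matrix(X)
  labels <- factor(as.character(labels), levels = c("control", "positive"))
  if (anyNA(labels))
    stop_idscreen("idscreen_contract_error",
                  "labels must be 'control' or 'positive'")
  if (length(labels) != nrow(X))
    stop_idscreen("idscreen_contract_error",
                  "%d labels for %d rows", length(labels), nrow(X))
  if (!all(is.finite(X)))
    stop_idscreen("idscreen_contract_error",
                  "feature table '%s' contains missing values", name)
  expected <- c(geometric30 = 30L, geometric_cvi31 = 31L, phonetic38 = 38L)
  if (name %in% names(expected) && ncol(X) != expected[[name]])
    stop_idscreen("idscreen_schema_error",
                  "feature set '%s' must have %d columns, got %d",
                  name, expected[[name]], ncol(X))
  structure(list(X = X, labels = labels, name = name,
                 subject_ids = subject_ids %||% as.character(seq_len(nrow(X)))),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> '%s': %d subjects x %d features (%d positive / %d control)\n",
              x$name, nrow(x$X), ncol(x$X),
              sum(x$labels == "positive"), sum(x$labels == "control")))
  invisible(x)
}

#' Assemble the three evaluation feature tables
#'
#' `geometric30` is the 30 geometric measurements; `geometric_cvi31` appends
#' the CVI as a 31st column; `phonetic38` is the reduced phonetic matrix.
#' All three share the subject order of `labels`.
#'
#' @param measurements Data frame `subject_id` + F01..F30
#'   (see [compute_features_cohort()]).
#' @param cvi Data frame `subject_id`, `cvi` (see [cvi_cohort()]).
#' @param phonetic_reduced Numeric matrix (rownames = subject ids), 38 columns.
#' @param labels Data frame `subject_id`, `group`.
#' @return Named list of three [feature_table()] objects.
#' @export
assemble_feature_tables <- function(measurements, cvi, phonetic_reduced, labels) {
  ids <- labels$subject_id
  check_ids <- function(have, what) {
    orphan <- setdiff(ids, have)
    extra <- setdiff(have, ids)
    if (length(orphan) || length(extra))
      stop_idscreen("idscreen_contract_error",
                    "subject id mismatch in %s%s%s", what,
                    if (length(orphan)) paste0("; missing: ", paste(orphan, collapse = ", ")) else "",
                    if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")) else "")
  }
  check_ids(measurements$subject_id, "measurements")
  check_ids(cvi$subject_id, "cvi")
  check_ids(rownames(phonetic_reduced), "phonetic matrix")

  fcols <- sprintf("F%02d", 1:30)
  geo <- as.matrix(measurements[match(ids, measurements$subject_id), fcols])
  rownames(geo) <- ids
  cvi_col <- cvi$cvi[match(ids, cvi$subject_id)]
  geo_cvi <- cbind(geo, CVI = cvi_col)
  phon <- phonetic_reduced[match(ids, rownames(phonetic_reduced)), , drop = FALSE]
  phon_name <- paste0("phonetic", ncol(phon))
  tabs <- list(feature_table(geo, labels$group, "geometric30", ids),
               feature_table(geo_cvi, labels$group, "geometric_cvi31", ids),
               feature_table(phon, labels$group, phon_name, ids))
  names(tabs) <- c("geometric30", "geometric_cvi31", phon_name)
  tabs
}

#' Stratified fold assignment
#'
#' Shuffles each class separately (under `seed`) and deals its members
#' round-robin across folds, so every fold holds both classes in near-cohort
#' proportion.
#'
#' @param labels Factor of class labels.
#' @param k Number of folds.
#' @param seed Integer seed (the caller's RNG stream is left untouched).
#' @return Integer vector of fold ids in 1..k.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 20230116L) {
  labels <- as.factor(labels)
  counts <- table(labels)
  small <- names(counts)[counts < k]
  if (length(small))
    stop_idscreen("idscreen_stratification_error",
                  "class '%s' has %d member(s), fewer than %d folds: a fold would lack the class",
                  small[1], counts[small[1]], k)
  fold <- integer(length(labels))
  with_local_seed(seed, {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Classification metrics from pooled predictions
#'
#' Accuracy plus precision/recall/F1 under the configured averaging:
#' `"weighted"` (per-class metrics weighted by true-class support, default),
#' `"macro"` (unweighted class mean), or `"positive"` (positive class only).
#' Undefined per-class ratios (no predictions or no members of a class) count
#' as 0.
#'
#' @param truth,pred Factors over the same levels.
#' @param averaging Averaging convention.
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(truth, pred,
                                   averaging = c("weighted", "macro", "positive")) {
  averaging <- match.arg(averaging)
  truth <- as.factor(truth)
  pred <- factor(as.character(pred), levels = levels(truth))
  cm <- table(truth = truth, pred = pred)
  tp <- diag(cm)
  prec_c <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec_c  <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1_c   <- ifelse(prec_c + rec_c > 0, 2 * prec_c * rec_c / (prec_c + rec_c), 0)
  wts <- switch(averaging,
    weighted = rowSums(cm) / sum(cm),
    macro    = rep(1 / nrow(cm), nrow(cm)),
    positive = as.numeric(levels(truth) == "positive"))
  c(accuracy = sum(tp) / sum(cm),
    precision = sum(wts * prec_c), recall = sum(wts * rec_c),
    f1 = sum(wts * f1_c))
}

.fit_classifier <- function(name, x, y) {
  # a training fold with no varying predictor carries no information; fall
  # back to the majority class (randomForest cannot split such data)
  if (all(apply(x, 2, function(v) v[1] == v))) {
    maj <- levels(y)[which.max(tabulate(y))]
    return(structure(list(majority = maj, levels = levels(y)),
                     class = "majority_classifier"))
  }
  switch(name,
    random_forest = randomForest::randomForest(x = x, y = y),
    adaboost      = ada_boost(x, y),
    gaussian_nb   = e1071::naiveBayes(x = as.data.frame(x), y = y),
    stop_idscreen("idscreen_config_error", "unknown classifier '%s'", name))
}

.predict_classifier <- function(name, fit, x) {
  if (inherits(fit, "majority_classifier"))
    return(factor(rep(fit$majority, nrow(x)), levels = fit$levels))
  switch(name,
    random_forest = predict(fit, x),
    adaboost      = predict(fit, x),
    gaussian_nb   = predict(fit, as.data.frame(x), type = "class"))
}

#' Fold-internal kernel-PCA preprocessing for [evaluate()]
#'
#' Fits the RBF kernel PCA on the training rows of each fold only and projects
#' the held-out rows with the training model, so the reduction never sees test
#' subjects.
#'
#' @inheritParams kpca_rbf
#' @return A preprocessing spec (list with `fit` and `transform`).
#' @export
kpca_preprocess <- function(n_components = 38L, gamma = NULL) {
  list(fit = function(X) kpca_rbf(X, n_components = n_components, gamma = gamma),
       transform = function(model, X) predict(model, X),
       description = sprintf("fold-internal RBF KPCA to %d components", n_components))
}

#' Cross-validated evaluation of screening classifiers
#'
#' Stratified k-fold cross-validation; per fold, any preprocessing is fit on
#' the training rows only, each classifier is fit and applied to the held-out
#' rows, and metrics are computed from the predictions pooled over folds.
#' Deterministic (bit-identical) for a fixed seed.
#'
#' @param table A [feature_table()].
#' @param classifiers Subset of `"random_forest"`, `"adaboost"`, `"gaussian_nb"`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed covering fold assignment and classifier randomness.
#' @param averaging Metric averaging, see [classification_metrics()].
#' @param preprocess Optional preprocessing spec such as [kpca_preprocess()].
#' @param feature_set_name Name reported for the feature set; defaults to the
#'   table's name.
#' @param chance_threshold Accuracy bar for the better-than-chance flag.
#' @return An `evaluation_report` data frame (one row per classifier:
#'   accuracy, precision, recall, f1, above_chance) with cross-validation
#'   provenance (fold assignment, seed, scheme, averaging) in attributes.
#' @export
evaluate <- function(table, classifiers = c("random_forest", "adaboost", "gaussian_nb"),
                     k = 5L, seed = 20230116L,
                     averaging = c("weighted", "macro", "positive"),
                     preprocess = NULL, feature_set_name = NULL,
                     chance_threshold = CHANCE_THRESHOLD) {
  stopifnot(inherits(table, "feature_table"))
  averaging <- match.arg(averaging)
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  if (min(table(table$labels)) < 2L)
    stop_idscreen("idscreen_contract_error", "need at least 2 subjects per class")
  name <- feature_set_name %||% table$name
  fold <- stratified_folds(table$labels, k = k, seed = seed)

  preds <- matrix(NA_character_, nrow(table$X), length(classifiers),
                  dimnames = list(NULL, classifiers))
  with_local_seed(seed + 1L, {
    for (f in seq_len(k)) {
      tr <- fold != f
      Xtr <- table$X[tr, , drop = FALSE]
      Xte <- table$X[!tr, , drop = FALSE]
      if (!is.null(preprocess)) {
        pp <- preprocess$fit(Xtr)
        Xtr <- preprocess$transform(pp, Xtr)
        Xte <- preprocess$transform(pp, Xte)
      }
      for (cl in classifiers) {
        fit <- .fit_classifier(cl, Xtr, table$labels[tr])
        preds[!tr, cl] <- as.character(.predict_classifier(cl, fit, Xte))
      }
    }
  })
  rows <- lapply(classifiers, function(cl) {
    m <- classification_metrics(table$labels, preds[, cl], averaging)
    data.frame(classifier = cl, feature_set = name, t(m),
               above_chance = unname(m["accuracy"] > chance_threshold))
  })
  report <- do.call(rbind, rows)
  structure(report, class = c("evaluation_report", "data.frame"),
            cv = list(scheme = "stratified k-fold", k = k, seed = seed,
                      folds = fold,
                      preprocess = if (!is.null(preprocess)) preprocess$description),
            averaging = averaging, chance_threshold = chance_threshold)
}

#' Flag report cells that beat the chance accuracy bar
#'
#' The bar (default 0.646) is the accuracy a classifier must strictly exceed
#' on this cohort composition to outperform random guessing; it is treated as
#' a fixed constant, not recomputed.
#'
#' @param report An `evaluation_report` (or any data frame with an `accuracy`
#'   column).
#' @param threshold Accuracy bar.
#' @return Named logical vector (classifier/feature-set per cell); the report's
#'   `above_chance` column is the same comparison.
#' @export
chance_comparison <- function(report, threshold = CHANCE_THRESHOLD) {
  flags <- report$accuracy > threshold
  names(flags) <- paste(report$classifier, report$feature_set, sep = ":")
  flags
}

#' Write an evaluation report as CSV
#' @param report An `evaluation_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
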