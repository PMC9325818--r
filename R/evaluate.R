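# AUROC, the heterogeneous confidence measure, and the random-forest-on-
# ECFP4 baseline.

#' Area under the ROC curve (midrank ties)
#'
#' The probability that a randomly chosen positive outranks a randomly
#' chosen negative, with tied scores counted 1/2 (midrank convention,
#' equivalent to the normalized Wilcoxon-Mann-Whitney statistic).
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores Numeric scores, same length.
#' @return AUC in \[0, 1\].
#' @export
auroc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  if (!all(labels %in% c(0, 1))) stop("auroc: labels must be 0/1")
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("auroc: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Heterogeneous confidence half-width
#'
#' `1.96 * sd(values) / sqrt(n)`: a confidence measure analogous to 1.96
#' standard errors, but with mean and "standard" deviation taken across
#' per-dataset AUC values from heterogeneous systems — a descriptive range
#' of fluctuation, not a true 95% interval.
#'
#' @param auc_values Numeric vector of per-dataset AUCs (length >= 2).
#' @return The half-width.
#' @export
heterogeneous_confidence <- function(auc_values) {
  if (length(auc_values) < 2) {
    stop("heterogeneous_confidence: need at least 2 values")
  }
  1.96 * stats::sd(auc_values) / sqrt(length(auc_values))
}

#' Per-slice evaluation report
#'
#' AUC of a score vector over the validation, early-test, late-test and
#' full-test slices of a chronological split.
#'
#' @param scores Named numeric vector of predicted activity probabilities
#'   (names = molecule ids covering the relevant slices).
#' @param dataset The `activity_dataset` (for labels).
#' @param split A `split_result`.
#' @return A data.frame with columns `slice`, `n`, `auc` (AUC is `NA` for
#'   a single-class slice).
#' @export
evaluation_report <- function(scores, dataset, split) {
  lab <- stats::setNames(dataset$label, dataset$id)
  slice_auc <- function(ids) {
    l <- lab[ids]; s <- scores[ids]
    if (length(unique(l)) < 2) return(NA_real_)
    auroc(l, s)
  }
  slices <- list(validation = split$validation_ids,
                 test_early = split$test_early_ids,
                 test_late = split$test_late_ids,
                 test_full = test_ids(split))
  data.frame(slice = names(slices),
             n = vapply(slices, length, integer(1)),
             auc = vapply(slices, slice_auc, numeric(1)),
             row.names = NULL)
}

#' Random-forest baseline on ECFP4 fingerprints
#'
#' A standard random forest (default 100 trees) trained on 2048-bit ECFP4
#' features of the chronological training slice, evaluated on the
#' validation/test slices. Deterministic given `seed`; remaining forest
#' hyperparameters stay at `randomForest` defaults and are recorded in the
#' returned report attributes.
#'
#' @param dataset An `activity_dataset`.
#' @param split A `split_result`.
#' @param n_trees Number of trees (default 100).
#' @param n_bits Fingerprint length (default 2048).
#' @param seed Integer seed.
#' @param graphs Optional pre-parsed graphs named by id.
#' @return List with `model` (the `randomForest` object), `report`
#'   (see [evaluation_report()]) and `scores` (named test-side
#'   probabilities).
#' @export
train_rf_baseline <- function(dataset, split, n_trees = 100L,
                              n_bits = 2048L, seed = 1L, graphs = NULL) {
  stopifnot(inherits(split, "split_result"))
  if (is.null(graphs)) {
    graphs <- parse_smiles_batch(stats::setNames(dataset$smiles, dataset$id))
  }
  fps <- lapply(graphs, ecfp4, n_bits = n_bits)
  X <- fp_matrix(fps)
  rownames(X) <- names(graphs)
  lab <- stats::setNames(dataset$label, dataset$id)
  tr <- training_ids(split, "final")
  if (length(unique(lab[tr])) < 2) {
    stop("train_rf_baseline: training slice contains a single class")
  }
  set.seed(seed)
  rf <- randomForest::randomForest(x = X[tr, , drop = FALSE],
                                   y = factor(lab[tr], levels = c(0, 1)),
                                   ntree = n_trees)
  eval_ids <- c(split$validation_ids, test_ids(split))
  scores <- stats::predict(rf, X[eval_ids, , drop = FALSE],
                           type = "prob")[, "1"]
  names(scores) <- eval_ids
  rep <- evaluation_report(scores, dataset, split)
  attr(rep, "rf_settings") <- list(ntree = n_trees,
                                   mtry = rf$mtry, seed = seed)
  list(model = rf, report = rep, scores = scores)
}

#' Evaluate a trained gCNN on a chronological split
#'
#' @param model A `gcnn_model`.
#' @param dataset An `activity_dataset`.
#' @param split A `split_result`.
#' @param graphs Optional pre-parsed graphs named by id.
#' @return List with `report` (see [evaluation_report()]) and `scores`.
#' @export
evaluate_gcnn <- function(model, dataset, split, graphs = NULL) {
  eval_ids <- c(split$validation_ids, test_ids(split))
  rows <- dataset[match(eval_ids, dataset$id), , drop = FALSE]
  if (is.null(graphs)) {
    graphs <- parse_smiles_batch(stats::setNames(rows$smiles, rows$id))
  } else {
    graphs <- graphs[eval_ids]
  }
  scores <- predict_gcnn(model, graphs)
  names(scores) <- eval_ids
  list(report = evaluation_report(scores, dataset, split), scores = scores)
}
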