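# Chronological train/validation/test slicing and inter-set
# molecular-similarity diagnostics.

#' Read an activity dataset from CSV/TSV
#'
#' Requires columns `id`, `smiles`, `label` (0/1) and `date` (ISO-8601);
#' extra columns are kept. The delimiter is inferred from the extension
#' (`.tsv` = tab, otherwise comma).
#'
#' @param path File path.
#' @return An `activity_dataset` data.frame.
#' @export
read_activity_csv <- function(path) {
  stopifnot(file.exists(path))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = NA)
  need <- c("id", "smiles", "label", "date")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("read_activity_csv: missing column(s): ",
                             paste(miss, collapse = ", "))
  if (anyDuplicated(df$id)) stop("read_activity_csv: duplicated ids")
  if (!all(df$label %in% c(0, 1))) stop("read_activity_csv: labels must be 0/1")
  parsed <- as.Date(as.character(df$date), format = "%Y-%m-%d")
  if (anyNA(parsed)) {
    stop("read_activity_csv: unparseable date(s) for id(s): ",
         paste(utils::head(df$id[is.na(parsed)], 10), collapse = ", "))
  }
  df$date <- parsed
  df$label <- as.integer(df$label)
  class(df) <- c("activity_dataset", class(df))
  df
}

#' Chronological train/validation/test split
#'
#' Records are stably sorted by (date, id) — ties in deposition date break
#' by lexicographic id — and sliced at date-rank fractions: the earliest
#' 70% form the hyperparameter-search training slice, 70-80% the
#' validation slice, 80-90% the "early" test slice and 90-100% the "late"
#' test slice. Final models train on the earliest 80% (train plus
#' validation); see [training_ids()].
#'
#' @param dataset An `activity_dataset` (needs `id`, `date`; `smiles` kept).
#' @param fractions Cut points as cumulative fractions (default
#'   `c(0.7, 0.8, 0.9)`); boundaries fall at `floor(f * N)` ranks.
#' @return An object of class `split_result`: list with `train_ids`,
#'   `validation_ids`, `test_early_ids`, `test_late_ids` and `boundaries`.
#' @export
chronological_split <- function(dataset, fractions = c(0.7, 0.8, 0.9)) {
  stopifnot(is.data.frame(dataset), all(c("id", "date") %in% names(dataset)))
  if (nrow(dataset) < 5) stop("chronological_split: need at least 5 records")
  stopifnot(length(fractions) == 3, all(diff(fractions) > 0),
            fractions[1] > 0, fractions[3] < 1)
  dates <- as.Date(dataset$date)
  if (anyNA(dates)) {
    stop("chronological_split: missing/unparseable date(s) for id(s): ",
         paste(utils::head(dataset$id[is.na(dates)], 10), collapse = ", "))
  }
  ord <- order(dates, dataset$id)
  ids <- dataset$id[ord]
  n <- length(ids)
  cut <- floor(fractions * n)
  if (any(duplicated(c(0, cut, n)))) {
    stop("chronological_split: dataset too small for the given fractions")
  }
  if (!is.null(dataset$smiles)) {
    dup <- intersect(dataset$smiles[ord][seq_len(cut[2])],
                     dataset$smiles[ord][(cut[2] + 1):n])
    if (length(dup) > 0) {
      sq_log(length(dup), " SMILES duplicated across the train/test boundary",
             level = "WARN")
    }
  }
  structure(list(
    train_ids = ids[seq_len(cut[1])],
    validation_ids = ids[(cut[1] + 1):cut[2]],
    test_early_ids = ids[(cut[2] + 1):cut[3]],
    test_late_ids = ids[(cut[3] + 1):n],
    boundaries = fractions
  ), class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf(paste0("<split_result> train %d | validation %d | ",
                     "test_early %d | test_late %d (cuts %s)\n"),
              length(x$train_ids), length(x$validation_ids),
              length(x$test_early_ids), length(x$test_late_ids),
              paste(x$boundaries, collapse = "/")))
  invisible(x)
}

#' Training ids for a pipeline stage
#'
#' `"final"` returns the earliest 80% (train + validation slices), the set
#' final models are retrained on; `"hyperopt"` returns the earliest 70%
#' used while searching hyperparameters.
#'
#' @param split A `split_result`.
#' @param stage `"final"` or `"hyperopt"`.
#' @return Character vector of ids, in chronological order.
#' @export
training_ids <- function(split, stage = c("final", "hyperopt")) {
  stage <- match.arg(stage)
  if (stage == "hyperopt") split$train_ids
  else c(split$train_ids, split$validation_ids)
}

#' Test ids (early + late slices)
#'
#' @param split A `split_result`.
#' @return Character vector of ids, in chronological order.
#' @export
test_ids <- function(split) c(split$test_early_ids, split$test_late_ids)

#' Mean nearest-neighbor Tanimoto similarity between two molecule sets
#'
#' For every fingerprint in `set_a`, the maximum Tanimoto similarity to
#' `set_b` (skipping the identical record when `exclude_self` and the sets
#' are the same collection), averaged over `set_a`.
#'
#' @param set_a,set_b Lists of `bit_fp` fingerprints (see [ecfp4()]).
#' @param exclude_self Skip the same-index record (use when `set_a` and
#'   `set_b` are the same list).
#' @return Mean nearest-neighbor similarity in \[0, 1\].
#' @export
mean_nn_similarity <- function(set_a, set_b, exclude_self = FALSE) {
  if (length(set_a) == 0 || length(set_b) == 0) {
    stop("mean_nn_similarity: empty fingerprint set")
  }
  if (exclude_self && length(set_a) < 2) {
    stop("mean_nn_similarity: exclude_self needs at least 2 members")
  }
  A <- fp_matrix(set_a)
  B <- fp_matrix(set_b)
  if (ncol(A) != ncol(B)) stop("mean_nn_similarity: mismatched n_bits")
  inter <- tcrossprod(A, B)
  pa <- rowSums(A); pb <- rowSums(B)
  uni <- outer(pa, pb, "+") - inter
  sim <- ifelse(uni == 0, 1, inter / pmax(uni, 1e-300))
  if (exclude_self) diag(sim) <- -Inf
  mean(apply(sim, 1, max))
}

#' Similarity diagnostics for a chronological split
#'
#' Mean nearest-neighbor ECFP4 Tanimoto similarities for the standard
#' comparisons: train-train and test-test (with self-exclusion),
#' train-test, and each test-side time slice (validation, early, late)
#' against the hyperopt-era training set.
#'
#' @param dataset An `activity_dataset` with `smiles`.
#' @param split A `split_result` for that dataset.
#' @param n_bits Fingerprint length (default 2048).
#' @param graphs Optional pre-parsed `mol_graph` list named by id (to avoid
#'   re-parsing).
#' @return A data.frame with columns `comparison`, `n_a`, `n_b`,
#'   `mean_nn_similarity`.
#' @export
similarity_report <- function(dataset, split, n_bits = 2048L, graphs = NULL) {
  stopifnot(inherits(split, "split_result"))
  if (is.null(graphs)) {
    graphs <- parse_smiles_batch(stats::setNames(dataset$smiles, dataset$id))
  }
  fps <- lapply(graphs, ecfp4, n_bits = n_bits)
  names(fps) <- dataset$id
  tr <- fps[split$train_ids]
  te <- fps[test_ids(split)]
  rows <- list(
    c("train-train", length(tr), length(tr),
      mean_nn_similarity(tr, tr, exclude_self = TRUE)),
    c("test-test", length(te), length(te),
      mean_nn_similarity(te, te, exclude_self = TRUE)),
    c("test-train", length(te), length(tr),
      mean_nn_similarity(te, tr)),
    c("validation-train", length(split$validation_ids), length(tr),
      mean_nn_similarity(fps[split$validation_ids], tr)),
    c("test_early-train", length(split$test_early_ids), length(tr),
      mean_nn_similarity(fps[split$test_early_ids], tr)),
    c("test_late-train", length(split$test_late_ids), length(tr),
      mean_nn_similarity(fps[split$test_late_ids], tr))
  )
  out <- data.frame(
    comparison = vapply(rows, `[[`, character(1), 1),
    n_a = as.integer(vapply(rows, `[[`, character(1), 2)),
    n_b = as.integer(vapply(rows, `[[`, character(1), 3)),
    mean_nn_similarity = as.numeric(vapply(rows, `[[`, character(1), 4)),
    stringsAsFactors = FALSE)
  out
}
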