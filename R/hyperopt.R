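# Greedy Gaussian hyperparameter search over (L2, conv1, conv2, conv3).
#
# As described, this is Gaussian perturbation sampling around a greedy
# incumbent — each iteration draws Gaussian-distributed candidates around
# the current seed vector, evaluates them, and reinserts the best as the
# next seed. Despite the customary name there is no surrogate model.

#' A point in hyperparameter space
#'
#' @param l2 Positive L2 regularization strength.
#' @param conv_sizes Three convolutional layer sizes, each within `bounds`.
#' @param bounds Inclusive integer bounds on layer sizes (default 4-256).
#' @return An object of class `hyper_vector`.
#' @export
hyper_vector <- function(l2, conv_sizes, bounds = c(4L, 256L)) {
  stopifnot(l2 > 0, length(conv_sizes) == 3,
            all(conv_sizes >= bounds[1]), all(conv_sizes <= bounds[2]))
  structure(list(l2 = l2, conv_sizes = as.integer(round(conv_sizes)),
                 bounds = as.integer(bounds)), class = "hyper_vector")
}

#' @export
print.hyper_vector <- function(x, ...) {
  cat(sprintf("<hyper_vector> l2 = %g, conv = (%s)\n", x$l2,
              paste(x$conv_sizes, collapse = ", ")))
  invisible(x)
}

#' Gaussian-distributed candidate hyperparameter vectors
#'
#' Draws `n` candidates around a seed vector: each dimension is sampled
#' from a normal with a 20% relative spread — `l2` on the log scale
#' (`log l2' ~ N(log l2, rel_sigma)`), layer sizes on the natural scale
#' (`~ N(size, rel_sigma * size)`), rounded to the nearest integer and
#' clamped to the bounds. Deterministic under `set.seed()`.
#'
#' @param seed_hv A `hyper_vector` to perturb.
#' @param n Number of candidates (default 80).
#' @param rel_sigma Relative spread (default 0.2; 0 returns copies of the
#'   seed).
#' @return A list of `n` `hyper_vector`s.
#' @export
sample_candidates <- function(seed_hv, n = 80L, rel_sigma = 0.2) {
  stopifnot(inherits(seed_hv, "hyper_vector"))
  if (n < 1) stop("sample_candidates: n must be >= 1")
  lapply(seq_len(n), function(k) {
    l2 <- exp(stats::rnorm(1, log(seed_hv$l2), rel_sigma))
    cs <- round(stats::rnorm(3, seed_hv$conv_sizes,
                             rel_sigma * seed_hv$conv_sizes))
    cs <- pmin(pmax(cs, seed_hv$bounds[1]), seed_hv$bounds[2])
    hyper_vector(l2, cs, bounds = seed_hv$bounds)
  })
}

#' Greedy Gaussian search
#'
#' Each iteration evaluates the incumbent seed and `n` Gaussian candidates
#' around it, then greedily reinserts the best as the next seed (the
#' incumbent is retained, without re-evaluation, when no candidate beats
#' it). A candidate on which the objective fails is skipped and logged,
#' not fatal.
#'
#' @param objective Function `hyper_vector -> numeric` to maximize.
#' @param seed_hv Starting `hyper_vector`.
#' @param iterations Number of iterations (default 10).
#' @param n Candidates per iteration (default 80).
#' @param rel_sigma Relative spread (default 0.2).
#' @param seed Integer RNG seed.
#' @return List with `best` (a `hyper_vector`), `best_value` and `history`
#'   (data.frame: per-iteration incumbent value and parameters; incumbent
#'   values are non-decreasing by construction).
#' @export
greedy_search <- function(objective, seed_hv, iterations = 10L, n = 80L,
                          rel_sigma = 0.2, seed = 1L) {
  stopifnot(inherits(seed_hv, "hyper_vector"), iterations >= 1)
  set.seed(seed)
  incumbent <- seed_hv
  inc_val <- objective(incumbent)
  if (!is.finite(inc_val)) stop("greedy_search: objective failed on the seed")
  history <- data.frame()
  for (it in seq_len(iterations)) {
    cands <- sample_candidates(incumbent, n = n, rel_sigma = rel_sigma)
    vals <- vapply(cands, function(hv) {
      v <- tryCatch(objective(hv), error = function(e) {
        sq_log("objective failed on candidate (", conditionMessage(e),
               "); skipped", level = "WARN")
        NA_real_
      })
      if (is.finite(v)) v else NA_real_
    }, numeric(1))
    n_eval <- sum(!is.na(vals))
    if (n_eval > 0 && max(vals, na.rm = TRUE) > inc_val) {
      best_k <- which.max(vals)
      incumbent <- cands[[best_k]]
      inc_val <- vals[best_k]
    }
    history <- rbind(history, data.frame(
      iteration = it, incumbent_value = inc_val, l2 = incumbent$l2,
      conv1 = incumbent$conv_sizes[1], conv2 = incumbent$conv_sizes[2],
      conv3 = incumbent$conv_sizes[3], n_evaluated = n_eval))
    sq_log(sprintf("iteration %d: incumbent %.4f, l2 %.3g, conv (%s)",
                   it, inc_val, incumbent$l2,
                   paste(incumbent$conv_sizes, collapse = ",")))
  }
  list(best = incumbent, best_value = inc_val, history = history)
}

#' QSAR validation objective for the hyperparameter search
#'
#' Returns a function mapping a `hyper_vector` to the mean validation-
#' slice AUC across datasets: for each dataset the model trains on the
#' earliest 70% of records and is scored on the 70-80% slice. A dataset
#' that fails is skipped with a log line; the mean runs over the rest.
#'
#' @param datasets List of `activity_dataset`s.
#' @param config Template [gcnn_config()] whose `conv_sizes` and `l2` the
#'   hyper-vector overrides.
#' @param splits Optional list of precomputed `split_result`s.
#' @param graphs_list Optional list of pre-parsed graph lists (named by
#'   id), parallel to `datasets`.
#' @return A function `hyper_vector -> numeric`.
#' @export
qsar_objective <- function(datasets, config = gcnn_config(),
                           splits = NULL, graphs_list = NULL) {
  stopifnot(length(datasets) >= 1)
  if (is.null(splits)) splits <- lapply(datasets, chronological_split)
  if (is.null(graphs_list)) {
    graphs_list <- lapply(datasets, function(ds)
      parse_smiles_batch(stats::setNames(ds$smiles, ds$id)))
  }
  function(hv) {
    stopifnot(inherits(hv, "hyper_vector"))
    cfg <- config
    cfg$conv_sizes <- hv$conv_sizes
    cfg$l2 <- hv$l2
    aucs <- vapply(seq_along(datasets), function(k) {
      tryCatch({
        ds <- datasets[[k]]; sp <- splits[[k]]; gs <- graphs_list[[k]]
        tr <- training_ids(sp, "hyperopt")
        m <- train_gcnn(ds[match(tr, ds$id), , drop = FALSE], cfg,
                        graphs = gs)
        va <- sp$validation_ids
        o <- predict_gcnn(m, gs[va])
        auroc(ds$label[match(va, ds$id)], o)
      }, error = function(e) {
        sq_log("dataset ", k, " failed in objective (",
               conditionMessage(e), "); skipped", level = "WARN")
        NA_real_
      })
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }
}

#' Write a search history as JSON lines
#'
#' One record per iteration, suitable for streaming inspection.
#'
#' @param history The `history` data.frame from [greedy_search()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_search_history <- function(history, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_len(nrow(history))) {
    writeLines(jsonlite::toJSON(as.list(history[r, ]), auto_unbox = TRUE,
                                digits = NA), con)
  }
  invisible(path)
}
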