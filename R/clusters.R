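# Confusion-quadrant partitioning and substructural clustering of salient
# fragments: density peak clustering (Rodriguez-Laio) with a minimal
# k-means (k = 2) fallback when the data are too sparse for densities.

#' Assign confusion-matrix quadrants
#'
#' TP (`l = 1, o > 0.5`), FP (`l = 0, o > 0.5`), TN (`l = 0, o < 0.5`),
#' FN (`l = 1, o < 0.5`). The boundary `o == 0.5` is treated as a negative
#' prediction (the strict inequalities leave it open).
#'
#' @param label Vector of reference labels in \{0, 1\}.
#' @param output Vector of model softmax outputs in \[0, 1\].
#' @return Character vector of quadrant labels (`"TP"`, `"FP"`, `"TN"`,
#'   `"FN"`).
#' @export
assign_quadrant <- function(label, output) {
  if (!all(label %in% c(0, 1))) stop("assign_quadrant: labels must be 0/1")
  stopifnot(length(label) == length(output),
            all(output >= 0 & output <= 1))
  pred <- output > 0.5
  ifelse(label == 1, ifelse(pred, "TP", "FN"), ifelse(pred, "FP", "TN"))
}

#' Density peak clustering of fingerprints
#'
#' The Rodriguez-Laio procedure on Jaccard distances
#' (`1 - `[tanimoto()]): local density `rho_i = #\{j != i : d_ij < d_c\}`,
#' separation `delta_i` = distance to the nearest point of higher density
#' (the densest point takes the global maximum distance), and
#' `gamma_i = rho_i * delta_i`. Cluster centers are the points above the
#' largest relative gap in the sorted gamma sequence (overridable with
#' `n_centers`); every remaining point joins the cluster of its nearest
#' higher-density neighbor. Ties in density break toward the lower index.
#'
#' @param fps List of `bit_fp` fingerprints (or a precomputed distance
#'   matrix via `dist_matrix`).
#' @param d_c Density cutoff distance; default is the 10th percentile of
#'   the pairwise distances.
#' @param dist_matrix Optional symmetric distance matrix (overrides `fps`).
#' @param n_centers Optional fixed number of centers.
#' @return List with `assignment` (integer cluster ids, 1-based, in
#'   population-agnostic center order), `centers` (point indices),
#'   `rho`, `delta`, `gamma`, `d_c`.
#' @export
dpc_cluster <- function(fps = NULL, d_c = NULL, dist_matrix = NULL,
                        n_centers = NULL) {
  D <- if (!is.null(dist_matrix)) dist_matrix else {
    M <- fp_matrix(fps)
    inter <- tcrossprod(M)
    pc <- rowSums(M)
    uni <- outer(pc, pc, "+") - inter
    1 - ifelse(uni == 0, 1, inter / pmax(uni, 1e-300))
  }
  n <- nrow(D)
  if (n == 1L) {
    return(list(assignment = 1L, centers = 1L, rho = 0L, delta = 0,
                gamma = 0, d_c = d_c %||% 0))
  }
  off <- D[upper.tri(D)]
  if (is.null(d_c)) d_c <- as.numeric(stats::quantile(off, 0.10))
  rho <- vapply(seq_len(n), function(i) sum(D[i, -i] < d_c), integer(1))
  ## density order: rho descending, index ascending; "higher density"
  ## means earlier in this order, which resolves ties deterministically
  ord <- order(-rho, seq_len(n))
  delta <- numeric(n)
  nn_hd <- integer(n)
  delta[ord[1]] <- max(D)
  nn_hd[ord[1]] <- ord[1]
  for (k in seq_len(n)[-1]) {
    i <- ord[k]
    higher <- ord[seq_len(k - 1)]
    j <- higher[which.min(D[i, higher])]
    delta[i] <- D[i, j]
    nn_hd[i] <- j
  }
  gamma <- rho * delta
  if (is.null(n_centers)) {
    gs <- sort(gamma, decreasing = TRUE)
    if (max(gs) - min(gs) < 1e-12) {
      n_centers <- 1L  # degenerate: no density structure at all
    } else {
      eps <- 1e-9
      ratios <- (gs[-length(gs)] + eps) / (gs[-1] + eps)
      n_centers <- which.max(ratios)
    }
  }
  centers <- order(-gamma, seq_len(n))[seq_len(n_centers)]
  assignment <- integer(n)
  assignment[centers] <- seq_along(centers)
  for (k in seq_len(n)) {
    i <- ord[k]
    if (assignment[i] == 0L) assignment[i] <- assignment[nn_hd[i]]
  }
  list(assignment = assignment, centers = centers, rho = rho,
       delta = delta, gamma = gamma, d_c = d_c)
}

#' Minimal k-means fallback clustering (k = 2)
#'
#' Lloyd iterations on fingerprints as 0/1 real vectors with
#' farthest-pair initialization; deterministic given `seed`. Degenerate
#' all-identical inputs collapse to a single cluster (logged), as does a
#' single point.
#'
#' @param fps List of `bit_fp` fingerprints.
#' @param seed Integer seed (tie-breaking inside `stats::kmeans`).
#' @return List with `assignment` (1- or 2-valued integer vector) and
#'   `centers` (matrix of cluster means).
#' @export
kmeans_fallback <- function(fps, seed = 1L) {
  if (length(fps) < 2) {
    sq_log("kmeans_fallback: fewer than 2 items; single singleton cluster")
    return(list(assignment = rep(1L, length(fps)), centers = NULL))
  }
  M <- fp_matrix(fps)
  D <- as.matrix(stats::dist(M))
  far <- which(D == max(D), arr.ind = TRUE)[1, ]
  if (max(D) < 1e-12) {
    sq_log("kmeans_fallback: all points identical; single cluster")
    return(list(assignment = rep(1L, length(fps)),
                centers = M[1, , drop = FALSE]))
  }
  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(M, centers = M[c(far[1], far[2]), ,
                                                      drop = FALSE],
                                       algorithm = "Lloyd", iter.max = 100))
  list(assignment = as.integer(km$cluster), centers = km$centers)
}

#' Cluster salient fragments within one confusion quadrant
#'
#' Collects the selected salient neighborhoods of the quadrant's test
#' molecules, converts their fragment SMILES to ECFP4 fingerprints, and
#' clusters them: density peak clustering when at least `min_points`
#' fragments have computable densities, otherwise the k-means (k = 2)
#' fallback. Clusters are ranked by population (ties toward the smallest
#' member id).
#'
#' @param explanations Named list of [explain()] results for the test
#'   molecules (names = molecule ids).
#' @param quadrants Named character vector of quadrant labels for the same
#'   ids (see [assign_quadrant()]).
#' @param quadrant Which quadrant to cluster (default `"TP"`).
#' @param n_bits Fragment fingerprint length (default 2048).
#' @param min_points Minimum fragment count for DPC (default 8).
#' @param d_c DPC cutoff (default: 10th-percentile heuristic).
#' @param seed Seed for the k-means fallback.
#' @return A list of `substructure_cluster` objects: each has `quadrant`,
#'   `members` (data.frame: `molecule_id`, `center`, `fragment_smiles`,
#'   `score`), `population`, `rank`, `method`.
#' @export
cluster_quadrant <- function(explanations, quadrants, quadrant = "TP",
                             n_bits = 2048L, min_points = 8L, d_c = NULL,
                             seed = 1L) {
  stopifnot(quadrant %in% c("TP", "FP", "TN", "FN"))
  ids <- names(explanations)
  ids <- ids[quadrants[ids] == quadrant]
  frag <- do.call(rbind, lapply(ids, function(id) {
    nbs <- explanations[[id]]$neighborhoods
    if (length(nbs) == 0) return(NULL)
    data.frame(molecule_id = id,
               center = vapply(nbs, `[[`, integer(1), "center"),
               fragment_smiles = vapply(nbs, function(nb)
                 nb$neighborhood$fragment_smiles, character(1)),
               score = vapply(nbs, `[[`, numeric(1), "score"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(frag) || nrow(frag) == 0) {
    sq_log("quadrant ", quadrant, " is empty: no clusters")
    return(list())
  }
  graphs <- parse_smiles_batch(frag$fragment_smiles)
  fps <- lapply(graphs, ecfp4, n_bits = n_bits)
  method <- "dpc"
  if (nrow(frag) < min_points) {
    method <- "kmeans"
  } else {
    res <- dpc_cluster(fps, d_c = d_c)
    if (all(res$rho == 0)) method <- "kmeans"  # too sparse for a density
  }
  if (method == "kmeans") {
    sq_log("quadrant ", quadrant, ": sparse input (", nrow(frag),
           " fragments), reverting to k-means fallback")
    res <- kmeans_fallback(fps, seed = seed)
  }
  asg <- res$assignment
  clusters <- lapply(sort(unique(asg)), function(cl) {
    mem <- frag[asg == cl, , drop = FALSE]
    structure(list(quadrant = quadrant, members = mem,
                   population = nrow(mem), method = method),
              class = "substructure_cluster")
  })
  pop <- vapply(clusters, `[[`, integer(1), "population")
  first_id <- vapply(clusters, function(cl) min(cl$members$molecule_id),
                     character(1))
  ord <- order(-pop, first_id)
  clusters <- clusters[ord]
  for (r in seq_along(clusters)) clusters[[r]]$rank <- r
  clusters
}

#' @export
print.substructure_cluster <- function(x, ...) {
  cat(sprintf("<substructure_cluster> %s rank %s: %d fragments (%s)\n",
              x$quadrant, x$rank %||% "?", x$population, x$method))
  invisible(x)
}

#' Full quadrant analysis for a trained model
#'
#' Predicts the test slice, assigns confusion quadrants, explains every
#' test molecule and clusters the salient fragments of each requested
#' quadrant.
#'
#' @param model A `gcnn_model`.
#' @param dataset An `activity_dataset`.
#' @param split A `split_result` for the dataset.
#' @param quadrants Which quadrants to cluster (default all four).
#' @param k_max Salient neighborhoods per molecule (default 5).
#' @param graphs Optional pre-parsed graphs named by id.
#' @param ... Passed to [cluster_quadrant()].
#' @return List with `quadrant_of` (named vector over test ids), `outputs`
#'   (named predictions), `explanations`, and `clusters` (named list of
#'   per-quadrant cluster lists).
#' @export
substructure_analysis <- function(model, dataset, split,
                                  quadrants = c("TP", "FP", "TN", "FN"),
                                  k_max = 5L, graphs = NULL, ...) {
  te <- test_ids(split)
  rows <- dataset[match(te, dataset$id), , drop = FALSE]
  if (is.null(graphs)) {
    graphs <- parse_smiles_batch(stats::setNames(rows$smiles, rows$id))
  } else {
    graphs <- graphs[te]
  }
  o <- predict_gcnn(model, graphs)
  names(o) <- te
  quadrant_of <- assign_quadrant(rows$label, o)
  names(quadrant_of) <- te
  explanations <- lapply(te, function(id)
    explain(model, graphs[[id]], k_max = k_max))
  names(explanations) <- te
  clusters <- lapply(quadrants, function(q)
    cluster_quadrant(explanations, quadrant_of, quadrant = q, ...))
  names(clusters) <- quadrants
  list(quadrant_of = quadrant_of, outputs = o,
       explanations = explanations, clusters = clusters)
}

#' Write quadrant clusters as JSON
#'
#' Layout: quadrant -> clusters -> members with fragment SMILES; atom
#' indices 0-based.
#'
#' @param clusters The `clusters` element of [substructure_analysis()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_cluster_json <- function(clusters, path) {
  out <- lapply(clusters, function(qcl) lapply(qcl, function(cl) list(
    rank = cl$rank, population = cl$population, method = cl$method,
    members = lapply(seq_len(nrow(cl$members)), function(r) list(
      molecule_id = cl$members$molecule_id[r],
      center = cl$members$center[r] - 1L,
      fragment_smiles = cl$members$fragment_smiles[r],
      score = cl$members$score[r])))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
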