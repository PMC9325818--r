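# Convert a saliency tensor into ranked salient atomic neighborhoods.
#
# Per fingerprint column the winning atom is the row argmax ("sorting the
# tensor column-wise with atomic indices conserved"); atoms are then scored
# by frequency (columns won) times a softmax over the winning atoms' mean
# winning amplitudes, and the top five become the molecule's salient
# neighborhoods.

#' Rank atomic neighborhoods from a saliency tensor
#'
#' For every fingerprint column `j`, the winning atom is
#' `argmax_i s[i, j]` with winning amplitude `s[a_j, j]`; columns that are
#' entirely zero carry no evidence and are skipped. Per winning atom:
#' `frequency` = number of columns won, `amplitude` = mean winning
#' amplitude, `score` = `frequency * softmax(amplitude)` where the softmax
#' (temperature 1) runs over all atoms that win at least one column.
#' Candidates are sorted by score, ties broken toward the lower atom index.
#'
#' @param saliency An `n_atom` x `n_col` non-negative matrix (128 columns
#'   in the standard architecture), or the list returned by
#'   [encode_gcnn()].
#' @param top_m Number of per-column contributors counted (default 1, the
#'   column argmax; larger values credit the `top_m` largest rows of each
#'   column).
#' @return A data.frame of candidates with columns `center`, `frequency`,
#'   `amplitude`, `score`, `rank` (empty for an all-zero tensor, which
#'   signals an untrained or dead encoder).
#' @export
rank_neighborhoods <- function(saliency, top_m = 1L) {
  if (is.list(saliency) && !is.null(saliency$saliency)) {
    saliency <- saliency$saliency
  }
  stopifnot(is.matrix(saliency), nrow(saliency) >= 1, top_m >= 1)
  if (any(saliency < 0)) stop("rank_neighborhoods: negative saliency entries")
  nz <- which(colSums(saliency) > 0)
  empty <- data.frame(center = integer(0), frequency = integer(0),
                      amplitude = numeric(0), score = numeric(0),
                      rank = integer(0))
  if (length(nz) == 0) {
    sq_log("all-zero saliency tensor: no candidates", level = "WARN")
    return(empty)
  }
  wins_atom <- integer(0)
  wins_amp <- numeric(0)
  for (j in nz) {
    col <- saliency[, j]
    m <- min(top_m, nrow(saliency))
    idx <- order(-col, seq_along(col))[seq_len(m)]
    idx <- idx[col[idx] > 0]
    wins_atom <- c(wins_atom, idx)
    wins_amp <- c(wins_amp, col[idx])
  }
  atoms <- sort(unique(wins_atom))
  freq <- vapply(atoms, function(a) sum(wins_atom == a), integer(1))
  amp <- vapply(atoms, function(a) mean(wins_amp[wins_atom == a]),
                numeric(1))
  sm <- exp(amp - max(amp))
  sm <- sm / sum(sm)
  score <- freq * sm
  ord <- order(-score, atoms)
  data.frame(center = atoms[ord], frequency = freq[ord],
             amplitude = amp[ord], score = score[ord],
             rank = seq_along(ord))
}

#' Select the top salient neighborhoods
#'
#' Takes the `min(k_max, n_candidates)` best-ranked candidates and
#' materializes each one's radius-3 bonded neighborhood (members and
#' fragment SMILES).
#'
#' @param candidates Ranked candidates from [rank_neighborhoods()].
#' @param graph The `mol_graph` the tensor came from.
#' @param k_max Maximum number of neighborhoods (default 5).
#' @param radius Neighborhood radius in bonds (default 3).
#' @param fragments Compute fragment SMILES (default `TRUE`).
#' @return A list of `salient_neighborhood` objects: each has `center`,
#'   `neighborhood`, `frequency`, `amplitude`, `score`, `rank`.
#' @export
select_salient <- function(candidates, graph, k_max = 5L, radius = 3L,
                           fragments = TRUE) {
  stopifnot(is.data.frame(candidates), inherits(graph, "mol_graph"))
  if (nrow(candidates) == 0) {
    sq_log("no salient neighborhood candidates to select")
    return(list())
  }
  k <- min(k_max, nrow(candidates))
  lapply(seq_len(k), function(r) {
    structure(list(
      center = candidates$center[r],
      neighborhood = atom_neighborhood(graph, candidates$center[r],
                                       radius = radius,
                                       fragment = fragments),
      frequency = candidates$frequency[r],
      amplitude = candidates$amplitude[r],
      score = candidates$score[r],
      rank = r), class = "salient_neighborhood")
  })
}

#' @export
print.salient_neighborhood <- function(x, ...) {
  cat(sprintf("<salient_neighborhood> rank %d: atom %d, freq %d, score %.3f (%s)\n",
              x$rank, x$center, x$frequency, x$score,
              x$neighborhood$fragment_smiles))
  invisible(x)
}

#' Explain a prediction: encode, rank, select
#'
#' Convenience wrapper composing [encode_gcnn()], [rank_neighborhoods()]
#' and [select_salient()].
#'
#' @param model A `gcnn_model`.
#' @param graph A `mol_graph` or SMILES string.
#' @param k_max Maximum neighborhoods (default 5).
#' @param top_m Per-column contributors (default 1).
#' @param fragments Compute fragment SMILES (default `TRUE`).
#' @return List with `graph`, `o` (predicted activity probability) and
#'   `neighborhoods` (list of `salient_neighborhood`).
#' @export
explain <- function(model, graph, k_max = 5L, top_m = 1L, fragments = TRUE) {
  if (is.character(graph)) graph <- parse_smiles(graph)
  enc <- encode_gcnn(model, graph)
  cand <- rank_neighborhoods(enc$saliency, top_m = top_m)
  list(graph = graph, o = enc$o, saliency = enc$saliency,
       neighborhoods = select_salient(cand, graph, k_max = k_max,
                                      fragments = fragments))
}

#' Write per-molecule saliency explanations as JSON
#'
#' Atom indices in the JSON are 0-based.
#'
#' @param explanations Named list of [explain()] results (names = molecule
#'   ids).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_saliency_json <- function(explanations, path) {
  recs <- lapply(names(explanations), function(id) {
    ex <- explanations[[id]]
    list(molecule_id = id, smiles = ex$graph$smiles, prediction = ex$o,
         neighborhoods = lapply(ex$neighborhoods, function(nb) list(
           rank = nb$rank, center = nb$center - 1L,
           member_atoms = nb$neighborhood$members - 1L,
           fragment_smiles = nb$neighborhood$fragment_smiles,
           frequency = nb$frequency, amplitude = nb$amplitude,
           score = nb$score)))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
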