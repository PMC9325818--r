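# Molecular parsing, graphs, circular fingerprints, similarity and
# bonded-neighborhood extraction. SMILES/SDF I/O is delegated to
# ChemmineR/ChemmineOB (OpenBabel); the graph container, Morgan fingerprint
# and BFS utilities live here.

.ELEMENTS <- c("C", "N", "O", "S", "F", "P", "Cl", "Br", "I")

## default valences used to infer implicit hydrogen counts from kekulized
## bond orders (hypervalent S/P get their usual extended valences)
.VALENCES <- list(C = 4, N = 3, O = 2, S = c(2, 4, 6), P = c(3, 5),
                  F = 1, Cl = 1, Br = 1, I = 1, B = 3, Si = 4)

## old-style MDL atom-line charge codes -> formal charge
.MDL_CHARGE <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0,
                 `5` = -1, `6` = -2, `7` = -3)

#' Parse a SMILES string into a molecular graph
#'
#' Converts a SMILES string to a heavy-atom molecular graph via OpenBabel.
#' Atom order follows the order of appearance in the SMILES string and is
#' fixed for the life of the object, so saliency rows always map back to
#' input atoms. Hydrogens stay implicit (they are counted per atom, never
#' materialized as nodes). Atom indices are 1-based in the R API; serialized
#' JSON uses 0-based indices.
#'
#' @param smiles A single non-empty SMILES string.
#' @return An object of class `mol_graph`: a list with `n_atom`, `smiles`,
#'   `atoms` (data.frame: `element`, `charge`, `aromatic`, `n_h`, `in_ring`,
#'   `degree`), `bonds` (data.frame: `i`, `j`, `order`), `adj` (neighbor
#'   index list) and `coords` (2D depiction coordinates).
#' @examples
#' g <- parse_smiles("CCO")
#' g$n_atom  # 3
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(trimws(smiles))) stop("parse_smiles: empty SMILES string")
  parse_smiles_batch(smiles)[[1L]]
}

#' Parse many SMILES strings at once
#'
#' Vectorized counterpart of [parse_smiles()]: a single OpenBabel call for
#' the whole vector, falling back to per-molecule parsing to name offenders
#' when any string fails.
#'
#' @param smiles Character vector of SMILES strings.
#' @param on_error `"stop"` (default) or `"drop"`; dropping logs the failed
#'   inputs and returns `NULL` entries removed.
#' @return A list of `mol_graph` objects (named after `smiles` names, if any).
#' @export
parse_smiles_batch <- function(smiles, on_error = c("stop", "drop")) {
  on_error <- match.arg(on_error)
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  bad <- !nzchar(trimws(smiles))
  if (any(bad)) stop("parse_smiles: empty SMILES at position(s) ",
                     paste(which(bad), collapse = ", "))
  nm <- names(smiles) %||% paste0("mol", seq_along(smiles))
  out <- try(suppressWarnings({
    sdf <- ChemmineR::smiles2sdf(stats::setNames(smiles, nm))
    if (length(sdf) != length(smiles)) stop("batch length mismatch")
    lapply(seq_along(smiles), function(k)
      .sdf_to_graph(sdf[[k]], smiles[k]))
  }), silent = TRUE)
  if (!inherits(out, "try-error")) {
    names(out) <- nm
    return(out)
  }
  ## isolate the offending molecule(s) one at a time
  res <- vector("list", length(smiles))
  fail <- character(0)
  for (k in seq_along(smiles)) {
    one <- try(suppressWarnings({
      s1 <- ChemmineR::smiles2sdf(stats::setNames(smiles[k], nm[k]))
      .sdf_to_graph(s1[[1]], smiles[k])
    }), silent = TRUE)
    if (inherits(one, "try-error")) fail <- c(fail, smiles[k])
    else res[[k]] <- one
  }
  if (length(fail) > 0 && on_error == "stop") {
    stop("parse_smiles: unparsable SMILES: ",
         paste(utils::head(fail, 5), collapse = "; "))
  }
  if (length(fail) > 0) {
    sq_log("dropped ", length(fail), " unparsable molecule(s)",
           level = "WARN")
  }
  names(res) <- nm
  Filter(Negate(is.null), res)
}

#' Read molecules from an SDF file
#'
#' Maps the first molecule block of each SDF record to a `mol_graph`.
#'
#' @param path Path to an SDF (V2000) file.
#' @return A list of `mol_graph` objects.
#' @export
read_sdf_molecules <- function(path) {
  stopifnot(file.exists(path))
  sdf <- ChemmineR::read.SDFset(path)
  smi <- as.character(ChemmineR::sdf2smiles(sdf))
  lapply(seq_along(sdf), function(k) .sdf_to_graph(sdf[[k]], smi[k]))
}

## Parse a raw V2000 molblock (as emitted by OpenBabel). ChemmineR's SDF
## reader mangles zero-bond molecules (single heavy atoms), so those fall
## back to this direct reader.
.graph_from_raw_sdf <- function(smiles) {
  txt <- ChemmineOB::convertFormat("SMI", "SDF", source = paste0(smiles, "\n"))
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  n <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(n) || n < 1L) stop("parse_smiles: no atoms parsed from '",
                               smiles, "'")
  at <- lines[5:(4 + n)]
  element <- trimws(substr(at, 32, 34))
  coords <- cbind(x = as.numeric(substr(at, 1, 10)),
                  y = as.numeric(substr(at, 11, 20)))
  charge <- unname(.MDL_CHARGE[trimws(substr(at, 37, 39))])
  charge[is.na(charge)] <- 0
  for (cl in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", cl)), " +")[[1]])
    k <- f[1]
    for (p in seq_len(k)) charge[f[2 * p]] <- f[2 * p + 1]
  }
  bl <- if (nb > 0) lines[(5 + n):(4 + n + nb)] else character(0)
  bonds <- data.frame(
    i = pmin(as.integer(substr(bl, 1, 3)), as.integer(substr(bl, 4, 6))),
    j = pmax(as.integer(substr(bl, 1, 3)), as.integer(substr(bl, 4, 6))),
    order = as.integer(substr(bl, 7, 9)))
  .assemble_graph(smiles, element, charge, coords, bonds, sdf1 = NULL)
}

## build the mol_graph container from a ChemmineR SDF object
.sdf_to_graph <- function(sdf1, smiles) {
  ab <- ChemmineR::atomblock(sdf1)
  n <- nrow(ab)
  if (is.null(n) || n < 1L || !("C6" %in% colnames(ab)) ||
      !all(grepl("^[A-Za-z]+_[0-9]+$", rownames(ab)))) {
    ## mangled block (ChemmineR mishandles zero-bond molecules)
    return(.graph_from_raw_sdf(smiles))
  }
  element <- sub("_[0-9]+$", "", rownames(ab))
  coords <- cbind(x = ab[, "C1"], y = ab[, "C2"])
  charge <- unname(.MDL_CHARGE[as.character(ab[, "C6"])])
  charge[is.na(charge)] <- 0

  bb <- ChemmineR::bondblock(sdf1)
  ## single-bond molecules come back as a bare vector
  if (!is.null(bb) && is.null(dim(bb))) bb <- matrix(bb, nrow = 1)
  if (is.null(bb) || nrow(bb) == 0L || ncol(bb) < 3L) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  } else {
    i <- pmin(bb[, 1], bb[, 2]); j <- pmax(bb[, 1], bb[, 2])
    bonds <- data.frame(i = as.integer(i), j = as.integer(j),
                        order = as.integer(bb[, 3]))
    if (any(bonds$i == bonds$j)) stop("parse_smiles: self-loop bond in '",
                                      smiles, "'")
  }
  .assemble_graph(smiles, element, charge, coords, bonds, sdf1)
}

## shared tail: adjacency, ring/aromatic perception, implicit hydrogens
.assemble_graph <- function(smiles, element, charge, coords, bonds, sdf1) {
  n <- length(element)
  adj <- rep(list(integer(0)), n)
  for (r in seq_len(nrow(bonds))) {
    adj[[bonds$i[r]]] <- c(adj[[bonds$i[r]]], bonds$j[r])
    adj[[bonds$j[r]]] <- c(adj[[bonds$j[r]]], bonds$i[r])
  }
  adj <- lapply(adj, sort)
  degree <- lengths(adj)

  aromatic <- rep(FALSE, n)
  in_ring <- rep(FALSE, n)
  if (nrow(bonds) >= 3L && !is.null(sdf1)) {
    rr <- try(suppressWarnings(
      ChemmineR::rings(sdf1, upper = 14, type = "all", arom = TRUE)),
      silent = TRUE)
    if (!inherits(rr, "try-error") && length(rr$RINGS) > 0) {
      for (k in seq_along(rr$RINGS)) {
        idx <- as.integer(sub(".*_", "", rr$RINGS[[k]]))
        in_ring[idx] <- TRUE
        if (isTRUE(rr$AROMATIC[[k]])) aromatic[idx] <- TRUE
      }
    }
  }

  ## implicit H from the smallest standard valence that accommodates the
  ## kekulized bond-order sum, shifted by formal charge
  bondsum <- vapply(seq_len(n), function(a) {
    rs <- bonds$order[bonds$i == a | bonds$j == a]
    if (length(rs) == 0) 0L else as.integer(sum(rs))
  }, integer(1))
  n_h <- vapply(seq_len(n), function(a) {
    vals <- .VALENCES[[element[a]]]
    if (is.null(vals)) return(0L)
    vals <- vals + charge[a]
    ok <- vals[vals >= bondsum[a]]
    if (length(ok) == 0) 0L else as.integer(min(ok) - bondsum[a])
  }, integer(1))

  structure(list(
    smiles = smiles, n_atom = as.integer(n),
    atoms = data.frame(element = element, charge = charge,
                       aromatic = aromatic, n_h = n_h, in_ring = in_ring,
                       degree = as.integer(degree)),
    bonds = bonds, adj = adj, coords = coords
  ), class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s: %d heavy atoms, %d bonds\n",
              x$smiles, x$n_atom, nrow(x$bonds)))
  invisible(x)
}

#' Shortest bond-path distance between two atoms
#'
#' @param graph A `mol_graph`.
#' @param i,j Atom indices (1-based).
#' @return Integer number of bonds on the shortest path; `Inf` when the
#'   atoms lie in disconnected fragments.
#' @export
bond_distance <- function(graph, i, j) {
  stopifnot(inherits(graph, "mol_graph"))
  .check_atom(graph, c(i, j))
  bond_distance_matrix(graph)[i, j]
}

#' All-pairs bond distances
#'
#' Breadth-first search from every atom. Disconnected pairs are `Inf`.
#'
#' @param graph A `mol_graph`.
#' @return An `n_atom` x `n_atom` symmetric matrix of bond counts.
#' @export
bond_distance_matrix <- function(graph) {
  stopifnot(inherits(graph, "mol_graph"))
  n <- graph$n_atom
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s; d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- unique(unlist(graph$adj[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(dist[nxt])]
      dist[nxt] <- d
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

.check_atom <- function(graph, idx) {
  if (any(idx < 1L | idx > graph$n_atom)) {
    stop("atom index out of range [1, ", graph$n_atom, "]: ",
         paste(idx[idx < 1L | idx > graph$n_atom], collapse = ", "))
  }
  invisible(TRUE)
}

#' Extract the bonded neighborhood around an atom
#'
#' The BFS ball of bond distance at most `radius` around `center`, together
#' with the canonical SMILES of the induced subgraph (all bonds between
#' members kept, with the parent's kekulized bond orders).
#'
#' @param graph A `mol_graph`.
#' @param center Atom index (1-based).
#' @param radius Maximum bond distance (default 3, matching the three
#'   graph convolutions feeding the saliency tensor).
#' @param fragment If `TRUE` (default) compute `fragment_smiles`.
#' @return An object of class `neighborhood`: list with `center`, `radius`,
#'   `members` (sorted atom indices) and `fragment_smiles`.
#' @export
atom_neighborhood <- function(graph, center, radius = 3L, fragment = TRUE) {
  stopifnot(inherits(graph, "mol_graph"))
  .check_atom(graph, center)
  stopifnot(radius >= 0)
  members <- center
  frontier <- center
  dist <- rep(Inf, graph$n_atom); dist[center] <- 0
  d <- 0
  while (length(frontier) > 0 && d < radius) {
    d <- d + 1
    nxt <- unique(unlist(graph$adj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    members <- c(members, nxt)
    frontier <- nxt
  }
  members <- sort(members)
  structure(list(
    center = as.integer(center), radius = as.integer(radius),
    members = as.integer(members),
    fragment_smiles = if (fragment) fragment_smiles(graph, members) else NA_character_
  ), class = "neighborhood")
}

#' Canonical SMILES of an induced subgraph
#'
#' Writes the subgraph induced by `members` (parent bond orders and formal
#' charges kept as-is) to a scratch SDF block and asks OpenBabel for its
#' canonical SMILES. Aromaticity is re-perceived on the fragment; partial
#' rings therefore come back with the parent's kekulized orders.
#'
#' @param graph A `mol_graph`.
#' @param members Atom indices of the fragment.
#' @return A canonical SMILES string, without atom maps.
#' @export
fragment_smiles <- function(graph, members) {
  stopifnot(inherits(graph, "mol_graph"))
  members <- sort(unique(as.integer(members)))
  .check_atom(graph, members)
  remap <- match(seq_len(graph$n_atom), members)
  keep <- graph$bonds$i %in% members & graph$bonds$j %in% members
  b <- graph$bonds[keep, , drop = FALSE]
  el <- graph$atoms$element[members]
  chg <- graph$atoms$charge[members]
  xy <- graph$coords[members, , drop = FALSE]
  lines <- c("fragment", " saliqsar", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     length(members), nrow(b)))
  old_code <- c(`3` = 1, `2` = 2, `1` = 3, `0` = 0, `-1` = 5, `-2` = 6,
                `-3` = 7)
  for (k in seq_along(members)) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
      xy[k, 1], xy[k, 2], 0, el[k],
      unname(old_code[as.character(chg[k])]) %||% 0))
  }
  for (r in seq_len(nrow(b))) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              remap[b$i[r]], remap[b$j[r]], b$order[r]))
  }
  if (any(chg != 0)) {
    for (k in which(chg != 0)) {
      lines <- c(lines, sprintf("M  CHG  1 %3d %3d", k, chg[k]))
    }
  }
  lines <- c(lines, "M  END", "$$$$")
  out <- ChemmineOB::convertFormat("SDF", "CAN",
                                   source = paste(lines, collapse = "\n"))
  smi <- strsplit(trimws(out), "[\t ]")[[1]][1]
  if (is.na(smi) || !nzchar(smi)) {
    stop("fragment_smiles: conversion failed for members ",
         paste(members, collapse = ","))
  }
  smi
}

#' Canonical SMILES of a whole molecule
#'
#' @param graph A `mol_graph`.
#' @return Canonical SMILES string.
#' @export
canonical_smiles <- function(graph) {
  fragment_smiles(graph, seq_len(graph$n_atom))
}

# ---------------------------------------------------------------------------
# ECFP4 (Morgan radius-2 hashed circular fingerprint)

#' Hashed circular fingerprint (ECFP4)
#'
#' Extended-connectivity fingerprint of diameter 4: two rounds of Morgan
#' identifier refinement over initial atom invariants (element, degree,
#' formal charge, implicit-H count, ring membership, aromaticity), with
#' every identifier from rounds 0-2 hashed onto `n_bits` bit positions.
#' Deterministic and invariant to the input atom ordering (neighbor
#' identifiers are sorted before hashing).
#'
#' @param graph A `mol_graph`.
#' @param n_bits Fingerprint length (default 2048).
#' @return An object of class `bit_fp`: sorted 0-based set-bit positions
#'   with attribute `n_bits`.
#' @export
ecfp4 <- function(graph, n_bits = 2048L) {
  stopifnot(inherits(graph, "mol_graph"), n_bits >= 1)
  at <- graph$atoms
  n <- graph$n_atom
  elem_code <- match(at$element, .ELEMENTS)
  elem_code[is.na(elem_code)] <- length(.ELEMENTS) + 1L
  ids <- vapply(seq_len(n), function(a) .sq_hash(c(
    1, elem_code[a], at$degree[a], at$charge[a] + 10, at$n_h[a],
    as.integer(at$in_ring[a]), as.integer(at$aromatic[a]))), numeric(1))
  all_ids <- ids
  ## bond order participates in the neighbor tuple, as in standard ECFP
  border <- lapply(seq_len(n), function(a) {
    nb <- graph$adj[[a]]
    vapply(nb, function(b) {
      r <- graph$bonds
      as.numeric(r$order[(r$i == min(a, b)) & (r$j == max(a, b))][1])
    }, numeric(1))
  })
  for (r in 1:2) {
    new_ids <- vapply(seq_len(n), function(a) {
      nb <- graph$adj[[a]]
      if (length(nb) == 0) return(.sq_hash(c(2, r, ids[a])))
      pairs <- cbind(border[[a]], ids[nb])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      .sq_hash(c(2, r, ids[a], as.vector(t(pairs))))
    }, numeric(1))
    ids <- new_ids
    all_ids <- c(all_ids, ids)
  }
  bits <- sort(unique(as.integer(unique(all_ids) %% n_bits)))
  structure(bits, n_bits = as.integer(n_bits), class = "bit_fp")
}

#' @export
print.bit_fp <- function(x, ...) {
  cat(sprintf("<bit_fp> %d/%d bits set\n", length(x), attr(x, "n_bits")))
  invisible(x)
}

#' Tanimoto similarity between two bit fingerprints
#'
#' |intersection| / |union|. Two empty fingerprints are treated as
#' identical (similarity 1), avoiding 0/0.
#'
#' @param a,b `bit_fp` objects of equal length.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  na <- attr(a, "n_bits"); nb <- attr(b, "n_bits")
  if (is.null(na) || is.null(nb) || na != nb) {
    stop("tanimoto: fingerprints have mismatched n_bits")
  }
  if (length(a) == 0 && length(b) == 0) return(1.0)
  inter <- length(intersect(as.integer(a), as.integer(b)))
  inter / (length(a) + length(b) - inter)
}

#' Stack bit fingerprints into a dense 0/1 matrix
#'
#' @param fps List of `bit_fp` objects sharing one `n_bits`.
#' @return A `length(fps)` x `n_bits` 0/1 matrix.
#' @export
fp_matrix <- function(fps) {
  stopifnot(length(fps) >= 1)
  nb <- attr(fps[[1]], "n_bits")
  if (any(vapply(fps, function(f) attr(f, "n_bits"), integer(1)) != nb)) {
    stop("fp_matrix: fingerprints have mismatched n_bits")
  }
  M <- matrix(0, length(fps), nb)
  for (k in seq_along(fps)) M[k, as.integer(fps[[k]]) + 1L] <- 1
  M
}

# ---------------------------------------------------------------------------
# Subgraph / motif matching (igraph colored VF2)

.graph_to_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = graph$n_atom, directed = FALSE)
  if (nrow(graph$bonds) > 0) {
    g <- igraph::add_edges(g, rbind(graph$bonds$i, graph$bonds$j))
  }
  ec <- match(graph$atoms$element, .ELEMENTS)
  ec[is.na(ec)] <- length(.ELEMENTS) + 1L
  igraph::V(g)$color <- ec
  if (nrow(graph$bonds) > 0) igraph::E(g)$color <- graph$bonds$order
  g
}

#' Find all embeddings of a motif in a molecule
#'
#' Colored VF2 subgraph matching: elements must match on atoms and bond
#' orders on bonds. Used to verify planted motifs and to locate motif atoms.
#'
#' @param graph Target `mol_graph`.
#' @param motif Motif as a `mol_graph` or SMILES string.
#' @return A list of integer vectors: for each embedding, the target atom
#'   indices the motif atoms map to (possibly empty list).
#' @export
motif_matches <- function(graph, motif) {
  if (is.character(motif)) motif <- parse_smiles(motif)
  gt <- .graph_to_igraph(graph)
  gp <- .graph_to_igraph(motif)
  ms <- igraph::subgraph_isomorphisms(
    gp, gt, method = "vf2",
    vertex.color1 = igraph::V(gt)$color, vertex.color2 = igraph::V(gp)$color,
    edge.color1 = if (nrow(graph$bonds) > 0) igraph::E(gt)$color else NULL,
    edge.color2 = if (nrow(motif$bonds) > 0) igraph::E(gp)$color else NULL)
  lapply(ms, as.integer)
}

#' Does a molecule contain a motif?
#'
#' @inheritParams motif_matches
#' @return `TRUE` if at least one embedding exists.
#' @export
has_motif <- function(graph, motif) length(motif_matches(graph, motif)) > 0
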