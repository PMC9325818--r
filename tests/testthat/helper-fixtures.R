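# Shared fixtures and independent oracles. Everything here is built in
# code at test time; heavyweight objects are cached for the session.

options(saliqsar.quiet = TRUE)

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

## a small, fully trained model on noise-free planted-motif data, shared
## across test files
fixture_model <- function() {
  cached("small_model", {
    spec <- generator_spec(n = 400, label_noise = 0, seed = 2001)
    ds <- generate_dataset(spec)
    sp <- chronological_split(ds)
    graphs <- parse_smiles_batch(stats::setNames(ds$smiles, ds$id))
    tr <- training_ids(sp, "final")
    model <- train_gcnn(ds[match(tr, ds$id), ],
                        gcnn_preset("optimized", epochs = 20, seed = 7),
                        graphs = graphs)
    list(spec = spec, dataset = ds, split = sp, graphs = graphs,
         model = model)
  })
}

## reorder the atoms of a mol_graph by a permutation (perm[new] = old)
permute_graph <- function(graph, perm) {
  inv <- order(perm)  # inv[old] = new
  bonds <- graph$bonds
  i2 <- inv[bonds$i]; j2 <- inv[bonds$j]
  bonds2 <- data.frame(i = pmin(i2, j2), j = pmax(i2, j2),
                       order = bonds$order)
  adj <- rep(list(integer(0)), graph$n_atom)
  for (r in seq_len(nrow(bonds2))) {
    adj[[bonds2$i[r]]] <- c(adj[[bonds2$i[r]]], bonds2$j[r])
    adj[[bonds2$j[r]]] <- c(adj[[bonds2$j[r]]], bonds2$i[r])
  }
  g <- graph
  g$atoms <- graph$atoms[perm, , drop = FALSE]
  rownames(g$atoms) <- NULL
  g$bonds <- bonds2
  g$adj <- lapply(adj, sort)
  g$coords <- graph$coords[perm, , drop = FALSE]
  g
}

## independent Morgan identifier loop (radius 2) using string identifiers;
## counts unique environment identifiers without any hashing scheme shared
## with the implementation
morgan_id_count <- function(graph, radius = 2) {
  at <- graph$atoms
  ids <- sprintf("[%s|%d|%d|%d|%d|%d]", at$element, at$degree, at$charge,
                 at$n_h, as.integer(at$in_ring), as.integer(at$aromatic))
  all_ids <- ids
  border <- function(a, b) {
    r <- graph$bonds
    r$order[(r$i == min(a, b)) & (r$j == max(a, b))][1]
  }
  for (r in seq_len(radius)) {
    new_ids <- vapply(seq_len(graph$n_atom), function(a) {
      nb <- graph$adj[[a]]
      parts <- sort(vapply(nb, function(b)
        paste0(border(a, b), ":", ids[b]), character(1)))
      paste0("r", r, "{", ids[a], "|", paste(parts, collapse = ","), "}")
    }, character(1))
    ids <- new_ids
    all_ids <- c(all_ids, ids)
  }
  length(unique(all_ids))
}

## brute-force saliency ranking oracle: enumerate every column's argmax
## and recompute frequencies/scores from scratch
rank_oracle <- function(S) {
  nz <- which(colSums(S) > 0)
  if (length(nz) == 0) return(data.frame(center = integer(0)))
  winners <- integer(0); amps <- numeric(0)
  for (j in nz) {
    best <- 1
    for (i in seq_len(nrow(S))) if (S[i, j] > S[best, j]) best <- i
    winners <- c(winners, best); amps <- c(amps, S[best, j])
  }
  atoms <- sort(unique(winners))
  freq <- sapply(atoms, function(a) sum(winners == a))
  amp <- sapply(atoms, function(a) mean(amps[winners == a]))
  e <- exp(amp - max(amp)); sm <- e / sum(e)
  score <- freq * sm
  ord <- order(-score, atoms)
  data.frame(center = atoms[ord], frequency = freq[ord],
             amplitude = amp[ord], score = score[ord])
}

## independent O(n^2) density-peak recomputation
dpc_oracle <- function(D, d_c) {
  n <- nrow(D)
  rho <- sapply(seq_len(n), function(i) sum(D[i, -i] < d_c))
  ord <- order(-rho, seq_len(n))
  delta <- numeric(n); nn <- integer(n)
  delta[ord[1]] <- max(D); nn[ord[1]] <- ord[1]
  for (k in 2:n) {
    i <- ord[k]; hi <- ord[1:(k - 1)]
    j <- hi[which.min(D[i, hi])]
    delta[i] <- D[i, j]; nn[i] <- j
  }
  list(rho = rho, delta = delta, gamma = rho * delta, nn = nn, ord = ord)
}

## brute-force pairwise AUROC
auroc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

## hand-built bit fingerprint
bitfp <- function(bits, n_bits = 16L) {
  structure(sort(unique(as.integer(bits))), n_bits = as.integer(n_bits),
            class = "bit_fp")
}
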