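# Molecular graph construction, circular fingerprints, similarity and
# bonded neighborhoods.

test_that("parse_smiles builds correct heavy-atom graphs", {
  g <- parse_smiles("C")
  expect_equal(g$n_atom, 1L)
  expect_equal(nrow(g$bonds), 0L)
  expect_equal(g$atoms$n_h, 4L)

  g <- parse_smiles("CCO")
  expect_equal(g$n_atom, 3L)
  expect_equal(nrow(g$bonds), 2L)
  expect_equal(g$atoms$element, c("C", "C", "O"))

  g <- parse_smiles("c1ccccc1")
  expect_equal(g$n_atom, 6L)
  expect_equal(nrow(g$bonds), 6L)
  expect_true(all(g$atoms$aromatic))
  expect_true(all(g$atoms$in_ring))
  expect_equal(g$atoms$n_h, rep(1L, 6))

  # charge perception
  g <- parse_smiles("C[N+](C)(C)C")
  expect_equal(g$atoms$charge[g$atoms$element == "N"], 1)
  g <- parse_smiles("CC(=O)[O-]")
  expect_equal(sum(g$atoms$charge), -1)
})

test_that("unparsable SMILES raise an error naming the input", {
  expect_error(parse_smiles("notasmiles[["), "unparsable|parse")
  expect_error(parse_smiles(""), "empty")
  expect_error(parse_smiles_batch(c("CC", "xx((")), "xx\\(\\(")
})

test_that("bond distances are BFS shortest paths with Inf for salts", {
  pent <- parse_smiles("CCCCC")
  expect_equal(bond_distance(pent, 1, 1), 0)
  expect_equal(bond_distance(pent, 1, 5), 4)
  D <- bond_distance_matrix(pent)
  expect_true(isSymmetric(D))
  salt <- parse_smiles("CC.O")
  expect_equal(bond_distance(salt, 1, 3), Inf)
  expect_error(bond_distance(pent, 1, 9), "out of range")
})

test_that("atom neighborhoods are BFS balls matching bond_distance", {
  g <- parse_smiles("C")
  expect_equal(atom_neighborhood(g, 1)$members, 1L)

  pent <- parse_smiles("CCCCC")
  expect_equal(atom_neighborhood(pent, 1, radius = 3)$members, 1:4)

  benz <- parse_smiles("c1ccccc1")
  nb <- atom_neighborhood(benz, 3, radius = 3)
  expect_equal(nb$members, 1:6)
  expect_equal(nb$fragment_smiles, "c1ccccc1")

  # oracle equivalence on a varied fixture set (all molecules <= 12 atoms)
  fix <- c("CCCCC", "c1ccccc1", "CC(C)CC(=O)N", "C1CCNCC1", "CC.OC",
           "c1ccncc1CO", "CC(=O)[O-]", "C")
  for (smi in fix) {
    g <- parse_smiles(smi)
    D <- bond_distance_matrix(g)
    for (a in seq_len(g$n_atom)) {
      for (r in 0:3) {
        nb <- atom_neighborhood(g, a, radius = r, fragment = FALSE)
        expect_equal(nb$members, which(D[a, ] <= r),
                     info = paste(smi, "atom", a, "radius", r))
      }
    }
  }
})

test_that("ecfp4 is deterministic, order-invariant, and matches the Morgan identifier count", {
  a <- ecfp4(parse_smiles("CCO"))
  b <- ecfp4(parse_smiles("OCC"))
  expect_identical(as.integer(a), as.integer(b))
  expect_gte(length(ecfp4(parse_smiles("C"))), 1)

  # popcount equals an independent Morgan identifier-loop enumeration
  for (smi in c("CCCCC", "CCO", "c1ccccc1", "CC(C)C")) {
    g <- parse_smiles(smi)
    expect_equal(length(ecfp4(g)), morgan_id_count(g), info = smi)
  }

  # invariance under 100 random atom renumberings
  set.seed(99)
  g <- parse_smiles("CC(C)Cc1ccc(cc1)C(C)C(=O)O")
  ref <- as.integer(ecfp4(g))
  for (k in 1:100) {
    gp <- permute_graph(g, sample(g$n_atom))
    expect_identical(as.integer(ecfp4(gp)), ref)
  }
})

test_that("tanimoto follows the set definition with the empty-set convention", {
  expect_equal(tanimoto(bitfp(c(1, 5)), bitfp(c(1, 5))), 1.0)
  expect_equal(tanimoto(bitfp(c(1, 2)), bitfp(c(3, 4))), 0.0)
  expect_equal(tanimoto(bitfp(1:3), bitfp(2:4)), 0.5)
  expect_equal(tanimoto(bitfp(integer(0)), bitfp(integer(0))), 1.0)
  expect_error(tanimoto(bitfp(1, n_bits = 16), bitfp(1, n_bits = 32)),
               "mismatch")
  # symmetry and self-similarity on random fingerprints
  set.seed(4)
  for (k in 1:20) {
    x <- bitfp(sample(0:15, 5), 16); y <- bitfp(sample(0:15, 5), 16)
    expect_equal(tanimoto(x, y), tanimoto(y, x))
    expect_equal(tanimoto(x, x), 1.0)
  }
})

test_that("fragment SMILES canonicalize induced subgraphs", {
  g <- parse_smiles("CCOC")  # members {2,3,4} -> COC
  expect_equal(fragment_smiles(g, 2:4), "COC")
  expect_equal(canonical_smiles(parse_smiles("OCC")),
               canonical_smiles(parse_smiles("CCO")))
})

test_that("motif matching finds planted fragments and nothing else", {
  g <- parse_smiles("c1ccc(cc1)S(N)(=O)=O")
  m <- motif_matches(g, "S(=O)(=O)N")
  expect_gte(length(m), 1)
  expect_true(all(g$atoms$element[m[[1]]] %in% c("S", "N", "O")))
  expect_false(has_motif(g, "C(=O)O"))
})

test_that("SDF reader round-trips a generated molecule set", {
  ds <- generate_dataset(generator_spec(n = 6, seed = 42))
  sdf <- ChemmineR::smiles2sdf(stats::setNames(ds$smiles, ds$id))
  path <- tempfile(fileext = ".sdf")
  ChemmineR::write.SDF(sdf, path)
  gs <- read_sdf_molecules(path)
  expect_length(gs, 6)
  ref <- parse_smiles_batch(ds$smiles)
  expect_equal(unname(vapply(gs, `[[`, integer(1), "n_atom")),
               unname(vapply(ref, `[[`, integer(1), "n_atom")))
})
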