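# Saliency ranking and salient-neighborhood selection.

test_that("singleton and degenerate tensors rank as expected", {
  # single-atom molecule: softmax over one atom is 1, score = 128
  S <- matrix(runif(128, 0.1, 1), 1, 128)
  cand <- rank_neighborhoods(S)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$frequency, 128L)
  expect_equal(cand$score, 128)

  # one atom winning every column of a 5-atom tensor
  S <- matrix(0.1, 5, 128); S[3, ] <- 5
  cand <- rank_neighborhoods(S)
  expect_equal(cand$center[1], 3)
  expect_equal(cand$frequency[1], 128L)

  # identical rows: per-column argmax gives every column to the lower
  # atom index (column conservation forbids double credit)
  S <- matrix(1, 2, 128)
  cand <- rank_neighborhoods(S)
  expect_equal(cand$center, 1)
  expect_equal(cand$frequency, 128L)

  # equal scores from disjoint column wins: lower atom index ranks first
  S <- matrix(0, 2, 4)
  S[1, 1:2] <- 2; S[2, 3:4] <- 2
  cand <- rank_neighborhoods(S)
  expect_equal(cand$score[1], cand$score[2])
  expect_equal(cand$center, c(1, 2))

  # all-zero tensor signals a dead encoder: empty candidate list
  expect_equal(nrow(rank_neighborhoods(matrix(0, 3, 128))), 0)
})

test_that("ranking matches the brute-force per-column-argmax oracle", {
  set.seed(55)
  for (k in 1:200) {
    n <- sample(2:6, 1); m <- sample(2:8, 1)
    S <- matrix(sample(c(0, 0.5, 1), n * m, replace = TRUE), n, m)
    got <- rank_neighborhoods(S)
    want <- rank_oracle(S)
    expect_equal(got$center, want$center)
    if (nrow(want) > 0) {
      expect_equal(got$frequency, want$frequency)
      expect_equal(got$score, want$score, tolerance = 1e-12)
    }
  }
})

test_that("column conservation and softmax normalization hold", {
  set.seed(56)
  for (k in 1:50) {
    S <- matrix(stats::rexp(5 * 128), 5, 128) *
      matrix(sample(0:1, 5 * 128, replace = TRUE, prob = c(0.2, 0.8)),
             5, 128)
    cand <- rank_neighborhoods(S)
    expect_equal(sum(cand$frequency), sum(colSums(S) > 0))
    # softmax over winning atoms sums to one
    e <- exp(cand$amplitude - max(cand$amplitude))
    expect_equal(sum(e / sum(e)), 1, tolerance = 1e-9)
    expect_true(all(cand$score > 0 & cand$score <= cand$frequency))
    expect_equal(cand$rank, seq_len(nrow(cand)))
  }
})

test_that("top-5 selection truncates to the available winning atoms", {
  g <- parse_smiles("CCCCCCCCCCCC")
  set.seed(57)
  # 10+ distinct winners -> exactly 5 selected
  S <- matrix(stats::runif(12 * 128), 12, 128)
  cand <- rank_neighborhoods(S)
  expect_gte(nrow(cand), 6)
  sel <- select_salient(cand, g, fragments = FALSE)
  expect_length(sel, 5)
  expect_equal(vapply(sel, `[[`, integer(1), "rank"), 1:5)

  # 3-atom molecule: only k < 5 available
  g3 <- parse_smiles("CCO")
  S3 <- matrix(stats::runif(3 * 128), 3, 128)
  sel3 <- select_salient(rank_neighborhoods(S3), g3, fragments = FALSE)
  expect_length(sel3, 3)
  sel1 <- select_salient(rank_neighborhoods(S3), g3, k_max = 1,
                         fragments = FALSE)
  expect_length(sel1, 1)
  expect_equal(sel1[[1]]$center, rank_neighborhoods(S3)$center[1])
  expect_length(select_salient(rank_neighborhoods(matrix(0, 3, 128)), g3),
                0)
})

test_that("top-m per column credits deeper contributors", {
  S <- rbind(c(3, 3), c(2, 2), c(1, 1))
  c1 <- rank_neighborhoods(S, top_m = 1)
  expect_equal(c1$center, 1)
  c2 <- rank_neighborhoods(S, top_m = 2)
  expect_setequal(c2$center, c(1, 2))
  expect_equal(sum(c2$frequency), 4)  # 2 columns x top-2
})

test_that("explain composes encode, rank and select deterministically", {
  fx <- fixture_model()
  g <- fx$graphs[[which(fx$dataset$label == 1)[1]]]
  ex1 <- explain(fx$model, g)
  ex2 <- explain(fx$model, g)
  expect_lte(length(ex1$neighborhoods), 5)
  expect_identical(vapply(ex1$neighborhoods, `[[`, integer(1), "center"),
                   vapply(ex2$neighborhoods, `[[`, integer(1), "center"))
  expect_equal(ex1$o, ex2$o)
  # fragments are canonical SMILES of radius-3 balls around the centers
  nb <- ex1$neighborhoods[[1]]
  expect_equal(nb$neighborhood$members,
               atom_neighborhood(g, nb$center, fragment = FALSE)$members)
  expect_true(nzchar(nb$neighborhood$fragment_smiles))
})

test_that("salient centers recover the planted motif on true positives", {
  # single-seed spot check; the full 5-seed contract runs in acceptance
  fx <- fixture_model()
  te <- test_ids(fx$split)
  o <- predict_gcnn(fx$model, fx$graphs[te])
  labs <- fx$dataset$label[match(te, fx$dataset$id)]
  tp <- te[assign_quadrant(labs, o) == "TP"]
  expect_gt(length(tp), 5)
  mg <- fx$spec$motif_graph
  hits <- vapply(tp, function(id) {
    g <- fx$graphs[[id]]
    ex <- explain(fx$model, g, fragments = FALSE)
    matoms <- unique(unlist(motif_matches(g, mg)))
    any(vapply(ex$neighborhoods, `[[`, integer(1), "center") %in% matoms)
  }, logical(1))
  expect_gte(mean(hits), 0.7)
})

test_that("saliency JSON uses 0-based indices and the documented layout", {
  fx <- fixture_model()
  g <- fx$graphs[[1]]
  ex <- list(MOL1 = explain(fx$model, g))
  path <- tempfile(fileext = ".json")
  write_saliency_json(ex, path)
  j <- jsonlite::read_json(path)
  expect_equal(j[[1]]$molecule_id, "MOL1")
  nb <- j[[1]]$neighborhoods[[1]]
  expect_equal(nb$center, ex$MOL1$neighborhoods[[1]]$center - 1L)
  expect_true(all(unlist(nb$member_atoms) >= 0))
})
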