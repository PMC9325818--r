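# Confusion quadrants and substructural clustering.

test_that("quadrant assignment follows the l/o table with o=0.5 negative", {
  expect_equal(assign_quadrant(1, 0.7), "TP")
  expect_equal(assign_quadrant(0, 0.7), "FP")
  expect_equal(assign_quadrant(1, 0.3), "FN")
  expect_equal(assign_quadrant(0, 0.3), "TN")
  expect_equal(assign_quadrant(1, 0.5), "FN")  # boundary rule
  expect_equal(assign_quadrant(0, 0.5), "TN")
  expect_error(assign_quadrant(2, 0.5), "0/1")
  # counts always partition the evaluation set
  set.seed(61)
  l <- sample(0:1, 50, replace = TRUE)
  o <- runif(50)
  q <- assign_quadrant(l, o)
  expect_equal(sum(table(q)), 50)
})

test_that("DPC separates well-separated groups and collapses identical points", {
  grp <- c(lapply(1:5, function(i) bitfp(1:4, 16)),
           lapply(1:5, function(i) bitfp(9:12, 16)))
  res <- dpc_cluster(grp, d_c = 0.5)
  expect_length(res$centers, 2)
  expect_equal(length(unique(res$assignment[1:5])), 1)
  expect_equal(length(unique(res$assignment[6:10])), 1)
  expect_false(res$assignment[1] == res$assignment[6])

  same <- lapply(1:6, function(i) bitfp(2:5, 16))
  res1 <- dpc_cluster(same, d_c = 0.5)
  expect_length(unique(res1$assignment), 1)
})

test_that("DPC matches the independent rho/delta/gamma recomputation", {
  set.seed(62)
  for (k in 1:50) {
    n <- 20
    pts <- matrix(runif(n * 2), n, 2)
    D <- as.matrix(stats::dist(pts))
    d_c <- stats::quantile(D[upper.tri(D)], 0.2)
    got <- dpc_cluster(dist_matrix = D, d_c = d_c)
    want <- dpc_oracle(D, d_c)
    expect_equal(got$rho, want$rho)
    expect_equal(got$delta, want$delta, tolerance = 1e-12)
    expect_equal(got$gamma, want$gamma, tolerance = 1e-12)
    # assignments: every non-center inherits its higher-density neighbor
    for (i in seq_len(n)) {
      if (!(i %in% got$centers)) {
        expect_equal(got$assignment[i], got$assignment[want$nn[i]])
      }
    }
  }
})

test_that("k-means fallback splits far-apart patterns and degenerates gracefully", {
  far <- c(lapply(1:5, function(i) bitfp(1:5, 32)),
           lapply(1:5, function(i) bitfp(20:24, 32)))
  res <- kmeans_fallback(far, seed = 3)
  expect_equal(length(unique(res$assignment)), 2)
  expect_equal(length(unique(res$assignment[1:5])), 1)
  expect_false(res$assignment[1] == res$assignment[10])

  two <- list(bitfp(1:3, 16), bitfp(8:10, 16))
  expect_setequal(kmeans_fallback(two)$assignment, c(1, 2))

  same <- lapply(1:4, function(i) bitfp(1:3, 16))
  expect_length(unique(kmeans_fallback(same)$assignment), 1)
  expect_length(kmeans_fallback(list(bitfp(1, 16)))$assignment, 1)
})

test_that("quadrant clustering partitions fragments and ranks by population", {
  fx <- fixture_model()
  res <- cached("analysis", substructure_analysis(
    fx$model, fx$dataset, fx$split, quadrants = c("TP", "TN")))
  expect_equal(sum(table(res$quadrant_of)), length(test_ids(fx$split)))
  tp <- res$clusters$TP
  expect_gt(length(tp), 0)
  pops <- vapply(tp, `[[`, integer(1), "population")
  expect_true(all(diff(pops) <= 0))  # ranked high to low
  expect_equal(vapply(tp, `[[`, integer(1), "rank"), seq_along(tp))
  # each fragment lands in exactly one cluster
  total <- sum(pops)
  n_frag <- sum(vapply(names(res$explanations), function(id)
    if (res$quadrant_of[id] == "TP")
      length(res$explanations[[id]]$neighborhoods) else 0L, integer(1)))
  expect_equal(total, n_frag)
})

test_that("sparse quadrants revert to the k-means fallback", {
  fx <- fixture_model()
  full <- cached("analysis", substructure_analysis(
    fx$model, fx$dataset, fx$split, quadrants = c("TP", "TN")))
  ids <- names(full$explanations)[full$quadrant_of == "TP"][1]
  # a single molecule contributes < 8 fragments -> k-means path
  cl <- cluster_quadrant(full$explanations[ids],
                         full$quadrant_of[ids], quadrant = "TP")
  expect_true(all(vapply(cl, `[[`, character(1), "method") == "kmeans"))
  expect_lte(length(cl), 2)
  # empty quadrant -> empty list
  expect_length(cluster_quadrant(full$explanations[ids],
                                 stats::setNames("FP", ids),
                                 quadrant = "TN"), 0)
})

test_that("two-motif actives produce fragment families that clusters separate", {
  res <- cached("two_motif_clusters", {
    spec <- generator_spec(n = 400, label_noise = 0, seed = 2101)
    ds <- two_motif_dataset(spec, motif_b = "C(=O)O")
    sp <- chronological_split(ds)
    graphs <- parse_smiles_batch(stats::setNames(ds$smiles, ds$id))
    tr <- training_ids(sp, "final")
    model <- train_gcnn(ds[match(tr, ds$id), ],
                        gcnn_preset("optimized", epochs = 25, seed = 5),
                        graphs = graphs)
    an <- substructure_analysis(model, ds, sp, quadrants = "TP",
                                graphs = graphs)
    list(ds = ds, an = an)
  })
  tp <- res$an$clusters$TP
  expect_gte(length(tp), 2)
  # purity of the top-2 clusters w.r.t. which motif the molecule carries
  motif_of <- stats::setNames(res$ds$motif_planted, res$ds$id)
  purity <- vapply(tp[1:2], function(cl) {
    fam <- motif_of[cl$members$molecule_id]
    max(table(fam)) / length(fam)
  }, numeric(1))
  expect_gte(mean(purity), 0.75)
})
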