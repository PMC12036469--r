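test_that("silhouette matches the hand example and the reference oracle", {
  pts <- matrix(c(0, 0.1, 10, 10.1))
  labs <- c(1, 1, 2, 2)
  s <- silhouette_score(pts, labs)
  ref <- mean(cluster::silhouette(labs, dist(pts))[, "sil_width"])
  expect_equal(s, ref, tolerance = 1e-12)
  expect_gt(s, 0.98)
})

test_that("silhouette conventions handle degenerate partitions", {
  # two identical + two identical points: zero within-cluster distance
  pts <- matrix(c(0, 0, 5, 5))
  expect_equal(silhouette_score(pts, c(1, 1, 2, 2)), 1)
  # single cluster scores 0
  expect_equal(silhouette_score(matrix(1:4), rep(1, 4)), 0)
})

test_that("k-means on a separated projection recovers planted regimes", {
  rg <- make_regime_embeddings(c(0, 10), per_regime = 10, seed = 2)
  proj <- project_samples(rg$embeddings, "energy")
  sol <- cluster_k(proj, 2, seed = 5)
  expect_equal(ari(sol$assignment$cluster, rg$truth), 1.0)
  # determinism
  sol2 <- cluster_k(proj, 2, seed = 5)
  expect_identical(sol$assignment, sol2$assignment)
  expect_error(cluster_k(proj, 25, seed = 1), "k")
})

test_that("identical points collapse to one effective cluster", {
  embs <- rep(list(matrix(rep(1, 10), 1)), 5)
  proj <- project_samples(embs, "energy")
  sol <- cluster_k(proj, 2, seed = 1)
  expect_equal(length(unique(sol$assignment$cluster)), 1)
  expect_equal(sol$silhouette, 0)
})

test_that("silhouette-by-k peaks at the planted number of regimes", {
  rg <- make_regime_embeddings(c(0, 8, 20), per_regime = 8, seed = 3)
  proj <- project_samples(rg$embeddings, "energy")
  tbl <- silhouette_by_k(proj, 2:6, seed = 4)
  expect_equal(tbl$k[which.max(tbl$silhouette)], 3L)
  expect_error(silhouette_by_k(proj, integer(0)), "non-empty")
})

test_that("consensus on perfectly separated data is exactly 0/1", {
  rg <- make_regime_embeddings(c(0, 12), per_regime = 10, seed = 6)
  proj <- project_samples(rg$embeddings, "energy")
  cm <- consensus_analysis(proj, 2, n_iterations = 50, seed = 7)
  sampled <- cm$co_occurrence_counts > 0
  same <- outer(rg$truth, rg$truth, "==")
  expect_true(all(cm$values[sampled & same] == 1))
  expect_true(all(cm$values[sampled & !same] == 0))
  expect_true(all(cm$values >= 0 & cm$values <= 1))
  expect_setequal(cm$order, seq_len(20))
  expect_error(consensus_analysis(proj, 2, subsample_fraction = 1.4),
               "subsample_fraction")
})

test_that("never co-sampled pairs are flagged by a zero count", {
  rg <- make_regime_embeddings(c(0, 12), per_regime = 3, seed = 8)
  proj <- project_samples(rg$embeddings, "energy")
  cm <- consensus_analysis(proj, 2, n_iterations = 1,
                           subsample_fraction = 0.5, seed = 2)
  expect_true(any(cm$co_occurrence_counts == 0))
  expect_true(all(cm$values[cm$co_occurrence_counts == 0] == 0))
})

test_that("risk groups order clusters by crude mortality, ties by id", {
  sol <- structure(list(k = 3L,
                        assignment = tibble::tibble(
                          id = sprintf("S%02d", 1:30),
                          cluster = rep(c(1L, 2L, 3L), each = 10)),
                        silhouette = 0.5, seed = 1L),
                   class = "cluster_solution")
  # cluster rates: 1 -> 0.05, 2 -> 0.01, 3 -> 0.02 deaths per person-year
  subjects <- tibble::tibble(
    id = sprintf("S%02d", 1:30),
    time_years = rep(10, 30),
    event = c(rep(c(1, 0), c(5, 5)), rep(c(1, 0), c(1, 9)),
              rep(c(1, 0), c(2, 8))))
  lab <- label_risk_groups(sol, subjects)
  got <- lab$risk_labels$risk_group[order(lab$risk_labels$cluster)]
  expect_equal(as.character(got), c("RG3", "RG1", "RG2"))
  # all equal rates: labels follow cluster id order
  subjects$event <- rep(c(1, 0), 15)
  lab2 <- label_risk_groups(sol, subjects)
  got2 <- lab2$risk_labels$risk_group[order(lab2$risk_labels$cluster)]
  expect_equal(as.character(got2), c("RG1", "RG2", "RG3"))
  expect_error(label_risk_groups(sol, subjects[1:5, ]), "missing outcome")
})

test_that("planted hazard gradients are recovered in at least 95% of seeds", {
  hit <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 80
    sol <- structure(list(k = 3L,
                          assignment = tibble::tibble(
                            id = as.character(1:(3 * n)),
                            cluster = rep(1:3, each = n)),
                          silhouette = 0, seed = 1L),
                     class = "cluster_solution")
    haz <- c(0.01, 0.04, 0.15)[rep(1:3, each = n)]
    t_death <- rexp(3 * n, haz)
    subjects <- tibble::tibble(id = as.character(1:(3 * n)),
                               time_years = pmin(t_death, 12),
                               event = as.integer(t_death <= 12))
    lab <- label_risk_groups(sol, subjects)
    identical(as.character(lab$risk_labels$risk_group[
      order(lab$risk_labels$cluster)]), c("RG1", "RG2", "RG3"))
  }, TRUE)
  expect_gte(mean(hit), 0.95)
})

test_that("cross-solution flows conserve cluster sizes", {
  a <- structure(list(k = 2L, assignment = tibble::tibble(
    id = as.character(1:12), cluster = rep(1:2, each = 6)),
    silhouette = 0, seed = 1L), class = "cluster_solution")
  b <- a
  fl <- cross_solution_flow(list(a, b))
  expect_true(all(fl$from == fl$to))
  expect_equal(sum(fl$n), 12)
  # nested refinement: each coarse cluster's outflow sums to its size
  c4 <- structure(list(k = 4L, assignment = tibble::tibble(
    id = as.character(1:12), cluster = rep(1:4, each = 3)),
    silhouette = 0, seed = 1L), class = "cluster_solution")
  fl2 <- cross_solution_flow(list(a, c4))
  out1 <- sum(fl2$n[fl2$from == "1"])
  expect_equal(out1, 6)
  bad <- structure(list(k = 2L, assignment = tibble::tibble(
    id = as.character(2:13), cluster = rep(1:2, each = 6)),
    silhouette = 0, seed = 1L), class = "cluster_solution")
  expect_error(cross_solution_flow(list(a, bad)), "differ")
})

test_that("a high-risk regime concentrates in one coarse cluster", {
  rg <- make_regime_embeddings(c(0, 3, 6, 9, 30), per_regime = 8, seed = 9)
  proj <- project_samples(rg$embeddings, "energy")
  sol2 <- cluster_k(proj, 2, seed = 3)
  hi <- sol2$assignment$cluster[rg$truth == 5]
  expect_gte(max(table(hi)) / length(hi), 0.8)
})
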