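#' Mean silhouette score of a partition
#'
#' Per point, `s = (b - a) / max(a, b)` where `a` is the mean distance to the
#' point's own cluster (excluding itself) and `b` the smallest mean distance
#' to another cluster. Conventions: singleton clusters score 0; when both
#' `a` and `b` are 0 the point scores 0; a single-cluster partition scores 0.
#'
#' @param x Feature matrix (rows = samples) or a `dist` object.
#' @param labels Integer/factor cluster assignment.
#' @return Mean silhouette over points.
#' @export
silhouette_score <- function(x, labels) {
  d <- if (inherits(x, "dist")) as.matrix(x) else as.matrix(dist(x))
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) return(0)
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- sum(d[i, own]) / (sum(own) - 1)
    b <- min(vapply(setdiff(seq_len(k), labels[i]), function(g) {
      mean(d[i, labels == g])
    }, 0))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# k-means with k-means++ seeding: each restart picks centers by the
# spreading heuristic (next center with probability proportional to squared
# distance from the nearest chosen center); best inertia kept.
kmeans_pp <- function(x, k, nstart = 10, iter_max = 300) {
  n <- nrow(x)
  best <- NULL
  for (s in seq_len(nstart)) {
    centers <- matrix(0, k, ncol(x))
    ci <- sample.int(n, 1)
    centers[1, ] <- x[ci, ]
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    for (j in seq_len(k - 1) + 1) {
      if (sum(d2) == 0) {
        ci <- sample.int(n, 1)
      } else {
        ci <- sample.int(n, 1, prob = d2)
      }
      centers[j, ] <- x[ci, ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
    fit <- suppressWarnings(kmeans(x, centers = centers, iter.max = iter_max))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' k-means on distance-projection feature vectors
#'
#' Runs k-means (Euclidean, multiple restarts, best inertia kept) on the rows
#' of the projection matrix and computes the partition's mean silhouette on
#' the same feature vectors. If the projection has fewer distinct rows than
#' `k`, the distinct rows define the clusters (silhouette 0 when only one
#' distinct point exists).
#'
#' @param projection A [project_samples()] result.
#' @param k Number of clusters, `2 <= k < N`.
#' @param seed Integer seed (restart initializations are seeded).
#' @param nstart Random restarts.
#' @param iter_max Iteration cap per restart.
#' @return An object of class `cluster_solution`: list with `k`,
#'   `assignment` (tibble `id`, `cluster`), `silhouette`, `seed`.
#' @export
cluster_k <- function(projection, k, seed = 1L, nstart = 10, iter_max = 300) {
  assert_that(inherits(projection, "distance_projection"),
              "`projection` must be a distance_projection")
  m <- projection$matrix
  n <- nrow(m)
  assert_that(k >= 2 && k < n, "`k` must satisfy 2 <= k < N")
  n_distinct <- nrow(unique(m))
  set.seed(seed)
  if (n_distinct < k) {
    cl <- as.integer(factor(apply(m, 1, paste, collapse = ",")))
    sil <- if (n_distinct == 1) 0 else silhouette_score(m, cl)
  } else {
    fit <- kmeans_pp(m, k, nstart = nstart, iter_max = iter_max)
    cl <- fit$cluster
    sil <- silhouette_score(m, cl)
  }
  structure(list(k = as.integer(k),
                 assignment = tibble(id = projection$ids, cluster = cl),
                 risk_labels = NULL,
                 silhouette = sil,
                 seed = as.integer(seed)),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("<cluster_solution> k = ", x$k, ", silhouette = ",
      signif(x$silhouette, 4), "\n", sep = "")
  tab <- table(x$assignment$risk_group %||% x$assignment$cluster)
  print(tab)
  invisible(x)
}

#' Mean silhouette across a range of k
#'
#' @param projection A [project_samples()] result.
#' @param k_range Integer vector of candidate k values.
#' @param seed Seed forwarded to [cluster_k()].
#' @return Tibble with columns `k`, `silhouette`.
#' @export
silhouette_by_k <- function(projection, k_range = 2:6, seed = 1L) {
  assert_that(length(k_range) > 0, "`k_range` must be non-empty")
  tibble(k = as.integer(k_range),
         silhouette = vapply(k_range, function(k) {
           cluster_k(projection, k, seed = seed)$silhouette
         }, 0))
}

#' Consensus matrix from subsampled clustering
#'
#' Repeatedly subsamples a fraction of samples and of feature columns,
#' reruns k-means, and records for each sample pair the proportion of
#' co-sampled iterations in which the pair landed in the same cluster.
#' Pairs never co-sampled have value 0 and count 0 (flagged by the count
#' matrix). Also returns the Ward ordering of the consensus matrix for
#' heatmap rendering.
#'
#' @param projection A [project_samples()] result.
#' @param k Number of clusters per iteration.
#' @param n_iterations Subsampling iterations.
#' @param subsample_fraction Fraction of samples and of features drawn
#'   without replacement each iteration, in (0, 1].
#' @param seed Integer seed.
#' @param nstart k-means restarts per iteration.
#' @return An object of class `consensus_matrix`: list with `values` (N x N
#'   in [0,1]), `co_occurrence_counts`, `order` (Ward permutation), `k`,
#'   `n_iterations`, `subsample_fraction`.
#' @export
consensus_analysis <- function(projection, k, n_iterations = 100,
                               subsample_fraction = 0.8, seed = 1L,
                               nstart = 5) {
  assert_that(inherits(projection, "distance_projection"),
              "`projection` must be a distance_projection")
  assert_that(subsample_fraction > 0 && subsample_fraction <= 1,
              "`subsample_fraction` must be in (0, 1]")
  m <- projection$matrix
  n <- nrow(m)
  ns <- max(2L, floor(subsample_fraction * n))
  nf <- max(1L, floor(subsample_fraction * n))
  assert_that(ns >= k, "subsample too small for k clusters")
  co <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  set.seed(seed)
  for (it in seq_len(n_iterations)) {
    ii <- sort(sample.int(n, ns))
    jj <- sort(sample.int(n, nf))
    sub <- m[ii, jj, drop = FALSE]
    if (nrow(unique(sub)) < k) next
    cl <- kmeans_pp(sub, k, nstart = nstart, iter_max = 100)$cluster
    cnt[ii, ii] <- cnt[ii, ii] + 1
    same <- outer(cl, cl, "==")
    co[ii, ii] <- co[ii, ii] + same
  }
  values <- ifelse(cnt > 0, co / cnt, 0)
  ord <- hclust(as.dist(1 - values), method = "ward.D2")$order
  structure(list(values = values, co_occurrence_counts = cnt, order = ord,
                 ids = projection$ids, k = as.integer(k),
                 n_iterations = n_iterations,
                 subsample_fraction = subsample_fraction),
            class = "consensus_matrix")
}

#' Label clusters as ordinal risk groups
#'
#' Sorts clusters by crude all-cause mortality rate (events per person-year)
#' computed from the subject table, ascending, and labels them RG1 (lowest
#' risk) through RGk (highest). Ties break by cluster id.
#'
#' @param solution A [cluster_k()] result.
#' @param subjects Tibble with columns `id`, `time_years`, `event` covering
#'   every clustered sample.
#' @return The solution with `risk_labels` (tibble `cluster`, `risk_group`,
#'   `death_rate`) and a `risk_group` column added to the assignment.
#' @export
label_risk_groups <- function(solution, subjects) {
  assert_that(inherits(solution, "cluster_solution"),
              "`solution` must be a cluster_solution")
  missing_ids <- setdiff(solution$assignment$id, subjects$id)
  if (length(missing_ids) > 0) {
    abort(paste0("missing outcome data for: ",
                 paste(utils::head(missing_ids, 5), collapse = ", "),
                 if (length(missing_ids) > 5) " ..." else ""))
  }
  joined <- left_join(solution$assignment, subjects, by = "id")
  rates <- joined |>
    group_by(.data$cluster) |>
    summarise(death_rate = sum(.data$event) / sum(.data$time_years),
              .groups = "drop") |>
    arrange(.data$death_rate, .data$cluster) |>
    mutate(risk_group = factor(paste0("RG", dplyr::row_number()),
                               levels = paste0("RG", seq_len(n()))))
  solution$risk_labels <- rates
  solution$assignment <- left_join(solution$assignment,
                                   rates[, c("cluster", "risk_group")],
                                   by = "cluster")
  solution
}

#' Sample flow between successive cluster solutions
#'
#' For each adjacent pair of solutions (e.g. k = 2 and k = 3) counts how many
#' samples move from each source cluster to each target cluster — the data
#' behind a Sankey flow diagram.
#'
#' @param solutions List of [cluster_k()] results sharing the sample set.
#' @return Tibble with columns `from_k`, `to_k`, `from`, `to`, `n`.
#' @export
cross_solution_flow <- function(solutions) {
  assert_that(length(solutions) >= 2, "need at least two solutions")
  ids <- solutions[[1]]$assignment$id
  for (s in solutions[-1]) {
    assert_that(setequal(s$assignment$id, ids), "sample sets differ")
  }
  lab <- function(s) {
    a <- s$assignment
    v <- as.character(a$risk_group %||% a$cluster)
    setNames(v, a$id)
  }
  out <- vector("list", length(solutions) - 1)
  for (i in seq_len(length(solutions) - 1)) {
    f <- lab(solutions[[i]])[ids]
    t <- lab(solutions[[i + 1]])[ids]
    out[[i]] <- as_tibble(as.data.frame(table(from = f, to = t),
                                        stringsAsFactors = FALSE)) |>
      rename(n = "Freq") |>
      filter(.data$n > 0) |>
      mutate(from_k = solutions[[i]]$k, to_k = solutions[[i + 1]]$k,
             .before = 1)
  }
  bind_rows(out)
}
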