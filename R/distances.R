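#' Energy distance between two univariate samples
#'
#' `D = 2 E|X - Y| - E|X - X'| - E|Y - Y'|` with all expectations taken over
#' ordered pairs including self-pairs. Non-negative; zero exactly when the
#' two samples are identical multisets. Computed with the sorted-sample
#' O(n log n) identities.
#'
#' @param x,y Non-empty numeric vectors (sizes may differ).
#' @return Non-negative scalar.
#' @export
energy_distance <- function(x, y) {
  assert_that(length(x) > 0 && length(y) > 0, "samples must be non-empty")
  cpp_energy_distance(x, y)
}

#' 1-D earth mover's distance between two samples
#'
#' The L1 area between the empirical CDFs, `integral |F_x - F_y|`; handles
#' unequal sample sizes.
#'
#' @inheritParams energy_distance
#' @return Non-negative scalar.
#' @export
earth_mover_distance_1d <- function(x, y) {
  assert_that(length(x) > 0 && length(y) > 0, "samples must be non-empty")
  cpp_emd1d(x, y)
}

#' Distance between two embedding matrices
#'
#' Embedding matrices are `embed_dim x n_epochs` with per-recording epoch
#' counts. For each embedding dimension the two time series are compared as
#' distributions (so unequal epoch counts are fine) and the per-dimension
#' distances are averaged.
#'
#' @param a,b Embedding matrices sharing `embed_dim` rows.
#' @param metric `"energy"` or `"earth_mover"`.
#' @return Non-negative scalar.
#' @export
embedding_pair_distance <- function(a, b, metric = c("energy", "earth_mover")) {
  metric <- match.arg(metric)
  assert_that(nrow(a) == nrow(b), "embedding dimensions differ")
  cpp_embedding_pair_distance(a, b, metric)
}

#' Project samples onto pairwise distances
#'
#' Computes the full symmetric distance matrix between all embedding
#' matrices. Row i is sample i's feature vector for k-means: its distance to
#' every sample (the zero self-entry is retained).
#'
#' @param embeddings List of embedding matrices sharing `embed_dim`.
#' @param metric `"energy"` or `"earth_mover"`.
#' @param ids Sample identifiers; default from list names or indices.
#' @return An object of class `distance_projection`: list with `matrix`
#'   (N x N), `ids`, `metric`.
#' @export
project_samples <- function(embeddings, metric = c("energy", "earth_mover"),
                            ids = NULL) {
  metric <- match.arg(metric)
  assert_that(length(embeddings) >= 2, "need at least two samples")
  dims <- vapply(embeddings, nrow, 0L)
  assert_that(length(unique(dims)) == 1, "embedding dimensions differ")
  ids <- ids %||% names(embeddings) %||% as.character(seq_along(embeddings))
  m <- cpp_pairwise_embedding_distance(embeddings, metric)
  dimnames(m) <- list(ids, ids)
  structure(list(matrix = m, ids = ids, metric = metric),
            class = "distance_projection")
}

#' @export
print.distance_projection <- function(x, ...) {
  cat("<distance_projection> ", nrow(x$matrix), " samples, metric = ",
      x$metric, "\n", sep = "")
  invisible(x)
}
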