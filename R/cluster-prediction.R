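#' Predict cluster membership from standard summary metrics
#'
#' Trains a gradient-boosted tree classifier (xgboost) to predict cluster
#' membership from polysomnography summary metrics, ranks features by total
#' gain, and reports held-out accuracy using all features, the single
#' top-importance feature, and the top five. One report row per supplied
#' cluster solution.
#'
#' @param metrics Tibble of per-recording summary metrics (numeric feature
#'   columns are used).
#' @param labels Data frame (or named list) with one column of cluster
#'   labels per solution, rows aligned with `metrics`.
#' @param split_fraction Stratified train fraction (default 80/20).
#' @param seed Seed for the split and the booster.
#' @param nrounds,max_depth,eta Boosting hyperparameters (300 trees of depth
#'   4 at learning rate 0.1 by default).
#' @return An object of class `predictability_report`: tibble with one row
#'   per solution (`solution`, `k`, `accuracy_full`, `accuracy_top1`,
#'   `accuracy_top5`, `top_features` list-column), with the split spec and
#'   seed as attributes.
#' @export
predict_clusters_from_metrics <- function(metrics, labels,
                                          split_fraction = 0.8, seed = 1L,
                                          nrounds = 300, max_depth = 4,
                                          eta = 0.1) {
  feats <- metrics[vapply(metrics, is.numeric, TRUE)]
  feats <- feats[vapply(feats, function(x) !all(is.na(x)), TRUE)]
  x_all <- as.matrix(feats)
  labels <- as_tibble(as.data.frame(labels, optional = TRUE))
  assert_that(nrow(labels) == nrow(metrics),
              "`labels` rows must align with `metrics`")
  rows <- vector("list", ncol(labels))
  for (j in seq_len(ncol(labels))) {
    y <- factor(labels[[j]])
    assert_that(nlevels(y) >= 2, "need at least two classes")
    set.seed(seed)
    tr <- unlist(lapply(levels(y), function(lv) {
      ix <- which(y == lv)
      sample(ix, max(1, floor(split_fraction * length(ix))))
    }))
    te <- setdiff(seq_along(y), tr)
    if (nlevels(droplevels(y[tr])) < nlevels(y)) {
      abort("a class is missing from the training split; use a larger cohort")
    }
    fit_acc <- function(cols) {
      fit <- fit_booster(x_all[tr, cols, drop = FALSE],
                         as.integer(y[tr]) - 1L, nlevels(y),
                         seed, nrounds, max_depth, eta)
      pred <- predict_booster(fit, x_all[te, cols, drop = FALSE], nlevels(y))
      list(fit = fit, acc = mean(pred == (as.integer(y[te]) - 1L)))
    }
    full <- fit_acc(colnames(x_all))
    imp <- booster_importance(full$fit, colnames(x_all))
    top1 <- imp$feature[1]
    top5 <- imp$feature[seq_len(min(5, nrow(imp)))]
    rows[[j]] <- tibble(
      solution = names(labels)[j],
      k = nlevels(y),
      accuracy_full = full$acc,
      accuracy_top1 = fit_acc(top1)$acc,
      accuracy_top5 = fit_acc(top5)$acc,
      top_features = list(imp)
    )
  }
  structure(bind_rows(rows), class = c("predictability_report",
                                       class(bind_rows(rows))),
            split_fraction = split_fraction, seed = seed)
}

fit_booster <- function(x, y0, k, seed, nrounds, max_depth, eta) {
  params <- list(max_depth = max_depth, eta = eta, nthread = 1, seed = seed)
  if (k == 2) {
    params$objective <- "binary:logistic"
  } else {
    params$objective <- "multi:softprob"
    params$num_class <- k
  }
  dtrain <- xgboost::xgb.DMatrix(x, label = y0, nthread = 1)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                     verbose = 0)
}

predict_booster <- function(fit, x, k) {
  p <- predict(fit, xgboost::xgb.DMatrix(x, nthread = 1))
  if (k == 2) return(as.integer(p >= 0.5))
  max.col(matrix(p, ncol = k, byrow = TRUE)) - 1L
}

booster_importance <- function(fit, feature_names) {
  if (length(feature_names) == 1) {
    return(tibble(feature = feature_names, gain = 1))
  }
  imp <- xgboost::xgb.importance(model = fit)
  imp <- tibble(feature = imp$Feature, gain = imp$Gain)
  # features never used by a split carry zero gain
  unused <- setdiff(feature_names, imp$feature)
  if (length(unused) > 0) {
    imp <- bind_rows(imp, tibble(feature = unused, gain = 0))
  }
  arrange(imp, dplyr::desc(.data$gain))
}
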