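#' Plot a Ward-ordered consensus heatmap
#'
#' @param object A [consensus_analysis()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.consensus_matrix <- function(object, ...) {
  v <- object$values[object$order, object$order]
  df <- tidyr::expand_grid(row = seq_len(nrow(v)), col = seq_len(ncol(v)))
  df$consensus <- as.numeric(v)[(df$col - 1) * nrow(v) + df$row]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$consensus)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Consensus matrix, k = %d (%d iterations)",
                                  object$k, object$n_iterations)) +
    ggplot2::theme_minimal()
}

#' Plot mean silhouette against the number of clusters
#'
#' @param silhouettes A [silhouette_by_k()] tibble.
#' @return A ggplot object.
#' @export
plot_silhouette_by_k <- function(silhouettes) {
  ggplot2::ggplot(silhouettes, ggplot2::aes(x = .data$k,
                                            y = .data$silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of clusters k", y = "mean silhouette") +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves per risk group
#'
#' @param object A [km_disease_free_survival()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_summary <- function(object, ...) {
  sf <- object$fit
  df <- tibble(time = sf$time, surv = sf$surv,
               group = rep(sub("^group=", "", names(sf$strata)),
                           sf$strata))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "years since sleep study", y = "survival probability",
                  color = "risk group") +
    ggplot2::theme_minimal()
}

#' Forest plot of exposure hazard ratios
#'
#' @param object A [fit_cox_model()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cox_risk_fit <- function(object, ...) {
  tb <- object$hr_table[object$hr_table$is_exposure, ]
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$hr, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lower,
                                         xmax = .data$ci_upper),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "hazard ratio (95% CI)", y = NULL,
                  title = sprintf("Cox model %d", object$model_id)) +
    ggplot2::theme_minimal()
}

#' Plot sample flow between cluster solutions
#'
#' A tile rendering of the cross-solution flow table (the data behind a
#' Sankey diagram): one panel per adjacent pair of solutions.
#'
#' @param flow A [cross_solution_flow()] tibble.
#' @return A ggplot object.
#' @export
plot_cluster_flow <- function(flow) {
  flow$panel <- sprintf("k=%d → k=%d", flow$from_k, flow$to_k)
  ggplot2::ggplot(flow, ggplot2::aes(x = .data$to, y = .data$from,
                                     fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "white") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::scale_fill_gradient(low = "grey70", high = "darkred") +
    ggplot2::labs(x = "target cluster", y = "source cluster") +
    ggplot2::theme_minimal()
}
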