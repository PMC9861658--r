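# ggplot2 displays for the main result types.

#' @export
autoplot.lstm_model <- function(object, ...) {
  df <- dplyr::mutate(object$losses,
                      step = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "mini-batch", y = "masked NLL",
                  title = "LSTM training loss") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gain_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$iteration, y = .data$value,
                               color = .data$loss)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "iteration", y = "loss",
                  title = "GAIN training losses") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.federation_result <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(object$report, "round", "auprc", "auroc"),
    -"round", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$round, y = .data$value,
                                   color = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "federated round", y = "test-set value",
                  title = "Per-round global-model performance") +
    ggplot2::theme_minimal()
}

#' Precision-recall curve for a set of prediction traces
#'
#' @param traces Prediction tibble from [predict_cohort()].
#' @return A ggplot object.
#' @export
plot_pr_curve <- function(traces) {
  ord <- order(traces$episode_score, decreasing = TRUE)
  y <- as.logical(traces$label)[ord]
  tp <- cumsum(y)
  df <- tibble::tibble(
    recall = tp / sum(y),
    precision = tp / seq_along(y)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh", color = "firebrick") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision",
                  title = sprintf("PR curve (AUPRC = %.3f)",
                                  auprc(traces$episode_score, traces$label))) +
    ggplot2::theme_minimal()
}

#' Heatmap of one episode's window grid and observation mask
#'
#' @param grids Grid tibble.
#' @param episode_id Which episode to draw (default: the first).
#' @return A ggplot object; observed cells colored by value, missing cells
#'   greyed.
#' @export
plot_episode_grid <- function(grids, episode_id = grids$episode_id[1]) {
  i <- match(episode_id, grids$episode_id)
  if (is.na(i)) abort("episode not found.")
  v <- grids$values[[i]]; m <- grids$mask[[i]]
  df <- tibble::tibble(
    window = rep(seq_len(nrow(v)) - 1L, ncol(v)),
    channel = rep(colnames(v) %||% as.character(seq_len(ncol(v))),
                  each = nrow(v)),
    value = as.vector(ifelse(m == 1, v, NA))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window, y = .data$channel,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = "one-hour window", y = NULL,
                  title = paste("Care episode", episode_id)) +
    ggplot2::theme_minimal()
}
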