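#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a similarity matrix
#'
#' @param object A `similarity_matrix`.
#' @param ... Unused.
#' @return A ggplot object (tile heatmap in model order).
#' @method autoplot similarity_matrix
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  n <- object$n
  df <- tibble::tibble(
    i = rep(seq_len(n), times = n),
    j = rep(seq_len(n), each = n),
    score = as.vector(object$values)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "model", y = "model", fill = object$measure,
      title = sprintf("%s, %d models", object$measure, n)
    )
}

#' Cluster-size and criterion overview
#'
#' Bar chart of cluster sizes, coloured by the `<R>/f` selection criterion
#' (lower is better; the winning cluster supplies the representative).
#'
#' @param object A `decoy_clusters`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot decoy_clusters
#' @export
autoplot.decoy_clusters <- function(object, ...) {
  cl <- object$clusters
  ggplot2::ggplot(cl, ggplot2::aes(
    x = factor(.data$cluster), y = .data$size, fill = .data$criterion
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "cluster", y = "size", fill = "<R>/f",
      title = sprintf("%s clustering, k = %d", object$method, object$k)
    )
}

#' Reference-score profile along an ensemble
#'
#' @param scores Tibble from [vs_reference()] (`model_id`, `score`).
#' @param measure Label for the y axis.
#' @return A ggplot object (scores in ensemble order).
#' @export
plot_reference_scores <- function(scores, measure = "score") {
  df <- dplyr::mutate(scores, model = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "model (ensemble order)", y = measure)
}
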