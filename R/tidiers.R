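#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a clustering result
#'
#' @param x A `decoy_clusters` object.
#' @param ... Unused.
#' @return One row per cluster: `cluster`, `size`, `f`, `mean_r`,
#'   `criterion`, `representative`, `representative_id`.
#' @method tidy decoy_clusters
#' @export
tidy.decoy_clusters <- function(x, ...) {
  ids <- x$model_ids %||% as.character(seq_along(x$labels))
  dplyr::mutate(x$clusters, representative_id = ids[.data$representative])
}

#' One-row summary of a clustering result
#'
#' @inheritParams tidy.decoy_clusters
#' @return A one-row tibble: `method`, `k`, `n_models`, `best_cluster`
#'   (the min `<R>/f` winner), `best_criterion`.
#' @method glance decoy_clusters
#' @export
glance.decoy_clusters <- function(x, ...) {
  cl <- x$clusters[order(x$clusters$criterion, x$clusters$cluster), ]
  tibble::tibble(
    method = x$method, k = x$k, n_models = length(x$labels),
    best_cluster = cl$cluster[1], best_criterion = cl$criterion[1]
  )
}

#' Per-model view of a clustering result
#'
#' @inheritParams tidy.decoy_clusters
#' @return One row per model: `model`, `model_id`, `cluster`,
#'   `is_representative`.
#' @method augment decoy_clusters
#' @export
augment.decoy_clusters <- function(x, ...) {
  ids <- x$model_ids %||% as.character(seq_along(x$labels))
  tibble::tibble(
    model = seq_along(x$labels),
    model_id = ids,
    cluster = x$labels,
    is_representative = seq_along(x$labels) %in% x$clusters$representative
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tidy a similarity matrix into its unordered pairs
#'
#' @param x A `similarity_matrix`.
#' @param ... Unused.
#' @return The [matrix_pairs()] tibble.
#' @method tidy similarity_matrix
#' @export
tidy.similarity_matrix <- function(x, ...) matrix_pairs(x)

#' @rdname tidy.similarity_matrix
#' @method glance similarity_matrix
#' @export
glance.similarity_matrix <- function(x, ...) {
  pr <- matrix_pairs(x)
  tibble::tibble(
    measure = x$measure, n_models = x$n,
    n_pairs = nrow(pr),
    min_score = if (nrow(pr)) min(pr$score) else NA_real_,
    mean_score = if (nrow(pr)) mean(pr$score) else NA_real_,
    max_score = if (nrow(pr)) max(pr$score) else NA_real_
  )
}
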