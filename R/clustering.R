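#' Per-cluster statistics and representative models
#'
#' Given a hard partition and the corresponding dissimilarity matrix, each
#' cluster is summarised by its size, its fraction `f = size / N` of the
#' ensemble, its mean internal distance `<R>` (the average over unordered
#' within-cluster pairs; 0 for singletons by convention), the selection
#' criterion `<R> / f`, and a representative model: the cluster medoid
#' (member minimising mean distance to its co-members, lowest index on
#' ties).
#'
#' @param labels Integer cluster label per model (values in `1:k`).
#' @param distances A dissimilarity `similarity_matrix` (zero diagonal).
#' @param method Name of the clustering method, recorded on the result.
#' @return An object of class `decoy_clusters`: list with `labels`, `k`,
#'   `method` and a per-cluster tibble `clusters` (columns `cluster`,
#'   `size`, `f`, `mean_r`, `criterion`, `representative`).
#' @export
cluster_stats <- function(labels, distances, method = "manual") {
  check_distance_matrix(distances)
  labels <- as.integer(labels)
  n <- distances$n
  if (length(labels) != n) stop("one label per model required", call. = FALSE)
  ks <- sort(unique(labels))
  d <- distances$values
  rows <- lapply(ks, function(k) {
    members <- which(labels == k)
    sz <- length(members)
    if (sz == 1L) {
      mean_r <- 0
      rep_idx <- members
    } else {
      sub <- d[members, members, drop = FALSE]
      mean_r <- sum(sub[upper.tri(sub)]) / (sz * (sz - 1) / 2)
      # medoid: minimum mean distance to co-members, first index on ties
      rep_idx <- members[which.min(rowSums(sub) / (sz - 1))]
    }
    f <- sz / n
    tibble::tibble(
      cluster = k, size = sz, f = f, mean_r = mean_r,
      criterion = mean_r / f, representative = rep_idx
    )
  })
  structure(
    list(
      labels = labels, k = length(ks), method = method,
      clusters = dplyr::bind_rows(rows),
      model_ids = colnames(d)
    ),
    class = "decoy_clusters"
  )
}

check_distance_matrix <- function(distances) {
  if (!inherits(distances, "similarity_matrix")) {
    stop("`distances` must be a similarity_matrix", call. = FALSE)
  }
  if (any(diag(distances$values) != 0)) {
    stop("matrix has a non-zero diagonal; convert similarities with to_distance()",
      call. = FALSE)
  }
  invisible(distances)
}

#' @export
print.decoy_clusters <- function(x, ...) {
  cat(sprintf("<decoy_clusters> %s, k = %d, N = %d\n", x$method, x$k, length(x$labels)))
  print(x$clusters)
  invisible(x)
}

#' Hierarchical agglomerative clustering of a distance matrix
#'
#' Standard agglomerative merging under single, maximum (complete) or
#' average linkage (via [stats::hclust()]), with the tree cut to exactly
#' `k` clusters.
#'
#' @param distances A dissimilarity `similarity_matrix` (zero diagonal; use
#'   [to_distance()] on similarity measures first).
#' @param linkage `"single"`, `"maximum"` or `"average"`.
#' @param k Number of clusters, `1 <= k <= N`.
#' @return A `decoy_clusters` object (see [cluster_stats()]).
#' @export
hierarchical_cluster <- function(distances, linkage = c("single", "maximum", "average"), k) {
  linkage <- match.arg(linkage)
  check_distance_matrix(distances)
  n <- distances$n
  k <- as.integer(k)
  if (k < 1L || k > n) stop(sprintf("k must be in 1..%d", n), call. = FALSE)
  hc_method <- c(single = "single", maximum = "complete", average = "average")[[linkage]]
  hc <- stats::hclust(stats::as.dist(distances$values), method = hc_method)
  labels <- stats::cutree(hc, k = k)
  res <- cluster_stats(as.integer(labels), distances, method = linkage)
  res$hclust <- hc
  res
}

#' K-means clustering of a distance matrix
#'
#' Each model is embedded as its row of the dissimilarity matrix (its
#' vector of distances to every model), and Lloyd's algorithm is run from
#' seeded random initial centres, keeping the best of `restarts` runs by
#' within-cluster sum of squares. Identical seed and inputs give identical
#' labels.
#'
#' @inheritParams hierarchical_cluster
#' @param seed Integer RNG seed for the initial centres.
#' @param restarts Number of random restarts (default 10).
#' @param max_iterations Lloyd iteration cap per restart (default 300).
#' @return A `decoy_clusters` object; `$wcss` carries the winning
#'   within-cluster sum of squares.
#' @export
kmeans_cluster <- function(distances, k, seed = 1L, restarts = 10L,
                           max_iterations = 300L) {
  check_distance_matrix(distances)
  n <- distances$n
  k <- as.integer(k)
  if (k < 1L || k > n) stop(sprintf("k must be in 1..%d", n), call. = FALSE)
  features <- distances$values
  km <- with_seed(seed, suppressWarnings(
    stats::kmeans(features, centers = k, nstart = restarts,
      iter.max = max_iterations, algorithm = "Lloyd")
  ))
  res <- cluster_stats(as.integer(km$cluster), distances, method = "kmeans")
  res$wcss <- km$tot.withinss
  res
}

#' Select the overall representative model
#'
#' The winning cluster minimises `<R> / f` -- favouring large, tight
#' clusters (ties broken by lowest cluster label); the model returned is
#' that cluster's medoid.
#'
#' @param result A `decoy_clusters` object.
#' @param distances The dissimilarity matrix the clustering was computed on.
#' @return Integer model index of the representative.
#' @export
select_representative <- function(result, distances) {
  if (!inherits(result, "decoy_clusters") || !nrow(result$clusters)) {
    stop("`result` must be a non-empty decoy_clusters object", call. = FALSE)
  }
  check_distance_matrix(distances)
  cl <- result$clusters
  win <- cl[order(cl$criterion, cl$cluster), ][1, ]
  as.integer(win$representative)
}

#' Write a plain-text cluster report (plus a CSV companion)
#'
#' One block per cluster with size, fraction, mean internal distance,
#' selection criterion and representative, followed by member ids; a
#' machine-readable CSV of the per-cluster table is written alongside
#' (path suffixed `.csv`).
#'
#' @param result A `decoy_clusters`.
#' @param path Output path for the text report.
#' @return Invisibly, the report path.
#' @export
write_cluster_report <- function(result, path) {
  ids <- result$model_ids
  if (is.null(ids)) ids <- as.character(seq_along(result$labels))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# method=%s k=%d n_models=%d", result$method, result$k,
    length(result$labels)), con)
  for (r in seq_len(nrow(result$clusters))) {
    cl <- result$clusters[r, ]
    writeLines(sprintf(
      "cluster %d size=%d f=%.4f <R>=%.3f <R>/f=%.3f representative=%s",
      cl$cluster, cl$size, cl$f, cl$mean_r, cl$criterion, ids[cl$representative]
    ), con)
    writeLines(paste(" ", ids[result$labels == cl$cluster]), con)
  }
  utils::write.csv(result$clusters, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}
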