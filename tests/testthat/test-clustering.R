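planted_distances <- function(sizes = c(8, 8, 8), seed = 1) {
  de <- make_decoy_ensemble(decoy_recipe(per_cluster_sizes = sizes, seed = seed))
  list(d = all_vs_all(de$ensemble, "rmsd"), labels = de$labels)
}

test_that("all three linkages recover a well-separated planted partition", {
  pl <- planted_distances()
  for (link in c("single", "maximum", "average")) {
    res <- hierarchical_cluster(pl$d, link, 3)
    expect_true(same_partition(res$labels, pl$labels), label = link)
    expect_equal(sum(res$clusters$size), 24)
    expect_equal(res$clusters$f, res$clusters$size / 24)
  }
})

test_that("k = N gives all singletons with <R> = 0", {
  pl <- planted_distances(c(4, 4))
  res <- hierarchical_cluster(pl$d, "average", 8)
  expect_equal(sort(unique(res$labels)), 1:8)
  expect_equal(res$clusters$mean_r, rep(0, 8))
  expect_equal(res$clusters$representative, 1:8)
})

test_that("single linkage equals the MST-cut oracle on small matrices", {
  skip_if_not_installed("igraph")
  set.seed(17)
  for (i in 1:5) {
    n <- sample(6:20, 1)
    pts <- matrix(rnorm(2 * n), ncol = 2)
    dm <- as.matrix(dist(pts))
    dimnames(dm) <- list(as.character(1:n), as.character(1:n))
    m <- decoyclust:::new_similarity_matrix(dm, "rmsd", 0)
    for (k in c(2, 3, 4)) {
      ours <- hierarchical_cluster(m, "single", k)$labels
      mst <- oracle_single_linkage(dm, k)
      expect_true(same_partition(ours, mst), label = sprintf("n=%d k=%d", n, k))
    }
  }
})

test_that("hierarchical partitions are invariant under model permutation", {
  pl <- planted_distances(c(6, 6, 6), seed = 3)
  set.seed(5)
  perm <- sample(18)
  vals <- pl$d$values[perm, perm]
  mp <- decoyclust:::new_similarity_matrix(vals, "rmsd", 0)
  for (link in c("single", "maximum", "average")) {
    orig <- hierarchical_cluster(pl$d, link, 3)$labels
    permuted <- hierarchical_cluster(mp, link, 3)$labels
    expect_true(same_partition(orig[perm], permuted), label = link)
  }
})

test_that("K-means recovers planted blobs, is seeded-deterministic, improves with restarts", {
  skip_if_not_installed("mclust")
  pl <- planted_distances(seed = 2)
  res <- kmeans_cluster(pl$d, 3, seed = 11, restarts = 10)
  expect_equal(mclust::adjustedRandIndex(res$labels, pl$labels), 1)

  res2 <- kmeans_cluster(pl$d, 3, seed = 11, restarts = 10)
  expect_identical(res$labels, res2$labels)

  one <- kmeans_cluster(pl$d, 1, seed = 99)
  expect_equal(unique(one$labels), 1L)

  # best-of-restarts objective can only improve with more restarts
  wcss1 <- kmeans_cluster(pl$d, 4, seed = 21, restarts = 1)$wcss
  wcss10 <- kmeans_cluster(pl$d, 4, seed = 21, restarts = 10)$wcss
  expect_lte(wcss10, wcss1 + 1e-9)

  expect_error(kmeans_cluster(pl$d, 25), "k must be")
})

test_that("clustering rejects a similarity matrix that was not converted", {
  ens <- make_decoy_ensemble(decoy_recipe(per_cluster_sizes = c(4, 4)))$ensemble
  mt <- all_vs_all(ens, "tm")
  expect_error(hierarchical_cluster(mt, "single", 2), "to_distance")
  expect_silent(hierarchical_cluster(to_distance(mt), "single", 2))
})

test_that("min(<R>/f) picks the large tight cluster and the medoid is deterministic", {
  # 50-member tight cluster (within ~0.5) vs 10-member loose one (within ~5)
  set.seed(23)
  n <- 60
  d <- matrix(0, n, n)
  tight <- 1:50
  loose <- 51:60
  fill <- function(idx, scale) {
    for (i in idx) for (j in idx) if (i < j) {
      v <- scale * runif(1, 0.8, 1.2)
      d[i, j] <<- v; d[j, i] <<- v
    }
  }
  fill(tight, 0.5); fill(loose, 5)
  d[tight, loose] <- 20; d[loose, tight] <- 20
  dimnames(d) <- list(sprintf("m%d", 1:n), sprintf("m%d", 1:n))
  m <- decoyclust:::new_similarity_matrix(d, "rmsd", 0)
  labels <- rep(c(1L, 2L), c(50, 10))
  res <- cluster_stats(labels, m)

  cl <- res$clusters
  expect_equal(cl$criterion, cl$mean_r / cl$f)
  expect_lt(cl$criterion[1], 1) # ~0.5 / (50/60)
  expect_gt(cl$criterion[2], 10) # ~5 / (10/60)
  rep_idx <- select_representative(res, m)
  expect_true(rep_idx %in% tight)
  sub <- d[tight, tight]
  expect_equal(rep_idx, tight[which.min(rowSums(sub))])
  expect_identical(rep_idx, select_representative(res, m))
})

test_that("all-singleton partitions fall back to the lowest-index winner", {
  pl <- planted_distances(c(3, 3))
  res <- hierarchical_cluster(pl$d, "single", 6)
  expect_equal(res$clusters$criterion, rep(0, 6))
  expect_equal(select_representative(res, pl$d), 1L)
})

test_that("k = 1 returns the medoid of the whole ensemble", {
  pl <- planted_distances(c(5, 5))
  res <- hierarchical_cluster(pl$d, "average", 1)
  expected <- which.min(rowSums(pl$d$values))
  expect_equal(select_representative(res, pl$d), as.integer(expected))
})

test_that("tidiers summarise clusterings consistently", {
  pl <- planted_distances(seed = 4)
  res <- hierarchical_cluster(pl$d, "average", 3)
  td <- tidy(res)
  expect_equal(nrow(td), 3)
  expect_true(all(td$representative_id %in% model_ids(
    make_decoy_ensemble(decoy_recipe(per_cluster_sizes = c(8, 8, 8), seed = 4))$ensemble)))
  gl <- glance(res)
  expect_equal(gl$k, 3)
  expect_equal(gl$best_criterion, min(td$criterion))
  au <- augment(res)
  expect_equal(nrow(au), 24)
  expect_equal(sum(au$is_representative), 3)

  path <- withr::local_tempfile()
  write_cluster_report(res, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".csv")))
  expect_equal(nrow(read.csv(paste0(path, ".csv"))), 3)
})
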