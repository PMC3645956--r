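# Independent oracles, deliberately built without touching the package's
# closed-form cRMSD path or the fragment-search internals.

# Kabsch-SVD RMSD with reflection correction: explicit optimal rotation,
# then plain per-atom RMSD of the transformed coordinates.
oracle_crmsd <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  C <- t(Bc) %*% Ac
  s <- svd(C)
  d <- sign(det(s$v) * det(s$u))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Brot <- Bc %*% t(R)
  sqrt(mean(rowSums((Brot - Ac)^2)))
}

# Superimpose B onto A on the atom subset `idx`, return transformed full B.
oracle_superpose <- function(A, B, idx) {
  Ai <- A[idx, , drop = FALSE]
  Bi <- B[idx, , drop = FALSE]
  ca <- colMeans(Ai); cb <- colMeans(Bi)
  C <- t(sweep(Bi, 2, cb)) %*% sweep(Ai, 2, ca)
  s <- svd(C)
  d <- sign(det(s$v) * det(s$u))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(sweep(B, 2, cb) %*% t(R), 2, ca, "+")
}

# Explicit O(N^2) double-loop dRMSD.
oracle_drmsd <- function(A, B) {
  n <- nrow(A)
  acc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      da <- sqrt(sum((A[i, ] - A[j, ])^2))
      db <- sqrt(sum((B[i, ] - B[j, ])^2))
      acc <- acc + (da - db)^2
    }
  }
  sqrt(2 * acc / (n * (n - 1)))
}

# Brute-force contact enumeration.
oracle_contacts <- function(A, cutoff, min_sep) {
  n <- nrow(A)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j - i >= min_sep && sqrt(sum((A[i, ] - A[j, ])^2)) < cutoff) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# Single-linkage partition via MST: cut the k-1 heaviest MST edges.
oracle_single_linkage <- function(dmat, k) {
  n <- nrow(dmat)
  g <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected", weighted = TRUE)
  mst <- igraph::mst(g)
  w <- igraph::E(mst)$weight
  if (k > 1) {
    drop <- order(w, decreasing = TRUE)[seq_len(k - 1)]
    mst <- igraph::delete_edges(mst, drop)
  }
  igraph::components(mst)$membership
}

# Are two labelings the same partition (up to renaming)?
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# A compact random chain pair for property loops.
random_pair <- function(n, noise = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(3 * n), ncol = 3) * 3
  B <- A + matrix(rnorm(3 * n, sd = noise), ncol = 3)
  list(A = A, B = B)
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)
  ), 3, 3, byrow = TRUE)
}

# The half-matched chain: atoms 1-4 identical, atoms 5-8 displaced far and
# incoherently so no rigid motion can recover more than the matched half.
half_matched_pair <- function() {
  A <- make_base_structure(8, "random_walk", seed = 11)$coords
  B <- A
  B[5:8, ] <- B[5:8, ] + rbind(c(100, 0, 0), c(0, -120, 0), c(0, 0, 140), c(90, 90, -90))
  list(A = A, B = B)
}

# Hand-built contact maps with known overlap: |A|=10, |B|=14, |A&B|=8.
constructed_cmo_maps <- function() {
  n <- 30L
  shared <- cbind(1:8, 11:18)
  only_a <- cbind(1:2, 21:22)
  only_b <- cbind(3:8, 23:28)
  list(
    A = structure(list(n = n, contacts = rbind(shared, only_a), cutoff = 8,
      min_separation = 0L), class = "contact_map"),
    B = structure(list(n = n, contacts = rbind(shared, only_b), cutoff = 8,
      min_separation = 0L), class = "contact_map")
  )
}
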