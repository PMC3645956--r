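#' @title Closed-form coordinate RMSD via the 3x3 covariance matrix
#'
#' @description
#' The minimum RMSD between two index-paired coordinate sets over all proper
#' rotations and translations can be obtained without ever constructing the
#' rotation: with both sets centred on their centroids and the per-atom
#' cross-covariance `M = (1/N) * sum(a_i b_i^T)`,
#'
#'   `cRMSD = sqrt(Rg_A^2 + Rg_B^2 - 2 (l1 + l2 + S l3))`
#'
#' where `l1 >= l2 >= l3 >= 0` are the singular values of `M` (square roots
#' of the eigenvalues of `M^T M`), `S` is the sign of `det(M)` (`-1` flags a
#' reflection being the unconstrained optimum, e.g. against a mirror image),
#' and `Rg` is the radius of gyration of each set about its centroid. The
#' eigenvalues of the symmetric 3x3 matrix `M^T M` are found as the roots of
#' its characteristic cubic (trigonometric solution), avoiding a full SVD;
#' a numerically degenerate cubic falls back to an SVD of `M`.
#'
#' @param A,B Coordinate matrices (n x 3) or [structure_model()]s of equal
#'   length (n >= 3).
#' @return For `covariance_decomposition()`: a list of class
#'   `covariance_decomposition` with the covariance matrix `M`, its ordered
#'   singular values `lambdas`, determinant sign `S` and the radii of
#'   gyration `Rg_A`, `Rg_B`. For `crmsd()`: the cRMSD in Angstroms (>= 0).
#' @export
#' @examples
#' A <- matrix(rnorm(60), ncol = 3)
#' crmsd(A, A + 1) # pure translation: 0
covariance_decomposition <- function(A, B) {
  A <- as_coords(A); B <- as_coords(B)
  check_pair(A, B, min_n = 3L)
  n <- nrow(A)
  Ac <- center_coords(A)
  Bc <- center_coords(B)
  M <- crossprod(Ac, Bc) / n
  detM <- det(M)
  S <- if (detM < 0) -1L else 1L
  lambdas <- singular_values3(M)
  structure(
    list(
      M = M,
      lambdas = lambdas,
      S = S,
      Rg_A = sqrt(mean(rowSums(Ac^2))),
      Rg_B = sqrt(mean(rowSums(Bc^2)))
    ),
    class = "covariance_decomposition"
  )
}

#' @rdname covariance_decomposition
#' @export
crmsd <- function(A, B) {
  d <- covariance_decomposition(A, B)
  l <- d$lambdas
  radicand <- d$Rg_A^2 + d$Rg_B^2 - 2 * (l[1] + l[2] + d$S * l[3])
  sqrt(max(0, radicand)) # round-off can push identical sets to -1e-16
}

center_coords <- function(X) sweep(X, 2, colMeans(X), "-")

check_pair <- function(A, B, min_n = 3L) {
  if (nrow(A) != nrow(B)) {
    stop(sprintf("coordinate sets differ in length (%d vs %d)", nrow(A), nrow(B)),
      call. = FALSE)
  }
  if (nrow(A) < min_n) {
    stop(sprintf("need at least %d atoms, got %d", min_n, nrow(A)), call. = FALSE)
  }
  invisible(NULL)
}

# Singular values of a 3x3 matrix M, descending: square roots of the
# eigenvalues of K = M^T M, obtained from the characteristic cubic by the
# trigonometric (Viete) solution. Falls back to svd(M) when the shifted
# cubic is numerically degenerate.
singular_values3 <- function(M) {
  K <- crossprod(M)
  mu <- (K[1, 1] + K[2, 2] + K[3, 3]) / 3
  Kd <- K - diag(mu, 3)
  p <- sum(Kd^2) / 6
  scale2 <- max(mu^2, sum(K^2))
  if (p <= 1e-12 * max(scale2, 1e-300)) {
    # (near-)triple eigenvalue; the shift is the answer
    ev <- rep(mu, 3)
  } else {
    r <- det(Kd) / 2 / p^1.5
    if (!is.finite(r) || abs(r) > 1 + 1e-8) {
      return(sort(svd(M)$d, decreasing = TRUE))
    }
    phi <- acos(min(1, max(-1, r))) / 3
    e1 <- mu + 2 * sqrt(p) * cos(phi)
    e3 <- mu + 2 * sqrt(p) * cos(phi + 2 * pi / 3)
    ev <- c(e1, 3 * mu - e1 - e3, e3)
  }
  sqrt(pmax(ev, 0))
}

#' Optimal proper rotation and translation (Kabsch)
#'
#' Returns the rigid transform (rotation with determinant +1, plus
#' translation) that minimises the RMSD of `B` superposed onto `A`. The
#' reflection case is handled by flipping the singular vector of the
#' smallest singular value, which also breaks ties deterministically for
#' degenerate (collinear or coincident) point sets. Applying the transform
#' to `B` and taking the plain per-atom RMSD reproduces [crmsd()].
#'
#' @inheritParams covariance_decomposition
#' @return A list of class `rigid_transform` with elements `rotation`
#'   (3x3, det +1) and `translation` (length-3, Angstroms).
#' @export
kabsch_rotation <- function(A, B) {
  A <- as_coords(A); B <- as_coords(B)
  check_pair(A, B, min_n = 3L)
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca, "-")
  Bc <- sweep(B, 2, cb, "-")
  C <- crossprod(Bc, Ac) # sum b_i a_i^T
  s <- svd(C)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  structure(
    list(rotation = R, translation = as.numeric(ca - R %*% cb)),
    class = "rigid_transform"
  )
}

#' Apply a rigid transform to coordinates
#'
#' @param transform A `rigid_transform` from [kabsch_rotation()].
#' @param X Coordinate matrix (n x 3) or [structure_model()].
#' @return Transformed n x 3 coordinate matrix.
#' @export
apply_transform <- function(transform, X) {
  X <- as_coords(X)
  sweep(X %*% t(transform$rotation), 2, transform$translation, "+")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\nrotation:\n")
  print(round(x$rotation, 6))
  cat("translation:", paste(round(x$translation, 3), collapse = " "), "\n")
  invisible(x)
}

# Plain per-atom RMSD without any superposition.
raw_rmsd <- function(A, B) {
  sqrt(mean(rowSums((A - B)^2)))
}
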