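#' Generate an idealised base structure
#'
#' Three deterministic chain geometries at C-alpha resolution:
#' * `helix` -- ideal alpha-helix trace (rise 1.5 A per residue, 100
#'   degrees per residue, 2.3 A helical radius), giving consecutive
#'   C-alpha distances of ~3.8 A;
#' * `extended` -- a flat zigzag strand with 3.8 A steps;
#' * `random_walk` -- fixed-length 3.8 A steps in seeded random directions.
#'
#' @param n Number of residues (>= 4).
#' @param kind `"helix"`, `"extended"` or `"random_walk"`.
#' @param seed Integer seed (only `random_walk` consumes randomness, but the
#'   id records it for all kinds).
#' @return A [structure_model()].
#' @export
make_base_structure <- function(n, kind = c("helix", "extended", "random_walk"),
                                seed = 1L) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (n < 4L) stop("need at least 4 residues", call. = FALSE)
  coords <- switch(kind,
    helix = {
      t <- seq_len(n) - 1L
      ang <- t * 100 * pi / 180
      cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * t)
    },
    extended = {
      t <- seq_len(n) - 1L
      cbind(3.3 * t, 1.9 * (t %% 2), 0)
    },
    random_walk = with_seed(seed, {
      steps <- matrix(stats::rnorm(3 * (n - 1)), ncol = 3)
      steps <- 3.8 * steps / sqrt(rowSums(steps^2))
      rbind(c(0, 0, 0), apply(steps, 2, cumsum))
    })
  )
  structure_model(coords, model_id = sprintf("synthetic:%s:%d:%d", kind, n, seed))
}

#' Mirror a structure
#'
#' Reflects the coordinates through the x = 0 plane. Internal distances are
#' preserved (so dRMSD to the original is 0) but chirality flips, so the
#' cRMSD of a chiral structure to its mirror image is positive.
#'
#' @param x A [structure_model()].
#' @return A [structure_model()] with negated x coordinates.
#' @export
mirror_structure <- function(x) {
  coords <- as_coords(x)
  coords[, 1] <- -coords[, 1]
  id <- if (inherits(x, "structure_model")) paste0(x$model_id, ":mirror") else "mirror"
  structure_model(coords, model_id = id,
    residue_numbers = if (inherits(x, "structure_model")) x$residue_numbers else NULL)
}

#' Recipe for a synthetic decoy ensemble with planted clusters
#'
#' Describes an ensemble in the style of a multi-trajectory decoy set:
#' several conformational clusters of equal-length models, each cluster a
#' deformed copy of a common base structure, members scattered around their
#' cluster seed by isotropic Gaussian coordinate noise. `between_offset`
#' states the intended cRMSD separation of cluster seeds; recipes with
#' `between_offset / within_noise_sd >= 5` are comfortably separable by
#' every clustering method in the package.
#'
#' @param n_residues Chain length (default 36, a villin-headpiece-sized
#'   subdomain).
#' @param per_cluster_sizes Integer vector of cluster sizes (default three
#'   clusters of 20).
#' @param within_noise_sd Per-coordinate Gaussian noise sd within a
#'   cluster, Angstroms (default 0.3).
#' @param between_offset Target cRMSD between neighbouring cluster seeds,
#'   Angstroms (default 6).
#' @param seed Integer RNG seed.
#' @return A list of class `decoy_recipe`.
#' @export
decoy_recipe <- function(n_residues = 36L, per_cluster_sizes = c(20L, 20L, 20L),
                         within_noise_sd = 0.3, between_offset = 6, seed = 1L) {
  structure(
    list(
      n_residues = as.integer(n_residues),
      n_clusters = length(per_cluster_sizes),
      per_cluster_sizes = as.integer(per_cluster_sizes),
      within_noise_sd = within_noise_sd,
      between_offset = between_offset,
      seed = as.integer(seed)
    ),
    class = "decoy_recipe"
  )
}

#' Generate a decoy ensemble with planted clusters
#'
#' Cluster seeds are hinge-deformed copies of an ideal helix: the C-terminal
#' half of the chain is rotated about an axis through the chain midpoint,
#' with the per-cluster hinge angle calibrated (by bisection on the
#' cRMSD-vs-angle curve, which is monotone over the searched range) so that
#' consecutive seeds are separated by approximately the recipe's
#' `between_offset` in cRMSD. A hinge is used rather than a translation
#' because rigid offsets are removed by superposition and would yield zero
#' between-cluster cRMSD. Members add isotropic Gaussian noise (sd =
#' `within_noise_sd`) per coordinate to their seed. Everything is a pure
#' function of the recipe, including its seed.
#'
#' @param recipe A [decoy_recipe()].
#' @return A list with `ensemble` (a `decoy_ensemble`) and `labels`
#'   (integer ground-truth cluster per model).
#' @export
make_decoy_ensemble <- function(recipe) {
  stopifnot(inherits(recipe, "decoy_recipe"))
  base <- make_base_structure(recipe$n_residues, "helix")$coords
  with_seed(recipe$seed, {
    step <- hinge_angle_for_offset(base, recipe$between_offset)
    seeds <- lapply(seq_len(recipe$n_clusters) - 1L, function(c) {
      s <- hinge_deform(base, c * step)
      s + matrix(stats::rnorm(length(s), sd = recipe$within_noise_sd), ncol = 3)
    })
    models <- list()
    labels <- integer(0)
    idx <- 0L
    for (c in seq_len(recipe$n_clusters)) {
      for (m in seq_len(recipe$per_cluster_sizes[c])) {
        idx <- idx + 1L
        noise <- matrix(stats::rnorm(length(base), sd = recipe$within_noise_sd), ncol = 3)
        models[[idx]] <- structure_model(
          seeds[[c]] + noise,
          model_id = sprintf("synthetic:c%d:m%d", c, m)
        )
        labels[idx] <- c
      }
    }
    list(ensemble = ensemble(models), labels = labels)
  })
}

# Rotate the second half of the chain about the x-axis through the midpoint
# C-alpha by `angle` radians (a smooth hinge deformation).
hinge_deform <- function(coords, angle) {
  n <- nrow(coords)
  mid <- n %/% 2L
  if (angle == 0 || mid >= n) return(coords)
  pivot <- coords[mid, ]
  R <- matrix(c(
    1, 0, 0,
    0, cos(angle), -sin(angle),
    0, sin(angle), cos(angle)
  ), 3, 3, byrow = TRUE)
  tail_idx <- (mid + 1L):n
  moved <- sweep(coords[tail_idx, , drop = FALSE], 2, pivot, "-") %*% t(R)
  coords[tail_idx, ] <- sweep(moved, 2, pivot, "+")
  coords
}

# Bisection for the hinge angle giving crmsd(base, hinged) ~= offset.
# Capped at 0.9*pi if the offset is beyond the hinge's reach.
hinge_angle_for_offset <- function(base, offset, tol = 1e-3) {
  hi <- 0.9 * pi
  if (crmsd(base, hinge_deform(base, hi)) <= offset) return(hi)
  lo <- 0
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (crmsd(base, hinge_deform(base, mid)) < offset) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}
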