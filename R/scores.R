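#' Distance RMSD between two equal-length models
#'
#' Root-mean-square deviation of the two structures' internal distance
#' matrices:
#' `sqrt( 2/(N(N-1)) * sum_{i<j} (d_ij^A - d_ij^B)^2 )`.
#' No superposition is involved, which also makes the score blind to
#' chirality: a structure and its mirror image have identical distance
#' matrices and hence dRMSD 0, while their cRMSD is positive.
#'
#' @param A,B Coordinate matrices (n x 3) or [structure_model()]s of equal
#'   length (n >= 2).
#' @return The dRMSD in Angstroms (>= 0).
#' @export
drmsd <- function(A, B) {
  A <- as_coords(A); B <- as_coords(B)
  check_pair(A, B, min_n = 2L)
  da <- stats::dist(A)
  db <- stats::dist(B)
  sqrt(mean((da - db)^2))
}

#' Binary residue contact map
#'
#' `(i, j)` (with `i < j`) is a contact iff the inter-atom distance is
#' strictly below `cutoff` and the sequence separation `|i - j|` is at least
#' `min_separation`. Defaults (8 Angstrom C-alpha cutoff, no separation
#' filter) are a documented package choice and configurable everywhere.
#'
#' @param A Coordinate matrix or [structure_model()].
#' @param cutoff Contact distance threshold in Angstroms (strict `<`).
#' @param min_separation Minimum `|i - j|` for a pair to count (default 0).
#' @return An object of class `contact_map` with fields `n`, `contacts`
#'   (m x 2 matrix of index pairs, `i < j`), `cutoff`, `min_separation`.
#' @export
#' @examples
#' cm <- contact_map(matrix(rnorm(30), ncol = 3), cutoff = 8)
#' nrow(cm$contacts)
contact_map <- function(A, cutoff = 8, min_separation = 0L) {
  A <- as_coords(A)
  if (!is.numeric(cutoff) || cutoff <= 0) stop("`cutoff` must be positive", call. = FALSE)
  n <- nrow(A)
  d <- as.matrix(stats::dist(A))
  idx <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  if (nrow(idx)) {
    sep <- abs(idx[, 2] - idx[, 1])
    idx <- idx[sep >= min_separation, , drop = FALSE]
  }
  structure(
    list(
      n = n,
      contacts = unname(idx[order(idx[, 1], idx[, 2]), , drop = FALSE]),
      cutoff = cutoff,
      min_separation = as.integer(min_separation)
    ),
    class = "contact_map"
  )
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf(
    "<contact_map> %d residues, %d contacts (< %.1f A, |i-j| >= %d)\n",
    x$n, nrow(x$contacts), x$cutoff, x$min_separation
  ))
  invisible(x)
}

#' Contact-map overlap (Sorensen similarity index)
#'
#' `S = 100 * 2 n(A & B) / (n(A) + n(B))` over the two contact sets. Two
#' empty maps are scored 100 (identical emptiness); one empty map against a
#' non-empty one scores 0 (the raw ratio is 0/0 in the first case).
#'
#' @param A,B `contact_map` objects over the same residue count, built with
#'   the same cutoff and separation parameters.
#' @return Similarity in percent, in `[0, 100]`.
#' @export
cmo_sorensen <- function(A, B) {
  if (!inherits(A, "contact_map") || !inherits(B, "contact_map")) {
    stop("inputs must be contact_map objects", call. = FALSE)
  }
  if (A$n != B$n) stop("contact maps cover different residue counts", call. = FALSE)
  if (A$cutoff != B$cutoff || A$min_separation != B$min_separation) {
    stop("contact maps built with different parameters", call. = FALSE)
  }
  na <- nrow(A$contacts); nb <- nrow(B$contacts)
  if (na + nb == 0L) return(100)
  ka <- A$contacts[, 1] * (A$n + 1) + A$contacts[, 2]
  kb <- B$contacts[, 1] * (B$n + 1) + B$contacts[, 2]
  inter <- length(intersect(ka, kb))
  100 * 2 * inter / (na + nb)
}

#' TM-score normalisation length d0
#'
#' `d0 = 1.24 (N - 15)^(1/3) - 1.8` Angstroms, floored at 0.5 since the
#' formula goes non-positive for chains of 17 residues or fewer and the
#' score needs a positive scale. In MaxSub mode the scale is fixed at
#' `d0 = 3.5` Angstroms regardless of length.
#'
#' @param n Residue count (>= 1).
#' @return d0 in Angstroms.
#' @export
d0_tm <- function(n) {
  max(1.24 * sign(n - 15) * abs(n - 15)^(1 / 3) - 1.8, 0.5)
}

D0_MAXSUB <- 3.5

#' GDT search parameters
#'
#' @param cutoffs The four GDT distance thresholds in Angstroms
#'   (default 1, 2, 4, 8; must be strictly increasing).
#' @param refine_cutoff Atom pairs closer than this are kept for the next
#'   refinement superposition (default 3.5 Angstroms).
#' @param stability_window Refinement stops once the selected-atom count is
#'   unchanged for this many consecutive iterations (default 4).
#' @param max_iterations Hard cap on refinement iterations per seed
#'   (default 100; guards against count oscillation).
#' @param extended If `TRUE` (the "gdtExt" mode), additional seed fragment
#'   lengths 8, 16, 32, ... below the chain length are used, giving a more
#'   exhaustive and hence never-smaller GDT_TS.
#' @return A list of class `gdt_params`.
#' @export
gdt_params <- function(cutoffs = c(1, 2, 4, 8), refine_cutoff = 3.5,
                       stability_window = 4L, max_iterations = 100L,
                       extended = FALSE) {
  if (any(diff(cutoffs) <= 0)) stop("`cutoffs` must be strictly increasing", call. = FALSE)
  if (refine_cutoff <= 0) stop("`refine_cutoff` must be positive", call. = FALSE)
  structure(
    list(
      cutoffs = cutoffs, refine_cutoff = refine_cutoff,
      stability_window = as.integer(stability_window),
      max_iterations = as.integer(max_iterations),
      extended = isTRUE(extended)
    ),
    class = "gdt_params"
  )
}

# Seed fragment lengths: all of {4, N/4, N/2, N} (integer division), plus
# powers of two 8, 16, 32, ... < N in extended mode; lengths < 4 dropped,
# duplicates removed.
gdt_fragment_lengths <- function(n, extended = FALSE) {
  lens <- c(4L, n %/% 4L, n %/% 2L, n)
  if (extended) {
    p <- 8L
    while (p < n) {
      lens <- c(lens, p)
      p <- p * 2L
    }
  }
  sort(unique(lens[lens >= 4L & lens <= n]))
}

#' Fragment-seeded superposition search (GDT_TS, TM-score, MaxSub)
#'
#' Exact GDT optimisation is NP-hard, so the score is computed by a
#' heuristic search shared by all three measures: every contiguous window
#' of each seed fragment length (stride 1) defines an initial Kabsch
#' superposition of the full chains; each seed is then refined by
#' repeatedly re-superposing on the subset of atom pairs closer than
#' `refine_cutoff` until the selected-atom count is stable for
#' `stability_window` consecutive iterations (or the subset drops below 3
#' atoms, or the iteration cap is hit). The requested measure is evaluated
#' over all N atom pairs at every superposition visited and the maximum
#' kept; for GDT_TS each cutoff's maximal count is tracked independently
#' and the score is `100 * mean(max C_c / N)` over the four cutoffs.
#'
#' @param A,B Coordinate matrices or [structure_model()]s of equal length
#'   (n >= 4).
#' @param params A [gdt_params()] object.
#' @param measure One of `"gdt_ts"`, `"tm"`, `"maxsub"`.
#' @return A list of class `search_score` with the score `value`, the
#'   `best_transform` (a `rigid_transform`), and `seeds_tried`.
#' @export
gdt_search <- function(A, B, params = gdt_params(),
                       measure = c("gdt_ts", "tm", "maxsub")) {
  measure <- match.arg(measure)
  A <- as_coords(A); B <- as_coords(B)
  check_pair(A, B, min_n = 4L)
  n <- nrow(A)
  lens <- gdt_fragment_lengths(n, params$extended)
  if (!length(lens)) stop("chain too short for any seed fragment", call. = FALSE)
  d0 <- switch(measure, tm = d0_tm(n), maxsub = D0_MAXSUB, gdt_ts = NA_real_)
  ncut <- length(params$cutoffs)

  max_counts <- integer(ncut) # per-cutoff maxima, tracked independently
  best_val <- -Inf            # scalar used to pick best_transform
  best_tf <- NULL
  seeds <- 0L

  visit <- function(tf) {
    d <- sqrt(rowSums((apply_transform(tf, B) - A)^2))
    if (measure == "gdt_ts") {
      counts <- vapply(params$cutoffs, function(cc) sum(d < cc), integer(1))
      max_counts <<- pmax(max_counts, counts)
      val <- sum(counts)
    } else {
      val <- mean(1 / (1 + (d / d0)^2))
    }
    if (val > best_val) {
      best_val <<- val
      best_tf <<- tf
    }
    d
  }

  for (len in lens) {
    for (s in seq_len(n - len + 1L)) {
      seeds <- seeds + 1L
      idx <- s:(s + len - 1L)
      tf <- kabsch_rotation(A[idx, , drop = FALSE], B[idx, , drop = FALSE])
      d <- visit(tf)
      counts_hist <- integer(0)
      for (it in seq_len(params$max_iterations)) {
        sel <- which(d < params$refine_cutoff)
        counts_hist <- c(counts_hist, length(sel))
        nh <- length(counts_hist)
        if (nh >= params$stability_window &&
            length(unique(counts_hist[(nh - params$stability_window + 1L):nh])) == 1L) {
          break
        }
        if (length(sel) < 3L) break
        tf <- kabsch_rotation(A[sel, , drop = FALSE], B[sel, , drop = FALSE])
        d <- visit(tf)
      }
    }
  }

  value <- if (measure == "gdt_ts") 100 * mean(max_counts / n) else best_val
  structure(
    list(
      value = value, best_transform = best_tf, seeds_tried = seeds,
      measure = measure,
      max_counts = if (measure == "gdt_ts") max_counts else NULL
    ),
    class = "search_score"
  )
}

#' @export
print.search_score <- function(x, ...) {
  cat(sprintf("<search_score> %s = %.4f (%d seeds)\n", x$measure, x$value, x$seeds_tried))
  invisible(x)
}

#' @rdname gdt_search
#' @export
gdt_ts <- function(A, B, params = gdt_params()) {
  gdt_search(A, B, params, "gdt_ts")$value
}

#' @rdname gdt_search
#' @export
tm_score <- function(A, B, params = gdt_params()) {
  gdt_search(A, B, params, "tm")$value
}

#' @rdname gdt_search
#' @export
maxsub <- function(A, B, params = gdt_params()) {
  gdt_search(A, B, params, "maxsub")$value
}
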