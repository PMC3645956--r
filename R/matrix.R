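#' Supported similarity measures
#'
#' Measure names accepted throughout the package: `"rmsd"` (coordinate RMSD
#' after optimal superposition), `"drmsd"`, `"gdt"` / `"gdtExt"` (GDT_TS,
#' standard or extended fragment seeding), `"tm"` (TM-score), `"maxsub"`,
#' `"cmo"` (contact-map overlap). Each has an identity self-score: 0 for the
#' RMSD-type measures, 1 for TM/MaxSub, 100 for GDT_TS and CMO.
#'
#' @format A character vector of measure names.
#' @export
MEASURES <- c("rmsd", "drmsd", "gdt", "gdtExt", "tm", "maxsub", "cmo")

measure_diagonal <- function(measure) {
  switch(measure,
    rmsd = 0, drmsd = 0, tm = 1, maxsub = 1, gdt = 100, gdtExt = 100, cmo = 100,
    stop(sprintf("unknown measure '%s'", measure), call. = FALSE)
  )
}

# TRUE for measures where larger means more similar.
measure_is_similarity <- function(measure) {
  measure %in% c("tm", "maxsub", "gdt", "gdtExt", "cmo")
}

# One scoring closure per measure, shared by all_vs_all / vs_reference.
# For contact maps the per-model map is precomputed once by the caller.
measure_fun <- function(measure, contact_cutoff = 8, min_separation = 0L) {
  switch(measure,
    rmsd = function(a, b) crmsd(a, b),
    drmsd = function(a, b) drmsd(a, b),
    tm = function(a, b) tm_score(a, b),
    maxsub = function(a, b) maxsub(a, b),
    gdt = function(a, b) gdt_ts(a, b),
    gdtExt = function(a, b) gdt_ts(a, b, gdt_params(extended = TRUE)),
    cmo = function(a, b) cmo_sorensen(a, b),
    stop(sprintf("unknown measure '%s'", measure), call. = FALSE)
  )
}

new_similarity_matrix <- function(values, measure, diagonal_value, n_evaluations = NA_integer_) {
  structure(
    list(
      n = nrow(values), measure = measure, values = values,
      diagonal_value = diagonal_value, n_evaluations = n_evaluations
    ),
    class = "similarity_matrix"
  )
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf(
    "<similarity_matrix> %s, %d x %d (diagonal %.0f)\n",
    x$measure, x$n, x$n, x$diagonal_value
  ))
  invisible(x)
}

#' All-versus-all similarity matrix
#'
#' Computes each of the N(N-1)/2 unordered pairs exactly once and mirrors
#' it, so the matrix is symmetric by construction even for the (potentially
#' asymmetric) heuristic search scores; the diagonal carries the measure's
#' identity self-score. Work may be split into chunks (`workers`), but the
#' chunking is deterministic and results are assembled in pair order, so
#' the matrix is bit-identical for any worker count.
#'
#' @param x A `decoy_ensemble` with uniform model lengths.
#' @param measure One of [MEASURES].
#' @param contact_cutoff,min_separation Contact-map parameters (used by
#'   `measure = "cmo"` only).
#' @param workers Number of deterministic work chunks (default 1).
#' @return A `similarity_matrix`; `$values` has model ids as dimnames and
#'   `$n_evaluations` records the number of pair evaluations performed.
#' @export
all_vs_all <- function(x, measure = "rmsd", contact_cutoff = 8,
                       min_separation = 0L, workers = 1L) {
  measure <- match.arg(measure, MEASURES)
  check_uniform(x)
  n <- length(x)
  ids <- model_ids(x)
  items <- pair_inputs(x, measure, contact_cutoff, min_separation)
  f <- measure_fun(measure)
  vals <- matrix(measure_diagonal(measure), n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    pairs <- utils::combn(n, 2L)
    chunks <- split_chunks(ncol(pairs), workers)
    scores <- numeric(ncol(pairs))
    for (ch in chunks) {
      scores[ch] <- vapply(ch, function(p) {
        f(items[[pairs[1, p]]], items[[pairs[2, p]]])
      }, numeric(1))
    }
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      vals[i, j] <- scores[p]
      vals[j, i] <- scores[p]
    }
  }
  new_similarity_matrix(vals, measure, measure_diagonal(measure),
    n_evaluations = if (n > 1L) ncol(pairs) else 0L)
}

# Per-model inputs to the scoring function: coordinates, or precomputed
# contact maps for CMO.
pair_inputs <- function(x, measure, contact_cutoff, min_separation) {
  if (measure == "cmo") {
    lapply(x, contact_map, cutoff = contact_cutoff, min_separation = min_separation)
  } else {
    lapply(x, function(m) m$coords)
  }
}

# Deterministic contiguous chunking of 1:n into `workers` pieces.
split_chunks <- function(n, workers) {
  workers <- max(1L, as.integer(workers))
  if (n == 0L) return(list())
  unname(split(seq_len(n), sort(rep_len(seq_len(min(workers, n)), n))))
}

#' Score every model against a reference structure
#'
#' For TM-score the normalisation length N (and hence d0) is that of the
#' reference; since all comparisons here are index-paired, the model length
#' must equal the reference length anyway.
#'
#' @param x A `decoy_ensemble`.
#' @param reference A [structure_model()] of the same length as the models.
#' @param measure One of [MEASURES].
#' @inheritParams all_vs_all
#' @return A tibble with columns `model_id` and `score`, in ensemble order.
#' @export
vs_reference <- function(x, reference, measure = "tm", contact_cutoff = 8,
                         min_separation = 0L) {
  measure <- match.arg(measure, MEASURES)
  if (!inherits(reference, "structure_model")) {
    stop("`reference` must be a structure_model", call. = FALSE)
  }
  if (!length(x)) return(tibble::tibble(model_id = character(0), score = numeric(0)))
  check_uniform(x)
  if (model_lengths(x)[1] != reference$n_atoms) {
    stop(sprintf(
      "model length %d does not match reference length %d",
      model_lengths(x)[1], reference$n_atoms
    ), call. = FALSE)
  }
  f <- measure_fun(measure)
  items <- pair_inputs(x, measure, contact_cutoff, min_separation)
  ref_item <- if (measure == "cmo") {
    contact_map(reference, cutoff = contact_cutoff, min_separation = min_separation)
  } else {
    reference$coords
  }
  tibble::tibble(
    model_id = model_ids(x),
    score = vapply(items, function(it) f(ref_item, it), numeric(1))
  )
}

#' Extract all unordered pairs of a similarity matrix as a tibble
#'
#' @param m A `similarity_matrix`.
#' @return A tibble with columns `i`, `j` (`i < j`), `id_a`, `id_b`,
#'   `score`, sorted by `(i, j)`.
#' @export
matrix_pairs <- function(m) {
  n <- m$n
  ids <- colnames(m$values)
  if (n < 2L) {
    return(tibble::tibble(
      i = integer(0), j = integer(0),
      id_a = character(0), id_b = character(0), score = numeric(0)
    ))
  }
  pr <- utils::combn(n, 2L)
  tibble::tibble(
    i = pr[1, ], j = pr[2, ],
    id_a = ids[pr[1, ]], id_b = ids[pr[2, ]],
    score = m$values[cbind(pr[1, ], pr[2, ])]
  )
}

#' Filter pairs strictly beyond a threshold
#'
#' Returns the unordered pairs whose score is strictly below (or strictly
#' above) `threshold`, sorted by `(i, j)` -- the in-package equivalent of
#' piping a three-column pair file through `awk '$3 < 3.2'`.
#'
#' @param m A `similarity_matrix`.
#' @param threshold Finite numeric threshold.
#' @param direction `"below"` or `"above"` (strict inequality either way).
#' @return A tibble as in [matrix_pairs()], restricted to matching pairs.
#' @export
filter_pairs <- function(m, threshold, direction = c("below", "above")) {
  direction <- match.arg(direction)
  if (!is.finite(threshold)) stop("`threshold` must be finite", call. = FALSE)
  pr <- matrix_pairs(m)
  keep <- if (direction == "below") pr$score < threshold else pr$score > threshold
  pr[keep, , drop = FALSE]
}

#' Convert a similarity matrix to a dissimilarity matrix
#'
#' RMSD-type measures are already dissimilarities and pass through
#' unchanged; TM/MaxSub become `1 - score` and GDT_TS/CMO become
#' `100 - score`, so the diagonal is 0 and the pair ordering is reversed
#' for similarity measures. Clustering consumes the result.
#'
#' @param m A `similarity_matrix`.
#' @return A `similarity_matrix` whose values are dissimilarities
#'   (measure name suffixed with `"_dist"` for converted measures).
#' @export
to_distance <- function(m) {
  if (!inherits(m, "similarity_matrix")) stop("`m` must be a similarity_matrix", call. = FALSE)
  if (!measure_is_similarity(m$measure)) {
    return(m)
  }
  top <- measure_diagonal(m$measure)
  new_similarity_matrix(top - m$values, paste0(m$measure, "_dist"), 0,
    n_evaluations = m$n_evaluations)
}
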