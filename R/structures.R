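#' Construct a structure model
#'
#' A structure model is one conformer reduced to an ordered set of C-alpha
#' (or other single-atom) coordinates in Angstroms, together with identity
#' metadata. All similarity measures in this package operate on these
#' index-paired coordinate sets; no sequence alignment is performed.
#'
#' @param coords Numeric matrix, one row per atom, three columns (x, y, z in
#'   Angstroms). All values must be finite.
#' @param model_id Character scalar identifying the model (conventionally
#'   `"<path>:<model index>"` for models read from files).
#' @param residue_numbers Integer vector of residue numbers as printed in the
#'   source PDB; defaults to `1:nrow(coords)`.
#' @return An object of class `structure_model` with fields `model_id`,
#'   `coords`, `n_atoms` and `residue_numbers`.
#' @export
#' @examples
#' m <- structure_model(matrix(rnorm(30), ncol = 3), "toy:1")
#' m$n_atoms
structure_model <- function(coords, model_id = "model", residue_numbers = NULL) {
  coords <- as_coords(coords)
  if (is.null(residue_numbers)) residue_numbers <- seq_len(nrow(coords))
  residue_numbers <- as.integer(residue_numbers)
  if (length(residue_numbers) != nrow(coords)) {
    stop("`residue_numbers` must have one entry per atom", call. = FALSE)
  }
  structure(
    list(
      model_id = as.character(model_id)[1],
      coords = coords,
      n_atoms = nrow(coords),
      residue_numbers = residue_numbers
    ),
    class = "structure_model"
  )
}

# Coerce and validate a coordinate set: numeric n x 3 matrix, finite entries.
as_coords <- function(x) {
  if (inherits(x, "structure_model")) return(x$coords)
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("coordinates must have 3 columns", call. = FALSE)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("coordinates must all be finite", call. = FALSE)
  dimnames(x) <- NULL
  x
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s: %d atoms\n", x$model_id, x$n_atoms))
  invisible(x)
}

#' Construct an ensemble of structure models
#'
#' @param models List of [structure_model()] objects in a fixed order.
#' @return An object of class `decoy_ensemble`; the `uniform_length` attribute
#'   records whether every model has the same atom count (required by all
#'   pairwise measures).
#' @export
ensemble <- function(models) {
  if (!length(models)) {
    return(structure(list(), class = "decoy_ensemble", uniform_length = TRUE))
  }
  ok <- vapply(models, inherits, logical(1), what = "structure_model")
  if (!all(ok)) stop("all elements must be structure_model objects", call. = FALSE)
  n <- vapply(models, function(m) m$n_atoms, integer(1))
  structure(models,
    class = "decoy_ensemble",
    uniform_length = length(unique(n)) == 1L
  )
}

#' @export
print.decoy_ensemble <- function(x, ...) {
  n <- vapply(x, function(m) m$n_atoms, integer(1))
  cat(sprintf(
    "<decoy_ensemble> %d models, %s\n", length(x),
    if (isTRUE(attr(x, "uniform_length"))) {
      sprintf("uniform length %d", if (length(n)) n[1] else 0L)
    } else {
      sprintf("non-uniform lengths (%d-%d)", min(n), max(n))
    }
  ))
  invisible(x)
}

#' Is every model in the ensemble the same length?
#' @param x A `decoy_ensemble`.
#' @return Logical scalar.
#' @export
uniform_length <- function(x) isTRUE(attr(x, "uniform_length"))

#' Atom counts of the models in an ensemble
#' @param x A `decoy_ensemble`.
#' @return Integer vector of per-model atom counts.
#' @export
model_lengths <- function(x) vapply(x, function(m) m$n_atoms, integer(1))

#' Model identifiers of an ensemble
#' @param x A `decoy_ensemble`.
#' @return Character vector of model ids in ensemble order.
#' @export
model_ids <- function(x) vapply(x, function(m) m$model_id, character(1))

# Stop with a named error if the ensemble mixes model lengths.
check_uniform <- function(x) {
  n <- model_lengths(x)
  if (length(unique(n)) > 1L) {
    bad <- which(n != n[1])
    stop(sprintf(
      "models have unequal lengths: %s has %d atoms but %s has %d",
      model_ids(x)[1], n[1], model_ids(x)[bad[1]], n[bad[1]]
    ), call. = FALSE)
  }
  invisible(x)
}
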