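#' Read models from a (possibly multi-model) PDB file
#'
#' Parses ATOM records (fixed wwPDB v3.3 columns) and keeps one atom per
#' residue matching `atom_name` (C-alpha by default). Files with
#' MODEL/ENDMDL delimiters yield one model per MODEL block; a file without
#' any MODEL record yields exactly one model. Alternate locations are
#' resolved to the first-encountered altloc per residue; HETATM records and
#' insertion codes are ignored. Models of differing lengths load fine --
#' the pairwise comparison functions reject non-uniform ensembles later.
#'
#' @param path Path to a PDB file.
#' @param atom_name Atom name to extract (default `"CA"`).
#' @return A [ensemble()] of [structure_model()]s, ids `"<path>:<k>"`.
#' @export
read_pdb_models <- function(path, atom_name = "CA") {
  if (!file.exists(path)) stop(sprintf("cannot read PDB file '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  starts <- which(rec == "MODEL ")
  if (length(starts) == 0L) {
    blocks <- list(lines)
  } else {
    ends <- c(starts[-1] - 1L, length(lines))
    blocks <- Map(function(s, e) lines[s:e], starts, ends)
  }
  models <- vector("list", length(blocks))
  for (k in seq_along(blocks)) {
    m <- parse_atom_block(blocks[[k]], atom_name)
    if (nrow(m$coords) == 0L) {
      stop(sprintf("model %d of '%s' has no '%s' atoms", k, path, atom_name),
        call. = FALSE)
    }
    models[[k]] <- structure_model(m$coords,
      model_id = sprintf("%s:%d", path, k),
      residue_numbers = m$resno
    )
  }
  ensemble(models)
}

# Parse the ATOM records of one model block. Fixed columns: name 13-16,
# altLoc 17, chain 22, resSeq 23-26, x/y/z 31-38/39-46/47-54.
parse_atom_block <- function(lines, atom_name) {
  atom <- lines[substr(lines, 1, 6) == "ATOM  "]
  if (!length(atom)) {
    return(list(coords = matrix(numeric(0), 0, 3), resno = integer(0)))
  }
  name <- trimws(substr(atom, 13, 16))
  keep <- name == atom_name
  atom <- atom[keep]
  if (!length(atom)) {
    return(list(coords = matrix(numeric(0), 0, 3), resno = integer(0)))
  }
  chain <- substr(atom, 22, 22)
  resno <- suppressWarnings(as.integer(substr(atom, 23, 26)))
  # first-encountered altloc per residue wins
  first <- !duplicated(paste(chain, resno))
  atom <- atom[first]
  resno <- resno[first]
  xyz <- cbind(
    as.numeric(substr(atom, 31, 38)),
    as.numeric(substr(atom, 39, 46)),
    as.numeric(substr(atom, 47, 54))
  )
  if (!all(is.finite(xyz))) stop("malformed ATOM coordinates", call. = FALSE)
  list(coords = xyz, resno = resno)
}

#' Read an ensemble from a one-column list file
#'
#' Each non-empty, non-comment line names a PDB file; each listed file
#' contributes its models (via [read_pdb_models()]) in line order. Blank
#' lines and lines starting with `#` are skipped; surrounding whitespace is
#' trimmed.
#'
#' @inheritParams read_pdb_models
#' @param path Path to the list file.
#' @return A [ensemble()] concatenating all listed models.
#' @export
read_list_file <- function(path, atom_name = "CA") {
  if (!file.exists(path)) stop(sprintf("cannot read list file '%s'", path), call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  keep <- nzchar(lines) & !startsWith(lines, "#")
  entries <- lines[keep]
  lineno <- which(keep)
  all_models <- list()
  for (i in seq_along(entries)) {
    if (!file.exists(entries[i])) {
      stop(sprintf("line %d of '%s': file '%s' not found", lineno[i], path, entries[i]),
        call. = FALSE)
    }
    ens <- read_pdb_models(entries[i], atom_name)
    all_models <- c(all_models, unclass(ens))
  }
  ensemble(all_models)
}

#' Write a three-column pair-score table
#'
#' One line per pair: model id A, model id B, score -- whitespace separated,
#' score in column 3 with three decimals so downstream threshold filters
#' (e.g. `awk '$3 < 3.2'`) work on the text as-is.
#'
#' @param pairs A data frame with columns `id_a`, `id_b`, `score` (as
#'   returned by [filter_pairs()] or [matrix_pairs()]).
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_pair_scores <- function(pairs, path) {
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop(sprintf("cannot write '%s': %s", path, conditionMessage(e)), call. = FALSE)
  })
  on.exit(close(con))
  if (nrow(pairs)) {
    writeLines(sprintf("%s %s %.3f", pairs$id_a, pairs$id_b, pairs$score), con)
  }
  invisible(path)
}

#' Write a similarity matrix as plain text
#'
#' Square whitespace-delimited matrix preceded by a header row of model ids.
#'
#' @param m A [similarity_matrix] object.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_matrix <- function(m, path) {
  ids <- colnames(m$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ids, collapse = " "), con)
  utils::write.table(format(m$values, nsmall = 3, digits = 3, trim = TRUE),
    con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Emits MODEL/ENDMDL-delimited blocks of C-alpha ATOM records with standard
#' fixed-column formatting (coordinates at three decimals). Used to
#' round-trip synthetic ensembles through the text interface.
#'
#' @param x A `decoy_ensemble`.
#' @param path Output path.
#' @param atom_name Atom name to write (default `"CA"`).
#' @param res_name Residue name to write (default `"ALA"`).
#' @return Invisibly, the path.
#' @export
write_pdb_ensemble <- function(x, path, atom_name = "CA", res_name = "ALA") {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (k in seq_along(x)) {
    m <- x[[k]]
    writeLines(sprintf("MODEL     %4d", k), con)
    for (i in seq_len(m$n_atoms)) {
      serial <- serial + 1L
      writeLines(sprintf(
        "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
        serial %% 100000L, paste0(" ", atom_name), " ", res_name, "A",
        m$residue_numbers[i] %% 10000L, " ",
        m$coords[i, 1], m$coords[i, 2], m$coords[i, 3], 1, 0
      ), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
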