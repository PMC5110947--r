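#' Read a C-alpha trace for one chain from a PDB file
#'
#' Parses a PDB source and extracts the ordered C-alpha trace of a single
#' chain, the coarse-grained representation on which the Gaussian network
#' model operates. Only `ATOM` records with atom name `CA` are used; HETATM
#' records are ignored. When a residue carries alternate locations, the
#' highest-occupancy CA is kept (ties broken by file order). Residues without
#' a CA atom are dropped with a warning; network node indices then refer to
#' positions in the retained trace while original residue numbers are kept
#' for reporting.
#'
#' @param pdb_source Path to a PDB file, or a character vector of PDB lines.
#' @param chain_id Single-character chain identifier to extract.
#' @param model_index Model to read from multi-model files (default first).
#'
#' @return A `ca_chain` object: a list with `chain_id`, `residues` (a tibble
#'   with `resno`, `insert`, `resid`), `coords` (an N x 3 matrix of C-alpha
#'   positions in Angstrom) and `n`, the residue count.
#'
#' @examples
#' sp <- synthetic_spec(n_chains = 1, length_range = c(30, 30), seed = 7)
#' ch <- generate_chain(sp, 1)
#' f <- tempfile(fileext = ".pdb")
#' write_ca_pdb(ch, f)
#' read_ca_chain(f, ch$chain_id)
#' @export
read_ca_chain <- function(pdb_source, chain_id, model_index = 1) {
  stopifnot(is.character(chain_id), length(chain_id) == 1)
  path <- pdb_source
  if (length(pdb_source) > 1 || grepl("\n", pdb_source[1], fixed = TRUE)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(pdb_source, "\n", fixed = TRUE)), path)
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = model_index > 1, rm.alt = FALSE,
                    verbose = FALSE),
    error = function(e) stop("PDB format error: ", conditionMessage(e), call. = FALSE)
  )
  atoms <- pdb$atom
  atoms$row <- seq_len(nrow(atoms))
  atoms <- atoms[atoms$type == "ATOM" & atoms$chain %in% chain_id, , drop = FALSE]
  if (nrow(atoms) == 0) {
    stop("chain not found: '", chain_id, "'", call. = FALSE)
  }
  if (model_index > 1) {
    if (is.null(dim(pdb$xyz)) || nrow(pdb$xyz) < model_index) {
      stop("model ", model_index, " not present (file has ",
           max(1, nrow(pdb$xyz)), ")", call. = FALSE)
    }
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    atoms$x <- xyz[atoms$row, 1]
    atoms$y <- xyz[atoms$row, 2]
    atoms$z <- xyz[atoms$row, 3]
  }
  atoms$insert[is.na(atoms$insert)] <- ""
  key <- paste(atoms$resno, atoms$insert, sep = "|")
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]

  no_ca <- setdiff(unique(key), paste(ca$resno, ca$insert, sep = "|"))
  if (length(no_ca) > 0) {
    rlang::warn(paste0("chain ", chain_id, ": dropped ", length(no_ca),
                       " residue(s) lacking a CA atom"))
  }
  if (nrow(ca) == 0 || length(unique(paste(ca$resno, ca$insert))) < 2) {
    stop("chain too short: need at least 2 CA-bearing residues in chain '",
         chain_id, "'", call. = FALSE)
  }
  # altloc rule: keep highest occupancy, ties by first occurrence
  ca$occ <- ifelse(is.na(ca$o), 1, ca$o)
  ca <- ca[order(match(paste(ca$resno, ca$insert, sep = "|"), unique(key)),
                 -ca$occ, ca$row), , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$resno, ca$insert, sep = "|")), , drop = FALSE]

  coords <- as.matrix(ca[, c("x", "y", "z")])
  if (any(!is.finite(coords))) {
    bad <- which(!stats::complete.cases(coords))[1]
    stop("PDB format error: non-numeric coordinates at atom serial ",
         ca$eleno[bad], call. = FALSE)
  }
  dimnames(coords) <- NULL
  new_ca_chain(
    chain_id = chain_id,
    residues = tibble::tibble(resno = ca$resno, insert = ca$insert,
                              resid = ca$resid),
    coords = coords
  )
}

new_ca_chain <- function(chain_id, residues, coords, index = NA_integer_) {
  stopifnot(nrow(residues) == nrow(coords), ncol(coords) == 3)
  if (anyDuplicated(paste(residues$resno, residues$insert))) {
    stop("duplicate residue identifiers in chain '", chain_id, "'", call. = FALSE)
  }
  structure(
    list(chain_id = chain_id, residues = residues, coords = coords,
         n = nrow(coords), index = index),
    class = "ca_chain"
  )
}

#' @export
print.ca_chain <- function(x, ...) {
  cat("<ca_chain> chain", x$chain_id, "with", x$n, "C-alpha residues\n")
  rng <- range(x$residues$resno)
  cat("  residue numbers", rng[1], "-", rng[2], "\n")
  invisible(x)
}

#' Coerce a C-alpha chain to a tibble of residue records
#'
#' @param x A `ca_chain`.
#' @param ... Unused.
#' @return A tibble with one row per residue: `chain_id`, `node` (1-based
#'   position in the retained trace), `resno`, `insert`, `resid`, `x`, `y`, `z`.
#' @method as_tibble ca_chain
#' @export
as_tibble.ca_chain <- function(x, ...) {
  tibble::tibble(
    chain_id = x$chain_id,
    node = seq_len(x$n),
    resno = x$residues$resno,
    insert = x$residues$insert,
    resid = x$residues$resid,
    x = x$coords[, 1], y = x$coords[, 2], z = x$coords[, 3]
  )
}

#' Read a hot-spot label file
#'
#' Labels are whitespace- or comma-delimited rows of
#' `chain_id residue_number [insertion_code] label` with label 0 (non-hot
#' spot) or 1 (hot spot). Lines starting with `#` and blank lines are
#' skipped. Residues absent from the file default to label 0 when joined
#' against a chain.
#'
#' @param label_source Path to a label file, or a character vector of lines.
#' @return A tibble (`label_set`) with columns `chain_id`, `resno`, `insert`,
#'   `label`.
#' @export
read_labels <- function(label_source) {
  lines <- label_source
  if (length(label_source) == 1 && !grepl("\n", label_source, fixed = TRUE) &&
      file.exists(label_source)) {
    lines <- readLines(label_source)
  } else if (length(label_source) == 1) {
    lines <- unlist(strsplit(label_source, "\n", fixed = TRUE))
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  out <- purrr::map(rows, function(i) {
    fields <- strsplit(trimws(lines[i]), "[[:space:],]+")[[1]]
    if (!length(fields) %in% c(3, 4)) {
      stop("label format error at line ", i, ": expected 3 or 4 fields, got ",
           length(fields), call. = FALSE)
    }
    lab <- fields[length(fields)]
    if (!lab %in% c("0", "1")) {
      stop("label format error at line ", i, ": label must be 0 or 1, got '",
           lab, "'", call. = FALSE)
    }
    resno <- suppressWarnings(as.integer(fields[2]))
    if (is.na(resno)) {
      stop("label format error at line ", i, ": residue number '", fields[2],
           "' is not an integer", call. = FALSE)
    }
    tibble::tibble(
      chain_id = fields[1],
      resno = resno,
      insert = if (length(fields) == 4) fields[3] else "",
      label = as.integer(lab)
    )
  })
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(chain_id = character(), resno = integer(),
                   insert = character(), label = integer())
  class(res) <- c("label_set", class(res))
  res
}

#' Write a hot-spot label file
#'
#' @param labels A tibble with `chain_id`, `resno`, `insert`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  body <- ifelse(
    labels$insert == "",
    sprintf("%s %d %d", labels$chain_id, labels$resno, labels$label),
    sprintf("%s %d %s %d", labels$chain_id, labels$resno, labels$insert,
            labels$label)
  )
  writeLines(c("# chain resno [insert] label", body), path)
  invisible(path)
}

#' Attach residue labels to a chain
#'
#' Joins a label set against a chain's residues; residues not listed in the
#' label set receive label 0. The join key is (chain id, residue number,
#' insertion code). Labeled residues that do not resolve to a residue of the
#' chain raise an error, since they indicate a chain/label mismatch.
#'
#' @param chain A `ca_chain`.
#' @param labels A label tibble as returned by [read_labels()].
#' @return Integer vector of 0/1 labels aligned with the chain's residues.
#' @export
chain_labels <- function(chain, labels) {
  y <- integer(chain$n)
  rows <- labels[labels$chain_id == chain$chain_id, , drop = FALSE]
  if (nrow(rows) == 0) return(y)
  key_chain <- paste(chain$residues$resno, chain$residues$insert, sep = "|")
  key_lab <- paste(rows$resno, rows$insert, sep = "|")
  hit <- match(key_lab, key_chain)
  if (anyNA(hit)) {
    miss <- rows[is.na(hit), , drop = FALSE]
    stop("labelled residue not present in chain ", chain$chain_id, ": resno ",
         paste(miss$resno, collapse = ", "), call. = FALSE)
  }
  y[hit] <- rows$label
  y
}

#' Assemble chains and labels into a hot-spot dataset
#'
#' The pipeline's tabular container: one row per chain with the chain object
#' and its aligned label vector as list-columns. All cross-validation and
#' grid-search functions take this tibble first, so calls chain with the
#' pipe.
#'
#' @param chains A list of `ca_chain` objects.
#' @param labels A label tibble ([read_labels()] / [plant_labels()] output),
#'   or `NULL` for all-zero labels.
#' @return A tibble with columns `chain_id`, `n`, `chain` (list), `label`
#'   (list of integer vectors).
#' @export
hotspot_data <- function(chains, labels = NULL) {
  stopifnot(length(chains) > 0)
  ids <- vapply(chains, function(ch) ch$chain_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate chain ids in dataset", call. = FALSE)
  tibble::tibble(
    chain_id = ids,
    n = vapply(chains, function(ch) ch$n, integer(1)),
    chain = chains,
    label = purrr::map(chains, function(ch) {
      if (is.null(labels)) integer(ch$n) else chain_labels(ch, labels)
    })
  )
}
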