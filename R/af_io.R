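# I/O for every external format the pipeline touches: predicted structures
# (PDB/mmCIF with pLDDT in the B-factor column), confidence JSON (pAE matrix,
# pTM/ipTM), aligned FASTA, homology-search hit tables, and result TSVs.

#' Construct a predicted model from an atom table
#'
#' A `predicted_model` is the atom-level substrate of contact detection: one
#' chain-resolved predicted structure with a per-residue confidence (pLDDT)
#' attached to every residue.
#'
#' @param atoms data.frame with columns `chain`, `resno` (1-based residue
#'   index within its chain), `resname` (3-letter code), `atom` (atom name),
#'   `element` (element symbol; hydrogens must be labelled "H"), `x`, `y`,
#'   `z` (angstrom) and `plddt` (0-100, identical for all atoms of a
#'   residue).
#' @param model_id identifier for the model.
#' @param source_path originating file path, or `NA`.
#' @return An object of class `predicted_model`.
#' @export
predicted_model <- function(atoms, model_id = "model", source_path = NA_character_) {
  needed <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z", "plddt")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms)[, needed]
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  m <- structure(
    list(model_id = model_id, atoms = atoms, source_path = source_path),
    class = "predicted_model"
  )
  validate_predicted_model(m)
  m
}

validate_predicted_model <- function(m) {
  a <- m$atoms
  if (nrow(a) == 0L) stop("model has no atoms")
  if (!all(is.finite(c(a$x, a$y, a$z)))) stop("non-finite atom coordinates")
  if (any(is.na(a$element) | a$element == "")) stop("element missing for some atoms")
  if (any(is.na(a$plddt))) stop("no confidence available: pLDDT missing for some residues")
  if (any(a$plddt < 0 | a$plddt > 100)) stop("pLDDT outside [0, 100]")
  for (ch in unique(a$chain)) {
    rn <- unique(a$resno[a$chain == ch])
    if (any(diff(rn) <= 0L)) {
      stop("residue indices not strictly increasing in chain ", ch)
    }
  }
  # AlphaFold writes one pLDDT per residue on every atom; disagreement
  # within a residue indicates a corrupted input.
  key <- paste(a$chain, a$resno)
  rng <- tapply(a$plddt, key, function(v) diff(range(v)))
  if (any(rng > 0.01)) {
    bad <- names(rng)[which(rng > 0.01)[1L]]
    stop("per-residue pLDDT disagreement (> 0.01) at residue ", bad)
  }
  invisible(m)
}

#' @export
print.predicted_model <- function(x, ...) {
  rt <- residue_table(x)
  cat("predicted_model '", x$model_id, "': ",
      length(unique(x$atoms$chain)), " chain(s), ",
      nrow(rt), " residues, ", nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Per-residue table of a predicted model
#'
#' @param model a `predicted_model`.
#' @return data.frame with one row per residue: `chain`, `resno`, `resname`,
#'   `plddt`, and `global_index` — the 1-based index of the residue in the
#'   concatenation of all chains in model order, which is the index space of
#'   the pAE matrix. The global index is always recomputed from the chain
#'   order, never stored.
#' @export
residue_table <- function(model) {
  a <- model$atoms
  first <- !duplicated(paste(a$chain, a$resno))
  rt <- data.frame(
    chain = a$chain[first], resno = a$resno[first],
    resname = a$resname[first], plddt = a$plddt[first],
    stringsAsFactors = FALSE
  )
  rt$global_index <- seq_len(nrow(rt))
  rt
}

#' Chain identifiers of a model, in file order
#' @param model a `predicted_model`.
#' @return character vector of chain ids.
#' @export
model_chains <- function(model) unique(model$atoms$chain)

element_from_name <- function(atom_name) {
  # fallback when the element column is blank: first alphabetic character of
  # the atom name (adequate for protein backbone/sidechain atoms incl. H)
  sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", atom_name)
}

#' Read a predicted structure
#'
#' Reads a PDB or mmCIF file as written by AlphaFold2 and returns a
#' [predicted_model]. For the PDB dialect, per-residue pLDDT is taken from
#' the B-factor column; all atoms of a residue must agree within 0.01 (as
#' AlphaFold writes them) or an error is raised. Hydrogen atoms are retained
#' and flagged by element.
#'
#' @param path file path.
#' @param dialect `"pdb"`, `"mmcif"`, or `"auto"` (by file extension).
#' @param plddt optional per-residue pLDDT vector (concatenated chain order)
#'   for files that carry no usable B-factor column.
#' @return a `predicted_model`.
#' @export
read_structure <- function(path, dialect = c("auto", "pdb", "mmcif"), plddt = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (dialect == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("failed to parse ", path, " as ", dialect, ": ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  elem <- at$elesy
  blank <- is.na(elem) | elem == ""
  if (any(blank)) elem[blank] <- element_from_name(at$elety[blank])
  b <- suppressWarnings(as.numeric(at$b))
  if (all(is.na(b)) || all(b == 0, na.rm = TRUE)) {
    if (is.null(plddt)) stop("no confidence available in ", path,
                             " (empty B-factor column and no pLDDT supplied)")
  }
  atoms <- data.frame(
    chain = as.character(at$chain), resno = as.integer(at$resno),
    resname = as.character(at$resid), atom = as.character(at$elety),
    element = toupper(elem), x = at$x, y = at$y, z = at$z,
    plddt = b, stringsAsFactors = FALSE
  )
  if (!is.null(plddt)) {
    key <- paste(atoms$chain, atoms$resno)
    uk <- unique(key)
    if (length(plddt) != length(uk)) {
      stop("supplied pLDDT length ", length(plddt),
           " does not match residue count ", length(uk))
    }
    atoms$plddt <- plddt[match(key, uk)]
  }
  predicted_model(atoms, model_id = sub("\\.[^.]+$", "", basename(path)),
                  source_path = path)
}

#' Write a predicted model as a PDB file
#'
#' Inverse of [read_structure()] on the PDB dialect; pLDDT is written into
#' the B-factor column of every atom. Coordinates are written to 3 decimals
#' and pLDDT to 2, the PDB fixed-format precision.
#'
#' @param model a `predicted_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  a <- model$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$resno, resid = a$resname, eleno = seq_len(nrow(a)),
    elety = a$atom, chain = a$chain, b = round(a$plddt, 2),
    elesy = a$element
  )
  invisible(path)
}

#' Construct a confidence bundle
#'
#' Holds the pairwise predicted aligned error (pAE) matrix and the global
#' pTM/ipTM scores of one predicted model. pAE is directional and is never
#' symmetrized: `pae[i, j]` is the expected error at residue j when the
#' prediction is aligned on residue i.
#'
#' @param pae square numeric matrix (angstrom), indexed over the
#'   concatenated residues of all chains in model order.
#' @param ptm,iptm optional scores in `[0, 1]`.
#' @return an object of class `confidence_bundle`.
#' @export
confidence_bundle <- function(pae, ptm = NULL, iptm = NULL) {
  pae <- as.matrix(pae)
  if (nrow(pae) != ncol(pae)) stop("pAE matrix must be square")
  if (any(pae < 0)) stop("pAE values must be >= 0")
  for (nm in c("ptm", "iptm")) {
    v <- get(nm)
    if (!is.null(v) && (v < 0 || v > 1)) stop(nm, " must lie in [0, 1]")
  }
  structure(list(pae = pae, ptm = ptm, iptm = iptm), class = "confidence_bundle")
}

#' Read an AlphaFold-style confidence JSON file
#'
#' Accepts the key `pae` or AlphaFold's `predicted_aligned_error` (possibly
#' wrapped in a one-element list, as pkl-converted files are), plus optional
#' `ptm` and `iptm`. The matrix is kept exactly as stored — no
#' symmetrization, no reordering.
#'
#' @param path JSON file path.
#' @param model optional `predicted_model`; if given, the matrix dimension is
#'   validated against the model's total residue count.
#' @return a `confidence_bundle`.
#' @export
read_confidence <- function(path, model = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(names(j)) && length(j) == 1L) j <- j[[1L]]
  pae <- j[["pae"]]
  if (is.null(pae)) pae <- j[["predicted_aligned_error"]]
  if (is.null(pae)) stop("no pAE matrix ('pae' or 'predicted_aligned_error') in ", path)
  if (is.list(pae)) pae <- do.call(rbind, pae)
  b <- confidence_bundle(pae,
                         ptm = if (!is.null(j[["ptm"]])) as.numeric(j[["ptm"]]),
                         iptm = if (!is.null(j[["iptm"]])) as.numeric(j[["iptm"]]))
  if (!is.null(model)) {
    n <- nrow(residue_table(model))
    if (nrow(b$pae) != n) {
      stop("pAE dimension mismatch: expected ", n, " residues, found ", nrow(b$pae))
    }
  }
  b
}

#' Write a confidence bundle as JSON
#' @param bundle a `confidence_bundle`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_confidence <- function(bundle, path) {
  out <- list(predicted_aligned_error = round(unname(bundle$pae), 2))
  if (!is.null(bundle$ptm)) out$ptm <- bundle$ptm
  if (!is.null(bundle$iptm)) out$iptm <- bundle$iptm
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Bundle five predicted models of a two-chain target
#'
#' AlphaFold2 Multimer emits five models per target; the *average models*
#' score measures contact agreement across them, so the bundle enforces that
#' all models share the same chain composition and residue counts.
#'
#' @param target_id identifier for the target complex.
#' @param models list of `n_models` lists, each with elements `model`
#'   (a `predicted_model`) and `confidence` (a `confidence_bundle`), in rank
#'   order (rank 1 first).
#' @param chain_roles named character vector mapping chain id to a role
#'   label (e.g. `c(A = "ORC3", B = "ORC6")`); exactly two roles.
#' @param n_models required number of models (default 5).
#' @return an object of class `multimer_prediction`.
#' @export
multimer_prediction <- function(target_id, models, chain_roles, n_models = 5L) {
  if (length(models) != n_models) {
    stop("expected ", n_models, " models, got ", length(models))
  }
  if (length(chain_roles) != 2L || is.null(names(chain_roles))) {
    stop("chain_roles must be a named vector of exactly two roles")
  }
  sig <- lapply(models, function(m) {
    rt <- residue_table(m$model)
    paste(rt$chain, rt$resno, collapse = ";")
  })
  if (length(unique(unlist(sig))) != 1L) {
    stop("models differ in chain composition or residue counts")
  }
  for (m in models) {
    n <- nrow(residue_table(m$model))
    if (nrow(m$confidence$pae) != n) {
      stop("pAE dimension mismatch: expected ", n, " residues, found ",
           nrow(m$confidence$pae))
    }
  }
  structure(list(target_id = target_id, models = models,
                 chain_roles = chain_roles),
            class = "multimer_prediction")
}

#' Read an aligned FASTA multiple sequence alignment
#'
#' @param path aligned FASTA file; gap character `-`; all rows must have
#'   equal length and unique identifiers.
#' @return object of class `msa`: list with `ids`, `seqs` (named uppercase
#'   character vector) and `width`.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  msa(ids, seqs)
}

#' Construct an alignment object
#' @param ids sequence identifiers (unique).
#' @param seqs aligned sequences (equal length, gap `-`).
#' @return an `msa` object.
#' @export
msa <- function(ids, seqs) {
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifier: ", ids[duplicated(ids)][1L])
  }
  w <- unique(nchar(seqs))
  if (length(w) != 1L) {
    # the first sequence defines the alignment width
    bad <- ids[nchar(seqs) != nchar(seqs[[1L]])][1L]
    stop("ragged alignment: row '", bad, "' differs in length")
  }
  names(seqs) <- ids
  structure(list(ids = ids, seqs = toupper(seqs), width = w), class = "msa")
}

#' Write an alignment as aligned FASTA
#' @param aln an `msa`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  writeLines(as.vector(rbind(paste0(">", aln$ids), aln$seqs)), path)
  invisible(path)
}

hit_table_columns <- c("query_subunit", "species", "taxon_group", "accession",
                       "percent_identity", "query_coverage", "sequence_length",
                       "is_partial", "has_X_residues")

#' Read a homology-search hit table
#'
#' Tab-delimited text with the named columns `query_subunit`, `species`,
#' `taxon_group`, `accession`, `percent_identity`, `query_coverage`,
#' `sequence_length`, `is_partial`, `has_X_residues`. Unknown columns are
#' kept (e.g. `covered_start`/`covered_end` used by [sequence_qc()], or a
#' search-program provenance column); a missing mandatory column is an
#' error.
#'
#' @param path TSV file path.
#' @return data.frame of hit records with parsed numeric/logical fields.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  h <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, comment.char = "#")
  missing_cols <- setdiff(hit_table_columns, names(h))
  if (length(missing_cols) > 0L) {
    stop("hit table lacks mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("percent_identity", "query_coverage")) {
    h[[col]] <- as.numeric(h[[col]])
    if (any(h[[col]] < 0 | h[[col]] > 100, na.rm = TRUE)) {
      stop(col, " outside [0, 100]")
    }
  }
  h$sequence_length <- as.integer(h$sequence_length)
  h$is_partial <- as.logical(h$is_partial)
  h$has_X_residues <- as.logical(h$has_X_residues)
  h
}

#' Write a result table with threshold metadata in the header
#'
#' Metadata (thresholds, seeds, package version) is echoed as `# key: value`
#' comment lines above the column header, so every result file records the
#' parameters that produced it.
#'
#' @param df data.frame to write.
#' @param path output TSV path.
#' @param meta named list of metadata values.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, meta = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, paste(meta[[nm]], collapse = ",")), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#' @param path TSV path.
#' @return data.frame; header metadata in attribute `"meta"`.
#' @export
read_result_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (l in hdr) {
    kv <- sub("^# ", "", l)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- sub("^[^:]+: ?", "", kv)
  }
  df <- read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  df
}
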