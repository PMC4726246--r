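#' Multi-frame structure model
#'
#' A `structure_model` holds a fixed atom table plus an ordered list of
#' coordinate frames (one per PDB MODEL record), the representation used by
#' all distance and RMSD operations.  Hydrogen atoms, if present in the
#' input, are dropped: all distance operations are defined over heavy atoms.
#'
#' @param atoms Data frame with columns `eleno`, `elety`, `resid`, `resno`,
#'   `chain`, `insert` (optional, defaults to `""`).
#' @param frames List of numeric matrices, each `nrow(atoms)` x 3 (x, y, z
#'   in Angstrom).
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, frames) {
  stopifnot(is.data.frame(atoms), is.list(frames), length(frames) >= 1L)
  need <- c("eleno", "elety", "resid", "resno", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$elesy <- .atom_element(atoms$elety)
  keep <- atoms$elesy != "H"
  atoms <- atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (ncol(f) != 3L) stop("each frame must be an n x 3 coordinate matrix")
    f <- f[keep, , drop = FALSE]
    if (nrow(f) != nrow(atoms))
      stop("frame atom count (", nrow(f), ") does not match atom table (",
           nrow(atoms), ")")
    dimnames(f) <- list(NULL, c("x", "y", "z"))
    f
  })
  structure(list(atoms = atoms, frames = frames), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", nrow(x$atoms), "heavy atoms,",
      length(x$frames), "frame(s),",
      length(unique(x$atoms$chain)), "chain(s) [",
      paste(sort(unique(x$atoms$chain)), collapse = ", "), "]\n")
  invisible(x)
}

#' Read a (multi-model) PDB file into a structure model
#'
#' Uses [bio3d::read.pdb()] with `multi = TRUE`; MODEL/ENDMDL records become
#' frames in file order.  Residue numbering, chain ids and insertion codes
#' are taken verbatim from the file.
#'
#' @param path Path to a PDB file.
#' @return A [structure_model()].
#' @export
read_structure_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(eleno = at$eleno, elety = at$elety, resid = at$resid,
                      resno = at$resno, chain = at$chain,
                      insert = ifelse(is.na(at$insert), "", at$insert),
                      stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  frames <- lapply(seq_len(nrow(xyz)), function(k)
    matrix(xyz[k, ], ncol = 3L, byrow = TRUE))
  structure_model(atoms, frames)
}

#' Write a structure model as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, fixed-column ATOM records, coordinates
#' at the PDB standard 3 decimals (so round-trips are exact to 0.001 A).
#'
#' @param model A [structure_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  xyz <- do.call(rbind, lapply(model$frames, function(f) as.vector(t(f))))
  a <- model$atoms
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno, resid = a$resid,
                   eleno = a$eleno, elety = a$elety, chain = a$chain,
                   insert = ifelse(a$insert == "", NA, a$insert))
  invisible(path)
}

# Index of one atom (chain, resno[, insert], elety) in the atom table;
# errors with a descriptive message when absent.
.atom_index <- function(model, chain, resno, elety, insert = "") {
  a <- model$atoms
  i <- which(a$chain == chain & a$resno == resno & a$elety == elety &
               a$insert == insert)
  if (length(i) == 0L)
    stop("atom ", elety, " of residue ", resno, insert, " chain ", chain,
         " not found in structure")
  i[1L]
}

# Residue rows (atom-table indices) of one residue.
.residue_rows <- function(model, chain, resno, insert = "") {
  a <- model$atoms
  i <- which(a$chain == chain & a$resno == resno & a$insert == insert)
  if (!length(i))
    stop("residue ", resno, insert, " chain ", chain, " not found in structure")
  i
}

# Per-frame coordinates of one atom as an n_frames x 3 matrix.
.atom_track <- function(model, idx) {
  do.call(rbind, lapply(model$frames, function(f) f[idx, , drop = FALSE]))
}
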