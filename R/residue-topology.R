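# Idealised side-chain topology for the 20 standard amino acids.
#
# Each side-chain atom is given in internal (Z-matrix) coordinates relative
# to three previously placed atoms: bond length to `parent` (Angstrom), bond
# angle with `ref2` (degrees), torsion ref3-ref2-parent-atom (degrees).
# Backbone atoms (N, CA, C, O) are placed by the helix generator.  Rotamers
# are fixed (chi ~ trans) -- the geometry is idealised, intended for
# synthetic structures with plausible (not force-field-accurate) side-chain
# reach.  Bond graph order doubles as the side-chain tree used by the
# reference-carbon branching rule.

.sc_def <- function(...) {
  m <- rbind(...)
  data.frame(atom = m[, 1], parent = m[, 2], ref2 = m[, 3], ref3 = m[, 4],
             length = as.numeric(m[, 5]), angle = as.numeric(m[, 6]),
             torsion = as.numeric(m[, 7]), stringsAsFactors = FALSE)
}

.cb <- c("CB", "CA", "N", "C", "1.530", "110.4", "-122.0")

.sidechain_topology <- list(
  GLY = .sc_def()[0, ],
  ALA = .sc_def(.cb),
  SER = .sc_def(.cb, c("OG",  "CB", "CA", "N", "1.420", "110.8", "180")),
  CYS = .sc_def(.cb, c("SG",  "CB", "CA", "N", "1.810", "114.4", "180")),
  VAL = .sc_def(.cb, c("CG1", "CB", "CA", "N", "1.530", "110.5", "180"),
                     c("CG2", "CB", "CA", "N", "1.530", "110.5", "-60")),
  THR = .sc_def(.cb, c("OG1", "CB", "CA", "N", "1.430", "109.6", "180"),
                     c("CG2", "CB", "CA", "N", "1.530", "110.5", "-60")),
  ILE = .sc_def(.cb, c("CG1", "CB", "CA", "N",  "1.530", "110.4", "180"),
                     c("CG2", "CB", "CA", "N",  "1.530", "110.5", "-60"),
                     c("CD1", "CG1", "CB", "CA", "1.520", "113.8", "180")),
  LEU = .sc_def(.cb, c("CG",  "CB", "CA", "N",  "1.530", "116.3", "180"),
                     c("CD1", "CG", "CB", "CA", "1.520", "110.7", "180"),
                     c("CD2", "CG", "CB", "CA", "1.520", "110.7", "60")),
  MET = .sc_def(.cb, c("CG", "CB", "CA", "N",  "1.520", "114.1", "180"),
                     c("SD", "CG", "CB", "CA", "1.800", "112.7", "180"),
                     c("CE", "SD", "CG", "CB", "1.790", "100.8", "180")),
  PHE = .sc_def(.cb, c("CG",  "CB",  "CA", "N",  "1.500", "113.8", "180"),
                     c("CD1", "CG",  "CB", "CA", "1.390", "120.3", "90"),
                     c("CD2", "CG",  "CB", "CA", "1.390", "120.3", "-90"),
                     c("CE1", "CD1", "CG", "CB", "1.390", "120.6", "180"),
                     c("CE2", "CD2", "CG", "CB", "1.390", "120.6", "180"),
                     c("CZ",  "CE1", "CD1", "CG", "1.390", "120.0", "0")),
  TYR = .sc_def(.cb, c("CG",  "CB",  "CA", "N",  "1.500", "113.8", "180"),
                     c("CD1", "CG",  "CB", "CA", "1.390", "120.3", "90"),
                     c("CD2", "CG",  "CB", "CA", "1.390", "120.3", "-90"),
                     c("CE1", "CD1", "CG", "CB", "1.390", "120.6", "180"),
                     c("CE2", "CD2", "CG", "CB", "1.390", "120.6", "180"),
                     c("CZ",  "CE1", "CD1", "CG", "1.390", "120.0", "0"),
                     c("OH",  "CZ",  "CE1", "CD1", "1.380", "119.9", "180")),
  TRP = .sc_def(.cb, c("CG",  "CB",  "CA",  "N",   "1.500", "113.6", "180"),
                     c("CD1", "CG",  "CB",  "CA",  "1.370", "126.9", "90"),
                     c("CD2", "CG",  "CB",  "CA",  "1.430", "126.7", "-90"),
                     c("NE1", "CD1", "CG",  "CB",  "1.380", "110.2", "180"),
                     c("CE2", "NE1", "CD1", "CG",  "1.370", "109.0", "0"),
                     c("CE3", "CD2", "CG",  "CB",  "1.400", "133.9", "0"),
                     c("CZ2", "CE2", "NE1", "CD1", "1.400", "122.4", "180"),
                     c("CZ3", "CE3", "CD2", "CG",  "1.390", "118.8", "180"),
                     c("CH2", "CZ2", "CE2", "NE1", "1.370", "117.5", "0")),
  HIS = .sc_def(.cb, c("CG",  "CB",  "CA", "N",  "1.500", "113.8", "180"),
                     c("ND1", "CG",  "CB", "CA", "1.380", "122.7", "90"),
                     c("CD2", "CG",  "CB", "CA", "1.360", "131.0", "-90"),
                     c("CE1", "ND1", "CG", "CB", "1.320", "109.3", "180"),
                     c("NE2", "CD2", "CG", "CB", "1.370", "107.2", "180")),
  ASP = .sc_def(.cb, c("CG",  "CB", "CA", "N",  "1.520", "113.1", "180"),
                     c("OD1", "CG", "CB", "CA", "1.250", "118.2", "0"),
                     c("OD2", "CG", "CB", "CA", "1.250", "118.2", "180")),
  ASN = .sc_def(.cb, c("CG",  "CB", "CA", "N",  "1.520", "112.7", "180"),
                     c("OD1", "CG", "CB", "CA", "1.230", "120.9", "0"),
                     c("ND2", "CG", "CB", "CA", "1.330", "116.5", "180")),
  GLU = .sc_def(.cb, c("CG",  "CB", "CA", "N",  "1.520", "114.1", "180"),
                     c("CD",  "CG", "CB", "CA", "1.520", "112.6", "180"),
                     c("OE1", "CD", "CG", "CB", "1.250", "118.2", "0"),
                     c("OE2", "CD", "CG", "CB", "1.250", "118.2", "180")),
  GLN = .sc_def(.cb, c("CG",  "CB", "CA", "N",  "1.520", "114.1", "180"),
                     c("CD",  "CG", "CB", "CA", "1.520", "112.6", "180"),
                     c("OE1", "CD", "CG", "CB", "1.230", "120.9", "0"),
                     c("NE2", "CD", "CG", "CB", "1.330", "116.5", "180")),
  LYS = .sc_def(.cb, c("CG", "CB", "CA", "N",  "1.520", "114.1", "180"),
                     c("CD", "CG", "CB", "CA", "1.520", "111.3", "180"),
                     c("CE", "CD", "CG", "CB", "1.520", "111.3", "180"),
                     c("NZ", "CE", "CD", "CG", "1.490", "111.9", "180")),
  ARG = .sc_def(.cb, c("CG",  "CB", "CA", "N",  "1.520", "114.1", "180"),
                     c("CD",  "CG", "CB", "CA", "1.520", "111.3", "180"),
                     c("NE",  "CD", "CG", "CB", "1.460", "112.0", "180"),
                     c("CZ",  "NE", "CD", "CG", "1.330", "124.2", "180"),
                     c("NH1", "CZ", "NE", "CD", "1.330", "120.0", "0"),
                     c("NH2", "CZ", "NE", "CD", "1.330", "120.0", "180")),
  PRO = .sc_def(c("CB", "CA", "N", "C", "1.530", "103.2", "-120"),
                c("CG", "CB", "CA", "N", "1.490", "104.5", "30"),
                c("CD", "CG", "CB", "CA", "1.510", "105.5", "-35")))

#' Side-chain topology of a standard residue
#'
#' Returns the idealised internal-coordinate definition of a residue's
#' side-chain heavy atoms (used by the synthetic-structure generator and by
#' the reference-carbon branching rule).
#'
#' @param resid Three-letter residue name (upper case).
#' @return Data frame with one row per side-chain heavy atom: `atom`,
#'   `parent`, `ref2`, `ref3`, `length`, `angle`, `torsion`.
#' @export
sidechain_topology <- function(resid) {
  resid <- toupper(resid)
  if (!resid %in% names(.sidechain_topology))
    stop("not a standard residue: ", resid)
  .sidechain_topology[[resid]]
}

# Element symbol from a PDB atom name ("CG1" -> "C", "OD1" -> "O", ...).
.atom_element <- function(elety) sub("^([A-Z]).*$", "\\1", toupper(elety))

#' Reference-carbon table for distance measurements
#'
#' Residue-pair distances in the contact analysis are measured between one
#' predefined side-chain carbon per residue: the carbon sitting just before
#' the last branching point ("ramification") of the side chain, so that the
#' measured point is insensitive to the terminal branch orientation.
#' Unbranched side chains use their terminal carbon and glycine falls back
#' to CA.  Two entries are deliberate overrides of that rule: MET uses CG
#' (keeping the point before the thioether sulfur rather than the terminal
#' methyl) and PRO uses CG (the ring closes onto the backbone nitrogen).
#' The table is returned as a plain named vector so callers can edit it and
#' pass the modified rule to [distance_series()] or [contact_matrix()].
#'
#' @return Named character vector mapping residue name to atom name.
#' @seealso [select_reference_carbon()], [derive_reference_carbon()]
#' @export
reference_carbon_table <- function() {
  c(ALA = "CB", ARG = "CZ", ASN = "CG", ASP = "CG", CYS = "CB",
    GLN = "CD", GLU = "CD", GLY = "CA", HIS = "CG", ILE = "CB",
    LEU = "CG", LYS = "CE", MET = "CG", PHE = "CG", PRO = "CG",
    SER = "CB", THR = "CB", TRP = "CG", TYR = "CG", VAL = "CB")
}

#' Reference carbon for one residue type
#'
#' @param resid Three-letter residue name.
#' @param rule Mapping residue -> atom name; defaults to
#'   [reference_carbon_table()].
#' @return Atom name (e.g. `"CG"` for LEU).
#' @export
#' @examples
#' select_reference_carbon("LEU")  # "CG"
select_reference_carbon <- function(resid, rule = reference_carbon_table()) {
  resid <- toupper(resid)
  atom <- rule[resid]
  if (any(is.na(atom)))
    stop("no reference-carbon rule for residue(s): ",
         paste(resid[is.na(atom)], collapse = ", "),
         " (supply an override via 'rule')")
  unname(atom)
}

#' Derive the reference carbon from the side-chain branching rule
#'
#' Walks the residue's side-chain tree and returns the last (deepest)
#' side-chain carbon whose set of heavy-atom successors branches into two or
#' more atoms; unbranched side chains map to their deepest carbon, glycine
#' to CA.  This reproduces [reference_carbon_table()] for every residue
#' except the two documented overrides (MET, PRO).
#'
#' @param resid Three-letter residue name.
#' @return Atom name.
#' @export
derive_reference_carbon <- function(resid) {
  resid <- toupper(resid)
  topo <- sidechain_topology(resid)
  if (nrow(topo) == 0L) return("CA")
  children <- function(a) topo$atom[topo$parent == a]
  depth <- function(a) {
    d <- 0L
    while (a != "CA") {
      a <- if (a %in% topo$atom) topo$parent[topo$atom == a] else "CA"
      d <- d + 1L
    }
    d
  }
  carbons <- topo$atom[.atom_element(topo$atom) == "C"]
  branched <- carbons[vapply(carbons, function(a) length(children(a)) >= 2L,
                             logical(1))]
  if (length(branched))
    return(branched[which.max(vapply(branched, depth, integer(1)))])
  carbons[which.max(vapply(carbons, depth, integer(1)))]
}
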