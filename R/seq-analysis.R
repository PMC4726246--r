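#' @keywords internal
.aa1 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

# Split a sequence argument (single string or character vector of single
# letters) into a validated upper-case letter vector.
.as_residues <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1L]]
  sequence <- toupper(sequence)
  bad <- setdiff(unique(sequence), .aa1)
  if (length(bad))
    stop("sequence contains non-standard residue letter(s): ",
         paste(bad, collapse = ", "),
         " (ambiguity codes are rejected, not imputed)")
  sequence
}

#' Parse residue labels of the form "L48"
#'
#' Converts labels combining a one-letter amino-acid code and a 1-based
#' sequence position (the conventional mutagenesis notation, e.g. `"Y59"`)
#' into a data frame.  Plain integers are accepted and get `NA` identities.
#'
#' @param x Character vector of labels, or an integer vector of positions.
#' @return Data frame with columns `aa` (one-letter code or `NA`) and `pos`.
#' @export
#' @examples
#' parse_residue(c("L48", "Y59"))
parse_residue <- function(x) {
  if (is.numeric(x)) {
    if (any(x < 1 | x != round(x)))
      stop("residue positions must be positive integers")
    return(data.frame(aa = rep(NA_character_, length(x)),
                      pos = as.integer(x)))
  }
  m <- regmatches(x, regexec("^([A-Za-z])([0-9]+)$", x))
  ok <- lengths(m) == 3L
  if (!all(ok))
    stop("cannot parse residue label(s): ", paste(x[!ok], collapse = ", "))
  aa <- toupper(vapply(m, `[`, "", 2L))
  bad <- setdiff(unique(aa), .aa1)
  if (length(bad))
    stop("unknown amino-acid code(s): ", paste(bad, collapse = ", "))
  pos <- as.integer(vapply(m, `[`, "", 3L))
  if (any(pos < 1)) stop("residue positions must be >= 1")
  data.frame(aa = aa, pos = pos)
}

#' Assign heptad letters relative to a register anchor
#'
#' Coiled-coil positions are labelled `a`-`g` with period 7; the anchor
#' position is defined to be an `a` site and consecutive positions advance
#' one letter cyclically.
#'
#' @param anchor 1-based position assigned the letter `a`.
#' @param pos Vector of 1-based positions to label.
#' @return Character vector of letters in `a`-`g`.
#' @export
#' @examples
#' assign_heptad(38, c(38, 41, 53, 54))  # "a" "d" "b" "c"
assign_heptad <- function(anchor, pos) {
  stopifnot(length(anchor) == 1L, anchor >= 1, all(pos >= 1))
  letters[((pos - anchor) %% 7) + 1L]
}

#' Count hits falling on a set of heptad site classes
#'
#' Tallies how many residues of a hit list land on given heptad positions
#' (e.g. the hydrophobic core sites `a` and `d`) under a register anchor.
#'
#' @param hits Residue positions: integer vector, labels like `"L48"`, or a
#'   data frame with a `pos` column (see [parse_residue()]).
#' @param anchor Register anchor position (an `a` site).
#' @param classes Non-empty subset of `letters[1:7]`.
#' @return Integer count.
#' @export
#' @examples
#' count_site_classes(c(48, 52, 53, 54, 55, 59, 62), 38, c("a", "d"))  # 5
count_site_classes <- function(hits, anchor, classes) {
  if (is.data.frame(hits)) pos <- hits$pos
  else pos <- parse_residue(hits)$pos
  if (!length(pos)) stop("hit list is empty")
  classes <- unique(tolower(classes))
  if (!length(classes) || !all(classes %in% letters[1:7]))
    stop("'classes' must be a non-empty subset of letters a-g")
  sum(assign_heptad(anchor, pos) %in% classes)
}

#' Scan a sequence for N-glycosylation sequons
#'
#' Finds every N-X-\[S/T\] motif with X != P.  A sequon is additionally
#' flagged as `disrupted_by_proline` when the residue immediately following
#' the S/T is a proline, which abolishes glycosylation at the asparagine
#' even though the N-X-S/T match itself is intact (the flag is informative;
#' the sequon is kept in the output).
#'
#' @param sequence Amino-acid sequence (string or letter vector).
#' @return Data frame with columns `asn_pos`, `motif` (the three motif
#'   residues) and `disrupted_by_proline`; zero rows when no sequon exists.
#' @export
#' @examples
#' scan_sequons("RYNLSQ")   # N at 3, motif "NLS", intact
#' scan_sequons("RYNLSP")   # same sequon, proline-disrupted
scan_sequons <- function(sequence) {
  s <- .as_residues(sequence)
  n <- length(s)
  out <- data.frame(asn_pos = integer(), motif = character(),
                    disrupted_by_proline = logical())
  if (n < 3L) return(out)
  for (i in seq_len(n - 2L)) {
    if (s[i] == "N" && s[i + 1L] != "P" && s[i + 2L] %in% c("S", "T")) {
      out <- rbind(out, data.frame(
        asn_pos = i,
        motif = paste0(s[i], s[i + 1L], s[i + 2L]),
        disrupted_by_proline = (i + 3L <= n && s[i + 3L] == "P")))
    }
  }
  rownames(out) <- NULL
  out
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [bio3d::read.fasta()] returning plain sequence
#' strings (alignment gaps, if any, are dropped).
#'
#' @param path Path to a FASTA file (single or multi record).
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  aln <- bio3d::read.fasta(path, rm.dup = FALSE)
  seqs <- apply(aln$ali, 1L, function(row)
    paste0(row[!row %in% c("-", ".")], collapse = ""))
  setNames(toupper(seqs), aln$id)
}
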