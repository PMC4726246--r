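#' Distance series between two residues across frames
#'
#' Measures, in every frame, the Euclidean distance between the reference
#' carbons of two residues (see [reference_carbon_table()]) and summarises
#' it as mean and standard deviation.  The pair is labelled `inter` when the
#' two chain ids differ, `intra` otherwise.
#'
#' @param model A [structure_model()].
#' @param res_a,res_b Lists (or one-row data frames) with elements `chain`
#'   and `resno` (optional `insert`).
#' @param rule Reference-carbon mapping, default [reference_carbon_table()].
#' @return Object of class `distance_series`: list with `res_a`, `res_b`,
#'   `atoms` (the two atom names used), `d` (per-frame distances, Angstrom),
#'   `mean`, `sd` and `relationship`.
#' @export
distance_series <- function(model, res_a, res_b,
                            rule = reference_carbon_table()) {
  stopifnot(inherits(model, "structure_model"))
  get_atom <- function(r) {
    ins <- if (is.null(r$insert)) "" else r$insert
    rows <- .residue_rows(model, r$chain, r$resno, ins)
    resid <- unique(model$atoms$resid[rows])[1L]
    elety <- select_reference_carbon(resid, rule)
    .atom_index(model, r$chain, r$resno, elety, ins)
  }
  ia <- get_atom(res_a); ib <- get_atom(res_b)
  d <- sqrt(rowSums((.atom_track(model, ia) - .atom_track(model, ib))^2))
  structure(list(
    res_a = res_a, res_b = res_b,
    atoms = c(model$atoms$elety[ia], model$atoms$elety[ib]),
    d = d, mean = mean(d), sd = if (length(d) > 1L) sd(d) else 0,
    relationship = if (identical(res_a$chain, res_b$chain)) "intra" else "inter"),
    class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("%s%s/%s -- %s%s/%s  (%s, %s-%s): %.2f +/- %.2f A over %d frame(s)\n",
              x$res_a$chain, x$res_a$resno, x$atoms[1],
              x$res_b$chain, x$res_b$resno, x$atoms[2],
              x$relationship, x$atoms[1], x$atoms[2],
              x$mean, x$sd, length(x$d)))
  invisible(x)
}

#' Residue-pair contact matrix over a trajectory
#'
#' Builds the full distance summary over a residue set for a dimer: for
#' every unordered residue pair \{i, j\} the inter-subunit series (residue i
#' on one chain vs residue j on the other) and, optionally, the
#' intra-subunit series.  Because the two symmetry-related copies of an
#' inter-subunit contact (i on A with j on B, and j on A with i on B) are
#' distinct in real coordinates, the cell of the unordered pair is the
#' per-frame **minimum** of the two copies, which makes the matrix exactly
#' symmetric; the same convention (minimum over the two chains) is used for
#' intra-subunit cells.  The diagonal holds homotypic pairs: residue i with
#' residue i of the opposing subunit.
#'
#' @param model A [structure_model()] with exactly the two chains in
#'   `chains` (more chains are allowed; only `chains` is analysed).
#' @param residues Integer vector of residue numbers (present in both
#'   chains).
#' @param chains Length-2 character vector of chain ids (default the first
#'   two chains of the model).
#' @param rule Reference-carbon mapping.
#' @param include_intra Also compute intra-subunit cells (default `TRUE`).
#' @return Object of class `cap_contact_matrix`: a data frame with columns
#'   `res_i`, `res_j`, `resid_i`, `resid_j`, `relationship`, `mean`, `sd`,
#'   and attributes `residues`, `chains`, `n_frames`, `series` (named list
#'   of per-frame distance vectors).
#' @export
contact_matrix <- function(model, residues, chains = NULL,
                           rule = reference_carbon_table(),
                           include_intra = TRUE) {
  stopifnot(inherits(model, "structure_model"))
  if (is.null(chains)) chains <- sort(unique(model$atoms$chain))[1:2]
  if (length(chains) != 2L || anyNA(chains))
    stop("inter-subunit analysis needs exactly two chains")
  residues <- sort(unique(as.integer(residues)))

  dser <- function(ri, ci, rj, cj)
    distance_series(model, list(chain = ci, resno = ri),
                    list(chain = cj, resno = rj), rule)$d

  rows <- list(); series <- list()
  resname <- function(r, ch)
    unique(model$atoms$resid[.residue_rows(model, ch, r)])[1L]
  for (ii in seq_along(residues)) for (jj in ii:length(residues)) {
    i <- residues[ii]; j <- residues[jj]
    # inter: minimum over the two symmetry-related copies
    d_inter <- pmin(dser(i, chains[1], j, chains[2]),
                    dser(j, chains[1], i, chains[2]))
    key <- paste0(i, ":", j, ":inter")
    series[[key]] <- d_inter
    rows[[key]] <- data.frame(
      res_i = i, res_j = j,
      resid_i = resname(i, chains[1]), resid_j = resname(j, chains[1]),
      relationship = "inter", mean = mean(d_inter),
      sd = if (length(d_inter) > 1L) sd(d_inter) else 0)
    if (include_intra && i != j) {
      d_intra <- pmin(dser(i, chains[1], j, chains[1]),
                      dser(i, chains[2], j, chains[2]))
      key <- paste0(i, ":", j, ":intra")
      series[[key]] <- d_intra
      rows[[key]] <- data.frame(
        res_i = i, res_j = j,
        resid_i = resname(i, chains[1]), resid_j = resname(j, chains[1]),
        relationship = "intra", mean = mean(d_intra),
        sd = if (length(d_intra) > 1L) sd(d_intra) else 0)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, residues = residues, chains = chains,
            n_frames = length(model$frames), series = series,
            class = c("cap_contact_matrix", "data.frame"))
}

#' Call interactions at a distance cutoff
#'
#' An interaction is called when the **mean** reference-carbon distance of a
#' pair is less than or equal to the cutoff (inclusive boundary).  The
#' relatively remote default of 6.0 Angstrom (rather than ~4 Angstrom for
#' direct carbon-carbon contact) compensates for the reference carbon not
#' being the closest atom of the side chain and for hydrogens being ignored.
#'
#' @param cm A `cap_contact_matrix` (or any data frame with a `mean`
#'   column).
#' @param cutoff Distance cutoff in Angstrom, > 0 (default 6.0).
#' @return `cm` with a logical `call` column added and attribute `cutoff`.
#' @export
call_interactions <- function(cm, cutoff = 6.0) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a single positive number (Angstrom)")
  cm$call <- cm$mean <= cutoff
  attr(cm, "cutoff") <- cutoff
  cm
}

#' Minimum side-chain heavy-atom distance in one frame
#'
#' The minimum over all pairs of side-chain heavy atoms (backbone N, CA, C,
#' O, OXT excluded) of the two residues.  Glycine, having no side-chain
#' heavy atom, falls back to CA.  Always less than or equal to the
#' reference-carbon distance for the same pair and frame.
#'
#' @inheritParams distance_series
#' @param frame Frame index (1-based).
#' @return Distance in Angstrom.
#' @export
min_sidechain_distance <- function(model, res_a, res_b, frame = 1L) {
  stopifnot(inherits(model, "structure_model"))
  if (frame < 1L || frame > length(model$frames))
    stop("frame ", frame, " out of range (model has ",
         length(model$frames), " frames)")
  backbone <- c("N", "CA", "C", "O", "OXT")
  side_rows <- function(r) {
    ins <- if (is.null(r$insert)) "" else r$insert
    rows <- .residue_rows(model, r$chain, r$resno, ins)
    sc <- rows[!model$atoms$elety[rows] %in% backbone]
    if (!length(sc)) sc <- rows[model$atoms$elety[rows] == "CA"]
    sc
  }
  ra <- side_rows(res_a); rb <- side_rows(res_b)
  f <- model$frames[[frame]]
  A <- f[ra, , drop = FALSE]; B <- f[rb, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(min(d2), 0))
}

#' Kabsch-superposed (or raw) RMSD between two coordinate sets
#'
#' With `superpose = TRUE` the second set is optimally least-squares
#' aligned onto the first (Kabsch algorithm via SVD, reflection-corrected)
#' before the root-mean-square deviation is computed; with
#' `superpose = FALSE` the raw RMSD of the coordinates as given.
#'
#' @param a,b Numeric n x 3 coordinate matrices with matching row order.
#' @param superpose Align before measuring (default `TRUE`).
#' @return RMSD in Angstrom.
#' @export
rmsd_kabsch <- function(a, b, superpose = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)) || ncol(a) != 3L)
    stop("coordinate sets must be n x 3 matrices of equal size")
  if (superpose) {
    if (nrow(a) < 3L) stop("superposition needs at least 3 atoms")
    ca <- colMeans(a); cb <- colMeans(b)
    a0 <- sweep(a, 2L, ca); b0 <- sweep(b, 2L, cb)
    s <- svd(crossprod(b0, a0))
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    b <- sweep(b0 %*% t(R), 2L, ca, "+")
    a <- a0 + matrix(ca, nrow(a), 3L, byrow = TRUE)
  }
  sqrt(mean(rowSums((a - b)^2)))
}

#' Per-frame RMSD of a trajectory against a reference frame
#'
#' Stability check for multi-frame models: RMSD of every frame against a
#' reference frame over a named atom selection (default the C-alpha trace),
#' after Kabsch superposition.
#'
#' @param model A [structure_model()].
#' @param ref Reference frame index (default 1).
#' @param elety Atom names to include (default `"CA"`).
#' @param superpose Align each frame first (default `TRUE`).
#' @return Numeric vector, one RMSD (Angstrom) per frame.
#' @export
frame_rmsd <- function(model, ref = 1L, elety = "CA", superpose = TRUE) {
  stopifnot(inherits(model, "structure_model"))
  sel <- which(model$atoms$elety %in% elety)
  if (!length(sel)) stop("selection matches no atoms")
  refxyz <- model$frames[[ref]][sel, , drop = FALSE]
  vapply(model$frames, function(f)
    rmsd_kabsch(refxyz, f[sel, , drop = FALSE], superpose), numeric(1))
}

#' Frames collected over a trajectory
#'
#' Number of structures collected when sampling a trajectory of the given
#' duration at a fixed interval: `duration / interval`, i.e. one structure
#' at the end of every interval and none at t = 0 (10 ns sampled every 4 ps
#' gives exactly 2500 frames).
#'
#' @param duration_ps Trajectory duration in ps, > 0.
#' @param interval_ps Sampling interval in ps, > 0; must divide the
#'   duration.
#' @return Integer frame count.
#' @export
#' @examples
#' frame_count(10 * 1000, 4)  # 2500
frame_count <- function(duration_ps, interval_ps) {
  if (!is.numeric(duration_ps) || !is.numeric(interval_ps) ||
      duration_ps <= 0 || interval_ps <= 0)
    stop("duration and interval must both be positive")
  n <- duration_ps / interval_ps
  if (abs(n - round(n)) > 1e-9 * max(1, n))
    stop("duration (", duration_ps, " ps) is not a multiple of the ",
         "sampling interval (", interval_ps, " ps)")
  as.integer(round(n))
}

#' Format a contact matrix in square (publication) layout
#'
#' Square character matrix over the residue set: diagonal and lower
#' triangle = inter-subunit cells (the diagonal being homotypic pairs,
#' residue i with i of the neighbouring subunit), upper triangle =
#' intra-subunit cells.  Cells read `"mean +/- sd"` with a `*` appended on
#' called interactions when calls are present.
#'
#' @param cm A `cap_contact_matrix`, ideally after [call_interactions()].
#' @param digits Decimals for mean/sd (default 1).
#' @return Character matrix with residue labels as dimnames.
#' @export
format_contact_table <- function(cm, digits = 1) {
  res <- attr(cm, "residues")
  lab <- vapply(res, function(r) {
    ri <- cm$resid_i[match(r, cm$res_i)]
    if (is.na(ri)) as.character(r) else paste0(bio3d::aa321(ri), r)
  }, character(1))
  out <- matrix("", length(res), length(res), dimnames = list(lab, lab))
  fmt <- function(row) {
    s <- sprintf("%.*f +/- %.*f", digits, row$mean, digits, row$sd)
    if (!is.null(row$call) && isTRUE(row$call)) paste0(s, " *") else s
  }
  for (k in seq_len(nrow(cm))) {
    i <- match(cm$res_i[k], res); j <- match(cm$res_j[k], res)
    if (cm$relationship[k] == "inter") out[max(i, j), min(i, j)] <- fmt(cm[k, ])
    else out[min(i, j), max(i, j)] <- fmt(cm[k, ])
  }
  out
}

#' Read a tidy contact-matrix CSV back into a `cap_contact_matrix`
#'
#' Inverse of [write_contact_csv()] for the tidy layout (per-frame series
#' are not stored in CSV and are therefore absent after a round trip).
#'
#' @param path CSV path written by `write_contact_csv(..., layout = "tidy")`.
#' @return A `cap_contact_matrix`.
#' @export
read_contact_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("res_i", "res_j", "relationship", "mean", "sd")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("contact CSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  structure(x, residues = sort(unique(c(x$res_i, x$res_j))),
            class = c("cap_contact_matrix", "data.frame"))
}

#' Write a contact matrix to CSV
#'
#' Writes the tidy pair table (one row per residue pair and relationship);
#' with `layout = "square"` the publication-style square table from
#' [format_contact_table()] is written instead.
#'
#' @param cm A `cap_contact_matrix`.
#' @param path Output CSV path.
#' @param layout `"tidy"` (default) or `"square"`.
#' @return `path`, invisibly.
#' @export
write_contact_csv <- function(cm, path, layout = c("tidy", "square")) {
  layout <- match.arg(layout)
  if (layout == "tidy") write.csv(as.data.frame(cm), path, row.names = FALSE)
  else write.csv(format_contact_table(cm), path)
  invisible(path)
}
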