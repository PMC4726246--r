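# Synthetic inputs with known ground truth: ideal dimeric helices with
# planted inter-chain contact distances, Gaussian-jittered
# pseudo-trajectories, and simulated oocyte screens.

# Evaluate code under a given seed without touching the caller's RNG state.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# NeRF atom placement: position of a new atom at bond length `r` from `p1`,
# bond angle `theta` (deg) with `p2`, torsion `phi` (deg) over p3-p2-p1.
.place_atom <- function(p1, p2, p3, r, theta, phi) {
  theta <- theta * pi / 180; phi <- phi * pi / 180
  bc <- p1 - p2; bc <- bc / sqrt(sum(bc^2))
  ab <- p2 - p3
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  d <- c(-r * cos(theta), r * sin(theta) * cos(phi), r * sin(theta) * sin(phi))
  p1 + d[1] * bc + d[2] * m2 + d[3] * n
}

# Build one ideal alpha-helix chain (backbone phi = -57, psi = -47,
# omega = 180; rise ~1.5 A per residue, ~100 degrees per turn) with full
# side-chain heavy atoms from the idealised topology.  Returns list(atoms,
# xyz) with xyz a single-frame coordinate matrix.
.build_helix_chain <- function(resids, chain = "A", start_resno = 1L) {
  resids <- toupper(resids)
  bad <- setdiff(unique(resids), names(.sidechain_topology))
  if (length(bad)) stop("non-standard residue(s): ", paste(bad, collapse = ", "))
  phi <- -57; psi <- -47; omega <- 180
  n_res <- length(resids)
  atoms <- list(); coords <- list()
  pos <- new.env(parent = emptyenv())  # per-residue named atom positions

  put <- function(name, xyz, resno, resid) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      elety = name, resid = resid, resno = resno, chain = chain,
      stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <<- xyz
    assign(paste0(resno, ".", name), xyz, envir = pos)
  }
  at <- function(resno, name) get(paste0(resno, ".", name), envir = pos)

  for (i in seq_len(n_res)) {
    resno <- start_resno + i - 1L
    resid <- resids[i]
    if (i == 1L) {
      N  <- c(0, 0, 0)
      CA <- c(1.458, 0, 0)
      ang <- 111 * pi / 180
      C  <- CA + 1.525 * c(cos(pi - ang), sin(pi - ang), 0)
      put("N", N, resno, resid); put("CA", CA, resno, resid)
      put("C", C, resno, resid)
    } else {
      prev <- resno - 1L
      N  <- .place_atom(at(prev, "C"), at(prev, "CA"), at(prev, "N"),
                        1.329, 117, psi)
      CA <- .place_atom(N, at(prev, "C"), at(prev, "CA"), 1.458, 121, omega)
      C  <- .place_atom(CA, N, at(prev, "C"), 1.525, 111, phi)
      put("N", N, resno, resid); put("CA", CA, resno, resid)
      put("C", C, resno, resid)
    }
    O <- .place_atom(at(resno, "C"), at(resno, "CA"), at(resno, "N"),
                     1.231, 121, psi + 180)
    put("O", O, resno, resid)
    topo <- .sidechain_topology[[resid]]
    if (nrow(topo)) for (k in seq_len(nrow(topo))) {
      xyz <- .place_atom(at(resno, topo$parent[k]), at(resno, topo$ref2[k]),
                         at(resno, topo$ref3[k]), topo$length[k],
                         topo$angle[k], topo$torsion[k])
      put(topo$atom[k], xyz, resno, resid)
    }
  }
  atoms <- do.call(rbind, atoms)
  atoms$eleno <- seq_len(nrow(atoms))
  list(atoms = atoms, xyz = do.call(rbind, coords))
}

.rot3 <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx); cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Build a synthetic dimeric helical cap with planted contact distances
#'
#' Constructs two identical ideal alpha-helices (full side-chain heavy
#' atoms) as chains A and B and rigidly places chain B so that the
#' reference-carbon distance of every planted pair matches its target to
#' within `tol` (default 0.05 A, comfortably inside the 0.1 A the PDB
#' format's 3-decimal coordinates support).  The placement is found by
#' multi-start rigid-body least squares over the 6 degrees of freedom of
#' chain B; a distance set that no rigid placement can realise (mutually
#' contradictory targets given the fixed helix geometry) raises an error.
#' With no planted pairs chain B is placed 25 A away from chain A, so no
#' residue pair can be called at a 6 A cutoff.
#'
#' @param residues Character vector of three-letter residue names (one
#'   helix; both chains get the same sequence).
#' @param pairs Data frame of planted contacts with columns `res_i`
#'   (residue number on chain A), `res_j` (on chain B) and `target`
#'   (Angstrom, > 0); `NULL` or zero rows for a well-separated dimer.
#' @param start_resno First residue number (default 1).
#' @param rule Reference-carbon mapping used for the planted distances.
#' @param tol Maximum allowed deviation from the targets (default 0.05 A).
#' @param seed Seed for the deterministic multi-start jitter.
#' @return A single-frame [structure_model()] with chains A and B and
#'   attribute `planted` (the realised pair table with `achieved`
#'   distances).
#' @export
make_toy_cap <- function(residues, pairs = NULL, start_resno = 1L,
                         rule = reference_carbon_table(), tol = 0.05,
                         seed = 1L) {
  A <- .build_helix_chain(residues, "A", start_resno)
  B <- .build_helix_chain(residues, "B", start_resno)
  n_at <- nrow(A$atoms)
  center <- colMeans(A$xyz)

  if (is.null(pairs) || nrow(pairs) == 0L) {
    # shift by the chain's own x-extent plus a clear margin, so the
    # closest atom pair is guaranteed >= ~16 A apart whatever the length
    shift <- diff(range(A$xyz[, 1])) + 16
    Bxyz <- sweep(B$xyz, 2L, c(shift, 0, 0), "+")
    pairs_out <- data.frame(res_i = integer(), res_j = integer(),
                            target = numeric(), achieved = numeric())
  } else {
    stopifnot(all(c("res_i", "res_j", "target") %in% names(pairs)),
              all(pairs$target > 0))
    refatom <- function(tab, resno) {
      resid <- tab$atoms$resid[match(resno, tab$atoms$resno)]
      if (is.na(resid)) stop("planted residue ", resno, " not in the chain")
      i <- which(tab$atoms$resno == resno &
                   tab$atoms$elety == select_reference_carbon(resid, rule))
      if (!length(i)) stop("no reference carbon for residue ", resno)
      i[1L]
    }
    ia <- vapply(pairs$res_i, function(r) refatom(A, r), integer(1))
    ib <- vapply(pairs$res_j, function(r) refatom(B, r), integer(1))
    Pa <- A$xyz[ia, , drop = FALSE]
    Bc <- sweep(B$xyz, 2L, center)  # rotate B about chain A's centroid

    objective <- function(th) {
      R <- .rot3(th[1], th[2], th[3])
      Pb <- sweep(Bc[ib, , drop = FALSE] %*% t(R), 2L,
                  center + th[4:6], "+")
      d <- sqrt(rowSums((Pa - Pb)^2))
      sum((d - pairs$target)^2)
    }
    starts <- .with_seed(seed, {
      base <- expand.grid(rz = c(0, pi / 2, pi, 3 * pi / 2),
                          tx = c(6, 9, 12), dz = c(-6, 0, 6))
      lapply(seq_len(nrow(base) * 2L), function(k) {
        b <- base[(k - 1L) %% nrow(base) + 1L, ]
        c(rnorm(1, 0, 0.2), rnorm(1, 0, 0.2), b$rz + rnorm(1, 0, 0.2),
          b$tx + rnorm(1, 0, 1), rnorm(1, 0, 1), b$dz + rnorm(1, 0, 1))
      })
    })
    best <- NULL
    for (th0 in starts) {
      fit <- tryCatch(optim(th0, objective, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-14)),
                      error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value))
        best <- fit
      if (!is.null(best) && best$value < (tol / 10)^2) break
    }
    th <- best$par
    R <- .rot3(th[1], th[2], th[3])
    Bxyz <- sweep(Bc %*% t(R), 2L, center + th[4:6], "+")
    achieved <- sqrt(rowSums((Pa - Bxyz[ib, , drop = FALSE])^2))
    if (max(abs(achieved - pairs$target)) > tol)
      stop("planted distance set is not realisable by a rigid placement of ",
           "chain B (worst deviation ",
           sprintf("%.2f", max(abs(achieved - pairs$target))),
           " A); the targets are mutually contradictory for this helix ",
           "geometry")
    pairs_out <- data.frame(pairs[, c("res_i", "res_j", "target")],
                            achieved = achieved)
  }

  atoms <- rbind(A$atoms, B$atoms)
  atoms$eleno <- seq_len(nrow(atoms))
  model <- structure_model(atoms, list(rbind(A$xyz, Bxyz)))
  attr(model, "planted") <- pairs_out
  model
}

#' Gaussian-jittered pseudo-trajectory
#'
#' Expands a single-frame model into `n_frames` frames, each the reference
#' coordinates plus i.i.d. Gaussian displacements (per atom and axis, SD
#' `sigma`).  A stand-in for a sampled MD trajectory with uncorrelated
#' thermal noise; frame 1 is already jittered (the reference itself is not
#' included).  Deterministic given `seed`.
#'
#' @param model A [structure_model()]; its first frame is the reference.
#' @param sigma Displacement SD in Angstrom (>= 0).
#' @param n_frames Number of frames to generate (>= 1).
#' @param seed Integer seed.
#' @return A [structure_model()] with `n_frames` frames (attributes of
#'   `model`, e.g. `planted`, are preserved).
#' @export
jitter_trajectory <- function(model, sigma, n_frames, seed = 1L) {
  stopifnot(inherits(model, "structure_model"), sigma >= 0, n_frames >= 1)
  ref <- model$frames[[1L]]
  frames <- .with_seed(seed, lapply(seq_len(n_frames), function(k)
    ref + matrix(rnorm(length(ref), 0, sigma), nrow(ref), 3L)))
  out <- structure_model(model$atoms, frames)
  attr(out, "planted") <- attr(model, "planted")
  out
}

#' Simulate a per-oocyte functional screen
#'
#' Draws per-oocyte current and surface-luminescence measurements for a set
#' of constructs with known true relative current and surface expression.
#' Noise is multiplicative lognormal (expression data are positive and
#' right-skewed) with coefficient of variation `cv`, parameterised so the
#' *mean* of the noise factor is 1 and recovered relative means are
#' unbiased.  Each batch (frog/day) gets its own lognormal wild-type scale
#' (SD `batch_sd` on the log scale), mimicking the large between-batch
#' expression differences that make per-batch normalisation necessary.
#'
#' @param constructs Data frame with columns `construct_id`, `rel_current`,
#'   `rel_surface` (true values, >= 0; `NA` rel_surface = construct not
#'   assayed for surface expression).  A reference row (`reference_id`,
#'   1, 1) is added if absent.
#' @param n_oocytes Oocytes per construct per batch (default 20).
#' @param cv Coefficient of variation of the multiplicative noise
#'   (default 0.3).
#' @param n_batches Number of batches (default 1).
#' @param batch_sd Log-scale SD of the per-batch scale (default 0.2).
#' @param base_current_uA Mean wild-type current (default 10).
#' @param base_luminescence_RLU Mean wild-type luminescence (default 1e5).
#' @param reference_id Reference construct id (default `"WT"`).
#' @param seed Integer seed.
#' @return Data frame with columns `construct_id`, `batch_id`,
#'   `current_uA`, `luminescence_RLU`, plus attribute `truth` (the
#'   construct table actually used).
#' @export
simulate_screen <- function(constructs, n_oocytes = 20, cv = 0.3,
                            n_batches = 1, batch_sd = 0.2,
                            base_current_uA = 10,
                            base_luminescence_RLU = 1e5,
                            reference_id = "WT", seed = 1L) {
  stopifnot(is.data.frame(constructs),
            all(c("construct_id", "rel_current", "rel_surface") %in%
                  names(constructs)),
            n_oocytes >= 2, cv >= 0, n_batches >= 1)
  if (any(constructs$rel_current < 0, na.rm = TRUE) ||
      any(constructs$rel_surface < 0, na.rm = TRUE))
    stop("true relative values must be >= 0")
  if (!reference_id %in% constructs$construct_id)
    constructs <- rbind(
      data.frame(construct_id = reference_id, rel_current = 1,
                 rel_surface = 1),
      constructs[, c("construct_id", "rel_current", "rel_surface")])
  sig <- sqrt(log(1 + cv^2))
  mu <- -sig^2 / 2  # mean-1 lognormal noise
  out <- .with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_batches), function(b) {
      cur_scale <- base_current_uA * exp(rnorm(1, 0, batch_sd))
      lum_scale <- base_luminescence_RLU * exp(rnorm(1, 0, batch_sd))
      do.call(rbind, lapply(seq_len(nrow(constructs)), function(k) {
        cc <- constructs[k, ]
        data.frame(
          construct_id = cc$construct_id,
          batch_id = paste0("batch", b),
          current_uA = cc$rel_current * cur_scale *
            exp(rnorm(n_oocytes, mu, sig)),
          luminescence_RLU = if (is.na(cc$rel_surface)) NA_real_ else
            cc$rel_surface * lum_scale * exp(rnorm(n_oocytes, mu, sig)))
      }))
    }))
  })
  rownames(out) <- NULL
  attr(out, "truth") <- constructs
  out
}

#' Construct a contact matrix fixture from planted pair statistics
#'
#' Builds a `cap_contact_matrix` directly from specified per-pair mean/SD
#' values, without any structure: unspecified pairs get the `background`
#' distance.  Used for concordance fixtures emulating the contact tables of
#' candidate structural models.
#'
#' @param residues Integer residue set of the square matrix.
#' @param pairs Data frame with columns `res_i`, `res_j`, `mean` and
#'   optionally `sd` (default 0.3) and `relationship` (default `"inter"`).
#' @param background Mean distance for all unspecified inter pairs
#'   (default 15).
#' @param n_frames Nominal frame count recorded on the object (default 100).
#' @return A `cap_contact_matrix` (no per-frame series attached).
#' @export
synthetic_contact_matrix <- function(residues, pairs, background = 15,
                                     n_frames = 100L) {
  residues <- sort(unique(as.integer(residues)))
  if (is.null(pairs$sd)) pairs$sd <- 0.3
  if (is.null(pairs$relationship)) pairs$relationship <- "inter"
  key <- function(i, j, rel) paste0(pmin(i, j), ":", pmax(i, j), ":", rel)
  planted <- setNames(seq_len(nrow(pairs)),
                      key(pairs$res_i, pairs$res_j, pairs$relationship))
  rows <- list()
  for (ii in seq_along(residues)) for (jj in ii:length(residues)) {
    i <- residues[ii]; j <- residues[jj]
    k <- key(i, j, "inter")
    rows[[k]] <- data.frame(
      res_i = i, res_j = j, resid_i = NA_character_, resid_j = NA_character_,
      relationship = "inter",
      mean = if (k %in% names(planted)) pairs$mean[planted[[k]]] else background,
      sd = if (k %in% names(planted)) pairs$sd[planted[[k]]] else 0.3)
    if (i != j) {
      k <- key(i, j, "intra")
      if (k %in% names(planted))
        rows[[k]] <- data.frame(
          res_i = i, res_j = j, resid_i = NA_character_,
          resid_j = NA_character_, relationship = "intra",
          mean = pairs$mean[planted[[k]]], sd = pairs$sd[planted[[k]]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, residues = residues, chains = c("A", "B"),
            n_frames = as.integer(n_frames),
            class = c("cap_contact_matrix", "data.frame"))
}
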