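# minimal two-residue model: one ALA per chain, CB at given coordinates
point_model <- function(frames_a, frames_b) {
  atoms <- data.frame(eleno = 1:4, elety = c("CA", "CB", "CA", "CB"),
                      resid = "ALA", resno = 1L, chain = c("A", "A", "B", "B"))
  frames <- Map(function(a, b) rbind(a + c(-1, 0, 0), a, b + c(1, 0, 0), b),
                frames_a, frames_b)
  structure_model(atoms, frames)
}

test_that("reference-carbon table and branching rule agree (documented overrides aside)", {
  tab <- reference_carbon_table()
  expect_equal(unname(tab[c("LEU", "VAL", "ALA", "GLY")]),
               c("CG", "CB", "CB", "CA"))
  expect_equal(select_reference_carbon("LEU"), "CG")
  expect_error(select_reference_carbon("XYZ"), "no reference-carbon rule")
  # rule-derived atom matches the shipped table except MET/PRO overrides
  for (res in setdiff(names(tab), c("MET", "PRO")))
    expect_equal(derive_reference_carbon(res), unname(tab[res]), info = res)
  # overrides stay user-editable
  rule <- tab; rule["LEU"] <- "CD1"
  expect_equal(select_reference_carbon("LEU", rule), "CD1")
})

test_that("distance series: fixed geometry gives exact mean and zero SD", {
  m <- point_model(replicate(10, c(0, 0, 0), simplify = FALSE),
                   replicate(10, c(3, 4, 0), simplify = FALSE))
  ds <- distance_series(m, list(chain = "A", resno = 1),
                        list(chain = "B", resno = 1))
  expect_equal(ds$mean, 5)
  expect_equal(ds$sd, 0)
  expect_equal(ds$relationship, "inter")
  ds2 <- distance_series(m, list(chain = "A", resno = 1),
                         list(chain = "A", resno = 1))
  expect_equal(ds2$relationship, "intra")
  expect_error(distance_series(m, list(chain = "A", resno = 9),
                               list(chain = "B", resno = 1)), "not found")
})

test_that("mean/SD over frames match a two-pass loop oracle to 1e-10", {
  cap <- toy_two_pair_cap()
  traj <- jitter_trajectory(cap, 0.3, 60, seed = 9)
  ds <- distance_series(traj, list(chain = "A", resno = 3),
                        list(chain = "B", resno = 3))
  # explicit per-frame loop with the textbook two-pass mean/SD
  idx_a <- which(traj$atoms$chain == "A" & traj$atoms$resno == 3 &
                   traj$atoms$elety == "CG")  # LEU reference carbon
  idx_b <- which(traj$atoms$chain == "B" & traj$atoms$resno == 3 &
                   traj$atoms$elety == "CG")
  d <- vapply(traj$frames, function(f)
    sqrt(sum((f[idx_a, ] - f[idx_b, ])^2)), numeric(1))
  m <- sum(d) / length(d)
  s <- sqrt(sum((d - m)^2) / (length(d) - 1))
  expect_equal(ds$d, d, tolerance = 1e-12)
  expect_equal(ds$mean, m, tolerance = 1e-10)
  expect_equal(ds$sd, s, tolerance = 1e-10)
})

test_that("trajectory distance statistics match an independent Monte-Carlo oracle", {
  cap <- toy_two_pair_cap()
  sigma <- 0.3
  traj <- jitter_trajectory(cap, sigma, 2500, seed = 31)
  ds <- distance_series(traj, list(chain = "A", resno = 3),
                        list(chain = "B", resno = 3))
  d0 <- attr(cap, "planted")$achieved[1]  # 4.5 A target
  # oracle: direct simulation of |d0*ex + (jitter difference)| at 10x frames
  set.seed(99)
  nmc <- 25000
  eps <- matrix(rnorm(3 * nmc, 0, sigma * sqrt(2)), ncol = 3)
  dmc <- sqrt((d0 + eps[, 1])^2 + eps[, 2]^2 + eps[, 3]^2)
  expect_lt(abs(ds$mean - mean(dmc)),
            3 * sd(dmc) / sqrt(2500) + 3 * sd(dmc) / sqrt(nmc))
  # SD of the distance ~ sqrt(2)*sigma within 20%
  expect_lt(abs(ds$sd - sqrt(2) * sigma), 0.2 * sqrt(2) * sigma)
})

test_that("interaction calls use an inclusive 6 A boundary on the mean", {
  cm <- synthetic_contact_matrix(
    residues = c(1, 2, 3),
    pairs = data.frame(res_i = c(1, 2, 3), res_j = c(1, 2, 3),
                       mean = c(5.99, 6.00, 6.01)))
  called <- call_interactions(cm, 6.0)
  diag_rows <- called$res_i == called$res_j
  expect_equal(called$call[diag_rows][order(called$res_i[diag_rows])],
               c(TRUE, TRUE, FALSE))
  expect_error(call_interactions(cm, 0), "positive")
  expect_error(call_interactions(cm, -1), "positive")
})

test_that("calls are monotone in the cutoff", {
  set.seed(12)
  cm <- synthetic_contact_matrix(
    residues = 1:8,
    pairs = data.frame(res_i = sample(1:8, 12, TRUE),
                       res_j = sample(1:8, 12, TRUE),
                       mean = runif(12, 3, 9)))
  c5 <- call_interactions(cm, 5.0)$call
  c6 <- call_interactions(cm, 6.0)$call
  expect_true(all(!c5 | c6))  # calls(5) subset of calls(6)
})

test_that("minimum side-chain distance matches brute force and bounds the reference distance", {
  cap <- toy_two_pair_cap()
  traj <- jitter_trajectory(cap, 0.2, 3, seed = 4)
  backbone <- c("N", "CA", "C", "O", "OXT")
  at <- traj$atoms
  for (fr in 1:3) for (i in c(3, 8)) for (j in c(3, 8)) {
    got <- min_sidechain_distance(traj, list(chain = "A", resno = i),
                                  list(chain = "B", resno = j), frame = fr)
    rows_i <- which(at$chain == "A" & at$resno == i & !at$elety %in% backbone)
    rows_j <- which(at$chain == "B" & at$resno == j & !at$elety %in% backbone)
    f <- traj$frames[[fr]]
    want <- Inf
    for (a in rows_i) for (b in rows_j)
      want <- min(want, sqrt(sum((f[a, ] - f[b, ])^2)))
    expect_equal(got, want, tolerance = 1e-10)
    ref <- distance_series(traj, list(chain = "A", resno = i),
                           list(chain = "B", resno = j))$d[fr]
    expect_lte(got, ref + 1e-12)
  }
  # glycine falls back to CA
  atoms <- data.frame(eleno = 1:2, elety = "CA", resid = "GLY", resno = 1L,
                      chain = c("A", "B"))
  g <- structure_model(atoms, list(rbind(c(0, 0, 0), c(2.5, 0, 0))))
  expect_equal(min_sidechain_distance(g, list(chain = "A", resno = 1),
                                      list(chain = "B", resno = 1)), 2.5)
})

test_that("RMSD is zero under rigid motion when superposing and matches bio3d", {
  set.seed(8)
  a <- matrix(rnorm(30), ncol = 3)
  expect_equal(rmsd_kabsch(a, a), 0, tolerance = 1e-12)
  # rigid rotation + translation
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  b <- a %*% t(R) + matrix(c(3, -2, 5), nrow(a), 3, byrow = TRUE)
  expect_lt(rmsd_kabsch(a, b, superpose = TRUE), 1e-8)
  # uniform 1 A x-shift without superposition
  expect_equal(rmsd_kabsch(a, a + matrix(c(1, 0, 0), nrow(a), 3, byrow = TRUE),
                           superpose = FALSE), 1)
  # independent implementation: bio3d fit + rmsd
  b2 <- b + matrix(rnorm(30, 0, 0.5), ncol = 3)
  want <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b2)), fit = TRUE)
  expect_equal(rmsd_kabsch(a, b2, superpose = TRUE), want, tolerance = 1e-3)
  expect_error(rmsd_kabsch(a, a[1:5, ]), "equal size")
})

test_that("frame RMSD of a gently jittered trajectory stays near the noise floor", {
  cap <- toy_two_pair_cap()
  traj <- jitter_trajectory(cap, 0.2, 10, seed = 2)
  r <- frame_rmsd(traj, ref = 1)
  expect_equal(r[1], 0, tolerance = 1e-12)
  # independent jitters: RMSD about sqrt(2)*sigma, certainly below 3 sigma
  expect_true(all(r[-1] > 0 & r[-1] < 3 * 0.2))
})

test_that("frame accounting divides duration by sampling interval", {
  expect_identical(frame_count(10 * 1000, 4), 2500L)
  expect_identical(frame_count(100 * 1000, 4), 25000L)
  expect_identical(frame_count(4, 4), 1L)
  expect_error(frame_count(10, 3), "not a multiple")
  expect_error(frame_count(-10, 4), "positive")
  expect_error(frame_count(10, 0), "positive")
})

test_that("structures round-trip through multi-model PDB at format precision", {
  cap <- toy_two_pair_cap()
  traj <- jitter_trajectory(cap, 0.3, 3, seed = 77)
  f <- tempfile(fileext = ".pdb")
  write_structure_pdb(traj, f)
  back <- read_structure_pdb(f)
  expect_equal(length(back$frames), 3L)
  expect_equal(back$atoms$elety, traj$atoms$elety)
  expect_equal(back$atoms$resno, traj$atoms$resno)
  expect_equal(back$atoms$chain, traj$atoms$chain)
  for (k in 1:3)
    expect_lt(max(abs(back$frames[[k]] - traj$frames[[k]])), 5.01e-4)
})

test_that("contact matrices are symmetric, labelled, and carry homotypic diagonals", {
  cap <- toy_two_pair_cap()
  traj <- jitter_trajectory(cap, 0.2, 20, seed = 5)
  cm <- contact_matrix(traj, c(3, 8))
  expect_s3_class(cm, "cap_contact_matrix")
  # unordered-pair storage: exactly one inter row per pair incl. diagonal
  inter <- cm[cm$relationship == "inter", ]
  expect_equal(nrow(inter), 3L)        # (3,3), (3,8), (8,8)
  expect_true(all(inter$res_i <= inter$res_j))
  # the (3,8) inter cell equals the per-frame minimum over both copies
  d1 <- distance_series(traj, list(chain = "A", resno = 3),
                        list(chain = "B", resno = 8))$d
  d2 <- distance_series(traj, list(chain = "A", resno = 8),
                        list(chain = "B", resno = 3))$d
  key <- attr(cm, "series")[["3:8:inter"]]
  expect_equal(key, pmin(d1, d2), tolerance = 1e-12)
  # square layout puts inter cells on/below the diagonal
  tab <- format_contact_table(call_interactions(cm))
  expect_equal(dim(tab), c(2L, 2L))
  expect_true(nzchar(tab[2, 1]) && nzchar(tab[1, 2]))
  # CSV round trip preserves means and calls
  f <- tempfile(fileext = ".csv")
  write_contact_csv(call_interactions(cm), f)
  back <- read_contact_csv(f)
  expect_equal(back$mean, call_interactions(cm)$mean, tolerance = 1e-12)
})
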