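# fixture contact matrices over the seven cap-hit residues, emulating the
# interaction patterns of candidate template models
fixture_matrix <- function(pairs, background = 12) {
  synthetic_contact_matrix(residues = cap_hits, pairs = pairs,
                           background = background)
}

trek2_like <- function() fixture_matrix(
  data.frame(res_i = c(48, 52, 53, 54, 59, 59),
             res_j = c(62, 55, 53, 54, 59, 62),
             mean = c(5.0, 5.2, 4.6, 4.8, 5.1, 5.5)),
  background = 8.5)

test_that("scoring tallies inter-subunit calls among hits and their coverage", {
  # no calls anywhere
  empty <- fixture_matrix(data.frame(res_i = 53, res_j = 53, mean = 9))
  r0 <- score_model(empty, cap_hits, "none")
  expect_equal(r0$n_inter_calls, 0L)
  expect_equal(r0$coverage, 0)
  # single homotypic call (Y59 with Y59 of the opposing subunit)
  twik <- fixture_matrix(data.frame(res_i = 59, res_j = 59, mean = 5.4))
  r1 <- score_model(twik, cap_hits, "twik1-template")
  expect_equal(r1$n_inter_calls, 1L)
  expect_equal(attr(r1, "covered"), 59L)
  expect_equal(r1$coverage, 1 / 7)
  # six planted interactions covering all seven hits
  r6 <- score_model(trek2_like(), cap_hits, "trek2-template")
  expect_equal(r6$n_inter_calls, 6L)
  expect_equal(r6$n_hits_covered, 7L)
  expect_equal(r6$coverage, 1)
  # a hit absent from the matrix is an error naming the residue
  expect_error(score_model(trek2_like(), c(cap_hits, 99)), "99")
})

test_that("intra-subunit calls are reported but excluded from the score", {
  cm <- fixture_matrix(data.frame(
    res_i = c(53, 48), res_j = c(53, 52), mean = c(5, 4),
    relationship = c("inter", "intra")))
  r <- score_model(cm, cap_hits)
  expect_equal(r$n_inter_calls, 1L)
  expect_equal(r$n_intra_calls, 1L)
  expect_equal(attr(r, "covered"), 53L)
})

test_that("score equals a brute-force tally over all matrix cells", {
  set.seed(44)
  for (k in 1:10) {
    res <- sort(sample(40:70, 8))
    hits <- sample(res, 5)
    pairs <- data.frame(res_i = sample(res, 12, TRUE),
                        res_j = sample(res, 12, TRUE),
                        mean = runif(12, 3, 10))
    cm <- call_interactions(synthetic_contact_matrix(res, pairs), 6)
    r <- score_model(cm, hits)
    # explicit loop over every cell
    n <- 0L; covered <- integer()
    for (row in seq_len(nrow(cm))) {
      if (cm$relationship[row] == "inter" && cm$call[row] &&
          cm$res_i[row] %in% hits && cm$res_j[row] %in% hits) {
        n <- n + 1L
        covered <- union(covered, c(cm$res_i[row], cm$res_j[row]))
      }
    }
    expect_equal(r$n_inter_calls, n)
    expect_equal(r$n_hits_covered, length(covered))
  }
})

test_that("adding a call between hits never decreases count or coverage", {
  base_pairs <- data.frame(res_i = c(53, 59), res_j = c(53, 62),
                           mean = c(5, 5))
  base <- score_model(fixture_matrix(base_pairs), cap_hits)
  for (extra in list(c(48, 62), c(52, 55), c(54, 54))) {
    more <- rbind(base_pairs,
                  data.frame(res_i = extra[1], res_j = extra[2], mean = 5))
    r <- score_model(fixture_matrix(more), cap_hits)
    expect_gte(r$n_inter_calls, base$n_inter_calls)
    expect_gte(r$coverage, base$coverage)
  }
})

test_that("ranking orders by call count, breaks ties by mean hit distance, stays stable", {
  twik <- score_model(fixture_matrix(
    data.frame(res_i = 59, res_j = 59, mean = 5.4), background = 14),
    cap_hits, "twik1-like")
  traak <- score_model(fixture_matrix(
    data.frame(res_i = c(48, 53, 59), res_j = c(54, 53, 59),
               mean = c(5.5, 5.0, 5.2)), background = 11),
    cap_hits, "traak-like")
  traak_swap <- score_model(fixture_matrix(
    data.frame(res_i = c(48, 52, 54), res_j = c(62, 55, 54),
               mean = c(5.0, 4.8, 4.6)), background = 9.5),
    cap_hits, "traak-swapped")
  trek2 <- score_model(trek2_like(), cap_hits, "trek2-swapped")
  ranked <- rank_models(list(twik, traak, traak_swap, trek2))
  expect_equal(ranked$n_inter_calls, c(6L, 3L, 3L, 1L))
  expect_equal(ranked$model_id[1], "trek2-swapped")
  expect_equal(ranked$model_id[4], "twik1-like")
  # tie between the two 3-call models goes to the smaller mean distance
  expect_equal(ranked$model_id[2], "traak-swapped")
  # permutation of the input
  expect_setequal(ranked$model_id,
                  c("twik1-like", "traak-like", "traak-swapped",
                    "trek2-swapped"))
  # independent comparator: sort key agreement
  o <- order(-ranked$n_inter_calls, ranked$mean_hit_distance)
  expect_equal(o, seq_len(4))
  # stability for full ties and the single-report case
  same <- rank_models(list(twik, twik))
  expect_equal(same$model_id, c("twik1-like", "twik1-like"))
  one <- rank_models(list(traak))
  expect_equal(one$rank, 1L)
  expect_error(rank_models(list()), "no reports")
})

test_that("hit lists read from text in either notation", {
  f <- tempfile()
  writeLines(c("# cap hits", "L48", "Y52", "", "Y59"), f)
  h <- read_hit_list(f)
  expect_equal(h$pos, c(48L, 52L, 59L))
  writeLines(c("48", "62"), f)
  expect_equal(read_hit_list(f)$pos, c(48L, 62L))
})
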