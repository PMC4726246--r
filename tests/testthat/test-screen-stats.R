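make_meas <- function(constructs, currents, batch = "b1") {
  data.frame(construct_id = rep(constructs, lengths(currents)),
             batch_id = batch, current_uA = unlist(currents))
}

test_that("normalisation sets the reference mean to 1 and scales others", {
  m <- make_meas(c("WT", "mut"), list(c(8, 10, 12), c(0.6, 0.7, 0.8)))
  out <- normalize_to_reference(m, "WT")
  expect_equal(mean(out$rel[out$construct_id == "WT"]), 1)
  expect_equal(mean(out$rel[out$construct_id == "mut"]), 0.07, tolerance = 1e-12)
  expect_error(normalize_to_reference(m, "absent"), "reference")
})

test_that("per-batch normalisation removes batch scale differences", {
  # two batches whose WT means differ 2-fold but mutant/WT ratios agree
  m <- rbind(make_meas(c("WT", "mut"), list(c(9, 11), c(4.5, 5.5)), "b1"),
             make_meas(c("WT", "mut"), list(c(18, 22), c(9, 11)), "b2"))
  out <- normalize_to_reference(m, "WT", per_batch = TRUE)
  b1 <- out$rel[out$construct_id == "mut" & out$batch_id == "b1"]
  b2 <- out$rel[out$construct_id == "mut" & out$batch_id == "b2"]
  expect_equal(b1, b2)
  expect_equal(mean(b1), 0.5)
  # global normalisation would differ between batches
  glob <- normalize_to_reference(m, "WT", per_batch = FALSE)
  expect_false(isTRUE(all.equal(
    glob$rel[glob$construct_id == "mut" & glob$batch_id == "b1"],
    glob$rel[glob$construct_id == "mut" & glob$batch_id == "b2"])))
  # reference missing from one batch errors under per-batch
  m2 <- rbind(m, make_meas("mut", list(c(1, 2)), "b3"))
  expect_error(normalize_to_reference(m2, "WT", per_batch = TRUE), "batch")
})

test_that("conductivity is the current/surface ratio with exact identity", {
  expect_equal(conductivity(1, 1), 1)
  expect_equal(conductivity(0.07, 0.07), 1)
  expect_equal(conductivity(0.07, 1), 0.07)
  # undefined (not 0, not Inf) when surface is absent or non-positive
  expect_true(is.na(conductivity(0.5, 0)))
  expect_true(is.na(conductivity(0.5, NA)))
  # identity rel_current = conductivity * rel_surface wherever defined
  set.seed(3)
  rc <- runif(50); rs <- runif(50)
  g <- conductivity(rc, rs)
  expect_equal(g * rs, rc, tolerance = 1e-15)
})

test_that("t-test equals the textbook pooled-variance oracle", {
  set.seed(21)
  for (k in 1:50) {
    a <- rnorm(sample(3:10, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(3:10, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
    got <- ttest_unpaired(a, b)
    want <- brute_ttest(a, b)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$p.value, want$p.value, tolerance = 1e-10)
    # symmetric in group order
    expect_equal(ttest_unpaired(b, a)$p.value, got$p.value, tolerance = 1e-12)
  }
})

test_that("t-test degenerate and extreme cases behave as documented", {
  expect_equal(ttest_unpaired(c(1, 1, 1), c(1, 1, 1))$p.value, 1)
  expect_equal(ttest_unpaired(c(1, 1, 1), c(2, 2, 2))$p.value, 0)
  expect_lt(ttest_unpaired(c(1, 2, 3), c(11, 12, 13))$p.value, 0.001)
  expect_error(ttest_unpaired(1, c(1, 2)), "at least 2")
})

test_that("mechanism classification separates trafficking from gating defects", {
  expect_equal(classify_mechanism(0.07, 0.07, 1.0), "trafficking_deficient")
  expect_equal(classify_mechanism(0.07, 1.0, 0.07), "gating_deficient")
  expect_equal(classify_mechanism(1.0, 1.0, 1.0), "normal")
  expect_equal(classify_mechanism(2.0, 1.0, 2.0), "gain")
  expect_equal(classify_mechanism(0.1, 0.2, 0.4), "mixed")
  expect_equal(classify_mechanism(0.1, NA, NA), "reduced_current_unresolved")
  expect_equal(classify_mechanism(0.9, NA, NA), "normal")
})

test_that("dominant-negative suppression is the mean ratio complement", {
  ref <- c(10, 12, 8, 11)
  expect_equal(dominant_negative(ref, ref)$suppression, 0)
  expect_equal(dominant_negative(ref, ref)$p.value, 1)
  half <- dominant_negative(0.5 * ref, ref)
  expect_equal(half$suppression, 0.5)
  boost <- dominant_negative(1.2 * ref, ref)
  expect_equal(boost$suppression, -0.2, tolerance = 1e-12)
  expect_true(boost$enhancement)
  expect_error(dominant_negative(ref, c(-1, -2, 0)), "positive")
})

test_that("step-current extraction averages the window", {
  tr <- data.frame(time = seq(0, 1, by = 0.01), current = 5)
  expect_equal(extract_step_current(tr, c(0.2, 0.8)), 5)
  ramp <- data.frame(time = seq(0, 1, by = 0.01),
                     current = seq(0, 1, by = 0.01))
  expect_equal(extract_step_current(ramp, c(0.4, 0.6)), 0.5)
  expect_error(extract_step_current(tr, c(0.5, 2)), "outside")
  # noisy plateau recovered within 3 SE
  set.seed(5)
  n <- 200
  noisy <- data.frame(time = seq_len(n), current = 3 + rnorm(n, 0, 0.2))
  est <- extract_step_current(noisy, c(1, n))
  expect_lt(abs(est - 3), 3 * 0.2 / sqrt(n))
})

test_that("screen summaries recover planted effects and flag hits", {
  constructs <- data.frame(
    construct_id = c("WT", "L48A", "K70A", "Q56A"),
    rel_current = c(1, 0.07, 0.07, 1),
    rel_surface = c(1, 0.07, 1, 1))
  scr <- simulate_screen(constructs, n_oocytes = 20, cv = 0.3,
                         n_batches = 2, seed = 101)
  summ <- summarize_screen(scr, "WT")
  expect_equal(summ$construct_id, constructs$construct_id)
  expect_equal(summ$rel_current[1], 1)  # reference = 1 by construction
  expect_equal(summ$mechanism,
               c("normal", "trafficking_deficient", "gating_deficient",
                 "normal"))
  expect_equal(summ$is_hit, c(FALSE, TRUE, TRUE, FALSE))
  # conductivity identity holds exactly in the summary
  ok <- !is.na(summ$conductivity)
  expect_equal(summ$conductivity[ok] * summ$rel_surface[ok],
               summ$rel_current[ok], tolerance = 1e-12)
})

test_that("noise-free screens recover the planted values exactly", {
  constructs <- data.frame(construct_id = c("WT", "m1", "m2"),
                           rel_current = c(1, 0.3, 0.8),
                           rel_surface = c(1, 0.6, 0.8))
  scr <- simulate_screen(constructs, n_oocytes = 5, cv = 0, seed = 1)
  summ <- summarize_screen(scr, "WT")
  expect_equal(summ$rel_current, constructs$rel_current, tolerance = 1e-12)
  expect_equal(summ$rel_surface, constructs$rel_surface, tolerance = 1e-12)
})

test_that("estimated relative values fall within 3 SE of truth (>= 95%)", {
  # the SE of a normalised mean includes the shared reference-mean term
  constructs <- data.frame(construct_id = c("WT", paste0("m", 1:5)),
                           rel_current = c(1, 0.07, 0.2, 0.5, 0.8, 1.2),
                           rel_surface = 1)
  n <- 20; cv <- 0.3
  hits <- 0; total <- 0
  for (seed in 1:40) {
    scr <- simulate_screen(constructs, n_oocytes = n, cv = cv,
                           n_batches = 1, seed = seed)
    summ <- summarize_screen(scr, "WT")
    for (k in 2:6) {
      truth <- constructs$rel_current[k]
      est <- summ$rel_current[summ$construct_id == constructs$construct_id[k]]
      se <- est * cv * sqrt(1 / n + 1 / n)  # construct + reference terms
      total <- total + 1
      if (abs(est - truth) <= 3 * se) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.95)
})
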