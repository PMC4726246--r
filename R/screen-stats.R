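#' Normalise measurements to a reference construct
#'
#' Divides each measurement by the mean of the reference construct, within
#' its batch when `per_batch` is set (the default; expression in oocytes
#' varies strongly between frogs/injection days, and normalising per batch
#' removes that).  The reference construct's mean relative value is 1 by
#' construction.
#'
#' @param measurements Data frame with columns `construct_id`, `batch_id`
#'   and the value column.
#' @param reference_id Construct id of the reference (wild type).
#' @param value Name of the value column (e.g. `"current_uA"`).
#' @param per_batch Normalise within batches (default `TRUE`); requires the
#'   reference in every batch.
#' @return The input data frame with an added `rel` column; rows with `NA`
#'   values keep `NA`.
#' @export
normalize_to_reference <- function(measurements, reference_id,
                                   value = "current_uA", per_batch = TRUE) {
  stopifnot(is.data.frame(measurements),
            all(c("construct_id", "batch_id", value) %in% names(measurements)))
  v <- measurements[[value]]
  is_ref <- measurements$construct_id == reference_id & !is.na(v)
  if (!any(is_ref))
    stop("reference construct '", reference_id,
         "' has no usable measurements for '", value, "'")
  if (per_batch) {
    batches <- unique(measurements$batch_id[!is.na(v)])
    ref_mean <- vapply(batches, function(b)
      mean(v[is_ref & measurements$batch_id == b]), numeric(1))
    if (anyNA(ref_mean))
      stop("reference '", reference_id, "' missing from batch(es): ",
           paste(batches[is.na(ref_mean)], collapse = ", "),
           " (use per_batch = FALSE or drop those batches)")
    if (any(ref_mean == 0))
      stop("reference mean is zero in batch(es): ",
           paste(batches[ref_mean == 0], collapse = ", "))
    measurements$rel <- v / ref_mean[match(measurements$batch_id, batches)]
  } else {
    m <- mean(v[is_ref])
    if (m == 0) stop("reference mean is zero")
    measurements$rel <- v / m
  }
  measurements
}

#' Conductivity ratio of a mutant
#'
#' The "conductivity" of a construct is its relative current divided by its
#' relative surface expression.  A trafficking-deficient mutant (less
#' channel protein at the membrane, normal gating) keeps a conductivity
#' near 1; a gating-deficient mutant (normal surface expression, impaired
#' permeation or open probability) has a conductivity well below 1.  The
#' ratio does not resolve single-channel conductance from open probability.
#'
#' @param rel_current Relative current amplitude (>= 0).
#' @param rel_surface Relative surface expression; the ratio is undefined
#'   (`NA`) when this is missing or <= 0.
#' @return `rel_current / rel_surface`, or `NA` where undefined.
#' @export
#' @examples
#' conductivity(0.07, 0.07)  # 1: pure trafficking defect
#' conductivity(0.07, 1.00)  # 0.07: pure gating defect
conductivity <- function(rel_current, rel_surface) {
  out <- rel_current / rel_surface
  out[is.na(rel_surface) | rel_surface <= 0] <- NA_real_
  out
}

#' Unpaired two-tailed Student's t-test
#'
#' Pooled-variance Student's t with `nA + nB - 2` degrees of freedom
#' (Welch's correction available via `welch = TRUE`), as used for
#' per-construct comparisons against wild type.  Degenerate zero-variance
#' inputs are handled explicitly: identical constant groups give p = 1,
#' constant groups with different means give p = 0.
#'
#' @param a,b Numeric vectors, each with at least 2 finite values.
#' @param welch Use the unequal-variance (Welch) variant.
#' @return List with `statistic` (t), `df`, `p.value`.
#' @export
ttest_unpaired <- function(a, b, welch = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 finite values")
  if (sd(a) == 0 && sd(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(statistic = if (eq) 0 else Inf,
                df = length(a) + length(b) - 2L,
                p.value = if (eq) 1 else 0))
  }
  tt <- t.test(a, b, var.equal = !welch)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value)
}

#' Classify the loss-of-function mechanism of a construct
#'
#' Deterministic label from relative current, relative surface expression
#' and conductivity:
#' * current not reduced: `normal`, or `gain` above `gain_threshold`;
#' * current reduced, surface expression normal: `gating_deficient`;
#' * current reduced, surface reduced, conductivity within the normal band:
#'   `trafficking_deficient`;
#' * current reduced, surface reduced, conductivity below the band:
#'   `mixed` (both mechanisms contribute);
#' * no surface data: `reduced_current_unresolved` (or `normal`).
#'
#' The numeric defaults (current/surface threshold 0.3 of wild type,
#' conductivity band \[0.5, 2\], gain above 1.5) are package choices -- they
#' separate strong loss-of-function hits from lesser reductions -- and are
#' fully configurable.
#'
#' @param rel_current,rel_surface,conductivity Scalars (vectors recycle);
#'   `rel_surface`/`conductivity` may be `NA`.
#' @param current_threshold Relative current below which a construct counts
#'   as loss-of-function (default 0.3).
#' @param conductivity_band Length-2 "normal conductivity" interval
#'   (default `c(0.5, 2)`).
#' @param surface_threshold Relative surface below which expression counts
#'   as reduced (default = `current_threshold`).
#' @param gain_threshold Relative current above which a construct is a
#'   `gain` (default 1.5).
#' @return Character vector of mechanism labels.
#' @export
classify_mechanism <- function(rel_current, rel_surface = NA,
                               conductivity = NA,
                               current_threshold = 0.3,
                               conductivity_band = c(0.5, 2),
                               surface_threshold = current_threshold,
                               gain_threshold = 1.5) {
  stopifnot(length(conductivity_band) == 2L,
            conductivity_band[1] < conductivity_band[2])
  n <- max(length(rel_current), length(rel_surface), length(conductivity))
  rel_current <- rep_len(rel_current, n)
  rel_surface <- rep_len(rel_surface, n)
  conductivity <- rep_len(conductivity, n)
  vapply(seq_len(n), function(k) {
    rc <- rel_current[k]; rs <- rel_surface[k]; g <- conductivity[k]
    if (rc >= current_threshold)
      return(if (rc > gain_threshold) "gain" else "normal")
    if (is.na(rs)) return("reduced_current_unresolved")
    if (rs >= surface_threshold) return("gating_deficient")
    # surface reduced; conductivity decides whether gating is also impaired
    if (!is.na(g) && g < conductivity_band[1]) "mixed"
    else "trafficking_deficient"
  }, character(1))
}

#' Summarise an alanine-scan screen
#'
#' Turns per-oocyte current (and optional surface luminescence)
#' measurements into per-construct summaries: sample sizes, mean +/- SEM
#' relative current and surface expression (normalised to the reference
#' construct via [normalize_to_reference()]), conductivity, a two-tailed
#' Student's t-test of the relative currents against the reference, a hit
#' flag and a mechanism label from [classify_mechanism()].
#'
#' @param measurements Data frame with columns `construct_id`, `batch_id`,
#'   `current_uA` and optionally `luminescence_RLU` (`NA` where a construct
#'   was not assayed for surface expression).
#' @param reference_id Reference (wild-type) construct id.
#' @param per_batch Per-batch normalisation (default `TRUE`).
#' @param current_threshold,conductivity_band Passed to
#'   [classify_mechanism()]; `current_threshold` together with
#'   `p_threshold` also defines the hit flag.
#' @param p_threshold p-value below which a reduced construct is flagged as
#'   a hit (default 0.001).
#' @param p_adjust Multiple-testing correction method for the hit flag
#'   (default `"none"`, matching per-construct reporting; e.g. `"holm"`).
#' @return Data frame, one row per construct: `construct_id`, `n_current`,
#'   `rel_current`, `sem_current`, `n_surface`, `rel_surface`,
#'   `sem_surface`, `conductivity`, `p_vs_ref`, `is_hit`, `mechanism`.
#' @export
summarize_screen <- function(measurements, reference_id = "WT",
                             per_batch = TRUE, current_threshold = 0.3,
                             conductivity_band = c(0.5, 2),
                             p_threshold = 0.001, p_adjust = "none") {
  cur <- normalize_to_reference(measurements, reference_id,
                                value = "current_uA", per_batch = per_batch)
  has_surface <- "luminescence_RLU" %in% names(measurements) &&
    any(!is.na(measurements$luminescence_RLU))
  if (has_surface)
    sur <- normalize_to_reference(measurements, reference_id,
                                  value = "luminescence_RLU",
                                  per_batch = per_batch)
  ids <- unique(measurements$construct_id)
  ref_rel <- cur$rel[cur$construct_id == reference_id & !is.na(cur$rel)]
  sem <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_

  out <- do.call(rbind, lapply(ids, function(id) {
    rc <- cur$rel[cur$construct_id == id & !is.na(cur$rel)]
    rs <- if (has_surface)
      sur$rel[sur$construct_id == id & !is.na(sur$rel)] else numeric()
    p <- if (id == reference_id) 1
         else if (length(rc) >= 2L) ttest_unpaired(rc, ref_rel)$p.value
         else NA_real_
    data.frame(
      construct_id = id,
      n_current = length(rc),
      rel_current = mean(rc), sem_current = sem(rc),
      n_surface = length(rs),
      rel_surface = if (length(rs)) mean(rs) else NA_real_,
      sem_surface = if (length(rs)) sem(rs) else NA_real_,
      p_vs_ref = p)
  }))
  out$conductivity <- conductivity(out$rel_current, out$rel_surface)
  p_adj <- stats::p.adjust(out$p_vs_ref, method = p_adjust)
  out$is_hit <- out$construct_id != reference_id &
    out$rel_current < current_threshold &
    !is.na(p_adj) & p_adj < p_threshold
  out$mechanism <- classify_mechanism(out$rel_current, out$rel_surface,
                                      out$conductivity, current_threshold,
                                      conductivity_band)
  rownames(out) <- NULL
  out
}

#' Dominant-negative current suppression
#'
#' Fractional suppression of a reference current by co-expression:
#' `1 - mean(co) / mean(reference)`.  Negative values mean the
#' co-expression *increased* the current (enhancement).  Significance from
#' [ttest_unpaired()].
#'
#' @param co_current Currents with the co-expressed construct.
#' @param reference_current Currents of the reference alone.
#' @return List with `suppression`, `enhancement` (logical), `statistic`,
#'   `p.value`, `n_co`, `n_ref`.
#' @export
dominant_negative <- function(co_current, reference_current) {
  co <- co_current[is.finite(co_current)]
  ref <- reference_current[is.finite(reference_current)]
  if (length(co) < 2L || length(ref) < 2L)
    stop("each group needs at least 2 finite values")
  if (mean(ref) <= 0) stop("reference mean current must be positive")
  tt <- ttest_unpaired(co, ref)
  s <- 1 - mean(co) / mean(ref)
  list(suppression = s, enhancement = s < 0,
       statistic = tt$statistic, p.value = tt$p.value,
       n_co = length(co), n_ref = length(ref))
}

#' Step-current amplitude from a trace
#'
#' Mean current over a time window of a (time, current) trace -- the
#' amplitude read-out at a voltage step plateau.
#'
#' @param trace Data frame with columns `time` and `current` (consistent
#'   units).
#' @param window Length-2 numeric interval `c(t0, t1)` inside the trace
#'   span.
#' @return Mean current over the window.
#' @export
extract_step_current <- function(trace, window) {
  stopifnot(is.data.frame(trace), all(c("time", "current") %in% names(trace)),
            length(window) == 2L)
  window <- sort(window)
  if (window[1] < min(trace$time) || window[2] > max(trace$time))
    stop("window [", window[1], ", ", window[2], "] outside trace span [",
         min(trace$time), ", ", max(trace$time), "]")
  sel <- trace$time >= window[1] & trace$time <= window[2]
  if (!any(sel)) stop("window contains no samples")
  mean(trace$current[sel])
}

#' Read a screen CSV
#'
#' Expects columns `construct_id`, `batch_id`, `current_uA` and optionally
#' `luminescence_RLU`.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_screen_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("construct_id", "batch_id", "current_uA")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("screen CSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.null(x$luminescence_RLU) &&
      any(x$luminescence_RLU < 0, na.rm = TRUE))
    stop("luminescence_RLU must be >= 0")
  x
}
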