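#' Sliding-window coiled-coil score
#'
#' Implements the Lupas sliding-window method: for every window of
#' `window` consecutive residues and every one of the seven possible heptad
#' registers, the window score is the weighted geometric mean of the
#' per-residue propensities (hydrophobic core positions `a` and `d` carry
#' weight `weighting`, all others weight 1):
#' \deqn{S = \left(\prod_i p_i^{w_i}\right)^{1/\sum_i w_i}}
#' Each sequence position is assigned the maximum window score over all
#' windows covering it and all registers.  A residue with propensity 0 at
#' its heptad position forces that window's score to 0.
#'
#' @param sequence Amino-acid sequence (string or letter vector); ambiguity
#'   codes are rejected.
#' @param window Window length; the bundled calibrations cover 14, 21, 28.
#' @param matrix_id Propensity table, see [coils_matrix()].
#' @param weighting Weight applied to `a`/`d` positions (default 2.5).
#' @return Numeric vector of per-position scores (length = sequence length),
#'   with attribute `"register"` giving the heptad letter of each position
#'   in its best-scoring window.
#' @seealso [coils_probability()], [coils_profile()]
#' @export
coils_score <- function(sequence, window = 28, matrix_id = "MTIDK",
                        weighting = 2.5) {
  s <- .as_residues(sequence)
  n <- length(s)
  if (n < window)
    stop("sequence length (", n, ") is shorter than the window (", window, ")")
  if (window < 7) stop("window must be at least one heptad (7)")
  P <- coils_matrix(matrix_id)

  best <- rep(0, n)
  best_letter <- rep(NA_character_, n)
  starts <- seq_len(n - window + 1L)

  for (off in 0:6) {
    # heptad index of every position under this register phase
    hept <- ((seq_len(n) - 1L + off) %% 7L) + 1L
    p <- P[cbind(match(s, rownames(P)), hept)]
    w <- ifelse(hept %in% c(1L, 4L), weighting, 1)
    lp <- ifelse(p > 0, log(pmax(p, .Machine$double.xmin)), 0)
    zero <- as.numeric(p == 0)
    # cumulative sums give every window's weighted log-mean in O(n)
    cw  <- cumsum(c(0, w))
    cwl <- cumsum(c(0, w * lp))
    cz  <- cumsum(c(0, zero))
    for (st in starts) {
      en <- st + window - 1L
      sc <- if (cz[en + 1L] - cz[st] > 0) 0 else
        exp((cwl[en + 1L] - cwl[st]) / (cw[en + 1L] - cw[st]))
      idx <- st:en
      upd <- sc > best[idx]
      if (any(upd)) {
        best[idx[upd]] <- sc
        best_letter[idx[upd]] <- letters[hept[idx[upd]]]
      }
    }
  }
  structure(best, register = best_letter)
}

#' Convert a coiled-coil score to a probability
#'
#' The score distributions of genuine coiled-coil and globular windows are
#' each modelled as a Gaussian; the probability is the ratio of densities
#' \deqn{p = \frac{G_{cc}(S)}{G_{cc}(S) + G_{g}(S)}}
#' evaluated with the bundled calibration for the given matrix, window and
#' weighting.  `p` is 0.5 exactly where the two densities are equal and
#' increases monotonically with the score above that crossover.
#'
#' @param score Numeric vector of scores (>= 0), e.g. from [coils_score()].
#' @inheritParams coils_score
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
coils_probability <- function(score, window = 28, matrix_id = "MTIDK",
                              weighting = 2.5) {
  if (any(score < 0)) stop("scores must be >= 0")
  g <- coils_gaussian(matrix_id, window, weighting)
  gcc <- dnorm(score, g$m_cc, g$sd_cc)
  gg  <- dnorm(score, g$m_g,  g$sd_g)
  gcc / (gcc + gg)
}

#' Per-position coiled-coil profile
#'
#' Convenience wrapper combining [coils_score()] and [coils_probability()]
#' into a per-position table, optionally with heptad letters from a fixed
#' register anchor (when `anchor` is `NULL` the letter of the best-scoring
#' window is reported instead).
#'
#' @inheritParams coils_score
#' @param anchor Optional register anchor position (an `a` site) used to
#'   label positions via [assign_heptad()].
#' @param offset 1-based sequence position of the first residue of
#'   `sequence` (default 1), so profiles of sub-regions keep the numbering
#'   of the full protein.
#' @return Data frame with columns `pos`, `aa`, `register`, `score`,
#'   `probability`.
#' @export
coils_profile <- function(sequence, window = 28, matrix_id = "MTIDK",
                          weighting = 2.5, anchor = NULL, offset = 1L) {
  s <- .as_residues(sequence)
  sc <- coils_score(s, window, matrix_id, weighting)
  pos <- seq_along(s) + offset - 1L
  reg <- if (is.null(anchor)) attr(sc, "register")
         else assign_heptad(anchor, pos)
  data.frame(pos = pos, aa = s, register = reg,
             score = as.numeric(sc),
             probability = coils_probability(as.numeric(sc), window,
                                             matrix_id, weighting))
}
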