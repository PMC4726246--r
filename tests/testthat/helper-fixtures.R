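# Shared fixtures and independent oracles.

# Bundled TASK-1 N-terminal sequence (positions = residue numbers).
task1_seq <- function() {
  read_fasta_sequences(system.file("extdata", "task1_m1p1.fasta",
                                   package = "k2pcap"))[[1L]]
}

# The seven cap-domain loss-of-function residues.
cap_hits <- c(48L, 52L, 53L, 54L, 55L, 59L, 62L)

# Brute-force sliding-window coiled-coil score: explicit loops over every
# window start, register offset and window position.  Independent of the
# cumulative-sum implementation in coils_score().
brute_coils_score <- function(sequence, window, matrix_id = "MTIDK",
                              weighting = 2.5) {
  s <- strsplit(toupper(sequence), "")[[1L]]
  P <- coils_matrix(matrix_id)
  n <- length(s)
  best <- rep(0, n)
  for (st in seq_len(n - window + 1L)) {
    for (off in 0:6) {
      logsum <- 0; wsum <- 0; zero <- FALSE
      for (k in 0:(window - 1L)) {
        pos <- st + k
        hept <- ((pos - 1L + off) %% 7L) + 1L
        p <- P[s[pos], hept]
        w <- if (hept %in% c(1L, 4L)) weighting else 1
        if (p == 0) zero <- TRUE else logsum <- logsum + w * log(p)
        wsum <- wsum + w
      }
      sc <- if (zero) 0 else exp(logsum / wsum)
      idx <- st:(st + window - 1L)
      best[idx] <- pmax(best[idx], sc)
    }
  }
  best
}

# Textbook pooled-variance two-sample t-test.
brute_ttest <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = t, df = na + nb - 2,
       p.value = 2 * pt(-abs(t), na + nb - 2))
}

# Random amino-acid sequence from the standard alphabet.
random_seq <- function(n) {
  paste0(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                  "F","P","S","T","W","Y","V"), n, replace = TRUE),
         collapse = "")
}

# Ideal heptad 28-mer: L at a/d, E at e, K at g, A at b/c/f.
ideal_heptad_28 <- function() paste(rep("LAALEAK", 4), collapse = "")

# Small leucine-rich dimeric cap with two planted homotypic contacts:
# residues 3-3 close (4.5 A) and 8-8 remote (9 A).  Memoised because the
# rigid placement is the slow part.
.toy_env <- new.env(parent = emptyenv())
toy_two_pair_cap <- function() {
  if (is.null(.toy_env$cap)) {
    .toy_env$cap <- make_toy_cap(
      rep(c("LEU", "ALA", "LEU", "SER", "TYR"), 2),
      pairs = data.frame(res_i = c(3L, 8L), res_j = c(3L, 8L),
                         target = c(4.5, 9.0)),
      seed = 42L)
  }
  .toy_env$cap
}
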