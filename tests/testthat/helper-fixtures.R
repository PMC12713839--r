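# Shared fixtures: small kinetics and hypnograms built in code.

# single-matrix kinetics (same dynamics in light and dark)
uniform_kinetics <- function(P, pi0 = c(W = 1, N = 0, R = 0)) {
  vigilance_kinetics(P, P, pi0 = pi0)
}

# simple well-mixed chain used by several property tests
mixing_matrix <- function(p_nr = 0.02) {
  matrix(c(0.90, 0.10, 0.00,
           0.08, 0.92 - p_nr, p_nr,
           0.10, 0.10, 0.80),
         nrow = 3, byrow = TRUE)
}

# hypnogram from a label string like "WWNNR"
hyp_from_string <- function(s, ...) {
  hypnogram(strsplit(s, "")[[1]], ...)
}

# brute-force transition scan: pairwise walk over labels
brute_transitions <- function(labels) {
  out <- stats::setNames(integer(6), c("W>N", "N>W", "N>R", "R>N", "R>W", "W>R"))
  for (i in seq_len(length(labels) - 1)) {
    if (labels[i] != labels[i + 1]) {
      key <- paste0(labels[i], ">", labels[i + 1])
      out[key] <- out[key] + 1L
    }
  }
  out
}

# brute-force Sokolove-Bushell Qp by explicit fold
brute_qp <- function(x, K) {
  N <- length(x) %/% K
  xs <- x[seq_len(K * N)]
  Mh <- numeric(K)
  for (h in seq_len(K)) Mh[h] <- mean(xs[seq(h, by = K, length.out = N)])
  Mbar <- mean(xs)
  N * sum((Mh - Mbar)^2) / mean((xs - Mbar)^2)
}
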