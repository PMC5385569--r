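# Shared fixtures, all generated in code under fixed seeds.

# Random valid model with interior parameters.
random_model <- function(Kn, Kd, M, D, seed = 1L) {
  set.seed(seed)
  rrow <- function(n) { x <- runif(n) + 0.05; x / sum(x) }
  E <- matrix(runif(Kn * M) * 0.9 + 0.05, Kn, M)
  nt <- array(0, c(Kn, Kn, Kd))
  for (d in seq_len(Kd)) for (j in seq_len(Kn)) nt[j, , d] <- rrow(Kn)
  dt <- matrix(0, Kd, Kd)
  for (d in seq_len(Kd)) dt[d, ] <- rrow(Kd)
  P0 <- matrix(rrow(Kn * Kd), Kn, Kd)
  dihmm_model(E, nt, dt, P0, D, paste0("m", seq_len(M)))
}

random_tracks <- function(L, M, seed = 1L, p = 0.4) {
  set.seed(seed)
  binarized_tracks(matrix(rbinom(L * M, 1L, p), L, M),
                   paste0("m", seq_len(M)))
}

# Near-deterministic model: sharp emissions (0.99/0.01), sticky transitions
# (diagonal 0.98) and domain-specific preferred state sets, so the generating
# path -- including the domain level -- is recoverable almost everywhere.
sharp_model <- function(Kn = 3L, Kd = 2L, M = 4L, D = 5L) {
  E <- matrix(0.01, Kn, M)
  for (k in seq_len(Kn))
    for (m in seq_len(M))
      if ((k - 1L) %/% 2^(m - 1L) %% 2L == 1L) E[k, m] <- 0.99
  nt <- array(0, c(Kn, Kn, Kd))
  for (d in seq_len(Kd)) {
    S <- which((seq_len(Kn) - 1L) %% Kd == d - 1L)
    for (j in seq_len(Kn)) {
      row <- rep(0.005 / max(Kn - 1, 1), Kn)
      if (j %in% S) {
        row[j] <- 0.98
        others <- setdiff(S, j)
        if (length(others)) row[others] <- 0.015 / length(others)
      } else {
        row[j] <- 0.02
        row[S] <- 0.97 / length(S)
      }
      nt[j, , d] <- row / sum(row)
    }
  }
  dt <- matrix(0.02 / max(Kd - 1, 1), Kd, Kd); diag(dt) <- 0.98
  if (Kd == 1L) dt <- matrix(1, 1L, 1L)
  P0 <- matrix(1 / (Kn * Kd), Kn, Kd)
  dihmm_model(E, nt, dt, P0, D, paste0("m", seq_len(M)))
}

# Flatten a (nuc, dom) path to the package's pair-state index.
pair_index <- function(nuc, dom, Kn) nuc + (dom - 1L) * Kn
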