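# Independent oracles used across the suite.  These are deliberately written
# from first principles (raw parameter arrays, dense enumeration, textbook
# recursions) and never call the package's inference code paths.

# Exhaustive enumeration over all pair-state sequences of a two-level chain.
# E: Kn x M emissions; nt: Kn x Kn x Kd (j -> k | destination domain);
# dt: Kd x Kd; P0: Kn x Kd; D: block size; X: L x M 0/1 observations.
# A domain change is allowed on the step entering bin i (1-based) iff
# (i - 1) %% D == 0.
enum_oracle <- function(E, nt, dt, P0, D, X) {
  Kn <- nrow(E); Kd <- nrow(dt); K <- Kn * Kd; L <- nrow(X)
  jn <- rep(seq_len(Kn), Kd)
  mu <- rep(seq_len(Kd), each = Kn)
  emis <- function(i, j) prod(ifelse(X[i, ] == 1, E[j, ], 1 - E[j, ]))
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
  w <- apply(paths, 1L, function(s) {
    p <- P0[jn[s[1L]], mu[s[1L]]] * emis(1L, jn[s[1L]])
    if (L > 1L) for (i in 2:L) {
      tp <- nt[jn[s[i - 1L]], jn[s[i]], mu[s[i]]] *
        (if ((i - 1L) %% D == 0L) dt[mu[s[i - 1L]], mu[s[i]]]
         else as.numeric(mu[s[i - 1L]] == mu[s[i]]))
      p <- p * tp * emis(i, jn[s[i]])
    }
    p
  })
  lik <- sum(w)
  gamma <- function(i) {
    g <- vapply(seq_len(K), function(s) sum(w[paths[, i] == s]), numeric(1L))
    g / lik
  }
  xi <- function(i) {
    x <- matrix(0, K, K)
    for (a in seq_len(K)) for (b in seq_len(K))
      x[a, b] <- sum(w[paths[, i] == a & paths[, i + 1L] == b])
    x / lik
  }
  list(lik = lik, loglik = log(lik), gamma = gamma, xi = xi,
       map = paths[which.max(w), ], paths = paths, w = w,
       jn = jn, mu = mu)
}

# Textbook scaled forward-backward for a flat (single-level) Bernoulli HMM.
flat_fb <- function(p0, A, E, X) {
  L <- nrow(X); K <- nrow(E)
  b <- matrix(0, L, K)
  for (k in seq_len(K))
    b[, k] <- apply(X, 1L, function(x) prod(ifelse(x == 1, E[k, ], 1 - E[k, ])))
  al <- matrix(0, L, K); sc <- numeric(L)
  a <- p0 * b[1L, ]; sc[1L] <- sum(a); al[1L, ] <- a / sc[1L]
  for (i in seq_len(L)[-1L]) {
    a <- as.vector(al[i - 1L, ] %*% A) * b[i, ]
    sc[i] <- sum(a); al[i, ] <- a / sc[i]
  }
  be <- matrix(0, L, K); be[L, ] <- 1
  for (i in rev(seq_len(L - 1L)))
    be[i, ] <- as.vector(A %*% (b[i + 1L, ] * be[i + 1L, ])) / sc[i + 1L]
  g <- al * be
  xi <- matrix(0, K, K)
  for (i in seq_len(L - 1L))
    xi <- xi + (al[i, ] %o% (b[i + 1L, ] * be[i + 1L, ])) * A / sc[i + 1L]
  list(loglik = sum(log(sc)), gamma = g, xi = xi,
       emit_on = t(g) %*% X, occ = colSums(g))
}

# Flat Baum-Welch with the same additive-pseudocount update scheme as the
# package; returns the per-iteration log-likelihood trace.
flat_bw <- function(p0, A, E, X, iters, pc = 1e-6) {
  trace <- numeric(iters)
  for (t in seq_len(iters)) {
    fb <- flat_fb(p0, A, E, X)
    trace[t] <- fb$loglik
    A <- (fb$xi + pc) / (rowSums(fb$xi) + ncol(A) * pc)
    E <- (fb$emit_on + pc) / (fb$occ + 2 * pc)
    p0 <- (fb$gamma[1L, ] + pc) / (1 + length(p0) * pc)
    p0 <- p0 / sum(p0)
  }
  list(trace = trace, A = A, E = E, p0 = p0)
}

# Optimal k-centre covering radius by brute force over centre subsets.
kcentre_opt_radius <- function(points, k) {
  n <- nrow(points)
  d <- as.matrix(dist(points))
  best <- Inf
  for (sub in utils::combn(n, k, simplify = FALSE)) {
    r <- max(apply(d[, sub, drop = FALSE], 1L, min))
    best <- min(best, r)
  }
  best
}

# Total-variation distance between two independent-Bernoulli product
# distributions over {0,1}^M, by full enumeration.
bernoulli_tv <- function(p, q) {
  M <- length(p)
  combos <- as.matrix(expand.grid(rep(list(0:1), M)))
  pr <- function(theta) apply(combos, 1L, function(x)
    prod(ifelse(x == 1, theta, 1 - theta)))
  sum(abs(pr(p) - pr(q))) / 2
}

# Poisson upper-tail probability by direct pmf summation (cap far beyond any
# mass at the rates used in tests).
pois_tail_sum <- function(c, lambda, cap = 2000L) {
  if (c <= 0) return(1)
  sum(dpois(c:cap, lambda))
}
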