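toy_cases <- list(
  list(Kn = 2L, Kd = 2L, D = 2L, L = 4L, M = 2L, seed = 21L),
  list(Kn = 3L, Kd = 2L, D = 2L, L = 5L, M = 2L, seed = 22L),
  list(Kn = 2L, Kd = 2L, D = 3L, L = 6L, M = 3L, seed = 23L)
)

test_that("forward likelihood, posteriors, pair marginals and Viterbi match exhaustive enumeration", {
  for (cfg in toy_cases) {
    m <- random_model(cfg$Kn, cfg$Kd, cfg$M, cfg$D, seed = cfg$seed)
    tr <- random_tracks(cfg$L, cfg$M, seed = cfg$seed + 100L)
    oracle <- enum_oracle(m$emissions, m$nuc_trans, m$dom_trans, m$initial,
                          cfg$D, tr$data)

    fw <- dihmm_forward(m, tr)
    expect_equal(fw$log_likelihood, oracle$loglik, tolerance = 1e-10)
    expect_equal(fw$log_likelihood, sum(log(fw$scales)))
    expect_equal(max(abs(rowSums(fw$alpha_hat) - 1)), 0, tolerance = 1e-9)

    post <- dihmm_posteriors(m, tr)
    for (i in seq_len(cfg$L))
      expect_equal(as.vector(post$gamma[i, , ]), oracle$gamma(i),
                   tolerance = 1e-10)

    xi <- pair_marginals(m, tr)
    for (i in seq_len(cfg$L - 1L))
      expect_equal(xi[i, , ], oracle$xi(i), tolerance = 1e-10)

    vt <- dihmm_viterbi(m, tr)
    expect_equal(pair_index(vt$nuc_states, vt$dom_states, cfg$Kn),
                 unname(oracle$map))
  }
})

test_that("single-pair-state chains reduce to a product of Bernoulli likelihoods", {
  m <- random_model(1, 1, 3, 4, seed = 31)
  tr <- random_tracks(12, 3, seed = 32)
  fw <- dihmm_forward(m, tr)
  ll <- sum(log(ifelse(tr$data == 1,
                       matrix(m$emissions, 12, 3, byrow = TRUE),
                       1 - matrix(m$emissions, 12, 3, byrow = TRUE))))
  expect_equal(fw$log_likelihood, ll)
  post <- dihmm_posteriors(m, tr)
  expect_true(all(post$gamma == 1))
  expect_equal(dihmm_viterbi(m, tr)$nuc_states, rep(1L, 12L))
})

test_that("uniform emissions factor out of the likelihood entirely", {
  m <- random_model(3, 2, 2, 4, seed = 41)
  m$emissions[] <- 0.5
  tr <- random_tracks(10, 2, seed = 42)
  expect_equal(dihmm_forward(m, tr)$log_likelihood, -10 * 2 * log(2))
})

test_that("forward and backward agree: alpha*beta is a distribution at every bin", {
  for (seed in 1:5) {
    m <- random_model(3, 2, 3, 4, seed = seed)
    tr <- random_tracks(37, 3, seed = seed + 50L)
    fw <- dihmm_forward(m, tr)
    beta <- dihmm_backward(m, tr, fw$scales)
    expect_equal(max(abs(rowSums(fw$alpha_hat * beta) - 1)), 0,
                 tolerance = 1e-9)
    expect_true(all(beta[nrow(beta), ] == 1))
  }
})

test_that("posterior domain marginals are constant within every block", {
  for (seed in 1:10) {
    m <- random_model(3, 2, 3, 5, seed = seed)
    tr <- random_tracks(53, 3, seed = seed + 70L)  # trailing partial block
    post <- dihmm_posteriors(m, tr)
    dm <- apply(post$gamma, c(1L, 3L), sum)
    blk <- rep(seq_len(ceiling(53 / 5)), each = 5L, length.out = 53L)
    for (b in unique(blk)) {
      rows <- dm[blk == b, , drop = FALSE]
      expect_lt(max(abs(sweep(rows, 2L, rows[1L, ]))), 1e-9)
    }
  }
})

test_that("with a single domain state all quantities equal a flat HMM's", {
  m <- random_model(3, 1, 3, 5, seed = 61)
  tr <- random_tracks(60, 3, seed = 62)
  fb <- flat_fb(m$initial[, 1L], m$nuc_trans[, , 1L], m$emissions, tr$data)
  fw <- dihmm_forward(m, tr)
  expect_equal(fw$log_likelihood, fb$loglik, tolerance = 1e-10)
  post <- dihmm_posteriors(m, tr)
  expect_equal(post$gamma[, , 1L], fb$gamma, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("pair marginals are consistent and respect structural zeros", {
  m <- random_model(2, 2, 2, 3, seed = 71)
  tr <- random_tracks(9, 2, seed = 72)
  xi <- pair_marginals(m, tr)
  post <- dihmm_posteriors(m, tr)
  Kn <- 2L
  for (i in seq_len(8L)) {
    expect_equal(sum(xi[i, , ]), 1, tolerance = 1e-9)
    expect_equal(rowSums(xi[i, , ]), as.vector(post$gamma[i, , ]),
                 tolerance = 1e-9)
    if (i %% 3L != 0L) {
      # off-domain blocks must be exactly zero away from boundaries
      for (mu in 1:2) for (nu in 1:2) if (mu != nu)
        expect_true(all(xi[i, (mu - 1L) * Kn + 1:2, (nu - 1L) * Kn + 1:2] == 0))
    }
  }
  expect_equal(dim(pair_marginals(m, binarized_tracks(
    tr$data[1L, , drop = FALSE], tr$mark_names))), c(0L, 4L, 4L))
})

test_that("decoders recover a near-deterministic generating path", {
  m <- sharp_model()
  sim <- simulate_tracks(m, length_bins = 10000L, seed = 81L)
  truth <- sim$paths[[1L]]
  vt <- dihmm_viterbi(m, sim$tracks[[1L]])
  expect_gte(mean(vt$nuc_states == truth$nuc_states), 0.99)
  expect_gte(mean(vt$dom_states == truth$dom_states), 0.99)
  # Viterbi joint log-probability can never exceed the total likelihood
  expect_lte(attr(vt, "log_prob"),
             dihmm_forward(m, sim$tracks[[1L]])$log_likelihood)
  pd <- posterior_decode(dihmm_posteriors(m, sim$tracks[[1L]]))
  expect_gte(mean(pd$nuc_states == vt$nuc_states), 0.99)
  expect_gte(mean(pd$dom_states == vt$dom_states), 0.99)
})

test_that("posterior decoding returns indicated paths and block-constant domains", {
  m <- random_model(2, 2, 2, 3, seed = 91)
  tr <- random_tracks(9, 2, seed = 92)
  post <- dihmm_posteriors(m, tr)
  pd <- posterior_decode(post)
  blk <- rep(1:3, each = 3L)
  expect_true(all(tapply(pd$dom_states, blk, function(d)
    length(unique(d))) == 1L))
  # indicator posteriors decode to exactly the indicated path
  ind <- post
  ind$gamma[] <- 0
  nuc <- c(2L, 1L, 2L, 1L, 1L, 2L, 1L, 2L, 2L)
  dom <- rep(c(1L, 2L, 1L), each = 3L)
  for (i in 1:9) ind$gamma[i, nuc[i], dom[i]] <- 1
  pd2 <- posterior_decode(ind)
  expect_equal(pd2$nuc_states, nuc)
  expect_equal(pd2$dom_states, dom)
})

test_that("emission probabilities multiply independent Bernoulli marks", {
  m <- random_model(2, 1, 2, 3, seed = 101)
  m$emissions[1L, ] <- c(0.9, 0.2)
  expect_equal(emission_prob(m, c(1, 0), 1), 0.9 * 0.8)
  m$emissions[] <- 0.5
  expect_equal(emission_prob(m, c(1, 1), 2), 0.25)
  m$emissions[1L, ] <- c(1, 0)
  expect_equal(emission_prob(m, c(1, 0), 1), 1)
  expect_error(emission_prob(m, c(1, 0, 1), 1), "length")
})

test_that("inference rejects incompatible marks and degenerate emission mass", {
  m <- random_model(2, 2, 2, 3, seed = 111)
  tr <- random_tracks(6, 2, seed = 112)
  tr$mark_names <- c("x", "y")
  colnames(tr$data) <- tr$mark_names
  expect_error(dihmm_forward(m, tr), "marks")
  m2 <- random_model(2, 2, 2, 3, seed = 113)
  m2$emissions[] <- 0    # every state says "never on"
  tr2 <- random_tracks(6, 2, seed = 114, p = 1)
  expect_error(dihmm_forward(m2, tr2), "underflow at position 1")
})
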