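test_that("sufficient statistics reduce to deterministic counts for one pair state", {
  m <- random_model(1, 1, 2, 4, seed = 201)
  tr <- random_tracks(13, 2, seed = 202)
  st <- accumulate_stats(m, tr)
  expect_equal(sum(st$xi_nuc), 12)                       # L - 1 steps
  expect_equal(unname(st$xi_boundary[1L, 1L]), 3)        # boundaries at 4, 8, 12
  expect_equal(unname(st$occupancy), 13)
  expect_equal(unname(st$gamma_first[1L, 1L]), 1)
  expect_equal(unname(st$emit_on[1L, ]), unname(colSums(tr$data)))
})

test_that("expected transition counts match enumeration-weighted path expectations", {
  m <- random_model(2, 2, 2, 2, seed = 211)
  tr <- random_tracks(4, 2, seed = 212)
  st <- accumulate_stats(m, tr)
  o <- enum_oracle(m$emissions, m$nuc_trans, m$dom_trans, m$initial, 2L,
                   tr$data)
  # oracle expectations of the same sufficient statistics
  xi_nuc_o <- array(0, c(2, 2, 2)); xi_b_o <- matrix(0, 2, 2)
  for (i in 1:3) {
    x <- o$xi(i)
    for (a in 1:4) for (b in 1:4) {
      xi_nuc_o[o$jn[a], o$jn[b], o$mu[b]] <-
        xi_nuc_o[o$jn[a], o$jn[b], o$mu[b]] + x[a, b]
      if (i %% 2L == 0L)
        xi_b_o[o$mu[a], o$mu[b]] <- xi_b_o[o$mu[a], o$mu[b]] + x[a, b]
    }
  }
  expect_equal(st$xi_nuc, xi_nuc_o, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(st$xi_boundary, xi_b_o, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(as.vector(st$gamma_first), o$gamma(1), tolerance = 1e-10)
  # expected-count conservation over all transition statistics
  expect_equal(sum(st$xi_nuc), 3, tolerance = 1e-10)
})

test_that("sufficient statistics are additive over sequences", {
  m <- random_model(2, 2, 3, 3, seed = 221)
  trA <- random_tracks(12, 3, seed = 222)
  trB <- random_tracks(9, 3, seed = 223)
  both <- combine_stats(accumulate_stats(m, trA), accumulate_stats(m, trB))
  sep <- lapply(list(trA, trB), function(tr) accumulate_stats(m, tr))
  expect_equal(both$xi_nuc, sep[[1L]]$xi_nuc + sep[[2L]]$xi_nuc)
  expect_equal(both$emit_on, sep[[1L]]$emit_on + sep[[2L]]$emit_on)
  expect_equal(both$n_sequences, 2L)
  expect_equal(both$log_likelihood,
               sep[[1L]]$log_likelihood + sep[[2L]]$log_likelihood)
})

test_that("parameter updates are the smoothed empirical frequencies", {
  # a deterministic single-path posterior: frozen stats built by hand
  st <- structure(list(
    xi_boundary = matrix(c(3, 1, 0, 2), 2L, 2L, byrow = TRUE),
    xi_nuc = array(c(4, 2, 1, 3, 0, 2, 2, 0), c(2L, 2L, 2L)),
    gamma_first = matrix(c(1, 0, 0, 0), 2L, 2L),
    emit_on = matrix(c(5, 1, 2, 6), 2L, 2L),
    occupancy = c(8, 7), n_sequences = 1L, log_likelihood = -1),
    class = "dihmm_stats")
  m <- update_parameters(st, pseudocount = 0, block_size = 4L,
                         mark_names = c("a", "b"))
  expect_equal(unname(m$dom_trans[1L, ]), c(3, 1) / 4)
  expect_equal(unname(m$dom_trans[2L, ]), c(0, 2) / 2)
  expect_equal(unname(m$nuc_trans[1L, , 1L]), c(4, 1) / 5)
  expect_equal(unname(m$emissions[1L, 1L]), 5 / 8)
  expect_equal(unname(m$initial[1L, 1L]), 1)
  expect_length(validate_model(m), 0L)
  # symmetric statistics give uniform parameters
  st$xi_boundary <- matrix(1, 2L, 2L)
  st$xi_nuc <- array(1, c(2L, 2L, 2L))
  st$gamma_first <- matrix(0.25, 2L, 2L)
  u <- update_parameters(st, pseudocount = 1e-6, block_size = 4L,
                         mark_names = c("a", "b"))
  expect_equal(unname(u$dom_trans), matrix(0.5, 2L, 2L))
  expect_equal(unname(u$initial), matrix(0.25, 2L, 2L))
  expect_error(update_parameters(st, pseudocount = -1), "pseudocount")
})

test_that("one EM step from the truth barely moves the parameters at large samples", {
  truth <- make_fixture_model(3, 2, 4, block_size = 10, separation = 0.35)
  sim <- simulate_tracks(truth, length_bins = 100000L, seed = 231L)
  st <- accumulate_stats(truth, sim$tracks[[1L]])
  m1 <- update_parameters(st, 1e-6, truth$block_size, truth$mark_names)
  expect_lt(max(abs(m1$emissions - truth$emissions)), 0.01)
})

test_that("EM log-likelihood trace is monotone and fixed points are detected", {
  # monotonicity on a random model/data pair
  m <- random_model(3, 2, 3, 4, seed = 241)
  tr <- random_tracks(120, 3, seed = 242)
  fit <- baum_welch(m, tr, max_iter = 20L, tol = -Inf)
  expect_equal(fit$iterations, 20L)
  expect_true(all(diff(fit$trace) >= -1e-8 * abs(fit$trace[-20L])))

  # a one-state model is its own MLE: constant trace, immediate convergence
  m1 <- random_model(1, 1, 2, 4, seed = 243)
  tr1 <- random_tracks(40, 2, seed = 244)
  st <- accumulate_stats(m1, tr1)
  mle <- update_parameters(st, 0, 4L, m1$mark_names)
  fit1 <- baum_welch(mle, tr1, max_iter = 10L, tol = 1e-4, pseudocount = 0)
  expect_true(fit1$converged)
  expect_lte(fit1$iterations, 2L)
  expect_equal(diff(range(fit1$trace)), 0, tolerance = 1e-9)
})

test_that("with one domain state training is numerically a flat Baum-Welch", {
  m0 <- random_model(3, 1, 3, 5, seed = 251)
  truth <- sharp_model(Kn = 3L, Kd = 1L, M = 3L, D = 5L)
  sim <- simulate_tracks(truth, length_bins = 800L, seed = 252L)
  iters <- 10L
  fit <- baum_welch(m0, sim$tracks[[1L]], max_iter = iters, tol = -Inf)
  oracle <- flat_bw(m0$initial[, 1L], m0$nuc_trans[, , 1L], m0$emissions,
                    sim$tracks[[1L]]$data, iters)
  expect_equal(fit$trace, oracle$trace, tolerance = 1e-9)
})

test_that("the fitting front-end pools sequences, is deterministic and validates marks", {
  truth <- make_fixture_model(3, 2, 4, block_size = 5, separation = 0.4)
  sim <- simulate_tracks(truth, length_bins = 3000L, n_tracks = 3L,
                         seed = 261L, cell_types = c("H1", "GM", "K5"))
  fit1 <- dihmm(sim$tracks[[1L]], 3, 2, block_size = 5, max_iter = 30L)
  direct <- baum_welch(init_kcentre(sim$tracks[[1L]], 3, 2, 5),
                       sim$tracks[[1L]], max_iter = 30L)
  expect_equal(fit1$model$emissions, direct$model$emissions)
  expect_equal(fit1$trace, direct$trace)

  fit1b <- dihmm(sim$tracks[[1L]], 3, 2, block_size = 5, max_iter = 30L)
  expect_equal(fit1b$model, fit1$model)

  # pooling all three simulated cell types is at least as accurate as the
  # single worst sequence, and uses a single shared parameter set
  pooled <- dihmm(sim$tracks, 3, 2, block_size = 5, max_iter = 60L)
  err <- function(m) max(abs(match_states(m, truth)$emissions -
                               truth$emissions))
  singles <- vapply(sim$tracks, function(tr)
    err(dihmm(tr, 3, 2, block_size = 5, max_iter = 60L)$model), numeric(1L))
  expect_lte(err(pooled$model), max(singles) + 1e-9)
  expect_equal(nrow(pooled$sequences), 3L)

  bad <- sim$tracks
  bad[[2L]]$mark_names <- paste0("x", 1:4)
  colnames(bad[[2L]]$data) <- bad[[2L]]$mark_names
  expect_error(dihmm(bad, 3, 2, block_size = 5), "inconsistent mark sets")
})

test_that("training from binarized files on disk matches training in memory", {
  truth <- make_fixture_model(2, 2, 3, block_size = 4, separation = 0.4)
  sim <- simulate_tracks(truth, length_bins = 800L, n_tracks = 2L, seed = 271L)
  dir <- withr::local_tempdir()
  for (i in 1:2)
    write_binarized(sim$tracks[[i]], file.path(dir, paste0("cell", i, ".txt")))
  fit_disk <- dihmm(dir, 2, 2, block_size = 4, max_iter = 10L)
  fit_mem <- dihmm(sim$tracks, 2, 2, block_size = 4, max_iter = 10L)
  expect_equal(fit_disk$model$emissions, fit_mem$model$emissions)
  expect_equal(fit_disk$trace, fit_mem$trace)
})
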