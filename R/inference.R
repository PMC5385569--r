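## Flattened state layout shared with the C++ core: pair (j, mu) maps to
## column s = j + (mu - 1) * K_n of the L x (K_n * K_d) matrices, i.e. the
## column-major vectorization of a K_n x K_d matrix.

check_compat <- function(model, tracks) {
  stopifnot(inherits(model, "dihmm_model"), inherits(tracks, "dihmm_tracks"))
  if (!identical(model$mark_names, tracks$mark_names))
    stopf("model marks (%s) do not match track marks (%s)",
          paste(model$mark_names, collapse = ","),
          paste(tracks$mark_names, collapse = ","))
  if (nrow(tracks$data) < 1L) stopf("empty track")
}

emission_matrix <- function(model, tracks)
  emission_matrix_cpp(tracks$data, model$emissions)

#' Per-bin state path at both annotation levels
#'
#' @param nuc_states,dom_states integer state indices per bin (1-based).
#' @param block_size bins per domain block; the domain state must be
#'   constant within each block (a trailing partial block counts as a
#'   block).
#' @return an object of class `dihmm_path`.
#' @export
state_path <- function(nuc_states, dom_states, block_size) {
  if (length(nuc_states) != length(dom_states))
    stopf("state vectors must have equal length")
  L <- length(nuc_states)
  blk <- rep(seq_len(ceiling(L / block_size)), each = block_size,
             length.out = L)
  if (any(vapply(split(dom_states, blk), function(d)
    length(unique(d)), integer(1L)) > 1L))
    stopf("domain states must be constant within each block")
  structure(list(nuc_states = as.integer(nuc_states),
                 dom_states = as.integer(dom_states),
                 block_size = as.integer(block_size)),
            class = "dihmm_path")
}

#' @export
print.dihmm_path <- function(x, ...) {
  cat(sprintf("State path: %d bins, block size %d\n", length(x$nuc_states),
              x$block_size))
  cat(sprintf("  nucleosome states used: %d; domain states used: %d\n",
              length(unique(x$nuc_states)), length(unique(x$dom_states))))
  invisible(x)
}

#' Scaled forward pass
#'
#' Computes the rescaled forward variables: at every position the scaling
#' factor is the normalizer that makes the rescaled forward row sum to one,
#' and the product of the scaling factors equals the sequence likelihood, so
#' `log_likelihood = sum(log(scales))`. The recursion uses the composite
#' transition with a domain change permitted exactly when the step crosses a
#' multiple of `block_size`. Cost is `O(L * K_d * K_n^2)` away from
#' boundaries; the full pair-state transition matrix is never materialized.
#'
#' @param model a [dihmm_model].
#' @param tracks a [binarized_tracks] object with matching marks.
#' @return an object of class `dihmm_forward` with elements `alpha_hat`
#'   (`L x (K_n*K_d)`, rows sum to 1), `scales` (length `L`) and
#'   `log_likelihood`.
#' @export
dihmm_forward <- function(model, tracks) {
  check_compat(model, tracks)
  B <- emission_matrix(model, tracks)
  fw <- forward_cpp(B, model$nuc_trans, model$dom_trans, model$initial,
                    model$block_size)
  structure(list(alpha_hat = fw$alpha, scales = fw$scales,
                 log_likelihood = fw$loglik),
            class = "dihmm_forward")
}

#' Rescaled backward pass
#'
#' Runs the backward recursion rescaled with the scaling factors of a
#' forward pass on the same model and tracks. With this convention the
#' termination row is all ones and the elementwise product of the rescaled
#' forward and backward variables is the joint posterior, so
#' `rowSums(alpha_hat * beta_hat) == 1` at every position.
#'
#' @inheritParams dihmm_forward
#' @param scales scaling factors from [dihmm_forward()] on the same input.
#' @return `L x (K_n*K_d)` matrix of rescaled backward variables.
#' @export
dihmm_backward <- function(model, tracks, scales) {
  check_compat(model, tracks)
  B <- emission_matrix(model, tracks)
  backward_cpp(B, model$nuc_trans, model$dom_trans, model$block_size, scales)
}

#' Joint posterior state probabilities
#'
#' `gamma[i, j, mu]` is the posterior probability that bin `i` is in
#' nucleosome state `j` and domain state `mu`, given the whole observed
#' sequence. Because domain transitions are restricted to block boundaries,
#' the domain marginal `apply(gamma, c(1, 3), sum)` is constant within every
#' block.
#'
#' @inheritParams dihmm_forward
#' @return an object of class `dihmm_posteriors` with elements `gamma`
#'   (`L x K_n x K_d` array), `scales`, `log_likelihood` and `block_size`.
#' @export
dihmm_posteriors <- function(model, tracks) {
  fw <- dihmm_forward(model, tracks)
  beta <- dihmm_backward(model, tracks, fw$scales)
  g <- fw$alpha_hat * beta
  L <- nrow(g)
  structure(list(gamma = array(g, c(L, model$n_nuc, model$n_dom)),
                 scales = fw$scales, log_likelihood = fw$log_likelihood,
                 block_size = model$block_size),
            class = "dihmm_posteriors")
}

## dense composite transition matrix over flattened pairs (test-scale only)
composite_matrix <- function(model, at_boundary) {
  Kn <- model$n_nuc; Kd <- model$n_dom
  A <- matrix(0, Kn * Kd, Kn * Kd)
  for (mu in seq_len(Kd)) for (nu in seq_len(Kd)) {
    f <- if (at_boundary) model$dom_trans[mu, nu] else as.numeric(mu == nu)
    if (f > 0)
      A[(mu - 1L) * Kn + seq_len(Kn), (nu - 1L) * Kn + seq_len(Kn)] <-
        f * model$nuc_trans[, , nu]
  }
  A
}

#' Posterior marginals of consecutive state pairs
#'
#' `xi[i, s, s']` is the posterior probability of being in flattened pair
#' state `s` at bin `i` and `s'` at bin `i + 1`. Entries whose domain states
#' differ are structurally zero except when the step crosses a block
#' boundary, and marginalizing over the second pair recovers the single-bin
#' posterior. This materializes a dense `(L-1) x K^2` array and is intended
#' for small inputs (testing and inspection); training accumulates the same
#' quantities in compiled code without materializing them.
#'
#' @inheritParams dihmm_forward
#' @return array of shape `(L-1) x (K_n*K_d) x (K_n*K_d)`; an empty array
#'   when `L == 1`.
#' @export
pair_marginals <- function(model, tracks) {
  check_compat(model, tracks)
  L <- nrow(tracks$data)
  K <- model$n_nuc * model$n_dom
  if (L == 1L) return(array(0, c(0L, K, K)))
  fw <- dihmm_forward(model, tracks)
  beta <- dihmm_backward(model, tracks, fw$scales)
  B <- emission_matrix(model, tracks)
  A_nb <- composite_matrix(model, FALSE)
  A_b <- composite_matrix(model, TRUE)
  bfac <- B[, rep(seq_len(model$n_nuc), model$n_dom), drop = FALSE]
  xi <- array(0, c(L - 1L, K, K))
  for (i in seq_len(L - 1L)) {
    A <- if (i %% model$block_size == 0L) A_b else A_nb
    xi[i, , ] <- (fw$alpha_hat[i, ] * A) *
      rep(bfac[i + 1L, ] * beta[i + 1L, ], each = K) / fw$scales[i + 1L]
  }
  xi
}

#' Viterbi decoding
#'
#' Finds the structurally valid state-pair path maximizing the joint
#' probability of path and observations, in log space; ties are broken
#' toward the lowest (nucleosome, domain) index pair.
#'
#' @inheritParams dihmm_forward
#' @return a [state_path] with attribute `log_prob`, the joint log
#'   probability of the decoded path.
#' @export
dihmm_viterbi <- function(model, tracks) {
  check_compat(model, tracks)
  B <- emission_matrix(model, tracks)
  vt <- viterbi_cpp(B, model$nuc_trans, model$dom_trans, model$initial,
                    model$block_size)
  p <- state_path(vt$nuc, vt$dom, model$block_size)
  attr(p, "log_prob") <- vt$logprob
  p
}

#' Posterior decoding
#'
#' Chooses each block's domain state as the argmax of its (block-constant)
#' posterior domain marginal, then each bin's nucleosome state as the argmax
#' of the joint posterior conditional on the chosen domain state. Ties go to
#' the lowest index. The result always satisfies block constancy by
#' construction.
#'
#' @param posteriors a [dihmm_posteriors] object.
#' @return a [state_path].
#' @export
posterior_decode <- function(posteriors) {
  stopifnot(inherits(posteriors, "dihmm_posteriors"))
  g <- posteriors$gamma
  L <- dim(g)[1L]; D <- posteriors$block_size
  blk <- rep(seq_len(ceiling(L / D)), each = D, length.out = L)
  dom_marg <- apply(g, c(1L, 3L), sum)
  dom_blk <- rowsum(dom_marg, blk)                # sums are fine for argmax
  dom_choice <- max.col(dom_blk, ties.method = "first")
  dom <- dom_choice[blk]
  nuc <- vapply(seq_len(L), function(i) which.max(g[i, , dom[i]]), integer(1L))
  state_path(nuc, dom, D)
}

#' Emission probability of one observation vector
#'
#' Product of independent Bernoulli mark likelihoods for a nucleosome-level
#' state; emissions do not depend on the domain-level state.
#'
#' @param model a [dihmm_model].
#' @param observation 0/1 vector of length `length(mark_names)`.
#' @param nuc_state nucleosome-level state index.
#' @return a probability.
#' @export
emission_prob <- function(model, observation, nuc_state) {
  if (length(observation) != length(model$mark_names))
    stopf("observation has length %d, expected %d", length(observation),
          length(model$mark_names))
  if (nuc_state < 1 || nuc_state > model$n_nuc)
    stopf("nucleosome state index out of range")
  e <- model$emissions[nuc_state, ]
  prod(ifelse(observation == 1, e, 1 - e))
}
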