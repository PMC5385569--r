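#' Sample a state path from the generative model
#'
#' Draws the initial state pair from the joint initial matrix, then walks
#' the chain: away from block boundaries the domain state is carried over
#' and the nucleosome state moves under the current domain's transition
#' matrix; at each block boundary the new domain is drawn first from the
#' domain transition matrix and the nucleosome step then uses the new
#' domain's matrix (destination-domain convention, mirroring inference).
#' Block constancy of the domain state holds by construction.
#'
#' @param model a [dihmm_model].
#' @param length_bins number of bins to sample (>= 1).
#' @param seed integer seed; the global RNG state is left untouched.
#' @return a [state_path].
#' @export
sample_path <- function(model, length_bins, seed = 1L) {
  bad <- validate_model(model)
  if (length(bad)) stopf("invalid model: %s", bad[1L])
  if (length_bins < 1L) stopf("length_bins must be >= 1")
  Kn <- model$n_nuc; Kd <- model$n_dom; D <- model$block_size
  withr::with_seed(seed, {
    s0 <- sample.int(Kn * Kd, 1L, prob = as.vector(model$initial))
    nuc <- integer(length_bins); dom <- integer(length_bins)
    nuc[1L] <- (s0 - 1L) %% Kn + 1L
    dom[1L] <- (s0 - 1L) %/% Kn + 1L
    if (length_bins > 1L) {
      u_dom <- runif(length_bins)
      u_nuc <- runif(length_bins)
      cum_nt <- apply(model$nuc_trans, c(1L, 3L), cumsum)  # Kn x Kn x Kd -> [k, j, d]
      cum_dt <- t(apply(model$dom_trans, 1L, cumsum))
      for (i in 2:length_bins) {
        if ((i - 1L) %% D == 0L) {
          dom[i] <- findInterval(u_dom[i], cum_dt[dom[i - 1L], ]) + 1L
        } else dom[i] <- dom[i - 1L]
        nuc[i] <- findInterval(u_nuc[i], cum_nt[, nuc[i - 1L], dom[i]]) + 1L
      }
    }
    state_path(nuc, dom, D)
  })
}

#' Sample binarized observations along a state path
#'
#' Each mark at each bin is an independent Bernoulli draw with the success
#' probability of the bin's nucleosome-level state; emissions do not depend
#' on the domain-level state.
#'
#' @param model a [dihmm_model].
#' @param path a [state_path] with states valid for `model`.
#' @param seed integer seed.
#' @param cell_type,chromosome labels for the resulting tracks.
#' @return a [binarized_tracks] object.
#' @export
sample_observations <- function(model, path, seed = 1L, cell_type = "sim",
                                chromosome = "chrS") {
  stopifnot(inherits(path, "dihmm_path"))
  if (max(path$nuc_states) > model$n_nuc)
    stopf("path states exceed the model's state count")
  L <- length(path$nuc_states); M <- length(model$mark_names)
  withr::with_seed(seed, {
    p <- model$emissions[path$nuc_states, , drop = FALSE]
    x <- matrix(as.integer(runif(L * M) < p), L, M)
    binarized_tracks(x, model$mark_names, cell_type, chromosome)
  })
}

#' Sample per-bin Poisson read counts along a state path
#'
#' Bins whose nucleosome-level state belongs to `enrichment_states` draw
#' counts from `Poisson(lambda_fg)`, all other bins from
#' `Poisson(lambda_bg)`. Exercises the binarization pipeline end to end.
#'
#' @param path a [state_path].
#' @param lambda_bg,lambda_fg background and enriched Poisson rates (> 0).
#' @param enrichment_states nucleosome-level states considered enriched.
#' @param seed integer seed.
#' @param mark_name label of the single simulated mark.
#' @param cell_type,chromosome,bin_size labels for the counts object.
#' @return a [bin_counts] object with one mark.
#' @export
sample_counts <- function(path, lambda_bg, lambda_fg, enrichment_states,
                          seed = 1L, mark_name = "mark1", cell_type = "sim",
                          chromosome = "chrS", bin_size = 200L) {
  stopifnot(inherits(path, "dihmm_path"))
  if (lambda_bg <= 0 || lambda_fg <= 0) stopf("rates must be positive")
  lam <- ifelse(path$nuc_states %in% enrichment_states, lambda_fg, lambda_bg)
  withr::with_seed(seed, {
    cnt <- matrix(rpois(length(lam), lam), ncol = 1L)
    bin_counts(cnt, mark_name, cell_type, chromosome, bin_size)
  })
}

#' Construct a well-separated fixture model
#'
#' Deterministic synthetic truth model for recovery experiments. Emission
#' rows are `0.5 +/- separation`, arranged as the binary code of the state
#' index over the marks so that all rows are mutually distinguishable.
#' Transitions are diagonal-dominant (diagonal 0.9 for a domain's preferred
#' states) and each domain-level state biases nucleosome transitions toward
#' its own preferred subset of nucleosome states (a round-robin partition),
#' which makes the domain states identifiable from the nucleosome-state
#' grammar they induce. The domain transition matrix has diagonal 0.9 with
#' the remainder spread uniformly; initial probabilities are uniform.
#'
#' @param n_nuc,n_dom,n_marks model dimensions; `n_marks` must allow
#'   `n_nuc` distinct binary codes (`2^n_marks >= n_nuc`).
#' @param block_size bins per domain block, default 10.
#' @param separation emission contrast in `(0, 0.5)`, default 0.35.
#' @param seed accepted for interface stability; the construction is
#'   deterministic.
#' @return a valid [dihmm_model].
#' @export
make_fixture_model <- function(n_nuc, n_dom, n_marks, block_size = 10L,
                               separation = 0.35, seed = NULL) {
  if (separation <= 0 || separation >= 0.5)
    stopf("separation must lie in (0, 0.5)")
  if (2^n_marks < n_nuc)
    stopf("%d marks cannot distinguish %d states", n_marks, n_nuc)
  E <- matrix(0.5 - separation, n_nuc, n_marks)
  for (k in seq_len(n_nuc))
    for (m in seq_len(n_marks))
      if ((k - 1L) %/% 2^(m - 1L) %% 2L == 1L) E[k, m] <- 0.5 + separation

  pref <- lapply(seq_len(n_dom), function(d)
    which((seq_len(n_nuc) - 1L) %% n_dom == d - 1L))
  nt <- array(0, c(n_nuc, n_nuc, n_dom))
  for (d in seq_len(n_dom)) {
    S <- pref[[d]]; notS <- setdiff(seq_len(n_nuc), S)
    for (j in seq_len(n_nuc)) {
      row <- numeric(n_nuc)
      if (j %in% S) {
        row[j] <- 0.9
        others <- setdiff(S, j)
        if (length(others)) row[others] <- 0.09 / length(others)
        else row[j] <- row[j] + 0.09
        if (length(notS)) row[notS] <- 0.01 / length(notS)
        else row[j] <- row[j] + 0.01
      } else {
        row[j] <- 0.1
        row[S] <- 0.85 / length(S)
        rest <- setdiff(notS, j)
        if (length(rest)) row[rest] <- 0.05 / length(rest)
        else row[j] <- row[j] + 0.05
      }
      nt[j, , d] <- row / sum(row)
    }
  }
  dt <- matrix(if (n_dom > 1L) 0.1 / (n_dom - 1L) else 0, n_dom, n_dom)
  diag(dt) <- if (n_dom > 1L) 0.9 else 1
  P0 <- matrix(1 / (n_nuc * n_dom), n_nuc, n_dom)
  dihmm_model(E, nt, dt, P0, block_size,
              paste0("mark", seq_len(n_marks)))
}

#' Simulate a bundle of sequences from a model
#'
#' Samples `n_tracks` independent (path, observations) pairs from the same
#' truth model, with per-sequence sub-seeds derived deterministically from
#' the bundle seed (path `i` uses `seed + 2*i - 1`, its observations
#' `seed + 2*i`), so regeneration with the same seed is bit-identical and
#' individual sequences can be re-drawn in isolation.
#'
#' @param model the truth [dihmm_model].
#' @param length_bins bins per sequence.
#' @param n_tracks number of sequences (e.g. simulated cell types).
#' @param seed integer bundle seed.
#' @param cell_types optional labels, default `sim1..simN`.
#' @param chromosome chromosome label shared by the bundle.
#' @return an object of class `dihmm_sim`: list with `truth_model`, `paths`,
#'   `tracks`, `seed` and `metadata`.
#' @export
simulate_tracks <- function(model, length_bins, n_tracks = 1L, seed = 1L,
                            cell_types = NULL, chromosome = "chrS") {
  cell_types <- cell_types %||% paste0("sim", seq_len(n_tracks))
  paths <- list(); tracks <- list()
  for (i in seq_len(n_tracks)) {
    paths[[i]] <- sample_path(model, length_bins, seed + 2L * i - 1L)
    tracks[[i]] <- sample_observations(model, paths[[i]], seed + 2L * i,
                                       cell_types[i], chromosome)
  }
  structure(list(truth_model = model, paths = paths, tracks = tracks,
                 seed = seed,
                 metadata = list(length_bins = length_bins,
                                 n_tracks = n_tracks,
                                 cell_types = cell_types,
                                 chromosome = chromosome)),
            class = "dihmm_sim")
}
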