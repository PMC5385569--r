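#' Expected sufficient statistics for one sequence
#'
#' Runs the scaled forward-backward recursions and accumulates the expected
#' counts needed by the Baum-Welch updates:
#' \describe{
#'   \item{xi_boundary}{`K_d x K_d` expected domain-transition counts,
#'     summed over block boundaries only.}
#'   \item{xi_nuc}{`K_n x K_n x K_d` expected nucleosome-transition counts
#'     `[j, k, v]`, credited to the destination domain `v` with the source
#'     domain marginalized out (away from boundaries source and destination
#'     domains coincide).}
#'   \item{gamma_first}{`K_n x K_d` joint posterior at the first bin.}
#'   \item{emit_on}{`K_n x M` expected count of (state, mark present),
#'     domain marginalized.}
#'   \item{occupancy}{expected bin count per nucleosome state.}
#' }
#' Statistics are additive over sequences; see [combine_stats()].
#'
#' @inheritParams dihmm_forward
#' @return an object of class `dihmm_stats`, which also carries the
#'   sequence log-likelihood and `n_sequences = 1`.
#' @export
accumulate_stats <- function(model, tracks) {
  check_compat(model, tracks)
  B <- emission_matrix(model, tracks)
  fw <- forward_cpp(B, model$nuc_trans, model$dom_trans, model$initial,
                    model$block_size)
  beta <- backward_cpp(B, model$nuc_trans, model$dom_trans,
                       model$block_size, fw$scales)
  st <- stats_cpp(B, fw$alpha, beta, fw$scales, model$nuc_trans,
                  model$dom_trans, model$block_size)
  g <- fw$alpha * beta                      # L x (Kn*Kd) joint posterior
  L <- nrow(g); Kn <- model$n_nuc; Kd <- model$n_dom
  gamma_nuc <- rowSums(array(g, c(L, Kn, Kd)), dims = 2L)  # domain marginal out
  gamma_nuc <- matrix(gamma_nuc, nrow = L)
  structure(list(
    xi_boundary = st$xi_boundary, xi_nuc = st$xi_nuc,
    gamma_first = matrix(g[1L, ], Kn, Kd),
    emit_on = t(gamma_nuc) %*% tracks$data,
    occupancy = colSums(gamma_nuc),
    n_sequences = 1L, log_likelihood = fw$loglik),
    class = "dihmm_stats")
}

#' Sum sufficient statistics over independent sequences
#'
#' @param ... `dihmm_stats` objects (or a single list of them).
#' @return their elementwise sum, with `n_sequences` and log-likelihoods
#'   added.
#' @export
combine_stats <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1L]], "dihmm_stats")) xs <- xs[[1L]]
  out <- xs[[1L]]
  for (s in xs[-1L]) {
    out$xi_boundary <- out$xi_boundary + s$xi_boundary
    out$xi_nuc <- out$xi_nuc + s$xi_nuc
    out$gamma_first <- out$gamma_first + s$gamma_first
    out$emit_on <- out$emit_on + s$emit_on
    out$occupancy <- out$occupancy + s$occupancy
    out$n_sequences <- out$n_sequences + s$n_sequences
    out$log_likelihood <- out$log_likelihood + s$log_likelihood
  }
  out
}

#' Re-estimate all parameter families from sufficient statistics
#'
#' The maximization step: the domain transition matrix is the row-normalized
#' boundary count matrix; each destination-domain slice of the nucleosome
#' transition tensor is its row-normalized expected count matrix; the joint
#' initial matrix is the average first-bin posterior over sequences; the
#' emission probabilities are expected mark-on counts over state occupancy.
#' A pseudocount is added to every numerator cell (with the matching total
#' added to the denominator) before normalization, so no parameter can be
#' absorbed at zero.
#'
#' @param stats a `dihmm_stats` object (possibly combined over sequences).
#' @param pseudocount non-negative additive smoothing, default `1e-6`.
#' @param block_size bins per domain block for the resulting model,
#'   default 20.
#' @param mark_names mark labels for the resulting model.
#' @return a valid [dihmm_model].
#' @export
update_parameters <- function(stats, pseudocount = 1e-6, block_size = 20L,
                              mark_names = NULL) {
  stopifnot(inherits(stats, "dihmm_stats"))
  if (pseudocount < 0) stopf("pseudocount must be non-negative")
  pc <- pseudocount
  Kn <- nrow(stats$gamma_first); Kd <- ncol(stats$gamma_first)
  M <- ncol(stats$emit_on)
  norm_rows <- function(m) (m + pc) / (rowSums(m) + ncol(m) * pc)
  nt <- array(0, c(Kn, Kn, Kd))
  for (d in seq_len(Kd))
    nt[, , d] <- norm_rows(matrix(stats$xi_nuc[, , d], Kn, Kn))
  E <- (stats$emit_on + pc) / (stats$occupancy + 2 * pc)
  P0 <- (stats$gamma_first + pc) / (stats$n_sequences + Kn * Kd * pc)
  P0 <- P0 / sum(P0)
  dihmm_model(E, nt, norm_rows(stats$xi_boundary), P0, block_size,
              mark_names %||% colnames(stats$emit_on))
}

#' Hierarchical Baum-Welch training
#'
#' Iterates expectation (forward-backward sufficient statistics, summed over
#' all sequences) and maximization ([update_parameters()]) from a starting
#' model until the log-likelihood gain of an iteration drops below `tol` or
#' `max_iter` is reached. The recorded trace is the total log-likelihood of
#' the model entering each iteration; by EM theory it is non-decreasing up
#' to the infinitesimal effect of the pseudocount and floating point.
#'
#' The stopping rule uses the absolute gain in total log-likelihood, not a
#' gain relative to the (large) magnitude of the log-likelihood itself: on
#' genome-scale sequences a relative rule is satisfied long before the
#' parameters stop moving, whereas an absolute threshold of `1e-4` is only
#' reached once successive parameter estimates agree to well below the
#' statistical precision of the data. Use `tol = -Inf` to force exactly
#' `max_iter` iterations.
#'
#' @param model a starting [dihmm_model].
#' @param tracks_list a [binarized_tracks] object or list of them, treated
#'   as statistically independent sequences sharing one parameter set.
#' @param max_iter maximum EM iterations, default 500.
#' @param tol convergence threshold on the absolute log-likelihood gain per
#'   iteration, default `1e-4`.
#' @param pseudocount additive smoothing in the M-step, default `1e-6`.
#' @param verbose log per-iteration likelihood to stderr.
#' @return list with elements `model` (the final [dihmm_model]), `trace`
#'   (log-likelihood per iteration), `iterations` and `converged`.
#' @export
baum_welch <- function(model, tracks_list, max_iter = 500L, tol = 1e-4,
                       pseudocount = 1e-6, verbose = FALSE) {
  if (inherits(tracks_list, "dihmm_tracks")) tracks_list <- list(tracks_list)
  if (max_iter < 1L) stopf("max_iter must be at least 1")
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    stats <- combine_stats(lapply(tracks_list, function(tr)
      accumulate_stats(model, tr)))
    ll <- stats$log_likelihood
    if (!is.finite(ll))
      stopf("non-finite log-likelihood at iteration %d", it)
    trace <- c(trace, ll)
    if (verbose)
      message(sprintf("iteration %3d: log-likelihood %.6f", it, ll))
    if (it > 1L && ll - trace[it - 1L] < tol) { converged <- TRUE; break }
    model <- update_parameters(stats, pseudocount, model$block_size,
                               model$mark_names)
  }
  list(model = model, trace = trace, iterations = length(trace),
       converged = converged)
}

#' Fit a hierarchical chromatin-state model
#'
#' The main fitting front-end: loads or accepts binarized tracks for one or
#' more (cell type, chromosome) sequences, initializes a model of the
#' requested size by two-scale k-centre clustering ([init_kcentre()]) and
#' trains it by hierarchical Baum-Welch ([baum_welch()]), pooling
#' information across all sequences under a single parameter set.
#'
#' @param x a [binarized_tracks] object, a list of them, or a character
#'   vector of paths (files, or a directory whose files are all in the
#'   binarized track format of [write_binarized()]).
#' @param n_nuc,n_dom numbers of nucleosome- and domain-level states; the
#'   reference configuration for human chromatin is 30 and 30.
#' @param block_size bins per domain block, default 20 (4 kb domains at
#'   200 bp bins).
#' @param max_iter,tol,pseudocount see [baum_welch()].
#' @param init optional starting [dihmm_model]; skips k-centre
#'   initialization.
#' @param seed accepted for interface stability; fitting is deterministic
#'   given the inputs.
#' @param verbose log per-iteration likelihood.
#' @return an object of class `dihmm`: a list with the fitted `model`, the
#'   log-likelihood `trace`, `iterations`, `converged`, per-sequence
#'   metadata `sequences`, the resolved `settings`, and the matched `call`.
#'   Supports `print`, `summary`, `coef`, `logLik`, `predict`, `simulate`
#'   and `plot`.
#' @seealso [predict.dihmm()], [simulate.dihmm()], [segment_genome()]
#' @export
dihmm <- function(x, n_nuc, n_dom, block_size = 20L, max_iter = 500L,
                  tol = 1e-4, pseudocount = 1e-6, init = NULL,
                  seed = NULL, verbose = FALSE) {
  if (is.character(x)) {
    files <- x
    if (length(x) == 1L && dir.exists(x))
      files <- list.files(x, full.names = TRUE)
    if (!length(files)) stopf("no binarized track files found")
    x <- lapply(files, read_binarized)
  }
  if (inherits(x, "dihmm_tracks")) x <- list(x)
  marks <- x[[1L]]$mark_names
  mismatch <- vapply(x, function(t) !identical(t$mark_names, marks),
                     logical(1L))
  if (any(mismatch))
    stopf("inconsistent mark sets across sequences: %s",
          paste(vapply(x[mismatch], function(t)
            paste0(t$cell_type, ":", t$chromosome), character(1L)),
            collapse = ", "))
  t0 <- proc.time()[["elapsed"]]
  model0 <- init %||% init_kcentre(x, n_nuc, n_dom, block_size,
                                   pseudocount = pseudocount, seed = seed)
  fit <- baum_welch(model0, x, max_iter, tol, pseudocount, verbose)
  structure(list(
    model = fit$model, trace = fit$trace, iterations = fit$iterations,
    converged = fit$converged,
    sequences = data.frame(
      cell_type = vapply(x, `[[`, character(1L), "cell_type"),
      chromosome = vapply(x, `[[`, character(1L), "chromosome"),
      n_bins = vapply(x, function(t) nrow(t$data), integer(1L))),
    settings = list(n_nuc = n_nuc, n_dom = n_dom, block_size = block_size,
                    max_iter = max_iter, tol = tol,
                    pseudocount = pseudocount, seed = seed),
    elapsed = proc.time()[["elapsed"]] - t0,
    call = match.call()), class = "dihmm")
}
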