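#' @export
print.dihmm <- function(x, ...) {
  cat("Hierarchical chromatin-state model fit\n")
  cat(sprintf("  states: %d nucleosome x %d domain; block size %d bins\n",
              x$model$n_nuc, x$model$n_dom, x$model$block_size))
  cat(sprintf("  sequences: %d (%s)\n", nrow(x$sequences),
              paste(paste0(x$sequences$cell_type, ":",
                           x$sequences$chromosome),
                    collapse = ", ")))
  cat(sprintf("  log-likelihood: %.3f after %d EM iteration(s)%s\n",
              x$trace[length(x$trace)], x$iterations,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' @export
summary.dihmm <- function(object, ...) {
  structure(list(fit = object,
                 ll_first = object$trace[1L],
                 ll_last = object$trace[length(object$trace)],
                 top_marks = apply(object$model$emissions, 1L, function(e)
                   paste(object$model$mark_names[e > 0.5], collapse = "+"))),
            class = "summary.dihmm")
}

#' @export
print.summary.dihmm <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  log-likelihood improved %.3f -> %.3f\n",
              x$ll_first, x$ll_last))
  cat("  dominant marks per nucleosome state:\n")
  for (k in seq_along(x$top_marks))
    cat(sprintf("    N%-3d %s\n", k,
                if (nzchar(x$top_marks[k])) x$top_marks[k] else "(none)"))
  invisible(x)
}

#' @export
coef.dihmm <- function(object, ...) {
  m <- object$model
  list(emissions = m$emissions, nuc_trans = m$nuc_trans,
       dom_trans = m$dom_trans, initial = m$initial)
}

#' @export
logLik.dihmm <- function(object, ...) {
  m <- object$model
  df <- m$n_nuc * length(m$mark_names) +
    m$n_dom * m$n_nuc * (m$n_nuc - 1L) +
    m$n_dom * (m$n_dom - 1L) +
    (m$n_nuc * m$n_dom - 1L)
  structure(object$trace[length(object$trace)], df = df,
            nobs = sum(object$sequences$n_bins), class = "logLik")
}

#' Decode new sequences with a fitted model
#'
#' @param object a fitted [dihmm] object.
#' @param tracks a [binarized_tracks] object or list of them.
#' @param type `"path"` for [state_path] objects, `"segments"` for stitched
#'   genomic segments at both levels, or `"posterior"` for
#'   [dihmm_posteriors] objects.
#' @param decoder `"viterbi"` or `"posterior"` (for types `"path"` and
#'   `"segments"`).
#' @param ... unused.
#' @return a named list (one element per track) of the requested objects;
#'   for `type = "segments"` a single combined data frame.
#' @export
predict.dihmm <- function(object, tracks,
                          type = c("path", "segments", "posterior"),
                          decoder = c("viterbi", "posterior"), ...) {
  type <- match.arg(type)
  decoder <- match.arg(decoder)
  if (inherits(tracks, "dihmm_tracks")) tracks <- list(tracks)
  if (type == "posterior") {
    out <- lapply(tracks, function(tr) dihmm_posteriors(object$model, tr))
    names(out) <- vapply(tracks, function(tr)
      paste(tr$cell_type, tr$chromosome, sep = "."), character(1L))
    return(out)
  }
  paths <- segment_genome(object$model, tracks, decoder)
  if (type == "path") return(paths)
  segs <- mapply(function(p, tr) rbind(
    stitch(p, "nucleosome", tr$bin_size, tr$chromosome, tr$cell_type),
    stitch(p, "domain", tr$bin_size, tr$chromosome, tr$cell_type)),
    paths, tracks, SIMPLIFY = FALSE)
  do.call(rbind, c(segs, list(make.row.names = FALSE)))
}

#' Simulate sequences from a fitted model
#'
#' @param object a fitted [dihmm] object.
#' @param nsim number of sequences.
#' @param seed integer seed.
#' @param length_bins bins per sequence; defaults to the length of the
#'   first training sequence.
#' @param ... unused.
#' @return a `dihmm_sim` bundle (see [simulate_tracks()]).
#' @export
simulate.dihmm <- function(object, nsim = 1L, seed = 1L,
                           length_bins = NULL, ...) {
  simulate_tracks(object$model,
                  length_bins %||% object$sequences$n_bins[1L],
                  n_tracks = nsim, seed = seed)
}

#' Plot the emission matrix of a fitted model
#'
#' Heatmap of Bernoulli emission probabilities (nucleosome states x marks),
#' the standard at-a-glance summary of what each state represents.
#'
#' @param x a fitted [dihmm] object or a [dihmm_model].
#' @param ... passed to [graphics::image()].
#' @export
plot.dihmm <- function(x, ...) {
  m <- if (inherits(x, "dihmm")) x$model else x
  E <- m$emissions
  graphics::image(seq_len(ncol(E)), seq_len(nrow(E)), t(E)[, nrow(E):1],
                  col = grDevices::hcl.colors(64, "Purples", rev = TRUE),
                  zlim = c(0, 1), axes = FALSE, xlab = "", ylab = "",
                  main = "Emission probabilities", ...)
  graphics::axis(1L, seq_len(ncol(E)), m$mark_names, las = 2, cex.axis = 0.8)
  graphics::axis(2L, seq_len(nrow(E)), paste0("N", nrow(E):1), las = 1,
                 cex.axis = 0.7)
  invisible(x)
}

#' @export
plot.dihmm_model <- plot.dihmm

#' @export
print.dihmm_sim <- function(x, ...) {
  cat(sprintf("Simulated bundle: %d sequence(s) of %d bins (seed %d)\n",
              x$metadata$n_tracks, x$metadata$length_bins, x$seed))
  invisible(x)
}
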