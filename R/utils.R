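`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## all permutations of 1..n as a matrix (n! rows); n is always tiny here
all_perms <- function(n) {
  if (n > 8L) stopf("exhaustive permutation matching limited to 8 states")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}

#' Match the states of one model to a reference model
#'
#' Finds the relabelling of nucleosome- and domain-level states that best
#' aligns `model` with `reference`, by exhaustive search over permutations
#' (exact Hungarian-style assignment; state counts in this package's
#' recovery experiments are small). Nucleosome states are matched first by
#' minimizing the total absolute difference between emission rows; domain
#' states are then matched by minimizing the absolute difference of the
#' domain transition matrix plus the (nucleosome-permuted) transition
#' tensors.
#'
#' @param model a [dihmm_model] to relabel.
#' @param reference the [dihmm_model] providing the target labelling.
#' @return the relabelled model, with attributes `nuc_perm` and `dom_perm`
#'   (index `i` of the output state corresponds to input state `perm[i]`).
#' @export
match_states <- function(model, reference) {
  stopifnot(inherits(model, "dihmm_model"), inherits(reference, "dihmm_model"))
  if (model$n_nuc != reference$n_nuc || model$n_dom != reference$n_dom)
    stopf("models must have identical state counts to be matched")
  Kn <- model$n_nuc; Kd <- model$n_dom

  pn_all <- all_perms(Kn)
  costs <- apply(pn_all, 1L, function(p)
    sum(abs(model$emissions[p, , drop = FALSE] - reference$emissions)))
  pn <- pn_all[which.min(costs), ]

  pd_all <- all_perms(Kd)
  costs <- apply(pd_all, 1L, function(p) {
    sum(abs(model$dom_trans[p, p, drop = FALSE] - reference$dom_trans)) +
      sum(abs(model$nuc_trans[pn, pn, p, drop = FALSE] - reference$nuc_trans))
  })
  pd <- pd_all[which.min(costs), ]

  out <- dihmm_model(
    emissions = model$emissions[pn, , drop = FALSE],
    nuc_trans = model$nuc_trans[pn, pn, pd, drop = FALSE],
    dom_trans = model$dom_trans[pd, pd, drop = FALSE],
    initial   = model$initial[pn, pd, drop = FALSE],
    block_size = model$block_size,
    mark_names = model$mark_names
  )
  attr(out, "nuc_perm") <- pn
  attr(out, "dom_perm") <- pd
  out
}
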