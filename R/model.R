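#' Construct a two-level hierarchical HMM parameter set
#'
#' Holds the four parameter families of the model:
#' \describe{
#'   \item{emissions}{`K_n x M` matrix; `emissions[k, m]` is the Bernoulli
#'     probability of observing mark `m` in nucleosome-level state `k`.
#'     Emissions are independent of the domain-level state.}
#'   \item{nuc_trans}{`K_n x K_n x K_d` array; `nuc_trans[j, k, v]` is the
#'     probability of moving from nucleosome state `j` to `k` when the
#'     destination domain-level state is `v` (nucleosome-level transitions
#'     are domain dependent).}
#'   \item{dom_trans}{`K_d x K_d` matrix of domain-level transition
#'     probabilities, applied only at block boundaries: domain-level
#'     transitions can occur only every `block_size` bins, so the minimum
#'     domain size is `block_size * bin_size`.}
#'   \item{initial}{`K_n x K_d` joint initial probability matrix over the
#'     state pair at the first bin.}
#' }
#'
#' @param emissions,nuc_trans,dom_trans,initial parameter arrays as above;
#'   `nuc_trans` may also be given as a list of `K_d` matrices (one per
#'   domain state).
#' @param block_size number of bins per domain block (>= 1), default 20.
#' @param mark_names ordered unique mark labels, one per emission column.
#' @param check validate the parameters and stop on violation (default).
#' @return an object of class `dihmm_model`.
#' @export
dihmm_model <- function(emissions, nuc_trans, dom_trans, initial,
                        block_size = 20L, mark_names = colnames(emissions),
                        check = TRUE) {
  emissions <- as.matrix(emissions)
  if (is.list(nuc_trans)) {
    mats <- lapply(nuc_trans, as.matrix)
    nuc_trans <- array(unlist(mats), dim = c(dim(mats[[1L]]), length(mats)))
  }
  dom_trans <- as.matrix(dom_trans)
  initial <- as.matrix(initial)
  mark_names <- as.character(mark_names %||% paste0("mark", seq_len(ncol(emissions))))
  colnames(emissions) <- mark_names
  m <- structure(list(
    n_nuc = nrow(emissions), n_dom = nrow(dom_trans),
    block_size = as.integer(block_size), mark_names = mark_names,
    emissions = emissions, nuc_trans = nuc_trans, dom_trans = dom_trans,
    initial = initial), class = "dihmm_model")
  if (check) {
    bad <- validate_model(m)
    if (length(bad)) stopf("invalid model:\n  %s", paste(bad, collapse = "\n  "))
  }
  m
}

#' Validate a model's probabilistic invariants
#'
#' Returns diagnostics instead of throwing: each violation names the
#' offending component and index. Checks shapes, probability ranges, row
#' stochasticity of every nucleosome transition slice and of the domain
#' transition matrix (tolerance `1e-9`), normalization of the joint initial
#' matrix, uniqueness of mark names, and `block_size >= 1`.
#'
#' @param model a [dihmm_model].
#' @param tol row-sum tolerance, default `1e-9`.
#' @return character vector of violation descriptions; empty if valid.
#' @export
validate_model <- function(model, tol = 1e-9) {
  v <- character()
  Kn <- model$n_nuc; Kd <- model$n_dom; M <- length(model$mark_names)
  if (Kn < 1L) v <- c(v, "n_nuc must be >= 1")
  if (Kd < 1L) v <- c(v, "n_dom must be >= 1")
  if (model$block_size < 1L) v <- c(v, "block_size must be >= 1")
  if (anyDuplicated(model$mark_names)) v <- c(v, "mark_names not unique")
  if (!identical(dim(model$emissions), c(Kn, M)))
    v <- c(v, "emissions: wrong shape")
  if (!identical(dim(model$nuc_trans), c(Kn, Kn, Kd)))
    v <- c(v, "nuc_trans: wrong shape")
  if (!identical(dim(model$dom_trans), c(Kd, Kd)))
    v <- c(v, "dom_trans: wrong shape")
  if (!identical(dim(model$initial), c(Kn, Kd)))
    v <- c(v, "initial: wrong shape")
  if (length(v)) return(v)

  rng <- function(x, what) {
    idx <- which(x < 0 | x > 1 | !is.finite(x), arr.ind = TRUE)
    if (length(idx))
      sprintf("%s[%s]: value outside [0, 1]", what,
              paste(idx[1L, ], collapse = ","))
  }
  v <- c(v, rng(model$emissions, "emissions"), rng(model$nuc_trans, "nuc_trans"),
         rng(model$dom_trans, "dom_trans"), rng(model$initial, "initial"))
  for (d in seq_len(Kd)) {
    rs <- rowSums(matrix(model$nuc_trans[, , d], Kn, Kn))
    bad <- which(abs(rs - 1) > tol)
    for (j in bad)
      v <- c(v, sprintf("nuc_trans[%d] row %d sums to %.12g, not 1", d, j, rs[j]))
  }
  rs <- rowSums(model$dom_trans)
  for (d in which(abs(rs - 1) > tol))
    v <- c(v, sprintf("dom_trans row %d sums to %.12g, not 1", d, rs[d]))
  s0 <- sum(model$initial)
  if (abs(s0 - 1) > tol)
    v <- c(v, sprintf("initial probabilities sum to %.12g, not 1", s0))
  v[!is.na(v) & nzchar(v)]
}

#' Composite transition probability between state pairs
#'
#' The transition from pair `(j, mu)` to `(k, nu)` decomposes into the
#' domain-level and domain-conditional nucleosome-level factors. Away from
#' block boundaries, domain-level transitions are impossible (a Kronecker
#' delta on the domain index) and the probability is
#' `[mu == nu] * nuc_trans[j, k, nu]`; at a block boundary it is
#' `dom_trans[mu, nu] * nuc_trans[j, k, nu]`. In both cases the
#' nucleosome-level factor uses the destination domain `nu`.
#'
#' @param model a [dihmm_model].
#' @param from,to state pairs `c(nucleosome, domain)` (1-based indices).
#' @param at_boundary does this step cross a block boundary?
#' @return a transition probability.
#' @export
composite_transition <- function(model, from, to, at_boundary) {
  j <- from[1L]; mu <- from[2L]; k <- to[1L]; nu <- to[2L]
  if (j < 1 || k < 1 || j > model$n_nuc || k > model$n_nuc ||
      mu < 1 || nu < 1 || mu > model$n_dom || nu > model$n_dom)
    stopf("state index out of range")
  tn <- model$nuc_trans[j, k, nu]
  if (at_boundary) model$dom_trans[mu, nu] * tn else (mu == nu) * tn
}

## Greedy farthest-point k-centre over the rows of `points` (Euclidean;
## equivalent to Hamming on 0/1 rows), with optional per-row weights: the
## next centre maximizes weight * distance to its nearest centre, the
## weighted-k-centre greedy rule.  With unit weights this is the classic
## 2-approximation.  Ties are broken toward the lexicographically smallest
## row.  Returns centre row indices.
kcentre_greedy <- function(points, k, first, w = rep(1, nrow(points))) {
  n <- nrow(points)
  ord <- do.call(order, c(lapply(seq_len(ncol(points)), function(j) points[, j])))
  rank_lex <- integer(n); rank_lex[ord] <- seq_len(n)
  centres <- first
  mind <- sqrt(colSums((t(points) - points[first, ])^2))
  while (length(centres) < k) {
    score <- w * mind
    best <- which(score == max(score))
    nxt <- best[which.min(rank_lex[best])]
    centres <- c(centres, nxt)
    mind <- pmin(mind, sqrt(colSums((t(points) - points[nxt, ])^2)))
  }
  centres
}

## hard-assign rows of `points` to nearest centre (Euclidean), ties to the
## lowest centre index
assign_nearest <- function(points, centres) {
  d2 <- vapply(seq_len(nrow(centres)), function(i)
    colSums((t(points) - centres[i, ])^2), numeric(nrow(points)))
  d2 <- matrix(d2, nrow = nrow(points))
  max.col(-d2, ties.method = "first")
}

#' Initialize a model by two-scale k-centre clustering
#'
#' Produces the starting point for Baum-Welch by clustering the data at both
#' scales. Bin-level 0/1 mark vectors are clustered into `n_nuc` centres by
#' greedy farthest-point k-centre under Hamming distance, weighted by
#' pattern frequency (the next centre maximizes frequency times distance to
#' its nearest centre; with equal weights this is the classic
#' 2-approximation, and the weighting keeps rare noise patterns from being
#' selected as centres). The first centre is the most frequent bin pattern,
#' with ties broken by lexicographic pattern order. Each bin is
#' hard-assigned to its nearest centre. Blocks of `block_size` bins are then
#' summarized by their nucleosome-state composition vectors (length `n_nuc`)
#' and clustered into `n_dom` centres by the same rule under Euclidean
#' distance, weighted by composition multiplicity, the first centre being
#' the most frequent composition vector. All four parameter families are
#' estimated from the resulting hard state assignment with an additive
#' pseudocount and row normalization.
#'
#' @param tracks a [binarized_tracks] object or a list of them (shared
#'   mark names required).
#' @param n_nuc,n_dom numbers of nucleosome- and domain-level states.
#' @param block_size bins per domain block, default 20.
#' @param pseudocount additive smoothing applied to every counted parameter,
#'   default `1e-6`.
#' @param emission_shrink weight in `[0, 1)` shrinking the hard-assignment
#'   emission estimates toward 0.5, default 0.25. Hard assignment saturates
#'   emissions at the extremes of the observed patterns; the shrinkage
#'   starts Baum-Welch in the interior of the parameter space, where the
#'   posterior E-step can still reassign bins.
#' @param seed unused in the default deterministic mode; accepted for
#'   interface stability.
#' @return a valid [dihmm_model].
#' @export
init_kcentre <- function(tracks, n_nuc, n_dom, block_size = 20L,
                         pseudocount = 1e-6, emission_shrink = 0.25,
                         seed = NULL) {
  if (inherits(tracks, "dihmm_tracks")) tracks <- list(tracks)
  marks <- tracks[[1L]]$mark_names
  for (t in tracks)
    if (!identical(t$mark_names, marks))
      stopf("all tracks must share the same mark names")
  X <- do.call(rbind, lapply(tracks, `[[`, "data"))
  M <- ncol(X)

  key <- X %*% (2^(seq_len(M) - 1L))
  tab <- table(key)
  ukey <- as.numeric(names(tab))
  U <- matrix(0L, length(ukey), M)
  for (m in seq_len(M)) U[, m] <- as.integer(ukey %/% 2^(m - 1L) %% 2)
  if (nrow(U) < n_nuc)
    stopf("only %d distinct bin patterns; cannot form %d nucleosome states",
          nrow(U), n_nuc)
  ## most frequent pattern; lexicographic (low key = low-order marks 0) ties
  lex <- order(-as.vector(tab), ukey)
  first <- lex[1L]
  cent <- kcentre_greedy(U, n_nuc, first, w = as.vector(tab))
  pat_assign <- assign_nearest(U, U[cent, , drop = FALSE])
  nuc_paths <- lapply(tracks, function(t) {
    k <- t$data %*% (2^(seq_len(M) - 1L))
    pat_assign[match(k, ukey)]
  })

  comp_of <- function(path) {
    nb <- ceiling(length(path) / block_size)
    blk <- rep(seq_len(nb), each = block_size, length.out = length(path))
    t(vapply(split(path, blk), function(p) tabulate(p, n_nuc) / length(p),
             numeric(n_nuc)))
  }
  comps <- lapply(nuc_paths, comp_of)
  C <- do.call(rbind, comps)
  if (nrow(C) < n_dom)
    stopf("only %d blocks; cannot form %d domain states", nrow(C), n_dom)
  ckey <- apply(C, 1L, paste, collapse = ",")
  urows <- !duplicated(ckey)
  UC <- C[urows, , drop = FALSE]
  cw <- as.vector(table(ckey)[ckey[urows]])
  ord <- do.call(order, c(lapply(seq_len(ncol(UC)), function(j) UC[, j])))
  rank_lex <- integer(nrow(UC)); rank_lex[ord] <- seq_len(nrow(UC))
  cand <- which(cw == max(cw))
  firstC <- cand[which.min(rank_lex[cand])]
  centC <- kcentre_greedy(UC, min(n_dom, nrow(UC)), firstC, w = cw)
  blk_assign <- assign_nearest(C, UC[centC, , drop = FALSE])

  ## expand block assignment to per-bin domain paths
  dom_paths <- list(); off <- 0L
  for (s in seq_along(tracks)) {
    nb <- nrow(comps[[s]])
    L <- length(nuc_paths[[s]])
    dom_paths[[s]] <- rep(blk_assign[off + seq_len(nb)],
                          each = block_size, length.out = L)
    off <- off + nb
  }

  estimate_from_paths(nuc_paths, dom_paths, tracks, n_nuc, n_dom,
                      block_size, marks, pseudocount, emission_shrink)
}

## Counted MLE with additive pseudocount, shared by init_kcentre and tests.
## Hard assignment saturates the emission estimates at the extremes of the
## data (a bin assigned to a centre contributes its marks wholesale), which
## can place EM at a self-consistent saturated fixed point; shrinking the
## initial emission rows toward the uninformative rate 0.5 starts EM in the
## interior of the parameter space instead.
estimate_from_paths <- function(nuc_paths, dom_paths, tracks, n_nuc, n_dom,
                                block_size, marks, pseudocount = 1e-6,
                                emission_shrink = 0.25) {
  M <- length(marks)
  emit_on <- matrix(0, n_nuc, M); occ <- numeric(n_nuc)
  nt_cnt <- array(0, c(n_nuc, n_nuc, n_dom))
  dt_cnt <- matrix(0, n_dom, n_dom)
  p0_cnt <- matrix(0, n_nuc, n_dom)
  for (s in seq_along(tracks)) {
    np <- nuc_paths[[s]]; dp <- dom_paths[[s]]; X <- tracks[[s]]$data
    L <- length(np)
    occ <- occ + tabulate(np, n_nuc)
    for (k in seq_len(n_nuc)) {
      sel <- np == k
      if (any(sel)) emit_on[k, ] <- emit_on[k, ] + colSums(X[sel, , drop = FALSE])
    }
    p0_cnt[np[1L], dp[1L]] <- p0_cnt[np[1L], dp[1L]] + 1
    if (L > 1L) {
      i <- seq_len(L - 1L)
      li <- np[i] + (np[i + 1L] - 1L) * n_nuc + (dp[i + 1L] - 1L) * n_nuc^2
      nt_cnt <- nt_cnt + array(tabulate(li, n_nuc^2 * n_dom),
                               c(n_nuc, n_nuc, n_dom))
      bnd <- i[i %% block_size == 0L]
      if (length(bnd)) {
        lb <- dp[bnd] + (dp[bnd + 1L] - 1L) * n_dom
        dt_cnt <- dt_cnt + matrix(tabulate(lb, n_dom^2), n_dom, n_dom)
      }
    }
  }
  norm_rows <- function(m) (m + pseudocount) /
    (rowSums(m) + ncol(m) * pseudocount)
  nt <- array(0, c(n_nuc, n_nuc, n_dom))
  for (d in seq_len(n_dom)) nt[, , d] <- norm_rows(nt_cnt[, , d])
  E <- (emit_on + pseudocount) / (occ + 2 * pseudocount)
  E <- (1 - emission_shrink) * E + emission_shrink * 0.5
  P0 <- (p0_cnt + pseudocount) / (sum(p0_cnt) + n_nuc * n_dom * pseudocount)
  dihmm_model(E, nt, norm_rows(dt_cnt), P0, block_size, marks)
}

#' Save / load a model as structured JSON text
#'
#' Human-readable serialization at full floating-point precision, with an
#' explicit format version and dimensions; `load_model(save_model(m))`
#' reproduces every parameter exactly.
#'
#' @param model a [dihmm_model].
#' @param file destination / source path.
#' @return `load_model` returns the model; `save_model` returns `file`
#'   invisibly.
#' @export
save_model <- function(model, file) {
  stopifnot(inherits(model, "dihmm_model"))
  payload <- list(
    format = "dihmm-model", version = 1L,
    n_nuc = model$n_nuc, n_dom = model$n_dom,
    block_size = model$block_size, mark_names = model$mark_names,
    emissions = model$emissions,
    nuc_trans = lapply(seq_len(model$n_dom), function(d) model$nuc_trans[, , d]),
    dom_trans = model$dom_trans, initial = model$initial)
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(file)
}

#' @rdname save_model
#' @export
load_model <- function(file) {
  p <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!identical(p$format, "dihmm-model"))
    stopf("not a dihmm model file (format tag '%s')", p$format %||% "missing")
  if (!identical(as.integer(p$version), 1L))
    stopf("unsupported model format version %s", p$version)
  Kn <- as.integer(p$n_nuc); Kd <- as.integer(p$n_dom)
  M <- length(p$mark_names)
  chk <- function(x, d, what)
    if (!identical(dim(as.matrix(x)), as.integer(d)))
      stopf("%s has shape %s, expected %s", what,
            paste(dim(as.matrix(x)), collapse = "x"),
            paste(d, collapse = "x"))
  chk(p$emissions, c(Kn, M), "emissions")
  chk(p$dom_trans, c(Kd, Kd), "dom_trans")
  chk(p$initial, c(Kn, Kd), "initial")
  nt <- array(0, c(Kn, Kn, Kd))
  raw_nt <- p$nuc_trans
  if (is.array(raw_nt) && length(dim(raw_nt)) == 3L) {
    # jsonlite simplifies the per-domain list of matrices to [slice, row, col]
    if (!identical(dim(raw_nt), as.integer(c(Kd, Kn, Kn))))
      stopf("nuc_trans has shape %s, expected %dx%dx%d",
            paste(dim(raw_nt), collapse = "x"), Kd, Kn, Kn)
    nt <- aperm(raw_nt, c(2L, 3L, 1L))
  } else if (is.list(raw_nt) && length(raw_nt) == Kd) {
    for (d in seq_len(Kd)) {
      chk(raw_nt[[d]], c(Kn, Kn), sprintf("nuc_trans[%d]", d))
      nt[, , d] <- as.matrix(raw_nt[[d]])
    }
  } else stopf("nuc_trans has shape inconsistent with %d domain states", Kd)
  dihmm_model(as.matrix(p$emissions), nt, as.matrix(p$dom_trans),
              as.matrix(p$initial), as.integer(p$block_size), p$mark_names)
}

#' @export
print.dihmm_model <- function(x, ...) {
  cat(sprintf(paste0("Hierarchical chromatin-state model: %d nucleosome x ",
                     "%d domain states\n"), x$n_nuc, x$n_dom))
  cat(sprintf("  %d marks (%s)\n", length(x$mark_names),
              paste(x$mark_names, collapse = ", ")))
  cat(sprintf("  block size: %d bins (minimum domain size %d bins)\n",
              x$block_size, x$block_size))
  invisible(x)
}
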