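## Per-chromosome state-per-bin expansion of a tiling segmentation.
## Returns a list of integer vectors (0 = unannotated), one per chromosome.
segments_to_bins <- function(segments, bin_size) {
  split_segs <- split(segments, segments$chromosome)
  lapply(split_segs, function(s) {
    s <- s[order(s$start), , drop = FALSE]
    n_bins <- as.integer(ceiling(max(s$end) / bin_size))
    out <- integer(n_bins)
    first <- s$start %/% bin_size
    last <- ceiling(s$end / bin_size) - 1L
    for (i in seq_len(nrow(s)))
      out[(first[i] + 1L):(last[i] + 1L)] <- s$state[i]
    out
  })
}

## bins (0-based indices per chromosome) overlapped by any interval
intervals_to_bins <- function(intervals, n_bins_by_chrom, bin_size) {
  masks <- lapply(n_bins_by_chrom, function(n) logical(n))
  for (i in seq_len(nrow(intervals))) {
    ch <- as.character(intervals$chromosome[i])
    if (!ch %in% names(masks)) next
    a <- max(0L, intervals$start[i] %/% bin_size)
    b <- min(length(masks[[ch]]) - 1L, ceiling(intervals$end[i] / bin_size) - 1L)
    if (b >= a) masks[[ch]][(a + 1L):(b + 1L)] <- TRUE
  }
  masks
}

#' Fold enrichment of states in an annotation
#'
#' For each state the enrichment is `(m/n) / (M/N)`: `m` bins of the state
#' overlapping the annotation, `n` annotated bins in total, `M` bins
#' occupied by the state and `N` bins in the genome, all on a fixed bin
#' grid (`bin_size` should be the bin width at the segmentation's level,
#' e.g. 200 bp for nucleosome-level and 4000 bp for domain-level
#' segments). A two-sided Fisher exact p-value on the corresponding 2x2
#' table accompanies each estimate. Undefined ratios (`n == 0` or
#' `M == 0`) are reported as `NA` with a note rather than silently.
#'
#' @param segments tiling segment data frame of one annotation level.
#' @param annotation interval data frame with columns `chromosome`,
#'   `start`, `end`.
#' @param bin_size grid width in bp.
#' @param p_adjust apply Benjamini-Hochberg correction across states.
#' @return data frame with columns `state`, `m`, `n`, `M`, `N`,
#'   `enrichment`, `p_value` and `note`.
#' @export
fold_enrichment <- function(segments, annotation, bin_size = 200L,
                            p_adjust = FALSE) {
  bins <- segments_to_bins(segments, bin_size)
  anno <- intervals_to_bins(annotation, lapply(bins, length), bin_size)
  state <- unlist(bins, use.names = FALSE)
  inanno <- unlist(anno[names(bins)], use.names = FALSE)
  keep <- state > 0L
  state <- state[keep]; inanno <- inanno[keep]
  N <- length(state); n <- sum(inanno)
  states <- sort(unique(state))
  res <- lapply(states, function(k) {
    M <- sum(state == k)
    m <- sum(state == k & inanno)
    if (n == 0L || M == 0L)
      return(data.frame(state = k, m = m, n = n, M = M, N = N,
                        enrichment = NA_real_, p_value = NA_real_,
                        note = "undefined: empty annotation or state"))
    fe <- (m / n) / (M / N)
    p <- fisher.test(matrix(c(m, n - m, M - m, N - n - M + m), 2L))$p.value
    data.frame(state = k, m = m, n = n, M = M, N = N, enrichment = fe,
               p_value = p, note = "")
  })
  out <- do.call(rbind, res)
  if (p_adjust) out$p_value <- stats::p.adjust(out$p_value, "BH")
  out
}

#' Enrichment of domain transitions in an interval set
#'
#' Compares the rate of domain-state transitions at block boundaries inside
#' a set of intervals (for example TAD boundaries or loop anchors from
#' Hi-C) with the genome-wide rate: fold change = (fraction of
#' interval-overlapping block boundaries that are domain transitions) /
#' (genome-wide fraction of block boundaries that are domain transitions),
#' with a two-sided Fisher exact test on the underlying 2x2 table.
#'
#' @param domain_segments tiling domain-level segments (possibly several
#'   chromosomes).
#' @param intervals interval data frame (`chromosome`, `start`, `end`).
#' @param bin_size bin width in bp, default 200.
#' @param block_size bins per domain block, default 20.
#' @return list with `fold_change`, `p_value`, the 2x2 `counts` matrix and
#'   a `note` (non-empty when undefined).
#' @export
boundary_enrichment <- function(domain_segments, intervals, bin_size = 200L,
                                block_size = 20L) {
  step <- bin_size * block_size
  trans <- logical(0); inside <- logical(0)
  for (ch in unique(domain_segments$chromosome)) {
    s <- domain_segments[domain_segments$chromosome == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    L_bp <- max(s$end)
    pos <- seq(step, L_bp - 1L, by = step)
    if (!length(pos)) next
    seg_at <- findInterval(pos, s$start)
    seg_before <- findInterval(pos - 1L, s$start)
    trans <- c(trans, s$state[seg_at] != s$state[seg_before])
    iv <- intervals[intervals$chromosome == ch, , drop = FALSE]
    ins <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(iv)))
      ins <- ins | (pos >= iv$start[i] & pos < iv$end[i])
    inside <- c(inside, ins)
  }
  if (!any(inside) || !any(trans))
    return(list(fold_change = NA_real_, p_value = NA_real_,
                counts = matrix(0, 2L, 2L),
                note = "undefined: no block boundaries in intervals or no transitions"))
  fold <- mean(trans[inside]) / mean(trans)
  cnt <- matrix(c(sum(trans & inside), sum(!trans & inside),
                  sum(trans & !inside), sum(!trans & !inside)), 2L)
  list(fold_change = fold, p_value = fisher.test(cnt)$p.value, counts = cnt,
       note = "")
}

#' Strand-aware state profiles around transcription start sites
#'
#' For each offset bin in a window around the TSS, the raw profile is the
#' fraction of TSSs annotated with each state at that offset; minus-strand
#' genes are flipped so that negative offsets are always upstream of
#' transcription. Each state's profile is then min-max normalized to
#' `[0, 1]`; states whose raw profile is flat are flagged instead of being
#' divided by zero.
#'
#' @param segments tiling segment data frame of one annotation level.
#' @param tss data frame with columns `chromosome`, `pos`, `strand`.
#' @param window_bp half-window size in bp (profile spans `+/- window_bp`);
#'   must be a multiple of `step_bp`.
#' @param step_bp offset bin width in bp, default 200.
#' @param bin_size segmentation grid width in bp, default 200.
#' @return list with `offsets` (bin start offsets), `raw` and `normalized`
#'   (state x offset matrices) and `flat` (logical per state).
#' @export
tss_enrichment_profile <- function(segments, tss, window_bp = 2000L,
                                   step_bp = 200L, bin_size = 200L) {
  if (nrow(tss) == 0L) stopf("no TSS provided")
  if (window_bp %% step_bp != 0L)
    stopf("window_bp must be a multiple of step_bp")
  bins <- segments_to_bins(segments, bin_size)
  offsets <- seq(-window_bp, window_bp - step_bp, by = step_bp)
  states <- sort(unique(segments$state))
  raw <- matrix(0, length(states), length(offsets),
                dimnames = list(states, offsets))
  denom <- numeric(length(offsets))
  for (i in seq_len(nrow(tss))) {
    ch <- as.character(tss$chromosome[i])
    if (!ch %in% names(bins)) next
    v <- bins[[ch]]
    r <- offsets + step_bp %/% 2L
    g <- if (identical(tss$strand[i], "-")) tss$pos[i] - r else tss$pos[i] + r
    b <- g %/% bin_size + 1L
    ok <- b >= 1L & b <= length(v)
    st <- rep(NA_integer_, length(offsets))
    st[ok] <- v[b[ok]]
    hit <- !is.na(st) & st > 0L
    denom[hit] <- denom[hit] + 1
    idx <- match(st[hit], states)
    for (q in seq_along(idx))
      raw[idx[q], which(hit)[q]] <- raw[idx[q], which(hit)[q]] + 1
  }
  raw <- sweep(raw, 2L, pmax(denom, 1), "/")
  rng <- apply(raw, 1L, function(x) diff(range(x)))
  flat <- rng == 0
  normalized <- raw
  if (any(!flat))
    normalized[!flat, ] <- t(apply(raw[!flat, , drop = FALSE], 1L,
                                   function(x) (x - min(x)) / diff(range(x))))
  normalized[flat, ] <- 0
  list(offsets = offsets, raw = raw, normalized = normalized,
       flat = setNames(flat, states))
}

#' Mean expression z-score per state and cell line
#'
#' Gene expression values are converted per gene into z-scores across cell
#' lines (population standard deviation); genes with constant expression
#' are excluded and counted. A state maps to a gene if any of its segments
#' overlaps the window `[TSS - flank, TSS + flank]` (inclusive at bp
#' resolution). For each state and cell line the z-scores of all mapped
#' genes are averaged.
#'
#' @param segments tiling segment data frame of one annotation level.
#' @param genes data frame with columns `gene`, `chromosome`, `tss`,
#'   `strand`, plus one numeric expression column per cell line.
#' @param expr_cols names of the expression columns (>= 2); defaults to all
#'   numeric columns not named above.
#' @param flank TSS window half-width in bp, default 2000.
#' @return list with `z` (state x cell line matrix of mean z-scores),
#'   `n_genes` (genes mapped per state) and `n_excluded` (constant-
#'   expression genes dropped).
#' @export
expression_by_state <- function(segments, genes, expr_cols = NULL,
                                flank = 2000L) {
  expr_cols <- expr_cols %||%
    setdiff(names(genes)[vapply(genes, is.numeric, logical(1L))],
            c("tss", "start", "end", "pos"))
  if (length(expr_cols) < 2L)
    stopf("z-scores require expression in at least 2 cell lines")
  ex <- as.matrix(genes[, expr_cols, drop = FALSE])
  mu <- rowMeans(ex)
  sd_pop <- sqrt(rowMeans((ex - mu)^2))
  keep <- sd_pop > 0
  z <- (ex[keep, , drop = FALSE] - mu[keep]) / sd_pop[keep]
  genes_k <- genes[keep, , drop = FALSE]
  states <- sort(unique(segments$state))
  zbar <- matrix(NA_real_, length(states), length(expr_cols),
                 dimnames = list(states, expr_cols))
  n_genes <- setNames(integer(length(states)), states)
  for (si in seq_along(states)) {
    segk <- segments[segments$state == states[si], , drop = FALSE]
    mapped <- logical(nrow(genes_k))
    for (gi in seq_len(nrow(genes_k))) {
      s <- segk[segk$chromosome == genes_k$chromosome[gi], , drop = FALSE]
      mapped[gi] <- any(s$start <= genes_k$tss[gi] + flank &
                          s$end > genes_k$tss[gi] - flank)
    }
    n_genes[si] <- sum(mapped)
    if (any(mapped))
      zbar[si, ] <- colMeans(z[mapped, , drop = FALSE])
  }
  list(z = zbar, n_genes = n_genes, n_excluded = sum(!keep))
}

#' Genome-wide state-frequency vectors
#'
#' Represents a segmentation as one numeric vector per state: the fraction
#' of each fixed window (default 4 kb, tiling each chromosome from 0)
#' covered by the state. These vectors are the inputs of
#' [similarity_score()].
#'
#' @param segments tiling segment data frame of one annotation level.
#' @param window_size window width in bp, default 4000.
#' @return an object of class `dihmm_freq`: list with `window_size`,
#'   `states`, `vectors` (state x window matrix) and `windows` (data frame
#'   of window coordinates).
#' @export
state_frequency_vectors <- function(segments, window_size = 4000L) {
  states <- sort(unique(segments$state))
  chroms <- unique(segments$chromosome)
  vec_list <- list(); win_list <- list()
  for (ch in chroms) {
    s <- segments[segments$chromosome == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    n_win <- as.integer(ceiling(max(s$end) / window_size))
    v <- matrix(0, length(states), n_win)
    for (i in seq_len(nrow(s))) {
      a <- s$start[i]; b <- s$end[i]
      k <- match(s$state[i], states)
      w1 <- a %/% window_size; w2 <- (b - 1L) %/% window_size
      if (w1 == w2) {
        v[k, w1 + 1L] <- v[k, w1 + 1L] + (b - a)
      } else {
        v[k, w1 + 1L] <- v[k, w1 + 1L] + ((w1 + 1L) * window_size - a)
        v[k, w2 + 1L] <- v[k, w2 + 1L] + (b - w2 * window_size)
        if (w2 > w1 + 1L)
          v[k, (w1 + 2L):w2] <- v[k, (w1 + 2L):w2] + window_size
      }
    }
    vec_list[[ch]] <- v / window_size
    win_list[[ch]] <- data.frame(chromosome = ch,
                                 start = (seq_len(n_win) - 1L) * window_size)
  }
  structure(list(window_size = as.integer(window_size), states = states,
                 vectors = do.call(cbind, vec_list),
                 windows = do.call(rbind, win_list)),
            class = "dihmm_freq")
}

#' Gini concentration index of a probability vector
#'
#' Relative mean absolute difference: `sum_ab |p_a - p_b| / (2 K^2 pbar)`
#' with `pbar = 1/K` for a probability vector of length `K`. A uniform
#' vector scores 0; a point mass scores `(K - 1)/K`. Used here to measure
#' how concentrated (specific) a conditional state-mapping distribution is.
#'
#' @param p non-negative vector summing to 1 (tolerance `1e-9`).
#' @return the Gini index, in `[0, (K-1)/K]`.
#' @export
gini_index <- function(p) {
  if (length(p) == 0L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stopf("p must be a non-negative vector summing to 1")
  K <- length(p)
  sum(abs(outer(p, p, "-"))) / (2 * K^2 * mean(p))
}

## dominant state index per window; NA where the window is unannotated
dominant_states <- function(freq) {
  v <- freq$vectors
  dom <- max.col(t(v), ties.method = "first")
  dom[colSums(v) == 0] <- NA_integer_
  dom
}

similarity_direction <- function(X, Y) {
  domX <- dominant_states(X); domY <- dominant_states(Y)
  KY <- nrow(Y$vectors)
  if (KY < 2L) stopf("similarity requires at least 2 states per annotation")
  ysd <- apply(Y$vectors, 1L, sd)
  Dx <- sort(unique(domX[!is.na(domX)]))
  terms <- vapply(Dx, function(k) {
    xk <- X$vectors[k, ]
    if (sd(xk) == 0) return(0)           # degenerate constant vector
    pcc <- rep(NA_real_, KY)
    pcc[ysd > 0] <- apply(Y$vectors[ysd > 0, , drop = FALSE], 1L, cor, xk)
    best <- if (all(is.na(pcc))) 0 else max(pcc, na.rm = TRUE)
    w <- which(domX == k & !is.na(domY))
    if (!length(w)) return(0)
    cond <- tabulate(domY[w], nbins = KY) / length(w)
    best * gini_index(cond) * KY / (KY - 1)
  }, numeric(1L))
  mean(terms)
}

#' Similarity score between two segmentations
#'
#' Composite agreement measure between two chromatin-state annotations on
#' the same window grid, combining (1) the similarity of the closest
#' matching states -- for each dominant state of one annotation, the best
#' Pearson correlation between its frequency vector and any state vector of
#' the other -- and (2) the specificity of the state mapping -- the Gini
#' index of the other annotation's dominant states over the windows where
#' the state dominates, normalized by `(K-1)/K` so a point-mass mapping
#' scores 1. Each direction averages these products over its dominant
#' states; the returned score is the mean of both directions. Identical
#' segmentations (up to state relabelling) score 1; independent
#' segmentations score near 0. States with constant (degenerate) frequency
#' vectors contribute 0 and windows without annotation are ignored.
#'
#' @param X,Y `dihmm_freq` objects on identical window grids.
#' @return a number, with attributes `forward` and `reverse` (the two
#'   directional scores).
#' @export
similarity_score <- function(X, Y) {
  stopifnot(inherits(X, "dihmm_freq"), inherits(Y, "dihmm_freq"))
  if (X$window_size != Y$window_size ||
      ncol(X$vectors) != ncol(Y$vectors))
    stopf("segmentations are on different window grids")
  f <- similarity_direction(X, Y)
  r <- similarity_direction(Y, X)
  structure((f + r) / 2, forward = f, reverse = r)
}
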