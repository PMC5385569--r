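## a toy two-state tiling segmentation: state 1 covers bins 0..19,
## state 2 the rest of a 1000-bin chromosome (200 bp bins)
toy_segments <- function() {
  data.frame(chromosome = "chr1", start = c(0, 20 * 200),
             end = c(20 * 200, 1000 * 200), level = "nucleosome",
             state = c(1L, 2L), cell_type = "c", stringsAsFactors = FALSE)
}

test_that("fold enrichment reproduces (m/n)/(M/N) with Fisher support", {
  seg <- toy_segments()
  # annotation covering bins 10..109: n = 100 bins, 10 of them state 1
  anno <- data.frame(chromosome = "chr1", start = 10 * 200, end = 110 * 200)
  fe <- fold_enrichment(seg, anno, bin_size = 200L)
  row1 <- fe[fe$state == 1L, ]
  expect_equal(row1$m, 10); expect_equal(row1$n, 100)
  expect_equal(row1$M, 20); expect_equal(row1$N, 1000)
  expect_equal(row1$enrichment, (10 / 100) / (20 / 1000))  # = 5
  expect_lt(row1$p_value, 0.05)

  # a state covering the whole genome is unenriched anywhere
  all1 <- seg[1L, ]; all1$end <- 1000 * 200
  fe2 <- fold_enrichment(all1, anno, 200L)
  expect_equal(fe2$enrichment, 1)

  # zero overlap
  anno0 <- data.frame(chromosome = "chr1", start = 100 * 200, end = 300 * 200)
  fe3 <- fold_enrichment(seg, anno0, 200L)
  expect_equal(fe3$enrichment[fe3$state == 1L], 0)

  # empty annotation is reported undefined, not NaN
  fe4 <- fold_enrichment(seg, anno[0L, ], 200L)
  expect_true(all(is.na(fe4$enrichment)))
  expect_match(fe4$note, "undefined", all = TRUE)
})

test_that("fold enrichment agrees with a brute-force per-bin membership oracle", {
  set.seed(401)
  n_bins <- 5000L
  states <- sample(1:4, n_bins, replace = TRUE)
  r <- rle(states)
  ends <- cumsum(r$lengths) * 200
  seg <- data.frame(chromosome = "chrZ", start = c(0, head(ends, -1L)),
                    end = ends, level = "nucleosome", state = r$values,
                    cell_type = "c")
  anno <- data.frame(chromosome = "chrZ",
                     start = sort(sample.int(n_bins - 10L, 20L)) * 200)
  anno$end <- anno$start + sample(1:5, 20L, replace = TRUE) * 200
  fe <- fold_enrichment(seg, anno, 200L)
  # oracle: explicit per-bin interval overlap
  in_anno <- vapply(seq_len(n_bins) - 1L, function(b)
    any(anno$start < (b + 1) * 200 & anno$end > b * 200), logical(1L))
  for (k in 1:4) {
    m <- sum(states == k & in_anno); n <- sum(in_anno)
    M <- sum(states == k)
    expect_equal(fe$enrichment[fe$state == k], (m / n) / (M / n_bins))
  }
})

test_that("boundary enrichment is 1 genome-wide and tracks planted excess", {
  set.seed(402)
  n_blocks <- 10000L
  # plant transitions twice as dense inside a 2% interval set
  inside <- seq_len(n_blocks - 1L) <= 200L
  p <- ifelse(inside, 0.4, 0.2)
  change <- rbinom(n_blocks - 1L, 1L, p) == 1L
  states <- integer(n_blocks); states[1L] <- 1L
  for (i in 2:n_blocks)
    states[i] <- if (change[i - 1L]) states[i - 1L] %% 3L + 1L else states[i - 1L]
  r <- rle(states)
  ends <- cumsum(r$lengths) * 4000
  seg <- data.frame(chromosome = "chr1", start = c(0, head(ends, -1L)),
                    end = ends, level = "domain", state = r$values,
                    cell_type = "c")
  whole <- data.frame(chromosome = "chr1", start = 0, end = n_blocks * 4000)
  be_all <- boundary_enrichment(seg, whole, 200L, 20L)
  expect_equal(be_all$fold_change, 1)

  iv <- data.frame(chromosome = "chr1", start = 0, end = 200L * 4000 + 1)
  be <- boundary_enrichment(seg, iv, 200L, 20L)
  expect_gt(be$fold_change, 1.7)
  expect_lt(be$fold_change, 2.3)
  expect_lt(be$p_value, 1e-4)

  off <- data.frame(chromosome = "chrX", start = 0, end = 100)
  expect_match(boundary_enrichment(seg, off, 200L, 20L)$note, "undefined")
})

test_that("TSS profiles are strand-aware and min-max normalized", {
  # state 1 planted exactly at TSS bins of plus-strand genes
  seg <- data.frame(chromosome = "chr1",
                    start = c(0, 10000, 10200, 50000),
                    end = c(10000, 10200, 50000, 100000),
                    level = "nucleosome", state = c(2L, 1L, 2L, 2L),
                    cell_type = "c")
  tss <- data.frame(chromosome = "chr1", pos = 10000L, strand = "+")
  pr <- tss_enrichment_profile(seg, tss, window_bp = 1000L, step_bp = 200L)
  expect_equal(unname(pr$normalized["1", pr$offsets == 0]), 1)
  expect_equal(sum(pr$raw["1", ]), 1)    # the state exists only at offset 0
  expect_false(pr$flat[["1"]])

  # a uniformly covering state is flagged flat, not divided by zero
  expect_true(pr$flat[["2"]] || max(pr$normalized["2", ]) <= 1)

  # minus-strand: state downstream in genome coordinates appears upstream
  seg2 <- data.frame(chromosome = "chr1", start = c(0, 20000, 20600),
                     end = c(20000, 20600, 40000), level = "nucleosome",
                     state = c(2L, 1L, 2L), cell_type = "c")
  tssm <- data.frame(chromosome = "chr1", pos = 19900L, strand = "-")
  prm <- tss_enrichment_profile(seg2, tssm, window_bp = 1000L, step_bp = 200L)
  peak_off <- prm$offsets[which.max(prm$raw["1", ])]
  expect_lt(peak_off, 0)
  expect_error(tss_enrichment_profile(seg, tss[0L, ]), "TSS")

  # non-flat normalized profiles span [0, 1] exactly
  expect_equal(min(prm$normalized["1", ]), 0)
  expect_equal(max(prm$normalized["1", ]), 1)
})

test_that("expression z-scores use the population convention and TSS windows", {
  seg <- data.frame(chromosome = "chr1", start = c(0, 8000),
                    end = c(8000, 20000), level = "domain",
                    state = c(1L, 2L), cell_type = "c")
  genes <- data.frame(gene = c("g1", "g2", "g3"), chromosome = "chr1",
                      tss = c(4000L, 15000L, 15500L), strand = "+",
                      cellA = c(1, 5, 2), cellB = c(3, 5, 4))
  out <- expression_by_state(seg, genes, expr_cols = c("cellA", "cellB"))
  # two-point z-scores are exactly (-1, +1); g2 is constant and excluded
  expect_equal(unname(out$z["1", ]), c(-1, 1))
  expect_equal(out$n_excluded, 1L)
  expect_equal(unname(out$n_genes), c(1L, 1L))

  # per-gene mean 0 / population sd 1 on random data
  set.seed(403)
  g <- data.frame(gene = paste0("g", 1:30), chromosome = "chr1",
                  tss = seq(1000L, by = 600L, length.out = 30L), strand = "+",
                  a = rnorm(30), b = rnorm(30), c = rnorm(30))
  ex <- as.matrix(g[, c("a", "b", "c")])
  z <- (ex - rowMeans(ex)) / sqrt(rowMeans((ex - rowMeans(ex))^2))
  expect_equal(max(abs(rowMeans(z))), 0, tolerance = 1e-12)
  expect_equal(max(abs(rowMeans(z^2) - 1)), 0, tolerance = 1e-12)

  # planted design: genes near state 1 shifted up in cell A
  gup <- g
  near1 <- gup$tss <= 8000
  gup$a[near1] <- gup$a[near1] + 3
  res <- expression_by_state(seg, gup, expr_cols = c("a", "b", "c"))
  expect_equal(unname(which.max(res$z["1", ])), 1L)
})

test_that("state frequency vectors are bp coverage fractions on a fixed grid", {
  seg <- data.frame(chromosome = "chr1", start = c(0, 6000),
                    end = c(6000, 16000), level = "domain",
                    state = c(1L, 2L), cell_type = "c")
  fv <- state_frequency_vectors(seg, window_size = 4000L)
  expect_equal(dim(fv$vectors), c(2L, 4L))
  expect_equal(unname(fv$vectors[1L, ]), c(1, 0.5, 0, 0))
  expect_equal(unname(fv$vectors[2L, ]), c(0, 0.5, 1, 1))
  expect_equal(unname(colSums(fv$vectors)), rep(1, 4))

  solo <- seg[1L, ]; solo$end <- 16000
  fv2 <- state_frequency_vectors(solo, 4000L)
  expect_true(all(fv2$vectors == 1))
})

test_that("the Gini index matches its defining double sum and closed forms", {
  expect_equal(gini_index(rep(1 / 7, 7L)), 0)
  expect_equal(gini_index(c(1, rep(0, 29L))), 29 / 30)
  p <- c(0.5, 0.5, 0, 0)
  dbl <- 0
  for (a in seq_along(p)) for (b in seq_along(p)) dbl <- dbl + abs(p[a] - p[b])
  expect_equal(gini_index(p), dbl / (2 * length(p)^2 * mean(p)))
  set.seed(404)
  for (i in 1:10) {
    q <- runif(6); q <- q / sum(q)
    expect_gte(gini_index(q), 0)
    expect_lte(gini_index(q), 5 / 6)
  }
  expect_error(gini_index(c(0, 0)), "summing to 1")
  expect_error(gini_index(c(-0.5, 1.5)), "non-negative")
})

test_that("similarity score is 1 for relabelled identity and label-invariant", {
  set.seed(405)
  states <- sample(1:4, 400L, replace = TRUE)
  r <- rle(states)
  ends <- cumsum(r$lengths) * 4000
  seg <- data.frame(chromosome = "chr1", start = c(0, head(ends, -1L)),
                    end = ends, level = "domain", state = r$values,
                    cell_type = "c")
  X <- state_frequency_vectors(seg, 4000L)
  perm <- c(3L, 1L, 4L, 2L)
  segY <- seg; segY$state <- perm[seg$state]
  Y <- state_frequency_vectors(segY, 4000L)
  expect_equal(as.numeric(similarity_score(X, Y)), 1, tolerance = 1e-10)
  expect_equal(as.numeric(similarity_score(X, X)), 1, tolerance = 1e-10)
  # symmetry and label invariance
  s1 <- similarity_score(X, Y); s2 <- similarity_score(Y, X)
  expect_equal(as.numeric(s1), as.numeric(s2))
  expect_error(similarity_score(X, state_frequency_vectors(seg, 8000L)),
               "window grids")
})
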