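#' Per-bin read counts for one (cell type, chromosome)
#'
#' Container for raw ChIP-seq signal preceding binarization: a non-negative
#' integer matrix of bins (rows) by marks (columns).
#'
#' @param counts non-negative integer matrix, `num_bins x num_marks`.
#' @param mark_names ordered, unique mark labels (one per column).
#' @param cell_type,chromosome labels.
#' @param bin_size bin width in bp (> 0).
#' @return an object of class `dihmm_counts`.
#' @export
bin_counts <- function(counts, mark_names = colnames(counts),
                       cell_type = "cell", chromosome = "chr",
                       bin_size = 200L) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L) stopf("empty counts matrix")
  if (is.null(mark_names)) stopf("mark_names are required")
  mark_names <- as.character(mark_names)
  if (anyDuplicated(mark_names)) stopf("mark_names must be unique")
  if (ncol(counts) != length(mark_names))
    stopf("counts has %d columns but %d mark names", ncol(counts),
          length(mark_names))
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be non-negative integers")
  if (bin_size <= 0) stopf("bin_size must be positive")
  storage.mode(counts) <- "integer"
  colnames(counts) <- mark_names
  structure(list(cell_type = as.character(cell_type),
                 chromosome = as.character(chromosome),
                 bin_size = as.integer(bin_size),
                 counts = counts, mark_names = mark_names),
            class = "dihmm_counts")
}

#' Binarized chromatin-mark tracks for one (cell type, chromosome)
#'
#' The observation matrix of the model: one 0/1 presence call per mark per
#' bin, as produced by [poisson_binarize()] or read from a ChromHMM-style
#' binarized text file.
#'
#' @param data 0/1 matrix, `num_bins x num_marks`.
#' @inheritParams bin_counts
#' @return an object of class `dihmm_tracks`.
#' @export
binarized_tracks <- function(data, mark_names = colnames(data),
                             cell_type = "cell", chromosome = "chr",
                             bin_size = 200L) {
  data <- as.matrix(data)
  if (nrow(data) < 1L) stopf("tracks must contain at least one bin")
  if (is.null(mark_names)) stopf("mark_names are required")
  mark_names <- as.character(mark_names)
  if (anyDuplicated(mark_names)) stopf("mark_names must be unique")
  if (ncol(data) != length(mark_names))
    stopf("data has %d columns but %d mark names", ncol(data),
          length(mark_names))
  if (!all(data %in% c(0L, 1L))) stopf("track entries must be 0 or 1")
  storage.mode(data) <- "integer"
  colnames(data) <- mark_names
  structure(list(cell_type = as.character(cell_type),
                 chromosome = as.character(chromosome),
                 bin_size = as.integer(bin_size),
                 data = data, mark_names = mark_names),
            class = "dihmm_tracks")
}

#' Bin aligned reads into fixed-width genomic bins
#'
#' Counts, per chromatin mark, the reads whose (optionally shifted) 5'
#' position falls in each bin `[b*bin_size, (b+1)*bin_size)`. The 5' position
#' of a plus-strand read `[start, end)` is `start`; of a minus-strand read it
#' is `end - 1`. The shift moves the 5' position toward the fragment centre
#' (`+shift` on the plus strand, `-shift` on the minus strand); shifted
#' positions are clamped to the chromosome. Coordinates are 0-based,
#' half-open (BED convention); the last partial bin at the chromosome end is
#' kept.
#'
#' @param reads data frame with columns `start`, `end` (0-based half-open),
#'   `strand` (`"+"`/`"-"`) and `mark`.
#' @param chrom_size chromosome length in bp.
#' @param bin_size bin width in bp, default 200.
#' @param shift 5'-end shift in bp, default 100; 0 disables.
#' @param mark_names optional ordered mark labels; reads carrying a mark not
#'   in this list are rejected. Defaults to the marks present, in order of
#'   first appearance.
#' @inheritParams bin_counts
#' @return a [bin_counts] object with `ceiling(chrom_size / bin_size)` bins.
#' @export
count_reads <- function(reads, chrom_size, bin_size = 200L, shift = 100L,
                        mark_names = NULL, cell_type = "cell",
                        chromosome = "chr") {
  req <- c("start", "end", "strand", "mark")
  if (!all(req %in% names(reads)))
    stopf("reads must have columns %s", paste(req, collapse = ", "))
  if (bin_size <= 0) stopf("bin_size must be positive")
  bad <- which(reads$start < 0 | reads$end > chrom_size |
                 reads$end <= reads$start)
  if (length(bad))
    stopf("read %d ([%d, %d)) lies outside the chromosome [0, %d)",
          bad[1L], reads$start[bad[1L]], reads$end[bad[1L]], chrom_size)
  if (!all(reads$strand %in% c("+", "-")))
    stopf("strand must be '+' or '-'")
  mark_names <- mark_names %||% unique(as.character(reads$mark))
  unknown <- setdiff(unique(as.character(reads$mark)), mark_names)
  if (length(unknown))
    stopf("unknown mark label(s): %s", paste(unknown, collapse = ", "))

  plus <- reads$strand == "+"
  pos <- ifelse(plus, reads$start + shift, reads$end - 1L - shift)
  pos <- pmin(pmax(pos, 0L), chrom_size - 1L)
  bin <- pos %/% bin_size + 1L
  n_bins <- as.integer(ceiling(chrom_size / bin_size))
  counts <- vapply(mark_names, function(m)
    tabulate(bin[reads$mark == m], nbins = n_bins), integer(n_bins))
  counts <- matrix(counts, nrow = n_bins,
                   dimnames = list(NULL, mark_names))
  bin_counts(counts, mark_names, cell_type, chromosome, bin_size)
}

#' Read strand-aware reads from a BED file
#'
#' Minimal BED reader for aligned-read intervals: columns 1-3 are
#' chromosome, start, end; column 6, when present, is the strand (missing
#' strand defaults to `+`). All records are assigned to one mark.
#'
#' @param file path to a BED file.
#' @param mark mark label to attach to every read.
#' @return data frame with columns `chrom`, `start`, `end`, `strand`, `mark`.
#' @export
read_reads_bed <- function(file, mark) {
  tab <- read.table(file, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  strand <- if (ncol(tab) >= 6L) tab[[6L]] else rep("+", nrow(tab))
  data.frame(chrom = tab[[1L]], start = tab[[2L]], end = tab[[3L]],
             strand = strand, mark = mark, stringsAsFactors = FALSE)
}

#' Poisson upper-tail enrichment call
#'
#' A count `c` is called enriched against background rate `lambda` iff
#' `c >= 1` and the Poisson upper-tail probability `P(X >= c | lambda)` is at
#' most `p_threshold`. Vectorized over `counts`.
#'
#' @param counts non-negative integer count(s).
#' @param lambda Poisson background rate.
#' @param p_threshold upper-tail probability threshold, default `1e-4`.
#' @return integer 0/1 vector of calls.
#' @export
poisson_call <- function(counts, lambda, p_threshold = 1e-4) {
  if (p_threshold <= 0 || p_threshold >= 1)
    stopf("p_threshold must lie in (0, 1)")
  as.integer(counts >= 1 &
               ppois(counts - 1, lambda, lower.tail = FALSE) <= p_threshold)
}

#' Binarize per-bin counts with a Poisson background model
#'
#' For each mark the background rate is its mean count per bin over the
#' chromosome being binarized; a bin is called present (1) iff its count is
#' at least 1 and the Poisson upper-tail probability of the count under the
#' background rate is at most `p_threshold` (default `1e-4`). No
#' input/control-track subtraction is performed.
#'
#' @param counts a [bin_counts] object.
#' @param p_threshold upper-tail probability threshold, default `1e-4`.
#' @return a [binarized_tracks] object of the same dimensions.
#' @export
poisson_binarize <- function(counts, p_threshold = 1e-4) {
  stopifnot(inherits(counts, "dihmm_counts"))
  x <- counts$counts
  if (length(x) == 0L) stopf("empty counts matrix")
  lambda <- colMeans(x)
  calls <- vapply(seq_along(lambda), function(m)
    poisson_call(x[, m], lambda[m], p_threshold), integer(nrow(x)))
  calls <- matrix(calls, nrow = nrow(x))
  binarized_tracks(calls, counts$mark_names, counts$cell_type,
                   counts$chromosome, counts$bin_size)
}

#' Write / read ChromHMM-compatible binarized track files
#'
#' Plain-text format: line 1 is `cell_type TAB chromosome`, line 2 the
#' tab-separated mark names, and each subsequent line the tab-separated 0/1
#' calls of one bin. The round trip is bit-exact.
#'
#' @param tracks a [binarized_tracks] object.
#' @param file destination / source path.
#' @param bin_size bin width to attach on reading (the format does not store
#'   it), default 200.
#' @return `read_binarized` returns a [binarized_tracks] object;
#'   `write_binarized` returns `file` invisibly.
#' @export
write_binarized <- function(tracks, file) {
  stopifnot(inherits(tracks, "dihmm_tracks"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(tracks$cell_type, tracks$chromosome, sep = "\t"), con)
  writeLines(paste(tracks$mark_names, collapse = "\t"), con)
  write.table(tracks$data, con, sep = "\t", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_binarized
#' @export
read_binarized <- function(file, bin_size = 200L) {
  lines <- readLines(file)
  if (length(lines) < 3L) stopf("binarized file must have at least 3 lines")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) != 2L)
    stopf("malformed header at line 1: expected 'cell_type<TAB>chromosome'")
  marks <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  data <- matrix(0L, length(body), length(marks))
  for (i in seq_along(body)) {
    tok <- body[[i]]
    if (length(tok) != length(marks))
      stopf("ragged row at line %d: %d fields, expected %d", i + 2L,
            length(tok), length(marks))
    if (!all(tok %in% c("0", "1")))
      stopf("non-binary token at line %d", i + 2L)
    data[i, ] <- as.integer(tok)
  }
  binarized_tracks(data, marks, header[1L], header[2L], bin_size)
}

#' @export
print.dihmm_counts <- function(x, ...) {
  cat(sprintf("Per-bin read counts: %s %s, %d bins x %d marks (%d bp bins)\n",
              x$cell_type, x$chromosome, nrow(x$counts),
              length(x$mark_names), x$bin_size))
  invisible(x)
}

#' @export
print.dihmm_tracks <- function(x, ...) {
  cat(sprintf("Binarized tracks: %s %s, %d bins x %d marks (%d bp bins)\n",
              x$cell_type, x$chromosome, nrow(x$data),
              length(x$mark_names), x$bin_size))
  cat(sprintf("  marks: %s\n", paste(x$mark_names, collapse = ", ")))
  cat(sprintf("  fraction of 1-calls: %.4f\n", mean(x$data)))
  invisible(x)
}
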