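#' Decode a set of sequences with a trained model
#'
#' Applies Viterbi or posterior decoding independently to each (cell type,
#' chromosome) track.
#'
#' @param model a [dihmm_model] (or a fitted [dihmm] object).
#' @param tracks_list a [binarized_tracks] object or list of them.
#' @param decoder `"viterbi"` (default; guarantees a jointly most probable
#'   structurally valid path) or `"posterior"`.
#' @return a named list of [state_path] objects
#'   (`"<cell_type>.<chromosome>"`).
#' @export
segment_genome <- function(model, tracks_list,
                           decoder = c("viterbi", "posterior")) {
  if (inherits(model, "dihmm")) model <- model$model
  decoder <- match.arg(decoder)
  if (inherits(tracks_list, "dihmm_tracks")) tracks_list <- list(tracks_list)
  out <- lapply(tracks_list, function(tr) {
    if (decoder == "viterbi") dihmm_viterbi(model, tr)
    else posterior_decode(dihmm_posteriors(model, tr))
  })
  names(out) <- vapply(tracks_list, function(tr)
    paste(tr$cell_type, tr$chromosome, sep = "."), character(1L))
  out
}

#' Stitch a state path into maximal genomic segments
#'
#' Consecutive bins with identical state are merged into one half-open
#' genomic segment (0-based bp coordinates); concatenating the segments
#' reproduces the path exactly. At the domain level, every segment length is
#' a multiple of `block_size * bin_size` except possibly the
#' chromosome-terminal segment.
#'
#' @param path a [state_path].
#' @param level `"nucleosome"` or `"domain"`.
#' @param bin_size bin width in bp, default 200.
#' @param chromosome,cell_type labels attached to every segment.
#' @return data frame with columns `chromosome`, `start`, `end`, `level`,
#'   `state`, `cell_type`.
#' @export
stitch <- function(path, level = c("nucleosome", "domain"), bin_size = 200L,
                   chromosome = "chr", cell_type = "cell") {
  stopifnot(inherits(path, "dihmm_path"))
  level <- match.arg(level)
  s <- if (level == "nucleosome") path$nuc_states else path$dom_states
  r <- rle(s)
  ends <- cumsum(r$lengths) * bin_size
  starts <- c(0, head(ends, -1L))
  data.frame(chromosome = chromosome, start = starts, end = ends,
             level = level, state = r$values, cell_type = cell_type,
             stringsAsFactors = FALSE)
}

#' Expand stitched segments back to a per-bin state vector
#'
#' Inverse of [stitch()] for one chromosome's segments.
#'
#' @param segments data frame as produced by [stitch()].
#' @param bin_size bin width in bp, default 200.
#' @return integer vector of per-bin states.
#' @export
unstitch <- function(segments, bin_size = 200L) {
  segments <- segments[order(segments$start), , drop = FALSE]
  rep(segments$state, (segments$end - segments$start) / bin_size)
}

default_labels <- function(segments) {
  pre <- ifelse(segments$level == "domain", "D", "N")
  paste0(pre, segments$state)
}

default_colors <- function(states) {
  pal <- grDevices::rainbow(max(states))
  rgb <- grDevices::col2rgb(pal)
  apply(rgb, 2L, paste, collapse = ",")[states]
}

#' Write segments to a BED9 file
#'
#' One line per segment: chrom, start, end, name, score 0, strand `.`,
#' thickStart/thickEnd mirroring start/end, and an itemRgb colour. Names
#' default to `N<state>` / `D<state>`; a `label_map` (named by state index)
#' overrides them and must cover every state present.
#'
#' @param segments segment data frame from [stitch()].
#' @param file destination path.
#' @param label_map optional named character vector, state index -> name.
#' @param color_map optional named character vector, state index ->
#'   `"r,g,b"`.
#' @return `file`, invisibly.
#' @export
write_bed <- function(segments, file, label_map = NULL, color_map = NULL) {
  if (nrow(segments) == 0L) {
    file.create(file)
    return(invisible(file))
  }
  segments <- segments[order(segments$chromosome, segments$start), ,
                       drop = FALSE]
  if (!is.null(label_map)) {
    missing <- setdiff(as.character(unique(segments$state)), names(label_map))
    if (length(missing))
      stopf("label_map is missing state(s): %s", paste(missing, collapse = ", "))
    name <- unname(label_map[as.character(segments$state)])
  } else name <- default_labels(segments)
  col <- if (!is.null(color_map)) unname(color_map[as.character(segments$state)])
         else default_colors(segments$state)
  bed <- data.frame(segments$chromosome, segments$start, segments$end, name,
                    0L, ".", segments$start, segments$end, col)
  write.table(bed, file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' Read segments back from a BED9 file written by [write_bed()]
#'
#' The annotation level and state index are recovered from default names
#' (`N<state>` for nucleosome level, `D<state>` for domain level).
#'
#' @param file BED path.
#' @param cell_type label to attach (BED does not store it).
#' @return segment data frame as produced by [stitch()].
#' @export
read_bed <- function(file, cell_type = "cell") {
  if (file.size(file) == 0L)
    return(data.frame(chromosome = character(), start = numeric(),
                      end = numeric(), level = character(), state = integer(),
                      cell_type = character(), stringsAsFactors = FALSE))
  tab <- read.table(file, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  name <- tab[[4L]]
  ok <- grepl("^[ND][0-9]+$", name)
  if (!all(ok))
    stopf("cannot recover state indices from name '%s'", name[!ok][1L])
  data.frame(chromosome = tab[[1L]], start = tab[[2L]], end = tab[[3L]],
             level = ifelse(substr(name, 1L, 1L) == "D", "domain",
                            "nucleosome"),
             state = as.integer(sub("^[ND]", "", name)),
             cell_type = cell_type, stringsAsFactors = FALSE)
}

#' Positions of domain-state changes along one chromosome
#'
#' Boundaries are the junctions between adjacent domain-level segments with
#' different states. Every boundary falls on a multiple of
#' `block_size * bin_size` (except possibly at a chromosome-terminal partial
#' block).
#'
#' @param domain_segments sorted, tiling domain-level segments of one
#'   chromosome.
#' @return numeric vector of boundary positions in bp (possibly empty).
#' @export
domain_boundaries <- function(domain_segments) {
  n <- nrow(domain_segments)
  if (n <= 1L) return(numeric(0))
  if (length(unique(domain_segments$chromosome)) > 1L)
    stopf("domain_boundaries expects segments of a single chromosome")
  if (is.unsorted(domain_segments$start, strictly = TRUE))
    stopf("segments must be sorted by start")
  if (any(domain_segments$start[-1L] != domain_segments$end[-n]))
    stopf("segments must tile the chromosome without gaps")
  changed <- domain_segments$state[-1L] != domain_segments$state[-n]
  domain_segments$end[-n][changed]
}

#' Genomic coverage fraction per state
#'
#' The fraction of annotated bp occupied by each state, per cell type and
#' level.
#'
#' @param segments segment data frame (may mix levels and cell types).
#' @return data frame with columns `cell_type`, `level`, `state`,
#'   `bp`, `fraction`.
#' @export
state_coverage <- function(segments) {
  segments$bp <- segments$end - segments$start
  agg <- stats::aggregate(bp ~ cell_type + level + state, segments, sum)
  tot <- stats::aggregate(bp ~ cell_type + level, segments, sum)
  names(tot)[3L] <- "total"
  out <- merge(agg, tot)
  out$fraction <- out$bp / out$total
  out[order(out$cell_type, out$level, out$state),
      c("cell_type", "level", "state", "bp", "fraction")]
}
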