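#' Read Refined-IBD-style segment files
#'
#' Parses a tab-delimited segment file with eight columns: sample1,
#' haplotype1, sample2, haplotype2, chromosome, start_bp, end_bp, LOD (the
#' Refined IBD output dialect; gzip transparent). Genetic-map coordinates are
#' attached to every segment by [interpolate_cM()], and the unordered sample
#' pair is canonicalised with the lexicographically smaller sample ID first.
#'
#' @param path path to the segment file.
#' @param map a [genetic_map()] used to assign cM endpoints.
#' @return A `segment_set`: a data.frame with columns `sample1`, `hap1`,
#'   `sample2`, `hap2`, `chrom`, `start_bp`, `end_bp`, `lod`, `start_cM`,
#'   `end_cM`, `length_cM`, carrying attributes `genome_length_cM`,
#'   `provenance` and `filter` (thresholds applied so far, if any).
#' @export
read_ibd_segments <- function(path, map) {
  stopifnot(inherits(map, "genetic_map"))
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE,
                         col.names = c("sample1", "hap1", "sample2", "hap2",
                                       "chrom", "start_bp", "end_bp", "lod"))
  if (nrow(d) == 0L) stop("empty segment file: ", path)
  for (col in c("start_bp", "end_bp", "lod")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    if (anyNA(v))
      stop("malformed segment file ", path, ": non-numeric ", col,
           " at line ", which(is.na(v))[1L])
    d[[col]] <- v
  }
  for (col in c("hap1", "hap2")) {
    v <- suppressWarnings(as.integer(d[[col]]))
    if (anyNA(v) || any(!v %in% 1:2))
      stop("malformed segment file ", path, ": haplotype index not in {1,2}",
           " at line ", which(is.na(v) | !v %in% 1:2)[1L])
    d[[col]] <- v
  }
  segment_set(d, map, provenance = path)
}

#' Assemble a segment set from a segment table
#'
#' Validates segment rows, canonicalises pair order, and attaches cM
#' coordinates from the map. Called by [read_ibd_segments()] and by the
#' simulators; useful directly when segments are built in memory.
#'
#' @param segments data.frame with columns `sample1`, `hap1`, `sample2`,
#'   `hap2`, `chrom`, `start_bp`, `end_bp`, `lod`.
#' @param map a [genetic_map()].
#' @param provenance character tag recorded on the result.
#' @return A `segment_set` data.frame (see [read_ibd_segments()]).
#' @export
segment_set <- function(segments, map, provenance = "in-memory") {
  stopifnot(inherits(map, "genetic_map"))
  need <- c("sample1", "hap1", "sample2", "hap2", "chrom",
            "start_bp", "end_bp", "lod")
  if (!all(need %in% names(segments)))
    stop("segment table needs columns: ", paste(need, collapse = ", "))
  d <- segments[need]
  d$chrom <- normalize_chrom(d$chrom)
  bad <- d$start_bp >= d$end_bp
  if (any(bad))
    stop("segment with start_bp >= end_bp at line ", which(bad)[1L])
  if (any(d$sample1 == d$sample2))
    stop("segment pairing a sample with itself at line ",
         which(d$sample1 == d$sample2)[1L])
  swap <- d$sample1 > d$sample2
  if (any(swap)) {
    tmp_s <- d$sample1[swap]; tmp_h <- d$hap1[swap]
    d$sample1[swap] <- d$sample2[swap]; d$hap1[swap] <- d$hap2[swap]
    d$sample2[swap] <- tmp_s;           d$hap2[swap] <- tmp_h
  }
  d$start_cM <- interpolate_cM(map, d$chrom, d$start_bp)
  d$end_cM <- interpolate_cM(map, d$chrom, d$end_bp)
  d$length_cM <- d$end_cM - d$start_cM
  structure(d,
            genome_length_cM = map$genome_length_cM,
            provenance = provenance,
            filter = NULL,
            class = c("segment_set", "data.frame"))
}

#' Write a segment set to the tab-delimited segment dialect
#'
#' Writes the eight physical columns (cM columns are recomputed from the map
#' on re-read), so write then read is value-identical.
#'
#' @param segs a `segment_set`.
#' @param path output path.
#' @export
write_ibd_segments <- function(segs, path) {
  stopifnot(inherits(segs, "segment_set"))
  out <- as.data.frame(segs)[c("sample1", "hap1", "sample2", "hap2",
                               "chrom", "start_bp", "end_bp", "lod")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Filter segments by genetic length and LOD score
#'
#' Retains segments with `length_cM >= min_length_cM` and
#' `lod >= min_lod`. The defaults are the standard array-data thresholds:
#' segments shorter than 2 cM are excluded (short calls have a high false
#' positive rate) and a LOD of 3 requires 1,000:1 support for the IBD model.
#' Both boundaries are inclusive on the retained side.
#'
#' @param segs a `segment_set`.
#' @param min_length_cM minimum genetic length in cM (default 2).
#' @param min_lod minimum LOD score (default 3).
#' @return The filtered `segment_set`; the applied thresholds are recorded in
#'   the `filter` attribute.
#' @export
filter_segments <- function(segs, min_length_cM = 2.0, min_lod = 3.0) {
  stopifnot(inherits(segs, "segment_set"))
  if (min_length_cM < 0 || min_lod < 0)
    stop("filter thresholds must be non-negative")
  keep <- segs$length_cM >= min_length_cM & segs$lod >= min_lod
  out <- segs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "genome_length_cM") <- attr(segs, "genome_length_cM")
  attr(out, "provenance") <- attr(segs, "provenance")
  prev <- attr(segs, "filter")
  attr(out, "filter") <- list(min_length_cM =
                                max(min_length_cM, prev$min_length_cM %||% 0),
                              min_lod = max(min_lod, prev$min_lod %||% 0))
  class(out) <- c("segment_set", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.segment_set <- function(x, ...) {
  f <- attr(x, "filter")
  cat("IBD segment set:", nrow(x), "segments,",
      length(unique(c(x$sample1, x$sample2))), "samples; total",
      format(sum(x$length_cM), digits = 6), "cM",
      if (!is.null(f)) sprintf("(filtered: length >= %g cM, LOD >= %g)",
                               f$min_length_cM, f$min_lod) else "(unfiltered)",
      "\n")
  invisible(x)
}

#' Read a sample panel
#'
#' A panel assigns every sample to exactly one population, optionally to a
#' region (a grouping of populations used for pooled summaries), and
#' optionally to geographic coordinates in decimal degrees. Tab-delimited
#' with a header; recognised columns: `sample`, `population`, `region`,
#' `lat`, `lon`.
#'
#' @param path path to the panel TSV.
#' @return A `population_panel` data.frame.
#' @export
read_panel <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  population_panel(d)
}

#' Construct a sample panel from a data.frame
#'
#' @param d data.frame with columns `sample` and `population`; optional
#'   `region`, `lat`, `lon`.
#' @return A `population_panel` data.frame.
#' @export
population_panel <- function(d) {
  if (!all(c("sample", "population") %in% names(d)))
    stop("panel needs columns 'sample' and 'population'")
  d$sample <- as.character(d$sample)
  d$population <- as.character(d$population)
  if (anyDuplicated(d$sample))
    stop("duplicate sample in panel: ",
         d$sample[anyDuplicated(d$sample)])
  structure(d, class = c("population_panel", "data.frame"))
}

#' Sample IDs belonging to a population
#' @param panel a `population_panel`.
#' @param population population label.
#' @return character vector of sample IDs.
#' @export
panel_samples <- function(panel, population) {
  out <- panel$sample[panel$population %in% population]
  if (length(out) == 0L)
    stop("no samples for population(s): ",
         paste(population, collapse = ", "))
  out
}

#' Read PCA coordinates
#'
#' Two dialects. `"evec"`: the Eigenstrat eigenvector layout — an optional
#' leading `#eigvals:` line, then one row per sample with the sample ID
#' first, K coordinates, and a trailing label token that is ignored.
#' `"tsv"`: tab-delimited with a header whose first column is `sample` and
#' remaining columns are the coordinates.
#'
#' @param path input path.
#' @param format `"evec"` or `"tsv"`.
#' @return A `pca_coords` object: numeric matrix (samples x K) with sample
#'   IDs as rownames and columns `PC1..PCK`.
#' @export
read_pca_coords <- function(path, format = c("evec", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- as.character(d[[1]])
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*#", lines)]
    lines <- lines[nzchar(trimws(lines))]
    toks <- strsplit(trimws(lines), "[ \t]+")
    k <- length(toks[[1]]) - 2L
    if (k < 1L) stop("evec file rows need sample, >=1 coordinate, label")
    if (any(vapply(toks, length, integer(1)) != k + 2L))
      stop("inconsistent column count in evec file")
    m <- t(vapply(toks, function(tk) as.numeric(tk[2:(k + 1L)]), numeric(k)))
    rownames(m) <- vapply(toks, `[`, character(1), 1L)
  }
  pca_coords(m)
}

#' Construct a PCA coordinate object
#' @param m numeric matrix, samples in rows (rownames = sample IDs),
#'   principal components in columns.
#' @return A `pca_coords` matrix with columns renamed `PC1..PCK`.
#' @export
pca_coords <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) stop("PCA coordinates need sample IDs as rownames")
  if (anyNA(m)) stop("PCA coordinates contain missing values")
  storage.mode(m) <- "double"
  colnames(m) <- paste0("PC", seq_len(ncol(m)))
  structure(m, class = c("pca_coords", "matrix", "array"))
}
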