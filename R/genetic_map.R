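#' Genetic maps: physical to genetic coordinates
#'
#' A genetic map is a per-chromosome piecewise-linear function from physical
#' position (bp) to genetic position (cM). Only autosomes (1-22) are
#' accepted; sex chromosomes and mitochondrial records are rejected because
#' the sharing statistics are defined on autosomal segments.
#'
#' @param anchors data.frame with columns `chrom`, `bp`, `cM`: the map
#'   anchors. Within each chromosome `bp` must be strictly increasing and
#'   `cM` non-decreasing.
#' @return An object of class `genetic_map`: a list with `anchors` (the
#'   validated anchor table, chromosome labels normalised to "1".."22") and
#'   `genome_length_cM` (sum over chromosomes of last minus first cM).
#' @examples
#' gm <- genetic_map(data.frame(chrom = "1",
#'                              bp = c(1e6, 2e6), cM = c(1, 3)))
#' gm$genome_length_cM  # 2
#' @export
genetic_map <- function(anchors) {
  stopifnot(is.data.frame(anchors))
  need <- c("chrom", "bp", "cM")
  if (!all(need %in% names(anchors)))
    stop("map anchors need columns: ", paste(need, collapse = ", "))
  anchors$chrom <- normalize_chrom(anchors$chrom)
  anchors$bp <- as.numeric(anchors$bp)
  anchors$cM <- as.numeric(anchors$cM)
  if (anyNA(anchors$bp) || anyNA(anchors$cM))
    stop("non-numeric bp or cM value in map anchors")
  if (any(anchors$bp < 0) || any(anchors$cM < 0))
    stop("map anchors must have bp >= 0 and cM >= 0")
  anchors <- anchors[order(match(anchors$chrom, autosome_labels())), ,
                     drop = FALSE]
  for (ch in unique(anchors$chrom)) {
    a <- anchors[anchors$chrom == ch, ]
    if (nrow(a) < 2L)
      stop("chromosome ", ch, " has fewer than 2 map anchors")
    dbp <- diff(a$bp)
    if (any(dbp <= 0)) {
      bad <- which(dbp <= 0)[1L] + 1L
      stop("non-monotonic bp in genetic map on chromosome ", ch,
           " at anchor ", bad)
    }
    if (any(diff(a$cM) < 0))
      stop("decreasing cM in genetic map on chromosome ", ch)
  }
  spans <- tapply(anchors$cM, anchors$chrom, function(x) max(x) - min(x))
  G <- sum(spans)
  if (G <= 0) stop("genome length must be positive")
  structure(list(anchors = anchors, genome_length_cM = G),
            class = "genetic_map")
}

autosome_labels <- function() as.character(1:22)

# Strip "chr" prefixes and reject anything that is not an autosome.
normalize_chrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  bad <- !(x %in% autosome_labels())
  if (any(bad))
    stop("non-autosomal or unrecognised chromosome label(s): ",
         paste(unique(chrom[bad]), collapse = ", "),
         " (autosomes 1-22 only)")
  x
}

#' Read a genetic map file
#'
#' Two text dialects are supported. `"hapmap"`: whitespace-delimited columns
#' chromosome, position (bp), recombination rate (ignored), cumulative map
#' position (cM), with an optional header line. `"plinkmap"`: the PLINK
#' `.map` layout chromosome, marker id, cM, bp.
#'
#' @param path path to the map file (plain text; gzip transparent).
#' @param format `"hapmap"` or `"plinkmap"`.
#' @return A [genetic_map()] object.
#' @export
read_genetic_map <- function(path, format = c("hapmap", "plinkmap")) {
  format <- match.arg(format)
  first <- readLines(path, n = 1L)
  tok <- strsplit(trimws(first), "[ \t]+")[[1]]
  header_bp_col <- if (format == "hapmap") 2L else 4L
  skip <- if (length(tok) >= header_bp_col &&
              is.na(suppressWarnings(as.numeric(tok[header_bp_col]))))
    1L else 0L
  d <- utils::read.table(path, header = FALSE, skip = skip,
                         stringsAsFactors = FALSE)
  if (format == "hapmap") {
    if (ncol(d) < 4L) stop("hapmap map needs 4 columns (chrom bp rate cM)")
    anchors <- data.frame(chrom = d[[1]], bp = d[[2]], cM = d[[4]])
  } else {
    if (ncol(d) < 4L) stop("plink map needs 4 columns (chrom id cM bp)")
    anchors <- data.frame(chrom = d[[1]], bp = d[[4]], cM = d[[3]])
  }
  genetic_map(anchors)
}

#' Interpolate genetic position at physical positions
#'
#' Linear interpolation between the flanking anchors of the map. Positions
#' outside the anchored range are clamped to the terminal anchor's cM value
#' rather than extrapolated, so out-of-range queries can never produce
#' negative or inflated segment lengths.
#'
#' @param map a [genetic_map()].
#' @param chrom chromosome label (scalar, recycled) or vector parallel to `bp`.
#' @param bp numeric vector of physical positions.
#' @return numeric vector of cM positions.
#' @examples
#' gm <- genetic_map(data.frame(chrom = "1", bp = c(1e6, 2e6), cM = c(1, 3)))
#' interpolate_cM(gm, "1", 1.5e6)  # 2
#' @export
interpolate_cM <- function(map, chrom, bp) {
  stopifnot(inherits(map, "genetic_map"))
  chrom <- normalize_chrom(chrom)
  if (length(chrom) == 1L) chrom <- rep(chrom, length(bp))
  stopifnot(length(chrom) == length(bp))
  out <- numeric(length(bp))
  for (ch in unique(chrom)) {
    a <- map$anchors[map$anchors$chrom == ch, ]
    if (nrow(a) == 0L) stop("chromosome ", ch, " not present in genetic map")
    idx <- chrom == ch
    out[idx] <- stats::approx(a$bp, a$cM, xout = bp[idx], method = "linear",
                              rule = 2, ties = "ordered")$y
  }
  out
}

#' Invert a genetic map: cM back to bp
#'
#' Used by the synthetic-segment generator to place segments drawn in cM
#' space onto physical coordinates. cM positions on a flat stretch of the map
#' resolve to the left-most bp of the stretch; out-of-range values clamp to
#' the terminal anchors. Results are rounded to integer bp.
#'
#' @inheritParams interpolate_cM
#' @param cM numeric vector of genetic positions.
#' @return numeric vector of bp positions.
#' @export
interpolate_bp <- function(map, chrom, cM) {
  stopifnot(inherits(map, "genetic_map"))
  chrom <- normalize_chrom(chrom)
  if (length(chrom) == 1L) chrom <- rep(chrom, length(cM))
  out <- numeric(length(cM))
  for (ch in unique(chrom)) {
    a <- map$anchors[map$anchors$chrom == ch, ]
    if (nrow(a) == 0L) stop("chromosome ", ch, " not present in genetic map")
    idx <- chrom == ch
    out[idx] <- stats::approx(a$cM, a$bp, xout = cM[idx], method = "linear",
                              rule = 2, ties = min)$y
  }
  round(out)
}

# Per-chromosome cM span table: chrom, cM_start, cM_end, span.
chromosome_spans <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  chroms <- unique(map$anchors$chrom)
  lo <- vapply(chroms, function(ch)
    min(map$anchors$cM[map$anchors$chrom == ch]), numeric(1))
  hi <- vapply(chroms, function(ch)
    max(map$anchors$cM[map$anchors$chrom == ch]), numeric(1))
  data.frame(chrom = chroms, cM_start = lo, cM_end = hi, span = hi - lo,
             row.names = NULL)
}

#' Build a constant-rate synthetic genetic map
#'
#' A uniform-rate map (default 1 cM/Mb, the genome-wide human average) over
#' `n_chrom` autosomes of equal genetic span. Convenient as the coordinate
#' system for simulations: 22 chromosomes of 150 cM give a 3,300 cM genome,
#' close to the autosomal total of the HapMap map.
#'
#' @param n_chrom number of autosomes (max 22).
#' @param span_cM genetic length of each chromosome in cM.
#' @param rate_cM_per_Mb constant recombination rate.
#' @return A [genetic_map()] object.
#' @export
synthetic_genetic_map <- function(n_chrom = 22, span_cM = 150,
                                  rate_cM_per_Mb = 1) {
  stopifnot(n_chrom >= 1, n_chrom <= 22, span_cM > 0, rate_cM_per_Mb > 0)
  bp_span <- span_cM / rate_cM_per_Mb * 1e6
  anchors <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
    data.frame(chrom = as.character(i), bp = c(1, 1 + bp_span),
               cM = c(0, span_cM))
  }))
  genetic_map(anchors)
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("Genetic map:", length(unique(x$anchors$chrom)), "autosomes,",
      nrow(x$anchors), "anchors, genome length",
      format(x$genome_length_cM, digits = 6), "cM\n")
  invisible(x)
}
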