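#' Population nearest-neighbour network from PCA coordinates
#'
#' For each sample, finds its `m` nearest neighbours by Euclidean distance
#' in the space of the first `K` principal components, under the constraint
#' that a neighbour must belong to a different population than the sample.
#' Neighbour links are aggregated into a directed population-level graph:
#' the weight of edge P -> Q is the number of (sample in P, neighbour in Q)
#' links, so out-weights from P always sum to `m x |P|`. Distance ties are
#' broken by sample ID, making the network independent of input order.
#'
#' @param coords a [pca_coords()] matrix.
#' @param panel a `population_panel` labelling every sample in `coords`.
#' @param K number of leading components to use (default 3).
#' @param m neighbours per sample (default 3).
#' @return A `population_network`: list with `edges` (data.frame `from`,
#'   `to`, `weight`), `nodes` (population sizes), `K`, `m`.
#' @export
build_network <- function(coords, panel, K = 3, m = 3) {
  stopifnot(inherits(coords, "pca_coords"),
            inherits(panel, "population_panel"))
  if (K < 1 || K > ncol(coords))
    stop("K must be between 1 and the number of available components (",
         ncol(coords), ")")
  if (m < 1) stop("m must be >= 1")
  ids <- rownames(coords)
  pop <- panel$population[match(ids, panel$sample)]
  if (anyNA(pop))
    stop("sample(s) in coordinates absent from panel: ",
         paste(ids[is.na(pop)][1:min(3, sum(is.na(pop)))], collapse = ", "))
  X <- coords[, seq_len(K), drop = FALSE]
  D <- as.matrix(stats::dist(X))
  n <- length(ids)
  from <- character(n * m); to <- character(n * m)
  for (i in seq_len(n)) {
    elig <- which(pop != pop[i])
    if (length(elig) < m)
      stop("sample ", ids[i], " has only ", length(elig),
           " other-population candidates; m = ", m, " requested")
    ord <- elig[order(D[i, elig], ids[elig])]
    nb <- ord[seq_len(m)]
    from[((i - 1) * m + 1):(i * m)] <- pop[i]
    to[((i - 1) * m + 1):(i * m)] <- pop[nb]
  }
  agg <- stats::aggregate(list(weight = rep(1L, length(from))),
                          by = list(from = from, to = to), FUN = sum)
  agg <- agg[order(agg$from, agg$to), , drop = FALSE]
  rownames(agg) <- NULL
  agg$weight <- as.integer(agg$weight)
  sizes <- table(pop)
  structure(list(edges = agg,
                 nodes = data.frame(population = names(sizes),
                                    n_samples = as.integer(sizes)),
                 K = as.integer(K), m = as.integer(m)),
            class = "population_network")
}

#' @export
print.population_network <- function(x, ...) {
  cat("Population nearest-neighbour network: ", nrow(x$nodes), " populations, ",
      nrow(x$edges), " directed edges (K = ", x$K, ", m = ", x$m, ")\n",
      sep = "")
  invisible(x)
}

#' Undirected view of a population network
#'
#' Sums the two directed weights of each unordered population pair; used for
#' visualisation parity with undirected graph layouts.
#'
#' @param net a `population_network`.
#' @return data.frame with `pop_a`, `pop_b` (sorted), `weight`.
#' @export
undirected_edges <- function(net) {
  stopifnot(inherits(net, "population_network"))
  e <- net$edges
  a <- pmin(e$from, e$to); b <- pmax(e$from, e$to)
  agg <- stats::aggregate(list(weight = e$weight),
                          by = list(pop_a = a, pop_b = b), FUN = sum)
  agg[order(agg$pop_a, agg$pop_b), , drop = FALSE]
}

#' Export a population network for Cytoscape
#'
#' Two dialects: `"tsv"` — a weighted edge table (`from`, `to`, `weight`)
#' with a header, loadable via Cytoscape's table import; `"sif"` — the
#' simple interaction format `source  nn  target` (one row per directed
#' edge; SIF carries no weights).
#'
#' @param net a `population_network`.
#' @param path output path.
#' @param format `"tsv"` or `"sif"`.
#' @export
export_network <- function(net, path, format = c("tsv", "sif")) {
  stopifnot(inherits(net, "population_network"))
  format <- match.arg(format)
  if (nrow(net$edges) == 0L) stop("network has no edges to export")
  if (format == "tsv") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    lines <- paste(net$edges$from, "nn", net$edges$to, sep = "\t")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a weighted edge table written by [export_network()]
#' @param path path to the TSV edge table.
#' @return data.frame with `from`, `to`, integer `weight`.
#' @export
read_network_edges <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  d$weight <- as.integer(d$weight)
  d
}

#' Correlation between a principal component and geography
#'
#' Squared Pearson correlation between one principal component and one
#' geographic axis (longitude or latitude) across samples. r-squared is
#' invariant to sign flips of the PC axis and to affine changes of units in
#' either variable.
#'
#' @param coords a [pca_coords()] matrix.
#' @param panel a `population_panel` with `lat`/`lon` columns.
#' @param pc_index which component (default 1).
#' @param axis `"longitude"` or `"latitude"`.
#' @return A `geo_correlation`: list with `pc_index`, `axis`, `r_squared`,
#'   `n`.
#' @export
pc_geo_correlation <- function(coords, panel, pc_index = 1,
                               axis = c("longitude", "latitude")) {
  stopifnot(inherits(coords, "pca_coords"),
            inherits(panel, "population_panel"))
  axis <- match.arg(axis)
  col <- if (axis == "longitude") "lon" else "lat"
  if (!col %in% names(panel))
    stop("panel has no '", col, "' column")
  if (pc_index < 1 || pc_index > ncol(coords))
    stop("pc_index out of range")
  ids <- rownames(coords)
  geo <- panel[[col]][match(ids, panel$sample)]
  pc <- coords[, pc_index]
  ok <- !is.na(geo) & !is.na(pc)
  if (sum(ok) < 3L)
    stop("need at least 3 samples with both PC and geographic coordinates")
  geo <- geo[ok]; pc <- pc[ok]
  if (stats::sd(geo) == 0 || stats::sd(pc) == 0)
    stop("correlation undefined: constant ", if (stats::sd(geo) == 0)
      "geographic coordinate" else "principal component")
  r2 <- stats::cor(geo, pc)^2
  structure(list(pc_index = as.integer(pc_index), axis = axis,
                 r_squared = r2, n = sum(ok)),
            class = "geo_correlation")
}

#' @export
print.geo_correlation <- function(x, ...) {
  cat(sprintf("PC%d vs %s: r^2 = %.4f (n = %d)\n",
              x$pc_index, x$axis, x$r_squared, x$n))
  invisible(x)
}
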