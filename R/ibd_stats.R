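#' Per-pair IBD totals
#'
#' Sums retained segment lengths over every unordered sample pair (across
#' all four haplotype pairings). Pairs with no segments are implicit zeros:
#' downstream statistics enumerate pairs from the panel, not from this
#' table.
#'
#' @param segs a `segment_set` (normally after [filter_segments()]).
#' @param panel a `population_panel` covering every sample that appears in
#'   the segments.
#' @return A `pair_sharing` data.frame with columns `sample1`, `sample2`
#'   (canonical order), `total_cM`, `n_segments`, `sharing_fraction`
#'   (total_cM divided by the genome length G), with attribute
#'   `genome_length_cM`.
#' @export
pair_totals <- function(segs, panel) {
  stopifnot(inherits(segs, "segment_set"),
            inherits(panel, "population_panel"))
  G <- attr(segs, "genome_length_cM")
  missing <- setdiff(unique(c(segs$sample1, segs$sample2)), panel$sample)
  if (length(missing) > 0L)
    stop("segment sample(s) absent from panel: ",
         paste(missing, collapse = ", "))
  if (nrow(segs) == 0L) {
    d <- data.frame(sample1 = character(), sample2 = character(),
                    total_cM = numeric(), n_segments = integer(),
                    sharing_fraction = numeric())
  } else {
    key <- paste(segs$sample1, segs$sample2, sep = "\r")
    tot <- tapply(segs$length_cM, key, sum)
    cnt <- tapply(segs$length_cM, key, length)
    parts <- strsplit(names(tot), "\r", fixed = TRUE)
    d <- data.frame(sample1 = vapply(parts, `[`, character(1), 1L),
                    sample2 = vapply(parts, `[`, character(1), 2L),
                    total_cM = as.numeric(tot),
                    n_segments = as.integer(cnt),
                    sharing_fraction = as.numeric(tot) / G,
                    row.names = NULL)
    d <- d[order(d$sample1, d$sample2), , drop = FALSE]
    rownames(d) <- NULL
  }
  structure(d, genome_length_cM = G,
            class = c("pair_sharing", "data.frame"))
}

#' Split pairs into retained and related-excluded
#'
#' A pair is excluded when its genome-sharing fraction (total haplotype-level
#' cM divided by the genome length G) is strictly greater than
#' `max_fraction`. Under this convention the expected fractions are about
#' 1.0 for full siblings, 0.5 for half siblings and avuncular pairs, and
#' 0.25 for first cousins, so the default 0.40 removes full sibs, half sibs
#' and avuncular pairs while retaining first cousins.
#'
#' @param pairs a `pair_sharing` table from [pair_totals()].
#' @param genome_length_cM genome length G in cM; defaults to the value
#'   recorded on `pairs`.
#' @param max_fraction exclusion threshold on the sharing fraction
#'   (strictly greater than); must lie in (0, 1].
#' @return list with elements `retained` and `excluded` (both
#'   `pair_sharing` tables) and integer counts `n_retained`, `n_excluded`.
#' @export
exclude_related <- function(pairs,
                            genome_length_cM = attr(pairs, "genome_length_cM"),
                            max_fraction = 0.40) {
  stopifnot(inherits(pairs, "pair_sharing"))
  if (!is.numeric(max_fraction) || max_fraction <= 0 || max_fraction > 1)
    stop("max_fraction must lie in (0, 1]")
  frac <- pairs$total_cM / genome_length_cM
  drop <- frac > max_fraction
  list(retained = pairs[!drop, , drop = FALSE],
       excluded = pairs[drop, , drop = FALSE],
       n_retained = sum(!drop), n_excluded = sum(drop))
}

# Pair totals / sharing fractions as dense matrices over two sample sets.
# Missing pairs are zeros; both (a,b) and (b,a) cells are filled, so the
# within-group matrix is symmetric. Used by the group statistics and the
# bootstrap.
pair_matrices <- function(pairs, samplesA, samplesB, genome_length_cM) {
  Tm <- matrix(0, length(samplesA), length(samplesB),
               dimnames = list(samplesA, samplesB))
  Nm <- Tm
  fill <- function(Tm, Nm, rs, cs) {
    r <- match(rs, samplesA); cc <- match(cs, samplesB)
    hit <- !is.na(r) & !is.na(cc)
    Tm[cbind(r[hit], cc[hit])] <- pairs$total_cM[hit]
    Nm[cbind(r[hit], cc[hit])] <- pairs$n_segments[hit]
    list(Tm, Nm)
  }
  res <- fill(Tm, Nm, pairs$sample1, pairs$sample2)
  res <- fill(res[[1]], res[[2]], pairs$sample2, pairs$sample1)
  list(total = res[[1]], nseg = res[[2]], frac = res[[1]] / genome_length_cM)
}

#' Mean IBD sharing between two sample groups
#'
#' The population-pair sharing statistic: the sum over retained pairs of the
#' pair's total IBD length, divided by the number of retained unique pairs
#' (within-group: n(n-1)/2; cross-group: |A| x |B|), giving
#' `mean_pairwise_cM`; and additionally divided by four times the genome
#' length — the four ways to pair chromosomes between two diploid people —
#' giving the dimensionless `mean_proportion`. Pairs with zero sharing
#' contribute zeros to the mean. Pairs whose sharing fraction exceeds
#' `max_fraction` are excluded as close relatives and counted.
#'
#' @param samplesA,samplesB character vectors of sample IDs; identical sets
#'   give the within-group statistic.
#' @param pairs a `pair_sharing` table from [pair_totals()].
#' @param genome_length_cM genome length G in cM; defaults to the value
#'   recorded on `pairs`.
#' @param max_fraction relatedness exclusion threshold (see
#'   [exclude_related()]).
#' @param label_a,label_b group labels recorded on the summary.
#' @return A one-row `sharing_summary` data.frame: `group_a`, `group_b`,
#'   `n_pairs`, `n_excluded`, `mean_pairwise_cM`, `mean_proportion`,
#'   `prop_pairs_with_ibd`.
#' @export
group_mean_ibd <- function(samplesA, samplesB, pairs,
                           genome_length_cM = attr(pairs, "genome_length_cM"),
                           max_fraction = 0.40,
                           label_a = "A", label_b = "B") {
  stopifnot(inherits(pairs, "pair_sharing"))
  samplesA <- as.character(samplesA); samplesB <- as.character(samplesB)
  if (length(samplesA) == 0L || length(samplesB) == 0L)
    stop("sample groups must be non-empty")
  within <- setequal(samplesA, samplesB)
  if (!within && length(intersect(samplesA, samplesB)) > 0L)
    stop("cross-group comparison with overlapping sample sets")
  if (within) samplesB <- samplesA
  pm <- pair_matrices(pairs, samplesA, samplesB, genome_length_cM)
  sel <- if (within) upper.tri(pm$total)
         else matrix(TRUE, length(samplesA), length(samplesB))
  tot <- pm$total[sel]; nsg <- pm$nseg[sel]
  frac <- tot / genome_length_cM
  keep <- frac <= max_fraction
  n_pairs <- sum(keep)
  if (n_pairs == 0L)
    stop("no retained pairs between groups '", label_a, "' and '", label_b,
         "' after relatedness exclusion")
  mean_cM <- sum(tot[keep]) / n_pairs
  summary_row(label_a, label_b, n_pairs, sum(!keep),
              mean_cM, mean_cM / (4 * genome_length_cM),
              sum(nsg[keep] >= 1) / n_pairs)
}

summary_row <- function(a, b, n_pairs, n_excl, mean_cM, mean_prop, prop_ibd) {
  structure(data.frame(group_a = a, group_b = b,
                       n_pairs = as.integer(n_pairs),
                       n_excluded = as.integer(n_excl),
                       mean_pairwise_cM = mean_cM,
                       mean_proportion = mean_prop,
                       prop_pairs_with_ibd = prop_ibd,
                       stringsAsFactors = FALSE),
            class = c("sharing_summary", "data.frame"))
}

#' Sharing summaries for every population pair
#'
#' Applies [group_mean_ibd()] to every unordered pair of populations
#' (including each population with itself) in the panel, or to a supplied
#' subset.
#'
#' @param pairs a `pair_sharing` table.
#' @param panel a `population_panel`.
#' @param populations populations to include (default: all in panel order).
#' @inheritParams group_mean_ibd
#' @return A `sharing_summary` data.frame, one row per unordered group pair.
#' @export
population_mean_ibd <- function(pairs, panel,
                                populations = unique(panel$population),
                                genome_length_cM = attr(pairs,
                                                        "genome_length_cM"),
                                max_fraction = 0.40) {
  res <- list()
  for (i in seq_along(populations)) {
    for (j in i:length(populations)) {
      res[[length(res) + 1L]] <-
        group_mean_ibd(panel_samples(panel, populations[i]),
                       panel_samples(panel, populations[j]),
                       pairs, genome_length_cM, max_fraction,
                       label_a = populations[i], label_b = populations[j])
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("sharing_summary", "data.frame"))
}

#' Region-pooled sharing summaries
#'
#' Pools populations into regions (e.g., grouping several European
#' populations into "Europe") and computes the pairwise statistic between
#' pooled sample sets. Identical to [group_mean_ibd()] on the pooled sets.
#'
#' @param regions named list mapping region label to a character vector of
#'   population labels; the regions must be disjoint.
#' @param pairs a `pair_sharing` table.
#' @param panel a `population_panel`.
#' @inheritParams group_mean_ibd
#' @return A `sharing_summary` data.frame, one row per unordered region pair.
#' @export
region_pooled_mean_ibd <- function(regions, pairs, panel,
                                   genome_length_cM = attr(pairs,
                                                           "genome_length_cM"),
                                   max_fraction = 0.40) {
  stopifnot(is.list(regions), length(regions) >= 1,
            !is.null(names(regions)))
  pops <- unlist(regions, use.names = FALSE)
  if (anyDuplicated(pops))
    stop("population assigned to more than one region: ",
         pops[anyDuplicated(pops)])
  if (any(vapply(regions, length, integer(1)) == 0L))
    stop("empty region in region mapping")
  labels <- names(regions)
  res <- list()
  for (i in seq_along(labels)) {
    for (j in i:length(labels)) {
      res[[length(res) + 1L]] <-
        group_mean_ibd(panel_samples(panel, regions[[i]]),
                       panel_samples(panel, regions[[j]]),
                       pairs, genome_length_cM, max_fraction,
                       label_a = labels[i], label_b = labels[j])
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("sharing_summary", "data.frame"))
}

#' Log-scale sharing heat-map matrix
#'
#' Arranges `log10(mean_proportion)` for every ordered group pair into a
#' symmetric matrix, rows and columns laid out in the supplied order (for
#' island transects: east to west). Group pairs with zero mean sharing are
#' masked as `NA` rather than floored at a pseudo-count.
#'
#' @param summaries a `sharing_summary` covering all pairs of the requested
#'   groups (unordered pairs suffice).
#' @param ordering character vector of group labels giving row/column order.
#' @return A `heatmap_matrix`: symmetric numeric matrix of
#'   `log10(mean_proportion)` with `NA` for masked cells.
#' @export
heatmap_matrix <- function(summaries, ordering) {
  stopifnot(inherits(summaries, "sharing_summary"))
  ordering <- as.character(ordering)
  n <- length(ordering)
  m <- matrix(NA_real_, n, n, dimnames = list(ordering, ordering))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  have <- key(summaries$group_a, summaries$group_b)
  for (i in seq_len(n)) {
    for (j in i:n) {
      k <- key(ordering[i], ordering[j])
      hit <- which(have == k)
      if (length(hit) == 0L)
        stop("missing summary for group pair ", ordering[i], " / ",
             ordering[j])
      mp <- summaries$mean_proportion[hit[1L]]
      m[i, j] <- m[j, i] <- if (mp > 0) log10(mp) else NA_real_
    }
  }
  structure(m, class = c("heatmap_matrix", "matrix", "array"))
}

#' Render a sharing heat map
#'
#' Base-graphics rendering of a [heatmap_matrix()]: higher (less negative)
#' log10 sharing toward the red end of the scale, masked cells in grey.
#'
#' @param m a `heatmap_matrix`.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @return invisibly, `m`.
#' @export
plot_ibd_heatmap <- function(m, main = "log10 mean IBD proportion", ...) {
  stopifnot(inherits(m, "heatmap_matrix"))
  n <- nrow(m)
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  z <- t(m[n:1, , drop = FALSE])
  graphics::image(seq_len(n), seq_len(n), z, col = pal, axes = FALSE,
                  xlab = "", ylab = "", main = main, ...)
  if (anyNA(z)) {
    idx <- which(is.na(z), arr.ind = TRUE)
    graphics::rect(idx[, 1] - 0.5, idx[, 2] - 0.5,
                   idx[, 1] + 0.5, idx[, 2] + 0.5,
                   col = "grey80", border = NA)
  }
  graphics::axis(1, seq_len(n), colnames(m), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(n), rev(rownames(m)), las = 2, cex.axis = 0.8)
  graphics::box()
  invisible(m)
}

#' Write sharing summaries as TSV
#' @param summaries a `sharing_summary`.
#' @param path output path.
#' @export
write_sharing_summary <- function(summaries, path) {
  utils::write.table(as.data.frame(summaries), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
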