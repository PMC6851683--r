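#' Genotype matrix container
#'
#' Diploid genotypes for biallelic markers: a samples x markers integer
#' matrix of counts of allele2 (0/1/2, `NA` = missing), a marker table, and
#' the sample panel giving population assignments.
#'
#' @param geno integer matrix, samples in rows (rownames = sample IDs),
#'   markers in columns (colnames = marker IDs), entries in `{0, 1, 2, NA}`.
#' @param snps data.frame with columns `id`, `chrom`, `bp`, `allele1`,
#'   `allele2`; one row per marker, in column order of `geno`.
#' @param panel a `population_panel` covering all samples.
#' @return A `genotype_matrix` (list with `geno`, `snps`, `panel`).
#' @export
genotype_matrix <- function(geno, snps, panel) {
  stopifnot(is.matrix(geno), inherits(panel, "population_panel"))
  need <- c("id", "chrom", "bp", "allele1", "allele2")
  if (!all(need %in% names(snps)))
    stop("snp table needs columns: ", paste(need, collapse = ", "))
  if (nrow(snps) != ncol(geno))
    stop("snp table rows (", nrow(snps), ") != genotype columns (",
         ncol(geno), ")")
  if (is.null(rownames(geno)) || is.null(colnames(geno)))
    stop("genotype matrix needs sample rownames and marker colnames")
  if (!identical(colnames(geno), as.character(snps$id)))
    stop("genotype column names do not match snp table ids")
  if (!all(rownames(geno) %in% panel$sample))
    stop("genotype sample(s) absent from panel")
  ok <- is.na(geno) | geno %in% 0:2
  if (!all(ok)) stop("genotype entries must be 0, 1, 2 or NA")
  bad <- is.na(snps$allele1) | is.na(snps$allele2) |
    snps$allele1 == snps$allele2
  if (any(bad)) stop("marker with missing or identical alleles: ",
                     snps$id[which(bad)[1L]])
  storage.mode(geno) <- "integer"
  structure(list(geno = geno, snps = as.data.frame(snps), panel = panel),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$geno), "samples x", ncol(x$geno),
      "markers;", format(100 * mean(is.na(x$geno)), digits = 3),
      "% missing\n")
  invisible(x)
}

#' Write genotypes as marker-per-row text
#'
#' Transposed text layout: a header `id chrom bp allele1 allele2 <sample
#' IDs...>`, then one tab-delimited row per marker with dosages (count of
#' allele2), missing coded `NA`.
#'
#' @param gm a `genotype_matrix`.
#' @param path output path.
#' @export
write_genotypes <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- cbind(gm$snps[c("id", "chrom", "bp", "allele1", "allele2")],
             as.data.frame(t(gm$geno)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from marker-per-row text
#' @param path path written by [write_genotypes()].
#' @param panel a `population_panel` covering the samples in the header.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, panel) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("id", "chrom", "bp", "allele1", "allele2")
  if (!all(meta %in% names(d)))
    stop("genotype file needs header columns: ", paste(meta, collapse = ", "))
  snps <- d[meta]
  snps$id <- as.character(snps$id)
  geno <- t(as.matrix(d[, setdiff(names(d), meta), drop = FALSE]))
  colnames(geno) <- snps$id
  genotype_matrix(geno, snps, panel)
}

# Subset a genotype matrix to a set of marker ids (order preserved).
subset_markers <- function(gm, keep_ids) {
  keep <- gm$snps$id %in% keep_ids
  genotype_matrix(gm$geno[, keep, drop = FALSE],
                  gm$snps[keep, , drop = FALSE], gm$panel)
}

qc_report_row <- function(filter, n_in, n_removed, params) {
  data.frame(filter = filter, n_in = as.integer(n_in),
             n_removed = as.integer(n_removed),
             n_out = as.integer(n_in - n_removed),
             params = params, stringsAsFactors = FALSE)
}

#' Remove strand-ambiguous markers
#'
#' Drops markers whose allele pair is A/T or C/G (order-insensitive). Such
#' markers read identically on both strands, so strand orientation cannot be
#' reconciled when merging array datasets genotyped on different platforms.
#'
#' @param gm a `genotype_matrix`, or a marker data.frame with `allele1` and
#'   `allele2` columns.
#' @return list with `kept` (same type as input), `removed` (marker IDs, or
#'   removed rows for a data.frame input) and a one-row `report`.
#' @export
drop_ambiguous_snps <- function(gm) {
  snps <- if (inherits(gm, "genotype_matrix")) gm$snps else gm
  if (!all(c("allele1", "allele2") %in% names(snps)))
    stop("marker table needs allele1 and allele2 columns")
  if (anyNA(snps$allele1) || anyNA(snps$allele2))
    stop("missing allele fields")
  pair <- paste(pmin(snps$allele1, snps$allele2),
                pmax(snps$allele1, snps$allele2))
  ambiguous <- pair %in% c("A T", "C G")
  report <- qc_report_row("ambiguous_alleles", nrow(snps), sum(ambiguous),
                          "pairs {A,T},{C,G}")
  if (inherits(gm, "genotype_matrix")) {
    list(kept = subset_markers(gm, snps$id[!ambiguous]),
         removed = snps$id[ambiguous], report = report)
  } else {
    list(kept = snps[!ambiguous, , drop = FALSE],
         removed = snps[ambiguous, , drop = FALSE], report = report)
  }
}

# Missing fraction per marker within each population: populations x markers.
population_missingness <- function(gm) {
  pops <- gm$panel$population[match(rownames(gm$geno), gm$panel$sample)]
  t(vapply(split(seq_len(nrow(gm$geno)), pops), function(idx) {
    colMeans(is.na(gm$geno[idx, , drop = FALSE]))
  }, numeric(ncol(gm$geno))))
}

#' Remove markers with high missingness in any population
#'
#' A marker is removed when its missing-genotype fraction strictly exceeds
#' `max_rate` in at least one population — markers badly typed in one source
#' dataset cause spurious structure after merging even when their overall
#' missingness is low.
#'
#' @param gm a `genotype_matrix`.
#' @param max_rate per-population missingness ceiling (default 0.20).
#' @return list with `kept` (`genotype_matrix`), `removed` (marker IDs),
#'   `report`.
#' @export
filter_population_missingness <- function(gm, max_rate = 0.20) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (max_rate < 0 || max_rate >= 1) stop("max_rate must lie in [0, 1)")
  pm <- population_missingness(gm)
  if (nrow(pm) == 0L) stop("panel assigns no populations")
  worst <- apply(pm, 2, max)
  drop <- worst > max_rate
  list(kept = subset_markers(gm, gm$snps$id[!drop]),
       removed = gm$snps$id[drop],
       report = qc_report_row("population_missingness", ncol(gm$geno),
                              sum(drop),
                              sprintf("max_rate=%g in any population",
                                      max_rate)))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' The exact conditional test for a biallelic marker: given the observed
#' allele counts, the probability of each possible heterozygote count under
#' random mating is computed exactly, and the p-value is the sum of the
#' probabilities of all configurations no more probable than the observed
#' one (two-sided). Preferred over the chi-squared approximation at the
#' extreme significance thresholds used in array QC.
#'
#' @param nAA,nAa,naa non-negative integer genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(nAA, nAa, naa) {
  counts <- c(nAA, nAa, naa)
  if (length(counts) != 3L || any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0L) stop("all genotype counts are zero")
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  nr <- min(nA, na)           # rare allele count
  hets <- seq(nr %% 2, nr, by = 2)
  # log P(het = h | allele counts) up to a constant:
  # n! / (nAA! h! naa!) * 2^h with nAA=(nA-h)/2, naa=(na-h)/2
  logp <- hets * log(2) - lfactorial((nA - hets) / 2) -
    lfactorial(hets) - lfactorial((na - hets) / 2)
  logp <- logp - max(logp)
  p <- exp(logp) / sum(exp(logp))
  obs <- p[match(nAa, hets)]
  sum(p[p <= obs * (1 + 1e-9)])
}

# Minor allele frequency and missing fraction per marker.
marker_stats <- function(gm) {
  g <- gm$geno
  nobs <- colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE)
  freq <- ifelse(nobs > 0, alt / (2 * nobs), NA_real_)
  data.frame(id = gm$snps$id,
             maf = pmin(freq, 1 - freq),
             missing = 1 - nobs / nrow(g),
             row.names = NULL)
}

#' Marker filters: MAF, Hardy-Weinberg, missingness
#'
#' Removes markers with minor allele frequency below `maf_min` (monomorphic
#' markers have MAF 0 and are removed), exact Hardy-Weinberg p-value below
#' `hwe_p_min`, or missing-genotype fraction strictly above `max_missing`.
#' A marker may fail several criteria; the report itemises each reason.
#'
#' @param gm a `genotype_matrix`.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_p_min minimum exact HWE p-value (default 1e-6).
#' @param max_missing maximum missing fraction (default 0.02).
#' @param per_population if `TRUE`, the HWE test is run within each
#'   population and a marker fails when any population falls below
#'   `hwe_p_min`; default tests the pooled sample.
#' @return list with `kept` (`genotype_matrix`), `removed` (marker IDs),
#'   `reasons` (data.frame id, fails_maf, fails_hwe, fails_missing) and
#'   `report` (one row per criterion plus the combined removal).
#' @export
filter_maf_hwe_missing <- function(gm, maf_min = 0.01, hwe_p_min = 1e-6,
                                   max_missing = 0.02,
                                   per_population = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  st <- marker_stats(gm)
  fails_maf <- is.na(st$maf) | st$maf < maf_min
  fails_missing <- st$missing > max_missing
  hwe_p_of <- function(g) {
    nAA <- sum(g == 0, na.rm = TRUE)
    nAa <- sum(g == 1, na.rm = TRUE)
    naa <- sum(g == 2, na.rm = TRUE)
    if (nAA + nAa + naa == 0L) return(1)
    hwe_exact_p(nAA, nAa, naa)
  }
  if (per_population) {
    pops <- gm$panel$population[match(rownames(gm$geno), gm$panel$sample)]
    fails_hwe <- apply(gm$geno, 2, function(g) {
      any(vapply(split(g, pops), hwe_p_of, numeric(1)) < hwe_p_min)
    })
  } else {
    fails_hwe <- apply(gm$geno, 2, hwe_p_of) < hwe_p_min
  }
  drop <- fails_maf | fails_hwe | fails_missing
  report <- rbind(
    qc_report_row("maf", ncol(gm$geno), sum(fails_maf),
                  sprintf("maf < %g", maf_min)),
    qc_report_row("hwe", ncol(gm$geno), sum(fails_hwe),
                  sprintf("exact p < %g%s", hwe_p_min,
                          if (per_population) " (per population)" else "")),
    qc_report_row("missingness", ncol(gm$geno), sum(fails_missing),
                  sprintf("missing > %g", max_missing)),
    qc_report_row("maf_hwe_missing_combined", ncol(gm$geno), sum(drop),
                  "union of the three criteria"))
  list(kept = subset_markers(gm, gm$snps$id[!drop]),
       removed = gm$snps$id[drop],
       reasons = data.frame(id = gm$snps$id, fails_maf = fails_maf,
                            fails_hwe = fails_hwe,
                            fails_missing = fails_missing,
                            row.names = NULL),
       report = report)
}

#' Windowed LD pruning
#'
#' Slides a `window`-marker window along each chromosome in steps of `step`
#' markers. Within a window, while any pair of retained markers has squared
#' Pearson genotype correlation above `r2_max` (pairwise-complete
#' observations), the pair with the highest r-squared is flagged and the
#' member with the higher missing rate is removed (ties broken by removing
#' the lexicographically later marker ID). Deterministic given the input
#' order, which must be sorted by (chromosome, bp).
#'
#' @param gm a `genotype_matrix` with markers sorted by chromosome and bp.
#' @param r2_max prune threshold on r-squared (default 0.8).
#' @param window window size in markers (default 50).
#' @param step step size in markers (default 5).
#' @return list with `kept` (`genotype_matrix`), `removed` (marker IDs),
#'   `report`.
#' @export
ld_prune <- function(gm, r2_max = 0.8, window = 50, step = 5) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (r2_max <= 0 || r2_max > 1) stop("r2_max must lie in (0, 1]")
  if (window < 2 || step < 1) stop("window must be >= 2 and step >= 1")
  snps <- gm$snps
  ord <- order(match(normalize_chrom(snps$chrom), autosome_labels()),
               snps$bp)
  if (!identical(ord, seq_len(nrow(snps))))
    stop("markers must be sorted by (chromosome, bp) before pruning")
  keep <- rep(TRUE, ncol(gm$geno))
  miss <- colMeans(is.na(gm$geno))
  chrom <- normalize_chrom(snps$chrom)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    starts <- seq(1L, max(1L, length(idx) - 1L), by = step)
    for (s in starts) {
      win <- idx[s:min(s + window - 1L, length(idx))]
      repeat {
        act <- win[keep[win]]
        if (length(act) < 2L) break
        r2 <- suppressWarnings(
          stats::cor(gm$geno[, act, drop = FALSE],
                     use = "pairwise.complete.obs")^2)
        r2[!is.finite(r2)] <- 0
        diag(r2) <- 0
        if (max(r2) <= r2_max) break
        hit <- which(r2 == max(r2), arr.ind = TRUE)
        hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
        i <- act[hit[1, 1]]; j <- act[hit[1, 2]]
        drop_ij <- if (miss[i] > miss[j]) i
          else if (miss[j] > miss[i]) j
          else if (snps$id[i] > snps$id[j]) i else j
        keep[drop_ij] <- FALSE
      }
      if (s + window - 1L >= length(idx)) break
    }
  }
  list(kept = subset_markers(gm, snps$id[keep]),
       removed = snps$id[!keep],
       report = qc_report_row("ld_prune", ncol(gm$geno), sum(!keep),
                              sprintf("r2 > %g, window %d, step %d",
                                      r2_max, window, step)))
}
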