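#' Bootstrap confidence interval for population-pair mean IBD
#'
#' Nonparametric bootstrap over individuals: each replicate draws `|A|`
#' individuals with replacement from group A and `|B|` from group B (up to
#' the original sample size of each group), recomputes the mean sharing
#' statistic over the resampled slot pairs, and the 95% interval is taken
#' from the 2.5% and 97.5% percentiles of the replicate distribution
#' (linear interpolation between order statistics). Duplicated draws are
#' treated as distinct slots; slot pairs holding the same original
#' individual (possible within a group) are dropped from the replicate
#' statistic, as is any pair excluded by the relatedness rule — exclusion is
#' applied within each replicate using the original pair fractions.
#'
#' @param samplesA,samplesB character vectors of sample IDs; identical sets
#'   give the within-group statistic.
#' @param pairs a `pair_sharing` table from [pair_totals()].
#' @param genome_length_cM genome length G in cM; defaults to the value
#'   recorded on `pairs`.
#' @param B number of bootstrap replicates (default 500).
#' @param seed integer seed; identical seed gives an identical result.
#' @param max_fraction relatedness exclusion threshold (see
#'   [exclude_related()]).
#' @param conf confidence level for the percentile interval.
#' @param label_a,label_b group labels recorded on the result.
#' @return A `bootstrap_result` (list) with the observed summary
#'   ([group_mean_ibd()]), `B`, `seed`, the replicate vectors
#'   `reps_mean_proportion` and `reps_mean_cM`, and fields `boot_mean`,
#'   `ci_lower`, `ci_upper` on the mean_proportion scale plus
#'   `boot_mean_cM`, `ci_lower_cM`, `ci_upper_cM` on the cM scale.
#' @export
bootstrap_group_pair <- function(samplesA, samplesB, pairs,
                                 genome_length_cM = attr(pairs,
                                                         "genome_length_cM"),
                                 B = 500L, seed = 1L,
                                 max_fraction = 0.40, conf = 0.95,
                                 label_a = "A", label_b = "B") {
  stopifnot(inherits(pairs, "pair_sharing"))
  if (B < 1L) stop("B must be >= 1")
  samplesA <- as.character(samplesA); samplesB <- as.character(samplesB)
  if (length(samplesA) == 0L || length(samplesB) == 0L)
    stop("sample groups must be non-empty")
  observed <- group_mean_ibd(samplesA, samplesB, pairs, genome_length_cM,
                             max_fraction, label_a, label_b)
  within <- setequal(samplesA, samplesB)
  if (within) samplesB <- samplesA
  pm <- pair_matrices(pairs, samplesA, samplesB, genome_length_cM)
  # validity of an (original a, original b) pairing: not the same individual,
  # not excluded as related
  valid <- pm$frac <= max_fraction
  if (within) diag(valid) <- FALSE
  nA <- length(samplesA); nB <- length(samplesB)
  reps_cM <- with_local_seed(seed, {
    vapply(seq_len(B), function(b) {
      ia <- sample.int(nA, nA, replace = TRUE)
      if (within) {
        sub_t <- pm$total[ia, ia, drop = FALSE]
        sub_v <- valid[ia, ia, drop = FALSE]
        sel <- upper.tri(sub_t)
        ok <- sub_v[sel]
        tt <- sub_t[sel]
      } else {
        ib <- sample.int(nB, nB, replace = TRUE)
        ok <- valid[ia, ib, drop = FALSE]
        tt <- pm$total[ia, ib, drop = FALSE]
      }
      n_ok <- sum(ok)
      if (n_ok == 0L) NA_real_ else sum(tt[ok]) / n_ok
    }, numeric(1))
  })
  if (anyNA(reps_cM))
    warning(sum(is.na(reps_cM)),
            " bootstrap replicate(s) had no retained pairs and were dropped")
  reps_cM <- reps_cM[!is.na(reps_cM)]
  reps_prop <- reps_cM / (4 * genome_length_cM)
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(reps_cM, c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(list(group_a = label_a, group_b = label_b,
                 observed = observed, B = as.integer(B),
                 seed = as.integer(seed), conf = conf,
                 reps_mean_cM = reps_cM,
                 reps_mean_proportion = reps_prop,
                 boot_mean_cM = mean(reps_cM),
                 ci_lower_cM = qs[1], ci_upper_cM = qs[2],
                 boot_mean = mean(reps_prop),
                 ci_lower = qs[1] / (4 * genome_length_cM),
                 ci_upper = qs[2] / (4 * genome_length_cM)),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(paste0("Bootstrap mean IBD, %s vs %s: observed %.4g ",
                     "(mean proportion), boot mean %.4g, %d%% CI ",
                     "[%.4g, %.4g], B = %d, seed = %d\n"),
              x$group_a, x$group_b, x$observed$mean_proportion,
              x$boot_mean, round(100 * x$conf), x$ci_lower, x$ci_upper,
              x$B, x$seed))
  invisible(x)
}

#' Bootstrap a focal group against several others
#'
#' One [bootstrap_group_pair()] per (focal, other) pair. Child seeds are
#' derived deterministically from the master seed and the pair of group
#' labels, so each pair's result is independent of the order in which the
#' other groups are listed.
#'
#' @param focal focal population label.
#' @param others character vector of comparison population labels.
#' @param pairs a `pair_sharing` table.
#' @param panel a `population_panel`.
#' @inheritParams bootstrap_group_pair
#' @return named list of `bootstrap_result`, one per element of `others`.
#' @export
bootstrap_panelwise <- function(focal, others, pairs, panel,
                                genome_length_cM = attr(pairs,
                                                        "genome_length_cM"),
                                B = 500L, seed = 1L, max_fraction = 0.40,
                                conf = 0.95) {
  stopifnot(inherits(panel, "population_panel"), length(others) >= 1)
  res <- lapply(others, function(other) {
    bootstrap_group_pair(panel_samples(panel, focal),
                         panel_samples(panel, other),
                         pairs, genome_length_cM, B,
                         seed = derive_seed(seed, focal, other),
                         max_fraction = max_fraction, conf = conf,
                         label_a = focal, label_b = other)
  })
  names(res) <- others
  res
}

#' Write bootstrap results as TSV
#' @param results a `bootstrap_result` or list of them.
#' @param path output path.
#' @export
write_bootstrap_results <- function(results, path) {
  if (inherits(results, "bootstrap_result")) results <- list(results)
  rows <- do.call(rbind, lapply(results, function(x) {
    data.frame(group_a = x$group_a, group_b = x$group_b, B = x$B,
               seed = x$seed,
               observed_mean_proportion = x$observed$mean_proportion,
               boot_mean = x$boot_mean,
               ci_lower = x$ci_lower, ci_upper = x$ci_upper)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Deterministic child seed from a master seed and labels: a polynomial
# rolling hash over the label characters, folded into [0, 2^31 - 2]. The
# label pair is sorted so (A,B) and (B,A) derive the same child seed.
derive_seed <- function(master, ...) {
  labels <- sort(as.character(c(...)))
  h <- as.numeric(master) %% 2147483647
  for (ch in utf8ToInt(paste(labels, collapse = "\r"))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

# Run code under a given seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
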