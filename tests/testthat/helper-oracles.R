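# Independent brute-force oracles. These deliberately share no code with the
# package internals: statistics are recomputed by explicit loops over
# enumerated pairs and raw segment scans.

# Sum of segment lengths for one unordered sample pair, scanning every row.
oracle_pair_total <- function(segs, a, b) {
  hit <- (segs$sample1 == a & segs$sample2 == b) |
    (segs$sample1 == b & segs$sample2 == a)
  list(total = sum(segs$length_cM[hit]), n = sum(hit))
}

# Group-pair summary by full pair enumeration.
oracle_group_summary <- function(segs, samplesA, samplesB, G,
                                 max_fraction = 0.40) {
  within <- setequal(samplesA, samplesB)
  pairs <- list()
  if (within) {
    ss <- sort(samplesA)
    for (i in seq_along(ss)) for (j in seq_along(ss)) if (i < j)
      pairs[[length(pairs) + 1L]] <- c(ss[i], ss[j])
  } else {
    for (a in samplesA) for (b in samplesB)
      pairs[[length(pairs) + 1L]] <- c(a, b)
  }
  tot <- nsg <- numeric(length(pairs))
  for (k in seq_along(pairs)) {
    o <- oracle_pair_total(segs, pairs[[k]][1], pairs[[k]][2])
    tot[k] <- o$total; nsg[k] <- o$n
  }
  keep <- tot / G <= max_fraction
  n_pairs <- sum(keep)
  mean_cM <- sum(tot[keep]) / n_pairs
  list(n_pairs = n_pairs, n_excluded = sum(!keep),
       mean_pairwise_cM = mean_cM,
       mean_proportion = mean_cM / (4 * G),
       prop_pairs_with_ibd = sum(nsg[keep] >= 1) / n_pairs)
}

# Exact HWE p-value by direct enumeration with plain factorials (valid for
# 2n <= 170); probability of het count h given allele counts, normalised.
oracle_hwe_p <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  hets <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  prob <- vapply(hets, function(h) {
    aa <- (nA - h) / 2; bb <- (na - h) / 2
    factorial(n) / (factorial(aa) * factorial(h) * factorial(bb)) *
      2^h * factorial(nA) * factorial(na) / factorial(2 * n)
  }, numeric(1))
  prob <- prob / sum(prob)
  obs <- prob[match(nAa, hets)]
  sum(prob[prob <= obs * (1 + 1e-9)])
}

# m nearest other-population neighbours per sample by explicit distance
# loops; returns the aggregated directed edge table.
oracle_network_edges <- function(coords, panel, K, m) {
  ids <- rownames(coords)
  pop <- panel$population[match(ids, panel$sample)]
  links <- list()
  for (i in seq_along(ids)) {
    dists <- rep(NA_real_, length(ids))
    for (j in seq_along(ids)) {
      if (pop[j] == pop[i]) next
      dists[j] <- sqrt(sum((coords[i, 1:K] - coords[j, 1:K])^2))
    }
    cand <- which(!is.na(dists))
    cand <- cand[order(dists[cand], ids[cand])]
    for (q in cand[seq_len(m)])
      links[[length(links) + 1L]] <- c(pop[i], pop[q])
  }
  d <- as.data.frame(do.call(rbind, links), stringsAsFactors = FALSE)
  names(d) <- c("from", "to")
  agg <- stats::aggregate(list(weight = rep(1L, nrow(d))),
                          by = list(from = d$from, to = d$to), FUN = sum)
  agg <- agg[order(agg$from, agg$to), ]
  rownames(agg) <- NULL
  agg$weight <- as.integer(agg$weight)
  agg
}

# Small fixture: a two-chromosome map with uneven rates.
fixture_map <- function() {
  genetic_map(data.frame(
    chrom = c("1", "1", "1", "2", "2"),
    bp = c(1e6, 2e6, 4e6, 5e5, 3e6),
    cM = c(1, 3, 4, 0, 5)))
}

# Small fixture: segment table builder.
fixture_segments <- function(rows, map) {
  d <- do.call(rbind, lapply(rows, function(r) {
    data.frame(sample1 = r[[1]], hap1 = as.integer(r[[2]]),
               sample2 = r[[3]], hap2 = as.integer(r[[4]]),
               chrom = r[[5]], start_bp = as.numeric(r[[6]]),
               end_bp = as.numeric(r[[7]]), lod = as.numeric(r[[8]]),
               stringsAsFactors = FALSE)
  }))
  segment_set(d, map)
}

# Random cohort simulated under the base model for oracle comparisons.
fixture_cohort <- function(pop_sizes, g = 20, lambda = 5, seed = 1,
                           map = synthetic_genetic_map()) {
  cfg <- sim_config(pop_sizes, g = g, lambda = lambda, map = map,
                    seed = seed)
  sim <- simulate_segments(cfg)
  segs <- filter_segments(sim$segments)
  list(segs = segs, panel = sim$panel, pairs = pair_totals(segs, sim$panel),
       G = map$genome_length_cM)
}
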