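#' Simulation configuration for synthetic IBD cohorts
#'
#' Defines the statistical structure of a synthetic cohort: population
#' sizes, the depth in generations `g(P,Q)` of the typical common ancestor
#' for pairs drawn from populations P and Q, and the expected number of
#' segments per pair `lambda(P,Q)`. Segment lengths follow the
#' recombination-clock law: a segment inherited from an ancestor `g`
#' generations back survives `2g` meioses, so its length is exponential
#' with mean `100 / (2 g)` cM.
#'
#' @param pop_sizes named integer vector: samples per population.
#' @param g symmetric positive matrix of common-ancestor depths in
#'   generations (rows/cols named by population), or a scalar used for all
#'   pairs.
#' @param lambda symmetric non-negative matrix of expected segment counts
#'   per sample pair, or a scalar.
#' @param map a [genetic_map()] to place segments on.
#' @param seed master seed recorded in the config.
#' @param ind_rate_sd standard deviation of per-individual multiplicative
#'   rate effects (Gamma distributed, mean 1). The default 0 gives the base
#'   model with iid pair counts; positive values add the individual-level
#'   heterogeneity in sharing propensity seen in real cohorts (families,
#'   villages), which is what resampling individuals in the bootstrap is
#'   designed to capture. Because the effects have mean 1 and individuals
#'   are independent, the expected pair count is still `lambda(P,Q)`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(pop_sizes, g, lambda,
                       map = synthetic_genetic_map(), seed = 1,
                       ind_rate_sd = 0) {
  stopifnot(inherits(map, "genetic_map"), length(pop_sizes) >= 1,
            !is.null(names(pop_sizes)), all(pop_sizes >= 1))
  pops <- names(pop_sizes)
  expand <- function(x, what, positive) {
    if (is.matrix(x)) {
      if (is.null(rownames(x))) dimnames(x) <- list(pops, pops)
      x <- x[pops, pops, drop = FALSE]
    } else {
      x <- matrix(x, length(pops), length(pops),
                  dimnames = list(pops, pops))
    }
    if (!isSymmetric(unname(x))) stop(what, " matrix must be symmetric")
    if (positive && any(x <= 0)) stop(what, " must be positive")
    if (!positive && any(x < 0)) stop(what, " must be non-negative")
    x
  }
  structure(list(pop_sizes = pop_sizes,
                 g = expand(g, "g", positive = TRUE),
                 lambda = expand(lambda, "lambda", positive = FALSE),
                 map = map, seed = seed, ind_rate_sd = ind_rate_sd),
            class = "sim_config")
}

# Sample IDs and panel for a config: P1_01, P1_02, ...
config_panel <- function(config, lon = NULL, lat = NULL) {
  pops <- names(config$pop_sizes)
  d <- do.call(rbind, lapply(pops, function(p) {
    n <- config$pop_sizes[[p]]
    data.frame(sample = sprintf("%s_%02d", p, seq_len(n)),
               population = p, stringsAsFactors = FALSE)
  }))
  if (!is.null(lon)) d$lon <- lon[d$population]
  if (!is.null(lat)) d$lat <- lat[d$population]
  population_panel(d)
}

#' Simulate IBD segments for a cohort
#'
#' For every unordered pair of distinct samples, the segment count is
#' Poisson with mean `lambda(P,Q)` (times the individual rate effects when
#' `ind_rate_sd > 0`), and each segment's length is exponential with mean
#' `100 / (2 g(P,Q))` cM. Segments are placed uniformly on the genome
#' (chromosome chosen proportional to its cM span), haplotype indices are
#' uniform, and LOD scores are drawn above 3 so the standard filters pass.
#' Identical config and seed give identical output.
#'
#' @param config a [sim_config()].
#' @return list with `segments` (a `segment_set`), `panel`
#'   (`population_panel`) and `truth` (generating parameters, including the
#'   per-individual rate effects and the expected mean segment length per
#'   population pair).
#' @export
simulate_segments <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  map <- config$map
  panel <- config_panel(config)
  ids <- panel$sample
  pop <- panel$population
  n <- length(ids)
  if (n < 2L) stop("need at least two samples to form pairs")
  spans <- chromosome_spans(map)
  with_local_seed(config$seed, {
    u <- if (config$ind_rate_sd > 0) {
      sh <- 1 / config$ind_rate_sd^2
      stats::setNames(stats::rgamma(n, shape = sh, rate = sh), ids)
    } else stats::setNames(rep(1, n), ids)
    ii <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    jj <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
    lam <- config$lambda[cbind(pop[ii], pop[jj])] * u[ii] * u[jj]
    cnt <- stats::rpois(length(lam), lam)
    if (sum(cnt) == 0L)
      stop("no segments generated; increase lambda")
    seg_pair <- rep(seq_along(cnt), cnt)
    gpair <- config$g[cbind(pop[ii], pop[jj])][seg_pair]
    len <- stats::rexp(length(seg_pair), rate = 2 * gpair / 100)
    ch_idx <- sample.int(nrow(spans), length(len), replace = TRUE,
                         prob = spans$span)
    lo <- spans$cM_start[ch_idx]
    hi <- spans$cM_end[ch_idx]
    start_cM <- lo + stats::runif(length(len)) * pmax(0, hi - lo - len)
    end_cM <- pmin(start_cM + len, hi)
    chrom <- spans$chrom[ch_idx]
    start_bp <- interpolate_bp(map, chrom, start_cM)
    end_bp <- pmax(interpolate_bp(map, chrom, end_cM), start_bp + 1)
    segs <- data.frame(sample1 = ids[ii][seg_pair],
                       hap1 = sample(1:2, length(len), replace = TRUE),
                       sample2 = ids[jj][seg_pair],
                       hap2 = sample(1:2, length(len), replace = TRUE),
                       chrom = chrom, start_bp = start_bp, end_bp = end_bp,
                       lod = 3 + stats::rexp(length(len), rate = 0.5),
                       stringsAsFactors = FALSE)
    list(segments = segment_set(segs, map, provenance = "simulate_segments"),
         panel = panel,
         truth = list(config = config, ind_effects = u,
                      mean_length_cM = 100 / (2 * config$g)))
  })
}

#' Relationship specification for close-relative simulation
#'
#' Expected haplotype-level genome-sharing fraction `f` and meiosis count
#' `m` for the four standard close relationships. Shared segments between
#' relatives separated by `m` meioses have exponential length with mean
#' `100 / m` cM; the expected total sharing (as a fraction of the genome
#' length G) is 1.0 for full siblings, 0.5 for half siblings and avuncular
#' pairs, and 0.25 for first cousins.
#'
#' @param type one of `"full_sib"`, `"half_sib"`, `"avuncular"`,
#'   `"first_cousin"`.
#' @return list with `type`, `f`, `meioses`.
#' @export
relationship_spec <- function(type = c("full_sib", "half_sib", "avuncular",
                                       "first_cousin")) {
  type <- match.arg(type)
  spec <- switch(type,
                 full_sib = list(f = 1.0, meioses = 2L),
                 half_sib = list(f = 0.5, meioses = 2L),
                 avuncular = list(f = 0.5, meioses = 3L),
                 first_cousin = list(f = 0.25, meioses = 4L))
  c(list(type = type), spec)
}

#' Simulate the IBD segments of one close-relative pair
#'
#' Draws segment lengths from the exponential law for the relationship's
#' meiosis count and lays them consecutively along the genome (splitting at
#' chromosome boundaries) until the total reaches `f x G`, truncating the
#' last segment, so the realised sharing fraction equals the relationship's
#' expectation exactly. This targets the expected fraction deterministically
#' — sufficient for testing the relatedness threshold — rather than
#' simulating meiosis.
#'
#' @param spec a [relationship_spec()] (or one of its type strings).
#' @param map a [genetic_map()].
#' @param seed integer seed.
#' @param sample_ids length-2 character vector of IDs for the pair.
#' @return A `segment_set` for the single pair.
#' @export
simulate_related_pair <- function(spec, map = synthetic_genetic_map(),
                                  seed = 1,
                                  sample_ids = c("REL_A", "REL_B")) {
  if (is.character(spec)) spec <- relationship_spec(spec)
  stopifnot(inherits(map, "genetic_map"), length(sample_ids) == 2L,
            sample_ids[1] != sample_ids[2])
  G <- map$genome_length_cM
  target <- spec$f * G
  if (target > G) stop("target sharing exceeds the genome length")
  spans <- chromosome_spans(map)
  offsets <- cumsum(c(0, spans$span))
  with_local_seed(seed, {
    lens <- numeric(0)
    while (sum(lens) < target) {
      lens <- c(lens, stats::rexp(max(16, ceiling(target * spec$meioses /
                                                    100)),
                                  rate = spec$meioses / 100))
    }
    over <- which(cumsum(lens) >= target)[1L]
    lens <- lens[seq_len(over)]
    lens[over] <- target - sum(lens[-over])
    lens <- lens[lens > 0]
    # consecutive placement on the concatenated genome, split at
    # chromosome boundaries
    ends <- cumsum(lens)
    starts <- ends - lens
    rows <- list()
    for (k in seq_along(lens)) {
      a <- starts[k]; b <- ends[k]
      while (a < b - 1e-12) {
        ci <- findInterval(a, offsets, rightmost.closed = TRUE)
        ci <- min(ci, nrow(spans))
        seg_end <- min(b, offsets[ci + 1L])
        rows[[length(rows) + 1L]] <-
          data.frame(chrom = spans$chrom[ci],
                     start_cM = spans$cM_start[ci] + (a - offsets[ci]),
                     end_cM = spans$cM_start[ci] + (seg_end - offsets[ci]))
        a <- seg_end
      }
    }
    d <- do.call(rbind, rows)
    start_bp <- interpolate_bp(map, d$chrom, d$start_cM)
    end_bp <- pmax(interpolate_bp(map, d$chrom, d$end_cM), start_bp + 1)
    segs <- data.frame(sample1 = sample_ids[1],
                       hap1 = sample(1:2, nrow(d), replace = TRUE),
                       sample2 = sample_ids[2],
                       hap2 = sample(1:2, nrow(d), replace = TRUE),
                       chrom = d$chrom, start_bp = start_bp,
                       end_bp = end_bp,
                       lod = 3 + stats::rexp(nrow(d), rate = 0.5),
                       stringsAsFactors = FALSE)
    segment_set(segs, map,
                provenance = paste0("simulate_related_pair:", spec$type))
  })
}

#' Simulate PCA coordinates with a geographic gradient
#'
#' The first component is a linear function of longitude plus Gaussian
#' noise (`PC1 = beta * lon + N(0, noise_sd^2)`); the remaining components
#' are pure Gaussian noise, optionally offset per population. Emulates the
#' east-west cline structure that makes the top component track longitude.
#'
#' @param panel a `population_panel` with a `lon` column.
#' @param K number of components (>= 2).
#' @param beta slope of the longitude gradient on PC1.
#' @param noise_sd standard deviation of the PC1 noise (>= 0).
#' @param seed integer seed.
#' @param other_sd standard deviation of the higher components.
#' @param cluster_sd if positive, each population also receives a Gaussian
#'   offset of this scale on components 2..K, creating population clusters.
#' @return list with `coords` (a [pca_coords()]) and `truth` (beta,
#'   noise_sd, and the analytic expected r-squared given the panel's
#'   longitudes).
#' @export
simulate_pca_coords <- function(panel, K = 3, beta = 1, noise_sd = 0.1,
                                seed = 1, other_sd = 1, cluster_sd = 0) {
  stopifnot(inherits(panel, "population_panel"), K >= 2)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!"lon" %in% names(panel)) stop("panel has no 'lon' column")
  n <- nrow(panel)
  with_local_seed(seed, {
    m <- matrix(stats::rnorm(n * K, sd = other_sd), n, K)
    m[, 1] <- beta * panel$lon + stats::rnorm(n, sd = noise_sd)
    if (cluster_sd > 0) {
      pops <- unique(panel$population)
      for (k in 2:K) {
        off <- stats::setNames(stats::rnorm(length(pops), sd = cluster_sd),
                               pops)
        m[, k] <- m[, k] + off[panel$population]
      }
    }
    rownames(m) <- panel$sample
    vx <- stats::var(panel$lon)
    list(coords = pca_coords(m),
         truth = list(beta = beta, noise_sd = noise_sd,
                      expected_r2 = if (noise_sd > 0)
                        beta^2 * vx / (beta^2 * vx + noise_sd^2) else 1))
  })
}

#' Simulate a genotype matrix with planted QC failures
#'
#' Background markers are drawn under Hardy-Weinberg equilibrium at
#' frequencies uniform in `maf_range` with no missingness. Disjoint planted
#' marker sets exercise each QC filter deterministically: strand-ambiguous
#' markers get A/T or C/G alleles; low-MAF markers carry exactly
#' `low_maf_count` copies of the minor allele; Hardy-Weinberg violators are
#' drawn with inbreeding coefficient `hwe_inbreeding` (heterozygote
#' deficit); per-population-missingness markers have exactly
#' `ceiling(pop_missing_rate x n)` missing entries in one population; LD
#' duplicates are exact copies of their left neighbour. The truth record
#' lists which markers should fail which filter.
#'
#' @param pop_sizes named integer vector of samples per population.
#' @param n_snps total marker count (including planted markers).
#' @param maf_range background allele-frequency range.
#' @param n_ambiguous,n_low_maf,n_hwe,n_pop_missing,n_ld_dup planted counts.
#' @param low_maf_count minor-allele copies at planted low-MAF markers.
#' @param hwe_inbreeding inbreeding coefficient of planted HWE violators.
#' @param pop_missing_rate missing fraction planted in the target
#'   population.
#' @param pop_missing_population population receiving the planted
#'   missingness (default: the first).
#' @param seed integer seed.
#' @return list with `gm` (a [genotype_matrix()]) and `truth` (marker ID
#'   sets `ambiguous`, `low_maf`, `hwe`, `pop_missing`, `ld_dup`).
#' @export
simulate_genotypes <- function(pop_sizes, n_snps,
                               maf_range = c(0.1, 0.45),
                               n_ambiguous = 0, n_low_maf = 0, n_hwe = 0,
                               n_pop_missing = 0, n_ld_dup = 0,
                               low_maf_count = 1, hwe_inbreeding = 0.8,
                               pop_missing_rate = 0.30,
                               pop_missing_population = names(pop_sizes)[1],
                               seed = 1) {
  stopifnot(!is.null(names(pop_sizes)), all(pop_sizes >= 1), n_snps >= 1)
  if (hwe_inbreeding < 0 || hwe_inbreeding > 1)
    stop("hwe_inbreeding must lie in [0, 1]")
  if (pop_missing_rate <= 0 || pop_missing_rate >= 1)
    stop("pop_missing_rate must lie in (0, 1)")
  n_planted <- n_ambiguous + n_low_maf + n_hwe + n_pop_missing + n_ld_dup
  if (n_planted > n_snps)
    stop("planted marker counts exceed n_snps")
  panel <- config_panel(list(pop_sizes = pop_sizes))
  n <- nrow(panel)
  with_local_seed(seed, {
    ids <- sprintf("M%05d", seq_len(n_snps))
    # chromosome blocks, bp increasing within: already sorted for pruning
    n_chr <- min(22L, n_snps)
    chrom <- as.character(rep(seq_len(n_chr),
                              length.out = n_snps)[order(rep(seq_len(n_chr),
                                                             length.out =
                                                               n_snps))])
    bp <- unlist(lapply(table(factor(chrom, levels = as.character(
      seq_len(n_chr)))), function(k) seq_len(k) * 10000))
    plain_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"),
                          ncol = 2, byrow = TRUE)
    pick <- plain_pairs[sample.int(4, n_snps, replace = TRUE), ,
                        drop = FALSE]
    snps <- data.frame(id = ids, chrom = chrom, bp = as.numeric(bp),
                       allele1 = pick[, 1], allele2 = pick[, 2],
                       stringsAsFactors = FALSE)
    # disjoint planted sets; LD duplicates must not sit at a chromosome
    # start (they copy their left neighbour)
    avail <- sample.int(n_snps)
    take <- function(k) {
      if (length(avail) < k) stop("not enough markers for planted sets")
      out <- avail[seq_len(k)]
      avail <<- avail[-seq_len(k)]
      sort(out)
    }
    idx_amb <- if (n_ambiguous > 0) take(n_ambiguous) else integer(0)
    idx_maf <- if (n_low_maf > 0) take(n_low_maf) else integer(0)
    idx_hwe <- if (n_hwe > 0) take(n_hwe) else integer(0)
    idx_pm <- if (n_pop_missing > 0) take(n_pop_missing) else integer(0)
    # duplicates must copy an unremarkable neighbour: not a chromosome
    # start, and the left neighbour not itself planted
    first_of_chrom <- !duplicated(chrom)
    planted <- c(idx_amb, idx_maf, idx_hwe, idx_pm)
    avail <- avail[!first_of_chrom[avail] &
                     !((avail - 1L) %in% planted)]
    idx_ld <- if (n_ld_dup > 0) take(n_ld_dup) else integer(0)
    p <- stats::runif(n_snps, maf_range[1], maf_range[2])
    geno <- matrix(stats::rbinom(n * n_snps, 2, rep(p, each = n)),
                   n, n_snps)
    # ambiguous alleles
    if (length(idx_amb) > 0) {
      amb_pairs <- matrix(c("A", "T", "C", "G"), ncol = 2, byrow = TRUE)
      sel <- amb_pairs[sample.int(2, length(idx_amb), replace = TRUE), ,
                       drop = FALSE]
      snps$allele1[idx_amb] <- sel[, 1]
      snps$allele2[idx_amb] <- sel[, 2]
    }
    # low MAF: exactly low_maf_count heterozygotes, rest reference
    for (j in idx_maf) {
      geno[, j] <- 0L
      geno[sample.int(n, low_maf_count), j] <- 1L
    }
    # HWE violation: heterozygote deficit at p = 0.5
    if (length(idx_hwe) > 0) {
      f <- hwe_inbreeding
      probs <- c(0.25 + f * 0.25, 0.5 * (1 - f), 0.25 + f * 0.25)
      for (j in idx_hwe)
        geno[, j] <- sample(0:2, n, replace = TRUE, prob = probs)
    }
    # per-population missingness: exact count in the target population
    if (length(idx_pm) > 0) {
      tgt <- which(panel$population == pop_missing_population)
      k <- ceiling(pop_missing_rate * length(tgt))
      for (j in idx_pm)
        geno[sample(tgt, k), j] <- NA_integer_
    }
    # LD duplicates: exact copy of the left neighbour
    for (j in idx_ld) geno[, j] <- geno[, j - 1L]
    rownames(geno) <- panel$sample
    colnames(geno) <- ids
    list(gm = genotype_matrix(geno, snps, panel),
         truth = list(ambiguous = ids[idx_amb], low_maf = ids[idx_maf],
                      hwe = ids[idx_hwe], pop_missing = ids[idx_pm],
                      ld_dup = ids[idx_ld], seed = seed))
  })
}
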