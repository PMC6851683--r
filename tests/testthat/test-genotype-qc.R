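make_gm <- function(geno, alleles = NULL, pops = NULL, chrom = NULL,
                    bp = NULL) {
  n <- nrow(geno); p <- ncol(geno)
  ids <- sprintf("M%03d", seq_len(p))
  rownames(geno) <- sprintf("S%03d", seq_len(n))
  colnames(geno) <- ids
  if (is.null(alleles))
    alleles <- matrix(rep(c("A", "G"), p), ncol = 2, byrow = TRUE)
  snps <- data.frame(id = ids,
                     chrom = if (is.null(chrom)) "1" else chrom,
                     bp = if (is.null(bp)) seq_len(p) * 1000 else bp,
                     allele1 = alleles[, 1], allele2 = alleles[, 2],
                     stringsAsFactors = FALSE)
  panel <- population_panel(data.frame(
    sample = rownames(geno),
    population = if (is.null(pops)) "P" else pops))
  genotype_matrix(geno, snps, panel)
}

test_that("ambiguous-allele removal is order-insensitive and exact", {
  geno <- matrix(rbinom(40, 2, 0.4), 10, 4)
  alleles <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("A", "G"))
  gm <- make_gm(geno, alleles)
  res <- drop_ambiguous_snps(gm)
  expect_equal(res$removed, c("M001", "M002", "M003"))
  expect_equal(colnames(res$kept$geno), "M004")
  expect_equal(res$report$n_in - res$report$n_removed, res$report$n_out)
  # data.frame input works too
  df <- data.frame(allele1 = c("A", "G"), allele2 = c("T", "A"))
  res2 <- drop_ambiguous_snps(df)
  expect_equal(nrow(res2$kept), 1)
  expect_error(drop_ambiguous_snps(data.frame(allele1 = NA_character_,
                                              allele2 = "A")),
               "missing allele")
})

test_that("per-population missingness uses a strict 20% boundary", {
  # 10 samples in each of two populations; marker 1: 30% missing in P only;
  # marker 2: exactly 20% everywhere; marker 3: fully observed
  geno <- matrix(1L, 20, 3)
  geno[1:3, 1] <- NA                 # 3/10 in P
  geno[1:2, 2] <- NA; geno[11:12, 2] <- NA   # 2/10 in both
  gm <- make_gm(geno, pops = rep(c("P", "Q"), each = 10))
  res <- filter_population_missingness(gm, max_rate = 0.20)
  expect_equal(res$removed, "M001")
  expect_equal(colnames(res$kept$geno), c("M002", "M003"))
  expect_error(filter_population_missingness(gm, max_rate = 1.5), "max_rate")
})

test_that("exact HWE test matches enumeration and is label-symmetric", {
  expect_equal(hwe_exact_p(25, 50, 25), 1)
  # spot values against the independent factorial oracle
  cases <- list(c(0, 50, 0), c(5, 0, 5), c(10, 5, 30), c(1, 1, 1),
                c(0, 1, 20), c(17, 2, 3), c(8, 24, 18))
  for (cs in cases) {
    expect_equal(hwe_exact_p(cs[1], cs[2], cs[3]),
                 oracle_hwe_p(cs[1], cs[2], cs[3]), tolerance = 1e-12)
    # swapping homozygote labels leaves p unchanged
    expect_equal(hwe_exact_p(cs[1], cs[2], cs[3]),
                 hwe_exact_p(cs[3], cs[2], cs[1]))
    p <- hwe_exact_p(cs[1], cs[2], cs[3])
    expect_gt(p, 0); expect_lte(p, 1)
  }
  expect_error(hwe_exact_p(0, 0, 0), "zero")
  expect_error(hwe_exact_p(-1, 2, 3), "non-negative")
})

test_that("MAF / HWE / missingness filter itemises reasons", {
  set.seed(42)
  n <- 100
  g_ok <- rbinom(n, 2, 0.3)
  g_rare <- c(1L, rep(0L, n - 1))                 # minor count 1: MAF 0.005
  g_hwe <- rep(c(0L, 2L), n / 2)                  # no heterozygotes
  g_miss <- g_ok; g_miss[1:3] <- NA               # 3% missing
  gm <- make_gm(cbind(g_ok, g_rare, g_hwe, g_miss))
  res <- filter_maf_hwe_missing(gm)
  expect_equal(sort(res$removed), c("M002", "M003", "M004"))
  expect_true(res$reasons$fails_maf[2])
  expect_true(res$reasons$fails_hwe[3])
  expect_true(res$reasons$fails_missing[4])
  expect_false(any(unlist(res$reasons[1, -1])))
  comb <- res$report[res$report$filter == "maf_hwe_missing_combined", ]
  expect_equal(comb$n_out, 1L)
  # monomorphic marker: MAF 0, removed, not an error
  gm0 <- make_gm(cbind(g_ok, rep(0L, n)))
  expect_true("M002" %in% filter_maf_hwe_missing(gm0)$removed)
  # balanced heterozygote counts are retained on the HWE criterion
  g_bal <- c(rep(0L, 25), rep(1L, 50), rep(2L, 25))
  gm1 <- make_gm(cbind(g_bal))
  expect_false(filter_maf_hwe_missing(gm1)$reasons$fails_hwe[1])
})

test_that("LD pruning removes one of any over-threshold pair", {
  set.seed(7)
  n <- 60
  base <- rbinom(n, 2, 0.4)
  geno <- cbind(base, base, rbinom(n, 2, 0.4), rbinom(n, 2, 0.4))
  gm <- make_gm(geno)
  res <- ld_prune(gm, r2_max = 0.8, window = 50, step = 5)
  expect_equal(length(res$removed), 1)       # exactly one of the twins
  expect_true(res$removed %in% c("M001", "M002"))
  # independent markers survive a prune untouched
  geno2 <- matrix(rbinom(n * 5, 2, 0.4), n, 5)
  gm2 <- make_gm(geno2)
  r2mat <- suppressWarnings(stats::cor(geno2)^2)
  if (max(r2mat[upper.tri(r2mat)]) < 0.8)
    expect_equal(length(ld_prune(gm2)$removed), 0)
  # unsorted markers are refused
  gm_bad <- make_gm(geno, bp = c(4000, 1000, 2000, 3000))
  expect_error(ld_prune(gm_bad), "sorted")
})

test_that("post-prune windows contain no pair above the threshold", {
  set.seed(19)
  n <- 80; p <- 100
  geno <- matrix(0L, n, p)
  geno[, 1] <- rbinom(n, 2, 0.4)
  for (j in 2:p) {
    # markov chain over markers: neighbours correlated, distance decays
    flip <- runif(n) < 0.35
    geno[, j] <- ifelse(flip, rbinom(n, 2, 0.4), geno[, j - 1])
  }
  gm <- make_gm(geno)
  res <- ld_prune(gm, r2_max = 0.8, window = 20, step = 5)
  kept <- res$kept$geno
  # exhaustive within-window scan of the retained panel
  for (s in seq(1, ncol(kept) - 1, by = 5)) {
    win <- s:min(s + 19, ncol(kept))
    if (length(win) < 2) next
    r2 <- suppressWarnings(stats::cor(kept[, win])^2)
    diag(r2) <- 0
    r2[!is.finite(r2)] <- 0
    expect_lte(max(r2), 0.8)
  }
})

test_that("genotype text files round-trip", {
  set.seed(3)
  sg <- simulate_genotypes(c(P = 12, Q = 8), 30, n_ambiguous = 3,
                           n_pop_missing = 2, seed = 5)
  f <- file.path(tempdir(), "geno.tsv")
  write_genotypes(sg$gm, f)
  back <- read_genotypes(f, sg$gm$panel)
  expect_equal(back$geno, sg$gm$geno)
  expect_equal(back$snps$allele1, sg$gm$snps$allele1)
})
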