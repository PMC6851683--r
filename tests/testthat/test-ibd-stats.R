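test_that("pair totals sum segment lengths per unordered pair", {
  gm <- fixture_map()
  segs <- fixture_segments(list(
    list("A", 1, "B", 2, "1", 1000000, 2500000, 5.0),   # 2.333.. cM
    list("B", 1, "A", 1, "2", 500000, 1500000, 4.0),    # 2 cM, same pair
    list("B", 1, "C", 1, "1", 1000000, 2000000, 7.5)), gm)
  panel <- population_panel(data.frame(sample = c("A", "B", "C"),
                                       population = c("P", "P", "Q")))
  pt <- pair_totals(segs, panel)
  ab <- pt[pt$sample1 == "A" & pt$sample2 == "B", ]
  expect_equal(ab$n_segments, 2L)
  expect_equal(ab$total_cM, segs$length_cM[1] + segs$length_cM[2])
  expect_equal(nrow(pt), 2)        # pair (A,C) has no segments: implicit zero
  expect_error(pair_totals(segs, population_panel(
    data.frame(sample = c("A", "B"), population = "P"))), "absent")
})

test_that("pair totals match a brute-force scan on a random cohort", {
  co <- fixture_cohort(c(P = 3, Q = 2), seed = 21)
  ids <- co$panel$sample
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    o <- oracle_pair_total(co$segs, ids[i], ids[j])
    row <- co$pairs[co$pairs$sample1 == min(ids[i], ids[j]) &
                      co$pairs$sample2 == max(ids[i], ids[j]), ]
    if (o$n == 0) {
      expect_equal(nrow(row), 0)
    } else {
      expect_equal(row$total_cM, o$total)
      expect_equal(row$n_segments, o$n)
    }
  }
})

test_that("relatedness exclusion is strict at the threshold", {
  G <- 1000
  pt <- structure(data.frame(sample1 = c("a", "c", "e"),
                             sample2 = c("b", "d", "f"),
                             total_cM = c(410, 400, 100),
                             n_segments = c(4L, 4L, 1L),
                             sharing_fraction = c(0.41, 0.40, 0.10)),
                  genome_length_cM = G,
                  class = c("pair_sharing", "data.frame"))
  res <- exclude_related(pt, G, max_fraction = 0.40)
  expect_equal(res$n_excluded, 1)                 # 0.41 out
  expect_equal(res$excluded$sample1, "a")
  expect_true("c" %in% res$retained$sample1)      # 0.40 exactly stays
  expect_error(exclude_related(pt, G, max_fraction = 0), "0, 1")
  expect_error(exclude_related(pt, G, max_fraction = 1.2), "0, 1")
})

test_that("single retained pair reproduces the closed-form statistic", {
  G <- 3500
  gm <- genetic_map(data.frame(chrom = "1", bp = c(0, 3.5e9),
                               cM = c(0, G)))
  segs <- fixture_segments(list(list("a", 1, "b", 1, "1", 0 + 1, 5e6 + 1,
                                     5.0)), gm)
  panel <- population_panel(data.frame(sample = c("a", "b"),
                                       population = c("A", "B")))
  pt <- pair_totals(segs, panel)
  s <- group_mean_ibd("a", "b", pt, G, label_a = "A", label_b = "B")
  expect_equal(s$mean_pairwise_cM, 5.0)
  expect_equal(s$mean_proportion, 5 / (4 * 3500))
  expect_equal(s$prop_pairs_with_ibd, 1.0)
  expect_equal(s$n_pairs, 1L)
})

test_that("group statistic enumerates the right pairs and is symmetric", {
  co <- fixture_cohort(c(P = 3, Q = 4), seed = 5)
  within <- group_mean_ibd(panel_samples(co$panel, "P"),
                           panel_samples(co$panel, "P"), co$pairs, co$G)
  expect_equal(within$n_pairs + within$n_excluded, 3L)   # 3*2/2
  cross <- group_mean_ibd(panel_samples(co$panel, "P"),
                          panel_samples(co$panel, "Q"), co$pairs, co$G)
  expect_equal(cross$n_pairs + cross$n_excluded, 12L)
  flipped <- group_mean_ibd(panel_samples(co$panel, "Q"),
                            panel_samples(co$panel, "P"), co$pairs, co$G)
  for (f in c("n_pairs", "mean_pairwise_cM", "mean_proportion",
              "prop_pairs_with_ibd"))
    expect_equal(cross[[f]], flipped[[f]])
  # mean_proportion is always mean_pairwise_cM / 4G
  expect_equal(cross$mean_proportion,
               cross$mean_pairwise_cM / (4 * co$G))
  expect_error(group_mean_ibd(character(0), "x", co$pairs, co$G),
               "non-empty")
})

test_that("group statistics equal the brute-force oracle", {
  co <- fixture_cohort(c(P = 5, Q = 4, R = 3), seed = 33)
  for (pair in list(c("P", "P"), c("P", "Q"), c("Q", "R"), c("R", "R"))) {
    got <- group_mean_ibd(panel_samples(co$panel, pair[1]),
                          panel_samples(co$panel, pair[2]),
                          co$pairs, co$G,
                          label_a = pair[1], label_b = pair[2])
    want <- oracle_group_summary(co$segs, panel_samples(co$panel, pair[1]),
                                 panel_samples(co$panel, pair[2]), co$G)
    expect_equal(got$n_pairs, want$n_pairs)
    expect_equal(got$mean_pairwise_cM, want$mean_pairwise_cM,
                 tolerance = 1e-12)
    expect_equal(got$mean_proportion, want$mean_proportion,
                 tolerance = 1e-12)
    expect_equal(got$prop_pairs_with_ibd, want$prop_pairs_with_ibd)
  }
})

test_that("zero-sharing groups give zero means, empty groups error", {
  gm <- fixture_map()
  segs <- fixture_segments(list(list("A", 1, "B", 1, "1", 1000000,
                                     2000000, 5.0)), gm)
  panel <- population_panel(data.frame(sample = c("A", "B", "C", "D"),
                                       population = c("P", "P", "Q", "Q")))
  pt <- pair_totals(segs, panel)
  s <- group_mean_ibd(panel_samples(panel, "Q"), panel_samples(panel, "Q"),
                      pt, gm$genome_length_cM)
  expect_equal(s$mean_pairwise_cM, 0)
  expect_equal(s$prop_pairs_with_ibd, 0)
})

test_that("region pooling equals the pooled-group statistic", {
  co <- fixture_cohort(c(P1 = 4, P2 = 3, Q = 5), seed = 77)
  pooled <- region_pooled_mean_ibd(list(EU = c("P1", "P2"), Other = "Q"),
                                   co$pairs, co$panel, co$G)
  # degenerate pooling: one region = one population
  qq <- pooled[pooled$group_a == "Other" & pooled$group_b == "Other", ]
  direct <- group_mean_ibd(panel_samples(co$panel, "Q"),
                           panel_samples(co$panel, "Q"), co$pairs, co$G)
  expect_equal(qq$mean_pairwise_cM, direct$mean_pairwise_cM)
  # pooled cross statistic equals the pair-count-weighted combination
  euq <- pooled[pooled$group_a == "EU" & pooled$group_b == "Other", ]
  p1q <- group_mean_ibd(panel_samples(co$panel, "P1"),
                        panel_samples(co$panel, "Q"), co$pairs, co$G)
  p2q <- group_mean_ibd(panel_samples(co$panel, "P2"),
                        panel_samples(co$panel, "Q"), co$pairs, co$G)
  expect_equal(euq$mean_pairwise_cM * euq$n_pairs,
               p1q$mean_pairwise_cM * p1q$n_pairs +
                 p2q$mean_pairwise_cM * p2q$n_pairs,
               tolerance = 1e-12)
  # oracle equivalence of the pooled statistic
  want <- oracle_group_summary(co$segs,
                               panel_samples(co$panel, c("P1", "P2")),
                               panel_samples(co$panel, "Q"), co$G)
  expect_equal(euq$mean_proportion, want$mean_proportion, tolerance = 1e-12)
  expect_error(region_pooled_mean_ibd(list(A = "P1", B = "P1"),
                                      co$pairs, co$panel, co$G),
               "more than one region")
  expect_error(region_pooled_mean_ibd(list(A = character(0)),
                                      co$pairs, co$panel, co$G), "empty")
})

test_that("heat-map matrix is log10, symmetric, ordered and masked", {
  mk <- function(a, b, mp)
    structure(data.frame(group_a = a, group_b = b, n_pairs = 1L,
                         n_excluded = 0L, mean_pairwise_cM = mp * 4000,
                         mean_proportion = mp, prop_pairs_with_ibd = 1),
              class = c("sharing_summary", "data.frame"))
  s <- do.call(rbind, list(mk("X", "X", 1e-3), mk("X", "Y", 1e-4),
                           mk("Y", "Y", 0)))
  class(s) <- c("sharing_summary", "data.frame")
  hm <- heatmap_matrix(s, c("X", "Y"))
  expect_equal(hm["X", "X"], -3)
  expect_equal(hm["X", "Y"], -4)
  expect_equal(hm["Y", "X"], -4)
  expect_true(is.na(hm["Y", "Y"]))            # zero sharing is masked
  hm2 <- heatmap_matrix(s, c("Y", "X"))       # permuted ordering
  expect_equal(hm2["X", "Y"], hm["X", "Y"])
  expect_equal(rownames(hm2), c("Y", "X"))
  expect_error(heatmap_matrix(s, c("X", "Y", "Z")), "missing summary")
  # rendering runs headless onto a null device
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot_ibd_heatmap(hm))
})

test_that("retained-pair bound caps the mean proportion at 0.10", {
  gm <- synthetic_genetic_map()
  co <- fixture_cohort(c(P = 5, Q = 5), seed = 13, map = gm)
  # add a near-sibling pair; it must be excluded, keeping the bound
  rel <- simulate_related_pair("full_sib", gm, seed = 2,
                               sample_ids = c("P_01", "Q_01"))
  all_segs <- segment_set(rbind(as.data.frame(co$segs)[1:8],
                                as.data.frame(rel)[1:8]), gm)
  pt <- pair_totals(filter_segments(all_segs), co$panel)
  s <- group_mean_ibd(panel_samples(co$panel, "P"),
                      panel_samples(co$panel, "Q"), pt, co$G)
  expect_equal(s$n_excluded, 1L)
  expect_lte(s$mean_proportion, 0.10)
})

test_that("summary TSV writer round-trips", {
  co <- fixture_cohort(c(P = 3, Q = 3), seed = 9)
  s <- population_mean_ibd(co$pairs, co$panel)
  f <- file.path(tempdir(), "summary.tsv")
  write_sharing_summary(s, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(s))
  expect_equal(back$mean_proportion, s$mean_proportion, tolerance = 1e-12)
})
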