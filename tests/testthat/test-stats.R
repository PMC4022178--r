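mk_summary <- function(genome_id, n_genes, group_sizes,
                       min_ids = rep(0.95, length(group_sizes))) {
  g <- length(group_sizes)
  data.frame(
    genome_id = genome_id, n_genes = n_genes,
    n_synologs = sum(group_sizes), n_groups = g,
    synolog_fraction = 100 * sum(group_sizes) / n_genes,
    mean_pair_identity = if (g > 0) 95 else NA_real_,
    n_high_identity_groups = if (g > 0) sum(min_ids >= 0.90) else 0L,
    subcategory_group_counts = I(list(integer(0))),
    stringsAsFactors = FALSE)
}

test_that("per-genome counts follow their definitions", {
  gen <- generate_genome(synthetic_design(
    n_background = 63, length_range = c(100, 200),
    planted_groups = list(list(size = 3), list(size = 2), list(size = 2)),
    rng_seed = 12))
  scan <- detect_synologs(gen$records,
                          detection_config("denovo", prescreen = TRUE))
  s <- scan$summary
  expect_equal(s$n_genes, 70L)
  expect_equal(s$n_synologs, 7L)
  expect_equal(s$n_groups, 3L)
  expect_equal(s$synolog_fraction, 10.0)
  expect_lte(s$n_groups, s$n_synologs / 2)

  # no groups
  empty <- summarize_genome(scan$groups[0, ], scan$records)
  expect_equal(empty$n_synologs, 0L)
  expect_equal(empty$n_groups, 0L)
  expect_equal(empty$synolog_fraction, 0)

  expect_error(summarize_genome(scan$groups, scan$records[0, ]), "scope")
})

test_that("summary counts on the standard fixture equal generator truth", {
  gen <- generate_genome(standard_fixture_design(rng_seed = 19))
  scan <- detect_synologs(gen$records,
                          detection_config("denovo", prescreen = TRUE))
  truth <- gen$truth
  planted <- truth[truth$role != "background" & !truth$is_truncated, ]
  expect_equal(scan$summary$n_genes, nrow(truth))
  expect_equal(scan$summary$n_synologs, nrow(planted))
  expect_equal(scan$summary$n_groups, length(unique(planted$role)))
  expect_equal(scan$summary$synolog_fraction,
               100 * nrow(planted) / nrow(truth))
  # per-subcategory group counts equal the design matrix
  truth_counts <- table(vapply(split(planted$subcategory, planted$role),
                               unique, character(1)))
  got <- scan$summary$subcategory_group_counts[[1]]
  expect_equal(got[sort(names(truth_counts))],
               c(truth_counts)[sort(names(truth_counts))])
})

test_that("median and unscaled MAD match hand-checked cases", {
  expect_equal(median_mad(5), c(median = 5, mad = 0))
  expect_equal(median_mad(c(1, 2, 3, 4, 100)), c(median = 3, mad = 1))
  expect_equal(median_mad(c(20, 20, 33, 7, 46)), c(median = 20, mad = 13))
  expect_error(median_mad(numeric(0)), "non-empty")
})

test_that("median/MAD agree with a sort-based oracle on random lists", {
  set.seed(33)
  for (k in 1:200) {
    x <- switch(sample(3, 1),
                rpois(sample(1:40, 1), 20),
                rnorm(sample(2:50, 1)),
                sample(0:5, sample(1:20, 1), replace = TRUE))
    expect_equal(median_mad(x), ref_median_mad(x))
  }
})

test_that("the outlier threshold is median + 2 x MAD", {
  expect_equal(outlier_threshold(20.0, 13.0), 46.0)
  expect_equal(outlier_threshold(30.0, 9.7), 49.4)
  expect_equal(outlier_threshold(0, 0), 0)
  expect_error(outlier_threshold(5, -1))
})

test_that("linear R-squared equals squared Pearson correlation", {
  x <- c(1, 4, 2, 8, 5)
  expect_equal(linear_r2(x, 2 * x + 1), 1.0)
  # hand oracle: cov^2 / (var x * var y) on a fixed 5-point set
  y <- c(2, 3, 9, 7, 1)
  hand <- (sum((x - mean(x)) * (y - mean(y))))^2 /
    (sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(linear_r2(x, y), hand)
  expect_error(linear_r2(rep(3, 5), y), "constant")
  expect_error(linear_r2(x, y[1:3]), "length")

  # independent permutations: R^2 near zero for most seeds
  set.seed(55)
  r2 <- replicate(40, {
    v <- rnorm(1000)
    linear_r2(v, sample(v))
  })
  expect_gte(mean(r2 < 0.05), 0.95)
})

test_that("cohort aggregation reproduces share and threshold bookkeeping", {
  one <- cohort_summarize(mk_summary("g1", 100, c(2, 3)))
  expect_equal(one$metrics$n_groups$median, 2)
  expect_equal(one$metrics$n_groups$mad, 0)
  expect_equal(one$metrics$n_groups$min, one$metrics$n_groups$max)
  expect_equal(one$zero_synolog_share, 0)

  # cohort shaped like the published one: 46 of 943 genomes without synologs,
  # 374 of 943 with at least one high-identity group
  set.seed(77)
  rows <- lapply(seq_len(943), function(i) {
    if (i <= 46) mk_summary(paste0("g", i), 100, integer(0))
    else mk_summary(paste0("g", i), 100, c(2, 2),
                    min_ids = if (i <= 46 + 374) c(0.95, 0.95)
                              else c(0.5, 0.5))
  })
  cohort <- cohort_summarize(do.call(rbind, rows))
  expect_equal(cohort$zero_synolog_share, 4.9)
  nearest <- cohort_summarize(do.call(rbind, rows), share_digits = 0)
  expect_equal(nearest$high_identity_share, 40)

  # permutation invariance of cohort medians/MADs
  perm <- cohort_summarize(do.call(rbind, rows[sample(943)]))
  expect_equal(perm$metrics, cohort$metrics)
  expect_equal(perm$zero_synolog_share, cohort$zero_synolog_share)
})

test_that("percentile ranks order genomes by group count and fraction", {
  rows <- do.call(rbind, list(mk_summary("low", 100, integer(0)),
                              mk_summary("mid", 100, c(2, 2)),
                              mk_summary("high", 100, c(2, 2, 2, 2))))
  cohort <- cohort_summarize(rows)
  ranks <- cohort$genome_ranks
  expect_equal(ranks$percentile_by_groups[ranks$genome_id == "high"], 100)
  expect_lt(ranks$percentile_by_groups[ranks$genome_id == "low"],
            ranks$percentile_by_groups[ranks$genome_id == "mid"])
})

test_that("size-2 groups force S = 2G and a perfect count/group correlation", {
  set.seed(41)
  rows <- do.call(rbind, lapply(1:12, function(i) {
    mk_summary(paste0("g", i), 200, rep(2, sample(0:8, 1)))
  }))
  expect_true(all(rows$n_synologs == 2 * rows$n_groups))
  cohort <- cohort_summarize(rows)
  expect_equal(cohort$r2_pairs$synologs_vs_groups, 1.0)
})

test_that("groups inherit the majority subcategory, ties lexicographic, unlabeled none", {
  groups <- data.frame(
    genome_id = "gx",
    group_id = c("g1", "g1", "g1", "g2", "g2", "g3", "g3"),
    gene_id = paste0("x", 1:7),
    family_id = NA_character_,
    subcategory = c("A", "A", "B", "B", "A", NA, NA),
    min_identity = 0.95, mean_identity = 0.97,
    stringsAsFactors = FALSE)
  counts <- subcategory_breakdown(groups)
  expect_equal(counts, c(A = 2L, none = 1L))  # g2 ties A/B -> A
  expect_equal(sum(counts), 3L)
  expect_equal(subcategory_breakdown(groups[0, ]), integer(0))
})
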