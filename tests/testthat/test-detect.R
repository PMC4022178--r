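fixture_config <- function(...) detection_config("denovo", prescreen = TRUE, ...)

small_design <- function(seed, n_background = 30, groups = 3)
  synthetic_design(
    n_background = n_background,
    length_range = c(100, 200),
    planted_groups = rep(list(list(size = 2, target_identity = 0.97)),
                         groups),
    rng_seed = seed)

test_that("severely truncated family members are flagged against the family median", {
  rec <- data.frame(
    gene_id = c("a", "b", "c"), genome_id = "gx", contig = "c1",
    start = c(1L, 1000L, 2000L), end = c(903L, 1909L, 2123L),
    strand = "+", family_id = "f1", category = NA_character_,
    subcategory = NA_character_,
    sequence = c(random_seq(300), random_seq(302), random_seq(40)),
    stringsAsFactors = FALSE)
  out <- filter_truncated(rec, detection_config("family"))
  expect_equal(out$flagged, "c")
  expect_equal(out$kept$gene_id, c("a", "b"))

  # all members equal length: none flagged
  rec$sequence <- replicate(3, random_seq(200))
  expect_equal(filter_truncated(rec, detection_config("family"))$flagged,
               character(0))

  # de novo mode passes records through (coverage rule handles truncation)
  out <- filter_truncated(rec, detection_config("denovo"))
  expect_equal(nrow(out$kept), 3L)
})

test_that("planted fragment copies are exactly the genes the family filter flags", {
  for (seed in c(2, 9)) {
    gen <- generate_genome(standard_fixture_design(rng_seed = seed))
    out <- filter_truncated(gen$records, detection_config("family"))
    expect_equal(sort(out$flagged),
                 sort(gen$truth$gene_id[gen$truth$is_truncated]))
  }
})

test_that("unrelated random proteins yield no candidate pairs", {
  set.seed(21)
  rec <- data.frame(
    gene_id = sprintf("g%02d", 1:5), genome_id = "gx", contig = "c1",
    start = seq(1L, by = 400L, length.out = 5),
    end = seq(303L, by = 400L, length.out = 5),
    strand = "+", family_id = NA_character_, category = NA_character_,
    subcategory = NA_character_,
    sequence = replicate(5, random_seq(100)), stringsAsFactors = FALSE)
  expect_equal(nrow(candidate_pairs(rec, detection_config("denovo"))), 0L)

  # two identical genes -> exactly one passing pair at identity 1
  rec$sequence[2] <- rec$sequence[1]
  pairs <- candidate_pairs(rec, detection_config("denovo"))
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$gene_a, "g01")
  expect_equal(pairs$gene_b, "g02")
  expect_equal(pairs$identity, 1.0)
})

test_that("a planted triple yields all three pairwise hits", {
  design <- synthetic_design(
    n_background = 50, length_range = c(100, 200),
    planted_groups = list(list(size = 3, target_identity = 0.98)),
    rng_seed = 31)
  gen <- generate_genome(design)
  pairs <- candidate_pairs(gen$records, detection_config("denovo"))
  expect_equal(nrow(pairs), 3L)
  members <- gen$truth$gene_id[gen$truth$role == "grp01"]
  expect_setequal(unique(c(pairs$gene_a, pairs$gene_b)), members)
})

test_that("groups are single-linkage connected components", {
  rec <- data.frame(
    gene_id = c("a", "b", "c", "d"), genome_id = "gx", contig = "c1",
    start = c(1L, 100L, 200L, 300L), end = c(50L, 150L, 250L, 350L),
    strand = "+", family_id = NA_character_, category = NA_character_,
    subcategory = NA_character_, sequence = "ACDEF",
    stringsAsFactors = FALSE)
  pairs <- data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                      identity = c(0.95, 0.92), stringsAsFactors = FALSE)
  grp <- build_groups(pairs, rec)
  expect_equal(length(unique(grp$group_id)), 1L)
  expect_setequal(grp$gene_id, c("a", "b", "c"))  # transitivity, no (a,c) edge
  expect_equal(unique(grp$min_identity), 0.92)
  expect_equal(unique(grp$mean_identity), mean(c(0.95, 0.92)))

  expect_equal(nrow(build_groups(pairs[0, ], rec)), 0L)
})

test_that("identical inputs produce byte-identical group tables", {
  gen <- generate_genome(standard_fixture_design(rng_seed = 13))
  f1 <- tempfile(); f2 <- tempfile()
  write_groups(detect_synologs(gen$records, fixture_config())$groups, f1)
  write_groups(detect_synologs(gen$records, fixture_config())$groups, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("raising the identity threshold never increases synolog or group counts", {
  for (seed in 1:3) {
    gen <- generate_genome(small_design(seed))
    hits <- align_all_pairs(gen$records, detection_config("denovo"))
    prev_s <- Inf; prev_g <- Inf
    for (t in c(0.5, 0.7, 0.85, 0.9, 0.95, 0.99)) {
      cfg <- detection_config("denovo", identity_threshold = t)
      pairs <- hits[synolog_criterion(hits, cfg), , drop = FALSE]
      grp <- build_groups(pairs, gen$records)
      s <- length(unique(grp$gene_id)); g <- length(unique(grp$group_id))
      expect_lte(s, prev_s); expect_lte(g, prev_g)
      prev_s <- s; prev_g <- g
    }
  }
})

test_that("the planted partition is recovered exactly on the standard fixture", {
  for (seed in c(4, 8, 15)) {
    gen <- generate_genome(standard_fixture_design(rng_seed = seed))
    scan <- detect_synologs(gen$records, fixture_config())
    expect_equal(canon_partition(detected_partition(scan$groups)),
                 canon_partition(planted_partition(gen$truth)),
                 info = paste("seed", seed))
  }
})

test_that("the k-mer prescreen is lossless: identical groups with and without it", {
  gen <- generate_genome(small_design(23, n_background = 40, groups = 4))
  exhaustive <- detect_synologs(gen$records, detection_config("denovo"))
  screened <- detect_synologs(gen$records, fixture_config())
  expect_equal(exhaustive$pairs, screened$pairs)
  expect_equal(exhaustive$groups, screened$groups)
})

test_that("family mode over planted families agrees with de novo detection", {
  gen <- generate_genome(standard_fixture_design(rng_seed = 6))
  denovo <- detect_synologs(gen$records, fixture_config())
  family <- detect_synologs(gen$records, detection_config("family"))
  expect_equal(canon_partition(detected_partition(denovo$groups)),
               canon_partition(detected_partition(family$groups)))
})

test_that("family mode requires family labels", {
  rec <- generate_genome(small_design(3))$records
  rec$family_id <- NA_character_
  expect_error(detect_synologs(rec, detection_config("family")), "family")
})

test_that("category filtering restricts scope before detection", {
  gen <- generate_genome(small_design(17))
  rec <- gen$records
  rec$category[seq(1, nrow(rec), by = 2)] <- "other"
  cfg <- detection_config("denovo", category_filter = "carbohydrate",
                          prescreen = TRUE)
  scan <- detect_synologs(rec, cfg)
  expect_equal(scan$summary$n_genes, sum(rec$category == "carbohydrate"))
  expect_error(detect_synologs(rec, detection_config(
    "denovo", category_filter = "missing_category")), "scope")
})
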