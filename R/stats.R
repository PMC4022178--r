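#' Per-genome synolog summary
#'
#' Condenses one genome's detection result into the counts the cohort
#' statistics are built on: N = genes in scope, S = synologs (genes belonging
#' to a group), G = groups, and the synolog fraction F = 100 * S / N — the
#' ratio of synologs to all genes in scope, as a percentage (full precision is
#' retained; round at reporting time). `mean_pair_identity` is the mean
#' percent identity over all within-group passing pairs, and a group is
#' counted as high-identity when every passing pair used in its construction
#' meets `high_identity_cutoff` (i.e. its `min_identity` does).
#'
#' @param groups a `synolog_groups` table from [build_groups()].
#' @param records_in_scope the record data frame the groups were detected in
#'   (after category and truncation filtering); genes appearing more than once
#'   are counted once.
#' @param pairs optional passing-pair table from [candidate_pairs()]; when
#'   supplied, `mean_pair_identity` is the exact per-pair mean, otherwise the
#'   unweighted mean of group mean identities.
#' @param high_identity_cutoff fraction, default 0.90.
#' @return a one-row data frame with columns `genome_id`, `n_genes`,
#'   `n_synologs`, `n_groups`, `synolog_fraction`, `mean_pair_identity`,
#'   `n_high_identity_groups` and the list column `subcategory_group_counts`.
#' @export
summarize_genome <- function(groups, records_in_scope, pairs = NULL,
                             high_identity_cutoff = 0.90) {
  n_genes <- length(unique(records_in_scope$gene_id))
  if (n_genes == 0L)
    stop("no genes in scope: synolog fraction undefined")
  s <- length(unique(groups$gene_id))
  per_group <- unique(groups[, c("group_id", "min_identity",
                                 "mean_identity")])
  g <- nrow(per_group)
  mean_id <- if (!is.null(pairs) && nrow(pairs) > 0L) mean(pairs$identity)
             else if (g > 0L) mean(per_group$mean_identity)
             else NA_real_
  out <- data.frame(
    genome_id = if (nrow(groups) > 0L) groups$genome_id[1L]
                else records_in_scope$genome_id[1L],
    n_genes = n_genes,
    n_synologs = s,
    n_groups = g,
    synolog_fraction = 100 * s / n_genes,
    mean_pair_identity = 100 * mean_id,
    n_high_identity_groups =
      sum(round(per_group$min_identity, 6L) >= high_identity_cutoff),
    stringsAsFactors = FALSE)
  out$subcategory_group_counts <- list(subcategory_breakdown(groups))
  class(out) <- c("genome_summaries", "data.frame")
  out
}

#' Median and (unscaled) median absolute deviation
#'
#' The median is the standard sample median (mean of the central pair for even
#' n); the MAD is the median of absolute deviations from the median, with no
#' consistency scaling (no 1.4826 factor) — the convention under which a
#' cohort with groups-per-genome median 20 and MAD 13 yields the outlier
#' threshold 46.
#'
#' @param values non-empty numeric vector.
#' @return named numeric vector `c(median = ..., mad = ...)`.
#' @examples
#' median_mad(c(20, 20, 33, 7, 46))  # median 20, mad 13
#' @export
median_mad <- function(values) {
  if (length(values) == 0L || anyNA(values))
    stop("values must be non-empty and free of NA")
  med <- stats::median(values)
  c(median = med, mad = stats::mad(values, center = med, constant = 1))
}

#' Outlier threshold: median + 2 x MAD
#'
#' The cutoff above which a genome's value is called unusually high relative
#' to the cohort.
#'
#' @param median,mad cohort median and unscaled MAD (`mad >= 0`).
#' @return `median + 2 * mad`.
#' @examples
#' outlier_threshold(20, 13)    # 46 synolog groups
#' outlier_threshold(30, 9.7)   # 49.4 percent synolog fraction
#' @export
outlier_threshold <- function(median, mad) {
  stopifnot(mad >= 0)
  median + 2 * mad
}

#' R-squared of a simple linear regression
#'
#' The squared Pearson correlation of x and y, identical to the ordinary
#' least-squares coefficient of determination for a one-predictor regression.
#'
#' @param x,y numeric vectors of equal length >= 3; neither may be constant
#'   (the fit is undefined).
#' @return R-squared in `[0, 1]`.
#' @export
linear_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("R-squared undefined for a constant variable")
  stats::cor(x, y)^2
}

#' Per-subcategory synolog group counts
#'
#' Assigns each group one subcategory — the majority label of its members,
#' lexicographically first on ties, `"none"` when members carry no label —
#' and tallies groups per subcategory. Counts sum to the number of groups.
#'
#' @param groups a `synolog_groups` table.
#' @return named integer vector of group counts (empty for no groups).
#' @export
subcategory_breakdown <- function(groups) {
  if (is.null(groups) || nrow(groups) == 0L)
    return(integer(0))
  labels <- vapply(split(groups$subcategory, groups$group_id), function(sub) {
    sub[is.na(sub)] <- "none"
    tab <- table(sub)
    names(tab)[order(-tab, names(tab), method = "radix")][1L]
  }, character(1))
  tab <- table(labels)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(names(counts), method = "radix")]
}

#' Cohort-level synolog statistics
#'
#' Aggregates per-genome summaries across a cohort: per-metric median,
#' unscaled MAD, min, max and the median + 2 x MAD outlier threshold;
#' simple-regression R-squared between synolog counts, group counts, gene
#' counts (and total protein counts when supplied); percentile ranks of every
#' genome by group count and by synolog fraction; the share of genomes with
#' no synologs at all; and the share of genomes carrying at least one
#' high-identity group. Average pair identity is summarized over the genomes
#' that contain synologs (it is undefined elsewhere).
#'
#' @param summaries a `genome_summaries` data frame (rbind of
#'   [summarize_genome()] rows), or a list of such one-row frames.
#' @param total_protein_counts optional named numeric vector (names =
#'   genome ids) of whole-proteome protein counts, enabling the
#'   groups-vs-total-proteins regression.
#' @param share_digits decimals used when rounding the two genome-share
#'   percentages; default 1 (set 0 for nearest-integer reporting).
#' @return an object of class `synolog_cohort`.
#' @export
cohort_summarize <- function(summaries, total_protein_counts = NULL,
                             share_digits = 1L) {
  if (is.list(summaries) && !is.data.frame(summaries))
    summaries <- do.call(rbind, summaries)
  stopifnot(nrow(summaries) >= 1L)
  metric_cols <- c("n_genes", "n_synologs", "n_groups", "synolog_fraction",
                   "mean_pair_identity")
  metrics <- lapply(metric_cols, function(col) {
    v <- summaries[[col]]
    if (col == "mean_pair_identity") v <- v[!is.na(v)]
    if (length(v) == 0L)
      return(list(median = NA_real_, mad = NA_real_, min = NA_real_,
                  max = NA_real_, outlier_threshold = NA_real_))
    mm <- median_mad(v)
    list(median = unname(mm["median"]), mad = unname(mm["mad"]),
         min = min(v), max = max(v),
         outlier_threshold = outlier_threshold(mm["median"], mm["mad"]))
  })
  names(metrics) <- metric_cols

  safe_r2 <- function(x, y) {
    if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(NA_real_)
    linear_r2(x, y)
  }
  r2 <- list(
    synologs_vs_groups = safe_r2(summaries$n_groups, summaries$n_synologs),
    groups_vs_genes = safe_r2(summaries$n_genes, summaries$n_groups))
  if (!is.null(total_protein_counts)) {
    tot <- total_protein_counts[summaries$genome_id]
    r2$groups_vs_total_proteins <- safe_r2(unname(tot), summaries$n_groups)
  }

  pct_rank <- function(v)
    100 * rank(v, ties.method = "max") / length(v)
  ranks <- data.frame(
    genome_id = summaries$genome_id,
    percentile_by_groups = pct_rank(summaries$n_groups),
    percentile_by_fraction = pct_rank(summaries$synolog_fraction),
    stringsAsFactors = FALSE)

  n <- nrow(summaries)
  structure(list(
    n_genomes = n,
    metrics = metrics,
    r2_pairs = r2,
    genome_ranks = ranks,
    zero_synolog_share = round(100 * sum(summaries$n_groups == 0) / n,
                               share_digits),
    high_identity_share = round(
      100 * sum(summaries$n_high_identity_groups > 0) / n, share_digits)
  ), class = "synolog_cohort")
}

#' @export
print.synolog_cohort <- function(x, ...) {
  cat(sprintf("Synolog cohort summary over %d genome(s)\n", x$n_genomes))
  for (nm in names(x$metrics)) {
    m <- x$metrics[[nm]]
    cat(sprintf("  %-22s median %.1f +/- %.1f (min %.1f, max %.1f), outliers > %.1f\n",
                nm, m$median, m$mad, m$min, m$max, m$outlier_threshold))
  }
  cat(sprintf("  genomes without synologs : %s%%\n", x$zero_synolog_share))
  cat(sprintf("  genomes with high-identity groups: %s%%\n",
              x$high_identity_share))
  for (nm in names(x$r2_pairs))
    cat(sprintf("  R^2 %-24s %s\n", nm,
                ifelse(is.na(x$r2_pairs[[nm]]), "undefined",
                       sprintf("%.2f", x$r2_pairs[[nm]]))))
  invisible(x)
}
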