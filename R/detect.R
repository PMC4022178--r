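#' Flag severely truncated family members
#'
#' Translated pseudogene fragments can carry near-perfect identity to their
#' full-length family partner over the fragment, so family-constrained
#' detection (which has no length requirement) checks the sequence set for
#' severely truncated proteins first: within each family of two or more
#' members, a sequence shorter than `truncation_fraction` times the family
#' median length is flagged and excluded from pairing and from all counts.
#' De novo detection needs no such check — its per-sequence coverage rule
#' already rejects truncated partners — so in that mode the records pass
#' through unflagged.
#'
#' @param records a proteome record data frame.
#' @param config a [detection_config()].
#' @return a list with `kept` (record data frame) and `flagged` (character
#'   vector of gene ids).
#' @export
filter_truncated <- function(records, config) {
  validate_records(records)
  if (config$mode != "family" || nrow(records) == 0L)
    return(list(kept = records, flagged = character(0)))
  lens <- nchar(records$sequence)
  flagged <- character(0)
  for (members in split(seq_len(nrow(records)), records$family_id)) {
    if (length(members) < 2L) next
    med <- stats::median(lens[members])
    short <- members[lens[members] < config$truncation_fraction * med]
    flagged <- c(flagged, records$gene_id[short])
  }
  flagged <- sort(flagged)
  list(kept = records[!records$gene_id %in% flagged, , drop = FALSE],
       flagged = flagged)
}

#' Synolog candidate pairs of one genome
#'
#' Evaluates every relevant intra-genome pair ([align_all_pairs()]) and keeps
#' the ones satisfying the synolog criterion ([synolog_criterion()]).
#'
#' @param records proteome record data frame from one genome; apply the
#'   category filter and truncation filter first (or use [detect_synologs()]).
#' @param config a [detection_config()].
#' @return data frame of passing pairwise hits sorted by (`gene_a`, `gene_b`).
#' @export
candidate_pairs <- function(records, config) {
  hits <- align_all_pairs(records, config)
  hits <- hits[synolog_criterion(hits, config), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Build synolog groups from passing pairs
#'
#' A synolog group is a set of two or more intra-genome homologs: a connected
#' component of the graph whose edges are the pairs passing the synolog
#' criterion (single linkage — two members of one group need not themselves
#' pass, they need a path of passing pairs). Group ids are deterministic:
#' `<genome_id>_g<ordinal>` with ordinals assigned by the lexicographically
#' smallest member gene id. Group `min_identity`/`mean_identity` are taken
#' over the passing pairs inside the group.
#'
#' @param pairs passing hits from [candidate_pairs()].
#' @param records the record data frame the pairs were computed from (for
#'   genome, family and subcategory labels).
#' @return a `synolog_groups` data frame: one row per (group, member) with
#'   columns `genome_id`, `group_id`, `gene_id`, `family_id`, `subcategory`,
#'   `min_identity`, `mean_identity`.
#' @export
build_groups <- function(pairs, records) {
  empty <- data.frame(genome_id = character(0), group_id = character(0),
                      gene_id = character(0), family_id = character(0),
                      subcategory = character(0), min_identity = numeric(0),
                      mean_identity = numeric(0), stringsAsFactors = FALSE)
  class(empty) <- c("synolog_groups", "data.frame")
  if (is.null(pairs) || nrow(pairs) == 0L) return(empty)

  g <- igraph::graph_from_data_frame(pairs[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  membership <- comp$membership  # named by gene_id
  genome <- unique(records$genome_id)

  comp_genes <- split(names(membership), membership)
  # deterministic ordinals: order components by smallest member gene id
  smallest <- vapply(comp_genes, function(gs) sort(gs, method = "radix")[1L],
                     character(1))
  comp_genes <- comp_genes[order(smallest, method = "radix")]

  rows <- vector("list", length(comp_genes))
  for (k in seq_along(comp_genes)) {
    genes <- sort(comp_genes[[k]], method = "radix")
    in_grp <- pairs$gene_a %in% genes & pairs$gene_b %in% genes
    ids <- pairs$identity[in_grp]
    ri <- match(genes, records$gene_id)
    rows[[k]] <- data.frame(
      genome_id = genome,
      group_id = sprintf("%s_g%03d", genome, k),
      gene_id = genes,
      family_id = records$family_id[ri],
      subcategory = records$subcategory[ri],
      min_identity = min(ids),
      mean_identity = mean(ids),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("synolog_groups", "data.frame")
  out
}

#' Detect synologs in one genome
#'
#' Runs the full per-genome detection pipeline: category filtering, the
#' truncated-protein check (family mode), pairwise evaluation of candidate
#' pairs, single-linkage group construction, and the per-genome summary.
#'
#' @param records proteome record data frame from one genome (e.g. from
#'   [read_proteome()] or [generate_genome()]).
#' @param config a [detection_config()].
#' @param high_identity_cutoff identity cutoff (fraction) used to label
#'   groups whose every passing pair meets it as high-identity groups;
#'   default 0.90.
#' @return an object of class `synolog_scan`: a list with `records` (in
#'   scope, after filters), `flagged_truncated`, `pairs`, `groups`, `summary`
#'   (one-row data frame, see [summarize_genome()]) and `config`.
#' @examples
#' design <- synthetic_design(n_background = 20,
#'                            planted_groups = list(list(size = 2)),
#'                            rng_seed = 7)
#' gen <- generate_genome(design)
#' scan <- detect_synologs(gen$records,
#'                         detection_config("denovo", prescreen = TRUE))
#' scan$summary$n_groups  # 1
#' @export
detect_synologs <- function(records, config = detection_config("denovo"),
                            high_identity_cutoff = 0.90) {
  validate_records(records)
  if (!is.null(config$category_filter))
    records <- records[!is.na(records$category) &
                         records$category == config$category_filter, ,
                       drop = FALSE]
  if (nrow(records) == 0L)
    stop("no records in scope", if (!is.null(config$category_filter))
      paste0(" for category '", config$category_filter, "'"))
  trunc <- filter_truncated(records, config)
  pairs <- candidate_pairs(trunc$kept, config)
  groups <- build_groups(pairs, trunc$kept)
  summary <- summarize_genome(groups, trunc$kept,
                              high_identity_cutoff = high_identity_cutoff)
  structure(list(records = trunc$kept,
                 flagged_truncated = trunc$flagged,
                 pairs = pairs, groups = groups, summary = summary,
                 config = config), class = "synolog_scan")
}

#' @export
print.synolog_scan <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Synolog scan of genome '%s' (%s mode)\n",
              s$genome_id, x$config$mode))
  cat(sprintf("  genes in scope : %d\n", s$n_genes))
  if (length(x$flagged_truncated) > 0L)
    cat(sprintf("  truncated, excluded: %d\n", length(x$flagged_truncated)))
  cat(sprintf("  synologs       : %d in %d groups\n",
              s$n_synologs, s$n_groups))
  cat(sprintf("  synolog fraction: %.1f%%\n", s$synolog_fraction))
  if (s$n_groups > 0L)
    cat(sprintf("  mean pair identity: %.1f%%\n", s$mean_pair_identity))
  invisible(x)
}

#' @export
summary.synolog_scan <- function(object, ...) {
  object$summary
}
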