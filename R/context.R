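#' Classify the genomic arrangement of a synolog group
#'
#' Orders all annotated genes along each contig by start coordinate and calls
#' the group:
#'
#' * `tandem` — all members lie on one contig and every pair of consecutive
#'   members (in gene-rank order) is separated by at most `max_intervening`
#'   non-member genes;
#' * `dispersed` — the members span more than one contig, or no two members
#'   are within `max_intervening` intervening genes of each other;
#' * `mixed` — otherwise (one contig, some but not all consecutive member
#'   pairs close together).
#'
#' Distances are counted in intervening genes (gene rank), not base pairs, so
#' calls are invariant under coordinate translation and strand flips and work
#' from an annotation table alone.
#'
#' @param group_genes character vector of the group's member gene ids.
#' @param annotations annotation data frame (or proteome records) covering at
#'   least every member and its contig companions.
#' @param max_intervening non-negative integer tolerance; default 2.
#' @return one of `"tandem"`, `"dispersed"`, `"mixed"`.
#' @export
classify_arrangement <- function(group_genes, annotations,
                                 max_intervening = 2L) {
  ri <- match(group_genes, annotations$gene_id)
  if (anyNA(ri))
    stop("group member(s) without coordinates: ",
         paste(group_genes[is.na(ri)], collapse = ", "))
  if (any(is.na(annotations$start[ri])))
    stop("group member(s) without coordinates")
  contigs <- unique(annotations$contig[ri])
  rank_tab <- gene_ranks(annotations)
  member_ranks <- rank_tab$rank[match(group_genes, rank_tab$gene_id)]

  if (length(contigs) > 1L) {
    return("dispersed")
  }
  r <- sort(member_ranks)
  gaps <- diff(r) - 1L  # intervening genes between consecutive members
  if (all(gaps <= max_intervening)) "tandem"
  else if (all(gaps > max_intervening)) "dispersed"
  else "mixed"
}

# per-contig gene ranks by start coordinate (ties broken by end, then id)
gene_ranks <- function(annotations) {
  out <- do.call(rbind, lapply(split(annotations, annotations$contig),
    function(a) {
      ord <- order(a$start, a$end, a$gene_id, method = "radix")
      data.frame(gene_id = a$gene_id[ord], contig = a$contig[ord],
                 rank = seq_along(ord), stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}

#' Profile the functional categories of a synolog group's gene neighbourhood
#'
#' For every member, takes up to `window` annotated genes on each side on the
#' same contig — skipping other members of the same group, which are partners
#' rather than context — and tallies their category labels. Genes without a
#' category count as `"unknown"`. Neighbours are counted once per member they
#' flank, so a gene sitting between two members contributes twice.
#'
#' @param group_genes character vector of member gene ids.
#' @param annotations annotation data frame (or proteome records).
#' @param window number of neighbouring genes per side (>= 1); default 5.
#' @return named integer vector of neighbour counts per category (empty when
#'   no members have neighbours).
#' @export
neighbor_category_profile <- function(group_genes, annotations, window = 5L) {
  stopifnot(window >= 1L)
  rank_tab <- gene_ranks(annotations)
  counts <- character(0)
  for (gene in group_genes) {
    i <- match(gene, rank_tab$gene_id)
    if (is.na(i))
      stop("group member without coordinates: ", gene)
    on_contig <- rank_tab[rank_tab$contig == rank_tab$contig[i], , drop = FALSE]
    on_contig <- on_contig[order(on_contig$rank), , drop = FALSE]
    pos <- which(on_contig$gene_id == gene)
    non_member <- !(on_contig$gene_id %in% group_genes)
    left <- which(non_member & seq_len(nrow(on_contig)) < pos)
    right <- which(non_member & seq_len(nrow(on_contig)) > pos)
    take <- c(utils::tail(left, window), utils::head(right, window))
    cats <- annotations$category[match(on_contig$gene_id[take],
                                       annotations$gene_id)]
    cats[is.na(cats)] <- "unknown"
    counts <- c(counts, cats)
  }
  if (length(counts) == 0L) return(integer(0))
  tab <- table(counts)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(names(out), method = "radix")]
}

#' Context calls for every synolog group
#'
#' Applies [classify_arrangement()] and [neighbor_category_profile()] to each
#' group of a detection result.
#'
#' @param groups a `synolog_groups` table.
#' @param annotations annotation data frame covering the genome.
#' @param max_intervening tandem tolerance; default 2.
#' @param window neighbours per side for the category profile; default 5.
#' @return data frame with one row per group: `group_id`, `arrangement`,
#'   `contig_count`, `n_members`, `window`, and the list column
#'   `neighbor_profile`.
#' @export
classify_groups_context <- function(groups, annotations, max_intervening = 2L,
                                    window = 5L) {
  ids <- unique(groups$group_id)
  rows <- lapply(ids, function(gid) {
    genes <- groups$gene_id[groups$group_id == gid]
    contigs <- unique(annotations$contig[match(genes, annotations$gene_id)])
    data.frame(group_id = gid,
               arrangement = classify_arrangement(genes, annotations,
                                                  max_intervening),
               contig_count = length(contigs),
               n_members = length(genes),
               window = as.integer(window),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows)
         else data.frame(group_id = character(0), arrangement = character(0),
                         contig_count = integer(0), n_members = integer(0),
                         window = integer(0), stringsAsFactors = FALSE)
  out$neighbor_profile <- lapply(ids, function(gid) {
    neighbor_category_profile(groups$gene_id[groups$group_id == gid],
                              annotations, window)
  })
  out
}

#' Write context calls as TSV
#'
#' @param context data frame from [classify_groups_context()].
#' @param path output path.
#' @export
write_context <- function(context, path) {
  out <- context
  out$neighbor_profile <- vapply(out$neighbor_profile, pack_counts,
                                 character(1))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(context)
}
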