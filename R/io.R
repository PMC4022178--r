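#' Proteome records
#'
#' A proteome is represented as a plain data frame with one row per
#' protein-coding gene and columns `gene_id`, `genome_id`, `contig`, `start`,
#' `end`, `strand`, `family_id`, `category`, `subcategory`, `sequence`.
#' Coordinates are 1-based inclusive; `strand` is `+` or `-`; `family_id`,
#' `category` and `subcategory` are `NA` when absent (an empty string in the
#' annotation file means absent). Sequences are amino-acid strings over the 20
#' canonical residues plus X; terminal `*` stop characters are stripped at
#' parse time and any other character is rejected.
#'
#' @name proteome-records
#' @keywords internal
NULL

ANNOTATION_COLUMNS <- c("gene_id", "genome_id", "contig", "start", "end",
                        "strand", "family_id", "category", "subcategory")

validate_records <- function(records) {
  need <- c(ANNOTATION_COLUMNS, "sequence")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0L)
    stop("records are missing column(s): ", paste(missing, collapse = ", "))
  dup <- records$gene_id[duplicated(records$gene_id)]
  if (length(dup) > 0L)
    stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "))
  if (any(is.na(records$start)) || any(is.na(records$end)) ||
      any(records$start < 1L) || any(records$end < records$start))
    stop("coordinates must satisfy 1 <= start <= end")
  if (!all(records$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  invisible(records)
}

blank_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  x
}

na_to_blank <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x
}

#' Read a proteome: FASTA sequences joined to an annotation table
#'
#' The first whitespace-delimited token of each FASTA header is the gene id;
#' each id must have exactly one row in the annotation table (tab-separated
#' with header `gene_id genome_id contig start end strand family_id category
#' subcategory`; empty string means absent). GFF3 is accepted as an
#' alternative coordinate source via [read_gff3_annotations()].
#'
#' @param fasta_source path to a protein FASTA file.
#' @param annotation_source path to the annotation TSV, or an annotation data
#'   frame (e.g. from [read_gff3_annotations()]).
#' @return a proteome record data frame, in FASTA order.
#' @export
read_proteome <- function(fasta_source, annotation_source) {
  seqs <- Biostrings::readAAStringSet(fasta_source)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate gene_id in FASTA: ", paste(unique(dup), collapse = ", "))
  ann <- if (is.data.frame(annotation_source)) annotation_source
         else read_annotations(annotation_source)
  miss <- setdiff(ids, ann$gene_id)
  if (length(miss) > 0L)
    stop("no annotation row for FASTA entr",
         if (length(miss) > 1L) "ies: " else "y: ",
         paste(miss, collapse = ", "))
  rec <- ann[match(ids, ann$gene_id), , drop = FALSE]
  rec$sequence <- vapply(seq_along(seqs), function(i) {
    s <- aa_clean(as.character(seqs[[i]]), ids[i])
    aa_encode(s, ids[i])  # rejects residues outside the alphabet
    s
  }, character(1))
  rownames(rec) <- NULL
  validate_records(rec)
  rec
}

#' @rdname read_proteome
#' @param records a proteome record data frame.
#' @param fasta_sink,annotation_sink output paths.
#' @export
write_proteome <- function(records, fasta_sink, annotation_sink) {
  validate_records(records)
  seqs <- Biostrings::AAStringSet(records$sequence)
  names(seqs) <- records$gene_id
  Biostrings::writeXStringSet(seqs, fasta_sink)
  write_annotations(records[, ANNOTATION_COLUMNS], annotation_sink)
  invisible(records)
}

#' Read or write an annotation table
#'
#' Tab-separated with the fixed header `gene_id genome_id contig start end
#' strand family_id category subcategory`; empty strings mean absent labels.
#'
#' @param path file path.
#' @return `read_annotations()`: a data frame with the columns above.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  missing <- setdiff(ANNOTATION_COLUMNS, names(ann))
  if (length(missing) > 0L)
    stop("annotation table is missing column(s): ",
         paste(missing, collapse = ", "))
  ann <- ann[, ANNOTATION_COLUMNS, drop = FALSE]
  ann$start <- as.integer(ann$start)
  ann$end <- as.integer(ann$end)
  for (col in c("family_id", "category", "subcategory"))
    ann[[col]] <- blank_to_na(ann[[col]])
  dup <- ann$gene_id[duplicated(ann$gene_id)]
  if (length(dup) > 0L)
    stop("duplicate gene_id in annotations: ",
         paste(unique(dup), collapse = ", "))
  ann
}

#' @rdname read_annotations
#' @param annotations an annotation data frame.
#' @export
write_annotations <- function(annotations, path) {
  out <- annotations[, ANNOTATION_COLUMNS, drop = FALSE]
  for (col in c("family_id", "category", "subcategory"))
    out[[col]] <- na_to_blank(out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(annotations)
}

#' Read gene coordinates from GFF3
#'
#' Extracts CDS features (falling back to `gene` features when a file has no
#' CDS) and converts them to the package annotation schema; the `ID` attribute
#' is the gene id. Family and category labels are left absent. Requires the
#' rtracklayer package.
#'
#' @param path GFF3 file.
#' @param genome_id genome label to stamp on every row.
#' @return an annotation data frame usable as `annotation_source` in
#'   [read_proteome()].
#' @export
read_gff3_annotations <- function(path, genome_id) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("GFF3 input requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- gr$type == "CDS"
  if (!any(keep)) keep <- gr$type == "gene"
  gr <- gr[keep]
  ids <- as.character(gr$ID)
  if (anyNA(ids) || any(ids == ""))
    stop("GFF3 features must carry an ID attribute")
  df <- as.data.frame(gr)
  data.frame(
    gene_id = ids,
    genome_id = genome_id,
    contig = as.character(df$seqnames),
    start = as.integer(df$start),
    end = as.integer(df$end),
    strand = as.character(df$strand),
    family_id = NA_character_,
    category = NA_character_,
    subcategory = NA_character_,
    stringsAsFactors = FALSE)
}

#' Write or read a synolog group table
#'
#' One row per (group, member): `genome_id`, `group_id`, `gene_id`,
#' `family_id`, `subcategory`, `min_identity`, `mean_identity` (group-level
#' identities repeated on each member row). Rows are ordered by `group_id`
#' then `gene_id` so output is byte-deterministic.
#'
#' @param groups a `synolog_groups` table from [build_groups()].
#' @param sink,path file path.
#' @export
write_groups <- function(groups, sink) {
  out <- as.data.frame(groups)
  out <- out[order(out$group_id, out$gene_id, method = "radix"), ,
             drop = FALSE]
  for (col in c("family_id", "subcategory"))
    out[[col]] <- na_to_blank(out[[col]])
  utils::write.table(out, sink, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(groups)
}

#' @rdname write_groups
#' @export
read_groups <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("genome_id", "group_id", "gene_id", "family_id", "subcategory",
            "min_identity", "mean_identity")
  missing <- setdiff(need, names(g))
  if (length(missing) > 0L)
    stop("group table is missing column(s): ",
         paste(missing, collapse = ", "))
  g <- g[, need, drop = FALSE]
  g$min_identity <- as.numeric(g$min_identity)
  g$mean_identity <- as.numeric(g$mean_identity)
  for (col in c("family_id", "subcategory"))
    g[[col]] <- blank_to_na(g[[col]])
  class(g) <- c("synolog_groups", "data.frame")
  g
}

#' Write or read per-genome summary tables
#'
#' One row per genome with counts, the synolog fraction (percent) and the
#' per-subcategory group counts packed as `label:count` pairs separated by
#' `;`.
#'
#' @param summaries a data frame of per-genome summaries
#'   (see [summarize_genome()]).
#' @param path file path.
#' @export
write_genome_summaries <- function(summaries, path) {
  out <- as.data.frame(summaries)
  out$subcategory_group_counts <-
    vapply(out$subcategory_group_counts, pack_counts, character(1))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(summaries)
}

#' @rdname write_genome_summaries
#' @export
read_genome_summaries <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  s$subcategory_group_counts <- lapply(s$subcategory_group_counts,
                                       unpack_counts)
  class(s) <- c("genome_summaries", "data.frame")
  s
}

pack_counts <- function(counts) {
  if (length(counts) == 0L) return("")
  counts <- counts[order(names(counts), method = "radix")]
  paste(sprintf("%s:%d", names(counts), as.integer(counts)), collapse = ";")
}

unpack_counts <- function(packed) {
  if (is.na(packed) || packed == "") return(integer(0))
  parts <- strsplit(packed, ";", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  counts <- vapply(kv, function(p) as.integer(p[2L]), integer(1))
  names(counts) <- vapply(kv, `[`, character(1), 1L)
  counts
}

#' Write a cohort summary as JSON
#'
#' @param cohort a `synolog_cohort` object from [cohort_summarize()].
#' @param path output path.
#' @export
write_cohort_json <- function(cohort, path) {
  jsonlite::write_json(unclass(cohort), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(cohort)
}

#' Write a plain-text run log with every resolved parameter and the RNG seed
#'
#' @param config a [detection_config()] (or any named list of settings).
#' @param path output path.
#' @param extra optional named list of further settings to record.
#' @export
write_run_log <- function(config, path, extra = list()) {
  settings <- unclass(config)
  settings$matrix <- NULL  # logged by name, not value
  settings <- c(settings, list(substitution_matrix = "BLOSUM62"), extra)
  lines <- c("# synologr run log",
             vapply(names(settings), function(nm) {
               v <- settings[[nm]]
               sprintf("%s = %s", nm,
                       if (is.null(v)) "NULL"
                       else paste(format(v), collapse = ","))
             }, character(1)))
  writeLines(lines, path)
  invisible(config)
}
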