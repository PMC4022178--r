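#' Pairwise protein alignment
#'
#' `global_align()` computes one optimal global (Needleman-Wunsch/Gotoh)
#' alignment under affine gap penalties; `local_align()` the optimal local
#' (Smith-Waterman) alignment. Both return the bookkeeping the synolog
#' criterion is built on: percent identity and per-sequence coverage.
#'
#' Identity denominators differ by alignment type, mirroring the two data
#' sources the two detection modes emulate:
#'
#' * global (family mode): identity = matches / residue-pair columns, i.e.
#'   columns where both sequences place a residue — gap columns do not dilute
#'   identity, and there is no length requirement;
#' * local (de novo mode): identity = matches / all columns of the local
#'   alignment (gap columns included), blast-style, and
#'   `coverage_x` = residues of x inside the alignment / full length of x.
#'
#' Global alignments cover both sequences end to end, so their coverages are 1
#' by construction. An X residue scores as the worst substitution and never
#' counts as a match. Traceback ties are broken diagonal > vertical >
#' horizontal so results are bit-reproducible.
#'
#' @param a,b protein sequences (single strings over the 20 canonical
#'   residues plus X).
#' @param matrix substitution matrix, default [blosum62()].
#' @param gap_open,gap_extend affine gap penalties; a gap of length k costs
#'   `gap_open + k * gap_extend`. Defaults 11/1.
#' @param ids optional character vector of length 2 with the gene ids to
#'   record as `gene_a` and `gene_b`.
#' @return a one-row data frame (a pairwise hit) with columns `gene_a`,
#'   `gene_b`, `identity`, `coverage_a`, `coverage_b`, `n_matches`,
#'   `n_columns`, `aligned_len_a`, `aligned_len_b`, `score`.
#' @examples
#' global_align("ACDEFG", "ACDEFG")$identity  # 1
#' local_align("HEAGAWGHEE", "PAWHEAE")$score
#' @export
global_align <- function(a, b, matrix = blosum62(), gap_open = 11,
                         gap_extend = 1, ids = c(NA, NA)) {
  ca <- aa_encode(a, "a"); cb <- aa_encode(b, "b")
  r <- .align_pair_cpp(ca, cb, matrix, gap_open, gap_extend, FALSE, X_CODE)
  identity <- if (r$n_respair > 0) r$n_matches / r$n_respair else 0
  hit_row(ids, identity, 1, 1, r, local = FALSE)
}

#' @rdname global_align
#' @export
local_align <- function(a, b, matrix = blosum62(), gap_open = 11,
                        gap_extend = 1, ids = c(NA, NA)) {
  ca <- aa_encode(a, "a"); cb <- aa_encode(b, "b")
  r <- .align_pair_cpp(ca, cb, matrix, gap_open, gap_extend, TRUE, X_CODE)
  identity <- if (r$n_columns > 0) r$n_matches / r$n_columns else 0
  hit_row(ids, identity,
          r$aligned_len_a / length(ca), r$aligned_len_b / length(cb),
          r, local = TRUE)
}

hit_row <- function(ids, identity, cov_a, cov_b, r, local) {
  data.frame(
    gene_a = as.character(ids[1L]), gene_b = as.character(ids[2L]),
    identity = identity, coverage_a = cov_a, coverage_b = cov_b,
    n_matches = as.integer(r$n_matches),
    n_columns = as.integer(r$n_columns),
    aligned_len_a = as.integer(r$aligned_len_a),
    aligned_len_b = as.integer(r$aligned_len_b),
    score = r$score, stringsAsFactors = FALSE)
}

#' The synolog criterion
#'
#' Decides whether a pairwise hit constitutes a synolog pair under the given
#' configuration. De novo mode: identity and both coverages must each meet
#' their thresholds (identity >= 90 percent along >= 90 percent of the full
#' length of both sequences, by default). Family mode: the two genes must
#' share a family label; identity is additionally thresholded only when the
#' configuration sets a numeric cutoff (no length requirement in this mode).
#'
#' Identities are rounded to 6 decimals before the `>=` comparison.
#'
#' @param hit a data frame of pairwise hits as returned by [global_align()] /
#'   [local_align()]; in family mode it must carry `family_a` and `family_b`
#'   columns.
#' @param config a [detection_config()].
#' @return logical vector, one element per row of `hit`.
#' @export
synolog_criterion <- function(hit, config) {
  id_ok <- function() round(hit$identity, 6L) >= config$identity_threshold
  if (config$mode == "denovo") {
    id_ok() &
      round(hit$coverage_a, 6L) >= config$coverage_threshold &
      round(hit$coverage_b, 6L) >= config$coverage_threshold
  } else {
    if (is.null(hit$family_a) || is.null(hit$family_b))
      stop("family mode requires family_a/family_b columns on hits")
    fam <- !is.na(hit$family_a) & !is.na(hit$family_b) &
      hit$family_a == hit$family_b
    if (is.na(config$identity_threshold)) fam else fam & id_ok()
  }
}

# Lossless prescreen bound. A passing de novo pair's local alignment has at
# least n_min = ceil(coverage * max(La, Lb)) columns (the coverage rule), and
# with identity >= t it has <= (1-t) n non-match columns, which split the
# matched columns into at most (1-t) n + 1 runs; the longest run of exact
# matches therefore has length >= t n / ((1-t) n + 1) — an exact substring
# present in both sequences. The bound is increasing in n, so if it reaches k
# at n_min, every passing pair must share a k-mer and pairs sharing none can
# be skipped without aligning. prescreen_min_length() returns the smallest
# sequence length L for which the guarantee holds when max(La, Lb) = L (Inf
# when the thresholds are too permissive for any guarantee, i.e.
# t <= k / (k + 1)); pairs where both sequences are shorter are always
# aligned.
prescreen_min_length <- function(config) {
  t <- config$identity_threshold - 1e-6  # rounding slack on the 6th decimal
  k <- config$prescreen_k
  cov <- config$coverage_threshold
  if (is.na(t) || cov <= 0 || t <= k / (k + 1))
    return(Inf)
  n0 <- k / (t - k * (1 - t))   # minimum column count for a length-k run
  ceiling(n0 / cov)
}

# candidate pair matrix (2 x P, i < j) of genes sharing at least one k-mer,
# built from an inverted k-mer index
shared_kmer_pairs <- function(seqs, k) {
  km <- lapply(seqs, kmer_set, k = k)
  gene <- rep(seq_along(seqs), lengths(km))
  kv <- unlist(km, use.names = FALSE)
  if (length(kv) == 0L) return(matrix(integer(0), nrow = 2))
  o <- order(kv, gene, method = "radix")
  kv <- kv[o]; gene <- gene[o]
  runs <- rle(kv)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  multi <- which(runs$lengths >= 2L)
  if (length(multi) == 0L) return(matrix(integer(0), nrow = 2))
  pm <- do.call(cbind, lapply(multi, function(q)
    utils::combn(gene[starts[q]:ends[q]], 2L)))
  pm[, !duplicated(pm[1L, ] * (max(pm) + 1) + pm[2L, ]), drop = FALSE]
}

# unique k-mer set of one sequence string
kmer_set <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  unique(substring(seq, 1:(L - k + 1L), k:L))
}

#' Align intra-genome protein pairs
#'
#' Computes pairwise hits for all unordered intra-genome pairs (de novo mode)
#' or all same-family pairs (family mode) of a record set. This is the
#' exhaustive evaluation step; [candidate_pairs()] filters its output by the
#' synolog criterion. With `config$prescreen = TRUE` (de novo mode), pairs
#' that provably cannot pass the thresholds because they share no exact
#' `prescreen_k`-mer are skipped; the skip is applied only where the shared
#' word is mathematically guaranteed for a passing pair, so the passing set
#' is unchanged.
#'
#' @param records a proteome record data frame (see [read_proteome()]).
#' @param config a [detection_config()].
#' @return data frame of pairwise hits sorted by (`gene_a`, `gene_b`); in
#'   family mode with `family_a`/`family_b` columns. With prescreening,
#'   skipped pairs are absent (they could not have passed).
#' @export
align_all_pairs <- function(records, config) {
  validate_records(records)
  if (length(unique(records$genome_id)) > 1L)
    stop("records must come from a single genome")
  n <- nrow(records)
  empty <- cbind(hit_row(c(NA, NA), 0, 0, 0,
                         list(n_matches = 0, n_columns = 0,
                              aligned_len_a = 0, aligned_len_b = 0,
                              score = 0), TRUE)[0, ],
                 if (config$mode == "family")
                   data.frame(family_a = character(0),
                              family_b = character(0)))
  if (n < 2L) return(empty)

  if (config$mode == "family") {
    if (all(is.na(records$family_id)))
      stop("family mode requires family_id labels on records in scope")
    idx <- split(seq_len(n), records$family_id)
    pair_i <- integer(0); pair_j <- integer(0)
    for (members in idx) {
      if (length(members) < 2L) next
      cmb <- utils::combn(sort(members), 2L)
      pair_i <- c(pair_i, cmb[1L, ]); pair_j <- c(pair_j, cmb[2L, ])
    }
  } else {
    L_star <- if (config$prescreen) prescreen_min_length(config) else Inf
    if (is.finite(L_star)) {
      lens <- nchar(records$sequence)
      shared <- shared_kmer_pairs(records$sequence, config$prescreen_k)
      # pairs where both sequences are below the guarantee length must be
      # aligned regardless of shared words
      small <- which(lens < L_star)
      if (length(small) >= 2L) {
        cmb <- utils::combn(small, 2L)
        shared <- cbind(shared, cmb)
        shared <- shared[, !duplicated(shared[1L, ] * (n + 1) + shared[2L, ]),
                         drop = FALSE]
      }
      ord <- order(shared[1L, ], shared[2L, ])
      pair_i <- shared[1L, ord]; pair_j <- shared[2L, ord]
    } else {
      cmb <- utils::combn(n, 2L)
      pair_i <- cmb[1L, ]; pair_j <- cmb[2L, ]
    }
  }
  if (length(pair_i) == 0L) return(empty)

  align1 <- if (config$mode == "denovo") local_align else global_align
  hits <- vector("list", length(pair_i))
  for (p in seq_along(pair_i)) {
    i <- pair_i[p]; j <- pair_j[p]
    hits[[p]] <- align1(records$sequence[i], records$sequence[j],
                        matrix = config$matrix, gap_open = config$gap_open,
                        gap_extend = config$gap_extend,
                        ids = c(records$gene_id[i], records$gene_id[j]))
  }
  hits <- do.call(rbind, hits)
  if (config$mode == "family") {
    fam <- records$family_id[match(hits$gene_a, records$gene_id)]
    hits$family_a <- fam
    hits$family_b <- records$family_id[match(hits$gene_b, records$gene_id)]
  }
  hits <- hits[order(hits$gene_a, hits$gene_b, method = "radix"), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}
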