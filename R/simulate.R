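#' Random protein sequence
#'
#' An i.i.d. uniform draw over the 20 canonical residues, using R's session
#' RNG (seed it with `set.seed()` for reproducibility). Two independent draws
#' of realistic length are effectively unrelated: their global identity stays
#' far below any homology threshold.
#'
#' @param length sequence length (>= 1).
#' @return a single protein sequence string.
#' @export
random_protein <- function(length) {
  if (length < 1L) stop("length must be >= 1")
  paste(sample(AA_ALPHABET[1:20], length, replace = TRUE), collapse = "")
}

#' Mutate a sequence to an exact target identity
#'
#' Substitutes exactly `round((1 - target_identity) * L)` distinct positions,
#' each to a uniformly chosen *different* residue; no indels, so the ungapped
#' identity of the copy to its parent is exactly `(L - m) / L`. Two copies
#' mutated independently from one parent at per-copy identity t have pairwise
#' identity at least `2t - 1` (their mutated position sets can at worst be
#' disjoint), which is how planted groups guarantee clearing a detection
#' cutoff.
#'
#' @param seq parent protein sequence.
#' @param target_identity fraction in `[0, 1]`.
#' @return mutated copy (same length as `seq`).
#' @export
mutate_to_identity <- function(seq, target_identity) {
  stopifnot(target_identity >= 0, target_identity <= 1)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  m <- round((1 - target_identity) * L)
  if (m == 0L) return(seq)
  pos <- sample.int(L, m)
  for (p in pos) {
    alt <- setdiff(AA_ALPHABET[1:20], chars[p])
    chars[p] <- sample(alt, 1L)
  }
  paste(chars, collapse = "")
}

#' Synthetic proteome design
#'
#' Describes a genome to simulate: unrelated background genes of random
#' composition plus planted synolog groups of controlled size, identity and
#' genomic arrangement, optionally with severely truncated decoy copies.
#' Each planted-group entry may set `size` (>= 2), `target_identity`
#' (copy-to-ancestor, default 0.97 so pairwise identity is guaranteed
#' >= 0.94), `subcategory`, `arrangement` (`"tandem"` or `"dispersed"`),
#' `truncated_copies` and `truncated_fraction` (length kept, default 0.3);
#' unset fields take those defaults.
#'
#' @param n_background number of unrelated background genes.
#' @param length_range integer pair, min/max gene length in residues (the
#'   default 100-400 covers typical bacterial protein sizes; lengths this far
#'   above ~30 make chance 90 percent identity between background genes
#'   negligible).
#' @param planted_groups list of group descriptors (see above).
#' @param n_contigs number of contigs the genes are spread over.
#' @param category category label stamped on every gene (default
#'   `"carbohydrate"`, emulating a per-category gene set).
#' @param genome_id genome label.
#' @param rng_seed integer seed; [generate_genome()] seeds the session RNG
#'   with it, so identical designs yield byte-identical output.
#' @return an object of class `synthetic_design`.
#' @export
synthetic_design <- function(n_background = 300L,
                             length_range = c(100L, 400L),
                             planted_groups = list(),
                             n_contigs = 1L,
                             category = "carbohydrate",
                             genome_id = "synthetic",
                             rng_seed = 1L) {
  stopifnot(n_background >= 0, length(length_range) == 2L,
            length_range[1] >= 30, length_range[2] >= length_range[1],
            n_contigs >= 1)
  groups <- lapply(seq_along(planted_groups), function(i) {
    g <- planted_groups[[i]]
    g$size <- if (is.null(g$size)) 2L else as.integer(g$size)
    if (g$size < 2L) stop("planted group size must be >= 2")
    if (is.null(g$target_identity)) g$target_identity <- 0.97
    stopifnot(g$target_identity >= 0, g$target_identity <= 1)
    if (is.null(g$subcategory)) g$subcategory <- NA_character_
    if (is.null(g$arrangement)) g$arrangement <- "dispersed"
    stopifnot(g$arrangement %in% c("tandem", "dispersed"))
    if (is.null(g$truncated_copies)) g$truncated_copies <- 0L
    if (is.null(g$truncated_fraction)) g$truncated_fraction <- 0.3
    g$label <- sprintf("grp%02d", i)
    g
  })
  structure(list(n_background = as.integer(n_background),
                 length_range = as.integer(length_range),
                 planted_groups = groups,
                 n_contigs = as.integer(n_contigs),
                 category = category,
                 genome_id = genome_id,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_design")
}

#' The standard synthetic fixture
#'
#' The scale echoes a single bacterial genome's carbohydrate gene set: 300
#' background genes plus 12 planted groups (four each of sizes 2, 3 and 4;
#' copy-to-ancestor identity 0.97, guaranteeing pairwise identity >= 0.94,
#' comfortably above a 0.90 cutoff), six tandem and six dispersed, spread over
#' four subcategories, with 3 severely truncated decoy copies (30 percent of
#' the ancestor length) attached to the first three groups.
#'
#' @param rng_seed integer seed.
#' @return a `synthetic_design`.
#' @export
standard_fixture_design <- function(rng_seed = 1L) {
  subcats <- c("central_carbohydrate_metabolism", "fermentation",
               "monosaccharides", "di_and_oligosaccharides")
  groups <- lapply(1:12, function(i) {
    list(size = c(2L, 3L, 4L)[(i - 1L) %% 3L + 1L],
         target_identity = 0.97,
         subcategory = subcats[(i - 1L) %% 4L + 1L],
         arrangement = if (i <= 6L) "tandem" else "dispersed",
         truncated_copies = if (i <= 3L) 1L else 0L,
         truncated_fraction = 0.3)
  })
  synthetic_design(n_background = 300L, length_range = c(100L, 400L),
                   planted_groups = groups, n_contigs = 1L,
                   rng_seed = rng_seed)
}

#' Generate a synthetic proteome with known ground truth
#'
#' Draws one random ancestor per planted group and emits `size` copies
#' mutated to the group's target identity (star topology, so pairwise
#' identities between copies are bounded below by `2t - 1`); truncated decoys
#' keep the first `truncated_fraction` of the ancestor. Tandem groups occupy
#' consecutive gene ranks on one contig; dispersed group members are placed
#' at least 20 ranks apart; background genes fill all remaining ranks.
#' Coordinates use a fixed nucleotide gene length of `3 * L + 3` and 100-bp
#' spacers. Output is deterministic given the design (including its
#' `rng_seed`, which seeds the session RNG).
#'
#' @param design a [synthetic_design()].
#' @return list with `records` (proteome record data frame, usable directly by
#'   [detect_synologs()] or writable via [write_proteome()]) and `truth`
#'   (data frame `gene_id`, `role` — planted group label or `"background"` —
#'   `is_truncated`, `subcategory`, `contig`, `rank`).
#' @export
generate_genome <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(design$rng_seed)
  sizes <- vapply(design$planted_groups, `[[`, integer(1), "size")
  trunc_counts <- vapply(design$planted_groups, function(g)
    as.integer(g$truncated_copies), integer(1))
  total <- design$n_background + sum(sizes) + sum(trunc_counts)
  if (total < 1L) stop("design emits no genes")

  # contiguous contig blocks, as even as possible
  block <- sort(rep_len(seq_len(design$n_contigs), total))
  free <- rep(TRUE, total)
  slot_of <- integer(0)   # filled below
  gene_slot <- list()     # per emitted gene: slot index

  rand_len <- function(n) sample(seq(design$length_range[1],
                                     design$length_range[2]), n,
                                 replace = TRUE)

  place_tandem <- function(size) {
    starts <- which(vapply(seq_len(total - size + 1L), function(p) {
      idx <- p:(p + size - 1L)
      all(free[idx]) && length(unique(block[idx])) == 1L
    }, logical(1)))
    if (length(starts) == 0L)
      stop("design infeasible: no free run of ", size,
           " consecutive ranks for a tandem group")
    p <- if (length(starts) == 1L) starts else sample(starts, 1L)
    p:(p + size - 1L)
  }
  place_dispersed <- function(size) {
    # rejection sampling: a poor early pick can strand later members, so
    # retry the whole group a bounded number of times before declaring the
    # design infeasible
    for (attempt in 1:200) {
      chosen <- integer(0)
      for (k in seq_len(size)) {
        cand <- which(free)
        if (length(chosen) > 0L)
          cand <- cand[vapply(cand, function(p)
            min(abs(p - chosen)) >= 20L, logical(1))]
        if (length(cand) == 0L) { chosen <- NULL; break }
        chosen <- c(chosen, if (length(cand) == 1L) cand
                            else sample(cand, 1L))
      }
      if (!is.null(chosen)) return(sort(chosen))
    }
    stop("design infeasible: cannot place dispersed members >= 20 ranks apart")
  }

  seqs <- character(total)
  role <- rep("background", total)
  is_trunc <- rep(FALSE, total)
  subcat <- rep(NA_character_, total)
  family <- rep(NA_character_, total)

  for (g in design$planted_groups) {
    L <- rand_len(1L)
    ancestor <- random_protein(L)
    slots <- if (g$arrangement == "tandem") place_tandem(g$size)
             else place_dispersed(g$size)
    free[slots] <- FALSE
    for (s in slots) {
      seqs[s] <- mutate_to_identity(ancestor, g$target_identity)
      role[s] <- g$label
      subcat[s] <- g$subcategory
      family[s] <- g$label
    }
    if (g$truncated_copies > 0L) {
      keep <- max(30L, floor(g$truncated_fraction * L))
      for (k in seq_len(g$truncated_copies)) {
        cand <- which(free)
        if (length(cand) == 0L) stop("design infeasible: no rank left")
        s <- if (length(cand) == 1L) cand else sample(cand, 1L)
        free[s] <- FALSE
        seqs[s] <- substr(ancestor, 1L, keep)
        role[s] <- g$label
        is_trunc[s] <- TRUE
        subcat[s] <- g$subcategory
        family[s] <- g$label
      }
    }
  }
  bg <- which(free)
  if (length(bg) != design$n_background)
    stop("internal placement accounting error")
  if (length(bg) > 0L) {
    lens <- rand_len(length(bg))
    seqs[bg] <- vapply(lens, random_protein, character(1))
  }

  # coordinates: rank order within each contig, 100-bp spacers
  width <- 3L * nchar(seqs) + 3L
  start <- integer(total); rank <- integer(total)
  for (b in seq_len(design$n_contigs)) {
    idx <- which(block == b)
    pos <- 1L
    for (j in seq_along(idx)) {
      start[idx[j]] <- pos
      rank[idx[j]] <- j
      pos <- pos + width[idx[j]] + 100L
    }
  }

  gene_id <- sprintf("g%04d", seq_len(total))
  contig <- sprintf("contig%02d", block)
  records <- data.frame(
    gene_id = gene_id,
    genome_id = design$genome_id,
    contig = contig,
    start = start,
    end = start + width - 1L,
    strand = sample(c("+", "-"), total, replace = TRUE),
    family_id = family,
    category = design$category,
    subcategory = subcat,
    sequence = seqs,
    stringsAsFactors = FALSE)
  validate_records(records)
  truth <- data.frame(gene_id = gene_id, role = role,
                      is_truncated = is_trunc, subcategory = subcat,
                      contig = contig, rank = rank, stringsAsFactors = FALSE)
  list(records = records, truth = truth, design = design)
}
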