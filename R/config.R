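#' Detection configuration
#'
#' Bundles every tunable of the synolog detection step. Two modes exist:
#'
#' * `"denovo"`: all intra-genome protein pairs are aligned locally; a pair is
#'   a synolog pair iff identity >= `identity_threshold` and the alignment
#'   covers at least `coverage_threshold` of the full length of *both*
#'   sequences. The coverage rule excludes spurious hits against severely
#'   truncated sequences.
#' * `"family"`: genes sharing a `family_id` are synolog pairs regardless of
#'   length; pairs are aligned globally to record identities. When
#'   `identity_threshold` is a number (rather than `NA`), families are
#'   re-partitioned into components of pairs meeting the cutoff — the
#'   two-stage analysis (all pairs, then >= 90 percent identity pairs).
#'   Severely truncated family members (shorter than `truncation_fraction`
#'   times the family median length) are flagged and excluded first.
#'
#' Identities are compared to the threshold after rounding to 6 decimals,
#' with `>=` semantics, so float-boundary behaviour is platform independent.
#'
#' @param mode `"denovo"` or `"family"`.
#' @param identity_threshold fraction in `[0,1]`, or `NA` (family mode only)
#'   for no identity cutoff. Default 0.90 in de novo mode, `NA` in family
#'   mode.
#' @param coverage_threshold fraction in `[0,1]`; de novo mode only.
#'   Default 0.90.
#' @param truncation_fraction fraction in `(0,1]`; family members shorter
#'   than this times the family median length are flagged. Default 0.5.
#' @param category_filter optional category label; only genes with this
#'   `category` are in scope.
#' @param max_intervening non-negative integer, the tandem-arrangement
#'   tolerance (genes allowed between consecutive group members). Default 2.
#' @param gap_open,gap_extend affine gap penalties; a gap of length k costs
#'   `gap_open + k * gap_extend`. Defaults 11 and 1 (blastp defaults).
#' @param matrix substitution matrix over the package alphabet;
#'   default [blosum62()].
#' @param prescreen logical; when `TRUE`, skip aligning pairs that provably
#'   cannot satisfy the thresholds because they share no exact
#'   `prescreen_k`-mer (only applied where the word-length guarantee holds;
#'   lossless). Default `FALSE` (exhaustive all-vs-all).
#' @param prescreen_k word length of the lossless prescreen. Default 8.
#' @param rng_seed integer seed recorded in run logs.
#' @return an object of class `detection_config`.
#' @export
detection_config <- function(mode = c("denovo", "family"),
                             identity_threshold = NULL,
                             coverage_threshold = 0.90,
                             truncation_fraction = 0.5,
                             category_filter = NULL,
                             max_intervening = 2L,
                             gap_open = 11,
                             gap_extend = 1,
                             matrix = blosum62(),
                             prescreen = FALSE,
                             prescreen_k = 8L,
                             rng_seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(identity_threshold))
    identity_threshold <- if (mode == "denovo") 0.90 else NA_real_
  if (is.na(identity_threshold)) {
    if (mode == "denovo")
      stop("identity_threshold is required in de novo mode")
  } else {
    stopifnot(identity_threshold >= 0, identity_threshold <= 1)
  }
  stopifnot(coverage_threshold >= 0, coverage_threshold <= 1,
            truncation_fraction > 0, truncation_fraction <= 1,
            max_intervening >= 0, gap_open >= 0, gap_extend >= 0,
            prescreen_k >= 2)
  structure(list(
    mode = mode,
    identity_threshold = identity_threshold,
    coverage_threshold = coverage_threshold,
    truncation_fraction = truncation_fraction,
    category_filter = category_filter,
    max_intervening = as.integer(max_intervening),
    gap_open = gap_open,
    gap_extend = gap_extend,
    matrix = matrix,
    prescreen = isTRUE(prescreen),
    prescreen_k = as.integer(prescreen_k),
    rng_seed = as.integer(rng_seed)
  ), class = "detection_config")
}

#' @export
print.detection_config <- function(x, ...) {
  cat("Synolog detection configuration\n")
  cat("  mode               :", x$mode, "\n")
  cat("  identity threshold :",
      if (is.na(x$identity_threshold)) "none (all family pairs)"
      else x$identity_threshold, "\n")
  if (x$mode == "denovo")
    cat("  coverage threshold :", x$coverage_threshold, "\n")
  if (x$mode == "family")
    cat("  truncation fraction:", x$truncation_fraction, "\n")
  if (!is.null(x$category_filter))
    cat("  category filter    :", x$category_filter, "\n")
  cat("  gap open/extend    :", x$gap_open, "/", x$gap_extend, "\n")
  cat("  prescreen          :",
      if (x$prescreen) sprintf("exact %d-mer (lossless)", x$prescreen_k)
      else "off (exhaustive)", "\n")
  invisible(x)
}
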