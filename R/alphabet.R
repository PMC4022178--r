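#' @name alphabet
#' @title Amino-acid alphabet and encoding
#' @description The accepted residue alphabet is the 20 canonical amino acids
#'   plus the ambiguity code X. X never counts as an alignment match and is
#'   scored as the worst substitution in the matrix. Terminal stop characters
#'   (`*`) are stripped at parse time; internal stops are rejected.
#' @keywords internal
NULL

# canonical order used everywhere: 20 residues then X
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y", "X")
X_CODE <- 21L

#' Validate and encode a protein sequence
#'
#' @param seq single character string of residues.
#' @param what label used in error messages (e.g. a gene id).
#' @return integer vector of residue codes (1..21).
#' @keywords internal
aa_encode <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("sequence must be a single string (", what, ")")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  if (length(chars) == 0L)
    stop("empty sequence (", what, ")")
  codes <- match(chars, AA_ALPHABET)
  if (anyNA(codes)) {
    bad <- unique(chars[is.na(codes)])
    stop("residue(s) outside the accepted alphabet in ", what, ": ",
         paste(bad, collapse = ", "))
  }
  codes
}

#' Clean a raw sequence string: strip terminal stops, reject internal ones
#' @keywords internal
aa_clean <- function(seq, what = "sequence") {
  seq <- toupper(seq)
  seq <- sub("\\*+$", "", seq)
  if (grepl("*", seq, fixed = TRUE))
    stop("internal stop character in ", what)
  seq
}

#' BLOSUM62 substitution matrix over the package alphabet
#'
#' The standard BLOSUM62 log-odds scores for the 20 canonical residues,
#' extended with the ambiguity code X scored as the matrix minimum (-4) against
#' everything, including itself, so an X can never contribute a favourable or
#' matching column.
#'
#' @return a 21 x 21 integer matrix with dimnames over the residue alphabet.
#' @export
#' @examples
#' blosum62()["A", "A"]  # 4
blosum62 <- function() {
  scores <- c(
     4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0, 0,-3,-2,
    -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-3,-2,
    -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-3,-4,-2,
    -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-3,-4,-3,
     0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-1,-2,-2,
    -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-2,-1,
    -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-2,-3,-2,
     0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-3,-2,-3,
    -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-3,-2, 2,
    -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1, 3,-3,-1,
    -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1, 1,-2,-1,
    -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-2,-3,-2,
    -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1, 1,-1,-1,
    -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2,-1, 1, 3,
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-2,-4,-3,
     1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-2,-3,-2,
     0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5, 0,-2,-2,
     0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0, 4,-3,-1,
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,-3,11, 2,
    -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2,-1, 2, 7)
  m20 <- matrix(as.integer(scores), nrow = 20, byrow = TRUE,
                dimnames = list(AA_ALPHABET[1:20], AA_ALPHABET[1:20]))
  m <- matrix(-4L, nrow = 21, ncol = 21,
              dimnames = list(AA_ALPHABET, AA_ALPHABET))
  m[1:20, 1:20] <- m20
  m
}
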