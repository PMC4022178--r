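# Independent reference implementations used as oracles. Written as plain,
# slow R so the fast path in the package never stands in for itself.

ORACLE_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y", "X")

oracle_encode <- function(s) match(strsplit(s, "", fixed = TRUE)[[1]],
                                   ORACLE_AA)

# Reference affine-gap DP (Gotoh) with the same declared conventions as the
# package: gap of length k costs go + k*ge; tie priority diagonal (M) >
# vertical (gap in b, consuming a) > horizontal; local mode prefers extending
# over restarting, best cell ties resolved to smallest i then smallest j.
ref_align <- function(a, b, local = FALSE, mat = blosum62(),
                      go = 11, ge = 1) {
  av <- oracle_encode(a); bv <- oracle_encode(b)
  n <- length(av); m <- length(bv)
  NEG <- -Inf
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  pM <- pX <- pY <- matrix("S", n + 1, m + 1)
  if (!local) {
    M[1, 1] <- 0
    for (i in seq_len(n)) {
      X[i + 1, 1] <- -(go + i * ge)
      pX[i + 1, 1] <- if (i == 1) "M" else "X"
    }
    for (j in seq_len(m)) {
      Y[1, j + 1] <- -(go + j * ge)
      pY[1, j + 1] <- if (j == 1) "M" else "Y"
    }
  }
  pick <- function(mv, xv, yv) {
    best <- mv; who <- "M"
    if (xv > best) { best <- xv; who <- "X" }
    if (yv > best) { best <- yv; who <- "Y" }
    list(best, who)
  }
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- mat[av[i], bv[j]]
    p <- pick(M[i, j], X[i, j], Y[i, j])
    if (local && p[[1]] < 0) p <- list(0, "S")
    if (p[[1]] > NEG) { M[i + 1, j + 1] <- s + p[[1]]; pM[i + 1, j + 1] <- p[[2]] }
    p <- pick(M[i, j + 1] - go - ge, X[i, j + 1] - ge, Y[i, j + 1] - go - ge)
    if (p[[1]] > NEG) { X[i + 1, j + 1] <- p[[1]]; pX[i + 1, j + 1] <- p[[2]] }
    p <- pick(M[i + 1, j] - go - ge, X[i + 1, j] - go - ge, Y[i + 1, j] - ge)
    if (p[[1]] > NEG) { Y[i + 1, j + 1] <- p[[1]]; pY[i + 1, j + 1] <- p[[2]] }
  }
  if (local) {
    score <- 0; ei <- 0; ej <- 0
    for (i in seq_len(n)) for (j in seq_len(m))
      if (M[i + 1, j + 1] > score) { score <- M[i + 1, j + 1]; ei <- i; ej <- j }
    if (score <= 0)
      return(list(score = 0, n_matches = 0, n_columns = 0, n_respair = 0,
                  len_a = 0, len_b = 0))
    state <- "M"
  } else {
    p <- pick(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
    score <- p[[1]]; state <- p[[2]]; ei <- n; ej <- m
  }
  i <- ei; j <- ej
  n_matches <- n_columns <- n_respair <- len_a <- len_b <- 0
  repeat {
    if (state == "M") {
      prev <- pM[i + 1, j + 1]
      n_columns <- n_columns + 1; n_respair <- n_respair + 1
      len_a <- len_a + 1; len_b <- len_b + 1
      if (av[i] == bv[j] && ORACLE_AA[av[i]] != "X")
        n_matches <- n_matches + 1
      i <- i - 1; j <- j - 1
      if (local && prev == "S") break
    } else if (state == "X") {
      prev <- pX[i + 1, j + 1]
      n_columns <- n_columns + 1; len_a <- len_a + 1
      i <- i - 1
    } else {
      prev <- pY[i + 1, j + 1]
      n_columns <- n_columns + 1; len_b <- len_b + 1
      j <- j - 1
    }
    state <- prev
    if (!local && i == 0 && j == 0) break
  }
  list(score = score, n_matches = n_matches, n_columns = n_columns,
       n_respair = n_respair, len_a = len_a, len_b = len_b)
}

ref_global_identity <- function(a, b, ...) {
  r <- ref_align(a, b, local = FALSE, ...)
  if (r$n_respair > 0) r$n_matches / r$n_respair else 0
}

ref_local <- function(a, b, ...) {
  r <- ref_align(a, b, local = TRUE, ...)
  list(identity = if (r$n_columns > 0) r$n_matches / r$n_columns else 0,
       coverage_a = r$len_a / nchar(a), coverage_b = r$len_b / nchar(b),
       score = r$score)
}

# Exhaustive enumeration of every global alignment of two tiny sequences,
# scoring each complete alignment directly (substitutions plus go + len*ge per
# gap run). Returns the optimal score. Only usable for lengths <= ~7.
enum_global_score <- function(a, b, mat = blosum62(), go = 11, ge = 1) {
  av <- oracle_encode(a); bv <- oracle_encode(b)
  best <- -Inf
  recurse <- function(i, j, cols) {
    if (i > length(av) && j > length(bv)) {
      # a gap run is a maximal stretch of gap columns in the SAME sequence;
      # adjacent gaps that switch sequence open a new run
      score <- 0; run <- 0; run_type <- 0L
      for (col in cols) {
        type <- if (col[1] > 0 && col[2] > 0) 0L else if (col[1] > 0) 1L else 2L
        if (type == 0L) {
          if (run > 0) { score <- score - go - run * ge; run <- 0 }
          score <- score + mat[col[1], col[2]]
        } else {
          if (run > 0 && type != run_type) {
            score <- score - go - run * ge; run <- 0
          }
          run <- run + 1; run_type <- type
        }
      }
      if (run > 0) score <- score - go - run * ge
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv))
      recurse(i + 1, j + 1, c(cols, list(c(av[i], bv[j]))))
    if (i <= length(av))
      recurse(i + 1, j, c(cols, list(c(av[i], 0L))))
    if (j <= length(bv))
      recurse(i, j + 1, c(cols, list(c(0L, bv[j]))))
    invisible()
  }
  recurse(1L, 1L, list())
  best
}

# sort-based median/MAD oracle: no calls into stats::median/mad
sort_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}
ref_median_mad <- function(x) {
  med <- sort_median(x)
  c(median = med, mad = sort_median(abs(x - med)))
}

random_seq <- function(n) paste(sample(ORACLE_AA[1:20], n, replace = TRUE),
                                collapse = "")

# canonical form of a partition: sorted member strings
canon_partition <- function(parts) {
  unname(sort(vapply(parts, function(g) paste(sort(g), collapse = ","),
                     character(1))))
}

planted_partition <- function(truth) {
  keep <- truth$role != "background" & !truth$is_truncated
  split(truth$gene_id[keep], truth$role[keep])
}

detected_partition <- function(groups) split(groups$gene_id, groups$group_id)
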