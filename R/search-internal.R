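# Integer-encoded hot path for the local search: alignments are m x l
# integer matrices with 0 for an indel and 1..K for the matrix row index of
# a residue.  Semantically identical to the character-level operations
# (block_moves / apply_move / bsp), which remain the reference interface and
# are cross-validated against these in the tests.

ialn_encode <- function(aln, alpha) {
  chars <- unclass(aln)
  idx <- match(chars, alpha)
  idx[chars == "-"] <- 0L
  if (anyNA(idx)) {
    stop("residue '", chars[is.na(idx) & chars != "-"][1L],
         "' is not covered by the substitution matrix")
  }
  dim(idx) <- dim(chars)
  idx
}

ialn_decode <- function(imat, alpha, ids = NULL) {
  chars <- c("-", alpha)[imat + 1L]
  dim(chars) <- dim(imat)
  msa_aln(chars, ids = ids)
}

# enumerate block moves on an integer alignment; returns a 4-column integer
# matrix (row, start, size, shift) in the deterministic sweep order
imoves <- function(imat, k) {
  m <- nrow(imat)
  l <- ncol(imat)
  acc <- vector("list", m)
  for (i in seq_len(m)) {
    gap <- imat[i, ] == 0L
    right_run <- integer(l)
    run <- 0L
    for (j in l:1L) {
      run <- if (gap[j]) run + 1L else 0L
      right_run[j] <- run
    }
    left_run <- integer(l)
    run <- 0L
    for (j in seq_len(l)) {
      run <- if (gap[j]) run + 1L else 0L
      left_run[j] <- run
    }
    rows_i <- list()
    for (start in seq_len(l)) {
      if (gap[start]) next
      end <- start
      while (end <= l && !gap[end] && (end - start + 1L) <= k) {
        size <- end - start + 1L
        g_right <- if (end < l) right_run[end + 1L] else 0L
        g_left <- if (start > 1L) left_run[start - 1L] else 0L
        n_mv <- g_right + g_left
        if (n_mv > 0L) {
          sh <- c(if (g_right > 0L) seq_len(g_right),
                  if (g_left > 0L) -seq_len(g_left))
          rows_i[[length(rows_i) + 1L]] <-
            cbind(i, start, size, sh, deparse.level = 0L)
        }
        end <- end + 1L
      }
    }
    if (length(rows_i)) acc[[i]] <- do.call(rbind, rows_i)
  }
  out <- do.call(rbind, acc)
  if (is.null(out)) out <- matrix(integer(0), 0L, 4L)
  out
}

# apply one move and strip all-gap columns
iapply <- function(imat, row, start, size, shift) {
  end <- start + size - 1L
  r <- imat[row, ]
  block <- r[start:end]
  r[start:end] <- 0L
  r[(start + shift):(end + shift)] <- block
  imat[row, ] <- r
  keep <- colSums(imat == 0L) < nrow(imat)
  if (all(keep)) imat else imat[, keep, drop = FALSE]
}

# biobjective score of an integer alignment; M is the bare substitution
# matrix, diag_m its diagonal
iscore <- function(imat, M, diag_m, count_double_gaps = FALSE) {
  m <- nrow(imat)
  l <- ncol(imat)
  g <- colSums(imat == 0L)
  d <- sum(g * (m - g))
  if (count_double_gaps) d <- d + sum(g * (g - 1L)) / 2
  if (m == 2L) {
    a <- imat[1L, ]
    b <- imat[2L, ]
    both <- a > 0L & b > 0L
    s <- if (any(both)) sum(M[cbind(a[both], b[both])]) else 0L
  } else {
    K <- nrow(M)
    col_of <- rep.int(seq_len(l), rep.int(m, l))
    pos <- imat > 0L
    counts <- tabulate(imat[pos] + K * (col_of[pos] - 1L), nbins = K * l)
    dim(counts) <- c(K, l)
    s <- (sum((M %*% counts) * counts) - sum(diag_m * rowSums(counts))) / 2
  }
  c(s = as.integer(round(s)), d = as.integer(round(d)))
}
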