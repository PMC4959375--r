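# Single-objective and biobjective sum-of-pairs scoring, and dominance.
#
# The biobjective score of an alignment is
#   BSP = (BSP_s, BSP_d),  BSP_s = sum_j S_s(j),  BSP_d = sum_j S_d(j),
# where S_s(j) sums the substitution-matrix score over all unordered residue
# pairs of column j, and S_d(j) counts the pairs of column j in which exactly
# one member is an indel (both-indel pairs count 0 under the default
# convention; set count_double_gaps = TRUE for the literal reading in which
# they count 1).  BSP_s is maximized, BSP_d minimized.

# residue index vector for an alignment against a matrix alphabet; errors on
# residues the matrix does not cover
aln_residue_index <- function(aln, matrix) {
  alpha <- rownames(matrix)
  chars <- unclass(aln)
  idx <- match(chars, alpha)
  bad <- is.na(idx) & chars != "-"
  if (any(bad)) {
    stop("residue '", chars[bad][1L], "' is not covered by the substitution matrix")
  }
  idx
}

#' Biobjective sum-of-pairs score
#'
#' Computes the score vector `(s, d)` of an alignment: `s` is the total
#' substitution score over all unordered row pairs in every column (indel
#' pairs contribute 0), `d` is the total count of column pairs with exactly
#' one indel (optionally also both-indel pairs).
#'
#' @param aln an [msa_aln()].
#' @param matrix substitution matrix (see [read_substitution_matrix()],
#'   [identity_matrix()]); default is the +1/-1 identity matrix over the
#'   alignment's alphabet.
#' @param count_double_gaps if `TRUE`, a pair of two indels also counts 1
#'   towards `d` (the literal reading of the column distance); default
#'   `FALSE`, which keeps all-gap columns score-neutral and preserves the
#'   identity `SP = s + W_d * d`.
#' @return Named integer vector `c(s = , d = )`.
#' @examples
#' bsp(msa_aln(c("AC-", "A-C")))  # c(s = 1, d = 2)
#' @export
bsp <- function(aln, matrix = NULL, count_double_gaps = FALSE) {
  aln <- as_aln(aln)
  if (is.null(matrix)) matrix <- default_matrix_for(unclass(aln))
  m <- nrow(aln)
  l <- ncol(aln)
  idx <- aln_residue_index(aln, matrix)
  gap <- unclass(aln) == "-"
  g <- colSums(gap)
  d <- sum(g * (m - g))
  if (count_double_gaps) d <- d + sum(g * (g - 1L)) / 2
  K <- nrow(matrix)
  col_of <- rep.int(seq_len(l), rep.int(m, l))
  keep <- !is.na(idx)
  counts <- tabulate(idx[keep] + K * (col_of[keep] - 1L), nbins = K * l)
  dim(counts) <- c(K, l)
  mm <- matrix
  attributes(mm) <- attributes(mm)["dim"]
  ss <- (sum((mm %*% counts) * counts) - sum(diag(mm) * rowSums(counts))) / 2
  c(s = as.integer(round(ss)), d = as.integer(round(d)))
}

#' Per-column biobjective score
#'
#' The column contributions `(S_s(j), S_d(j))` that [bsp()] sums.
#'
#' @inheritParams bsp
#' @param j 1-based column index.
#' @return Named integer vector `c(s = , d = )` for column `j`.
#' @export
column_score_pair <- function(aln, j, matrix = NULL, count_double_gaps = FALSE) {
  aln <- as_aln(aln)
  if (j < 1L || j > ncol(aln)) {
    stop("column index ", j, " out of range 1..", ncol(aln))
  }
  col <- unclass(aln)[, j, drop = FALSE]
  # single-column alignment through bsp keeps the two code paths identical
  one <- structure(col, class = class(aln))
  bsp(one, matrix = matrix, count_double_gaps = count_double_gaps)
}

#' Single-objective sum-of-pairs score
#'
#' The classical weighted sum-of-pairs: residue pairs score by the
#' substitution matrix, residue-indel pairs score `w_d`, indel-indel pairs
#' score 0.  Computed directly from its definition (not via [bsp()]), so the
#' identity `SP = BSP_s + W_d * BSP_d` can be tested rather than assumed.
#'
#' @inheritParams bsp
#' @param w_d integer weight of one indel pair.
#' @return Integer score.
#' @export
sum_of_pairs <- function(aln, matrix = NULL, w_d = -1L) {
  aln <- as_aln(aln)
  if (is.null(matrix)) matrix <- default_matrix_for(unclass(aln))
  chars <- unclass(aln)
  m <- nrow(chars)
  alpha <- rownames(matrix)
  total <- 0L
  for (i in seq_len(m - 1L)) {
    for (k in (i + 1L):m) {
      a <- chars[i, ]
      b <- chars[k, ]
      ga <- a == "-"
      gb <- b == "-"
      both <- !ga & !gb
      if (any(both)) {
        ia <- match(a[both], alpha)
        ib <- match(b[both], alpha)
        if (anyNA(ia) || anyNA(ib)) {
          stop("residue not covered by the substitution matrix")
        }
        total <- total + sum(matrix[cbind(ia, ib)])
      }
      total <- total + as.integer(w_d) * sum(xor(ga, gb))
    }
  }
  as.integer(total)
}

#' Compare two score vectors by Pareto dominance
#'
#' `v1` dominates `v2` iff `v1["s"] >= v2["s"]` and `v1["d"] <= v2["d"]` with
#' at least one strict inequality (substitution score maximized, indel count
#' minimized).
#'
#' @param v1,v2 score vectors as returned by [bsp()] (numeric length 2,
#'   substitution score first).
#' @return One of `"dominates"`, `"dominated"`, `"equal"`, `"incomparable"`.
#' @examples
#' compare_scores(c(5, 2), c(4, 3))  # "dominates"
#' @export
compare_scores <- function(v1, v2) {
  s1 <- v1[[1L]]; d1 <- v1[[2L]]
  s2 <- v2[[1L]]; d2 <- v2[[2L]]
  if (s1 == s2 && d1 == d2) return("equal")
  if (s1 >= s2 && d1 <= d2) return("dominates")
  if (s2 >= s1 && d2 <= d1) return("dominated")
  "incomparable"
}
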