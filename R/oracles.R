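# Independent oracles: exact biobjective pairwise dynamic programming,
# exhaustive pairwise enumeration, brute-force condition-checking
# neighborhoods, and grid-counting hypervolume.  These deliberately share no
# traversal code with the modules they validate.

# quadratic non-dominated filter local to the oracles (maximize s, minimize d)
oracle_nondominated <- function(V) {
  V <- unique(V)
  n <- nrow(V)
  if (n <= 1L) return(V)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (V[j, 1L] >= V[i, 1L] && V[j, 2L] <= V[i, 2L] &&
          (V[j, 1L] > V[i, 1L] || V[j, 2L] < V[i, 2L])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  V[keep, , drop = FALSE]
}

#' Exact biobjective Pareto front of a pairwise alignment
#'
#' Dynamic programming over the pairwise alignment lattice that propagates a
#' Pareto set of (substitution score, indel count) vectors per cell: a
#' match/mismatch step adds the substitution score, a gap step adds 1 to the
#' indel count.  Returns the complete non-dominated score set with one
#' witness alignment per vector.  Intended for sequences up to a few tens of
#' residues; the complexity grows with the front size per cell.
#'
#' @param a,b residue strings (no gaps).
#' @param matrix substitution matrix; default +1/-1 identity over the
#'   sequences' alphabet.
#' @return A list of class `msa_exact_front` with elements `vectors`
#'   (non-dominated integer matrix, columns `s`, `d`, sorted by decreasing
#'   `s`) and `witnesses` (list of 2-row [msa_aln()], one per vector).
#' @examples
#' exact_pairwise_front("A", "C")$vectors  # (0, 2) and (-1, 0)
#' @export
exact_pairwise_front <- function(a, b, matrix = NULL) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) < 1L || nchar(b) < 1L) stop("sequences must be non-empty")
  if (is.null(matrix)) matrix <- default_matrix_for(c(strsplit(a, "")[[1L]],
                                                      strsplit(b, "")[[1L]]))
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  alpha <- rownames(matrix)
  ia <- match(av, alpha)
  ib <- match(bv, alpha)
  if (anyNA(ia) || anyNA(ib)) {
    stop("residue not covered by the substitution matrix")
  }
  n <- length(av)
  p <- length(bv)
  # per-cell Pareto set: matrix of (s, d) plus parallel witness strings
  prune <- function(cell) {
    if (nrow(cell$v) <= 1L) return(cell)
    ord <- order(-cell$v[, 1L], cell$v[, 2L])
    v <- cell$v[ord, , drop = FALSE]
    ra <- cell$ra[ord]
    rb <- cell$rb[ord]
    keep <- logical(nrow(v))
    best_d <- Inf
    for (t in seq_len(nrow(v))) {
      if (v[t, 2L] < best_d) {
        keep[t] <- TRUE
        best_d <- v[t, 2L]
      }
    }
    list(v = v[keep, , drop = FALSE], ra = ra[keep], rb = rb[keep])
  }
  prev <- vector("list", p + 1L)
  prev[[1L]] <- list(v = base::matrix(c(0L, 0L), 1L, 2L), ra = "", rb = "")
  for (j in seq_len(p)) {
    base <- prev[[j]]
    prev[[j + 1L]] <- list(v = cbind(base$v[, 1L], base$v[, 2L] + 1L),
                           ra = paste0(base$ra, "-"),
                           rb = paste0(base$rb, bv[j]))
  }
  for (i in seq_len(n)) {
    cur <- vector("list", p + 1L)
    up <- prev[[1L]]
    cur[[1L]] <- list(v = cbind(up$v[, 1L], up$v[, 2L] + 1L),
                      ra = paste0(up$ra, av[i]),
                      rb = paste0(up$rb, "-"))
    for (j in seq_len(p)) {
      diag_cell <- prev[[j]]
      up_cell <- prev[[j + 1L]]
      left_cell <- cur[[j]]
      sc <- matrix[ia[i], ib[j]]
      v <- rbind(cbind(diag_cell$v[, 1L] + sc, diag_cell$v[, 2L]),
                 cbind(up_cell$v[, 1L], up_cell$v[, 2L] + 1L),
                 cbind(left_cell$v[, 1L], left_cell$v[, 2L] + 1L))
      ra <- c(paste0(diag_cell$ra, av[i]),
              paste0(up_cell$ra, av[i]),
              paste0(left_cell$ra, "-"))
      rb <- c(paste0(diag_cell$rb, bv[j]),
              paste0(up_cell$rb, "-"),
              paste0(left_cell$rb, bv[j]))
      cur[[j + 1L]] <- prune(list(v = v, ra = ra, rb = rb))
    }
    prev <- cur
  }
  final <- prev[[p + 1L]]
  colnames(final$v) <- c("s", "d")
  witnesses <- lapply(seq_len(nrow(final$v)), function(t) {
    msa_aln(c(final$ra[t], final$rb[t]), ids = c("a", "b"))
  })
  structure(list(vectors = final$v, witnesses = witnesses),
            class = "msa_exact_front")
}

#' @export
print.msa_exact_front <- function(x, ...) {
  cat("Exact pairwise front:", nrow(x$vectors), "non-dominated score vectors\n")
  print(x$vectors)
  invisible(x)
}

#' Exhaustive-enumeration pairwise front
#'
#' Recursively enumerates every feasible pairwise alignment (no all-gap
#' column, so the total length is at most `nchar(a) + nchar(b)`), records
#' every achievable (substitution score, indel count) vector, and filters
#' the non-dominated set with an all-pairs check.  Exponential; only for
#' short sequences (lengths up to ~8), where it serves as the independent
#' ground truth for [exact_pairwise_front()].
#'
#' @inheritParams exact_pairwise_front
#' @return Integer matrix of the non-dominated vectors, columns `s`, `d`,
#'   sorted by decreasing `s`.
#' @export
enumerate_pairwise_front <- function(a, b, matrix = NULL) {
  a <- toupper(a); b <- toupper(b)
  if (is.null(matrix)) matrix <- default_matrix_for(c(strsplit(a, "")[[1L]],
                                                      strsplit(b, "")[[1L]]))
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  alpha <- rownames(matrix)
  ia <- match(av, alpha)
  ib <- match(bv, alpha)
  n <- length(av)
  p <- length(bv)
  M <- matrix
  attributes(M) <- attributes(M)["dim"]
  q <- min(n, p)
  s_min <- min(0L, min(M) * q)
  s_max <- max(0L, max(M) * q)
  off <- 1L - s_min
  seen <- base::matrix(FALSE, s_max - s_min + 1L, n + p + 1L)
  rec <- function(i, j, s, d) {
    if (i == 0L && j == 0L) {
      seen[s + off, d + 1L] <<- TRUE
      return(invisible(NULL))
    }
    if (i > 0L && j > 0L) rec(i - 1L, j - 1L, s + M[ia[i], ib[j]], d)
    if (i > 0L) rec(i - 1L, j, s, d + 1L)
    if (j > 0L) rec(i, j - 1L, s, d + 1L)
    invisible(NULL)
  }
  rec(n, p, 0L, 0L)
  hits <- which(seen, arr.ind = TRUE)
  V <- cbind(s = hits[, 1L] - off, d = hits[, 2L] - 1L)
  storage.mode(V) <- "integer"
  V <- oracle_nondominated(V)
  V[order(-V[, 1L], V[, 2L]), , drop = FALSE]
}

#' Brute-force k-block neighborhood
#'
#' Enumerates every same-length rewrite of every single row (all placements
#' of that row's residues, in order, among the columns) and keeps those
#' satisfying the neighbor conditions directly: at most `k` residues change
#' position, and the changed positions are contiguous in both the original
#' and the rewritten row.  Results are stripped of all-gap columns and
#' deduplicated.  Independent of the move-based enumerator in
#' [neighbors()]; exponential, for small alignments only.
#'
#' @inheritParams neighbors
#' @return A list of [msa_aln()] objects.
#' @export
brute_force_neighbors <- function(aln, k) {
  aln <- as_aln(aln)
  chars <- unclass(aln)
  m <- nrow(chars)
  l <- ncol(chars)
  out <- list()
  seen <- character(0)
  for (i in seq_len(m)) {
    row <- chars[i, ]
    res <- row[row != "-"]
    cnt <- length(res)
    pi_b <- which(row != "-")
    if (cnt == l) next  # gap-free row admits no rewrite
    placements <- utils::combn(l, cnt)
    for (c in seq_len(ncol(placements))) {
      pi_c <- placements[, c]
      changed <- which(pi_b != pi_c)
      if (!length(changed) || length(changed) > k) next
      if (length(changed) > 1L) {
        if (any(diff(pi_b[changed]) != 1L) || any(diff(pi_c[changed]) != 1L)) next
      }
      cand <- chars
      newrow <- rep("-", l)
      newrow[pi_c] <- res
      cand[i, ] <- newrow
      class(cand) <- class(aln)
      nb <- strip_all_gap_columns(cand)
      key <- aln_key(nb)
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- nb
      }
    }
  }
  out
}

#' Grid-counting hypervolume
#'
#' Counts the integer unit cells of the rectangle `[s_ref, max s] x
#' [min d, d_ref]` dominated by some front point — exact for integer
#' coordinates and fully independent of the sweep in [hypervolume()].
#'
#' @inheritParams hypervolume
#' @return Non-negative number.
#' @export
grid_hypervolume <- function(front, ref) {
  V <- as_score_matrix(front)
  if (!nrow(V)) return(0)
  s_ref <- ref[[1L]]
  d_ref <- ref[[2L]]
  xs <- s_ref:(max(V[, 1L]) - 1L)
  ys <- min(V[, 2L]):(d_ref - 1L)
  if (!length(xs) || !length(ys)) return(0)
  cells <- base::matrix(FALSE, length(xs), length(ys))
  for (t in seq_len(nrow(V))) {
    cover_x <- xs < V[t, 1L]
    cover_y <- ys >= V[t, 2L]
    cells[cover_x, cover_y] <- TRUE
  }
  as.numeric(sum(cells))
}
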