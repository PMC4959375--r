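# Non-dominated archive, dominance filtering and 2-D hypervolume.

#' Create an empty Pareto archive
#'
#' The archive holds pairwise non-dominated, pairwise distinct score vectors,
#' one representative alignment per vector, and an explored flag used by the
#' local search.
#'
#' @return An object of class `msa_archive`.
#' @export
new_archive <- function() {
  structure(list(scores = matrix(integer(0), 0L, 2L,
                                 dimnames = list(NULL, c("s", "d"))),
                 alns = list(),
                 explored = logical(0)),
            class = "msa_archive")
}

#' @export
print.msa_archive <- function(x, ...) {
  cat("Pareto archive:", nrow(x$scores), "entries\n")
  if (nrow(x$scores)) {
    ord <- order(-x$scores[, 1L], x$scores[, 2L])
    print(x$scores[ord, , drop = FALSE])
  }
  invisible(x)
}

#' Number of archive entries
#' @param archive an `msa_archive`.
#' @return Integer count.
#' @export
archive_size <- function(archive) nrow(archive$scores)

#' Archived score front
#'
#' @param archive an `msa_archive`.
#' @return Integer matrix with columns `s`, `d`, sorted by decreasing `s`.
#' @export
archive_front <- function(archive) {
  S <- archive$scores
  S[order(-S[, 1L], S[, 2L]), , drop = FALSE]
}

#' Insert an alignment into a Pareto archive
#'
#' The candidate is accepted iff its score vector is neither dominated by nor
#' equal to any archived vector; on acceptance every archived entry dominated
#' by the candidate is removed.  The archive keeps the first alignment that
#' achieved a score vector and rejects later equal vectors.
#'
#' @param archive an `msa_archive`.
#' @param aln the candidate [msa_aln()].
#' @param score its score vector from [bsp()]; computed by the caller so that
#'   evaluation counting stays in one place.
#' @return A list with elements `archive` (updated) and `accepted` (logical).
#' @export
archive_insert <- function(archive, aln, score) {
  s <- as.integer(score[[1L]])
  d <- as.integer(score[[2L]])
  S <- archive$scores
  if (nrow(S)) {
    # weakly dominated (includes equality): reject
    if (any(S[, 1L] >= s & S[, 2L] <= d)) {
      return(list(archive = archive, accepted = FALSE))
    }
    keep <- !(S[, 1L] <= s & S[, 2L] >= d)
    archive$scores <- S[keep, , drop = FALSE]
    archive$alns <- archive$alns[keep]
    archive$explored <- archive$explored[keep]
  }
  archive$scores <- rbind(archive$scores, c(s = s, d = d))
  archive$alns[[length(archive$alns) + 1L]] <- aln
  archive$explored <- c(archive$explored, FALSE)
  list(archive = archive, accepted = TRUE)
}

#' Merge two archives
#'
#' Inserts every entry of `b` into `a` and filters dominated entries — the
#' merge-and-filter acceptance criterion of the iterated search.
#'
#' @param a,b `msa_archive` objects.
#' @return The merged `msa_archive`.
#' @export
archive_merge <- function(a, b) {
  for (i in seq_len(archive_size(b))) {
    res <- archive_insert(a, b$alns[[i]], b$scores[i, ])
    a <- res$archive
    if (res$accepted) a$explored[archive_size(a)] <- b$explored[i]
  }
  a
}

#' Filter a set of score vectors to its non-dominated subset
#'
#' @param vectors numeric matrix with two columns (substitution score,
#'   indel count) or a vector of length 2.
#' @return Integer matrix of the distinct non-dominated vectors, sorted by
#'   decreasing substitution score.
#' @examples
#' filter_nondominated(rbind(c(5, 2), c(4, 3), c(6, 1)))  # only (6, 1)
#' @export
filter_nondominated <- function(vectors) {
  V <- as_score_matrix(vectors)
  V <- unique(V)
  if (nrow(V) <= 1L) return(V[order(-V[, 1L]), , drop = FALSE])
  ord <- order(-V[, 1L], V[, 2L])
  V <- V[ord, , drop = FALSE]
  best_d <- V[1L, 2L]
  keep <- c(TRUE, rep(FALSE, nrow(V) - 1L))
  for (i in 2L:nrow(V)) {
    if (V[i, 2L] < best_d) {
      keep[i] <- TRUE
      best_d <- V[i, 2L]
    }
  }
  V[keep, , drop = FALSE]
}

# internal: coerce fronts/vectors to an integer matrix with columns s, d
as_score_matrix <- function(x) {
  if (inherits(x, "msa_archive")) x <- x$scores
  if (is.null(dim(x))) {
    if (length(x) != 2L) stop("a score vector has exactly 2 components")
    x <- matrix(x, 1L, 2L)
  }
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("score matrices have exactly 2 columns")
  storage.mode(x) <- "integer"
  colnames(x) <- c("s", "d")
  rownames(x) <- NULL
  x
}

#' Reference point for hypervolume computation
#'
#' The point `(min s - 1, max d + 1)` over the given vectors, which every
#' input vector strictly dominates.
#'
#' @param vectors score vectors (matrix, archive, or length-2 vector).
#' @return Named integer vector `c(s = , d = )`.
#' @export
reference_point <- function(vectors) {
  V <- as_score_matrix(vectors)
  if (!nrow(V)) stop("reference_point needs at least one score vector")
  c(s = min(V[, 1L]) - 1L, d = max(V[, 2L]) + 1L)
}

#' Hypervolume of a score front
#'
#' Area of the region dominated by the front and bounded by the reference
#' point: the union over front points `(s, d)` of the rectangles
#' `[s_ref, s] x [d, d_ref]`.  Computed by sorting on the substitution score
#' and summing disjoint slabs; exact for integer scores.  Every point must be
#' strictly better than the reference point in both objectives.
#'
#' @param front score vectors (matrix, archive, or length-2 vector); a
#'   dominated input is filtered first.
#' @param ref reference point as from [reference_point()].
#' @return Non-negative number.
#' @examples
#' hypervolume(c(10, 2), c(s = 5, d = 4))  # 10
#' @export
hypervolume <- function(front, ref) {
  V <- as_score_matrix(front)
  if (!nrow(V)) return(0)
  s_ref <- ref[[1L]]
  d_ref <- ref[[2L]]
  bad <- V[, 1L] <= s_ref | V[, 2L] >= d_ref
  if (any(bad)) {
    p <- V[which(bad)[1L], ]
    stop("front point (", p[1L], ", ", p[2L],
         ") does not strictly dominate the reference point (",
         s_ref, ", ", d_ref, ")")
  }
  V <- filter_nondominated(V)  # sorted by decreasing s, increasing d
  hv <- 0
  d_prev <- d_ref
  for (i in seq_len(nrow(V))) {
    hv <- hv + (V[i, 1L] - s_ref) * (d_prev - V[i, 2L])
    d_prev <- V[i, 2L]
  }
  as.numeric(unname(hv))
}

#' Write an archive to disk
#'
#' Writes `front.tsv` (columns `entry`, `s`, `d`) and one aligned-FASTA file
#' per entry (`aln_<entry>.fasta`) into `dir`.
#'
#' @param archive an `msa_archive`.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_archive <- function(archive, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  front <- archive_front(archive)
  ord <- order(-archive$scores[, 1L], archive$scores[, 2L])
  tab <- data.frame(entry = seq_len(nrow(front)), s = front[, 1L], d = front[, 2L])
  utils::write.table(tab, file.path(dir, "front.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (i in seq_along(ord)) {
    write_fasta(archive$alns[[ord[i]]],
                file.path(dir, sprintf("aln_%03d.fasta", i)))
  }
  invisible(dir)
}
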