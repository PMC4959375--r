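# k-block neighborhood: a move slides a contiguous block of at most k
# residues of one row into the contiguous indel run adjacent to it, one
# direction at a time.  Two alignments are k-block neighbors iff they have
# equal size, differ in exactly one row, and the residues whose positions
# differ are at most k and occupy contiguous positions in both alignments.
# Every such neighbor is realized by one block slide, because residue order
# is preserved and a block can only travel across indels.

#' Enumerate the valid block moves of an alignment
#'
#' Moves are listed in a fixed deterministic sweep: rows top to bottom, block
#' start left to right, block size 1..k, right shifts before left shifts,
#' increasing shift distance.
#'
#' @param aln an [msa_aln()].
#' @param k maximum block size (positive integer).
#' @return A data frame with columns `row`, `start` (leftmost block column),
#'   `size` (block length) and `shift` (signed offset; negative = left).
#' @export
block_moves <- function(aln, k) {
  aln <- as_aln(aln)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  chars <- unclass(aln)
  l <- ncol(chars)
  rows <- integer(0); starts <- integer(0); sizes <- integer(0); shifts <- integer(0)
  for (i in seq_len(nrow(chars))) {
    gap <- chars[i, ] == "-"
    # run length of consecutive indels starting at / ending at each column
    right_run <- integer(l)  # indels at and after j (within the run)
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
    for (start in seq_len(l)) {
      if (gap[start]) next
      max_size <- 0L
      j <- start
      while (j <= l && !gap[j] && (j - start + 1L) <= k) {
        max_size <- j - start + 1L
        j <- j + 1L
      }
      for (size in seq_len(max_size)) {
        end <- start + size - 1L
        g_right <- if (end < l) right_run[end + 1L] else 0L
        g_left <- if (start > 1L) left_run[start - 1L] else 0L
        if (g_right > 0L) {
          rows <- c(rows, rep.int(i, g_right))
          starts <- c(starts, rep.int(start, g_right))
          sizes <- c(sizes, rep.int(size, g_right))
          shifts <- c(shifts, seq_len(g_right))
        }
        if (g_left > 0L) {
          rows <- c(rows, rep.int(i, g_left))
          starts <- c(starts, rep.int(start, g_left))
          sizes <- c(sizes, rep.int(size, g_left))
          shifts <- c(shifts, -seq_len(g_left))
        }
      }
    }
  }
  data.frame(row = rows, start = starts, size = sizes, shift = shifts)
}

#' Apply a block move
#'
#' Slides the block of `move$size` residues starting at column `move$start`
#' of row `move$row` by `move$shift` positions (all crossed positions must be
#' indels), then deletes any all-gap column that the move created.
#'
#' @param aln an [msa_aln()].
#' @param move a list or one-row data frame with elements `row`, `start`,
#'   `size`, `shift` (as produced by [block_moves()]).
#' @return The neighboring [msa_aln()].
#' @export
apply_move <- function(aln, move) {
  aln <- as_aln(aln)
  chars <- unclass(aln)
  i <- as.integer(move$row)
  start <- as.integer(move$start)
  size <- as.integer(move$size)
  shift <- as.integer(move$shift)
  l <- ncol(chars)
  end <- start + size - 1L
  if (i < 1L || i > nrow(chars)) stop("move row out of range")
  if (start < 1L || end > l) stop("move block out of range")
  if (shift == 0L) stop("move shift must be nonzero")
  row <- chars[i, ]
  if (any(row[start:end] == "-")) stop("move block contains an indel")
  if (shift > 0L) {
    if (end + shift > l) stop("move shifts block past the alignment end")
    crossed <- row[(end + 1L):(end + shift)]
  } else {
    if (start + shift < 1L) stop("move shifts block past the alignment start")
    crossed <- row[(start + shift):(start - 1L)]
  }
  if (any(crossed != "-")) stop("move block would cross a residue")
  block <- row[start:end]
  row[start:end] <- "-"
  row[(start + shift):(end + shift)] <- block
  chars[i, ] <- row
  out <- chars
  class(out) <- class(aln)
  strip_all_gap_columns(out)
}

#' k-block neighbors of an alignment
#'
#' The set of alignments reachable by one valid block move, each stripped of
#' all-gap columns and deduplicated by row-tuple equality.  A gapless
#' alignment has no neighbors.
#'
#' @inheritParams block_moves
#' @return A list of [msa_aln()] objects in sweep order (first occurrence on
#'   duplication).
#' @seealso [brute_force_neighbors()] for the independent condition-checking
#'   oracle used in tests.
#' @export
neighbors <- function(aln, k) {
  aln <- as_aln(aln)
  moves <- block_moves(aln, k)
  out <- list()
  seen <- character(0)
  for (r in seq_len(nrow(moves))) {
    nb <- apply_move(aln, moves[r, ])
    key <- aln_key(nb)
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- nb
    }
  }
  out
}

#' Number of distinct k-block neighbors
#'
#' @inheritParams block_moves
#' @return Non-negative integer, `length(neighbors(aln, k))`.
#' @export
count_neighbors <- function(aln, k) {
  length(neighbors(aln, k))
}
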