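# Alignment data model: equal-length rows over the residue alphabet plus '-',
# feasibility diagnosis, column surgery and pairwise projection.

#' Construct a multiple sequence alignment
#'
#' An `msa_aln` is an m x l character matrix over the residue alphabet plus
#' the indel character `'-'`.  The constructor enforces equal row lengths;
#' the remaining feasibility conditions (no all-gap column, agreement with a
#' sequence set) are diagnosed by [validate_alignment()].
#'
#' @param rows character vector of aligned row strings, or an m x l character
#'   matrix of single characters.
#' @param ids optional row identifiers (rownames).
#' @return A character matrix of class `msa_aln`.
#' @examples
#' msa_aln(c("AC-", "A-C"))
#' @export
msa_aln <- function(rows, ids = NULL) {
  if (is.matrix(rows)) {
    mat <- rows
  } else {
    rows <- toupper(as.character(rows))
    if (length(rows) < 2L) stop("an alignment needs at least 2 rows")
    lens <- nchar(rows)
    if (length(unique(lens)) != 1L) {
      stop("rows have unequal lengths: ", paste(lens, collapse = ", "))
    }
    if (lens[1L] == 0L) stop("alignment rows are empty")
    mat <- do.call(rbind, strsplit(rows, ""))
  }
  if (!is.null(ids)) rownames(mat) <- as.character(ids)
  class(mat) <- c("msa_aln", class(matrix()))
  mat
}

# internal: accept msa_aln, plain matrix, or row strings
as_aln <- function(x) {
  if (inherits(x, "msa_aln")) return(x)
  msa_aln(x)
}

#' Alignment rows as strings
#'
#' @param aln an [msa_aln()].
#' @return Character vector of row strings.
#' @export
aln_rows <- function(aln) {
  unname(apply(unclass(aln), 1L, paste, collapse = ""))
}

#' @export
print.msa_aln <- function(x, ...) {
  cat("Alignment:", nrow(x), "rows x", ncol(x), "columns\n")
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("row", seq_len(nrow(x)))
  rows <- aln_rows(x)
  for (i in seq_along(rows)) cat(sprintf("  %-12s %s\n", ids[i], rows[i]))
  invisible(x)
}

#' Recover the unaligned sequences of an alignment
#'
#' Applies the gap-removing homomorphism to each row.
#'
#' @param aln an [msa_aln()].
#' @param alphabet as in [seq_set()].
#' @return A [seq_set()].
#' @export
aln_sequences <- function(aln, alphabet = "auto") {
  aln <- as_aln(aln)
  seq_set(gsub("-", "", aln_rows(aln), fixed = TRUE),
          ids = rownames(aln), alphabet = alphabet)
}

#' Diagnose alignment feasibility
#'
#' Checks the three feasibility conditions of a multiple sequence alignment:
#' (i) all rows have equal length, (ii) deleting the indels from row i yields
#' sequence i exactly, and (iii) no column consists only of indels.  An empty
#' report means the alignment is feasible.  Coordinates in the report are
#' 1-based.
#'
#' @param aln an [msa_aln()], a character matrix, or a character vector of row
#'   strings (possibly ragged, to allow diagnosing condition i).
#' @param sequences optional [seq_set()] to check condition (ii) against; when
#'   omitted only conditions (i) and (iii) are checked.
#' @return A data frame with columns `condition` ("i", "ii" or "iii"), `row`,
#'   `column` and `message`; zero rows iff feasible.
#' @export
validate_alignment <- function(aln, sequences = NULL) {
  out <- data.frame(condition = character(), row = integer(),
                    column = integer(), message = character(),
                    stringsAsFactors = FALSE)
  add <- function(cond, row, col, msg) {
    rbind(out, data.frame(condition = cond, row = row, column = col,
                          message = msg, stringsAsFactors = FALSE))
  }
  if (!is.matrix(aln)) {
    rows <- toupper(as.character(aln))
    lens <- nchar(rows)
    if (length(unique(lens)) != 1L) {
      for (i in which(lens != lens[1L])) {
        out <- add("i", i, NA_integer_,
                   sprintf("row %d has length %d, row 1 has length %d",
                           i, lens[i], lens[1L]))
      }
      return(out)
    }
    aln <- msa_aln(rows)
  }
  m <- nrow(aln)
  l <- ncol(aln)
  gap <- unclass(aln) == "-"
  for (j in which(colSums(gap) == m)) {
    out <- add("iii", NA_integer_, j, sprintf("column %d contains only indels", j))
  }
  if (!is.null(sequences)) {
    stripped <- gsub("-", "", aln_rows(aln), fixed = TRUE)
    if (length(stripped) != length(sequences$seqs)) {
      out <- add("ii", NA_integer_, NA_integer_,
                 sprintf("alignment has %d rows but sequence set has %d",
                         length(stripped), length(sequences$seqs)))
    } else {
      for (i in which(stripped != sequences$seqs)) {
        out <- add("ii", i, NA_integer_,
                   sprintf("row %d does not reduce to sequence %s",
                           i, sequences$ids[i]))
      }
    }
  }
  out
}

#' Test alignment feasibility
#'
#' @inheritParams validate_alignment
#' @return `TRUE` iff [validate_alignment()] reports no violation.
#' @export
is_feasible <- function(aln, sequences = NULL) {
  nrow(validate_alignment(aln, sequences)) == 0L
}

#' Delete all-gap columns
#'
#' Removes every column consisting only of indels, preserving the residue
#' order of every row.  Idempotent.
#'
#' @param aln an [msa_aln()].
#' @return An [msa_aln()] with no all-gap column.
#' @export
strip_all_gap_columns <- function(aln) {
  aln <- as_aln(aln)
  keep <- colSums(unclass(aln) == "-") < nrow(aln)
  if (!any(keep)) stop("all columns consist only of indels")
  if (all(keep)) return(aln)
  out <- unclass(aln)[, keep, drop = FALSE]
  class(out) <- class(aln)
  out
}

#' Project an alignment onto a pair of rows
#'
#' Extracts rows `i` and `k` and removes columns where both are indels,
#' yielding the induced feasible pairwise alignment.
#'
#' @param aln an [msa_aln()].
#' @param i,k distinct 1-based row indices.
#' @return A 2-row [msa_aln()].
#' @export
project_pair <- function(aln, i, k) {
  aln <- as_aln(aln)
  m <- nrow(aln)
  if (i < 1L || i > m || k < 1L || k > m) {
    stop("row index out of range (alignment has ", m, " rows)")
  }
  if (i == k) stop("project_pair needs two distinct rows")
  out <- unclass(aln)[c(i, k), , drop = FALSE]
  keep <- colSums(out == "-") < 2L
  out <- out[, keep, drop = FALSE]
  class(out) <- c("msa_aln", class(matrix()))
  out
}

# internal: canonical dedup key for an alignment
aln_key <- function(aln) {
  paste(apply(unclass(aln), 1L, paste, collapse = ""), collapse = "\n")
}
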