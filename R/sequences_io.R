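# Reading and writing sequences, alignments and substitution matrices.

#' Built-in residue alphabets
#'
#' The 20 standard amino-acid one-letter codes and the 4 DNA bases.
#'
#' @name alphabets
#' @keywords internal
PROTEIN_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' @rdname alphabets
#' @keywords internal
DNA_ALPHABET <- c("A", "C", "G", "T")

resolve_alphabet <- function(alphabet, residues = character()) {
  if (is.null(alphabet) || identical(alphabet, "auto")) {
    chars <- unique(unlist(strsplit(residues, "")))
    if (length(chars) && all(chars %in% DNA_ALPHABET)) DNA_ALPHABET else PROTEIN_ALPHABET
  } else if (identical(alphabet, "protein")) {
    PROTEIN_ALPHABET
  } else if (identical(alphabet, "dna")) {
    DNA_ALPHABET
  } else {
    chars <- unique(unlist(strsplit(toupper(alphabet), "")))
    if ("-" %in% chars) stop("alphabet must not contain the indel character '-'")
    sort(chars)
  }
}

#' Construct a sequence set
#'
#' A `seq_set` holds m >= 2 unaligned, non-empty sequences over a residue
#' alphabet.  The indel character `'-'` is never allowed in a sequence set;
#' gapped inputs belong in an alignment (see [msa_aln()]).
#'
#' @param sequences character vector of residue strings (gap-free, non-empty).
#' @param ids unique sequence identifiers; defaults to `seq1..seqm`.
#' @param alphabet `"auto"` (infer DNA vs protein), `"protein"`, `"dna"`, or a
#'   string/character vector of allowed residue characters.
#' @return An object of class `seq_set`: a list with elements `ids`, `seqs`
#'   (uppercase residue strings) and `alphabet` (character vector).
#' @examples
#' seq_set(c("ACDE", "ACE"))
#' @export
seq_set <- function(sequences, ids = NULL, alphabet = "auto") {
  sequences <- toupper(as.character(sequences))
  m <- length(sequences)
  if (m < 2L) stop("a sequence set needs at least 2 sequences, got ", m)
  if (any(nchar(sequences) == 0L)) {
    stop("empty sequence at position ", which(nchar(sequences) == 0L)[1L])
  }
  if (is.null(ids)) ids <- paste0("seq", seq_len(m))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifier: ", ids[duplicated(ids)][1L])
  }
  if (any(grepl("-", sequences, fixed = TRUE))) {
    bad <- ids[grepl("-", sequences, fixed = TRUE)][1L]
    stop("gap character in unaligned input (record ", bad, ")")
  }
  alpha <- resolve_alphabet(alphabet, sequences)
  chars <- unique(unlist(strsplit(sequences, "")))
  if (!all(chars %in% alpha)) {
    bad <- setdiff(chars, alpha)[1L]
    offender <- ids[grepl(bad, sequences, fixed = TRUE)][1L]
    stop("residue '", bad, "' in record ", offender,
         " is outside the declared alphabet")
  }
  structure(list(ids = ids, seqs = sequences, alphabet = alpha),
            class = "seq_set")
}

#' @export
print.seq_set <- function(x, ...) {
  cat("Sequence set:", length(x$seqs), "sequences, lengths",
      paste(range(nchar(x$seqs)), collapse = "-"),
      sprintf("(alphabet of %d residues)\n", length(x$alphabet)))
  for (i in seq_along(x$seqs)) {
    s <- x$seqs[i]
    if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
    cat(sprintf("  %-12s %s\n", x$ids[i], s))
  }
  invisible(x)
}

#' Read unaligned sequences from a FASTA file
#'
#' Sequences are uppercased on read; gap characters are rejected because a
#' sequence set is by definition unaligned.
#'
#' @param path path to a FASTA file.
#' @param alphabet as in [seq_set()].
#' @return A [seq_set()].
#' @export
read_fasta <- function(path, alphabet = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE, seqonly = FALSE)
  if (length(recs) == 0L) stop("empty FASTA file: ", path)
  seq_set(vapply(recs, function(r) as.character(r)[1L], character(1)),
          ids = names(recs), alphabet = alphabet)
}

#' Write a sequence set or alignment to FASTA
#'
#' @param x a [seq_set()] or [msa_aln()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "seq_set")) {
    seqs <- x$seqs
    ids <- x$ids
  } else if (inherits(x, "msa_aln")) {
    seqs <- aln_rows(x)
    ids <- rownames(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  } else {
    stop("x must be a seq_set or msa_aln")
  }
  seqinr::write.fasta(as.list(seqs), names = ids, file.out = path,
                      as.string = TRUE, nbchar = 60)
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_alignment <- function(x, path) {
  if (!inherits(x, "msa_aln")) stop("x must be an msa_aln")
  write_fasta(x, path)
}

#' Read an alignment from aligned FASTA or Clustal format
#'
#' All rows must have equal length after parsing.  Validation against a
#' particular sequence set is a separate step, [validate_alignment()].
#'
#' @param path path to the alignment file.
#' @param format `"fasta"` (aligned FASTA) or `"clustal"`.
#' @return An [msa_aln()].
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                               forceDNAtolower = FALSE)
    if (length(recs) == 0L) stop("empty alignment file: ", path)
    rows <- toupper(vapply(recs, function(r) as.character(r)[1L], character(1)))
    ids <- names(recs)
  } else {
    msa <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    rows <- toupper(as.character(msa))
    ids <- names(rows)
    rows <- unname(rows)
  }
  if (length(unique(nchar(rows))) != 1L) {
    stop("ragged alignment: row lengths ", paste(nchar(rows), collapse = ", "))
  }
  msa_aln(rows, ids = ids)
}

#' Read a substitution matrix in NCBI text format
#'
#' Accepts the de-facto PAM/BLOSUM interchange dialect: `#` comment lines, a
#' header row of residue characters, then one row per residue of integer
#' scores (an optional leading row label is allowed).  The matrix must be
#' square, integer and symmetric.
#'
#' @param path path to the matrix file.
#' @return A symmetric integer matrix with residue dimnames and a `"name"`
#'   attribute (the file's base name).
#' @seealso [identity_matrix()] for the default +1/-1 matrix.
#' @export
read_substitution_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L) stop("not a substitution matrix file: ", path)
  header <- strsplit(lines[[1L]], "\\s+")[[1L]]
  if (any(nchar(header) != 1L)) {
    stop("matrix header must be single residue characters, got: ",
         paste(header, collapse = " "))
  }
  n <- length(header)
  body <- lines[-1L]
  if (length(body) != n) {
    stop("matrix has ", length(body), " rows for ", n, " header residues")
  }
  mat <- matrix(0L, n, n, dimnames = list(header, header))
  for (i in seq_len(n)) {
    cells <- strsplit(body[[i]], "\\s+")[[1L]]
    if (length(cells) == n + 1L) {
      if (cells[[1L]] != header[[i]]) {
        stop("row label '", cells[[1L]], "' does not match header residue '",
             header[[i]], "'")
      }
      cells <- cells[-1L]
    }
    if (length(cells) != n) {
      stop("row ", i, " has ", length(cells), " cells, expected ", n)
    }
    vals <- suppressWarnings(as.numeric(cells))
    if (anyNA(vals) || any(vals != round(vals))) {
      stop("non-integer cell in matrix row ", i)
    }
    mat[i, ] <- as.integer(vals)
  }
  if (!isSymmetric(unname(mat))) {
    bad <- which(mat != t(mat), arr.ind = TRUE)[1L, ]
    stop("asymmetric matrix: score(", header[bad[1L]], ",", header[bad[2L]],
         ") != score(", header[bad[2L]], ",", header[bad[1L]], ")")
  }
  attr(mat, "name") <- basename(path)
  mat
}

#' Identity substitution matrix
#'
#' The default scoring matrix: `match` on the diagonal and `mismatch`
#' elsewhere (+1/-1 unless overridden).
#'
#' @param alphabet as in [seq_set()]; a `seq_set` is also accepted.
#' @param match,mismatch integer scores for equal and unequal residue pairs.
#' @return An integer matrix with residue dimnames.
#' @export
identity_matrix <- function(alphabet = "protein", match = 1L, mismatch = -1L) {
  if (inherits(alphabet, "seq_set")) alphabet <- alphabet$alphabet
  alpha <- resolve_alphabet(alphabet)
  n <- length(alpha)
  mat <- matrix(as.integer(mismatch), n, n, dimnames = list(alpha, alpha))
  diag(mat) <- as.integer(match)
  attr(mat, "name") <- "identity"
  mat
}

# Pick a scoring matrix for an alignment/sequence set when none was given:
# the +1/-1 identity matrix over the observed alphabet (extended to the
# standard protein alphabet so related inputs share one matrix).
default_matrix_for <- function(chars) {
  chars <- setdiff(unique(as.vector(chars)), "-")
  if (length(chars) && all(chars %in% DNA_ALPHABET)) return(identity_matrix("dna"))
  identity_matrix(paste(sort(unique(c(PROTEIN_ALPHABET, chars))), collapse = ""))
}
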