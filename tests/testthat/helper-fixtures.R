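# Shared fixtures and independent mini-oracles for the test suite.
# Everything is generated in code; no data files.

DNA4 <- c("A", "C", "G", "T")

# random feasible alignment: every row keeps >= 1 residue, no all-gap column
random_alignment <- function(m = NULL, l = NULL, alphabet = DNA4,
                             gap_prob = 0.3) {
  if (is.null(m)) m <- sample(2:4, 1)
  if (is.null(l)) l <- sample(3:8, 1)
  repeat {
    mat <- matrix(ifelse(stats::runif(m * l) < gap_prob, "-",
                         sample(alphabet, m * l, replace = TRUE)), m, l)
    if (all(rowSums(mat != "-") >= 1) && all(colSums(mat == "-") < m)) {
      return(msa_aln(apply(mat, 1, paste, collapse = "")))
    }
  }
}

random_sequences <- function(m = NULL, len_range = c(3, 10), alphabet = DNA4) {
  if (is.null(m)) m <- sample(2:4, 1)
  seq_set(vapply(seq_len(m), function(i) {
    paste(sample(alphabet, sample(len_range[1]:len_range[2], 1), replace = TRUE),
          collapse = "")
  }, character(1)))
}

# canonical sortable keys of a list of alignments (set comparison)
aln_keys <- function(alns) {
  sort(vapply(alns, function(x) paste(aln_rows(x), collapse = "|"), character(1)))
}

# independent sum-of-pairs oracle: plain triple loop over columns and row
# pairs, no vectorization shared with bsp()
naive_bsp <- function(aln, matrix = NULL, count_double_gaps = FALSE) {
  chars <- unclass(aln)
  if (is.null(matrix)) matrix <- momsa:::default_matrix_for(chars)
  m <- nrow(chars)
  s <- 0L
  d <- 0L
  for (j in seq_len(ncol(chars))) {
    for (i in seq_len(m - 1)) {
      for (k in (i + 1):m) {
        a <- chars[i, j]
        b <- chars[k, j]
        if (a == "-" && b == "-") {
          if (count_double_gaps) d <- d + 1L
        } else if (a == "-" || b == "-") {
          d <- d + 1L
        } else {
          s <- s + matrix[a, b]
        }
      }
    }
  }
  c(s = as.integer(s), d = d)
}

# quadratic all-pairs non-dominated filter (oracle for filter_nondominated)
quad_nondominated <- function(V) {
  V <- unique(V)
  keep <- vapply(seq_len(nrow(V)), function(i) {
    !any(vapply(seq_len(nrow(V)), function(j) {
      j != i && V[j, 1] >= V[i, 1] && V[j, 2] <= V[i, 2] &&
        (V[j, 1] > V[i, 1] || V[j, 2] < V[i, 2])
    }, logical(1)))
  }, logical(1))
  V[keep, , drop = FALSE]
}

# random integer front for hypervolume checks (not necessarily non-dominated)
random_front <- function(n = NULL) {
  if (is.null(n)) n <- sample(1:8, 1)
  cbind(s = sample(-5:15, n, replace = TRUE),
        d = sample(0:12, n, replace = TRUE))
}

# random feasible alignment OF a given sequence set (random gap padding)
random_alignment_of <- function(seqs, extra = 2) {
  l <- max(nchar(seqs$seqs)) + sample(0:extra, 1)
  rows <- vapply(seqs$seqs, function(s) {
    n <- nchar(s)
    gap_at <- if (l > n) sort(sample.int(l, l - n)) else integer(0)
    row <- character(l)
    row[gap_at] <- "-"
    row[setdiff(seq_len(l), gap_at)] <- strsplit(s, "")[[1]]
    paste(row, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  strip_all_gap_columns(msa_aln(rows, ids = seqs$ids))
}

write_temp_fasta <- function(ids, seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}
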