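# Reference-hypervolume percentage protocol and SP/TC quality ratios.

#' Merge run fronts into a reference front
#'
#' Implements the relative-performance protocol: the score fronts of a
#' collection of runs are merged, the non-dominated scores extracted, the
#' reference point set to (minimum substitution score - 1, maximum indel
#' count + 1) over the union, and the hypervolume of the merged front against
#' that point taken as the reference hypervolume.
#'
#' @param fronts a list of score fronts (two-column matrices or
#'   `msa_archive` objects), optionally named by run label.
#' @return A list with elements `front` (merged non-dominated matrix), `ref`
#'   (reference point) and `ref_hv` (reference hypervolume).
#' @export
reference_front <- function(fronts) {
  if (inherits(fronts, "msa_archive") || (is.matrix(fronts) && ncol(fronts) == 2L)) {
    fronts <- list(fronts)
  }
  if (!length(fronts)) stop("reference_front needs at least one run")
  all_vecs <- do.call(rbind, lapply(fronts, as_score_matrix))
  if (!nrow(all_vecs)) stop("reference_front needs at least one score vector")
  front <- filter_nondominated(all_vecs)
  ref <- reference_point(all_vecs)
  list(front = front, ref = ref, ref_hv = hypervolume(front, ref))
}

#' Hypervolume percentage of a run
#'
#' `100 * hypervolume(front, ref) / ref_hv`; 100 for the reference front
#' itself, 0 for an empty front.
#'
#' @param front a run's score front.
#' @param ref reference point shared by all runs.
#' @param ref_hv reference hypervolume (must be positive).
#' @return Percentage in `[0, 100]`.
#' @export
hv_percentage <- function(front, ref, ref_hv) {
  if (!is.numeric(ref_hv) || ref_hv <= 0) stop("ref_hv must be positive")
  100 * hypervolume(front, ref) / ref_hv
}

# residue ordinal per cell: entry (i, j) is the index of the residue of row i
# sitting in column j, or NA for an indel
residue_ordinals <- function(aln) {
  chars <- unclass(aln)
  t(apply(chars, 1L, function(row) {
    ord <- cumsum(row != "-")
    ord[row == "-"] <- NA_integer_
    ord
  }))
}

# keys of all aligned residue pairs of an alignment: one string per
# (row pair, column) where both rows hold residues
aligned_pair_keys <- function(ords) {
  m <- nrow(ords)
  keys <- character(0)
  for (i in seq_len(m - 1L)) {
    for (k in (i + 1L):m) {
      both <- !is.na(ords[i, ]) & !is.na(ords[k, ])
      if (any(both)) {
        keys <- c(keys, paste(i, k, ords[i, both], ords[k, both], sep = ":"))
      }
    }
  }
  keys
}

#' SP and TC quality ratios against a reference alignment
#'
#' `sp` is the fraction of residue pairs aligned together in the reference
#' that are also aligned together in the test alignment ("correctly aligned
#' pairs").  `tc` is the fraction of reference columns whose full residue
#' tuple is reproduced as a column of the test alignment ("columns correctly
#' aligned").  Both alignments must reduce to the same sequences.
#'
#' When `matrix` is supplied a weighted SP variant is also returned, with
#' each reference residue pair weighted by its substitution score instead of
#' counted; the unweighted ratio is the standard measure.
#'
#' @param test,reference [msa_aln()] objects over the same sequence set.
#' @param matrix optional substitution matrix for the weighted SP variant.
#' @param mask optional logical or integer vector selecting the reference
#'   columns to score (core-block annotation); default all columns.
#' @return A list with elements `sp`, `tc` (fractions in `[0, 1]`) and, when
#'   `matrix` is given, `sp_weighted`.
#' @examples
#' sp_tc_ratios(msa_aln(c("AB-", "A-B")), msa_aln(c("AB", "AB")))
#' @export
sp_tc_ratios <- function(test, reference, matrix = NULL, mask = NULL) {
  test <- as_aln(test)
  reference <- as_aln(reference)
  strip_test <- gsub("-", "", aln_rows(test), fixed = TRUE)
  strip_ref <- gsub("-", "", aln_rows(reference), fixed = TRUE)
  if (length(strip_test) != length(strip_ref) || any(strip_test != strip_ref)) {
    stop("test and reference alignments are bound to different sequence sets")
  }
  if (!is.null(mask)) {
    reference <- unclass(reference)[, mask, drop = FALSE]
    class(reference) <- c("msa_aln", "matrix", "array")
  }
  ro <- residue_ordinals(reference)
  to <- residue_ordinals(test)
  ref_pairs <- aligned_pair_keys(ro)
  test_pairs <- aligned_pair_keys(to)
  hit <- ref_pairs %in% test_pairs
  sp <- if (length(ref_pairs)) sum(hit) / length(ref_pairs) else NaN
  col_key <- function(ords) {
    apply(ords, 2L, function(col) paste(ifelse(is.na(col), ".", col), collapse = ","))
  }
  ref_cols <- col_key(ro)
  test_cols <- col_key(to)
  tc <- sum(test_cols %in% ref_cols) / length(ref_cols)
  out <- list(sp = sp, tc = tc)
  if (!is.null(matrix)) {
    rc <- unclass(reference)
    m <- nrow(rc)
    w <- numeric(0)
    keys <- character(0)
    for (i in seq_len(m - 1L)) {
      for (k in (i + 1L):m) {
        both <- !is.na(ro[i, ]) & !is.na(ro[k, ])
        if (any(both)) {
          keys <- c(keys, paste(i, k, ro[i, both], ro[k, both], sep = ":"))
          w <- c(w, matrix[cbind(rc[i, both], rc[k, both])])
        }
      }
    }
    w <- w - min(w, 0) + as.numeric(min(w, 0) < 0)  # shift to positive weights
    out$sp_weighted <- if (sum(w) > 0) sum(w[keys %in% test_pairs]) / sum(w) else NaN
  }
  out
}

#' Tab-separated evaluation report
#'
#' Writes one row per run: label, best substitution score and its indel
#' count, hypervolume percentage, and (when a reference alignment is given)
#' SP/TC ratios of the best-substitution-score alignment.
#'
#' @param archives named list of `msa_archive` objects (one per run).
#' @param path output file.
#' @param reference optional reference [msa_aln()] for SP/TC.
#' @param matrix optional substitution matrix for the weighted SP variant.
#' @return The report data frame, invisibly; written to `path`.
#' @export
write_evaluation_report <- function(archives, path, reference = NULL,
                                    matrix = NULL) {
  rf <- reference_front(archives)
  labels <- names(archives)
  if (is.null(labels)) labels <- paste0("run", seq_along(archives))
  rows <- lapply(seq_along(archives), function(i) {
    a <- archives[[i]]
    best <- which.max(a$scores[, 1L])
    row <- data.frame(label = labels[i],
                      bsp_s = a$scores[best, 1L],
                      bsp_d = a$scores[best, 2L],
                      hv_pct = hv_percentage(a$scores, rf$ref, rf$ref_hv))
    if (!is.null(reference)) {
      r <- sp_tc_ratios(a$alns[[best]], reference, matrix = matrix)
      row$sp <- r$sp
      row$tc <- r$tc
    }
    row
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
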