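# Synthetic sequence families: a random ancestor evolved independently into
# m descendants by i.i.d. substitutions and geometric-length indels.  The
# generator emulates equidistant protein families at a chosen divergence; it
# anchors all testing without external benchmark data.

#' Describe a synthetic family model
#'
#' @param m number of descendant sequences (>= 2).
#' @param ancestor_length length of the random ancestor (positive).
#' @param substitution_rate per-site probability that a copied residue is
#'   replaced by a different random residue.
#' @param indel_rate per-site probability of an indel event (split evenly
#'   between insertion and deletion).
#' @param max_indel_length truncation of the geometric indel length.
#' @param alphabet as in [seq_set()] (`"protein"` by default).
#' @param seed optional integer seed for [generate_family()].
#' @return A list of class `msa_family_model`.
#' @export
family_model <- function(m = 4L, ancestor_length = 10L,
                         substitution_rate = 0.15, indel_rate = 0.05,
                         max_indel_length = 2L, alphabet = "protein",
                         seed = NULL) {
  if (m < 2L) stop("m must be >= 2")
  if (ancestor_length < 1L) stop("ancestor_length must be positive")
  if (substitution_rate < 0 || substitution_rate > 1) {
    stop("substitution_rate must be in [0, 1]")
  }
  if (indel_rate < 0 || indel_rate > 1) stop("indel_rate must be in [0, 1]")
  if (max_indel_length < 1L) stop("max_indel_length must be positive")
  structure(list(m = as.integer(m),
                 ancestor_length = as.integer(ancestor_length),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 max_indel_length = as.integer(max_indel_length),
                 alphabet = resolve_alphabet(alphabet),
                 seed = seed),
            class = "msa_family_model")
}

# truncated geometric indel length in 1..max_len
rgeom_trunc <- function(p, max_len) {
  len <- 1L + stats::rgeom(1L, p)
  min(len, max_len)
}

#' Generate a related sequence family
#'
#' Draws one random ancestor and derives each descendant independently:
#' every ancestor site may be substituted, deleted (starting a run of
#' truncated-geometric length) or preceded by an insertion of random
#' residues.  Deterministic under the model's seed.
#'
#' @param model a [family_model()].
#' @return A [seq_set()] of `model$m` sequences.
#' @export
generate_family <- function(model) {
  if (!inherits(model, "msa_family_model")) stop("model must be a family_model()")
  if (!is.null(model$seed)) set.seed(model$seed)
  alpha <- model$alphabet
  anc <- sample(alpha, model$ancestor_length, replace = TRUE)
  p_event <- model$indel_rate / 2
  derive <- function() {
    out <- character(0)
    skip <- 0L
    for (pos in seq_along(anc)) {
      if (model$indel_rate > 0 && stats::runif(1L) < p_event) {
        ins <- rgeom_trunc(0.5, model$max_indel_length)
        out <- c(out, sample(alpha, ins, replace = TRUE))
      }
      if (skip > 0L) {
        skip <- skip - 1L
        next
      }
      if (model$indel_rate > 0 && stats::runif(1L) < p_event) {
        skip <- rgeom_trunc(0.5, model$max_indel_length) - 1L
        next
      }
      res <- anc[pos]
      if (model$substitution_rate > 0 &&
          stats::runif(1L) < model$substitution_rate) {
        res <- sample(setdiff(alpha, res), 1L)
      }
      out <- c(out, res)
    }
    if (!length(out)) {
      stop("degenerate model: an empty sequence was produced; ",
           "lower indel_rate or lengthen the ancestor")
    }
    paste(out, collapse = "")
  }
  seqs <- vapply(seq_len(model$m), function(i) derive(), character(1))
  seq_set(seqs, ids = paste0("seq", seq_len(model$m)),
          alphabet = paste(alpha, collapse = ""))
}

#' Mean pairwise identity of a sequence set
#'
#' Identity of the gapless prefix-free pairing is ill-defined without an
#' alignment, so each pair is aligned implicitly position-by-position up to
#' the shorter length; this is a crude but monotone divergence diagnostic
#' used to characterize generated families.
#'
#' @param sequences a [seq_set()].
#' @return Fraction in `[0, 1]`.
#' @keywords internal
mean_pairwise_identity <- function(sequences) {
  seqs <- strsplit(sequences$seqs, "")
  m <- length(seqs)
  ids <- c()
  for (i in seq_len(m - 1L)) {
    for (k in (i + 1L):m) {
      n <- min(length(seqs[[i]]), length(seqs[[k]]))
      ids <- c(ids, mean(seqs[[i]][seq_len(n)] == seqs[[k]][seq_len(n)]))
    }
  }
  mean(ids)
}
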