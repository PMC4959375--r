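# Pareto local search and Pareto iterated local search.
#
# PLS keeps an archive of mutually non-dominated alignments.  It repeatedly
# picks an unexplored archive entry at random, enumerates its full k-block
# neighborhood, and offers every neighbor to the archive; newly accepted
# entries are unexplored.  It terminates "naturally" when every entry has
# been explored (a Pareto local optimal set) or when the evaluation /
# wall-clock budget is exhausted.
#
# PILS (iterated variant) runs PLS, then P rounds of: perturb a spread
# selection of archived alignments by inserting a gap run into every row,
# re-run PLS from the perturbed set alone, and accept by merging the two
# archives and filtering dominated scores.  The total budget is split
# equally over the P + 1 PLS runs.

K_TOKENS <- c(Min = 1, `Min/2` = 2, `Min/4` = 4, `Min/8` = 8, `Min/16` = 16)

#' Resolve a k specifier against the shortest sequence length
#'
#' Accepts an absolute integer or one of the fractional tokens `"Min"`,
#' `"Min/2"`, `"Min/4"`, `"Min/8"`, `"Min/16"`, resolved as
#' `ceiling(Min / c)` with a floor of 1.
#'
#' @param k integer or fractional token.
#' @param min_len length of the shortest sequence.
#' @return Positive integer.
#' @export
resolve_k <- function(k, min_len) {
  if (is.character(k)) {
    if (!k %in% names(K_TOKENS)) {
      stop("unknown k specifier '", k, "'; use an integer or one of ",
           paste(names(K_TOKENS), collapse = ", "))
    }
    k <- ceiling(min_len / K_TOKENS[[k]])
  }
  max(1L, as.integer(k))
}

#' Search configuration
#'
#' @param k neighborhood bound: positive integer or fractional token (see
#'   [resolve_k()]).
#' @param P number of perturbation rounds for [pils()].
#' @param perturb_select number of archived alignments perturbed per round.
#' @param gap_size length of the indel run inserted by perturbation; default
#'   `max(1, ceiling(Min/16))`, resolved against the instance.
#' @param n_starts number of random starting alignments when none are given.
#' @param max_evals evaluation budget (number of alignments scored); `Inf`
#'   means run to natural termination.
#' @param max_seconds wall-clock budget in seconds; `Inf` to disable.
#' @param seed optional integer seed applied on entry to [pls()]/[pils()];
#'   identical inputs, config and seed give identical archives under
#'   evaluation-count budgets.
#' @param matrix substitution matrix; default +1/-1 identity over the input
#'   alphabet.
#' @param count_double_gaps see [bsp()].
#' @param audit if `TRUE`, brute-force check archive non-domination after
#'   every insertion (test instrumentation; quadratic in archive size).
#' @return A list of class `msa_search_config`.
#' @export
search_config <- function(k = "Min", P = 4L, perturb_select = 5L,
                          gap_size = NULL, n_starts = 5L,
                          max_evals = Inf, max_seconds = Inf,
                          seed = NULL, matrix = NULL,
                          count_double_gaps = FALSE, audit = FALSE) {
  if (!is.infinite(max_evals)) max_evals <- as.numeric(max_evals)
  cfg <- list(k = k, P = as.integer(P), perturb_select = as.integer(perturb_select),
              gap_size = gap_size, n_starts = as.integer(n_starts),
              max_evals = max_evals, max_seconds = max_seconds,
              seed = seed, matrix = matrix,
              count_double_gaps = isTRUE(count_double_gaps),
              audit = isTRUE(audit))
  if (cfg$P < 0L) stop("P must be >= 0")
  if (cfg$perturb_select < 1L) stop("perturb_select must be >= 1")
  class(cfg) <- "msa_search_config"
  cfg
}

# shortest sequence length of an alignment (residues per row, gaps removed)
aln_min_len <- function(aln) {
  min(rowSums(unclass(aln) != "-"))
}

#' Random starting alignment
#'
#' Pads every sequence to the length of the longest one by inserting the
#' required number of indels at uniformly random positions; the longest
#' sequence receives none.  The result is always feasible (the longest row
#' is gap-free, so no column can be all-gap) and has the minimum possible
#' alignment length, hence a small number of indels.
#'
#' @param sequences a [seq_set()].
#' @return A feasible [msa_aln()] of length `max(nchar(sequences))`.
#' @export
random_start <- function(sequences) {
  seqs <- sequences$seqs
  l <- max(nchar(seqs))
  rows <- vapply(seqs, function(s) {
    n <- nchar(s)
    if (n == l) return(s)
    gap_at <- sort(sample.int(l, l - n))
    row <- character(l)
    row[gap_at] <- "-"
    row[-gap_at] <- strsplit(s, "")[[1L]]
    paste(row, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  msa_aln(rows, ids = sequences$ids)
}

# quadratic non-domination audit used when config$audit is on
count_dominated_pairs <- function(S) {
  n <- nrow(S)
  if (n < 2L) return(0L)
  bad <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- compare_scores(S[i, ], S[j, ])
      if (r != "incomparable") bad <- bad + 1L
    }
  }
  bad
}

#' Pareto local search
#'
#' @param starts a list of feasible starting [msa_aln()] objects (a single
#'   alignment is also accepted).
#' @param config a [search_config()].
#' @return An `msa_archive` with attributes `evals` (alignments scored),
#'   `natural` (`TRUE` iff the search stopped because the archive is a
#'   Pareto local optimal set rather than on budget) and, when auditing,
#'   `audit_violations`.
#' @export
pls <- function(starts, config = search_config()) {
  if (inherits(starts, "msa_aln")) starts <- list(starts)
  if (!length(starts)) stop("pls needs at least one starting alignment")
  if (!is.null(config$seed)) set.seed(config$seed)
  smat <- config$matrix
  if (is.null(smat)) smat <- default_matrix_for(unclass(as_aln(starts[[1L]])))
  alpha <- rownames(smat)
  M <- smat
  attributes(M) <- attributes(M)["dim"]
  diag_m <- diag(M)
  k <- resolve_k(config$k, aln_min_len(as_aln(starts[[1L]])))
  ids <- rownames(as_aln(starts[[1L]]))
  deadline <- if (is.finite(config$max_seconds)) {
    Sys.time() + config$max_seconds
  } else {
    NULL
  }
  evals <- 0
  violations <- 0L
  arch <- new_archive()
  # Starts seed the search even when their score is dominated on insertion
  # (they are expanded regardless); only archive membership is Pareto-gated.
  pending <- list()
  for (st in starts) {
    imat <- ialn_encode(as_aln(st), alpha)
    keep <- colSums(imat == 0L) < nrow(imat)
    if (!all(keep)) imat <- imat[, keep, drop = FALSE]
    sc <- iscore(imat, M, diag_m, config$count_double_gaps)
    evals <- evals + 1
    res <- archive_insert(arch, imat, sc)
    arch <- res$archive
    if (!res$accepted) pending[[length(pending) + 1L]] <- imat
    if (config$audit && res$accepted) {
      violations <- violations + count_dominated_pairs(arch$scores)
    }
  }
  natural <- TRUE
  budget_left <- function() {
    evals < config$max_evals &&
      (is.null(deadline) || Sys.time() < deadline)
  }
  expand <- function(current) {
    mv <- imoves(current, k)
    for (r in seq_len(nrow(mv))) {
      if (!budget_left()) return(FALSE)
      nb <- iapply(current, mv[r, 1L], mv[r, 2L], mv[r, 3L], mv[r, 4L])
      sc <- iscore(nb, M, diag_m, config$count_double_gaps)
      evals <<- evals + 1
      res <- archive_insert(arch, nb, sc)
      arch <<- res$archive
      if (config$audit && res$accepted) {
        violations <<- violations + count_dominated_pairs(arch$scores)
      }
    }
    TRUE
  }
  repeat {
    open <- which(!arch$explored)
    if (!length(open) && !length(pending)) break
    if (!budget_left()) {
      natural <- FALSE
      break
    }
    if (length(pending)) {
      current <- pending[[1L]]
      pending <- pending[-1L]
    } else {
      pick <- open[sample.int(length(open), 1L)]
      current <- arch$alns[[pick]]
      arch$explored[pick] <- TRUE
    }
    if (!expand(current)) {
      natural <- FALSE
      break
    }
  }
  arch$alns <- lapply(arch$alns, ialn_decode, alpha = alpha, ids = ids)
  attr(arch, "evals") <- evals
  attr(arch, "natural") <- natural
  if (config$audit) attr(arch, "audit_violations") <- violations
  arch
}

#' Perturb archived alignments by gap insertion
#'
#' Selects up to `perturb_select` archived alignments whose score vectors are
#' spread across the front (sorting by indel count and taking the entries at
#' the 0, 1/4, 1/2, 3/4 and 1 quantile positions, topping up at random), then
#' inserts one indel run of length `gap_size` at a uniformly random position
#' into every row of each selected alignment.
#'
#' @param archive a non-empty `msa_archive`.
#' @param config a [search_config()].
#' @return A list of feasible perturbed [msa_aln()] objects.
#' @export
perturb_archive <- function(archive, config = search_config()) {
  n <- archive_size(archive)
  if (!n) stop("cannot perturb an empty archive")
  gap_size <- config$gap_size
  if (is.null(gap_size)) {
    gap_size <- max(1L, ceiling(aln_min_len(archive$alns[[1L]]) / 16))
  }
  gap_size <- as.integer(gap_size)
  want <- min(config$perturb_select, n)
  ord <- order(archive$scores[, 2L], archive$scores[, 1L])
  q <- c(0, 0.25, 0.5, 0.75, 1)[seq_len(min(5L, want))]
  sel <- unique(ord[ceiling(q * (n - 1L)) + 1L])
  if (length(sel) < want) {
    pool <- setdiff(seq_len(n), sel)
    sel <- c(sel, pool[sample.int(length(pool), want - length(sel))])
  }
  lapply(sel, function(i) {
    chars <- unclass(archive$alns[[i]])
    l <- ncol(chars)
    rows <- vapply(seq_len(nrow(chars)), function(r) {
      row <- paste(chars[r, ], collapse = "")
      at <- sample.int(l + 1L, 1L) - 1L  # insert after position `at`
      paste0(substr(row, 1L, at), strrep("-", gap_size),
             substr(row, at + 1L, l))
    }, character(1))
    strip_all_gap_columns(msa_aln(rows, ids = rownames(chars)))
  })
}

#' Pareto iterated local search
#'
#' Runs [pls()] on the starting alignments, then rounds of perturbation (gap
#' insertion into a spread selection of archived alignments), PLS restarted
#' from the perturbed set alone, and merge-and-filter acceptance.  Each
#' inner PLS run is capped at `budget / (P + 1)` — the equal-slice rule of
#' the iterated search.
#'
#' Round semantics follow the budget: with a finite budget (`max_evals`
#' and/or `max_seconds`) perturbation rounds repeat until the total budget
#' is exhausted, so `P` governs the slice granularity — small `P` gives few
#' deep PLS runs, large `P` many shallow ones.  With an unbounded budget
#' exactly `P` rounds are executed (every PLS run then terminates
#' naturally).  With `P = 0` the search reduces to plain [pls()] on the
#' full budget.
#'
#' @param sequences a [seq_set()]; used to build `n_starts` random starting
#'   alignments when `starts` is not given.
#' @param config a [search_config()].
#' @param starts optional list of starting [msa_aln()] objects.
#' @return An `msa_archive` with attributes `evals`, `natural` (all PLS runs
#'   terminated naturally), `rounds` (list of score fronts after the initial
#'   PLS and after each acceptance step, for monotonicity auditing) and,
#'   when auditing, `audit_violations`.
#' @export
pils <- function(sequences = NULL, config = search_config(), starts = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(starts)) {
    if (is.null(sequences)) stop("pils needs sequences or starting alignments")
    starts <- lapply(seq_len(config$n_starts), function(i) random_start(sequences))
  }
  if (inherits(starts, "msa_aln")) starts <- list(starts)
  P <- config$P
  finite_budget <- is.finite(config$max_evals) || is.finite(config$max_seconds)
  deadline <- if (is.finite(config$max_seconds)) {
    Sys.time() + config$max_seconds
  } else {
    NULL
  }
  inner <- config
  inner$seed <- NULL
  if (is.finite(config$max_evals)) inner$max_evals <- config$max_evals / (P + 1)
  if (is.finite(config$max_seconds)) inner$max_seconds <- config$max_seconds / (P + 1)
  if (is.null(inner$matrix)) {
    inner$matrix <- default_matrix_for(unclass(as_aln(starts[[1L]])))
  }
  arch <- pls(starts, inner)
  evals <- attr(arch, "evals")
  natural <- attr(arch, "natural")
  violations <- attr(arch, "audit_violations")
  rounds <- list(archive_front(arch))
  r <- 0L
  repeat {
    r <- r + 1L
    if (P == 0L) break
    if (finite_budget) {
      if (is.finite(config$max_evals) && evals >= config$max_evals) break
      if (!is.null(deadline) && Sys.time() >= deadline) break
    } else if (r > P) {
      break
    }
    slice <- inner
    if (is.finite(config$max_evals)) {
      slice$max_evals <- min(inner$max_evals, config$max_evals - evals)
    }
    if (!is.null(deadline)) {
      slice$max_seconds <- min(inner$max_seconds,
                               as.numeric(deadline - Sys.time(), units = "secs"))
    }
    pert <- perturb_archive(arch, slice)
    arch2 <- pls(pert, slice)
    evals <- evals + attr(arch2, "evals")
    natural <- natural && attr(arch2, "natural")
    if (config$audit) violations <- violations + attr(arch2, "audit_violations")
    arch <- archive_merge(arch, arch2)
    if (config$audit) violations <- violations + count_dominated_pairs(arch$scores)
    rounds[[length(rounds) + 1L]] <- archive_front(arch)
  }
  attr(arch, "evals") <- evals
  attr(arch, "natural") <- natural
  attr(arch, "rounds") <- rounds
  if (config$audit) attr(arch, "audit_violations") <- violations
  arch
}

#' Hypervolume trajectory of an iterated search
#'
#' Computes the hypervolume of every per-round front recorded by [pils()]
#' against one common reference point (derived from the union of all rounds),
#' so the merge-and-filter acceptance guarantee — hypervolume never decreases
#' between rounds — can be audited.
#'
#' @param result an archive returned by [pils()].
#' @return Numeric vector of hypervolumes, one per round.
#' @export
pils_round_hypervolumes <- function(result) {
  rounds <- attr(result, "rounds")
  if (is.null(rounds)) stop("result carries no per-round fronts; use pils()")
  ref <- reference_point(do.call(rbind, rounds))
  vapply(rounds, hypervolume, numeric(1), ref = ref)
}

#' Verify that an archive is a Pareto local optimal set
#'
#' Re-sweeps the full k-block neighborhood of every archived alignment and
#' counts how many neighbors the archive would accept.  When [pls()]
#' terminated naturally the count is 0.
#'
#' @param archive an `msa_archive`.
#' @param config the [search_config()] the archive was produced with.
#' @return Number of would-be acceptances (integer).
#' @export
verify_local_optimum <- function(archive, config = search_config()) {
  if (!archive_size(archive)) return(0L)
  matrix <- config$matrix
  if (is.null(matrix)) matrix <- default_matrix_for(unclass(archive$alns[[1L]]))
  k <- resolve_k(config$k, aln_min_len(archive$alns[[1L]]))
  accepted <- 0L
  for (i in seq_len(archive_size(archive))) {
    for (nb in neighbors(archive$alns[[i]], k)) {
      sc <- bsp(nb, matrix = matrix,
                count_double_gaps = config$count_double_gaps)
      res <- archive_insert(archive, nb, sc)
      if (res$accepted) accepted <- accepted + 1L
    }
  }
  accepted
}
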