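# The heuristic-recovery experiment shared by several acceptance checks:
# 20 two-sequence synthetic families (lengths 8-12), exact biobjective DP
# front per family, 10 budgeted PILS runs per family (P = 4, k = Min,
# 20000 evaluations, non-domination auditing on), plus one unbudgeted PLS
# run per family for the natural-termination fixed-point check.  Computed
# once and cached for the session.

recovery_instances <- function(n = 20) {
  out <- list()
  s <- 0
  while (length(out) < n) {
    s <- s + 1
    fam <- generate_family(family_model(m = 2, ancestor_length = 10, seed = s))
    if (all(nchar(fam$seqs) >= 8 & nchar(fam$seqs) <= 12)) {
      out[[length(out) + 1]] <- fam
    }
  }
  out
}

run_recovery_experiment <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    instances <- recovery_instances(20)
    runs <- list()
    for (i in seq_along(instances)) {
      fam <- instances[[i]]
      exact <- exact_pairwise_front(fam$seqs[1], fam$seqs[2])
      seeds <- lapply(1:10, function(s) {
        cfg <- search_config(k = "Min", P = 4, max_evals = 20000,
                             seed = i * 100 + s, audit = TRUE)
        arch <- pils(fam, cfg)
        ref <- reference_point(rbind(exact$vectors, archive_front(arch)))
        list(front = archive_front(arch),
             rounds_hv = pils_round_hypervolumes(arch),
             audit_violations = attr(arch, "audit_violations"),
             archive_sizes = vapply(attr(arch, "rounds"), nrow, integer(1)),
             pct = 100 * hypervolume(archive_front(arch), ref) /
               hypervolume(exact$vectors, ref))
      })
      cfg_nat <- search_config(k = "Min", audit = TRUE)
      set.seed(i)
      nat <- pls(lapply(1:5, function(j) random_start(fam)), cfg_nat)
      runs[[i]] <- list(family = fam, exact = exact, seeds = seeds,
                        natural_pls = nat, natural_cfg = cfg_nat)
    }
    cache <<- runs
    cache
  }
})
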