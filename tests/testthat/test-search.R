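test_that("k specifiers resolve against the shortest sequence length", {
  expect_identical(resolve_k(3, 10), 3L)
  expect_identical(resolve_k("Min", 10), 10L)
  expect_identical(resolve_k("Min/2", 10), 5L)
  expect_identical(resolve_k("Min/4", 10), 3L)   # ceiling
  expect_identical(resolve_k("Min/16", 10), 1L)  # floor of 1
  expect_error(resolve_k("Min/3", 10), "specifier")
})

test_that("random_start pads to the longest sequence and stays feasible", {
  s <- seq_set(c("ACDE", "AC"))
  set.seed(51)
  a <- random_start(s)
  expect_identical(ncol(a), 4L)
  expect_identical(aln_rows(a)[1], "ACDE")
  expect_identical(sum(unclass(a)[2, ] == "-"), 2L)

  eq <- seq_set(c("ACD", "CDE"))
  expect_identical(aln_rows(random_start(eq)), c("ACD", "CDE"))

  placements <- character(0)
  for (i in 1:1000) {
    x <- random_start(s)
    expect_identical(nrow(validate_alignment(x, s)), 0L)
    placements <- c(placements, aln_rows(x)[2])
  }
  expect_identical(length(unique(placements)), 6L)  # all C(4,2) placements
})

test_that("a Pareto-local-optimal start is a PLS fixed point", {
  # gapless identical rows: no moves exist, archive is the start itself
  a <- msa_aln(c("ACGT", "ACGT"))
  cfg <- search_config(k = 2)
  arch <- pls(a, cfg)
  expect_identical(archive_size(arch), 1L)
  expect_true(attr(arch, "natural"))
  expect_identical(verify_local_optimum(arch, cfg), 0L)
})

test_that("PLS archives never exceed the exact pairwise front hypervolume", {
  set.seed(52)
  for (rep in 1:5) {
    s <- random_sequences(m = 2, len_range = c(5, 9))
    ef <- exact_pairwise_front(s$seqs[1], s$seqs[2])
    arch <- pls(lapply(1:3, function(i) random_start(s)),
                search_config(k = "Min", audit = TRUE))
    expect_identical(attr(arch, "audit_violations"), 0L)
    ref <- reference_point(rbind(ef$vectors, archive_front(arch)))
    expect_lte(hypervolume(archive_front(arch), ref),
               hypervolume(ef$vectors, ref))
  }
})

test_that("P = 0 reduces the iterated search to plain PLS", {
  s <- seq_set(c("ACGTAC", "ACTAC", "AGGTC"))
  r1 <- pils(s, search_config(k = "Min", P = 0, max_evals = 2000, seed = 7))
  set.seed(7)
  starts <- lapply(1:5, function(i) random_start(s))
  r2 <- pls(starts, search_config(k = "Min", max_evals = 2000))
  expect_identical(archive_front(r1), archive_front(r2))
  expect_identical(length(attr(r1, "rounds")), 1L)
})

test_that("perturbation lengthens rows, keeps feasibility and spans the front", {
  set.seed(53)
  a1 <- new_archive()
  a1 <- archive_insert(a1, msa_aln(c("AC-G", "A-CG")), c(2, 2))$archive
  p <- perturb_archive(a1, search_config(gap_size = 2))
  expect_identical(length(p), 1L)
  expect_lte(ncol(p[[1]]), 4L + 2L)  # stripping may remove aligned inserts
  expect_gte(ncol(p[[1]]), 4L)

  # archive of 6: selection always includes both extremes of the front
  # (the min-indel entry and the max-substitution-score entry); parents are
  # identifiable after perturbation by their residue content
  arch <- new_archive()
  dummy <- function(i) msa_aln(c(paste0(strrep("A", i), strrep("-", 7 - i)),
                                 paste0(strrep("-", i), strrep("C", 7 - i))))
  for (i in 1:6) arch <- archive_insert(arch, dummy(i), c(i, 2 * i))$archive
  sel <- perturb_archive(arch, search_config(gap_size = 1))
  expect_identical(length(sel), 5L)
  parent <- vapply(sel, function(x) sum(unclass(x) == "A"), integer(1))
  expect_true(all(c(1L, 6L) %in% parent))

  for (rep in 1:200) {
    pp <- perturb_archive(arch, search_config(gap_size = 1))
    for (x in pp) {
      expect_identical(nrow(validate_alignment(x)), 0L)
    }
  }
})

test_that("iterated search hypervolume never decreases across rounds", {
  set.seed(54)
  for (rep in 1:3) {
    s <- random_sequences(m = 3, len_range = c(5, 8))
    r <- pils(s, search_config(k = "Min/2", P = 3, max_evals = 3000,
                               seed = rep, audit = TRUE))
    hv <- pils_round_hypervolumes(r)
    expect_true(all(diff(hv) >= 0))
    expect_identical(attr(r, "audit_violations"), 0L)
  }
})

test_that("identical seed and evaluation budget replay byte-identically", {
  s <- seq_set(c("ACGTACG", "ACTACG", "AGGTCA"))
  cfg <- search_config(k = "Min/2", P = 2, max_evals = 4000, seed = 99)
  r1 <- pils(s, cfg)
  r2 <- pils(s, cfg)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
})
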