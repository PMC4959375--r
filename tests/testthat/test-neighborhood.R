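test_that("apply_move slides a block across adjacent indels and strips", {
  expect_identical(aln_rows(apply_move(msa_aln(c("AC", "A-")),
                                       list(row = 2, start = 1, size = 1, shift = 1))),
                   c("AC", "-A"))
  # shifting C of row 1 left creates an all-gap column that is deleted
  expect_identical(aln_rows(apply_move(msa_aln(c("A-C", "AB-")),
                                       list(row = 1, start = 3, size = 1, shift = -1))),
                   c("AC", "AB"))
  expect_error(apply_move(msa_aln(c("ACG", "A-G")),
                          list(row = 2, start = 1, size = 1, shift = 2)),
               "cross a residue")
  expect_error(apply_move(msa_aln(c("A-C", "AB-")),
                          list(row = 1, start = 2, size = 1, shift = 1)),
               "indel")
})

test_that("applied moves always preserve feasibility", {
  set.seed(31)
  tried <- 0
  while (tried < 300) {
    a <- random_alignment()
    mv <- block_moves(a, sample(1:3, 1))
    if (!nrow(mv)) next
    tried <- tried + 1
    nb <- apply_move(a, mv[sample.int(nrow(mv), 1), ])
    seqs <- seq_set(gsub("-", "", aln_rows(a), fixed = TRUE))
    expect_identical(nrow(validate_alignment(nb, seqs)), 0L)
  }
})

test_that("the worked neighborhood example yields its stripped, deduplicated set", {
  a <- msa_aln(c("A-C", "AB-"))
  nb <- neighbors(a, 1)
  # three raw moves exist, but row-2 "A-B" carries an all-gap column and
  # collapses onto "AC"/"AB" after stripping
  expect_identical(nrow(block_moves(a, 1)), 3L)
  expect_identical(aln_keys(nb), sort(c("-AC|AB-", "AC|AB")))
  expect_identical(count_neighbors(a, 1), 2L)
  expect_identical(neighbors(msa_aln(c("ACG", "ACG")), 2), list())
  expect_identical(count_neighbors(msa_aln(c("AC", "GT")), 3), 0L)
})

test_that("neighborhoods nest in k and are symmetric up to stripping", {
  set.seed(32)
  for (rep in 1:40) {
    a <- random_alignment()
    k <- sample(1:2, 1)
    small <- neighbors(a, k)
    large_keys <- aln_keys(neighbors(a, k + 1))
    expect_true(all(aln_keys(small) %in% large_keys))
    expect_true(count_neighbors(a, k) <= count_neighbors(a, k + 1))
    for (y in small) {
      if (ncol(y) == ncol(a)) {  # no column was stripped
        expect_true(paste(aln_rows(a), collapse = "|") %in%
                      vapply(neighbors(y, k),
                             function(z) paste(aln_rows(z), collapse = "|"),
                             character(1)))
      }
    }
  }
})

test_that("move-based neighbors equal the brute-force condition checker", {
  set.seed(33)
  for (rep in 1:60) {
    a <- random_alignment()
    k <- sample(1:3, 1)
    expect_identical(aln_keys(neighbors(a, k)),
                     aln_keys(brute_force_neighbors(a, k)))
  }
})

test_that("the integer-encoded search path reproduces the reference operations", {
  set.seed(34)
  alpha <- rownames(identity_matrix("dna"))
  M <- unname(identity_matrix("dna"))
  for (rep in 1:40) {
    a <- random_alignment()
    k <- sample(1:3, 1)
    imat <- momsa:::ialn_encode(a, alpha)
    mv_ref <- block_moves(a, k)
    mv_int <- momsa:::imoves(imat, k)
    expect_identical(nrow(mv_ref), nrow(mv_int))
    if (nrow(mv_ref)) {
      expect_identical(unname(as.matrix(mv_ref)), unname(mv_int))
    }
    if (nrow(mv_int)) {
      r <- sample.int(nrow(mv_int), 1)
      nb_int <- momsa:::iapply(imat, mv_int[r, 1], mv_int[r, 2],
                               mv_int[r, 3], mv_int[r, 4])
      nb_ref <- apply_move(a, mv_ref[r, ])
      expect_identical(aln_rows(momsa:::ialn_decode(nb_int, alpha)),
                       aln_rows(nb_ref))
      expect_identical(momsa:::iscore(nb_int, M, diag(M)), bsp(nb_ref))
    }
  }
})
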