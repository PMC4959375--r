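test_that("the merged reference front and its hypervolume follow the protocol", {
  one <- matrix(c(5L, 2L), 1, dimnames = list(NULL, c("s", "d")))
  rf1 <- reference_front(list(one))
  expect_identical(unname(rf1$front), unname(one))
  expect_equal(hv_percentage(one, rf1$ref, rf1$ref_hv), 100)

  rf <- reference_front(list(run1 = one,
                             run2 = matrix(c(6L, 1L), 1)))
  expect_identical(unname(rf$front), matrix(c(6L, 1L), 1))
  expect_identical(rf$ref, c(s = 4L, d = 3L))
  expect_identical(rf$ref_hv, 4)
  expect_equal(hv_percentage(one, rf$ref, rf$ref_hv), 25)
  expect_equal(hv_percentage(rf$front, rf$ref, rf$ref_hv), 100)
  expect_equal(hv_percentage(matrix(integer(0), 0, 2), rf$ref, rf$ref_hv), 0)
})

test_that("the reference hypervolume bounds every individual run", {
  set.seed(61)
  for (rep in 1:30) {
    runs <- lapply(1:3, function(i) filter_nondominated(random_front()))
    rf <- reference_front(runs)
    for (r in runs) {
      expect_lte(hypervolume(r, rf$ref), rf$ref_hv)
      expect_lte(hv_percentage(r, rf$ref, rf$ref_hv), 100)
    }
  }
})

test_that("SP and TC ratios match hand counts", {
  ref <- msa_aln(c("AB", "AB"))
  test <- msa_aln(c("AB-", "A-B"))
  r <- sp_tc_ratios(test, ref)
  # pair A1-A1 survives, B2-B2 is lost; reference column (A,A) is reproduced
  # by test column 1, column (B,B) is not
  expect_equal(r$sp, 0.5)
  expect_equal(r$tc, 0.5)

  same <- sp_tc_ratios(ref, ref)
  expect_equal(same$sp, 1)
  expect_equal(same$tc, 1)

  expect_error(sp_tc_ratios(msa_aln(c("AC", "AC")), ref), "different sequence")
})

test_that("quality ratios are invariant under pairing-preserving rewrites", {
  # swapping adjacent single-residue columns moves indels around without
  # changing any residue pairing or any full-column tuple
  set.seed(62)
  checked <- 0
  tries <- 0
  while (checked < 30 && tries < 5000) {
    tries <- tries + 1
    seqs <- random_sequences(m = 3, len_range = c(2, 5))
    ref <- random_alignment_of(seqs)
    test <- random_alignment_of(seqs)
    chars <- unclass(test)
    single <- which(colSums(chars != "-") == 1)
    adj <- single[which(diff(single) == 1)]
    if (!length(adj)) next
    j <- adj[1]
    if (which(chars[, j] != "-") == which(chars[, j + 1] != "-")) next
    swapped <- chars
    swapped[, c(j, j + 1)] <- chars[, c(j + 1, j)]
    test2 <- msa_aln(apply(swapped, 1, paste, collapse = ""))
    if (!identical(gsub("-", "", aln_rows(test2)), gsub("-", "", aln_rows(test)))) next
    r1 <- sp_tc_ratios(test, ref)
    r2 <- sp_tc_ratios(test2, ref)
    expect_identical(r1, r2)
    checked <- checked + 1
  }
})

test_that("perfect column recovery implies perfect pair recovery", {
  set.seed(63)
  for (rep in 1:50) {
    ref <- random_alignment()
    test <- if (rep %% 2 == 0) ref else {
      nb <- neighbors(ref, 1)
      if (!length(nb)) ref else nb[[sample.int(length(nb), 1)]]
    }
    r <- sp_tc_ratios(test, ref)
    if (isTRUE(all.equal(r$tc, 1))) expect_equal(r$sp, 1)
  }
})

test_that("evaluation reports carry one labelled row per run", {
  a1 <- new_archive()
  a1 <- archive_insert(a1, msa_aln(c("AC", "AC")), c(2, 0))$archive
  a2 <- new_archive()
  a2 <- archive_insert(a2, msa_aln(c("AC-", "A-C")), c(1, 2))$archive
  path <- tempfile(fileext = ".tsv")
  rep <- write_evaluation_report(list(good = a1, weak = a2), path,
                                 reference = msa_aln(c("AC", "AC")))
  tab <- read.delim(path)
  expect_identical(tab$label, c("good", "weak"))
  expect_equal(tab$hv_pct[1], 100)
  expect_lt(tab$hv_pct[2], 100)
  expect_equal(tab$sp[1], 1)
})
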