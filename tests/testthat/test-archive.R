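test_that("archive insertion follows the dominance contract", {
  a <- new_archive()
  r <- archive_insert(a, msa_aln(c("AC", "AC")), c(5, 2))
  expect_true(r$accepted)
  expect_identical(unname(r$archive$scores), matrix(c(5L, 2L), 1))

  r2 <- archive_insert(r$archive, msa_aln(c("AC", "CA")), c(4, 3))
  expect_false(r2$accepted)
  r3 <- archive_insert(r$archive, msa_aln(c("AC", "CA")), c(6, 1))
  expect_true(r3$accepted)
  expect_identical(unname(r3$archive$scores), matrix(c(6L, 1L), 1))

  # equal score vectors keep the first representative
  r4 <- archive_insert(r3$archive, msa_aln(c("CA", "AC")), c(6, 1))
  expect_false(r4$accepted)
  expect_identical(archive_size(r4$archive), 1L)
})

test_that("any insertion sequence ends as the batch non-dominated filter", {
  set.seed(41)
  dummy <- msa_aln(c("AC", "AC"))
  for (rep in 1:60) {
    V <- random_front(sample(3:12, 1))
    a <- new_archive()
    for (i in seq_len(nrow(V))) {
      a <- archive_insert(a, dummy, V[i, ])$archive
    }
    expect_identical(archive_front(a), filter_nondominated(V))
  }
})

test_that("filter_nondominated matches the quadratic all-pairs oracle", {
  expect_identical(unname(filter_nondominated(rbind(c(5, 2), c(4, 3), c(6, 1)))),
                   matrix(c(6L, 1L), 1))
  f <- filter_nondominated(rbind(c(5, 2), c(7, 4)))
  expect_identical(unname(f), matrix(c(7L, 5L, 4L, 2L), 2))
  set.seed(42)
  for (rep in 1:200) {
    V <- random_front(sample(1:10, 1))
    got <- filter_nondominated(V)
    want <- quad_nondominated(V)
    expect_identical(got[order(got[, 1], got[, 2]), , drop = FALSE],
                     unname(want[order(want[, 1], want[, 2]), , drop = FALSE]) |>
                       (\(x) {colnames(x) <- c("s", "d"); storage.mode(x) <- "integer"; x})())
  }
})

test_that("reference_point is one unit beyond the observed ranges", {
  expect_identical(reference_point(rbind(c(5, 2), c(7, 4))), c(s = 4L, d = 5L))
  expect_identical(reference_point(c(3, 0)), c(s = 2L, d = 1L))
  set.seed(43)
  V <- random_front(6)
  ref <- reference_point(V)
  expect_true(all(V[, 1] > ref[["s"]] & V[, 2] < ref[["d"]]))
  expect_error(reference_point(matrix(integer(0), 0, 2)), "at least one")
})

test_that("sweep hypervolume matches closed forms and the grid oracle", {
  expect_identical(hypervolume(c(10, 2), c(s = 5, d = 4)), 10)
  expect_identical(hypervolume(matrix(integer(0), 0, 2), c(s = 0, d = 5)), 0)
  expect_identical(hypervolume(rbind(c(10, 2), c(8, 1)), c(s = 5, d = 4)), 13)
  expect_error(hypervolume(c(4, 2), c(s = 5, d = 4)), "dominate")
  set.seed(44)
  for (rep in 1:100) {
    V <- random_front()
    ref <- reference_point(V)
    expect_identical(hypervolume(V, ref), grid_hypervolume(V, ref))
  }
})

test_that("hypervolume is monotone under adding a non-dominated point", {
  set.seed(45)
  for (rep in 1:50) {
    V <- filter_nondominated(random_front(6))
    ref <- reference_point(rbind(V, c(-6, 13)))
    extra <- c(max(V[, 1]) + 1L, sample(0:12, 1))
    expect_gte(hypervolume(rbind(V, extra), ref), hypervolume(V, ref))
  }
})

test_that("archives round-trip to disk as a front table plus FASTA files", {
  a <- new_archive()
  a <- archive_insert(a, msa_aln(c("AC-", "A-C"), ids = c("x", "y")), c(1, 2))$archive
  a <- archive_insert(a, msa_aln(c("AC", "AC"), ids = c("x", "y")), c(0, 0))$archive
  d <- tempfile()
  write_archive(a, d)
  tab <- read.delim(file.path(d, "front.tsv"))
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$s, c(1L, 0L))
  b <- read_alignment(file.path(d, "aln_001.fasta"))
  expect_identical(aln_rows(b), c("AC-", "A-C"))
})
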