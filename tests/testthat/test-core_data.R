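test_that("construction validates counts and length constraints", {
  L <- velocity_lengths()
  d <- make_scd(matrix(c(3, 0), 2, 1), matrix(0, 2, 1), matrix(1, 2, 1), L)
  expect_s3_class(d, "SplicingCountData")
  expect_equal(dim(d), c(2L, 1L))
  expect_equal(as.matrix(d$counts$iso1)[, 1], c(3, 0))

  expect_error(make_scd(matrix(-1, 2, 1), matrix(0, 2, 1), matrix(0, 2, 1), L),
               "non-negative integers")
  expect_error(make_scd(matrix(1.5, 2, 1), matrix(0, 2, 1), matrix(0, 2, 1), L),
               "c1.*e1")
  # l12 = l21 = 0 and l13 = l23 are enforced
  expect_error(splicing_count_data(matrix(0, 1, 1), matrix(0, 1, 1),
                                   matrix(0, 1, 1),
                                   matrix(c(1, 1, 0, 0, 1, 0), 1, 6),
                                   "c1", "e1"),
               "l12 = l21 = 0")
  expect_error(splicing_count_data(matrix(0, 1, 1), matrix(0, 1, 1),
                                   matrix(0, 1, 1),
                                   matrix(c(1, 0, 5, 0, 1, 4), 1, 6),
                                   "c1", "e1"),
               "l13 = l23")
  # unique reads demand a positive unique length
  expect_error(splicing_count_data(matrix(2, 1, 1), matrix(0, 1, 1),
                                   matrix(0, 1, 1),
                                   matrix(c(0, 0, 1, 0, 1, 1), 1, 6),
                                   "c1", "e1"),
               "l11 = 0")
})

test_that("write/load round-trips randomly generated sparse tensors", {
  set.seed(101)
  for (rep in 1:3) {
    M <- sample(3:8, 1); N <- sample(2:6, 1)
    mk <- function() matrix(rpois(M * N, 0.8), M, N)
    L <- effective_lengths_se(sample(50:200, 1), sample(20:80, 1),
                              sample(50:200, 1), read_len = 10)
    d <- make_scd(mk(), mk(), mk(), L)
    dir <- withr::local_tempdir()
    write_splice_counts(d, dir)
    d2 <- load_splice_counts(dir)
    expect_equal(as.matrix(d2$counts$iso1), as.matrix(d$counts$iso1),
                 ignore_attr = TRUE)
    expect_equal(as.matrix(d2$counts$iso2), as.matrix(d$counts$iso2),
                 ignore_attr = TRUE)
    expect_equal(as.matrix(d2$counts$ambiguous), as.matrix(d$counts$ambiguous),
                 ignore_attr = TRUE)
    expect_equal(d2$lengths, d$lengths)
    expect_equal(d2$cell_ids, d$cell_ids)
    expect_equal(d2$event_ids, d$event_ids)
    # writing the loaded object reproduces identical sorted triplets
    dir2 <- withr::local_tempdir()
    write_splice_counts(d2, dir2)
    for (f in c("isoform1.mtx", "isoform2.mtx", "ambiguous.mtx"))
      expect_identical(sort(readLines(file.path(dir2, f))),
                       sort(readLines(file.path(dir, f))))
  }
})

test_that("dimension mismatches are rejected with the offending file named", {
  d <- make_scd(matrix(1, 2, 2), matrix(1, 2, 2), matrix(0, 2, 2),
                velocity_lengths())
  dir <- withr::local_tempdir()
  write_splice_counts(d, dir)
  # overwrite one group with a 3 x 2 matrix (events x cells on disk)
  Matrix::writeMM(Matrix::Matrix(matrix(1, 3, 2), sparse = TRUE),
                  file.path(dir, "isoform2.mtx"))
  expect_error(load_splice_counts(dir), "isoform2\\.mtx")

  dir2 <- withr::local_tempdir()
  write_splice_counts(d, dir2)
  writeLines(c("cell_id", "c1", "c2", "c3"), file.path(dir2, "cells.tsv"))
  expect_error(load_splice_counts(dir2), "cells\\.tsv")
})

test_that("filter_events applies the four pooled rules in order", {
  # 40 cells x 4 events engineered against the thresholds:
  #   keep : total 60, unique 35 in 35 cells, minor fraction 0.2
  #   e_tot: total 40 (fails rule 1 even with many unique cells)
  #   e_cel: plenty of reads but unique reads confined to 10 cells
  #   e_min: unique reads 9999 vs 1 (fraction 1e-4)
  M <- 40
  s1 <- s2 <- s3 <- matrix(0, M, 4)
  s1[1:35, 1] <- c(rep(1, 28), rep(0, 7)); s2[1:35, 1] <- c(rep(0, 28), rep(1, 7))
  s3[1:25, 1] <- 1                                    # keep: 60 total
  s1[1:35, 2] <- 1; s3[1:5, 2] <- 1                   # e_tot: 40 total
  s1[1:10, 3] <- 30; s2[1:10, 3] <- 30                # e_cel: 10 cells
  s1[1:40, 4] <- 250; s1[1, 4] <- 249; s2[1, 4] <- 1  # e_min: 9999 vs 1
  d <- make_scd(s1, s2, s3, default_L(),
                event_ids = c("keep", "e_tot", "e_cel", "e_min"))
  fl <- filter_events(d)
  expect_equal(fl$data$event_ids, "keep")
  expect_equal(fl$report$rule, c(NA, "total_reads", "cells_with_unique",
                                 "minor_fraction"))
  # rule order: a 40-read event fails rule 1 first even if others also fail
  expect_equal(fl$report$kept, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("filtering is idempotent, order-preserving, and partitions events", {
  set.seed(7)
  M <- 50; N <- 30
  mk <- function(lam) matrix(rpois(M * N, lam), M, N)
  d <- make_scd(mk(1.2), mk(0.6), mk(0.8), default_L())
  fl <- filter_events(d)
  expect_setequal(c(fl$data$event_ids,
                    fl$report$event_id[!fl$report$kept]), d$event_ids)
  expect_equal(sum(fl$report$kept) + sum(!fl$report$kept), N)
  # surviving order is the input order
  expect_identical(fl$data$event_ids,
                   d$event_ids[d$event_ids %in% fl$data$event_ids])
  expect_identical(fl$data$cell_ids, d$cell_ids)
  # idempotence
  fl2 <- filter_events(fl$data)
  expect_true(all(fl2$report$kept))
  expect_identical(fl2$data$event_ids, fl$data$event_ids)
})

test_that("an event with zero unique reads fails by convention, not error", {
  s3 <- matrix(20, 10, 1)
  z <- matrix(0, 10, 1)
  d <- splicing_count_data(z, z, s3, matrix(c(5, 0, 9, 0, 5, 9), 1, 6),
                           paste0("c", 1:10), "amb_only")
  fl <- filter_events(d, filter_thresholds(min_total_reads = 50,
                                           min_unique_reads = 0,
                                           min_cells_with_unique = 0))
  expect_false(fl$report$kept)
  expect_equal(fl$report$rule, "minor_fraction")
})
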