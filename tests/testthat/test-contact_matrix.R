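test_that("positions map to bins by half-open 0-based arithmetic", {
  sch <- binning_scheme("chr12", 113090000, 116170000, 20000)
  expect_equal(sch$n_bins, 154)
  expect_equal(bin_index(sch, 113090001), 1L)
  expect_equal(bin_index(sch, 113110000), 1L)   # last base of bin 1
  expect_equal(bin_index(sch, 113110001), 2L)   # first base of bin 2
  expect_true(is.na(bin_index(sch, 113090000))) # before the region
  expect_true(is.na(bin_index(sch, 116170001))) # past the region
  # trailing partial bin is kept
  sch2 <- binning_scheme("chr1", 0, 50000, 20000)
  expect_equal(sch2$n_bins, 3)
  expect_equal(bin_index(sch2, 45000), 3L)
})

test_that("empty or malformed schemes are rejected", {
  expect_error(binning_scheme("chr1", 100, 100, 20000), "empty region")
  expect_error(binning_scheme("chr1", 0, 100, 0), "bin_size")
})

test_that("bin_contacts places pairs and conserves counts", {
  sch <- binning_scheme("chr12", 113090000, 116170000, 20000)
  p <- data.frame(chrom_a = "chr12", pos_a = 113090100,
                  chrom_b = "chr12", pos_b = 113110050)
  cm <- bin_contacts(p, sch)
  expect_equal(cm$values[1, 2], 1)
  expect_equal(cm$values[2, 1], 1)
  expect_equal(sum(cm$values), 2)  # one off-diagonal event, mirrored

  # both ends in bin 1: diagonal incremented once
  p2 <- data.frame(chrom_a = "chr12", pos_a = 113090100,
                   chrom_b = "chr12", pos_b = 113090200)
  cm2 <- bin_contacts(p2, sch)
  expect_equal(cm2$values[1, 1], 1)

  # conservation: upper triangle + diagonal sums to accepted pair count
  set.seed(1)
  n <- 1000
  pr <- data.frame(chrom_a = "chr12",
                   pos_a = sample(113090001:116170000, n, TRUE),
                   chrom_b = "chr12",
                   pos_b = sample(113090001:116170000, n, TRUE))
  cm3 <- bin_contacts(pr, sch)
  ut <- cm3$values[upper.tri(cm3$values, diag = TRUE)]
  expect_equal(sum(ut), n)
  expect_equal(cm3$values, t(cm3$values))

  # out-of-region / off-chromosome ends are ignored
  pr$chrom_b[1:10] <- "chr1"
  cm4 <- bin_contacts(pr, sch)
  expect_equal(sum(cm4$values[upper.tri(cm4$values, diag = TRUE)]), n - 10)
})

test_that("pair reader rejects malformed records with a line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "chrom_a\tpos_a\tchrom_b\tpos_b",
               "chr1\t100\tchr2\t200", "chr1\tnot_a_number\tchr2\t300"), f)
  expect_error(read_contact_pairs(f), "line 4")
  writeLines(c("chrom_a\tpos_a\tchrom_b\tpos_b", "chr1\t100\tchr2"), f)
  expect_error(read_contact_pairs(f), "line 2")
  writeLines(c("chrom_a\tpos_a\tchrom_b\tpos_b", "chr1\t100\tchr2\t250"), f)
  expect_equal(read_contact_pairs(f)$pos_b, 250)
})

test_that("low-coverage masking follows the median-fraction rule", {
  sch <- binning_scheme("chr1", 0, 100000, 20000)
  cm <- bin_contacts(data.frame(chrom_a = character(), pos_a = numeric(),
                                chrom_b = character(), pos_b = numeric()), sch)
  # hand-built 5x5 with row sums 100,100,100,100,10
  v <- matrix(0, 5, 5)
  v[1, 2] <- v[2, 1] <- 45; v[1, 3] <- v[3, 1] <- 45
  v[2, 3] <- v[3, 2] <- 45; v[2, 4] <- v[4, 2] <- 10
  v[3, 4] <- v[4, 3] <- 10; v[1, 4] <- v[4, 1] <- 10
  v[4, 5] <- v[5, 4] <- 10; v[4, 4] <- 60 / 2 * 2
  diag(v)[4] <- 60
  stopifnot(rowSums(v) == c(100, 100, 100, 100, 10))
  cm$values <- v
  out <- mask_low_coverage(cm, 0.2)
  expect_equal(out$mask, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_true(all(out$values[5, ] == 0), all(out$values[, 5] == 0))

  # uniform matrix: nothing masked
  cm$values <- matrix(1, 5, 5)
  expect_true(all(mask_low_coverage(cm, 0.2)$mask))

  # an all-zero row is masked
  v2 <- matrix(1, 5, 5); v2[3, ] <- 0; v2[, 3] <- 0
  cm$values <- v2
  expect_false(mask_low_coverage(cm, 0.2)$mask[3])

  # fully empty matrix errors
  cm$values <- matrix(0, 5, 5)
  expect_error(mask_low_coverage(cm, 0.2), "all bins masked")
})

make_cm <- function(v, mask = rep(TRUE, nrow(v)), state = "raw") {
  sch <- binning_scheme("chrT", 0, nrow(v) * 1000, 1000)
  cm <- bin_contacts(data.frame(chrom_a = character(), pos_a = numeric(),
                                chrom_b = character(), pos_b = numeric()), sch)
  cm$values <- v
  cm$mask <- mask
  cm$normalization_state <- state
  cm
}

test_that("ice_balance matches an independent fixed-point oracle", {
  v <- matrix(c(4, 2, 2, 2, 2, 0, 2, 0, 2), 3, 3)
  bal <- ice_balance(make_cm(v), tol = 1e-9)
  expect_equal(bal$values, ice_oracle(v), tolerance = 1e-6)
  expect_equal(sum(bal$values), sum(v))  # mass preserved
})

test_that("ice_balance equalizes row sums, preserves symmetry and mask", {
  set.seed(42)
  n <- 12
  v <- matrix(rpois(n * n, 20), n, n)
  v <- v + t(v)
  mask <- rep(TRUE, n); mask[c(3, 9)] <- FALSE
  v[!mask, ] <- 0; v[, !mask] <- 0
  bal <- ice_balance(make_cm(v, mask), tol = 1e-8)
  rs <- rowSums(bal$values)[mask]
  expect_lt((max(rs) - min(rs)) / min(rs), 1e-8)
  expect_equal(bal$values, t(bal$values))
  expect_true(all(bal$values[!mask, ] == 0))
  # idempotence: balancing a balanced matrix is a no-op (up to tol)
  bal2 <- ice_balance(bal, tol = 1e-8)
  expect_equal(bal2$values, bal$values, tolerance = 1e-6)
  # constant matrix is already balanced: unchanged
  vc <- matrix(5, 4, 4)
  expect_equal(ice_balance(make_cm(vc))$values, vc)
})

test_that("distance_correct divides by per-diagonal means", {
  # homogeneous decay: all unmasked entries become exactly 1
  n <- 8
  f <- function(s) 2^-s
  v <- outer(seq_len(n), seq_len(n), function(i, j) f(abs(i - j)))
  oe <- distance_correct(make_cm(v, state = "balanced"))
  expect_true(all(abs(oe$values - 1) < 1e-12))

  # hand oracle on a 4x4 input: one entry at twice its diagonal mean
  v2 <- outer(seq_len(4), seq_len(4), function(i, j) f(abs(i - j)))
  v2[1, 3] <- v2[3, 1] <- 2 * 0.25
  oe2 <- distance_correct(make_cm(v2, state = "balanced"))
  # diagonal |i-j|=2 entries are {0.5, 0.25}; mean = 0.375
  expect_equal(oe2$values[1, 3], 0.5 / 0.375)
  expect_equal(oe2$values[2, 4], 0.25 / 0.375)
  expect_equal(oe2$values, t(oe2$values))

  # an all-zero off-diagonal band is flagged invalid, no division by zero
  v3 <- outer(seq_len(5), seq_len(5), function(i, j) f(abs(i - j)))
  v3[abs(row(v3) - col(v3)) == 3] <- 0
  oe3 <- distance_correct(make_cm(v3, state = "balanced"))
  expect_true(3 %in% attr(oe3, "invalid_diagonals"))
  expect_true(all(is.finite(oe3$values)))
})

test_that("contact matrices and pairs round-trip through TSV", {
  sch <- binning_scheme("chr12", 0, 80000, 20000)
  set.seed(3)
  pr <- data.frame(chrom_a = "chr12", pos_a = sample(80000, 50, TRUE),
                   chrom_b = "chr12", pos_b = sample(80000, 50, TRUE))
  cm <- bin_contacts(pr, sch)
  cm$mask[2] <- FALSE
  f <- withr::local_tempfile(fileext = ".tsv")
  write_contact_matrix(cm, f)
  back <- read_contact_matrix(f)
  expect_equal(back$values, cm$values, ignore_attr = TRUE)
  expect_equal(back$mask, cm$mask)
  expect_equal(back$scheme$n_bins, sch$n_bins)

  fp <- withr::local_tempfile(fileext = ".tsv")
  write_contact_pairs(pr, fp, comment = "synthetic")
  pr2 <- read_contact_pairs(fp)
  expect_equal(pr2$pos_a, pr$pos_a)
})
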