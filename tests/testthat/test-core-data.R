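# Data model: containers, I/O, normalisation, masking/fills, Pearson
# connectivity and the deterministic halving pyramid.

test_that("roi_timeseries enforces its shape and finiteness invariants", {
  expect_error(roi_timeseries(matrix(1:8, 1, 8)), "N >= 2")
  expect_error(roi_timeseries(matrix(1:14, 2, 7)), "T >= 8")
  m <- matrix(runif(24), 3, 8); m[2, 5] <- NaN
  expect_error(roi_timeseries(m), "ROI row 2, timepoint 5")
  ts <- roi_timeseries(matrix(runif(48), 3, 16))
  expect_identical(dim(ts), c(3L, 16L))
})

test_that("delimited round-trips preserve values and reject bad input", {
  d <- withr::local_tempdir()
  ts <- small_subject(5)
  for (fmt in c("tsv", "csv", "rds")) {
    f <- file.path(d, paste0("x.", fmt))
    write_timeseries(ts, f)
    back <- read_timeseries(f)
    expect_equal(back$values, ts$values, tolerance = 1e-12, ignore_attr = TRUE)
  }
  # labels survive a TSV round-trip via the leading column
  f2 <- file.path(d, "lab.tsv")
  write_timeseries(ts, f2)
  expect_identical(read_timeseries(f2)$roi_labels, ts$roi_labels)

  expect_error(read_timeseries(file.path(d, "absent.tsv")), "not found")
  one_row <- file.path(d, "one.tsv")
  writeLines(paste(1:16, collapse = "\t"), one_row)
  expect_error(read_timeseries(one_row), "N >= 2")
  bad <- file.path(d, "bad.tsv")
  writeLines(c(paste(c(1:7, "NaN", 9:16), collapse = "\t"),
               paste(1:16, collapse = "\t")), bad)
  expect_error(read_timeseries(bad), "row 1, column 8")
})

test_that("mask JSON round-trips and validates indices", {
  d <- withr::local_tempdir()
  m <- missing_mask(c(7, 2), "gaussian")
  expect_identical(m$missing_indices, c(2L, 7L))
  f <- file.path(d, "mask.json")
  write_mask(m, f)
  expect_identical(read_mask(f), m)
  expect_error(missing_mask(integer(0)), "at least one")
  expect_error(missing_mask(c(2, 2)), "unique")
  expect_error(missing_mask(0), ">= 1")
  expect_error(missing_mask(1:4, "zero", n_rois = 4), "remain observed")
})

test_that("min-max normalisation is global, exact at the bounds, idempotent", {
  m <- rbind(c(2, 4, 6, rep(4, 5)), rep(3, 8))
  out <- normalize_minmax(roi_timeseries(m))$values
  expect_equal(out[1, 1:3], c(0, 0.5, 1))   # global min 2, max 6
  expect_equal(min(out), 0); expect_equal(max(out), 1)
  expect_equal(normalize_minmax(out)$values, out)
  expect_error(normalize_minmax(matrix(5, 2, 8)), "degenerate")
})

test_that("fill strategies behave as specified and leave observed rows alone", {
  ts <- small_subject(6)
  v <- ts$values
  zero <- apply_mask_and_fill(ts, missing_mask(3, "zero"))
  expect_identical(zero$values[-3, ], v[-3, ])
  expect_true(all(zero$values[3, ] == 0))

  pr <- apply_mask_and_fill(ts, missing_mask(3, "prior"))
  expect_equal(pr$values[3, ], colMeans(v[-3, ]))

  # prior over identical observed rows reproduces that row exactly
  dup <- roi_timeseries(rbind(v[1, ], v[1, ], v[1, ], v[2, ]))
  pd <- apply_mask_and_fill(dup, missing_mask(4, "prior"))
  expect_equal(pd$values[4, ], v[1, ])

  r1 <- apply_mask_and_fill(ts, missing_mask(3, "random"), seed = 42)
  r2 <- apply_mask_and_fill(ts, missing_mask(3, "random"), seed = 42)
  expect_identical(r1$values, r2$values)
  expect_true(all(r1$values[3, ] >= 0 & r1$values[3, ] <= 1))
  g1 <- apply_mask_and_fill(ts, missing_mask(3, "gaussian"), seed = 42)
  expect_true(all(g1$values[3, ] >= 0 & g1$values[3, ] <= 1))
  expect_error(apply_mask_and_fill(ts, missing_mask(3, "random")), "seed")
})

test_that("pcc_matrix matches a two-pass covariance oracle and its conventions", {
  # worked conventions
  set.seed(30)
  C <- pcc_matrix(rbind(0:2, 2:0, c(1, 3, 5), runif(3)))
  expect_equal(diag(C), rep(1, 4))
  expect_equal(C[1, 2], -1)
  expect_equal(C[1, 3], 1)
  expect_true(isSymmetric(C, tol = 1e-12))

  # constant row convention: finite, zero off-diagonal, unit diagonal
  cm <- rbind(rep(0.3, 10), runif(10), runif(10))
  Cc <- pcc_matrix(cm)
  expect_equal(Cc[1, 2], 0); expect_equal(Cc[1, 1], 1)

  # oracle: direct two-pass covariance / sd computation
  for (s in 1:20) {
    x <- rand_mat(8, 32, s)
    C1 <- pcc_matrix(x)
    mu <- rowMeans(x)
    xc <- x - mu
    oracle <- (xc %*% t(xc)) /
      (sqrt(rowSums(xc^2)) %o% sqrt(rowSums(xc^2)))
    diag(oracle) <- 1
    expect_equal(C1, oracle, tolerance = 1e-10)
  }
})

test_that("deterministic halving and the pyramid obey floor semantics", {
  expect_equal(dh_resample(matrix(c(1, 2, 3, 4), 1), 1),
               matrix(c(1.5, 3.5), 1))
  x <- rand_mat(4, 187, 9)
  expect_identical(ncol(dh_resample(x, 1)), 93L)
  expect_identical(dh_resample(x, 0), x)
  expect_error(dh_resample(x, 4), "k")

  py <- build_pyramid(rand_mat(3, 64, 10))
  expect_identical(vapply(py, ncol, integer(1)), c(64L, 32L, 16L, 8L))
  py2 <- build_pyramid(rand_mat(3, 187, 11))
  expect_identical(vapply(py2, ncol, integer(1)), c(187L, 93L, 46L, 23L))

  # averaging preserves constants
  pc <- build_pyramid(matrix(0.7, 2, 16))
  expect_true(all(vapply(pc, function(m) all(m == 0.7), logical(1))))

  # halving commutes with ROI permutation
  x <- rand_mat(6, 40, 12)
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(dh_resample(x[perm, ], 2), dh_resample(x, 2)[perm, ])
})
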