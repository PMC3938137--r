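test_that("quantile normalization matches the rank-average oracle", {
  # identical columns are a fixed point
  m <- matrix(c(1, 5, 3, 1, 5, 3), 3, 2,
              dimnames = list(paste0("P", 1:3), c("S1", "S2")))
  expect_equal(intensities(quantileNormalize(toyDataset(m))), m)

  # worked 3x2 example: reference distribution (1.5, 3.5, 5.5)
  d <- toyDataset(matrix(c(1, 3, 5, 2, 6, 4), 3, 2,
                         dimnames = list(paste0("P", 1:3), c("S1", "S2"))))
  qn <- intensities(quantileNormalize(d))
  expect_equal(unname(qn[, 1]), c(1.5, 3.5, 5.5))
  expect_equal(unname(qn[, 2]), c(1.5, 5.5, 3.5))

  # random matrices: per-sample sorted vectors identical, oracle agreement
  for (seed in c(42, 7)) {
    d <- randomDataset(500, 6, seed = seed)
    qn <- intensities(quantileNormalize(d))
    sorted <- apply(qn, 2, sort)
    expect_lt(max(abs(sorted - sorted[, 1])), 1e-12 * max(abs(sorted)))
    expect_equal(qn, qnOracle(intensities(d)), tolerance = 1e-12)
    # rank order preserved within each sample
    for (j in 1:6)
      expect_identical(order(qn[, j]), order(intensities(d)[, j]))
  }
})

test_that("quantile normalization is idempotent with equal column means", {
  d <- randomDataset(400, 5, seed = 3)
  once <- quantileNormalize(d)
  twice <- quantileNormalize(once)
  expect_equal(intensities(twice), intensities(once), tolerance = 1e-12)
  cm <- colMeans(intensities(once))
  expect_lt(diff(range(cm)), 1e-10 * mean(cm))
})

test_that("quantile normalization agrees with the limma reference", {
  skip_if_not_installed("limma")
  x <- intensities(randomDataset(300, 4, seed = 11))
  mine <- intensities(quantileNormalize(ExpressionDataset(x)))
  ref <- limma::normalizeQuantiles(x)
  expect_equal(unname(mine), unname(as.matrix(ref)), tolerance = 1e-10)
})

test_that("ties within a column share the mean of their occupied ranks", {
  m <- matrix(c(1, 1, 5, 2, 4, 6), 3, 2,
              dimnames = list(paste0("P", 1:3), c("S1", "S2")))
  qn <- intensities(quantileNormalize(toyDataset(m)))
  ref <- rowMeans(apply(m, 2, sort))
  expect_equal(unname(qn[1:2, 1]), rep(mean(ref[1:2]), 2))
  expect_equal(unname(qn[3, 1]), unname(ref[3]))
})

test_that("normalization refuses missing values and single samples", {
  m <- matrix(c(1, NA, 3, 4), 2, 2,
              dimnames = list(c("P1", "P2"), c("S1", "S2")))
  expect_error(quantileNormalize(toyDataset(m)), "missing")
  one <- matrix(1:3, 3, 1, dimnames = list(paste0("P", 1:3), "S1"))
  expect_error(quantileNormalize(toyDataset(one)), ">= 2 samples")
})

test_that("detection filter removes a probe only when every sample fails", {
  det <- rbind(P1 = c(0.2, 0.9, 0.01),
               P2 = c(0.9, 0.2, 0.01),
               P3 = c(0.9, 0.3, 0.2),
               P4 = c(0.9, 0.9, 0.04))
  colnames(det) <- paste0("S", 1:3)
  m <- matrix(100, 4, 3, dimnames = dimnames(det))
  res <- filterByDetection(toyDataset(m, detection = det), alpha = 0.05)
  # P1 detected in S3 (0.01), P2 detected in S3, P4 detected in S3; P3 never
  expect_identical(probeIds(res$data), c("P1", "P2", "P4"))
  expect_identical(res$report@removed, "P3")

  no_det <- toyDataset(m)
  expect_error(filterByDetection(no_det, 0.05), "filterByIntensity")
})

test_that("detection filter matches exhaustive 2-sample truth table", {
  vals <- c(0.04, 0.06)
  grid <- expand.grid(s1 = vals, s2 = vals)
  det <- as.matrix(grid)
  rownames(det) <- sprintf("P%d", seq_len(nrow(det)))
  colnames(det) <- c("S1", "S2")
  m <- matrix(50, nrow(det), 2, dimnames = dimnames(det))
  res <- filterByDetection(toyDataset(m, detection = det), alpha = 0.05)
  removed_oracle <- rownames(det)[grid$s1 > 0.05 & grid$s2 > 0.05]
  expect_identical(res$report@removed, removed_oracle)
  expect_length(removed_oracle, 1)             # only (0.06, 0.06)
})

test_that("intensity filter keeps probes detected in any one sample", {
  m <- matrix(c(85, 10, 300, 120, 20, 300, 40, 15, 300), 3, 3,
              dimnames = list(paste0("P", 1:3), paste0("S", 1:3)))
  res <- filterByIntensity(toyDataset(m), floor = 90)
  expect_identical(probeIds(res$data), c("P1", "P3"))   # [85,120,40] stays
  expect_identical(res$report@removed, "P2")

  res0 <- filterByIntensity(toyDataset(m), floor = 0)
  expect_length(res0$report@removed, 0)
})

test_that("variance filter removes the stated fraction with stable ties", {
  m <- rbind(P1 = c(5, 5, 5),        # var 0
             P2 = c(4, 5, 6),        # var 1
             P3 = c(3, 5, 7),        # var 4
             P4 = c(1, 5, 9))        # var 16
  colnames(m) <- paste0("S", 1:3)
  res <- filterLowVariance(toyDataset(m), fraction = 0.5)
  expect_identical(res$report@removed, c("P1", "P2"))
  expect_identical(probeIds(res$data), c("P3", "P4"))

  expect_identical(probeIds(filterLowVariance(toyDataset(m), 0)$data),
                   rownames(m))

  tied <- rbind(P1 = c(1, 2), P2 = c(1, 2), P3 = c(0, 9))
  colnames(tied) <- c("S1", "S2")
  res_t <- filterLowVariance(toyDataset(tied), fraction = 1 / 3)
  expect_identical(res_t$report@removed, "P1")  # earlier probe goes first
})

test_that("filters commute with sample reordering and reports add up", {
  set.seed(21)
  m <- matrix(runif(60, 10, 200), 10, 6,
              dimnames = list(sprintf("P%02d", 1:10), sprintf("S%d", 1:6)))
  det <- matrix(runif(60), 10, 6, dimnames = dimnames(m))
  d <- toyDataset(m, detection = det)
  perm <- c(4, 1, 6, 2, 5, 3)
  dp <- toyDataset(m[, perm], detection = det[, perm])
  for (call in list(
    function(x) filterByDetection(x, 0.4),
    function(x) filterByIntensity(x, 100),
    function(x) filterLowVariance(x, 0.3))) {
    a <- call(d); b <- call(dp)
    expect_identical(a$report@removed, b$report@removed)
    expect_identical(a$report@before - a$report@after,
                     length(a$report@removed))
    expect_true(all(a$report@removed %in% probeIds(d)))
  }
})
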