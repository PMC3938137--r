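makeTwoGroup <- function(m) {
  samples <- colnames(m)
  g <- GroupAssignment(samples, rep(c("ctrl", "trt"),
                                    each = length(samples) / 2),
                       c("ctrl", "trt"))
  list(data = ExpressionDataset(m), groups = g)
}

test_that("two-group statistics match hand computation and a Welch oracle", {
  m <- cbind(C1 = c(10, 8), C2 = c(12, 8), C3 = c(14, 8),
             T1 = c(20, 8), T2 = c(24, 8), T3 = c(28, 8))
  rownames(m) <- c("P1", "P2")
  fx <- makeTwoGroup(m)
  res <- twoGroupStats(fx$data, fx$groups, "trt", "ctrl")
  expect_equal(res$fold_change[1], 24 / 12)
  expect_equal(res$log2_fold_change, log2(res$fold_change))
  expect_equal(res$p_value[1],
               welchOracle(log2(c(20, 24, 28)), log2(c(10, 12, 14))),
               tolerance = 1e-12)
  # identical groups: fold change 1, p-value 1 (t statistic 0)
  expect_equal(res$fold_change[2], 1)
  expect_equal(res$p_value[2], 1)
})

test_that("two-group statistics are invariant to sample permutation", {
  set.seed(8)
  m <- matrix(2^rnorm(60, 8), 6, 10,
              dimnames = list(paste0("P", 1:6), paste0("S", 1:10)))
  fx <- makeTwoGroup(m)
  res <- twoGroupStats(fx$data, fx$groups, "trt", "ctrl")
  perm <- sample(10)
  res_p <- twoGroupStats(ExpressionDataset(m[, perm]), fx$groups,
                         "trt", "ctrl")
  expect_equal(res_p$p_value, res$p_value, tolerance = 1e-12)
  expect_equal(res_p$fold_change, res$fold_change, tolerance = 1e-12)
})

test_that("two-group statistics enforce their preconditions", {
  m <- cbind(C1 = c(10, 10), T1 = c(20, 20), T2 = c(22, 0))
  rownames(m) <- c("P1", "P2")
  d <- ExpressionDataset(m)
  g <- GroupAssignment(colnames(m), c("ctrl", "trt", "trt"))
  expect_error(twoGroupStats(d, g, "trt", "ctrl"), ">= 2 samples")
  m2 <- cbind(C1 = c(10, 10), C2 = c(11, 11), T1 = c(20, 0), T2 = c(22, 5))
  rownames(m2) <- c("P1", "P2")
  g2 <- GroupAssignment(colnames(m2), c("ctrl", "ctrl", "trt", "trt"))
  expect_error(twoGroupStats(ExpressionDataset(m2), g2, "trt", "ctrl"), "P2")
})

test_that("volcano selection keeps both directions and partitions input", {
  res <- data.frame(
    probe_id = paste0("P", 1:4),
    mean_test = 1, mean_control = 1,
    fold_change = c(2.0, 0.5, 1.9, 3.0),
    log2_fold_change = log2(c(2.0, 0.5, 1.9, 3.0)),
    p_value = c(0.04, 0.01, 1e-9, 0.2),
    significant = FALSE, stringsAsFactors = FALSE)
  kept <- selectVolcano(res, 2, 0.05)
  expect_identical(kept$probe_id, c("P1", "P2"))   # up and 2-fold down kept
  expect_true(all(kept$significant))
  # P3 fails the fold criterion despite a tiny p-value; P4 fails on p
  expect_identical(setdiff(res$probe_id, kept$probe_id), c("P3", "P4"))
  expect_error(selectVolcano(res, 0.5, 0.05), ">= 1")

  # loosening either cutoff never drops a previously kept probe
  for (cut in list(c(1.5, 0.05), c(2, 0.25))) {
    looser <- selectVolcano(res, cut[1], cut[2])
    expect_true(all(kept$probe_id %in% looser$probe_id))
  }
})

test_that("trend correlation reproduces the ramp formula exactly", {
  m <- rbind(P1 = c(10, 20, 30, 40), P2 = c(1, 3, 2, 4))
  colnames(m) <- paste0("S", 1:4)
  d <- ExpressionDataset(m)
  g <- GroupAssignment(colnames(m), paste0("t", 1:4))
  r <- timeseriesR(d, g)
  expect_equal(r$r[1], 1)
  expect_equal(r$r[2], 0.8)                       # covariance 4 / (sqrt5*sqrt5)

  # affine invariance: aB + c with a > 0 leaves r unchanged
  d2 <- ExpressionDataset(3.7 * m + 11, )
  expect_equal(timeseriesR(d2, g)$r, r$r, tolerance = 1e-12)
})

test_that("trend correlation equals a textbook Pearson implementation", {
  set.seed(19)
  n <- 12
  m <- matrix(runif(200 * n, 1, 100), 200,
              dimnames = list(sprintf("P%03d", 1:200), paste0("S", 1:n)))
  g <- GroupAssignment(colnames(m), paste0("t", 1:n))
  r <- timeseriesR(ExpressionDataset(m), g)
  oracle <- apply(m, 1, function(b) pearsonOracle(seq_len(n), b))
  expect_equal(r$r, unname(oracle), tolerance = 1e-12)
})

test_that("trend correlation sorts samples by level order, not file order", {
  m <- rbind(P1 = c(30, 10, 40, 20))
  colnames(m) <- c("s_t3", "s_t1", "s_t4", "s_t2")
  d <- ExpressionDataset(m)
  g <- GroupAssignment(colnames(m), c("t3", "t1", "t4", "t2"),
                       levels = c("t1", "t2", "t3", "t4"))
  expect_equal(timeseriesR(d, g)$r, 1)            # perfectly rising in time
})

test_that("degenerate trend inputs are handled as specified", {
  m <- rbind(P1 = c(1, 2, 3), P2 = c(5, 5, 5))
  colnames(m) <- paste0("S", 1:3)
  g <- GroupAssignment(colnames(m), paste0("t", 1:3))
  expect_warning(r <- timeseriesR(ExpressionDataset(m), g), "zero-variance")
  expect_identical(r$probe_id, "P1")
  two <- ExpressionDataset(m[, 1:2])
  g2 <- GroupAssignment(colnames(m)[1:2], c("t1", "t2"))
  expect_error(timeseriesR(two, g2), ">= 3 samples")
})

test_that("trend ranking favours quiet probes with separated group means", {
  # P1: no within-group variation; P2: same means, noisy; P3 fails |r|
  m <- rbind(P1 = c(10, 10, 10, 20, 20, 20, 30, 30, 30),
             P2 = c(8, 10, 12, 18, 20, 22, 28, 30, 32),
             P3 = c(20, 10, 30, 10, 30, 20, 30, 10, 20))
  colnames(m) <- paste0("S", 1:9)
  d <- ExpressionDataset(m)
  g <- GroupAssignment(colnames(m), rep(c("t1", "t2", "t3"), each = 3))
  r <- timeseriesR(d, g)
  ranked <- selectAndRankTrends(r, d, g, r_threshold = 0.6)
  expect_identical(ranked$probe_id, c("P1", "P2"))
  expect_identical(ranked$rank, 1:2)
  expect_gt(ranked$rank_score[1], ranked$rank_score[2])
})

test_that("high r thresholds reject pure-noise profiles", {
  set.seed(7)
  n <- 24
  m <- matrix(2^rnorm(500 * n, 8, 0.5), 500,
              dimnames = list(sprintf("P%03d", 1:500), paste0("S", 1:n)))
  g <- GroupAssignment(colnames(m), paste0("t", rep(1:6, each = 4)),
                       levels = paste0("t", 1:6))
  r <- timeseriesR(ExpressionDataset(m), g)
  ranked <- selectAndRankTrends(r, ExpressionDataset(m), g, 0.99)
  expect_lte(nrow(ranked), 2)                     # essentially empty
})

test_that("null two-group p-values are close to uniform", {
  sim <- genTwoGroup(n_probes = 800, n_de = 0, seed = 4)
  res <- twoGroupStats(sim$data, sim$groups, "trt", "ctrl")
  ks <- suppressWarnings(ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})
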