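# Shared fixtures and independent oracles used across the suite.

toyDataset <- function(m = NULL, detection = NULL) {
  if (is.null(m)) {
    m <- matrix(c(1, 3, 5, 2, 6, 4), 3, 2,
                dimnames = list(paste0("P", 1:3), c("S1", "S2")))
  }
  ExpressionDataset(m, detection = detection)
}

randomDataset <- function(n_probes, n_samples, seed = 1, min = 1, max = 100) {
  set.seed(seed)
  m <- matrix(runif(n_probes * n_samples, min, max), n_probes,
              dimnames = list(sprintf("P%04d", seq_len(n_probes)),
                              sprintf("S%02d", seq_len(n_samples))))
  ExpressionDataset(m)
}

# sample one integer uniformly from lo:hi (safe when lo == hi)
sampleRange <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1)

# textbook Pearson correlation, written out from the definition
pearsonOracle <- function(a, b) {
  am <- mean(a); bm <- mean(b)
  sum((a - am) * (b - bm)) /
    sqrt(sum((a - am)^2) * sum((b - bm)^2))
}

# Welch two-sample t-test p-value from first principles
welchOracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(t), df)
}

# hypergeometric pmf by exhaustive enumeration of all C(M, n) draws
hyperEnumOracle <- function(x, M, K, n) {
  if (n == 0) return(as.numeric(x == 0))
  draws <- utils::combn(M, n)
  hits <- colSums(draws <= K)   # genes 1..K are the marked ones
  sum(hits == x) / ncol(draws)
}

# quantile-normalization oracle: sort each column, average across columns
# at each rank, map back through each column's rank order (no-ties case)
qnOracle <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) out[, j] <- ref[rank(m[, j])]
  out
}

writeTempTsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

toyOboLines <- function() {
  c("format-version: 1.2",
    "",
    "[Term]", "id: T:0001", "name: root", "namespace: biological_process",
    "",
    "[Term]", "id: T:0002", "name: child a",
    "namespace: biological_process", "is_a: T:0001 ! root",
    "",
    "[Term]", "id: T:0003", "name: child b",
    "namespace: biological_process", "is_a: T:0001 ! root",
    "",
    "[Term]", "id: T:0004", "name: grandchild",
    "namespace: biological_process", "is_a: T:0002 ! child a",
    "",
    "[Term]", "id: T:0005", "name: gone", "is_obsolete: true")
}
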