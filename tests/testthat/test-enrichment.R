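test_that("hypergeometric pmf and tail match small worked cases", {
  expect_equal(hypergeomPmf(1, M = 5, K = 2, n = 2), 0.6)
  expect_equal(hypergeomTail(2, M = 5, K = 2, n = 2), 0.1)
  expect_equal(hypergeomTail(3, M = 10, K = 4, n = 5), 66 / 252)
  expect_equal(hypergeomPmf(3, M = 3, K = 3, n = 3), 1)  # all marked
  expect_equal(hypergeomTail(0, M = 40, K = 7, n = 11), 1)
})

test_that("pmf normalizes and rejects out-of-support arguments", {
  for (M in c(6, 17, 60)) {
    K <- floor(M / 3); n <- floor(M / 2)
    lo <- max(0, n + K - M)
    s <- sum(vapply(lo:min(n, K), hypergeomPmf, numeric(1),
                    M = M, K = K, n = n))
    expect_equal(s, 1, tolerance = 1e-12)
  }
  expect_error(hypergeomPmf(3, M = 5, K = 2, n = 2), "support")
  expect_error(hypergeomPmf(0, M = 10, K = 6, n = 7), "support")  # lo = 3
  expect_error(hypergeomPmf(1, M = 5, K = 6, n = 2), "K <= M")
  expect_error(hypergeomTail(3, M = 5, K = 2, n = 2), "support")
})

test_that("pmf agrees exactly with exhaustive draw enumeration", {
  for (M in c(4, 7, 9)) {
    for (K in 0:M) {
      for (n in c(0:2, M %/% 2, M)) {
        for (x in max(0, n + K - M):min(n, K)) {
          expect_equal(hypergeomPmf(x, M, K, n),
                       hyperEnumOracle(x, M, K, n), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("log-space path agrees with stats::phyper/dhyper at scale", {
  set.seed(13)
  for (i in 1:50) {
    M <- sample(100:1000, 1)
    K <- sample.int(M, 1)
    n <- sample.int(M, 1)
    x <- sampleRange(max(0, n + K - M), min(n, K))
    expect_equal(hypergeomPmf(x, M, K, n), dhyper(x, K, M - K, n),
                 tolerance = 1e-10)
    expect_equal(hypergeomTail(x, M, K, n),
                 phyper(x - 1, K, M - K, n, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("tail is non-increasing in x and 1 at the support minimum", {
  M <- 30; K <- 12; n <- 9
  xs <- max(0, n + K - M):min(n, K)
  tails <- vapply(xs, hypergeomTail, numeric(1), M = M, K = K, n = n)
  expect_equal(tails[1], 1)
  expect_true(all(diff(tails) <= 1e-15))
})

test_that("gene-set enrichment computes counts against the background", {
  background <- paste0("g", 1:10)
  collection <- GeneSetCollection(list(hit = paste0("g", 1:4),
                                       other = paste0("g", 8:10)))
  query <- paste0("g", c(1, 2, 3, 9, 10))
  res <- enrichGeneSets(query, background, collection)
  hit <- res[res$set == "hit", ]
  expect_identical(c(hit$K, hit$x, hit$n, hit$M), c(4L, 3L, 5L, 10L))
  expect_equal(hit$p_value, 66 / 252)

  # query == background draws every set completely: x = K, p = 1
  res_all <- enrichGeneSets(background, background, collection)
  expect_true(all(res_all$x == res_all$K))
  expect_true(all(res_all$p_value == 1))
})

test_that("enrichment is invariant to gene order, case and duplicates", {
  background <- paste0("g", 1:40)
  collection <- GeneSetCollection(list(s1 = paste0("g", 1:10),
                                       s2 = paste0("g", 30:40)))
  q <- paste0("g", c(1:6, 31:33))
  base <- enrichGeneSets(q, background, collection)
  messy <- enrichGeneSets(rev(c(q, toupper(q))), background, collection)
  expect_equal(messy, base)
})

test_that("query genes outside the background are dropped with a warning", {
  background <- paste0("g", 1:20)
  collection <- GeneSetCollection(list(s = paste0("g", 1:5)))
  expect_warning(res <- enrichGeneSets(c("g1", "g2", "zzz"), background,
                                       collection), "outside")
  expect_identical(res$n[1], 2L)
  expect_error(enrichGeneSets(character(), background, collection), "empty")
})

test_that("a planted set ranks first on its fixture", {
  sim <- genGenesetsAndOntology(seed = 11)
  res <- enrichGeneSets(sim$query, sim$background, sim$collection)
  expect_identical(res$set[1], sim$truth$planted_set)
  expect_lt(res$p_value[1], res$p_value[2] / 100)
})

test_that("GO enrichment propagates annotations along is_a ancestry", {
  obo <- writeTempTsv(toyOboLines())
  ann <- writeTempTsv(c(paste0("g", 1:4, "\tT:0004"),
                        paste0("g", 5:12, "\tT:0003")))
  ont <- readOntology(obo, ann)
  background <- paste0("g", 1:12)
  # genes of the grandchild term count for its parent and the root
  res <- enrichGO(paste0("g", 1:4), background, ont)
  expect_false("T:0001" %in% res$term)           # root excluded
  gc_row <- res[res$term == "T:0004", ]
  pa_row <- res[res$term == "T:0002", ]
  expect_identical(gc_row$K, 4L)
  # T:0002 has identical gene content to its only annotated child
  expect_identical(pa_row$K, 4L)
  expect_equal(pa_row$p_value, gc_row$p_value)
  expect_identical(res$term[1:2], c("T:0002", "T:0004"))
})

test_that("a planted GO leaf and its ancestors dominate the ranking", {
  sim <- genGenesetsAndOntology(seed = 11)
  res <- enrichGO(sim$query, sim$background, sim$ontology)
  leaf <- sim$truth$planted_term
  anc <- setdiff(termAncestors(sim$ontology, leaf),
                 ontologyRoots(sim$ontology))
  top <- res$term[seq_len(length(anc) + 1)]
  expect_setequal(top, c(leaf, anc))
})

test_that("the DOT export contains significant terms plus their ancestry", {
  obo <- writeTempTsv(toyOboLines())
  ann <- writeTempTsv(c("g1\tT:0004", "g2\tT:0002", "g3\tT:0003"))
  ont <- readOntology(obo, ann)
  rec <- data.frame(term = "T:0004", name = "grandchild",
                    namespace = "biological_process", K = 1L, x = 1L,
                    n = 1L, M = 3L, p_value = 1e-5,
                    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".dot")
  exportGoGraph(rec, ont, path)
  dot <- readLines(path)
  for (node in c("T:0004", "T:0002", "T:0001"))
    expect_true(any(grepl(node, dot, fixed = TRUE)))
  expect_false(any(grepl("T:0003", dot, fixed = TRUE)))
  expect_true(any(grepl('"T:0004" -> "T:0002"', dot, fixed = TRUE)))

  exportGoGraph(rec[0, ], ont, path)
  expect_false(any(grepl("T:", readLines(path), fixed = TRUE)))
})

test_that("density-only compatibility mode reports the point mass", {
  background <- paste0("g", 1:10)
  collection <- GeneSetCollection(list(s = paste0("g", 1:4)))
  q <- paste0("g", c(1, 2, 3, 9, 10))
  tail_p <- enrichGeneSets(q, background, collection)$p_value
  pmf_p <- enrichGeneSets(q, background, collection, pmf_mode = TRUE)$p_value
  expect_equal(pmf_p, hypergeomPmf(3, 10, 4, 5))
  expect_gt(tail_p, pmf_p)                        # tail includes x = 4
})
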