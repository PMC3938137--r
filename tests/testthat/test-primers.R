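test_that("GC fraction is an exact count ratio over ACGT only", {
  expect_equal(gcFraction("ATGC"), 0.5)
  expect_equal(gcFraction("GGCC"), 1.0)
  expect_equal(gcFraction("ATAT"), 0.0)
  expect_error(gcFraction("ATGN"), "non-ACGT")
  expect_error(gcFraction(""), "empty")
})

test_that("Wallace rule melting temperatures are exact", {
  expect_equal(meltingTemperature("ACGT", "wallace"), 12)
  expect_equal(meltingTemperature("AAAATTTT", "wallace"), 16)
  # enumerated short oligos against independent base counting
  set.seed(1)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(2:12, 1), TRUE),
               collapse = "")
    counts <- table(factor(strsplit(s, "")[[1]], c("A", "C", "G", "T")))
    expect_equal(meltingTemperature(s, "wallace"),
                 2 * (counts[["A"]] + counts[["T"]]) +
                   4 * (counts[["G"]] + counts[["C"]]))
  }
})

test_that("nearest-neighbor Tm respects duplex symmetry", {
  set.seed(2)
  for (i in 1:200) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(15:30, 1), TRUE),
               collapse = "")
    expect_equal(meltingTemperature(s), meltingTemperature(reverseComplement(s)),
                 tolerance = 1e-9)
  }
  # physically plausible range for typical qPCR oligos
  expect_gt(meltingTemperature("ACGTTGCAACGTTGCAACGT"), 45)
  expect_lt(meltingTemperature("ACGTTGCAACGTTGCAACGT"), 75)
  expect_error(meltingTemperature("ACGT", method = "zipper"))
})

test_that("homopolymer runs are measured correctly", {
  expect_identical(maxHomopolymerRun("AAAT"), 3L)
  expect_identical(maxHomopolymerRun("ACGT"), 1L)
  expect_identical(maxHomopolymerRun("TTTTT"), 5L)
})

test_that("hairpin detection matches an exhaustive substring oracle", {
  hairpinOracle <- function(seq, min_stem, min_loop) {
    ch <- strsplit(seq, "")[[1]]
    L <- length(ch)
    best <- 0
    for (len in seq_len(L)) {
      if (len < min_stem) next
      for (i in seq_len(max(0, L - len + 1))) {
        for (j in seq_len(max(0, L - len + 1))) {
          if (j - (i + len - 1) - 1 >= min_loop) {
            a <- paste(ch[i:(i + len - 1)], collapse = "")
            b <- paste(ch[j:(j + len - 1)], collapse = "")
            if (a == reverseComplement(b)) best <- max(best, len)
          }
        }
      }
    }
    list(hairpin = best >= min_stem, stem_length = best)
  }
  hp <- hairpinCheck("GGGGAAAACCCC", min_stem = 4, min_loop = 4)
  expect_true(hp$hairpin)
  expect_identical(hp$stem_length, 4L)
  expect_false(hairpinCheck("ACACACACAC", 4, 3)$hairpin)
  expect_false(hairpinCheck("ACGTACGT", 5, 3)$hairpin)  # stem > |seq|/2

  set.seed(3)
  for (i in 1:40) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(10:18, 1), TRUE),
               collapse = "")
    mine <- hairpinCheck(s, 3, 3)
    oracle <- hairpinOracle(s, 3, 3)
    expect_identical(mine$hairpin, oracle$hairpin)
    if (oracle$hairpin) expect_identical(mine$stem_length,
                                         as.integer(oracle$stem_length))
  }
})

test_that("dimer scores count complementary runs and are symmetric", {
  expect_identical(dimerScore("AAAA", "TTTT"), 4L)
  expect_identical(dimerScore("ACGT", "ACGT"), 4L)   # palindrome self-dimer
  expect_identical(dimerScore("AAAA", "AAAA"), 0L)   # A-A never pairs
  set.seed(4)
  for (i in 1:50) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(6:20, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(6:20, 1), TRUE),
               collapse = "")
    expect_identical(dimerScore(a, b), dimerScore(b, a))
  }
})

unboundedConstraints <- function(...) {
  primerConstraints(gc_min = 0, gc_max = 1, tm_min = -Inf, tm_max = Inf,
                    run_max = 1000, hairpin_stem = 900, dimer_max = 1000,
                    ...)
}

test_that("unconstrained enumeration yields the closed-form window count", {
  set.seed(5)
  tmpl <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  cst <- unboundedConstraints(length_min = 18, length_max = 22,
                              amplicon_min = 30, amplicon_max = 120)
  res <- designPrimers(tmpl, cst, top_k = 1)
  L <- nchar(tmpl)
  expected <- sum(vapply(18:22, function(l) L - l + 1, numeric(1)))
  expect_identical(nrow(res$candidates), as.integer(2 * expected))
})

test_that("homopolymer templates produce no candidates under the run filter", {
  res <- designPrimers(strrep("A", 200), primerConstraints())
  expect_identical(nrow(res$pairs), 0L)
  expect_gt(sum(res$attrition$forward), 0)   # attrition counts, not an error
})

test_that("the planted compliant pair ranks first on simulated templates", {
  sim <- genTemplate(seed = 9)
  res <- designPrimers(sim$template)
  expect_gte(nrow(res$pairs), 1)
  expect_identical(res$pairs$fwd_start[1], sim$truth$fwd_start)
  expect_identical(res$pairs$rev_start[1], sim$truth$rev_start)
  expect_identical(res$pairs$fwd_seq[1], sim$truth$fwd_seq)
  expect_identical(res$pairs$amplicon_length[1], sim$truth$amplicon_length)
})

test_that("every emitted primer satisfies every active constraint", {
  sim <- genTemplate(seed = 42)
  cst <- primerConstraints()
  res <- designPrimers(sim$template, cst)
  for (i in seq_len(nrow(res$candidates))) {
    s <- res$candidates$sequence[i]
    expect_gte(nchar(s), cst$length_min)
    expect_lte(nchar(s), cst$length_max)
    expect_gte(gcFraction(s), cst$gc_min)
    expect_lte(gcFraction(s), cst$gc_max)
    tm <- meltingTemperature(s)
    expect_gte(tm, cst$tm_min); expect_lte(tm, cst$tm_max)
    expect_lte(maxHomopolymerRun(s), cst$run_max)
    expect_false(hairpinCheck(s, cst$hairpin_stem, cst$hairpin_loop)$hairpin)
    expect_lte(dimerScore(s, s), cst$dimer_max)
  }
  for (i in seq_len(nrow(res$all_pairs))) {
    p <- res$all_pairs[i, ]
    expect_gte(p$amplicon_length, cst$amplicon_min)
    expect_lte(p$amplicon_length, cst$amplicon_max)
    expect_lte(p$tm_difference, cst$tm_diff_max)
    expect_lte(p$cross_dimer, cst$dimer_max)
  }
})

test_that("feasibility pass cells correspond exactly to emitted pairs", {
  sim <- genTemplate(seed = 7)
  res <- designPrimers(sim$template)
  expect_identical(sum(res$feasibility == "pass"), nrow(res$all_pairs))
})

test_that("tightening a constraint never adds a candidate", {
  set.seed(6)
  tmpl <- genTemplate(seed = 6)$template
  loose <- designPrimers(tmpl, primerConstraints())
  tight_sets <- list(primerConstraints(gc_min = 0.45, gc_max = 0.55),
                     primerConstraints(tm_min = 58, tm_max = 62),
                     primerConstraints(run_max = 3),
                     primerConstraints(dimer_max = 5))
  key <- function(cand) paste(cand$strand, cand$start, cand$length)
  for (cst in tight_sets) {
    tight <- designPrimers(tmpl, cst)
    expect_true(all(key(tight$candidates) %in% key(loose$candidates)))
  }
})
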