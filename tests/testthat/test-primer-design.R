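# Degenerate primer design: consensus coding, candidate ranking against a
# brute-force window scan, and the hairpin/dimer/Tm heuristics.

test_that("column_consensus returns the minimal covering IUPAC code", {
  expect_equal(column_consensus("A"), "A")
  expect_equal(column_consensus(c("C", "T")), "Y")
  expect_equal(column_consensus(c("A", "C", "G", "T")), "N")
  expect_equal(column_consensus(c("C", "T", "C", "C")), "Y")
  expect_equal(column_consensus(c("A", "-", "A")), "A")
  expect_true(is.na(column_consensus(c("-", "-"))))
  expect_error(column_consensus(c("A", "R")), "concrete")
})

test_that("consensus degeneracy reflects observed column variation", {
  base <- strrep("ACGTTGCA", 4)
  aln <- c(s1 = base, s2 = base, s3 = base)
  cands <- design_primers(aln, length_range = c(10, 12),
                          max_degeneracy = 1)
  expect_true(all(cands$degeneracy == 1))
  expect_true(all(cands$three_prime_run == cands$end - cands$start + 1))
  # one varying column inside the window doubles the degeneracy
  aln2 <- aln
  substr(aln2[["s2"]], 5, 5) <- "A" # T -> A gives W at column 5
  expect_equal(consensus_sequence(aln2),
               paste0("ACGTWGCA", strrep("ACGTTGCA", 3)))
  cands2 <- design_primers(aln2, length_range = c(10, 10),
                           max_degeneracy = 4)
  covering <- cands2[cands2$start <= 5 & cands2$end >= 5, ]
  outside <- cands2[cands2$start > 5, ]
  expect_true(all(covering$degeneracy == 2))
  expect_true(all(outside$degeneracy == 1))
})

test_that("a planted conserved window is recovered as the top candidate", {
  withr::with_seed(19, {
    len <- 120
    motif <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    win <- 51:70 # planted conserved window
    mat <- matrix(rep(motif, 6), nrow = 6, byrow = TRUE)
    # every column outside the window varies in exactly one sequence, so
    # the planted window is the unique degeneracy-1 stretch
    for (col in setdiff(seq_len(len), win)) {
      row <- sample(6, 1)
      mat[row, col] <- sample(setdiff(c("A", "C", "G", "T"),
                                      mat[row, col]), 1)
    }
    aln <- setNames(apply(mat, 1, paste, collapse = ""), paste0("s", 1:6))
  })
  cands <- design_primers(aln, length_range = c(20, 20),
                          max_degeneracy = 4096,
                          min_three_prime_run = 0)
  # brute-force oracle: minimum-degeneracy window over a raw scan
  win_deg <- vapply(seq_len(120 - 19), function(s) {
    prod(vapply(s:(s + 19), function(j) {
      length(unique(mat[, j]))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(cands$start[1], which.min(win_deg))
  expect_equal(cands$start[1], 51)
  expect_equal(cands$degeneracy[1], 1)
  # ranking is stable under reordering of the alignment rows
  cands_shuffled <- design_primers(aln[c(4, 2, 6, 1, 3, 5)],
                                   length_range = c(20, 20),
                                   max_degeneracy = 4096,
                                   min_three_prime_run = 0)
  expect_equal(cands$seq, cands_shuffled$seq)
  # an impossible threshold yields no candidates plus a diagnostic
  none <- design_primers(aln, length_range = c(20, 20),
                         max_degeneracy = 1, min_three_prime_run = 21)
  expect_equal(nrow(none), 0)
  expect_false(is.null(attr(none, "best_failing")))
})

test_that("dimer scores agree with a quadratic brute-force check", {
  expect_equal(dimer_score("AAAA", "TTTT")$score, 4)
  expect_equal(dimer_score("ACGT", "ACGT")$score, 4) # palindrome self-dimer
  # oracle: longest common complementary run over all alignments of a
  # against revcomp(b)
  oracle_dimer <- function(a, b) {
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(oracle_revcomp(b), "")[[1]] # a aligned to revcomp(b)
    best <- 0
    for (off in (-length(cb) + 1):(length(ca) - 1)) {
      run <- 0
      for (i in seq_along(ca)) {
        j <- i - off
        ok <- j >= 1 && j <= length(cb) &&
          length(intersect(ORACLE_IUPAC[[ca[i]]],
                           ORACLE_IUPAC[[cb[j]]])) > 0
        if (ok) {
          run <- run + 1
          best <- max(best, run)
        } else {
          run <- 0
        }
      }
    }
    best
  }
  withr::with_seed(23, {
    for (i in 1:15) {
      a <- random_degenerate_string(sample(6:14, 1))
      b <- random_degenerate_string(sample(6:14, 1))
      expect_equal(dimer_score(a, b)$score, oracle_dimer(a, b))
    }
  })
})

test_that("hairpin_score finds self-foldback stems with a minimal loop", {
  # GGGG ... CCCC folds back with a 4-base loop: stem 4
  expect_gte(hairpin_score("GGGGAACTTCCCC"), 4)
  # no antiparallel self-complementary stem of length 3 anywhere
  expect_lt(hairpin_score("AAAAAAAAAAAA"), 3)
  # adjacent stem halves can't fold back: only the outermost G:C pair has
  # a loop of >= 3 between its partners
  expect_equal(hairpin_score("GGGCCC"), 1)
})

test_that("tm_estimate uses Wallace for short and GC/length above 14", {
  expect_equal(tm_estimate("AAAATTTT"), 16)
  expect_equal(tm_estimate("GGGGCCCC"), 32)
  # 20-mer with 10 G/C: 64.9 + 41 * (10 - 16.4) / 20 = 51.78
  s20 <- "ACGTACGTACGTACGTACGT"
  expect_equal(tm_estimate(s20), 64.9 + 41 * (10 - 16.4) / 20)
  # degenerate positions contribute expected GC: S is always G/C
  expect_equal(tm_estimate("SSSSAAAA"), tm_estimate("GCGCAAAA"))
})

test_that("M13 tagging is reversible and excluded from arithmetic", {
  p <- "ATGCAYGTMACBGGDTTTARAAG"
  tagged <- tag_m13(p, "forward")
  expect_equal(nchar(tagged), nchar(p) + 18)
  expect_equal(strip_m13(tagged, "forward"), p)
  expect_equal(degeneracy(tagged), degeneracy(p))
  expect_error(tag_m13(tagged, "forward"), "already")
  expect_error(strip_m13(p, "reverse"), "does not start")
})
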