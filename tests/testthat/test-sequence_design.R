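# Library design: reverse complement, palindrome screening, fold proxy,
# candidate selection, chimera assembly, charge bookkeeping.

test_that("reverse_complement handles hand-checkable cases and is an involution", {
  expect_identical(reverse_complement("GTAC"), "GTAC")
  expect_identical(reverse_complement("AAAA"), "TTTT")
  expect_identical(reverse_complement("ACGTT"), "AACGT")
  withr::with_seed(11, {
    for (i in 1:20) {
      s <- random_dna(sample(5:80, 1))
      expect_identical(reverse_complement(reverse_complement(s)), s)
    }
  })
  expect_error(reverse_complement("ACGX"), "position 4")
})

test_that("find_palindromes reports known hits", {
  hits <- find_palindromes("GTACGTAC", 6)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 0L)
  expect_equal(hits$length, 8L)
  expect_identical(hits$segment, "GTACGTAC")

  hits <- find_palindromes("GAATTC", 6)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$length, 6L)

  expect_equal(nrow(find_palindromes("AAAAAAAA", 4)), 0L)
  expect_error(find_palindromes("ACGT", 5), "even")
})

test_that("find_palindromes matches the brute-force substring oracle", {
  withr::with_seed(101, {
    for (i in 1:60) {
      s <- random_dna(60)
      got <- find_palindromes(s, 6)
      want <- oracle_palindromes(s, 6)
      expect_equal(got$start, want$start, info = s)
      expect_equal(got$length, want$length, info = s)
    }
  })
})

test_that("every reported palindrome segment is its own reverse complement", {
  withr::with_seed(202, {
    for (i in 1:30) {
      s <- random_dna(50)
      hits <- find_palindromes(s, 4)
      for (seg in hits$segment)
        expect_identical(reverse_complement(seg), seg)
    }
  })
})

test_that("shuffle_library conserves composition and is seed-deterministic", {
  s <- "ACGTACGTAAGGCCTT"
  lib <- shuffle_library(s, n = 100, seed = 42)
  expect_length(lib, 100L)
  comp0 <- table(strsplit(s, "")[[1L]])
  for (x in lib)
    expect_equal(table(strsplit(x, "")[[1L]]), comp0)
  expect_identical(lib, shuffle_library(s, n = 100, seed = 42))
  expect_false(identical(lib, shuffle_library(s, n = 100, seed = 43)))
  expect_error(shuffle_library(s, n = 0), ">= 1")
})

test_that("fold_proxy solves hand-checkable structures", {
  expect_equal(fold_proxy("AAAAAAA")$pair_count, 0L)
  fp <- fold_proxy("GGGGAAAACCCC", min_loop = 3)
  expect_equal(fp$pair_count, 4L)
  expect_equal(nchar(fp$structure), 12L)
  # dot-bracket consistent with reported pairs
  expect_equal(sum(strsplit(fp$structure, "")[[1L]] == "("), nrow(fp$pairs))
})

test_that("fold_proxy equals the exhaustive-enumeration oracle on 15-mers", {
  withr::with_seed(303, {
    for (i in 1:25) {
      s <- random_dna(15)
      expect_equal(fold_proxy(s, 3)$pair_count, oracle_fold_count(s, 3),
                   info = s)
    }
    # and on shorter lengths with a different loop minimum
    for (i in 1:10) {
      s <- random_dna(sample(5:12, 1))
      expect_equal(fold_proxy(s, 2)$pair_count, oracle_fold_count(s, 2),
                   info = s)
    }
  })
})

test_that("fold_proxy pairs are nested, disjoint and respect the loop minimum", {
  withr::with_seed(404, {
    for (i in 1:15) {
      s <- random_dna(30)
      fp <- fold_proxy(s, 3)
      if (!nrow(fp$pairs)) next
      idx <- c(fp$pairs)
      expect_equal(anyDuplicated(idx), 0L)
      expect_true(all(fp$pairs[, 2] - fp$pairs[, 1] - 1 >= 3))
      # nestedness: no crossing pairs
      if (nrow(fp$pairs) > 1) {
        for (a in seq_len(nrow(fp$pairs) - 1)) {
          for (b in (a + 1):nrow(fp$pairs)) {
            p <- fp$pairs[a, ]; q <- fp$pairs[b, ]
            crossing <- (p[1] < q[1] && q[1] < p[2] && p[2] < q[2]) ||
                        (q[1] < p[1] && p[1] < q[2] && q[2] < p[2])
            expect_false(crossing)
          }
        }
      }
    }
  })
})

test_that("select_candidate filters palindromes then ranks by pair count", {
  lib <- c(a = "GTACGTACAA", b = "AAAAAAAAAA")
  expect_identical(unname(select_candidate(lib, 6, 1)), "AAAAAAAAAA")
  expect_identical(unname(select_candidate(c(x = "ACGTA"), 6, 1)), "ACGTA")
  expect_error(select_candidate(c(a = "GTACGTAC"), 6, 1), "palindrome")
  expect_error(select_candidate(lib, 6, rank = 5), "rank")

  # seeded library vs independent filter-then-sort oracle
  lib20 <- shuffle_library("ACGTACGTAAGGCCTTACGT", n = 20, seed = 7)
  keep <- vapply(lib20, function(s) nrow(oracle_palindromes(s, 6)) == 0L,
                 logical(1))
  surv <- lib20[keep]
  counts <- vapply(surv, function(s) oracle_fold_count(s, 3), integer(1))
  for (r in seq_len(min(3L, length(surv)))) {
    expect_identical(select_candidate(lib20, 6, r),
                     surv[order(counts)][r])
  }
  # survivor property
  sel <- select_candidate(lib20, 6, 1)
  expect_equal(nrow(find_palindromes(sel, 6)), 0L)
})

test_that("assemble_chimera splices regions correctly", {
  expect_identical(assemble_chimera("AAAAAAAA", "TTTTTTTT", list(c(2, 5))),
                   "TTAAATTT")
  expect_identical(assemble_chimera("AAAA", "TTTT", list(c(0, 4))), "AAAA")
  expect_identical(assemble_chimera("AAAA", "TTTT", list()), "TTTT")
  s <- random_dna(30, seed = 5)
  expect_identical(assemble_chimera(s, s, list(c(3, 9), c(12, 20))), s)
  expect_error(assemble_chimera("AAA", "TTTT", list()), "equal length")
  expect_error(assemble_chimera("AAAA", "TTTT", list(c(0, 3), c(2, 4))),
               "overlap")
  expect_error(assemble_chimera("AAAA", "TTTT", list(c(2, 5))), "bounds")
})

test_that("peptide_net_charge counts side chains only", {
  expect_equal(peptide_net_charge("LGKSGRLPGKSGRV"), 4)
  expect_equal(peptide_net_charge("GG"), 0)
  expect_equal(peptide_net_charge("KRDE"), 0)
  expect_equal(peptide_net_charge("HHHH"), 0)
  expect_error(peptide_net_charge("KXZ"), "position 2")
})

test_that("charge_stoichiometry reproduces the phosphodiester charge model", {
  expect_equal(charge_stoichiometry(76, 5)$ratio, 15)
  expect_equal(charge_stoichiometry(76, 5)$n_peptides, 15L)
  expect_equal(charge_stoichiometry(2, 1)$n_peptides, 1L)
  cs <- charge_stoichiometry(76, 4)
  expect_equal(cs$ratio, 18.75)
  expect_equal(cs$n_peptides, 19L)
  expect_error(charge_stoichiometry(76, 0), "positive")
})
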