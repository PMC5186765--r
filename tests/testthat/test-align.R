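test_that("self-alignment score equals the sum of diagonal matrix entries", {
  scheme <- scoring_scheme("protein")
  al <- local_align("MKVLA", "MKVLA", scheme)
  expected <- sum(diag(scheme$matrix[c("M", "K", "V", "L", "A"),
                                     c("M", "K", "V", "L", "A")]))
  expect_equal(al$raw_score, expected)
  expect_equal(al$identity_pct, 100)
  expect_equal(al$coverage_query_pct, 100)
  expect_equal(al$coverage_subject_pct, 100)
})

test_that("local alignment floors at zero for unalignable pairs", {
  al <- local_align("AAAA", "CCCC", scoring_scheme("protein"))
  expect_true(al$empty)
  expect_equal(al$raw_score, 0)
  expect_equal(al$identity_pct, 0)
})

test_that("global alignment of length-mismatched sequences opens one gap", {
  al <- global_align("MK", "MAK", scoring_scheme("protein"))
  expect_equal(nchar(al$aligned_query), 3)
  expect_equal(lengths(regmatches(al$aligned_query,
                                  gregexpr("-", al$aligned_query))), 1)
})

test_that("Karlin-Altschul bitscores and E-values follow the closed form", {
  scheme <- scoring_scheme("protein")
  # bitscore 20 over a 1e6-residue search space
  s20 <- (20 * log(2) + log(scheme$kappa)) / scheme$lambda
  res <- evalue_of(s20, 1000, 1000, scheme)
  expect_equal(res$bitscore, 20)
  expect_equal(res$evalue, 1e6 * 2^-20)
  res100 <- evalue_of(100, 250, 4000, scheme)
  expect_equal(res100$bitscore, (26.7 - log(0.041)) / log(2))
  expect_error(evalue_of(10, 0, 5, scheme), "positive")
  # E is strictly decreasing in the raw score
  ev <- evalue_of(1:50, 100, 1000, scheme)$evalue
  expect_true(all(diff(ev) < 0))
})

test_that("affine DP with equal open/extend matches the linear-gap oracle", {
  # exhaustive small instances over a 4-letter DNA alphabet
  scheme <- scoring_scheme("dna", gap_open = 2L, gap_extend = 2L)
  sub <- scheme$matrix
  set.seed(101)
  seqs <- vapply(rep(1:12, length.out = 36), random_dna_chr, "")
  for (pair in combn(seq_along(seqs), 2, simplify = FALSE)) {
    a <- seqs[pair[1]]; b <- seqs[pair[2]]
    expect_equal(local_align(a, b, scheme)$raw_score,
                 sw_linear_oracle(a, b, sub, 2),
                 info = paste(a, b))
    expect_equal(global_align(a, b, scheme)$raw_score,
                 nw_linear_oracle(a, b, sub, 2),
                 info = paste(a, b))
  }
})

test_that("affine DP matches the oracle on random protein pairs", {
  scheme <- scoring_scheme("protein", gap_open = 4L, gap_extend = 4L)
  set.seed(202)
  for (i in 1:60) {
    a <- random_protein_chr(sample(5:40, 1))
    b <- random_protein_chr(sample(5:40, 1))
    expect_equal(local_align(a, b, scheme)$raw_score,
                 sw_linear_oracle(a, b, scheme$matrix, 4))
  }
})

test_that("alignment score is symmetric and self-score dominates", {
  scheme <- scoring_scheme("protein")
  set.seed(303)
  seqs <- vapply(rep(20:40, length.out = 8), random_protein_chr, "")
  for (i in seq_along(seqs)) {
    self <- local_align(seqs[i], seqs[i], scheme)$raw_score
    for (j in seq_along(seqs)) {
      sij <- local_align(seqs[i], seqs[j], scheme)$raw_score
      expect_equal(sij, local_align(seqs[j], seqs[i], scheme)$raw_score)
      expect_gte(self, sij)
    }
  }
})

test_that("search_db ranks hits and applies the E-value cutoff", {
  scheme <- scoring_scheme("protein")
  set.seed(404)
  target <- random_protein_chr(120)
  db <- Biostrings::AAStringSet(setNames(
    c(vapply(rep(100, 20), random_protein_chr, ""), target),
    c(paste0("d", 1:20), "self")))
  hits <- search_db(target, db, scheme, e_cutoff = 1e-5)
  expect_equal(hits$sid[1], "self")
  expect_equal(hits$pident[1], 100)
  # unrelated random database yields nothing at 1e-5
  lone <- search_db(random_protein_chr(120), db[1:20], scheme, 1e-5)
  expect_equal(nrow(lone), 0)
  # ties in E are broken by bitscore then subject id
  twin_db <- Biostrings::AAStringSet(c(b_twin = target, a_twin = target))
  twins <- search_db(target, twin_db, scheme, 1e-5)
  expect_equal(twins$sid, c("a_twin", "b_twin"))
})
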