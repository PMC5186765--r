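test_that("center-star alignment degaps to the inputs and handles pairs", {
  msa <- center_star_align(c(a = "MKVLAW", b = "MKVLW", c = "MKVLAW"))
  expect_equal(unname(nchar(msa$rows)), rep(msa$ncol, 3))
  expect_equal(gsub("-", "", msa$rows[["b"]]), "MKVLW")
  # identical sequences align without gaps
  same <- center_star_align(c(x = "MKVL", y = "MKVL"))
  expect_false(any(grepl("-", same$rows)))
  # two sequences reduce to their global alignment
  al <- global_align("MKVLAW", "MKVLW")
  two <- center_star_align(c(p = "MKVLAW", q = "MKVLW"))
  expect_equal(unname(two$rows), c(al$aligned_query, al$aligned_subject))
  expect_error(center_star_align(c(only = "MKV")), "two")
})

test_that("center choice is no worse than any other star (sum of pairs)", {
  set.seed(21)
  base <- random_protein_chr(40)
  mutate <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    pos <- sample(seq_along(v), k)
    v[pos] <- vapply(v[pos], function(x) sample(setdiff(AA_LETTERS, x), 1), "")
    paste(v, collapse = "")
  }
  seqs <- c(s1 = base, s2 = mutate(base, 4), s3 = mutate(base, 6),
            s4 = mutate(base, 8))
  scheme <- scoring_scheme("protein")
  chosen <- sum_of_pairs_score(center_star_align(seqs, scheme), scheme)
  # brute force: force every sequence to act as the star center
  for (c_idx in seq_along(seqs)) {
    forced <- orphancore:::star_align_around(seqs, c_idx, scheme)
    expect_gte(chosen + 1e-9, sum_of_pairs_score(forced, scheme))
  }
})

test_that("consensus and conservation follow the modal rules", {
  msa <- structure(list(rows = c(r1 = "AV-A", r2 = "AV-A", r3 = "VVAA",
                                 r4 = "VV-A"),
                        ncol = 4L), class = "msa_result")
  cp <- consensus_profile(msa)
  # ties alphabetical (A vs V at col 1 is 2/2), gap-majority at col 3
  expect_equal(cp$consensus, "AV-A")
  expect_equal(cp$conservation, c(0.5, 1, 1, 1))
})

test_that("PSSM scores are finite, maximal for conserved residues, and separate members from shuffles", {
  set.seed(31)
  base <- random_protein_chr(60)
  seqs <- setNames(rep(base, 4), paste0("m", 1:4))
  msa <- center_star_align(seqs)
  pssm <- build_pssm(msa)
  expect_true(all(is.finite(pssm$scores)))
  # each column scores highest for the conserved residue
  chars <- strsplit(base, "")[[1]]
  for (j in seq_len(ncol(pssm$scores))) {
    expect_equal(rownames(pssm$scores)[which.max(pssm$scores[, j])], chars[j])
  }
  # direct closed-form check of one column (4 identical residues)
  aa <- chars[1]
  expect_equal(unname(pssm$scores[aa, 1]),
               log2(((4 + 0.5 / 20) / (4 + 0.5)) / (1 / 20)))
  # member scores beat shuffled versions of themselves
  member_score <- pssm_score(pssm, base)
  for (i in 1:100) {
    shuf <- paste(sample(chars), collapse = "")
    expect_gt(member_score, pssm_score(pssm, shuf))
  }
})

test_that("columns with majority gaps are dropped from PSSMs only", {
  msa <- structure(list(rows = c(r1 = "MK-A", r2 = "MK-A", r3 = "MKVA",
                                 r4 = "MK-A"),
                        ncol = 4L), class = "msa_result")
  pssm <- build_pssm(msa)
  expect_equal(ncol(pssm$scores), 3)
  expect_equal(pssm$kept_columns, c(1L, 2L, 4L))
})
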