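test_that("backtranslation places codons and gap triplets correctly", {
  msa <- structure(list(rows = c(a = "MK", b = "MK"), ncol = 2L),
                   class = "msa_result")
  ca <- backtranslate(msa, c(a = "ATGAAA", b = "ATGAAG"))
  expect_equal(unname(ca["a"]), "ATGAAA")
  msa2 <- structure(list(rows = c(a = "M-K", b = "MAK"), ncol = 3L),
                    class = "msa_result")
  ca2 <- backtranslate(msa2, c(a = "ATGAAA", b = "ATGGCTAAA"))
  expect_equal(unname(ca2["a"]), "ATG---AAA")
  # terminal stops are tolerated, internal stops and mismatches are not
  ca3 <- backtranslate(msa, c(a = "ATGAAATAA", b = "ATGAAG"))
  expect_equal(unname(ca3["a"]), "ATGAAA")
  expect_error(backtranslate(msa, c(a = "ATGTAAAAA", b = "ATGAAG")),
               "internal stop")
  expect_error(backtranslate(msa, c(a = "ATGGGG", b = "ATGAAG")),
               "does not translate")
})

test_that("the worked single-change example matches hand-computed NG86", {
  est <- ng86_pairwise("GGGGGGGGGGGG", "GGAGGGGGGGGG")
  expect_equal(est$S, 4)
  expect_equal(est$N, 8)
  expect_equal(est$Sd, 1)
  expect_equal(est$Nd, 0)
  expect_equal(est$ps, 0.25)
  expect_equal(est$Ks, -0.75 * log(1 - 1 / 3))
  expect_equal(est$Ka, 0)
  # identical rows: everything zero, omega undefined
  same <- ng86_pairwise("ATGAAA", "ATGAAA")
  expect_equal(same$Sd + same$Nd, 0)
  expect_false(same$omega_defined)
})

test_that("NG86 matches the pathway-enumerating oracle on random pairs", {
  set.seed(51)
  for (i in 1:100) {
    n <- sample(5:25, 1)
    s1 <- random_sense_codons(n)
    # derive s2 by mutating a few nucleotides, keeping codons sense
    v <- strsplit(s1, "")[[1]]
    for (k in sample(length(v), sample(1:6, 1))) {
      old <- v[k]
      v2 <- v
      v2[k] <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      cod <- paste(v2[(3 * ((k - 1) %/% 3) + 1):(3 * ((k - 1) %/% 3) + 3)],
                   collapse = "")
      if (ng_code[[cod]] != "*") v <- v2
    }
    s2 <- paste(v, collapse = "")
    est <- ng86_pairwise(s1, s2)
    orc <- ng_oracle(s1, s2)
    expect_equal(est$S, orc$S, tolerance = 1e-9)
    expect_equal(est$N, orc$N, tolerance = 1e-9)
    expect_equal(est$Sd, orc$Sd, tolerance = 1e-9)
    expect_equal(est$Nd, orc$Nd, tolerance = 1e-9)
  }
})

test_that("NG86 is symmetric and conserves sites over comparable codons", {
  set.seed(61)
  for (i in 1:20) {
    s1 <- random_sense_codons(20)
    s2 <- random_sense_codons(20)
    ab <- ng86_pairwise(s1, s2)
    ba <- ng86_pairwise(s2, s1)
    expect_equal(ab$S, ba$S)
    expect_equal(ab$Sd, ba$Sd)
    expect_equal(ab$Nd, ba$Nd)
    expect_equal(ab$S + ab$N, 3 * ab$n_codons)
  }
  # gapped codons are skipped
  gapped <- ng86_pairwise("ATG---AAA", "ATGGCGAAA")
  expect_equal(gapped$n_codons, 2)
})

test_that("family omega averages defined pairs and flags degenerate cases", {
  fam <- simulate_codon_family(0.2, n_seqs = 3, n_codons = 100,
                               divergence = 0.2, seed = 71)
  om <- family_omega(fam$cds)
  expect_true(om$defined)
  expect_equal(nrow(om$pairs), 3)
  expect_equal(om$omega_mean,
               mean(om$pairs$omega[!is.na(om$pairs$omega)]))
  # all-identical family: no defined pair
  same <- setNames(rep(random_sense_codons(50), 3), paste0("s", 1:3))
  om2 <- family_omega(same)
  expect_false(om2$defined)
  expect_equal(om2$n_excluded, 3)
})

test_that("a purifying-selection simulation yields omega well below one", {
  fam <- simulate_codon_family(0, n_seqs = 2, n_codons = 200,
                               divergence = 0.2, seed = 81)
  est <- ng86_pairwise(fam$cds[[1]], fam$cds[[2]])
  # only synonymous changes were accepted; pathway averaging of multi-hit
  # codons can contribute at most a sliver of apparent Ka
  expect_lt(est$Ka, 0.01)
  expect_gt(est$Ks, 0.05)
  expect_true(all(fam$realized$accepted_nonsyn == 0))
})
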