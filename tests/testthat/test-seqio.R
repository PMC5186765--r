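test_that("read_fasta parses headers, wrapping, and case", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a first protein", "MKV", ">b", "mkv", "LAW"), f)
  recs <- read_fasta(f, "protein")
  expect_equal(names(recs), c("a", "b"))
  expect_equal(as.character(recs), c(a = "MKV", b = "MKVLAW"))
})

test_that("read_fasta rejects duplicate ids and illegal residues", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MKV", ">a", "MKL"), f)
  expect_error(read_fasta(f, "protein"), "duplicate.*a")
  writeLines(c(">a", "MKJV"), f)
  expect_error(read_fasta(f, "protein"), "illegal.*position 3")
  writeLines(character(), f)
  expect_warning(empty <- read_fasta(f, "protein"), "empty")
  expect_length(empty, 0)
})

test_that("fasta round-trip is the identity and honors line width", {
  set.seed(1)
  recs <- Biostrings::AAStringSet(setNames(
    vapply(sample(30:200, 8), random_protein_chr, ""),
    paste0("p", 1:8)))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f, width = 60)
  lines <- readLines(f)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
  back <- read_fasta(f, "protein")
  expect_equal(as.character(back), as.character(recs))
})

test_that("translate_cds follows the bacterial code and strips the stop", {
  expect_equal(translate_cds("ATGAAA"), "MK")
  expect_equal(translate_cds("ATGAAATAA"), "MK")
  expect_error(translate_cds("ATGTA"), "divisible")
  expect_error(translate_cds("ATGTAAAAA"), "internal stop")
})

test_that("six-frame translation maps peptides back to forward coordinates", {
  fr <- six_frame_translate("ATGAAA")
  expect_equal(nrow(fr), 6)
  expect_equal(fr$peptide[fr$frame == 1], "MK")
  fr2 <- six_frame_translate("TTTCAT")
  expect_equal(fr2$peptide[fr2$frame == -1], "MK")
  expect_warning(out <- six_frame_translate("AT"), "shorter")
  expect_equal(nrow(out), 0)
})

test_that("six-frame coordinates relocate and retranslate to the same peptide", {
  set.seed(7)
  contig <- random_dna_chr(300)
  fr <- six_frame_translate(contig)
  for (i in seq_len(nrow(fr))) {
    sub <- substr(contig, fr$source_start[i], fr$source_end[i])
    if (fr$frame[i] < 0) sub <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
    expect_equal(as.character(Biostrings::translate(
      Biostrings::DNAString(sub),
      genetic.code = Biostrings::getGeneticCode("11"),
      no.init.codon = TRUE)), fr$peptide[i])
    expect_equal(nchar(fr$peptide[i]),
                 (fr$source_end[i] - fr$source_start[i] + 1) %/% 3)
  }
})

test_that("stop-split segments carry correct nucleotide spans", {
  set.seed(11)
  contig <- random_dna_chr(240)
  segs <- split_at_stops(six_frame_translate(contig), min_aa = 5)
  expect_gt(nrow(segs), 0)
  for (i in seq_len(nrow(segs))) {
    sub <- substr(contig, segs$source_start[i], segs$source_end[i])
    if (segs$frame[i] < 0) sub <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
    expect_equal(as.character(Biostrings::translate(
      Biostrings::DNAString(sub),
      genetic.code = Biostrings::getGeneticCode("11"),
      no.init.codon = TRUE)), segs$peptide[i])
    expect_false(grepl("*", segs$peptide[i], fixed = TRUE))
  }
})
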