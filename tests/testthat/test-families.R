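# a tiny two-genome universe with hand-built proteins for edge-level tests
two_genome_setup <- function() {
  set.seed(121)
  shared <- random_protein_chr(90)
  list(
    pa = proteome("gA", "sp1", Biostrings::AAStringSet(
      c(`gA|p1` = shared, `gA|p2` = random_protein_chr(80)))),
    pb = proteome("gB", "sp2", Biostrings::AAStringSet(
      c(`gB|p1` = shared, `gB|p2` = random_protein_chr(80)))))
}

test_that("identical proteins across two genomes form one reciprocal pair", {
  s <- two_genome_setup()
  hits <- all_vs_all(list(s$pa, s$pb))
  expect_setequal(unique(hits$qid), c("gA|p1", "gB|p1"))
  edges <- bbbh_edges(hits)
  expect_equal(nrow(edges), 1)
  expect_equal(sort(c(edges$protein_a, edges$protein_b)),
               c("gA|p1", "gB|p1"))
  expect_error(all_vs_all(list(s$pa)), "two")
})

test_that("families are single-linkage components with singleton fill-in", {
  edges <- data.frame(protein_a = c("a1", "b1"), protein_b = c("b1", "c1"),
                      genome_a = c("A", "B"), genome_b = c("B", "C"),
                      evalue_ab = 1e-30, evalue_ba = 1e-30,
                      identity_pct = 90, coverage_a_pct = 95,
                      coverage_b_pct = 95, stringsAsFactors = FALSE)
  prot <- list(
    proteome("A", "s1", Biostrings::AAStringSet(c(a1 = "MKVLAW"))),
    proteome("B", "s2", Biostrings::AAStringSet(c(b1 = "MKVLAW"))),
    proteome("C", "s3", Biostrings::AAStringSet(c(c1 = "MKVLAW",
                                                  c2 = "MWWWAC"))))
  fams <- build_families(edges, prot)
  expect_equal(length(unique(fams$family_id)), 2)
  fam_of <- setNames(fams$family_id, fams$protein_id)
  expect_equal(unname(fam_of["a1"]), unname(fam_of["b1"]))
  expect_equal(unname(fam_of["a1"]), unname(fam_of["c1"]))
  expect_false(fam_of[["c2"]] == fam_of[["a1"]])
  # sub-threshold identity breaks the edge
  edges_low <- edges
  edges_low$identity_pct <- c(49, 90)
  fams_low <- build_families(edges_low, prot)
  fam_of_low <- setNames(fams_low$family_id, fams_low$protein_id)
  expect_false(fam_of_low[["a1"]] == fam_of_low[["b1"]])
})

test_that("core requires presence in every genome; one-genome runs are all core", {
  fams <- data.frame(
    family_id = c("F1", "F1", "F1", "F2", "F2", "F3"),
    genome_id = c("A", "B", "C", "A", "B", "A"),
    protein_id = paste0("p", 1:6), stringsAsFactors = FALSE)
  pan <- partition_core(fams, c("A", "B", "C"))
  expect_equal(pan$partitions$core, "F1")
  expect_equal(pan$partitions$accessory, "F2")
  expect_equal(pan$partitions$singleton, "F3")
  pan1 <- partition_core(fams[fams$genome_id == "A", ], "A")
  expect_setequal(pan1$partitions$core, c("F1", "F2", "F3"))
  expect_error(partition_core(fams, character()), "empty")
})

test_that("the partition property holds on a simulated pan-genome", {
  sim <- simulate_pan_genome(tiny_config(seed = 131))
  hits <- all_vs_all(sim$proteomes)
  fams <- build_families(bbbh_edges(hits), sim$proteomes)
  n_prot <- sum(vapply(sim$proteomes, function(p) length(p$proteins), 0L))
  expect_equal(nrow(fams), n_prot)
  expect_false(anyDuplicated(fams$protein_id) > 0)
  # monotonicity: raising min_identity never enlarges any family
  edges <- bbbh_edges(hits)
  sizes <- function(f) sort(table(f$family_id), decreasing = TRUE)
  s50 <- sizes(build_families(edges, sim$proteomes, min_identity = 50))
  s90 <- sizes(build_families(edges, sim$proteomes, min_identity = 90))
  expect_gte(length(s90), length(s50))
  expect_lte(max(s90), max(s50))
})

test_that("the orphan screen rejects families with reference homologs", {
  sim <- simulate_pan_genome(tiny_config(seed = 141))
  hits <- all_vs_all(sim$proteomes)
  fams <- build_families(bbbh_edges(hits), sim$proteomes)
  pan <- partition_core(fams, names(sim$proteomes))
  orphans <- orphan_screen(pan, sim$proteomes, sim$refdb)
  mem <- sim$truth$members
  truth_of <- function(f) unique(mem$family_id[mem$protein_id %in%
    fams$protein_id[fams$family_id == f]])
  recovered <- sort(unlist(lapply(orphans, truth_of)))
  expect_equal(recovered, sort(sim$truth$orphan_families))
  # a family whose member sits verbatim in the reference db is rejected
  prot <- sim$proteomes[[1]]$proteins
  spiked <- c(sim$refdb, Biostrings::AAStringSet(
    setNames(as.character(prot[1]), "spike")))
  orphans2 <- orphan_screen(pan, sim$proteomes, spiked)
  fam_hit <- fams$family_id[fams$protein_id == names(prot)[1]]
  expect_false(fam_hit %in% orphans2)
  # empty refdb: warning, everything comes back
  expect_warning(all_orph <- orphan_screen(pan, sim$proteomes,
                                           Biostrings::AAStringSet()),
                 "empty")
  expect_setequal(all_orph, pan$partitions$core)
})

test_that("profile confirmation accepts decoy-only refdbs and spots profile-level homologs", {
  sim <- simulate_pan_genome(tiny_config(seed = 151))
  mem <- sim$truth$members
  orphan_fam <- sim$truth$orphan_families[1]
  members <- pooled_members(sim, orphan_fam)
  set.seed(152)
  decoys <- Biostrings::AAStringSet(setNames(
    vapply(rep(100, 40), random_protein_chr, ""), paste0("d", 1:40)))
  expect_true(profile_confirm(members, decoys, n_shuffles = 200))
  # plant a 45%-identity homolog of the family: profile search must see it
  hom <- mutate_identity(as.character(members[[1]]), 0.45)
  spiked <- c(decoys, Biostrings::AAStringSet(c(planted_hom = hom)))
  expect_false(profile_confirm(members, spiked, n_shuffles = 200))
  expect_warning(skip <- profile_confirm(members[1], decoys,
                                         n_shuffles = 50), "single")
  expect_true(is.na(skip))
})
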