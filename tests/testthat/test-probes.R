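probe_setup <- function(seed = 161) {
  sim <- simulate_pan_genome(tiny_config(seed = seed))
  fam_ids <- sim$truth$orphan_families
  type_strains <- vapply(unique(vapply(sim$proteomes, function(p)
    p$species_label, "")), function(sp) {
    names(sim$proteomes)[vapply(sim$proteomes, function(p)
      p$species_label, "") == sp][1]
  }, "")
  probes <- lapply(type_strains, function(g)
    build_species_probe(sim$truth$members, sim$proteomes, fam_ids, g))
  names(probes) <- vapply(probes, function(p) p$species_label, "")
  list(sim = sim, probes = probes, fam_ids = fam_ids)
}

test_that("species probes concatenate one gene per family in order", {
  st <- probe_setup()
  pr <- st$probes[[1]]
  expect_equal(names(pr$genes), st$fam_ids)
  expect_equal(sum(Biostrings::width(pr$genes)),
               Biostrings::width(pr$concat))
  # determinism: rebuilding gives the identical probe
  again <- build_species_probe(st$sim$truth$members, st$sim$proteomes,
                               st$fam_ids, pr$genome_id)
  expect_identical(as.character(pr$concat), as.character(again$concat))
  # the genes are exactly the truth-table planted CDS
  p <- st$sim$proteomes[[pr$genome_id]]
  mem <- st$sim$truth$members
  for (f in st$fam_ids) {
    pid <- mem$protein_id[mem$family_id == f & mem$genome_id == pr$genome_id]
    expect_equal(as.character(pr$genes[[f]]), as.character(p$cds[[pid]]))
  }
  expect_error(build_species_probe(st$sim$truth$members, st$sim$proteomes,
                                   c(st$fam_ids, "no_such"), pr$genome_id),
               "no member")
})

test_that("a probe recognizes its source genome and ignores alien ones", {
  st <- probe_setup()
  pr <- st$probes[[1]]
  own <- probe_vs_genome_identity(pr, st$sim$genomes[[pr$genome_id]])
  expect_gte(own$identity_pct, 99)
  expect_true(all(own$per_family$found))
  expect_equal(sum(own$per_family$weight), 1)
  set.seed(162)
  alien <- Biostrings::DNAStringSet(c(alien = random_dna_chr(5000)))
  none <- probe_vs_genome_identity(pr, alien)
  expect_equal(none$identity_pct, 0)
  expect_false(any(none$per_family$found))
})

test_that("the identity matrix is diagonally dominant and strand/order invariant", {
  st <- probe_setup()
  im <- identity_matrix(st$probes, st$sim$genomes)
  expect_equal(colnames(im$matrix), names(st$sim$genomes))
  species_of <- vapply(st$sim$proteomes, function(p) p$species_label, "")
  for (g in colnames(im$matrix)) {
    own <- im$matrix[species_of[[g]], g]
    expect_true(all(own > im$matrix[rownames(im$matrix) !=
                                      species_of[[g]], g]))
  }
  # reverse-complementing every contig changes nothing
  g1 <- names(st$sim$genomes)[1]
  rc <- Biostrings::reverseComplement(st$sim$genomes[[g1]])
  pr <- st$probes[[1]]
  expect_equal(probe_vs_genome_identity(pr, rc)$identity_pct,
               probe_vs_genome_identity(pr, st$sim$genomes[[g1]])$identity_pct,
               tolerance = 1e-9)
})

test_that("species assignment picks the right probe and flags edge cases", {
  st <- probe_setup()
  species_of <- vapply(st$sim$proteomes, function(p) p$species_label, "")
  for (g in names(st$sim$genomes)) {
    call <- assign_species(st$sim$genomes[[g]], st$probes)
    expect_equal(call$best_label, species_of[[g]])
    expect_false(call$ambiguous)
  }
  # identical probes are ambiguous
  twin <- st$probes[c(1, 1)]
  names(twin) <- c("t1", "t2")
  g1 <- names(st$sim$genomes)[1]
  expect_true(assign_species(st$sim$genomes[[g1]], twin)$ambiguous)
  # a genome with no homologs gets no call
  set.seed(163)
  alien <- Biostrings::DNAStringSet(c(alien = random_dna_chr(4000)))
  expect_true(assign_species(alien, st$probes)$no_call)
})

test_that("an intermediate-divergence strain maps to its nearest species", {
  cfg <- tiny_config(seed = 171)
  cfg$intermediate_strain <- TRUE
  sim <- simulate_pan_genome(cfg)
  fam_ids <- sim$truth$orphan_families
  species_of <- vapply(sim$proteomes, function(p) p$species_label, "")
  type_strains <- vapply(unique(species_of), function(sp)
    names(sim$proteomes)[species_of == sp][1], "")
  probes <- lapply(type_strains, function(g)
    build_species_probe(sim$truth$members, sim$proteomes, fam_ids, g))
  names(probes) <- unique(species_of)
  call <- assign_species(sim$intermediate$genome, probes)
  expect_equal(call$best_label, sim$truth$intermediate$nearest_species)
})
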