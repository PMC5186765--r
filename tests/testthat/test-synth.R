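test_that("the pan-genome generator is deterministic and matches its config", {
  cfg <- tiny_config(seed = 42)
  sim1 <- simulate_pan_genome(cfg)
  sim2 <- simulate_pan_genome(cfg)
  expect_equal(length(sim1$proteomes), sum(cfg$strains_per_species))
  n_fam <- cfg$n_core_shared + cfg$n_orphan + cfg$n_traps
  expect_equal(nrow(sim1$truth$families), n_fam)
  expect_equal(length(sim1$refdb),
               cfg$refdb_decoys + cfg$n_core_shared + cfg$n_traps)
  # byte-identical under the same seed
  expect_identical(as.character(sim1$refdb), as.character(sim2$refdb))
  expect_identical(as.character(sim1$genomes[[1]]),
                   as.character(sim2$genomes[[1]]))
  # different seed, different output
  sim3 <- simulate_pan_genome(tiny_config(seed = 43))
  expect_false(identical(as.character(sim1$refdb),
                         as.character(sim3$refdb)))
})

test_that("proteome CDS always translate back to their proteins", {
  sim <- simulate_pan_genome(tiny_config(seed = 44))
  for (p in sim$proteomes) expect_length(p$flagged, 0)
})

test_that("realized identities sit near the configured targets", {
  sim <- simulate_pan_genome(tiny_config(seed = 45))
  aud <- audit_pan_genome(sim, n_families = 3)
  intra <- mean(aud$identity_pct[aud$level == "intra"])
  inter <- mean(aud$identity_pct[aud$level == "inter"])
  expect_equal(intra, 100 * sim$config$intra_species_identity, tolerance = 0.03)
  expect_equal(inter, 100 * sim$config$inter_species_identity, tolerance = 0.05)
})

test_that("strain genomes embed every gene at its annotated location", {
  sim <- simulate_pan_genome(tiny_config(seed = 46))
  gid <- names(sim$genomes)[1]
  contig <- as.character(sim$genomes[[gid]][[1]])
  ann <- sim$annotations[[gid]]
  p <- sim$proteomes[[gid]]
  fam_rows <- ann[!ann$product_tag %in% c("dnaA", "dnaN"), ]
  for (i in seq_len(nrow(fam_rows))) {
    gene <- substr(contig, fam_rows$start[i], fam_rows$end[i])
    expect_equal(gene, as.character(p$cds[[fam_rows$gene_id[i]]]))
  }
})

test_that("codon-family simulation respects the omega dial", {
  fam0 <- simulate_codon_family(0, n_seqs = 3, n_codons = 100,
                                divergence = 0.1, seed = 47)
  expect_true(all(fam0$realized$accepted_nonsyn == 0))
  fam1 <- simulate_codon_family(1, n_seqs = 2, n_codons = 100,
                                divergence = 0.1, seed = 47)
  expect_gt(sum(fam1$realized$accepted_nonsyn), 0)
  # determinism
  rep1 <- simulate_codon_family(0.3, seed = 48)
  rep2 <- simulate_codon_family(0.3, seed = 48)
  expect_identical(rep1$cds, rep2$cds)
  # no internal stops ever
  for (s in fam1$cds) {
    expect_false(grepl("\\*", translate_cds(paste0(s, "TAA"))))
  }
})

test_that("metagenome simulation yields the expected read count and truth", {
  sim <- simulate_pan_genome(tiny_config(seed = 49))
  gid <- names(sim$genomes)[1]
  ann <- sim$annotations[[gid]]
  ann$contig <- names(sim$genomes[[gid]])
  mg <- simulate_metagenome(sim$genomes[gid], read_length = 150,
                            fold_coverage = 5, seed = 50, annotation = ann)
  L <- sum(Biostrings::width(sim$genomes[[gid]]))
  expect_equal(length(mg$reads), round(L * 5 / 150))
  expect_true(all(Biostrings::width(mg$reads) == 150))
  # at 5x coverage essentially every gene is touched
  expect_true(all(mg$gene_coverage$covered_fraction > 0.5))
  # reads really come from where the truth says
  ori <- mg$origins[1, ]
  frag <- substr(as.character(sim$genomes[[gid]][[ori$contig]]),
                 ori$start, ori$end)
  if (ori$strand == "-") {
    frag <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(frag)))
  }
  expect_equal(as.character(mg$reads[[1]]), frag)
})
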