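# codon bookkeeping for the generators: sense codons of the bacterial code,
# grouped by amino acid
synth_env <- new.env(parent = emptyenv())

codon_groups <- function() {
  if (!is.null(synth_env$groups)) return(synth_env$groups)
  code <- getGeneticCode("11")
  sense <- code[code != "*"]
  synth_env$groups <- split(names(sense), unname(sense))
  synth_env$groups
}

random_protein <- function(len) {
  paste(c("M", sample(AA20, len - 1L, replace = TRUE)), collapse = "")
}

random_cds_for <- function(protein) {
  groups <- codon_groups()
  chars <- strsplit(protein, "")[[1]]
  codons <- vapply(chars, function(aa) {
    opts <- groups[[aa]]
    opts[sample.int(length(opts), 1L)]
  }, "")
  paste(c(codons, "TAA"), collapse = "")
}

# Mutate a protein/CDS pair: a fraction `q` of residues get a new random
# amino acid (codon re-drawn); unchanged residues swap to a random
# synonymous codon with probability `syn_rate`.
mutate_gene <- function(protein, cds, q, syn_rate) {
  groups <- codon_groups()
  chars <- strsplit(protein, "")[[1]]
  L <- length(chars)
  n_cod <- (nchar(cds) - 3L) / 3L
  stopifnot(n_cod == L)
  starts <- 3L * (seq_len(L) - 1L) + 1L
  codons <- substring(cds, starts, starts + 2L)
  n_mut <- rbinom(1L, L - 1L, q)  # the initial M is kept
  mut_pos <- if (n_mut > 0) 1L + sample.int(L - 1L, n_mut) else integer()
  for (p in mut_pos) {
    new_aa <- sample(AA20[AA20 != chars[p]], 1L)
    chars[p] <- new_aa
    opts <- groups[[new_aa]]
    codons[p] <- opts[sample.int(length(opts), 1L)]
  }
  syn_pos <- setdiff(which(runif(L) < syn_rate), mut_pos)
  for (p in syn_pos) {
    opts <- groups[[chars[p]]]
    codons[p] <- opts[sample.int(length(opts), 1L)]
  }
  list(protein = paste(chars, collapse = ""),
       cds = paste(c(codons, "TAA"), collapse = ""))
}

#' Configuration for the synthetic pan-genome generator
#'
#' Defaults emulate the study design the pipeline targets: a genus of four
#' species with 2/2/3/2 strains (nine genomes), a shared core with diverged
#' out-of-genus homologs in the reference database, a handful of planted
#' genus-restricted (orphan) core families, near-orphan "trap" families
#' whose only out-of-genus homolog sits at ~35% identity, per-strain
#' accessory genes, about 98% within-species and 75% between-species
#' protein identity, and a 500-sequence decoy reference database.
#'
#' @param n_species Number of species (default 4).
#' @param strains_per_species Integer vector of strain counts per species
#'   (default `c(2, 2, 3, 2)`, nine strains).
#' @param n_core_shared Core families that also have a diverged homolog in
#'   the reference database (default 20).
#' @param n_orphan Genus-restricted core families (default 5).
#' @param n_traps Core families with a ~`trap_identity` reference homolog,
#'   which must be rejected by the orphan screen (default 2).
#' @param n_accessory Accessory genes per strain (default 10).
#' @param intra_species_identity,inter_species_identity Target pairwise
#'   protein identities (defaults 0.98 and 0.75).
#' @param homolog_identity Identity of reference homologs of shared core
#'   families (default 0.60).
#' @param trap_identity Identity of the planted trap homologs
#'   (default 0.35).
#' @param refdb_decoys Number of unrelated decoy proteins in the reference
#'   database (default 500).
#' @param protein_len_range Protein length range in residues
#'   (default 80--400).
#' @param syn_rate_species,syn_rate_strain Probability that a conserved
#'   residue swaps to a synonymous codon along a species/strain branch
#'   (defaults 0.10 and 0.02).
#' @param intermediate_strain Add an extra unlabeled strain at intermediate
#'   divergence from one species, emulating a misassigned isolate
#'   (default TRUE).
#' @param intermediate_identity Protein identity of that strain to its
#'   nearest species (default 0.88).
#' @param seed Seed for all randomness (integer).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_species = 4L, strains_per_species = c(2L, 2L, 3L, 2L),
                         n_core_shared = 20L, n_orphan = 5L, n_traps = 2L,
                         n_accessory = 10L,
                         intra_species_identity = 0.98,
                         inter_species_identity = 0.75,
                         homolog_identity = 0.60, trap_identity = 0.35,
                         refdb_decoys = 500L,
                         protein_len_range = c(80L, 400L),
                         syn_rate_species = 0.10, syn_rate_strain = 0.02,
                         intermediate_strain = TRUE,
                         intermediate_identity = 0.88, seed = 1L) {
  stopifnot(length(strains_per_species) == n_species,
            all(strains_per_species >= 1L),
            intra_species_identity > 0, intra_species_identity <= 1,
            inter_species_identity > 0, inter_species_identity <= 1,
            n_core_shared >= 0, n_orphan >= 0, n_traps >= 0,
            refdb_decoys >= 0)
  structure(as.list(environment()), class = "synth_config")
}

#' Simulate a pan-genome with a truth table
#'
#' Generates ancestral core-family proteins, evolves them down a
#' species/strain hierarchy by point substitutions calibrated to the target
#' identities (each species branch substitutes `1 - sqrt(inter)` of
#' residues, each strain branch `1 - sqrt(intra)`, so pairwise identities
#' land near the targets), derives coding sequences by seeded synonymous
#' codon choice, adds per-strain accessory genes, and builds a reference
#' database of decoys plus planted homologs. Each strain also receives a
#' single-contig genome: its genes concatenated in shuffled order with
#' random intergenic spacers, led by dnaA/dnaN marker genes near the
#' origin-proximal end.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_pan_genome` with elements `proteomes`
#'   (list of [proteome()]), `refdb` (`AAStringSet`), `genomes` (named list
#'   of single-contig `DNAStringSet`s), `annotations` (named list of
#'   data.frames with `gene_id`, `start`, `end`, `strand`, `product_tag`),
#'   `truth` (family categories, member table, intermediate-strain info),
#'   `intermediate` (extra proteome + genome or NULL), and `config`.
#' @export
simulate_pan_genome <- function(config = synth_config()) {
  set.seed(config$seed)
  q_species <- 1 - sqrt(config$inter_species_identity)
  q_strain <- 1 - sqrt(config$intra_species_identity)

  n_fam <- config$n_core_shared + config$n_orphan + config$n_traps
  fam_ids <- sprintf("fam%02d", seq_len(n_fam))
  category <- rep(c("core_with_homolog", "orphan_core", "trap_core"),
                  c(config$n_core_shared, config$n_orphan, config$n_traps))
  lens <- sample(seq(config$protein_len_range[1], config$protein_len_range[2]),
                 n_fam, replace = TRUE)
  ancestors <- lapply(lens, function(L) {
    p <- random_protein(L)
    list(protein = p, cds = random_cds_for(p))
  })
  names(ancestors) <- fam_ids

  # species-level variants
  species_ids <- sprintf("sp%d", seq_len(config$n_species))
  species_genes <- lapply(species_ids, function(sp) {
    lapply(ancestors, function(anc)
      mutate_gene(anc$protein, anc$cds, q_species, config$syn_rate_species))
  })
  names(species_genes) <- species_ids

  proteomes <- list()
  genomes <- list()
  annotations <- list()
  members <- list()
  for (s in seq_len(config$n_species)) {
    for (t in seq_len(config$strains_per_species[s])) {
      gid <- sprintf("%s_st%d", species_ids[s], t)
      fam_genes <- lapply(species_genes[[s]], function(g)
        mutate_gene(g$protein, g$cds, q_strain, config$syn_rate_strain))
      acc <- lapply(seq_len(config$n_accessory), function(i) {
        p <- random_protein(sample(seq(config$protein_len_range[1],
                                       config$protein_len_range[2]), 1L))
        list(protein = p, cds = random_cds_for(p))
      })
      names(acc) <- sprintf("acc%02d", seq_len(config$n_accessory))
      built <- assemble_strain(gid, species_ids[s], fam_genes, acc)
      proteomes[[gid]] <- built$proteome
      genomes[[gid]] <- built$genome
      annotations[[gid]] <- built$annotation
      members[[gid]] <- built$members
    }
  }

  # reference database: decoys + homologs of shared families + trap homologs
  decoys <- lapply(seq_len(config$refdb_decoys), function(i)
    random_protein(sample(seq(config$protein_len_range[1],
                              config$protein_len_range[2]), 1L)))
  refdb <- setNames(unlist(decoys), sprintf("decoy%04d",
                                            seq_len(config$refdb_decoys)))
  for (f in which(category == "core_with_homolog")) {
    hom <- mutate_gene(species_genes[[1]][[f]]$protein,
                       species_genes[[1]][[f]]$cds,
                       1 - config$homolog_identity, 0)
    refdb[paste0("homolog_", fam_ids[f])] <- hom$protein
  }
  for (f in which(category == "trap_core")) {
    hom <- mutate_gene(species_genes[[1]][[f]]$protein,
                       species_genes[[1]][[f]]$cds,
                       1 - config$trap_identity, 0)
    refdb[paste0("traphom_", fam_ids[f])] <- hom$protein
  }
  refdb <- AAStringSet(refdb)

  intermediate <- NULL
  inter_truth <- NULL
  if (config$intermediate_strain) {
    near_sp <- species_ids[min(2L, config$n_species)]
    gid <- "intermediate_st1"
    fam_genes <- lapply(species_genes[[near_sp]], function(g)
      mutate_gene(g$protein, g$cds, 1 - config$intermediate_identity,
                  config$syn_rate_species))
    built <- assemble_strain(gid, NA_character_, fam_genes, list())
    intermediate <- list(proteome = built$proteome, genome = built$genome,
                         annotation = built$annotation)
    inter_truth <- list(genome_id = gid, nearest_species = near_sp)
  }

  member_tab <- do.call(rbind, members)
  rownames(member_tab) <- NULL
  truth <- list(
    families = data.frame(family_id = fam_ids, category = category,
                          stringsAsFactors = FALSE),
    members = member_tab,
    orphan_families = fam_ids[category == "orphan_core"],
    intermediate = inter_truth)
  structure(list(proteomes = proteomes, refdb = refdb, genomes = genomes,
                 annotations = annotations, truth = truth,
                 intermediate = intermediate, config = config),
            class = "synth_pan_genome")
}

# Lay one strain's genes onto a single circular-style contig: dnaA and dnaN
# first, then family and accessory genes in shuffled order, separated by
# random spacers.
assemble_strain <- function(gid, species_label, fam_genes, acc_genes) {
  prot <- c(vapply(fam_genes, `[[`, "", "protein"),
            vapply(acc_genes, `[[`, "", "protein"))
  cds <- c(vapply(fam_genes, `[[`, "", "cds"),
           vapply(acc_genes, `[[`, "", "cds"))
  local_ids <- c(names(fam_genes), names(acc_genes))
  pids <- paste(gid, local_ids, sep = "|")
  names(prot) <- pids
  names(cds) <- pids
  tags <- c(names(fam_genes), rep("accessory", length(acc_genes)))
  names(tags) <- pids

  # marker genes for origin prediction (not part of the proteome analysis)
  markers <- list(dnaA = random_cds_for(random_protein(150L)),
                  dnaN = random_cds_for(random_protein(120L)))
  order_idx <- sample(length(pids))
  spacer <- function() paste(sample(NT4, sample(100:300, 1L), replace = TRUE),
                             collapse = "")
  seq_parts <- character()
  ann <- list()
  pos <- 0L
  add_gene <- function(id, seq, tag) {
    sp <- spacer()
    seq_parts <<- c(seq_parts, sp, seq)
    start <- pos + nchar(sp) + 1L
    end <- start + nchar(seq) - 1L
    pos <<- end
    ann[[length(ann) + 1L]] <<- data.frame(
      gene_id = id, start = start, end = end, strand = "+",
      product_tag = tag, stringsAsFactors = FALSE)
  }
  add_gene(paste(gid, "dnaA", sep = "|"), markers$dnaA, "dnaA")
  add_gene(paste(gid, "dnaN", sep = "|"), markers$dnaN, "dnaN")
  for (i in order_idx) add_gene(pids[i], cds[[pids[i]]], tags[[pids[i]]])
  seq_parts <- c(seq_parts, spacer())
  contig <- DNAStringSet(paste(seq_parts, collapse = ""))
  names(contig) <- paste0(gid, "_contig1")

  fam_tags <- tags[tags != "accessory"]
  members <- data.frame(family_id = unname(fam_tags), genome_id = gid,
                        protein_id = names(fam_tags),
                        stringsAsFactors = FALSE)
  list(proteome = proteome(gid, species_label, AAStringSet(prot),
                           DNAStringSet(cds)),
       genome = contig,
       annotation = do.call(rbind, ann),
       members = members)
}

#' Post-hoc identity audit of a simulated pan-genome
#'
#' Measures realized within-species and between-species protein identities
#' on the planted families by global alignment, for comparison against the
#' configured targets.
#'
#' @param sim A [simulate_pan_genome()] result.
#' @param n_families Number of families to audit (default 5).
#' @param scheme Protein [scoring_scheme()].
#' @return A data.frame with columns `level` (`intra`/`inter`) and
#'   `identity_pct`.
#' @export
audit_pan_genome <- function(sim, n_families = 5L,
                             scheme = scoring_scheme("protein")) {
  mem <- sim$truth$members
  fams <- head(unique(mem$family_id), n_families)
  prot <- pooled_proteins(sim$proteomes)
  species_of <- vapply(sim$proteomes, function(p) p$species_label, "")
  rows <- list()
  for (f in fams) {
    m <- mem[mem$family_id == f, ]
    for (pair in combn(seq_len(nrow(m)), 2, simplify = FALSE)) {
      a <- m$protein_id[pair[1]]; b <- m$protein_id[pair[2]]
      same_sp <- species_of[[m$genome_id[pair[1]]]] ==
        species_of[[m$genome_id[pair[2]]]]
      al <- global_align(prot[[a]], prot[[b]], scheme)
      rows[[length(rows) + 1L]] <- data.frame(
        level = if (same_sp) "intra" else "inter",
        identity_pct = al$identity_pct, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a codon family under a target dN/dS
#'
#' Starting from a random ancestral CDS, each sequence accumulates accepted
#' point substitutions until it reaches `divergence / 2` substitutions per
#' site (so sequence pairs sit near `divergence`). Proposals are uniform
#' over positions and alternative bases; synonymous proposals are always
#' accepted, nonsynonymous proposals with probability `omega_target`, and
#' stop-creating proposals never.
#'
#' @param omega_target Acceptance probability of nonsynonymous proposals
#'   (the simulated dN/dS).
#' @param n_seqs Number of descendant sequences (default 2).
#' @param n_codons CDS length in codons (default 300).
#' @param divergence Target pairwise divergence in substitutions per site
#'   (default 0.2).
#' @param seed Optional seed.
#' @return A list with `cds` (named character vector; no terminal stop),
#'   `ancestor`, and `realized` (per-sequence accepted synonymous /
#'   nonsynonymous counts).
#' @export
simulate_codon_family <- function(omega_target, n_seqs = 2L, n_codons = 300L,
                                  divergence = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  code <- getGeneticCode("11")
  sense <- names(code)[code != "*"]
  anc <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
  n_target <- round(divergence / 2 * 3 * n_codons)
  evolve <- function() {
    chars <- strsplit(anc, "")[[1]]
    n_acc <- 0L; n_syn <- 0L; n_non <- 0L
    guard <- 0L
    while (n_acc < n_target) {
      guard <- guard + 1L
      if (guard > 1e7) stop("substitution target unreachable")
      pos <- sample.int(length(chars), 1L)
      nt <- sample(NT4[NT4 != chars[pos]], 1L)
      cstart <- 3L * ((pos - 1L) %/% 3L) + 1L
      old_codon <- paste(chars[cstart:(cstart + 2L)], collapse = "")
      new_chars <- chars
      new_chars[pos] <- nt
      new_codon <- paste(new_chars[cstart:(cstart + 2L)], collapse = "")
      if (code[[new_codon]] == "*") next
      if (code[[new_codon]] == code[[old_codon]]) {
        chars <- new_chars; n_acc <- n_acc + 1L; n_syn <- n_syn + 1L
      } else if (runif(1) < omega_target) {
        chars <- new_chars; n_acc <- n_acc + 1L; n_non <- n_non + 1L
      }
    }
    list(seq = paste(chars, collapse = ""), syn = n_syn, non = n_non)
  }
  res <- lapply(seq_len(n_seqs), function(i) evolve())
  cds <- setNames(vapply(res, `[[`, "", "seq"),
                  sprintf("seq%d", seq_len(n_seqs)))
  realized <- data.frame(seq = names(cds),
                         accepted_syn = vapply(res, `[[`, 0L, "syn"),
                         accepted_nonsyn = vapply(res, `[[`, 0L, "non"))
  list(cds = cds, ancestor = anc, realized = realized,
       omega_target = omega_target)
}

#' Simulate a shotgun metagenome from source genomes
#'
#' Draws uniform random fragments (reads) from a pool of genomes at the
#' requested fold coverage; half the reads are reverse-complemented. When a
#' gene annotation is supplied, the truth table reports the fraction of each
#' annotated gene covered by at least one read.
#'
#' @param genomes Named list of `DNAStringSet`s (or one `DNAStringSet`);
#'   contig names must be unique.
#' @param read_length Read length in nt (default 150).
#' @param fold_coverage Mean coverage of the pooled genomes.
#' @param seed Optional seed.
#' @param annotation Optional data.frame with columns `contig`, `gene_id`,
#'   `start`, `end`, `product_tag` for truth reporting.
#' @return A list with `reads` (`DNAStringSet`), `origins` (data.frame
#'   `read`, `contig`, `start`, `end`, `strand`), and `gene_coverage`
#'   (data.frame `gene_id`, `product_tag`, `covered_fraction`, or NULL).
#' @export
simulate_metagenome <- function(genomes, read_length = 150L, fold_coverage = 1,
                                seed = NULL, annotation = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is(genomes, "DNAStringSet")) genomes <- list(pool = genomes)
  pool <- do.call(c, unname(lapply(genomes, DNAStringSet)))
  stopifnot(!anyDuplicated(names(pool)))
  widths <- Biostrings::width(pool)
  usable <- widths >= read_length
  if (!any(usable)) stop("no contig is at least one read long")
  total <- sum(widths)
  n_reads <- max(1L, round(total * fold_coverage / read_length))
  contig_idx <- sample(which(usable), n_reads, replace = TRUE,
                       prob = widths[usable])
  starts <- vapply(contig_idx, function(i)
    sample.int(widths[i] - read_length + 1L, 1L), 0L)
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  reads <- vector("list", n_reads)
  for (r in seq_len(n_reads)) {
    frag <- subseq(pool[[contig_idx[r]]], starts[r],
                   starts[r] + read_length - 1L)
    if (strands[r] == "-") frag <- reverseComplement(frag)
    reads[[r]] <- frag
  }
  reads <- DNAStringSet(reads)
  names(reads) <- sprintf("read%06d", seq_len(n_reads))
  origins <- data.frame(read = names(reads),
                        contig = names(pool)[contig_idx],
                        start = starts, end = starts + read_length - 1L,
                        strand = strands, stringsAsFactors = FALSE)
  gene_coverage <- NULL
  if (!is.null(annotation)) {
    gene_coverage <- do.call(rbind, lapply(seq_len(nrow(annotation)),
                                           function(i) {
      g <- annotation[i, ]
      ov <- origins[origins$contig == g$contig &
                      origins$end >= g$start & origins$start <= g$end, ,
                    drop = FALSE]
      covered <- rep(FALSE, g$end - g$start + 1L)
      for (j in seq_len(nrow(ov))) {
        lo <- max(ov$start[j], g$start) - g$start + 1L
        hi <- min(ov$end[j], g$end) - g$start + 1L
        covered[lo:hi] <- TRUE
      }
      data.frame(gene_id = g$gene_id, product_tag = g$product_tag,
                 covered_fraction = mean(covered), stringsAsFactors = FALSE)
    }))
  }
  list(reads = reads, origins = origins, gene_coverage = gene_coverage)
}
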