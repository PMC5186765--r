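#' Build a species-level concatenated nucleotide probe
#'
#' Concatenates the coding sequences of the chosen strain's members of the
#' given families, in family order, into one probe (one gene per family).
#'
#' @param family_table Family membership table (columns `family_id`,
#'   `genome_id`, `protein_id`), e.g. from [build_families()] or a truth
#'   table.
#' @param proteomes List of [proteome()] objects (supplies the CDS).
#' @param family_ids Ordered character vector of families to include.
#' @param genome_id The strain whose genes are used.
#' @param species_label Label carried by the probe (defaults to the
#'   strain's species).
#' @return An object of class `species_probe`: list with `species_label`,
#'   `genome_id`, `genes` (named `DNAStringSet`, one per family, terminal
#'   stop codons retained), `concat` (single `DNAStringSet`).
#' @export
build_species_probe <- function(family_table, proteomes, family_ids,
                                genome_id, species_label = NULL) {
  pidx <- vapply(proteomes, function(p) p$genome_id, "") == genome_id
  if (!any(pidx)) stop("unknown genome: ", genome_id)
  prot <- proteomes[pidx][[1]]
  if (is.null(species_label)) species_label <- prot$species_label
  genes <- character(length(family_ids))
  for (i in seq_along(family_ids)) {
    rows <- family_table$family_id == family_ids[i] &
      family_table$genome_id == genome_id
    if (!any(rows)) stop("genome ", genome_id, " has no member of family ",
                         family_ids[i])
    pid <- family_table$protein_id[rows][1]
    genes[i] <- as.character(prot$cds[[pid]])
  }
  genes <- DNAStringSet(setNames(genes, family_ids))
  concat <- DNAStringSet(paste(as.character(genes), collapse = ""))
  names(concat) <- paste0(species_label, "_probe")
  structure(list(species_label = species_label, genome_id = genome_id,
                 genes = genes, concat = concat),
            class = "species_probe")
}

#' @export
print.species_probe <- function(x, ...) {
  cat(sprintf("<species_probe> %s (%s): %d genes, %d nt\n", x$species_label,
              x$genome_id, length(x$genes), sum(Biostrings::width(x$genes))))
  invisible(x)
}

#' Percent identity of a concatenated probe against a genome
#'
#' Each constituent gene is searched against the genome (both strands) with
#' `blastn` under the same scoring as the package's nucleotide scheme
#' (match +2 / mismatch -3, gap open 5 / extend 2); the best hit with
#' E-value at most `e_cutoff` contributes its percent identity. The
#' probe-level value is the length-weighted mean over genes, with genes
#' lacking a passing hit contributing identity 0 at full weight (so absent
#' families depress the cell). Genome-scale nucleotide search is delegated
#' to the BLAST+ executables, as for [ani()].
#'
#' @param probe A [build_species_probe()] result.
#' @param genome A `DNAStringSet` of contigs.
#' @param e_cutoff E-value floor for a gene to count as found
#'   (default `1e-10`).
#' @return A list with `identity_pct` (the length-weighted cell value) and
#'   `per_family` (data.frame `family_id`, `gene_length`, `identity_pct`,
#'   `found`, `weight`; weights sum to 1).
#' @export
probe_vs_genome_identity <- function(probe, genome, e_cutoff = 1e-10) {
  genome <- DNAStringSet(genome)
  stopifnot(length(genome) > 0)
  td <- tempfile("probe")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  qf <- file.path(td, "genes.fasta")
  sf <- file.path(td, "genome.fasta")
  writeXStringSet(probe$genes, qf)
  writeXStringSet(genome, sf)
  run_quiet("makeblastdb", c("-in", sf, "-dbtype", "nucl"))
  out <- file.path(td, "hits.tsv")
  run_quiet("blastn", c("-task", "blastn", "-query", qf, "-db", sf,
                        "-reward", "2", "-penalty", "-3",
                        "-gapopen", "5", "-gapextend", "2", "-dust", "no",
                        "-evalue", format(e_cutoff, scientific = TRUE),
                        "-outfmt", shQuote("6 qseqid pident bitscore evalue"),
                        "-out", out))
  hits <- tryCatch(read.delim(out, header = FALSE,
                              col.names = c("qseqid", "pident", "bitscore",
                                            "evalue")),
                   error = function(e) NULL)
  best_id <- setNames(rep(0, length(probe$genes)), names(probe$genes))
  found <- setNames(rep(FALSE, length(probe$genes)), names(probe$genes))
  if (!is.null(hits) && nrow(hits)) {
    hits <- hits[hits$evalue <= e_cutoff, , drop = FALSE]
    hits <- hits[order(hits$qseqid, -hits$bitscore), , drop = FALSE]
    top <- hits[!duplicated(hits$qseqid), , drop = FALSE]
    best_id[top$qseqid] <- top$pident
    found[top$qseqid] <- TRUE
  }
  per <- data.frame(family_id = names(probe$genes),
                    gene_length = Biostrings::width(probe$genes),
                    identity_pct = unname(best_id), found = unname(found),
                    stringsAsFactors = FALSE)
  per$weight <- per$gene_length / sum(per$gene_length)
  list(identity_pct = sum(per$identity_pct * per$weight), per_family = per)
}

#' Probe-by-genome identity matrix
#'
#' @param probes Named list of [build_species_probe()] objects (rows).
#' @param genomes Named list of `DNAStringSet`s (columns; input order
#'   preserved).
#' @param e_cutoff Per-gene E-value floor.
#' @return A list with `matrix` (probes x genomes percent identities) and
#'   `breakdown` (nested per-cell per-family tables).
#' @export
identity_matrix <- function(probes, genomes, e_cutoff = 1e-10) {
  m <- matrix(NA_real_, length(probes), length(genomes),
              dimnames = list(names(probes), names(genomes)))
  breakdown <- list()
  for (p in names(probes)) {
    breakdown[[p]] <- list()
    for (g in names(genomes)) {
      cell <- probe_vs_genome_identity(probes[[p]], genomes[[g]], e_cutoff)
      m[p, g] <- cell$identity_pct
      breakdown[[p]][[g]] <- cell$per_family
    }
  }
  list(matrix = m, breakdown = breakdown)
}

#' Assign a genome to the best-matching species probe
#'
#' @param genome A `DNAStringSet` of contigs.
#' @param probes Named list of [build_species_probe()] objects.
#' @param e_cutoff Per-gene E-value floor.
#' @param margin_pts Ambiguity margin in percentage points (default 2): the
#'   call is ambiguous when the top two probes are closer than this.
#' @return A list with `best_label`, `best_probe`, `identity_pct`, `margin`,
#'   `ambiguous`, `no_call` (TRUE when no probe finds any gene), and
#'   `scores` (named vector).
#' @export
assign_species <- function(genome, probes, e_cutoff = 1e-10,
                           margin_pts = 2) {
  scores <- vapply(probes, function(p)
    probe_vs_genome_identity(p, genome, e_cutoff)$identity_pct, 0)
  if (all(scores == 0)) {
    return(list(best_label = NA_character_, best_probe = NA_character_,
                identity_pct = 0, margin = 0, ambiguous = FALSE,
                no_call = TRUE, scores = scores))
  }
  ord <- order(-scores, names(probes))
  best <- ord[1]
  margin <- if (length(scores) > 1L) scores[best] - scores[ord[2]] else Inf
  list(best_label = probes[[best]]$species_label,
       best_probe = names(probes)[best],
       identity_pct = unname(scores[best]), margin = unname(margin),
       ambiguous = margin < margin_pts, no_call = FALSE, scores = scores)
}

#' Genus-level protein probe set
#'
#' Pools every family member protein of every strain (families x strains
#' sequences when complete) for translated metagenome screening.
#'
#' @param family_table Membership table (`family_id`, `genome_id`,
#'   `protein_id`).
#' @param proteomes List of [proteome()] objects.
#' @param family_ids Families to include.
#' @return A list of class `genus_probe`: `proteins` (named `AAStringSet`)
#'   and `info` (data.frame `protein_id`, `family_id`, `genome_id`,
#'   `species_label`).
#' @export
genus_probe <- function(family_table, proteomes, family_ids) {
  keep <- family_table$family_id %in% family_ids
  tab <- family_table[keep, , drop = FALSE]
  prot <- pooled_proteins(proteomes)
  species_of <- setNames(vapply(proteomes, function(p) p$species_label, ""),
                         vapply(proteomes, function(p) p$genome_id, ""))
  seqs <- prot[tab$protein_id]
  structure(list(
    proteins = seqs,
    info = data.frame(protein_id = tab$protein_id,
                      family_id = tab$family_id, genome_id = tab$genome_id,
                      species_label = unname(species_of[tab$genome_id]),
                      stringsAsFactors = FALSE)),
    class = "genus_probe")
}

#' Write an identity matrix as TSV (probes as rows)
#' @param im An [identity_matrix()] result.
#' @param path Output TSV path.
#' @export
write_identity_matrix <- function(im, path) {
  df <- data.frame(probe = rownames(im$matrix), im$matrix,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
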