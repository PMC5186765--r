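#' Construct a proteome object
#'
#' A proteome couples the predicted protein sequences of one genome with
#' their coding sequences. Every protein must be the table-11 translation of
#' its CDS (terminal stop stripped); pairs that fail this check are flagged
#' and excluded from codon-level analyses.
#'
#' @param genome_id Unique genome identifier.
#' @param species_label Species the genome belongs to.
#' @param proteins A named [Biostrings::AAStringSet].
#' @param cds A named [Biostrings::DNAStringSet]; names must match
#'   `names(proteins)` where present.
#' @return An object of class `proteome` with fields `genome_id`,
#'   `species_label`, `proteins`, `cds`, and `flagged` (protein ids whose CDS
#'   is missing or does not translate back to the protein).
#' @export
proteome <- function(genome_id, species_label, proteins, cds = NULL) {
  stopifnot(!is.null(names(proteins)), !anyDuplicated(names(proteins)))
  flagged <- character()
  if (!is.null(cds)) {
    for (id in names(proteins)) {
      if (!id %in% names(cds)) {
        flagged <- c(flagged, id)
        next
      }
      pep <- tryCatch(translate_cds(cds[[id]]), error = function(e) NA_character_)
      if (is.na(pep) || pep != as.character(proteins[[id]])) {
        flagged <- c(flagged, id)
      }
    }
  }
  structure(list(genome_id = genome_id, species_label = species_label,
                 proteins = proteins, cds = cds, flagged = flagged),
            class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat(sprintf("<proteome> %s (%s): %d proteins, %d flagged\n", x$genome_id,
              x$species_label, length(x$proteins), length(x$flagged)))
  invisible(x)
}

#' All-vs-all homology search across a set of proteomes
#'
#' Every protein of every genome is searched against the pooled proteins of
#' all *other* genomes (within-genome hits never contribute to reciprocal
#' best-hit edges). Exact local DP with a score-only pre-pass; hits with
#' E-value at most `e_cutoff` are kept.
#'
#' @param proteomes A list of [proteome()] objects (at least 2).
#' @param scheme A protein [scoring_scheme()].
#' @param e_cutoff E-value cutoff (default `1e-5`).
#' @return Hit table as in [search_db()], plus columns `qgenome`, `sgenome`.
#' @export
all_vs_all <- function(proteomes, scheme = scoring_scheme("protein"),
                       e_cutoff = 1e-5) {
  if (length(proteomes) < 2L) stop("need at least two proteomes")
  gids <- vapply(proteomes, function(p) p$genome_id, "")
  stopifnot(!anyDuplicated(gids))
  all_prot <- do.call(c, unname(lapply(proteomes, function(p) p$proteins)))
  ids <- unname(unlist(lapply(proteomes, function(p) names(p$proteins))))
  if (anyDuplicated(ids)) stop("protein ids must be unique across genomes")
  names(all_prot) <- ids
  genome_of <- rep(gids, vapply(proteomes, function(p) length(p$proteins), 0L))
  names(genome_of) <- ids

  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    qg <- unname(genome_of[[i]])
    db <- all_prot[genome_of != qg]
    hits <- search_db(all_prot[[i]], db, scheme, e_cutoff, query_id = ids[i])
    if (nrow(hits)) {
      hits$qgenome <- qg
      hits$sgenome <- unname(genome_of[hits$sid])
      out[[i]] <- hits
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- empty_hit_table()
    res$qgenome <- character()
    res$sgenome <- character()
  }
  rownames(res) <- NULL
  res
}

#' Reciprocal (bidirectional) best-hit edges
#'
#' For every ordered (query genome, subject genome) pair, the best hit of a
#' query protein is the one with minimal E-value, ties broken by maximal
#' bitscore and then lexicographic subject id. An undirected edge is emitted
#' when two proteins in different genomes are each other's best hit and both
#' directions pass `e_cutoff`.
#'
#' @param hits Output of [all_vs_all()].
#' @param e_cutoff E-value cutoff (default `1e-5`).
#' @return A data.frame with one row per edge: `protein_a`, `protein_b`,
#'   `genome_a`, `genome_b`, `evalue_ab`, `evalue_ba`, `identity_pct`,
#'   `coverage_a_pct`, `coverage_b_pct` (identity/coverage from the stored
#'   a-to-b alignment, where a < b lexicographically).
#' @export
bbbh_edges <- function(hits, e_cutoff = 1e-5) {
  hits <- hits[hits$evalue <= e_cutoff, , drop = FALSE]
  if (!nrow(hits)) return(empty_edge_table())
  # best hit per (query protein, subject genome)
  key <- paste(hits$qid, hits$sgenome, sep = "\r")
  ord <- order(key, hits$evalue, -hits$bitscore, hits$sid)
  hits <- hits[ord, , drop = FALSE]
  best <- hits[!duplicated(paste(hits$qid, hits$sgenome, sep = "\r")), ,
               drop = FALSE]
  # pair key with lexicographically smaller protein first
  a_first <- best$qid < best$sid
  pk <- ifelse(a_first, paste(best$qid, best$sid, sep = "\r"),
               paste(best$sid, best$qid, sep = "\r"))
  tab <- table(pk)
  recip <- names(tab)[tab == 2L]
  if (!length(recip)) return(empty_edge_table())
  fwd <- best[a_first & pk %in% recip, , drop = FALSE]   # a -> b direction
  rev <- best[!a_first & pk %in% recip, , drop = FALSE]  # b -> a direction
  fwd <- fwd[order(paste(fwd$qid, fwd$sid, sep = "\r")), , drop = FALSE]
  rev <- rev[order(paste(rev$sid, rev$qid, sep = "\r")), , drop = FALSE]
  stopifnot(identical(fwd$qid, rev$sid), identical(fwd$sid, rev$qid))
  data.frame(protein_a = fwd$qid, protein_b = fwd$sid,
             genome_a = fwd$qgenome, genome_b = fwd$sgenome,
             evalue_ab = fwd$evalue, evalue_ba = rev$evalue,
             identity_pct = fwd$pident,
             coverage_a_pct = fwd$qcov, coverage_b_pct = fwd$scov,
             stringsAsFactors = FALSE)
}

empty_edge_table <- function() {
  data.frame(protein_a = character(), protein_b = character(),
             genome_a = character(), genome_b = character(),
             evalue_ab = numeric(), evalue_ba = numeric(),
             identity_pct = numeric(), coverage_a_pct = numeric(),
             coverage_b_pct = numeric(), stringsAsFactors = FALSE)
}

#' Build protein families from reciprocal best-hit edges
#'
#' Edges are retained when the stored alignment has identity at least
#' `min_identity` percent and both coverages at least `min_coverage`
#' percent; families are the connected components of the retained edge graph
#' (single linkage). Proteins with no retained edge become singleton
#' families, so every protein belongs to exactly one family.
#'
#' @param edges Output of [bbbh_edges()].
#' @param proteomes The list of [proteome()] objects (supplies the universe
#'   of proteins).
#' @param min_identity,min_coverage Percent thresholds (defaults 50/50).
#' @return A data.frame (the family table) with columns `family_id`,
#'   `genome_id`, `protein_id`.
#' @export
build_families <- function(edges, proteomes, min_identity = 50,
                           min_coverage = 50) {
  keep <- edges$identity_pct >= min_identity &
    edges$coverage_a_pct >= min_coverage &
    edges$coverage_b_pct >= min_coverage
  edges <- edges[keep, , drop = FALSE]
  ids <- unname(unlist(lapply(proteomes, function(p) names(p$proteins))))
  genome_of <- rep(vapply(proteomes, function(p) p$genome_id, ""),
                   vapply(proteomes, function(p) length(p$proteins), 0L))
  names(genome_of) <- ids
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(match(edges$protein_a, ids),
                                    match(edges$protein_b, ids)))
  }
  comp <- igraph::components(g)$membership
  # stable family ids: number components by their first protein in input order
  first_seen <- !duplicated(comp)
  renum <- match(comp, comp[first_seen])
  fam_ids <- sprintf("F%04d", renum)
  data.frame(family_id = fam_ids, genome_id = unname(genome_of[ids]),
             protein_id = ids, stringsAsFactors = FALSE)
}

#' Partition families into core, accessory, and singleton sets
#'
#' A family is core when it has at least one member in every genome; strains
#' of the same species count as distinct genomes. Non-core families with
#' more than one member are accessory; one-member families are singletons
#' (tracked separately within the accessory set).
#'
#' @param family_table Output of [build_families()].
#' @param genome_ids Character vector of all genome ids in the run.
#' @return An object of class `pan_genome`: list with `genome_ids`,
#'   `families` (the family table), and `partitions` (`core`, `accessory`,
#'   `singleton` family-id vectors).
#' @export
partition_core <- function(family_table, genome_ids) {
  if (!length(genome_ids)) stop("empty genome list")
  sizes <- tapply(family_table$protein_id, family_table$family_id, length)
  span <- tapply(family_table$genome_id, family_table$family_id,
                 function(g) length(unique(g)))
  fams <- names(span)
  core <- fams[span == length(genome_ids)]
  singleton <- fams[sizes == 1L & !fams %in% core]
  accessory <- setdiff(fams, c(core, singleton))
  # invariant: every protein in exactly one family
  stopifnot(!anyDuplicated(family_table$protein_id))
  structure(list(genome_ids = genome_ids, families = family_table,
                 partitions = list(core = core, accessory = accessory,
                                   singleton = singleton)),
            class = "pan_genome")
}

#' @export
print.pan_genome <- function(x, ...) {
  p <- x$partitions
  cat(sprintf("<pan_genome> %d genomes, %d families (%d core, %d accessory, %d singleton)\n",
              length(x$genome_ids), length(unique(x$families$family_id)),
              length(p$core), length(p$accessory), length(p$singleton)))
  invisible(x)
}

#' Screen core families for taxonomic restriction (orphan status)
#'
#' A core family is an orphan-core candidate when *no* member protein has
#' any hit in the reference database at the E-value cutoff. The reference
#' database stands in for a comprehensive protein collection with all
#' target-genus entries removed (the caller's responsibility; ids with the
#' prefix `exclude_prefix`, if given, are dropped defensively).
#'
#' @param pan A [partition_core()] result.
#' @param proteomes The list of [proteome()] objects.
#' @param refdb Named `AAStringSet` of reference proteins.
#' @param scheme A protein [scoring_scheme()].
#' @param e_cutoff E-value cutoff (default `1e-5`).
#' @param exclude_prefix Optional id prefix identifying target-genus entries
#'   that must not be in the reference database.
#' @return Character vector of orphan-core family ids.
#' @export
orphan_screen <- function(pan, proteomes, refdb,
                          scheme = scoring_scheme("protein"),
                          e_cutoff = 1e-5, exclude_prefix = NULL) {
  if (!is.null(exclude_prefix)) {
    refdb <- refdb[!startsWith(names(refdb), exclude_prefix)]
  }
  if (length(refdb) == 0L) {
    warning("empty reference database: all core families reported as orphan")
    return(pan$partitions$core)
  }
  prot <- pooled_proteins(proteomes)
  n_db <- sum(Biostrings::width(refdb))
  orphans <- character()
  for (fam in pan$partitions$core) {
    members <- pan$families$protein_id[pan$families$family_id == fam]
    hit_found <- FALSE
    for (id in members) {
      sc <- local_scores(prot[[id]], refdb, scheme)
      ev <- evalue_of(sc, length(prot[[id]]), n_db, scheme)$evalue
      if (any(ev <= e_cutoff & sc > 0)) {
        hit_found <- TRUE
        break
      }
    }
    if (!hit_found) orphans <- c(orphans, fam)
  }
  orphans
}

pooled_proteins <- function(proteomes) {
  all_prot <- do.call(c, unname(lapply(proteomes, function(p) p$proteins)))
  names(all_prot) <- unname(unlist(lapply(proteomes, function(p) names(p$proteins))))
  all_prot
}

#' Profile-based confirmation of an orphan family
#'
#' Builds a position-specific scoring matrix from the family's multiple
#' alignment and scans the reference database with it, mimicking the
#' profile-search step (PSI-BLAST/HMMER-like) used to confirm that a family
#' has no remote homologs outside the genus. PSSM score significance uses
#' the Karlin-Altschul form with parameters re-estimated from maximal PSSM
#' scores of shuffled decoy sequences (Gumbel fit; `n_shuffles` shuffles,
#' deterministic given the RNG state).
#'
#' @param family_members Named `AAStringSet` of the family's proteins
#'   (at least 2; with a single member, confirmation is skipped with a
#'   warning and `NA` returned).
#' @param refdb Named `AAStringSet` reference database.
#' @param e_cutoff Confirmation E-value cutoff (default `1e-4`).
#' @param n_shuffles Number of shuffled decoys for the null fit
#'   (default 1000).
#' @param pseudocount PSSM pseudocount weight (default 0.5).
#' @return `TRUE` when no reference sequence reaches E <= `e_cutoff`
#'   (confirmed orphan), `FALSE` otherwise, `NA` when skipped.
#' @export
profile_confirm <- function(family_members, refdb, e_cutoff = 1e-4,
                            n_shuffles = 1000L, pseudocount = 0.5) {
  if (length(family_members) < 2L) {
    warning("single-member family: profile confirmation skipped")
    return(NA)
  }
  msa <- center_star_align(family_members)
  pssm <- build_pssm(msa, pseudocount = pseudocount)
  obs <- vapply(seq_along(refdb), function(i)
    pssm_best_score(pssm, as.character(refdb[[i]])), 0)
  # null: maximal PSSM scores on residue-shuffled decoys drawn from refdb
  pick <- sample(length(refdb), n_shuffles, replace = TRUE)
  null <- vapply(pick, function(i) {
    s <- paste(sample(strsplit(as.character(refdb[[i]]), "")[[1]]),
               collapse = "")
    pssm_best_score(pssm, s)
  }, 0)
  # method-of-moments Gumbel fit: lambda = pi/(sd*sqrt(6)), mu = mean - gamma/lambda
  lam <- pi / (sd(null) * sqrt(6))
  mu <- mean(null) - 0.5772156649 / lam
  p_ge <- 1 - exp(-exp(-lam * (obs - mu)))
  ev <- length(refdb) * p_ge
  !any(ev <= e_cutoff)
}

# best ungapped PSSM-vs-sequence score over all full-overlap offsets (the
# shorter of {window, sequence} slides along the longer; residues outside
# the PSSM alphabet score 0)
pssm_best_score <- function(pssm, seq_chr) {
  v <- match(strsplit(seq_chr, "")[[1]], rownames(pssm$scores))
  L <- length(v)
  W <- ncol(pssm$scores)
  if (L == 0L) return(0)
  if (L >= W) {
    # M[i, j]: score of sequence residue i in PSSM column j
    M <- pssm$scores[v, , drop = FALSE]
    M[is.na(v), ] <- 0
    r <- numeric(L - W + 1L)
    for (j in seq_len(W)) r <- r + M[j:(j + L - W), j]
  } else {
    r <- numeric(W - L + 1L)
    for (i in seq_len(L)) {
      if (is.na(v[i])) next
      r <- r + pssm$scores[v[i], i:(i + W - L)]
    }
  }
  max(r)
}
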