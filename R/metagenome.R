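#' Translated search of nucleotide sequences against family protein probes
#'
#' Each contig (or read) is translated in all six frames; peptides are split
#' at stop codons into ORF-like segments which are locally aligned against
#' every probe protein (exact DP with a score-only pre-pass). Hits with
#' E-value at most `e_cutoff` are reported with amino-acid identity, probe
#' protein coverage, and a truncation flag set when the aligned segment
#' reaches within `edge_nt` nucleotides of a contig end while the probe
#' protein is not fully covered.
#'
#' E-values use the segment length as `m` and the total residue count of
#' the probe set as `n`.
#'
#' @param contigs Named `DNAStringSet` of contigs or reads.
#' @param probe A [genus_probe()] (or any list with `proteins` and `info`
#'   in that format).
#' @param scheme Protein [scoring_scheme()].
#' @param e_cutoff E-value cutoff (default `1e-5`).
#' @param min_seg_aa Minimum peptide segment length to search (default 10).
#' @param edge_nt Distance to a contig end that counts as reaching it
#'   (default 3).
#' @return A data.frame with columns `contig_id`, `frame`, `family_id`,
#'   `species_label`, `protein_id`, `identity_pct`, `coverage_pct` (of the
#'   probe protein), `bitscore`, `evalue`, `truncated`.
#' @export
translated_search <- function(contigs, probe,
                              scheme = scoring_scheme("protein"),
                              e_cutoff = 1e-5, min_seg_aa = 10L,
                              edge_nt = 3L) {
  stopifnot(length(contigs) > 0)
  if (is.null(names(contigs))) {
    names(contigs) <- sprintf("contig%06d", seq_along(contigs))
  }
  frames <- six_frame_frames(contigs)
  segs <- NULL
  if (!is.null(frames) && nrow(frames)) {
    widths <- setNames(Biostrings::width(contigs), names(contigs))
    sp <- split_at_stops(frames, min_aa = min_seg_aa)
    if (nrow(sp)) {
      sp$contig_len <- unname(widths[sp$contig_id])
      segs <- sp
    }
  }
  hits <- empty_screen_table()
  if (is.null(segs) || !nrow(segs)) return(hits)
  seg_set <- AAStringSet(segs$peptide)
  names(seg_set) <- sprintf("seg%06d", seq_len(nrow(segs)))
  n_db <- sum(Biostrings::width(probe$proteins))
  seg_len <- Biostrings::width(seg_set)
  out <- list()
  for (p in seq_along(probe$proteins)) {
    sc <- local_scores_set(seg_set, probe$proteins[[p]], scheme)
    bits <- (scheme$lambda * sc - log(scheme$kappa)) / log(2)
    ev <- seg_len * n_db * 2^(-bits)
    pass <- which(ev <= e_cutoff & sc > 0)
    if (!length(pass)) next
    # one vectorized traceback call per probe protein over its passing
    # segments; segments are the patterns, the protein the subject
    b <- batch_local_align(seg_set[pass], probe$proteins[[p]], scheme)
    info <- probe$info[p, ]
    prot_len <- Biostrings::width(probe$proteins)[p]
    seg <- segs[pass, , drop = FALSE]
    # nucleotide span of the aligned part of each segment
    nt_lo <- ifelse(seg$frame > 0,
                    seg$source_start + 3L * (b$pstart - 1L),
                    seg$source_end - 3L * b$pend + 1L)
    nt_hi <- ifelse(seg$frame > 0,
                    seg$source_start + 3L * b$pend - 1L,
                    seg$source_end - 3L * (b$pstart - 1L))
    cov <- 100 * (b$send - b$sstart + 1) / prot_len
    at_edge <- nt_lo <= edge_nt | nt_hi >= seg$contig_len - edge_nt + 1L
    out[[length(out) + 1L]] <- data.frame(
      contig_id = seg$contig_id, frame = seg$frame,
      family_id = info$family_id, species_label = info$species_label,
      protein_id = info$protein_id,
      identity_pct = 100 * b$nmatch / b$aln_width,
      coverage_pct = cov,
      bitscore = bits[pass], evalue = ev[pass],
      truncated = at_edge & cov < 99.9,
      stringsAsFactors = FALSE)
  }
  if (length(out)) hits <- do.call(rbind, out)
  rownames(hits) <- NULL
  hits
}

# Six-frame translation of a whole contig set at once (vectorized over
# contigs per frame); returns frame rows with a contig_id column, as
# consumed by split_at_stops().
six_frame_frames <- function(contigs, table = "11") {
  code <- getGeneticCode(table)
  w <- Biostrings::width(contigs)
  rc <- reverseComplement(contigs)
  out <- list()
  for (off in 0:2) {
    n_cod <- (w - off) %/% 3L
    keep <- which(n_cod >= 1L)
    if (!length(keep)) next
    fwd <- subseq(contigs[keep], off + 1L, off + 3L * n_cod[keep])
    pep_f <- as.character(translate(fwd, genetic.code = code,
                                    if.fuzzy.codon = "solve",
                                    no.init.codon = TRUE))
    out[[length(out) + 1L]] <- data.frame(
      contig_id = names(contigs)[keep], frame = off + 1L,
      peptide = unname(pep_f), source_start = off + 1L,
      source_end = off + 3L * n_cod[keep], stringsAsFactors = FALSE)
    rev <- subseq(rc[keep], off + 1L, off + 3L * n_cod[keep])
    pep_r <- as.character(translate(rev, genetic.code = code,
                                    if.fuzzy.codon = "solve",
                                    no.init.codon = TRUE))
    out[[length(out) + 1L]] <- data.frame(
      contig_id = names(contigs)[keep], frame = -(off + 1L),
      peptide = unname(pep_r),
      source_start = w[keep] - off - 3L * n_cod[keep] + 1L,
      source_end = w[keep] - off, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# vectorized local scores of a set of queries against one subject
local_scores_set <- function(queries, subject, scheme) {
  g <- bs_gap(scheme)
  s <- Biostrings::pairwiseAlignment(
    pattern = queries, subject = subject, type = "local",
    substitutionMatrix = scheme$matrix,
    gapOpening = g$opening, gapExtension = g$extension, scoreOnly = TRUE)
  pmax(s, 0)
}

empty_screen_table <- function() {
  data.frame(contig_id = character(), frame = integer(),
             family_id = character(), species_label = character(),
             protein_id = character(), identity_pct = numeric(),
             coverage_pct = numeric(), bitscore = numeric(),
             evalue = numeric(), truncated = logical(),
             stringsAsFactors = FALSE)
}

#' Species-by-family presence report from translated-search hits
#'
#' Keeps the best hit (by bitscore) for every (species, family) cell and
#' calls the genus present when any hit exists at all.
#'
#' @param hits A [translated_search()] hit table.
#' @param all_species Character vector of species labels to report.
#' @param all_families Character vector of family ids to report.
#' @return An object of class `screen_report`: list with `cells` (one row
#'   per species x family: best identity/coverage/evalue or NA when
#'   absent), `genus_detected`, and `detected_species` (species with at
#'   least one hit).
#' @export
presence_report <- function(hits, all_species, all_families) {
  grid <- expand.grid(species_label = all_species, family_id = all_families,
                      stringsAsFactors = FALSE)
  cells <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- hits$species_label == grid$species_label[i] &
      hits$family_id == grid$family_id[i]
    if (!any(sel)) {
      return(data.frame(grid[i, ], present = FALSE,
                        identity_pct = NA_real_, coverage_pct = NA_real_,
                        evalue = NA_real_, truncated = NA,
                        stringsAsFactors = FALSE))
    }
    h <- hits[sel, , drop = FALSE]
    best <- h[which.max(h$bitscore), ]
    data.frame(grid[i, ], present = TRUE,
               identity_pct = best$identity_pct,
               coverage_pct = best$coverage_pct, evalue = best$evalue,
               truncated = best$truncated, stringsAsFactors = FALSE)
  })
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  structure(list(cells = cells,
                 genus_detected = nrow(hits) > 0,
                 detected_species = sort(unique(hits$species_label))),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> genus %s; species: %s\n",
              if (x$genus_detected) "DETECTED" else "not detected",
              if (length(x$detected_species))
                paste(x$detected_species, collapse = ", ") else "-"))
  invisible(x)
}

#' Write a screen report as TSV
#' @param report A [presence_report()] result.
#' @param path Output TSV path.
#' @export
write_screen_report <- function(report, path) {
  write.table(report$cells, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
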