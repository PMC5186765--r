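#' Tetranucleotide z-score signature of a genome
#'
#' For every 4-mer `w = w1 w2 w3 w4`, the expected count under a maximal-order
#' Markov model is `E = n(w1 w2 w3) * n(w2 w3 w4) / n(w2 w3)` with variance
#' `E * (n(w2 w3) - n(w1 w2 w3)) * (n(w2 w3) - n(w2 w3 w4)) / n(w2 w3)^2`;
#' the signature entry is `z = (obs - E) / sqrt(var)`. Counts are taken on
#' every contig and its reverse complement and summed (windows never cross
#' contig boundaries), so a genome and its reverse complement have identical
#' signatures by construction.
#'
#' @param genome A `DNAStringSet` (one entry per contig) or character vector.
#' @param genome_id Identifier stored with the signature.
#' @return An object of class `tetra_signature`: list with `genome_id` and
#'   `z` (named 256-vector; words with zero expected variance get z = 0 and
#'   are listed in `degenerate`).
#' @export
tetra_signature <- function(genome, genome_id = "genome") {
  genome <- DNAStringSet(genome)
  if (length(genome) == 0L || sum(Biostrings::width(genome)) == 0L) {
    stop("empty genome")
  }
  if (sum(Biostrings::width(genome)) < 1e4) {
    warning("genome shorter than 10 kb: tetranucleotide z-scores are noisy")
  }
  both <- c(genome, reverseComplement(genome))
  n2 <- colSums(oligonucleotideFrequency(both, 2))
  n3 <- colSums(oligonucleotideFrequency(both, 3))
  n4 <- colSums(oligonucleotideFrequency(both, 4))
  words <- names(n4)
  w123 <- substr(words, 1, 3)
  w234 <- substr(words, 2, 4)
  w23 <- substr(words, 2, 3)
  E <- n3[w123] * n3[w234] / n2[w23]
  varz <- E * (n2[w23] - n3[w123]) * (n2[w23] - n3[w234]) / n2[w23]^2
  z <- (n4 - E) / sqrt(varz)
  # a palindromic 4-mer is counted twice per occurrence when both strands
  # are pooled (its forward and reverse-complement observations coincide),
  # which inflates its z by sqrt(2); rescale to unit null variance
  pal <- words == as.character(reverseComplement(DNAStringSet(words)))
  z[pal] <- z[pal] / sqrt(2)
  bad <- !is.finite(z)
  z[bad] <- 0
  structure(list(genome_id = genome_id, z = setNames(as.numeric(z), words),
                 degenerate = words[bad]),
            class = "tetra_signature")
}

#' Pearson correlation between two tetranucleotide signatures
#'
#' @param a,b [tetra_signature()] objects.
#' @return Correlation in \[-1, 1\]; 1.0 for a signature against itself.
#' @export
tetra_correlation <- function(a, b) {
  stopifnot(inherits(a, "tetra_signature"), inherits(b, "tetra_signature"))
  cor(a$z, b$z)
}

#' Average nucleotide identity by the fragment (BLAST) method
#'
#' The query genome is cut into consecutive `fragment`-length pieces which
#' are aligned to the subject genome with `blastn`; fragments whose best hit
#' has at least `min_id` percent identity over at least `min_frag_cov`
#' percent of the fragment length are kept, and the directional ANI is the
#' mean identity of the kept fragments. The reported ANI averages the two
#' directions.
#'
#' Requires the `blastn` and `makeblastdb` executables on the PATH.
#'
#' @param query_genome,subject_genome `DNAStringSet`s (or character vectors).
#' @param fragment Fragment length in nt (default 1020).
#' @param min_id Minimum percent identity of a kept fragment (default 30).
#' @param min_frag_cov Minimum alignment coverage of the fragment in percent
#'   (default 70).
#' @return A list with `ani` (percent; `NA` with `defined = FALSE` when no
#'   fragment passes in either direction), `defined`, and per-direction
#'   `forward`/`reverse` lists (`ani`, `n_fragments`, `n_kept`).
#' @export
ani <- function(query_genome, subject_genome, fragment = 1020L,
                min_id = 30, min_frag_cov = 70) {
  f <- ani_directional(query_genome, subject_genome, fragment, min_id,
                       min_frag_cov)
  r <- ani_directional(subject_genome, query_genome, fragment, min_id,
                       min_frag_cov)
  vals <- c(f$ani, r$ani)
  ok <- !is.na(vals)
  list(ani = if (any(ok)) mean(vals[ok]) else NA_real_,
       defined = any(ok), forward = f, reverse = r)
}

ani_directional <- function(query, subject, fragment, min_id, min_frag_cov) {
  query <- DNAStringSet(query)
  subject <- DNAStringSet(subject)
  stopifnot(sum(Biostrings::width(query)) > 0,
            sum(Biostrings::width(subject)) > 0)
  frags <- chop_fragments(query, fragment)
  td <- tempfile("ani")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  qf <- file.path(td, "frags.fasta")
  sf <- file.path(td, "subject.fasta")
  writeXStringSet(frags, qf)
  writeXStringSet(subject, sf)
  run_quiet("makeblastdb", c("-in", sf, "-dbtype", "nucl"))
  out <- file.path(td, "hits.tsv")
  run_quiet("blastn", c("-task", "blastn", "-query", qf, "-db", sf,
                        "-reward", "1", "-penalty", "-1", "-dust", "no",
                        "-evalue", "1e-15", "-xdrop_gap", "150",
                        "-outfmt", shQuote("6 qseqid pident length bitscore"),
                        "-out", out))
  hits <- tryCatch(read.delim(out, header = FALSE,
                              col.names = c("qseqid", "pident", "length",
                                            "bitscore")),
                   error = function(e) NULL)
  n_frags <- length(frags)
  if (is.null(hits) || !nrow(hits)) {
    return(list(ani = NA_real_, n_fragments = n_frags, n_kept = 0L))
  }
  # best hit per fragment by bitscore
  hits <- hits[order(hits$qseqid, -hits$bitscore), , drop = FALSE]
  best <- hits[!duplicated(hits$qseqid), , drop = FALSE]
  frag_len <- Biostrings::width(frags)[match(best$qseqid, names(frags))]
  keep <- best$pident >= min_id & best$length >= min_frag_cov / 100 * frag_len
  if (!any(keep)) {
    return(list(ani = NA_real_, n_fragments = n_frags, n_kept = 0L))
  }
  list(ani = mean(best$pident[keep]), n_fragments = n_frags,
       n_kept = sum(keep))
}

chop_fragments <- function(genome, fragment) {
  pieces <- list()
  k <- 0L
  for (i in seq_along(genome)) {
    L <- Biostrings::width(genome)[i]
    starts <- seq(1L, L, by = fragment)
    for (s in starts) {
      k <- k + 1L
      pieces[[k]] <- subseq(genome[[i]], s, min(s + fragment - 1L, L))
    }
  }
  out <- DNAStringSet(pieces)
  names(out) <- sprintf("frag%06d", seq_len(k))
  out
}

run_quiet <- function(cmd, args) {
  if (Sys.which(cmd) == "") stop("executable not found on PATH: ", cmd)
  status <- system2(cmd, args, stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop(cmd, " failed with exit status ", status)
  invisible(status)
}
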