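#' @import methods
#' @importFrom Biostrings AAStringSet DNAStringSet DNAString AAString
#'   readAAStringSet readDNAStringSet writeXStringSet reverseComplement
#'   translate getGeneticCode oligonucleotideFrequency subseq
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols
#' @importFrom stats cor sd rbinom runif setNames
#' @importFrom utils write.table read.delim head combn
NULL

PROTEIN_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                      "R","S","T","V","W","Y","X","*")
DNA_ALPHABET <- c("A","C","G","T","N")

#' Read a multi-record FASTA file into a validated sequence set
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] /
#' [Biostrings::readDNAStringSet()] that enforces the contracts the rest of
#' the pipeline relies on: unique, whitespace-free identifiers; non-empty,
#' uppercased residues; and a restricted alphabet (20 amino acids plus `X`
#' and `*` for proteins; `ACGTN` for DNA).
#'
#' @param path Path to a FASTA file. Lines may be wrapped arbitrarily.
#' @param alphabet `"protein"` or `"dna"`.
#' @return An [Biostrings::AAStringSet] or [Biostrings::DNAStringSet] named by
#'   the first whitespace-delimited token of each header. The full headers are
#'   kept in the `description` metadata column.
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- if (alphabet == "protein") {
    readAAStringSet(path)
  } else {
    readDNAStringSet(path)
  }
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(set)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (any(ids == "")) stop("FASTA header with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  chr <- setNames(toupper(as.character(set)), ids)
  set <- if (alphabet == "protein") AAStringSet(chr) else DNAStringSet(chr)
  S4Vectors::mcols(set)$description <- sub("^\\S+\\s*", "", headers)
  validate_alphabet(set, alphabet, path)
  set
}

validate_alphabet <- function(set, alphabet, label = "input") {
  allowed <- if (alphabet == "protein") PROTEIN_ALPHABET else DNA_ALPHABET
  freq <- Biostrings::alphabetFrequency(set)
  bad_cols <- setdiff(colnames(freq)[colSums(freq) > 0], allowed)
  if (length(bad_cols)) {
    # locate the first offender for the error message
    for (i in seq_along(set)) {
      chars <- strsplit(as.character(set[[i]]), "")[[1]]
      pos <- which(!chars %in% allowed)
      if (length(pos)) {
        stop(sprintf("illegal %s residue '%s' at position %d of '%s' (%s)",
                     alphabet, chars[pos[1]], pos[1], names(set)[i], label))
      }
    }
  }
  w <- Biostrings::width(set)
  if (any(w == 0L)) stop("empty sequence(s): ",
                         paste(names(set)[w == 0L], collapse = ", "))
  invisible(TRUE)
}

#' Write sequences to FASTA with fixed line width
#'
#' @param records A named [Biostrings::XStringSet].
#' @param path Output path.
#' @param width Maximum sequence line width (default 60).
#' @return `path`, invisibly. `read_fasta(write_fasta(x))` recovers `x`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  writeXStringSet(records, filepath = path, width = width)
  invisible(path)
}

#' Translate a coding sequence
#'
#' Translates a CDS under a chosen genetic code (bacterial table 11 by
#' default). A terminal stop codon is stripped from the result; an internal
#' stop codon is an error. `N`-containing codons that are ambiguous translate
#' to `X`.
#'
#' @param cds A DNA string (character or [Biostrings::DNAString]) whose length
#'   is divisible by 3.
#' @param table Genetic code identifier as understood by
#'   [Biostrings::getGeneticCode()] (default `"11"`).
#' @return The protein sequence as a character scalar.
#' @export
translate_cds <- function(cds, table = "11") {
  cds <- DNAString(as.character(cds))
  if (length(cds) %% 3L != 0L) {
    stop("CDS length ", length(cds), " is not divisible by 3")
  }
  pep <- as.character(translate(cds, genetic.code = getGeneticCode(table),
                                if.fuzzy.codon = "solve"))
  n <- nchar(pep)
  if (substr(pep, n, n) == "*") pep <- substr(pep, 1L, n - 1L)
  stop_at <- regexpr("*", pep, fixed = TRUE)
  if (stop_at > 0) {
    stop("internal stop codon at protein position ", stop_at)
  }
  pep
}

#' Six-frame translation of a nucleotide sequence
#'
#' Translates all six reading frames of a contig, mapping every peptide back
#' to 1-based inclusive coordinates on the forward strand. Stop codons are
#' retained as `*`; downstream translated-search code splits peptides at
#' stops before aligning.
#'
#' @param contig A named single-sequence [Biostrings::DNAStringSet], a
#'   [Biostrings::DNAString], or a character scalar.
#' @param table Genetic code identifier (default `"11"`).
#' @return A data.frame with columns `frame` (+1,+2,+3,-1,-2,-3), `peptide`,
#'   `source_start`, `source_end` (forward-strand, 1-based inclusive). Empty
#'   (zero-row) for contigs shorter than 3 nt, with a warning.
#' @export
six_frame_translate <- function(contig, table = "11") {
  if (is(contig, "DNAStringSet")) {
    stopifnot(length(contig) == 1L)
    contig <- contig[[1]]
  }
  contig <- DNAString(as.character(contig))
  L <- length(contig)
  empty <- data.frame(frame = integer(), peptide = character(),
                      source_start = integer(), source_end = integer(),
                      stringsAsFactors = FALSE)
  if (L < 3L) {
    warning("contig shorter than 3 nt; no translation")
    return(empty)
  }
  code <- getGeneticCode(table)
  rc <- reverseComplement(contig)
  out <- vector("list", 6L)
  k <- 0L
  for (off in 0:2) {
    n_codons <- (L - off) %/% 3L
    if (n_codons < 1L) next
    # forward frame +(off+1): nt off+1 .. off+3*n_codons
    fwd <- subseq(contig, off + 1L, off + 3L * n_codons)
    pep_f <- as.character(translate(fwd, genetic.code = code,
                                    if.fuzzy.codon = "solve",
                                    no.init.codon = TRUE))
    k <- k + 1L
    out[[k]] <- data.frame(frame = off + 1L, peptide = pep_f,
                           source_start = off + 1L,
                           source_end = off + 3L * n_codons,
                           stringsAsFactors = FALSE)
    # reverse frame -(off+1): first off nt of the reverse complement skipped,
    # which corresponds to the LAST off nt of the forward strand
    rev <- subseq(rc, off + 1L, off + 3L * n_codons)
    pep_r <- as.character(translate(rev, genetic.code = code,
                                    if.fuzzy.codon = "solve",
                                    no.init.codon = TRUE))
    k <- k + 1L
    out[[k]] <- data.frame(frame = -(off + 1L), peptide = pep_r,
                           source_start = L - off - 3L * n_codons + 1L,
                           source_end = L - off,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[seq_len(k)])
  res[order(match(res$frame, c(1L, 2L, 3L, -1L, -2L, -3L))), , drop = FALSE]
}

#' Split six-frame peptides at stop codons into ORF-like segments
#'
#' @param frames Output of [six_frame_translate()].
#' @param min_aa Minimum segment length to keep (default 10 residues).
#' @return A data.frame with columns `frame`, `peptide`, `source_start`,
#'   `source_end` where each row is a stop-free peptide segment and the
#'   coordinates are the forward-strand nucleotide span of that segment.
#' @export
split_at_stops <- function(frames, min_aa = 10L) {
  rows <- vector("list", nrow(frames))
  for (i in seq_len(nrow(frames))) {
    pep <- frames$peptide[i]
    frame <- frames$frame[i]
    segs <- segment_runs(pep)
    if (nrow(segs) == 0L) next
    segs <- segs[segs$len >= min_aa, , drop = FALSE]
    if (nrow(segs) == 0L) next
    # aa position j (1-based within the frame peptide) occupies nt
    # [s0 + 3(j-1), s0 + 3j - 1] on the frame's own strand
    if (frame > 0) {
      nt_start <- frames$source_start[i] + 3L * (segs$start - 1L)
      nt_end <- frames$source_start[i] + 3L * segs$end - 1L
    } else {
      nt_end <- frames$source_end[i] - 3L * (segs$start - 1L)
      nt_start <- frames$source_end[i] - 3L * segs$end + 1L
    }
    df <- data.frame(frame = frame,
                     peptide = substring(pep, segs$start, segs$end),
                     source_start = nt_start, source_end = nt_end,
                     stringsAsFactors = FALSE)
    if ("contig_id" %in% names(frames)) df$contig_id <- frames$contig_id[i]
    rows[[i]] <- df
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(frame = integer(), peptide = character(),
                      source_start = integer(), source_end = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# maximal stop-free runs within a peptide; returns start/end/len (aa coords)
segment_runs <- function(pep) {
  chars <- strsplit(pep, "")[[1]]
  keep <- chars != "*"
  if (!any(keep)) return(data.frame(start = integer(), end = integer(),
                                    len = integer()))
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values
  data.frame(start = starts[ok], end = ends[ok],
             len = r$lengths[ok])
}

#' Reverse complement of a DNA character string
#' @param x character scalar over ACGTN
#' @return character scalar
#' @keywords internal
revcomp_chr <- function(x) {
  as.character(reverseComplement(DNAString(x)))
}
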