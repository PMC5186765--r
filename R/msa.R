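AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Center-star multiple alignment
#'
#' Progressive multiple alignment around the center sequence, the member
#' maximizing the summed pairwise global alignment score against all the
#' others. Each remaining sequence is aligned to the center and merged under
#' the "once a gap, always a gap" rule. The families this package aligns are
#' highly conserved, where center-star progressive error is minimal.
#'
#' @param seqs A named `AAStringSet` or named character vector (>= 2
#'   sequences).
#' @param scheme A protein [scoring_scheme()].
#' @return An object of class `msa_result`: list with `rows` (named
#'   character vector of equal-length gapped strings, input order preserved)
#'   and `ncol`.
#' @export
center_star_align <- function(seqs, scheme = scoring_scheme("protein")) {
  seqs_chr <- setNames(as.character(seqs), names(seqs))
  if (is.null(names(seqs_chr)) || anyDuplicated(names(seqs_chr))) {
    stop("sequences must be uniquely named")
  }
  k <- length(seqs_chr)
  if (k < 2L) stop("need at least two sequences")
  scores <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      s <- global_align(seqs_chr[i], seqs_chr[j], scheme)$raw_score
      scores[i, j] <- s
      scores[j, i] <- s
    }
  }
  center <- which.max(rowSums(scores))
  star_align_around(seqs_chr, center, scheme)
}

# progressive star alignment around a fixed center index
star_align_around <- function(seqs_chr, center, scheme) {
  k <- length(seqs_chr)
  master <- strsplit(seqs_chr[center], "")[[1]]
  rows <- list()
  rows[[names(seqs_chr)[center]]] <- master
  for (i in seq_len(k)[-center]) {
    al <- global_align(seqs_chr[center], seqs_chr[i], scheme)
    cg <- strsplit(al$aligned_query, "")[[1]]
    sg <- strsplit(al$aligned_subject, "")[[1]]
    merged <- merge_into_star(master, rows, cg, sg)
    master <- merged$master
    rows <- merged$rows
    rows[[names(seqs_chr)[i]]] <- merged$new_row
  }
  out <- vapply(rows, paste, "", collapse = "")
  out <- out[names(seqs_chr)]  # restore input order
  res <- structure(list(rows = out, ncol = nchar(out[[1]])),
                   class = "msa_result")
  stopifnot(all(nchar(out) == res$ncol))
  # degap identity invariant
  stopifnot(identical(unname(gsub("-", "", out)), unname(seqs_chr)))
  res
}

# Merge one center-vs-sequence pairwise alignment into the growing star MSA.
# master: current gapped center row (char vector); rows: list of char
# vectors (same length as master); cg/sg: gapped center and new sequence
# from the pairwise alignment (degapped cg == degapped master).
merge_into_star <- function(master, rows, cg, sg) {
  n_exist <- length(rows)
  out_master <- character(0)
  out_rows <- rep(list(character(0)), n_exist)
  names(out_rows) <- names(rows)
  new_row <- character(0)
  i <- 1L  # position in master
  j <- 1L  # position in cg/sg
  Lm <- length(master)
  Lc <- length(cg)
  while (i <= Lm || j <= Lc) {
    if (i <= Lm && master[i] == "-") {
      # column where some earlier sequence inserted relative to the center
      out_master <- c(out_master, "-")
      for (r in seq_len(n_exist)) out_rows[[r]] <- c(out_rows[[r]], rows[[r]][i])
      new_row <- c(new_row, "-")
      i <- i + 1L
    } else if (j <= Lc && cg[j] == "-") {
      # the new sequence inserts relative to the center
      out_master <- c(out_master, "-")
      for (r in seq_len(n_exist)) out_rows[[r]] <- c(out_rows[[r]], "-")
      new_row <- c(new_row, sg[j])
      j <- j + 1L
    } else {
      # both carry the same center residue
      out_master <- c(out_master, master[i])
      for (r in seq_len(n_exist)) out_rows[[r]] <- c(out_rows[[r]], rows[[r]][i])
      new_row <- c(new_row, sg[j])
      i <- i + 1L
      j <- j + 1L
    }
  }
  list(master = out_master, rows = out_rows, new_row = new_row)
}

#' @export
print.msa_result <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", length(x$rows), x$ncol))
  invisible(x)
}

#' Write a multiple alignment as aligned FASTA
#' @param msa An `msa_result`.
#' @param path Output path.
#' @export
write_msa <- function(msa, path) {
  write_fasta(AAStringSet(msa$rows), path)
}

#' Sum-of-pairs score of a multiple alignment
#'
#' Column-wise sum over all row pairs of substitution scores, with affine
#' gap penalties per pairwise projection (used to compare star choices).
#' @param msa An `msa_result`.
#' @param scheme A protein [scoring_scheme()].
#' @return Numeric score.
#' @export
sum_of_pairs_score <- function(msa, scheme = scoring_scheme("protein")) {
  ids <- names(msa$rows)
  total <- 0
  for (pair in combn(ids, 2, simplify = FALSE)) {
    a <- strsplit(msa$rows[[pair[1]]], "")[[1]]
    b <- strsplit(msa$rows[[pair[2]]], "")[[1]]
    keep <- !(a == "-" & b == "-")
    a <- a[keep]; b <- b[keep]
    total <- total + pairwise_projection_score(a, b, scheme)
  }
  total
}

pairwise_projection_score <- function(a, b, scheme) {
  s <- 0
  in_gap <- FALSE
  for (k in seq_along(a)) {
    if (a[k] == "-" || b[k] == "-") {
      s <- s - if (in_gap) scheme$gap_extend else scheme$gap_open
      in_gap <- TRUE
    } else {
      s <- s + scheme$matrix[a[k], b[k]]
      in_gap <- FALSE
    }
  }
  s
}

#' Consensus sequence and per-column conservation of an MSA
#'
#' The consensus residue of a column is its modal residue (ties broken
#' alphabetically); a gap is emitted only when more than half the rows are
#' gapped. Conservation is the modal residue's frequency among non-gap rows.
#'
#' @param msa An `msa_result`.
#' @return A list with `consensus` (string) and `conservation` (numeric
#'   vector in \[0, 1\], one entry per column).
#' @export
consensus_profile <- function(msa) {
  m <- do.call(rbind, strsplit(unname(msa$rows), ""))
  cons <- character(ncol(m))
  conserv <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    n_gap <- sum(col == "-")
    res <- col[col != "-"]
    if (length(res)) {
      tab <- table(res)
      top <- sort(names(tab)[tab == max(tab)])[1]
      conserv[j] <- max(tab) / length(res)
    } else {
      top <- "-"
      conserv[j] <- 0
    }
    cons[j] <- if (n_gap > length(col) / 2) "-" else top
  }
  list(consensus = paste(cons, collapse = ""), conservation = conserv)
}

#' Build a position-specific scoring matrix from an MSA
#'
#' Columns with more than 50% gaps are dropped. The log-odds score of
#' residue `aa` in a column with `count` occurrences among `rows_nongap`
#' non-gap rows is
#' `log2(((count + pseudocount * bg) / (rows_nongap + pseudocount)) / bg)`.
#'
#' @param msa An `msa_result`.
#' @param pseudocount Pseudocount weight (default 0.5).
#' @param background Either `"uniform"` or a named numeric vector of
#'   background frequencies over the 20 amino acids summing to 1.
#' @return A list of class `pssm`: `scores` (20 x columns matrix),
#'   `background`, `pseudocount`, `kept_columns` (original column indices).
#' @export
build_pssm <- function(msa, pseudocount = 0.5, background = "uniform") {
  if (length(msa$rows) == 0L) stop("empty MSA")
  if (identical(background, "uniform")) {
    bg <- setNames(rep(1 / 20, 20), AA20)
  } else {
    stopifnot(setequal(names(background), AA20),
              abs(sum(background) - 1) < 1e-8)
    bg <- background[AA20]
  }
  m <- do.call(rbind, strsplit(unname(msa$rows), ""))
  gap_frac <- colMeans(m == "-")
  keep <- which(gap_frac <= 0.5)
  scores <- matrix(NA_real_, 20, length(keep),
                   dimnames = list(AA20, NULL))
  for (jj in seq_along(keep)) {
    col <- m[, keep[jj]]
    res <- col[col %in% AA20]
    nn <- length(res)
    counts <- table(factor(res, levels = AA20))
    scores[, jj] <- log2(((as.numeric(counts) + pseudocount * bg) /
                            (nn + pseudocount)) / bg)
  }
  structure(list(scores = scores, background = bg,
                 pseudocount = pseudocount, kept_columns = keep),
            class = "pssm")
}

#' Score a single ungapped sequence against a PSSM at offset zero
#'
#' Utility used in tests and reporting: sums the PSSM scores of the
#' sequence's residues along consecutive columns (sequence and PSSM must
#' have equal length).
#' @param pssm A [build_pssm()] result.
#' @param seq Character scalar protein sequence.
#' @return Numeric score.
#' @export
pssm_score <- function(pssm, seq) {
  v <- strsplit(as.character(seq), "")[[1]]
  stopifnot(length(v) == ncol(pssm$scores))
  idx <- match(v, rownames(pssm$scores))
  sum(pssm$scores[cbind(idx[!is.na(idx)], which(!is.na(idx)))])
}

#' Write a PSSM as TSV (rows = residues, columns = positions)
#' @param pssm A [build_pssm()] result.
#' @param path Output TSV path.
#' @export
write_pssm <- function(pssm, path) {
  df <- as.data.frame(pssm$scores)
  colnames(df) <- paste0("pos", seq_len(ncol(pssm$scores)))
  write.table(cbind(residue = rownames(pssm$scores), df), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
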