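#' Scoring schemes for pairwise alignment
#'
#' Bundles a substitution matrix, affine gap penalties, and the
#' Karlin-Altschul parameters used to convert raw Smith-Waterman scores into
#' bit scores and E-values. A gap of length L costs
#' `gap_open + (L - 1) * gap_extend`, so setting `gap_open == gap_extend`
#' gives linear gap costs.
#'
#' Protein defaults are BLOSUM62 with gap open 11 / extend 1 and the
#' published gapped Karlin-Altschul parameters lambda = 0.267, K = 0.041.
#' The `X` row/column of the matrix is forced to 0 so that ambiguous
#' residues are neutral. Nucleotide defaults are match +2 / mismatch -3,
#' gap open 5 / extend 2, lambda = 0.625, K = 0.41; `N` is neutral.
#'
#' @param type `"protein"` or `"dna"`.
#' @param gap_open,gap_extend Non-negative gap penalties
#'   (`gap_extend <= gap_open`).
#' @param lambda,kappa Karlin-Altschul parameters (> 0).
#' @param matrix Optional full substitution matrix overriding the default.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(type = c("protein", "dna"),
                           gap_open = NULL, gap_extend = NULL,
                           lambda = NULL, kappa = NULL, matrix = NULL) {
  type <- match.arg(type)
  if (type == "protein") {
    if (is.null(matrix)) {
      matrix <- get_blosum62()
      matrix["X", ] <- 0
      matrix[, "X"] <- 0
    }
    if (is.null(gap_open)) gap_open <- 11L
    if (is.null(gap_extend)) gap_extend <- 1L
    if (is.null(lambda)) lambda <- 0.267
    if (is.null(kappa)) kappa <- 0.041
  } else {
    if (is.null(matrix)) {
      matrix <- base_dna_matrix()
    }
    if (is.null(gap_open)) gap_open <- 5L
    if (is.null(gap_extend)) gap_extend <- 2L
    if (is.null(lambda)) lambda <- 0.625
    if (is.null(kappa)) kappa <- 0.41
  }
  stopifnot(isSymmetric(unname(matrix)), gap_open >= 0, gap_extend >= 0,
            gap_extend <= gap_open, lambda > 0, kappa > 0)
  structure(list(type = type, matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, kappa = kappa),
            class = "scoring_scheme")
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

base_dna_matrix <- function(match = 2, mismatch = -3) {
  m <- matrix(mismatch, 5, 5,
              dimnames = list(DNA_ALPHABET, DNA_ALPHABET))
  diag(m) <- match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

# Biostrings charges gapOpening once plus gapExtension per gapped position,
# i.e. a length-L gap costs gapOpening + L*gapExtension. Our convention is
# gap_open + (L-1)*gap_extend, hence the offset.
bs_gap <- function(scheme) {
  list(opening = scheme$gap_open - scheme$gap_extend,
       extension = scheme$gap_extend)
}

as_xstring <- function(x, type) {
  if (type == "protein") AAString(as.character(x)) else DNAString(as.character(x))
}

as_xstringset <- function(x, type) {
  if (is(x, "XStringSet")) return(x)
  if (type == "protein") AAStringSet(x) else DNAStringSet(x)
}

#' Bit score and E-value from a raw alignment score
#'
#' Karlin-Altschul statistics: `bitscore = (lambda * S - ln(kappa)) / ln(2)`
#' and `E = m * n * 2^(-bitscore)` for a query of `m` residues searched
#' against `n` database residues.
#'
#' @param raw_score Integer raw alignment score.
#' @param m Query length in residues (> 0).
#' @param n Total residue count of the searched database (> 0).
#' @param scheme A [scoring_scheme()].
#' @return A list with elements `bitscore` and `evalue`.
#' @export
evalue_of <- function(raw_score, m, n, scheme) {
  if (any(m <= 0) || any(n <= 0)) stop("m and n must be positive")
  bits <- (scheme$lambda * raw_score - log(scheme$kappa)) / log(2)
  list(bitscore = bits, evalue = m * n * 2^(-bits))
}

#' Optimal pairwise alignment with affine gaps
#'
#' `local_align()` computes the optimal Smith-Waterman local alignment,
#' `global_align()` the Needleman-Wunsch global alignment (end gaps
#' penalized). Dynamic programming is exact (no heuristics) and is delegated
#' to [Biostrings::pairwiseAlignment()].
#'
#' Identity is computed over all aligned columns including gap columns;
#' coverages are relative to the full query/subject lengths. E-values use
#' `m = length(a)`, `n = length(b)`.
#'
#' @param a,b Sequences (character or `XString`), same alphabet as `scheme`.
#' @param scheme A [scoring_scheme()].
#' @param query_id,subject_id Identifiers carried into the result.
#' @return A list of class `alignment_result` with fields `query_id`,
#'   `subject_id`, `raw_score`, `bitscore`, `evalue`, `identity_pct`,
#'   `coverage_query_pct`, `coverage_subject_pct`, `query_span`,
#'   `subject_span`, `aligned_query`, `aligned_subject`, and `empty` (TRUE
#'   when no positive-scoring local alignment exists; identity is then
#'   reported as 0).
#' @export
local_align <- function(a, b, scheme = scoring_scheme("protein"),
                        query_id = "query", subject_id = "subject") {
  pair_align(a, b, scheme, type = "local", query_id, subject_id)
}

#' @rdname local_align
#' @export
global_align <- function(a, b, scheme = scoring_scheme("protein"),
                         query_id = "query", subject_id = "subject") {
  pair_align(a, b, scheme, type = "global", query_id, subject_id)
}

pair_align <- function(a, b, scheme, type, query_id, subject_id) {
  a <- as_xstring(a, scheme$type)
  b <- as_xstring(b, scheme$type)
  if (length(a) == 0L || length(b) == 0L) stop("empty sequence")
  g <- bs_gap(scheme)
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = type,
    substitutionMatrix = scheme$matrix,
    gapOpening = g$opening, gapExtension = g$extension)
  s <- Biostrings::score(aln)
  m <- length(a); n <- length(b)
  if (type == "local" && s <= 0) {
    ka <- evalue_of(0, m, n, scheme)
    return(structure(list(
      query_id = query_id, subject_id = subject_id, raw_score = 0,
      bitscore = ka$bitscore, evalue = ka$evalue, identity_pct = 0,
      coverage_query_pct = 0, coverage_subject_pct = 0,
      query_span = c(NA_integer_, NA_integer_),
      subject_span = c(NA_integer_, NA_integer_),
      aligned_query = "", aligned_subject = "", empty = TRUE),
      class = "alignment_result"))
  }
  aq <- as.character(Biostrings::alignedPattern(aln))
  as_ <- as.character(Biostrings::alignedSubject(aln))
  ncol_aln <- nchar(aq)
  nid <- Biostrings::nmatch(aln)
  qs <- c(Biostrings::start(Biostrings::pattern(aln)),
          Biostrings::end(Biostrings::pattern(aln)))
  ss <- c(Biostrings::start(Biostrings::subject(aln)),
          Biostrings::end(Biostrings::subject(aln)))
  ka <- evalue_of(s, m, n, scheme)
  structure(list(
    query_id = query_id, subject_id = subject_id, raw_score = s,
    bitscore = ka$bitscore, evalue = ka$evalue,
    identity_pct = 100 * nid / ncol_aln,
    coverage_query_pct = 100 * (qs[2] - qs[1] + 1) / m,
    coverage_subject_pct = 100 * (ss[2] - ss[1] + 1) / n,
    query_span = qs, subject_span = ss,
    aligned_query = aq, aligned_subject = as_, empty = FALSE),
    class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment> %s vs %s  score=%g bits=%.1f E=%.3g id=%.1f%% cov=%.1f/%.1f%%\n",
              x$query_id, x$subject_id, x$raw_score, x$bitscore, x$evalue,
              x$identity_pct, x$coverage_query_pct, x$coverage_subject_pct))
  invisible(x)
}

# Vectorized full local alignment of many patterns against one subject;
# returns one row per pattern with score, identity numerator/denominator
# and both spans (S4 dispatch cost is paid once per call, not per pair).
batch_local_align <- function(patterns, subject, scheme) {
  g <- bs_gap(scheme)
  aln <- Biostrings::pairwiseAlignment(
    pattern = patterns, subject = subject, type = "local",
    substitutionMatrix = scheme$matrix,
    gapOpening = g$opening, gapExtension = g$extension)
  data.frame(
    score = Biostrings::score(aln),
    nmatch = Biostrings::nmatch(aln),
    aln_width = Biostrings::nchar(aln),
    pstart = Biostrings::start(Biostrings::pattern(aln)),
    pend = Biostrings::end(Biostrings::pattern(aln)),
    sstart = Biostrings::start(Biostrings::subject(aln)),
    send = Biostrings::end(Biostrings::subject(aln)))
}

# Vectorized local scores of one query against a database set (no traceback).
local_scores <- function(query, db, scheme) {
  g <- bs_gap(scheme)
  s <- Biostrings::pairwiseAlignment(
    pattern = db, subject = as_xstring(query, scheme$type), type = "local",
    substitutionMatrix = scheme$matrix,
    gapOpening = g$opening, gapExtension = g$extension, scoreOnly = TRUE)
  pmax(s, 0)
}

#' Exhaustive search of a query against a sequence database
#'
#' (Named `search_db` to avoid masking `base::search`.)
#'
#' Scores the query against every database sequence (exact local DP, score
#' pass first, full traceback only for sequences meeting the E-value
#' cutoff). The database size `n` used for E-values is the total residue
#' count of `db` at call time.
#'
#' @param query A named character scalar or single `XString`; its id is
#'   taken from `query_id`.
#' @param db A named `XStringSet` (or named character vector).
#' @param scheme A [scoring_scheme()].
#' @param e_cutoff Maximum E-value to report (default `1e-5`).
#' @param query_id Identifier for the query.
#' @return A data.frame with columns `qid, sid, pident, qcov, scov, bitscore,
#'   evalue, qstart, qend, sstart, send`, sorted by E-value ascending, then
#'   bitscore descending, then subject id.
#' @export
search_db <- function(query, db, scheme = scoring_scheme("protein"),
                   e_cutoff = 1e-5, query_id = "query") {
  if (length(db) == 0L) stop("empty database")
  db <- as_xstringset(db, scheme$type)
  q <- as_xstring(query, scheme$type)
  m <- length(q)
  n_db <- sum(Biostrings::width(db))
  sc <- local_scores(q, db, scheme)
  ka <- evalue_of(sc, m, n_db, scheme)
  pass <- which(ka$evalue <= e_cutoff & sc > 0)
  if (length(pass)) {
    # one vectorized traceback call: db entries are the patterns, the query
    # is the single subject
    b <- batch_local_align(db[pass], q, scheme)
    out <- data.frame(qid = query_id, sid = names(db)[pass],
                      pident = 100 * b$nmatch / b$aln_width,
                      qcov = 100 * (b$send - b$sstart + 1) / m,
                      scov = 100 * (b$pend - b$pstart + 1) /
                        Biostrings::width(db)[pass],
                      bitscore = ka$bitscore[pass], evalue = ka$evalue[pass],
                      qstart = b$sstart, qend = b$send,
                      sstart = b$pstart, send = b$pend,
                      stringsAsFactors = FALSE)
  } else {
    out <- empty_hit_table()
  }
  out[order(out$evalue, -out$bitscore, out$sid), , drop = FALSE]
}

empty_hit_table <- function() {
  data.frame(qid = character(), sid = character(), pident = numeric(),
             qcov = numeric(), scov = numeric(), bitscore = numeric(),
             evalue = numeric(), qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(), stringsAsFactors = FALSE)
}

#' Write a hit table in the fixed tabular format
#'
#' @param hits A hit table as returned by [search_db()] or [all_vs_all()].
#' @param path Output TSV path.
#' @export
write_hit_table <- function(hits, path) {
  cols <- c("qid", "sid", "pident", "qcov", "scov", "bitscore", "evalue",
            "qstart", "qend", "sstart", "send")
  write.table(hits[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
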