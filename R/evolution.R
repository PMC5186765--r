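NT4 <- c("A", "C", "G", "T")

# cached codon bookkeeping for NG86 (standard amino acid translations;
# bacterial code 11 differs from the standard code only in start codons)
ng86_env <- new.env(parent = emptyenv())

ng86_tables <- function() {
  if (!is.null(ng86_env$tab)) return(ng86_env$tab)
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  # synonymous site fraction per codon position: fraction of the three
  # possible point changes that preserve the amino acid; changes creating a
  # stop codon count as nonsynonymous, so every codon contributes exactly
  # three sites and S + N = 3 * (number of codons)
  syn_sites <- matrix(0, length(codons), 3, dimnames = list(codons, NULL))
  for (cdn in codons) {
    aa <- code[[cdn]]
    for (pos in 1:3) {
      alt <- NT4[NT4 != substr(cdn, pos, pos)]
      n_syn <- 0
      for (nt in alt) {
        mut <- cdn
        substr(mut, pos, pos) <- nt
        if (code[[mut]] != "*" && code[[mut]] == aa) n_syn <- n_syn + 1
      }
      syn_sites[cdn, pos] <- n_syn / 3
    }
  }
  ng86_env$tab <- list(code = code, syn_sites = syn_sites,
                       path_cache = new.env(parent = emptyenv()))
  ng86_env$tab
}

# pathway-averaged synonymous/nonsynonymous difference counts between two
# sense codons; pathways passing through a stop codon are excluded (when all
# are blocked, the average runs over all pathways)
ng86_path_counts <- function(c1, c2) {
  tab <- ng86_tables()
  key <- paste0(c1, c2)
  hit <- tab$path_cache[[key]]
  if (!is.null(hit)) return(hit)
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(diff_pos)
  res <- if (d == 0L) {
    c(sd = 0, nd = 0)
  } else {
    perms <- permutations_of(diff_pos)
    path_sd <- numeric(0)
    path_nd <- numeric(0)
    blocked_sd <- numeric(0)
    blocked_nd <- numeric(0)
    for (ord in perms) {
      cur <- c1
      sd_i <- 0; nd_i <- 0
      blocked <- FALSE
      for (pos in ord) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(c2, pos, pos)
        if (tab$code[[nxt]] == "*") blocked <- TRUE
        if (tab$code[[nxt]] == tab$code[[cur]]) sd_i <- sd_i + 1
        else nd_i <- nd_i + 1
        cur <- nxt
      }
      if (blocked) {
        blocked_sd <- c(blocked_sd, sd_i); blocked_nd <- c(blocked_nd, nd_i)
      } else {
        path_sd <- c(path_sd, sd_i); path_nd <- c(path_nd, nd_i)
      }
    }
    if (length(path_sd)) {
      c(sd = mean(path_sd), nd = mean(path_nd))
    } else {
      c(sd = mean(blocked_sd), nd = mean(blocked_nd))
    }
  }
  assign(key, res, envir = tab$path_cache)
  res
}

permutations_of <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out <- c(out, list(c(x[i], rest)))
  }
  out
}

#' Back-translate a protein MSA into a codon alignment
#'
#' Replaces every aligned residue by its source codon and every gap by
#' `---`, after checking that each CDS (terminal stop stripped) translates
#' exactly to its degapped MSA row.
#'
#' @param protein_msa An `msa_result` from [center_star_align()].
#' @param cds_map Named `DNAStringSet` (or named character) of coding
#'   sequences, names matching the MSA rows.
#' @return An object of class `codon_alignment`: named character vector of
#'   equal-length gapped codon strings (gap codon `---`).
#' @export
backtranslate <- function(protein_msa, cds_map) {
  cds_map <- setNames(as.character(cds_map), names(cds_map))
  out <- character(length(protein_msa$rows))
  names(out) <- names(protein_msa$rows)
  for (id in names(protein_msa$rows)) {
    if (!id %in% names(cds_map)) stop("no CDS for sequence '", id, "'")
    cds <- cds_map[[id]]
    pep <- translate_cds(cds)  # errors on internal stops
    row <- protein_msa$rows[[id]]
    degapped <- gsub("-", "", row)
    if (pep != degapped) {
      n <- min(nchar(pep), nchar(degapped))
      mism <- which(strsplit(pep, "")[[1]][seq_len(n)] !=
                      strsplit(degapped, "")[[1]][seq_len(n)])
      stop(sprintf("CDS of '%s' does not translate to its MSA row (first mismatch at residue %d)",
                   id, if (length(mism)) mism[1] else n + 1L))
    }
    if (nchar(cds) %% 3L == 0L && nchar(cds) / 3L == nchar(pep) + 1L) {
      cds <- substr(cds, 1L, nchar(cds) - 3L)  # drop terminal stop codon
    }
    chars <- strsplit(row, "")[[1]]
    codons <- character(length(chars))
    ci <- 0L
    for (k in seq_along(chars)) {
      if (chars[k] == "-") {
        codons[k] <- "---"
      } else {
        codons[k] <- substr(cds, 3L * ci + 1L, 3L * ci + 3L)
        ci <- ci + 1L
      }
    }
    out[id] <- paste(codons, collapse = "")
  }
  stopifnot(length(unique(nchar(out))) == 1L)
  structure(out, class = "codon_alignment")
}

#' Nei-Gojobori (1986) pairwise Ka/Ks with Jukes-Cantor correction
#'
#' Counts synonymous (S) and nonsynonymous (N) sites averaged over the two
#' sequences, and synonymous/nonsynonymous differences (Sd, Nd) averaged
#' over all substitution pathways that avoid stop codons. Proportions are
#' corrected with the Jukes-Cantor formula `d = -(3/4) ln(1 - 4p/3)`;
#' a proportion of 3/4 or more marks the pair as saturated. Codons with a
#' gap or an ambiguous base in either row are skipped.
#'
#' @param row_a,row_b Gapped codon strings of equal length (length divisible
#'   by 3).
#' @return A list of class `kaks_estimate` with fields `S`, `N`, `Sd`, `Nd`,
#'   `ps`, `pn`, `Ks`, `Ka`, `omega`, `omega_defined`, `saturated`,
#'   `n_codons` (comparable codons).
#' @export
ng86_pairwise <- function(row_a, row_b) {
  row_a <- as.character(row_a); row_b <- as.character(row_b)
  stopifnot(nchar(row_a) == nchar(row_b), nchar(row_a) %% 3L == 0L)
  tab <- ng86_tables()
  n_cod <- nchar(row_a) / 3L
  starts <- 3L * (seq_len(n_cod) - 1L) + 1L
  ca <- substring(row_a, starts, starts + 2L)
  cb <- substring(row_b, starts, starts + 2L)
  ok <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb) &
    ca %in% rownames(tab$syn_sites) & cb %in% rownames(tab$syn_sites) &
    tab$code[ca] != "*" & tab$code[cb] != "*"
  ca <- ca[ok]; cb <- cb[ok]
  if (!length(ca)) stop("no comparable codons")
  s_a <- sum(tab$syn_sites[ca, ])
  s_b <- sum(tab$syn_sites[cb, ])
  S <- (s_a + s_b) / 2
  N <- 3 * length(ca) - S
  Sd <- 0; Nd <- 0
  for (k in seq_along(ca)) {
    if (ca[k] != cb[k]) {
      cnt <- ng86_path_counts(ca[k], cb[k])
      Sd <- Sd + cnt[["sd"]]
      Nd <- Nd + cnt[["nd"]]
    }
  }
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  saturated <- ps >= 0.75 || pn >= 0.75
  jc <- function(p) if (p < 0.75) abs(-0.75 * log(1 - 4 * p / 3)) else NA_real_
  Ks <- jc(ps)
  Ka <- jc(pn)
  omega_defined <- !saturated && !is.na(Ks) && Ks > 0
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
                 Ks = Ks, Ka = Ka,
                 omega = if (omega_defined) Ka / Ks else NA_real_,
                 omega_defined = omega_defined, saturated = saturated,
                 n_codons = length(ca)),
            class = "kaks_estimate")
}

#' @export
print.kaks_estimate <- function(x, ...) {
  cat(sprintf("<ng86> S=%.2f N=%.2f Sd=%.2f Nd=%.2f Ks=%s Ka=%s omega=%s%s\n",
              x$S, x$N, x$Sd, x$Nd, format(x$Ks), format(x$Ka),
              format(x$omega), if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

#' Family-level omega: mean of defined pairwise Ka/Ks ratios
#'
#' Averages Ka/Ks over all within-family sequence pairs. Pairs where Ks is
#' zero or the Jukes-Cantor correction saturates carry no defined ratio;
#' they are excluded from the mean and counted.
#'
#' @param codon_alignment A [backtranslate()] result (>= 2 rows).
#' @return A list with `omega_mean` (NA with `defined = FALSE` when no pair
#'   has a defined ratio), `defined`, `n_excluded`, and `pairs` (per-pair
#'   data.frame with S, N, Sd, Nd, Ka, Ks, omega, saturated).
#' @export
family_omega <- function(codon_alignment) {
  ids <- names(codon_alignment)
  if (length(ids) < 2L) stop("need at least two rows")
  rows <- combn(ids, 2, simplify = FALSE)
  recs <- lapply(rows, function(p) {
    est <- ng86_pairwise(codon_alignment[[p[1]]], codon_alignment[[p[2]]])
    data.frame(seq_a = p[1], seq_b = p[2], S = est$S, N = est$N,
               Sd = est$Sd, Nd = est$Nd, Ka = est$Ka, Ks = est$Ks,
               omega = est$omega, saturated = est$saturated,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, recs)
  defined <- !is.na(pairs$omega)
  list(omega_mean = if (any(defined)) mean(pairs$omega[defined]) else NA_real_,
       defined = any(defined),
       n_excluded = sum(!defined),
       pairs = pairs)
}

#' Write a per-family Ka/Ks table as TSV
#' @param family_id Family identifier written into each row.
#' @param omega A [family_omega()] result.
#' @param path Output TSV path.
#' @export
write_kaks_table <- function(family_id, omega, path) {
  df <- cbind(family_id = family_id, omega$pairs)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
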