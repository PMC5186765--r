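# Independent brute-force oracles used to validate the fast implementations.
# These are deliberately written from the primary definitions, not by
# calling the package's own code paths.

AA_LETTERS <- c("A","C","D","E","F","G","H","I","K","L",
                "M","N","P","Q","R","S","T","V","W","Y")

random_protein_chr <- function(len) {
  paste(sample(AA_LETTERS, len, replace = TRUE), collapse = "")
}

random_dna_chr <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# quadratic linear-gap Smith-Waterman (score only): each gapped position
# costs `gap` regardless of run length
sw_linear_oracle <- function(a, b, submat, gap) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  H <- matrix(0, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      H[i + 1, j + 1] <- max(0,
                             H[i, j] + submat[av[i], bv[j]],
                             H[i, j + 1] - gap,
                             H[i + 1, j] - gap)
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# quadratic linear-gap Needleman-Wunsch (score only), end gaps penalized
nw_linear_oracle <- function(a, b, submat, gap) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  F <- matrix(0, m + 1, n + 1)
  F[, 1] <- -gap * (0:m)
  F[1, ] <- -gap * (0:n)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      F[i + 1, j + 1] <- max(F[i, j] + submat[av[i], bv[j]],
                             F[i, j + 1] - gap,
                             F[i + 1, j] - gap)
    }
  }
  F[m + 1, n + 1]
}

# ---- Nei-Gojobori oracle -------------------------------------------------

ng_code <- Biostrings::GENETIC_CODE

ng_is_stop <- function(codon) ng_code[[codon]] == "*"

# synonymous site count of one codon (stop-producing changes count as
# nonsynonymous so each codon carries exactly 3 sites)
ng_oracle_sites <- function(codon) {
  nts <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    for (nt in nts) {
      if (nt == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (!ng_is_stop(mut) && ng_code[[mut]] == ng_code[[codon]]) {
        s <- s + 1 / 3
      }
    }
  }
  s
}

ng_all_orders <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (k in seq_along(v)) {
    for (tail in ng_all_orders(v[-k])) out[[length(out) + 1]] <- c(v[k], tail)
  }
  out
}

# pathway-averaged (sd, nd) between two sense codons; pathways through stop
# codons dropped (all-blocked pairs fall back to the unrestricted average)
ng_oracle_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  valid <- list(); all_paths <- list()
  for (ord in ng_all_orders(pos)) {
    cur <- c1; sd <- 0; nd <- 0; through_stop <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (ng_is_stop(nxt)) through_stop <- TRUE
      if (ng_code[[nxt]] == ng_code[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    rec <- c(sd, nd)
    all_paths[[length(all_paths) + 1]] <- rec
    if (!through_stop) valid[[length(valid) + 1]] <- rec
  }
  use <- if (length(valid)) valid else all_paths
  colMeans(do.call(rbind, use))
}

# full NG86 S, N, Sd, Nd for two equal-length ungapped codon sequences
ng_oracle <- function(seq1, seq2) {
  n_cod <- nchar(seq1) / 3
  S <- 0; Sd <- 0; Nd <- 0
  for (k in seq_len(n_cod)) {
    c1 <- substr(seq1, 3 * k - 2, 3 * k)
    c2 <- substr(seq2, 3 * k - 2, 3 * k)
    S <- S + (ng_oracle_sites(c1) + ng_oracle_sites(c2)) / 2
    d <- ng_oracle_diffs(c1, c2)
    Sd <- Sd + d[1]
    Nd <- Nd + d[2]
  }
  list(S = S, N = 3 * n_cod - S, Sd = Sd, Nd = Nd)
}

random_sense_codons <- function(n) {
  sense <- names(ng_code)[ng_code != "*"]
  paste(sample(sense, n, replace = TRUE), collapse = "")
}

# small synthetic pan-genome configuration shared by the unit tests (the
# acceptance tests use the full default configuration)
tiny_config <- function(seed = 42) {
  synth_config(n_species = 3L, strains_per_species = c(1L, 1L, 2L),
               n_core_shared = 3L, n_orphan = 2L, n_traps = 1L,
               n_accessory = 2L, refdb_decoys = 30L,
               protein_len_range = c(60L, 120L),
               intermediate_strain = FALSE, seed = seed)
}

# pooled protein set of one truth family
pooled_members <- function(sim, family_id) {
  mem <- sim$truth$members
  ids <- mem$protein_id[mem$family_id == family_id]
  prot <- do.call(c, unname(lapply(sim$proteomes, function(p) p$proteins)))
  names(prot) <- unlist(lapply(sim$proteomes, function(p) names(p$proteins)))
  prot[ids]
}

# substitute residues until roughly `target` identity remains
mutate_identity <- function(seq, target) {
  v <- strsplit(seq, "")[[1]]
  idx <- sample(seq_along(v), round((1 - target) * length(v)))
  v[idx] <- vapply(v[idx], function(x) sample(setdiff(AA_LETTERS, x), 1), "")
  paste(v, collapse = "")
}
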