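# Bjellqvist pKa set as used by the ExPASy Compute pI/Mw tool: side-chain
# values plus residue-specific terminal values.
BJELLQVIST_PKA <- list(
  side_pos = c(K = 10.00, R = 12.00, H = 5.98),
  side_neg = c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00),
  nterm_default = 7.50,
  nterm = c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
            E = 7.70),
  cterm_default = 3.55,
  cterm = c(D = 4.55, E = 4.75)
)

# ExPASy average residue masses (Da); a free protein adds one water.
AA_AVG_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_AVG_MASS <- 18.01524

# Kyte-Doolittle hydropathy values
KYTE_DOOLITTLE <- c(
  A = 1.8,  R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  E = -3.5, Q = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8,  K = -3.9, M = 1.9,  F = 2.8,  P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over ionizable groups with the Bjellqvist pKa
#' table (the constants behind the ExPASy isoelectric-point tool): positive
#' contributions from the N-terminus, K, R, and H; negative from the
#' C-terminus, D, E, C, and Y. Terminal pKa values are residue-specific.
#'
#' @param seq Protein sequence (character scalar); `X` carries no charge.
#' @param pH pH value.
#' @param pka_set pKa table in the format of `BJELLQVIST_PKA` (the default).
#' @return Net charge (numeric scalar), strictly decreasing in pH.
#' @export
net_charge <- function(seq, pH, pka_set = BJELLQVIST_PKA) {
  seq <- as.character(seq)
  if (!nchar(seq)) stop("empty sequence")
  chars <- strsplit(seq, "")[[1]]
  first <- chars[1]
  last <- chars[length(chars)]
  pos_pka <- c(
    if (first %in% names(pka_set$nterm)) pka_set$nterm[[first]] else pka_set$nterm_default,
    rep(pka_set$side_pos[["K"]], sum(chars == "K")),
    rep(pka_set$side_pos[["R"]], sum(chars == "R")),
    rep(pka_set$side_pos[["H"]], sum(chars == "H")))
  neg_pka <- c(
    if (last %in% names(pka_set$cterm)) pka_set$cterm[[last]] else pka_set$cterm_default,
    rep(pka_set$side_neg[["D"]], sum(chars == "D")),
    rep(pka_set$side_neg[["E"]], sum(chars == "E")),
    rep(pka_set$side_neg[["C"]], sum(chars == "C")),
    rep(pka_set$side_neg[["Y"]], sum(chars == "Y")))
  sum(1 / (1 + 10^(pH - pos_pka))) - sum(1 / (1 + 10^(neg_pka - pH)))
}

#' Isoelectric point of a protein
#'
#' Bisection on pH in \[0, 14\] until the absolute net charge drops below
#' `tol` (default 1e-4); the charge function is strictly monotone in pH so
#' the root is unique.
#'
#' @inheritParams net_charge
#' @param tol Charge tolerance at the returned pH.
#' @return The pI (numeric scalar in \[0, 14\]).
#' @export
isoelectric_point <- function(seq, pka_set = BJELLQVIST_PKA, tol = 1e-4) {
  seq <- as.character(seq)
  if (!nchar(seq)) stop("empty sequence")
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- net_charge(seq, mid, pka_set)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Molecular weight of a protein (average masses)
#'
#' Sum of average residue masses plus one water. `X` residues contribute
#' the mean of the 20 standard masses.
#'
#' @param seq Protein sequence (character scalar, non-empty).
#' @return Molecular weight in daltons.
#' @export
molecular_weight <- function(seq) {
  seq <- as.character(seq)
  if (!nchar(seq)) stop("empty sequence")
  chars <- strsplit(seq, "")[[1]]
  mass <- AA_AVG_MASS[chars]
  mass[chars == "X"] <- mean(AA_AVG_MASS)
  if (anyNA(mass)) stop("unknown residue: ",
                        paste(unique(chars[is.na(mass)]), collapse = ", "))
  sum(mass) + WATER_AVG_MASS
}

#' Kyte-Doolittle hydropathy profile
#'
#' Centered sliding-window mean of Kyte-Doolittle values. Positions whose
#' window does not fit entirely inside the sequence are `NA`.
#'
#' @param seq Protein sequence (character scalar).
#' @param window Odd window width (default 19).
#' @return Numeric vector of length `nchar(seq)`; all-`NA` with a warning if
#'   the sequence is shorter than the window.
#' @export
hydropathy_profile <- function(seq, window = 19L) {
  seq <- as.character(seq)
  stopifnot(window %% 2L == 1L)
  chars <- strsplit(seq, "")[[1]]
  vals <- KYTE_DOOLITTLE[chars]
  vals[is.na(vals)] <- 0  # X and other non-standard residues are neutral
  L <- length(chars)
  prof <- rep(NA_real_, L)
  if (L < window) {
    warning("sequence shorter than the hydropathy window")
    return(prof)
  }
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, vals))
  centers <- (half + 1L):(L - half)
  prof[centers] <- (cs[centers + half + 1L] - cs[centers - half]) / window
  prof
}

#' Predict transmembrane segments from a hydropathy profile
#'
#' A candidate segment is a maximal run of window centers above `threshold`;
#' runs separated by dips of at most `merge_gap` centers are merged, each
#' run is expanded by half a window on both sides (the residues its windows
#' actually cover), overlapping expansions are united, and only segments of
#' at least `min_len` residues are reported. This is a deliberately simple
#' hydropathy-based caller, an approximation to HMM-based predictors,
#' exercised on synthetic constructs only.
#'
#' @param profile Output of [hydropathy_profile()].
#' @param threshold Hydropathy threshold (default 1.6).
#' @param min_len Minimum segment length in residues (default 19).
#' @param merge_gap Maximum below-threshold dip to bridge (default 3).
#' @param window Window width used to build the profile (default 19).
#' @return A data.frame with columns `start`, `end` (1-based inclusive,
#'   non-overlapping residue intervals).
#' @export
predict_tm_segments <- function(profile, threshold = 1.6, min_len = 19L,
                                merge_gap = 3L, window = 19L) {
  above <- !is.na(profile) & profile > threshold
  empty <- data.frame(start = integer(), end = integer())
  if (!any(above)) return(empty)
  half <- (window - 1L) %/% 2L
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # bridge short dips between runs of above-threshold window centers
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
      if (gap <= merge_gap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  # expand each run of centers to the residues its windows cover
  merged$start <- pmax(1L, merged$start - half)
  merged$end <- pmin(length(profile), merged$end + half)
  # unite overlapping expansions
  out <- merged[1, , drop = FALSE]
  if (nrow(merged) > 1L) {
    for (i in 2:nrow(merged)) {
      if (merged$start[i] <= out$end[nrow(out)] + 1L) {
        out$end[nrow(out)] <- max(out$end[nrow(out)], merged$end[i])
      } else {
        out <- rbind(out, merged[i, ])
      }
    }
  }
  out <- out[out$end - out$start + 1L >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Physicochemical feature profile of a protein
#'
#' Convenience wrapper computing isoelectric point, molecular weight,
#' hydropathy profile, and transmembrane segment calls in one pass.
#'
#' @param seq Protein sequence (character scalar).
#' @param window,threshold,min_len Parameters of the hydropathy/TM caller.
#' @return A list with `length`, `pI`, `mw`, `hydropathy`, `tm_segments`.
#' @export
feature_profile <- function(seq, window = 19L, threshold = 1.6,
                            min_len = 19L) {
  seq <- as.character(seq)
  prof <- suppressWarnings(hydropathy_profile(seq, window))
  list(length = nchar(seq),
       pI = isoelectric_point(seq),
       mw = molecular_weight(seq),
       hydropathy = prof,
       tm_segments = predict_tm_segments(prof, threshold, min_len))
}

#' Feature table for a set of proteins
#'
#' @param proteins Named `AAStringSet` or named character vector.
#' @return A data.frame with columns `id`, `length`, `pI`, `mw`,
#'   `n_tm_segments`, `tm_segments` (semicolon-separated `start-end` list).
#' @export
feature_table <- function(proteins) {
  seqs <- setNames(as.character(proteins), names(proteins))
  rows <- lapply(names(seqs), function(id) {
    fp <- feature_profile(seqs[[id]])
    data.frame(id = id, length = fp$length, pI = fp$pI, mw = fp$mw,
               n_tm_segments = nrow(fp$tm_segments),
               tm_segments = paste(sprintf("%d-%d", fp$tm_segments$start,
                                           fp$tm_segments$end),
                                   collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
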