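#' Default Rep motif patterns
#'
#' Degenerate patterns (POSIX character classes) for the rolling-circle
#' replication endonuclease motifs I--III and the superfamily-3 helicase
#' motifs (Walker-A, Walker-B, Motif C, arginine finger). The arginine
#' finger is positional: the first `R` at or after the Motif C hit.
#'
#' @return Named character vector of regular expressions, in the canonical
#'   N- to C-terminal order.
#' @export
rep_motif_patterns <- function() {
  c("RCR-I"      = "[FYW]T[LIV][NT]N",
    "RCR-II"     = "H[LIV][HQ]",
    "RCR-III"    = "Y..K",
    "Walker-A"   = "G....GK[ST]",
    "Walker-B"   = "[ILVMF][ILVMF]DD",
    "Motif-C"    = "[ILVMF][ILVMF]SN",
    "Arg-finger" = "R")
}

#' Scan a protein for Rep (RCR + SF3 helicase) motifs
#'
#' Records the leftmost hit of each motif (the arginine finger is the first
#' `R` at or after the Motif C hit), checks that the found motifs appear in
#' the canonical order, and calls the protein a Rep when at least `quorum`
#' motifs are present in order.
#'
#' @param protein Amino-acid string without internal stops.
#' @param patterns Named pattern vector (default [rep_motif_patterns()]), in
#'   required order.
#' @param quorum Minimum number of ordered motif hits for `is_rep`
#'   (default 4).
#' @return List with `hits` (tibble: `motif`, `aa_pos` 0-based, `matched`),
#'   `order_ok`, `n_core_hits`, `is_rep`.
#' @export
scan_rep_motifs <- function(protein, patterns = rep_motif_patterns(),
                            quorum = 4L) {
  stopifnot(is.character(protein), length(protein) == 1L)
  if (nchar(protein) < 50L) abort("too short for Rep scan")
  nm <- names(patterns)
  pos <- rep(NA_integer_, length(patterns))
  matched <- rep(NA_character_, length(patterns))
  for (k in seq_along(patterns)) {
    if (nm[k] == "Arg-finger") {
      ci <- match("Motif-C", nm)
      from <- if (!is.na(pos[ci])) pos[ci] + 1L else 1L
      m <- regexpr(patterns[k], substr(protein, from, nchar(protein)))
      if (m[1] != -1L) {
        pos[k] <- from + as.integer(m) - 1L
        matched[k] <- substr(protein, pos[k], pos[k] + attr(m, "match.length") - 1L)
      }
    } else {
      m <- regexpr(patterns[k], protein)
      if (m[1] != -1L) {
        pos[k] <- as.integer(m)
        matched[k] <- substr(protein, pos[k], pos[k] + attr(m, "match.length") - 1L)
      }
    }
  }
  hits <- tibble(motif = nm[!is.na(pos)], aa_pos = pos[!is.na(pos)] - 1L,
                 matched = matched[!is.na(pos)])
  found <- pos[!is.na(pos)]
  # Motifs must appear in canonical order; Motif C and the arginine finger
  # may coincide in position ordering (R directly after the motif).
  order_ok <- length(found) <= 1L || !is.unsorted(found, strictly = FALSE)
  n <- nrow(hits)
  list(hits = hits, order_ok = order_ok, n_core_hits = n,
       is_rep = n >= quorum && order_ok)
}

#' TOP-IDP per-residue disorder propensity scale
#'
#' Published compositional disorder propensities (higher = more
#' disorder-promoting), min-max normalised to `[0, 1]` so that tryptophan
#' scores 0 and proline 1.
#'
#' @return Named numeric vector over the 20 amino acids.
#' @export
disorder_scale <- function() {
  raw <- c(A = 0.06, R = 0.180, N = 0.007, D = 0.192, C = -0.02, Q = 0.318,
           E = 0.736, G = 0.166, H = 0.303, I = -0.486, L = -0.326,
           K = 0.586, M = -0.397, F = -0.697, P = 0.987, S = 0.341,
           T = 0.059, W = -0.884, Y = -0.510, V = -0.121)
  (raw - min(raw)) / (max(raw) - min(raw))
}

#' Per-residue intrinsic disorder profile
#'
#' Scores each residue by a fixed propensity scale and smooths with a
#' centered moving average (window truncated at the termini). Unknown
#' residue letters score 0.5 and are flagged.
#'
#' @param protein Amino-acid string.
#' @param window Odd smoothing window (default 15).
#' @param scale Named propensity vector in `[0, 1]`
#'   (default [disorder_scale()]).
#' @param threshold Score at or above which a residue counts as disordered
#'   (default 0.5).
#' @return List of class `cress_disorder`: `scores` (length = protein
#'   length), `raw` (unsmoothed), `frac_disordered_first100`,
#'   `n_first` (residues actually available, flagged short if < 100),
#'   `short`, `unknown_residues`.
#' @export
disorder_profile <- function(protein, window = 15L, scale = disorder_scale(),
                             threshold = 0.5) {
  stopifnot(is.character(protein), length(protein) == 1L, nchar(protein) > 0L)
  if (window < 3L || window %% 2L == 0L) abort("window must be odd and >= 3")
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  raw <- unname(scale[aa])
  unknown <- sum(is.na(raw))
  raw[is.na(raw)] <- 0.5
  n <- length(raw)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, raw))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  scores <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  nf <- min(100L, n)
  structure(list(scores = scores, raw = raw,
                 frac_disordered_first100 = mean(scores[seq_len(nf)] >= threshold),
                 n_first = nf, short = n < 100L,
                 unknown_residues = unknown),
            class = "cress_disorder")
}

#' Call putative capsids among non-Rep major ORFs
#'
#' Each major ORF other than the designated Rep is scored by its intrinsic
#' disorder profile; an ORF whose first 100 residues have a fraction of
#' disordered positions at or above `theta` is called a putative capsid.
#' A genome with a Rep but no called capsid is labelled a "circular
#' molecule" downstream.
#'
#' @param major_orfs Tibble from [select_major_orfs()].
#' @param rep_id `orf_id` of the Rep (excluded from candidates); may be `NA`.
#' @param theta Calling threshold on `frac_disordered_first100`
#'   (default 0.5).
#' @param window Smoothing window for [disorder_profile()].
#' @return Tibble: `orf_id`, `frac_disordered_first100`, `called`, `basis`
#'   (`"idp_profile"`), `short`.
#' @export
call_capsids <- function(major_orfs, rep_id, theta = 0.5, window = 15L) {
  cand <- major_orfs[is.na(rep_id) | major_orfs$orf_id != rep_id, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(tibble(orf_id = character(), frac_disordered_first100 = double(),
                  called = logical(), basis = character(), short = logical()))
  }
  rows <- map(seq_len(nrow(cand)), function(i) {
    prof <- disorder_profile(cand$protein[i], window = window)
    tibble(orf_id = cand$orf_id[i],
           frac_disordered_first100 = prof$frac_disordered_first100,
           called = prof$frac_disordered_first100 >= theta,
           basis = "idp_profile", short = prof$short)
  })
  list_rbind(rows)
}
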