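DNA_CODE <- c(A = 0L, C = 1L, G = 2L, T = 3L, N = 4L)

encode_seq <- function(s, alphabet) {
  idx <- match(strsplit(s, "", fixed = TRUE)[[1]], names(alphabet))
  if (anyNA(idx)) abort("sequence contains letters outside the alphabet")
  unname(alphabet[idx])
}

aa_alphabet <- function() {
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V", "X", "*")
  setNames(seq_along(aas) - 1L, aas)
}

nt_submat <- function(match = 2, mismatch = -1) {
  m <- matrix(mismatch, 5, 5)
  diag(m) <- match
  # N never rewarded nor over-penalised: score 0 against anything.
  m[5, ] <- 0; m[, 5] <- 0
  m
}

aa_submat <- function() {
  b62 <- get_blosum62()
  ab <- names(aa_alphabet())
  m <- matrix(0, length(ab), length(ab), dimnames = list(ab, ab))
  common <- intersect(ab, rownames(b62))
  m[common, common] <- b62[common, common]
  unname(m)
}

blosum_env <- new.env(parent = emptyenv())
get_blosum62 <- function() {
  if (is.null(blosum_env$b62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum_env$b62 <- e$BLOSUM62
  }
  blosum_env$b62
}

#' Alignment parameter defaults
#'
#' Nucleotide alignments score match +2 / mismatch -1 with affine gaps
#' (open -4, extend -1: a gap of length k costs 4 + k). Amino-acid
#' alignments use BLOSUM62 with gap open -10 / extend -1.
#'
#' @param mode `"nt"` or `"aa"`.
#' @return List: `submat`, `alphabet`, `gap_open`, `gap_ext`.
#' @export
align_params <- function(mode = c("nt", "aa")) {
  mode <- match.arg(mode)
  if (mode == "nt") {
    list(submat = nt_submat(), alphabet = DNA_CODE, gap_open = -4, gap_ext = -1)
  } else {
    list(submat = aa_submat(), alphabet = aa_alphabet(),
         gap_open = -10, gap_ext = -1)
  }
}

#' Global pairwise identity (SDT-style)
#'
#' Aligns two sequences end-to-end with an affine-gap global aligner and
#' returns the fraction of identical columns over all alignment columns
#' (terminal and internal gap columns count in the denominator, matching the
#' gap-penalising identity convention of sequence demarcation analyses).
#' Traceback ties are resolved deterministically (diagonal, then up, then
#' left).
#'
#' @param a,b Sequences (character scalars) over a shared alphabet.
#' @param mode `"nt"` or `"aa"` (selects scoring defaults).
#' @param params Optional list overriding [align_params()] fields.
#' @param ignore_terminal_gaps Drop leading/trailing gap columns from the
#'   denominator (useful when short terminal overhangs are registration
#'   artifacts; default `FALSE`).
#' @return Fraction in `[0, 1]`, with attribute `alignment` (list:
#'   `score`, `n_identical`, `n_columns`).
#' @export
pairwise_identity <- function(a, b, mode = c("nt", "aa"), params = NULL,
                              ignore_terminal_gaps = FALSE) {
  mode <- match.arg(mode)
  if (!nzchar(a) || !nzchar(b)) abort("empty sequence")
  p <- align_params(mode)
  if (!is.null(params)) p[names(params)] <- params
  ai <- encode_seq(toupper(a), p$alphabet)
  bi <- encode_seq(toupper(b), p$alphabet)
  r <- nw_affine(ai, bi, p$submat, p$gap_open, p$gap_ext)
  ncol <- r$n_columns
  nid <- r$n_identical
  if (ignore_terminal_gaps) {
    both <- r$a_idx >= 0L & r$b_idx >= 0L
    first <- which(both)[1]; last <- tail(which(both), 1)
    keep <- seq(first, last)
    ncol <- length(keep)
    nid <- sum(both[keep] & {
      ia <- r$a_idx[keep] + 1L; ib <- r$b_idx[keep] + 1L
      ok <- both[keep]
      out <- logical(length(keep))
      out[ok] <- ai[ia[ok]] == bi[ib[ok]]
      out
    })
  }
  pi <- nid / ncol
  attr(pi, "alignment") <- list(score = r$score, n_identical = nid,
                                n_columns = ncol)
  pi
}

#' Circular-aware genome-wide pairwise identity
#'
#' Sequence demarcation identity operates on linearised genomes, so circular
#' genomes must be registered first. When both genomes have called origins
#' each is rotated so its nonamer starts at position 0 and identity is
#' computed in forward and reverse-complement orientation, taking the
#' maximum. Otherwise the second genome is scanned over rotations at a
#' coarse step (length/32), the best is refined within one step, in both
#' orientations.
#'
#' @param ga,gb [cress_genome] objects.
#' @param ori_a,ori_b Optional [call_ori()] results for the two genomes.
#' @param params Optional alignment parameter overrides.
#' @return Fraction in `[0, 1]` with attribute `registration` (list:
#'   `method`, `rotation_b`, `orientation`).
#' @export
circular_genome_identity <- function(ga, gb, ori_a = NULL, ori_b = NULL,
                                     params = NULL) {
  stopifnot(inherits(ga, "cress_genome"), inherits(gb, "cress_genome"))
  orient <- function(g) list(fwd = g$seq, rev = revcomp_chr(g$seq))
  if (!is.null(ori_a) && !is.null(ori_b)) {
    a0 <- rotate_genome(ga, ori_a$nonamer$pos)$seq
    gb_r <- rotate_genome(gb, ori_b$nonamer$pos)
    cand <- c(fwd = gb_r$seq,
              rev = rotate_genome(revcomp(gb), genome_length(gb) - ori_b$nonamer$pos - 9L)$seq)
    pis <- vapply(cand, function(s) as.numeric(pairwise_identity(a0, s, "nt", params)),
                  double(1))
    best <- which.max(pis)
    out <- pis[[best]]
    attr(out, "registration") <- list(method = "ori_anchored",
                                      rotation_b = ori_b$nonamer$pos,
                                      orientation = names(pis)[best])
    return(out)
  }
  # Rotation scan fallback.
  L <- genome_length(gb)
  step <- max(1L, L %/% 32L)
  a0 <- ga$seq
  try_rot <- function(seqb, offs) {
    vapply(offs, function(k) {
      s <- paste0(substr(seqb, k + 1L, L), substr(seqb, 1L, k))
      as.numeric(pairwise_identity(a0, s, "nt", params))
    }, double(1))
  }
  best <- list(pi = -1, rot = 0L, orient = "fwd")
  for (ornt in c("fwd", "rev")) {
    sb <- if (ornt == "fwd") gb$seq else revcomp_chr(gb$seq)
    coarse <- seq.int(0L, L - 1L, by = step)
    pis <- try_rot(sb, coarse)
    k0 <- coarse[which.max(pis)]
    fine <- unique(((k0 - step):(k0 + step)) %% L)
    pis2 <- try_rot(sb, fine)
    if (max(pis2) > best$pi) {
      best <- list(pi = max(pis2), rot = fine[which.max(pis2)], orient = ornt)
    }
  }
  out <- best$pi
  attr(out, "registration") <- list(method = "rotation_scan",
                                    rotation_b = best$rot,
                                    orientation = best$orient)
  out
}

#' Build a pairwise-identity matrix
#'
#' @param seqs Named character vector of sequences (mode `"rep_aa"` or
#'   `"nt_linear"`), or a named list of [cress_genome] objects (mode
#'   `"genome_nt_circular"`).
#' @param mode One of `"genome_nt_circular"`, `"nt_linear"`, `"rep_aa"`.
#' @param oris Optional named list of [call_ori()] results (circular mode).
#' @param params Optional alignment parameter overrides.
#' @return A `cress_pim` object: `ids`, `values` (symmetric matrix with unit
#'   diagonal), `mode`.
#' @export
build_pi_matrix <- function(seqs, mode = c("genome_nt_circular", "nt_linear",
                                           "rep_aa"),
                            oris = NULL, params = NULL) {
  mode <- match.arg(mode)
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids)) abort("duplicate or missing ids")
  n <- length(seqs)
  if (n < 2L) abort("need at least 2 sequences")
  v <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      pi <- switch(mode,
        genome_nt_circular = circular_genome_identity(
          seqs[[i]], seqs[[j]], oris[[ids[i]]], oris[[ids[j]]], params),
        nt_linear = pairwise_identity(seqs[[i]], seqs[[j]], "nt", params),
        rep_aa = pairwise_identity(seqs[[i]], seqs[[j]], "aa", params))
      v[i, j] <- v[j, i] <- as.numeric(pi)
    }
  }
  dimnames(v) <- list(ids, ids)
  structure(list(ids = ids, values = v, mode = mode), class = "cress_pim")
}

#' @export
print.cress_pim <- function(x, ...) {
  cat(sprintf("<cress_pim> %d x %d pairwise identities (%s)\n",
              length(x$ids), length(x$ids), x$mode))
  print(round(x$values, 3))
  invisible(x)
}

#' @describeIn build_pi_matrix Tidy a PI matrix into a long tibble of pairs.
#' @param x A `cress_pim`.
#' @param ... Unused.
#' @export
tidy.cress_pim <- function(x, ...) {
  n <- length(x$ids)
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble(id1 = x$ids[idx[, 1]], id2 = x$ids[idx[, 2]],
         identity = x$values[idx], mode = x$mode)
}
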