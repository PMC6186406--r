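translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# ORF scan of one strand of a circular genome. `s` is the strand sequence
# (forward, or the reverse complement). Returns 0-based [start, end) intervals
# in the coordinates of `s` (end may exceed L for origin-spanning ORFs).
scan_strand_orfs <- function(s, L, circular, require_atg) {
  trip <- if (circular) strrep(s, 3L) else s
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  lo <- if (circular) L else 0L       # starts accepted in [lo, lo + L)
  for (f in 0:2) {
    starts <- seq.int(f + 1L, nchar(trip) - 2L, by = 3L)
    codons <- substring(trip, starts, starts + 2L)
    is_stop <- codons %in% stops
    is_start <- if (require_atg) codons == "ATG" else !is_stop
    stop_i <- which(is_stop)
    if (length(stop_i) == 0L) {
      # No stop anywhere in this frame cycle: endless reading frame.
      cand <- which(is_start)
      cand <- cand[starts[cand] - 1L >= lo & starts[cand] - 1L < lo + L]
      if (length(cand) > 0L) {
        i <- cand[1]
        p0 <- starts[i] - 1L
        ncod <- L %/% 3L
        prot <- translate_codons(codons[i:(i + ncod - 1L)])
        out[[length(out) + 1L]] <- list(start = p0 - lo, len = ncod * 3L,
                                        protein = prot, no_stop = TRUE)
      }
      next
    }
    prev <- c(0L, stop_i[-length(stop_i)])
    for (k in seq_along(stop_i)) {
      si <- stop_i[k]
      seg <- seq.int(prev[k] + 1L, si)
      cand <- seg[is_start[seg]]
      if (length(cand) == 0L) next
      i <- cand[1]
      p0 <- starts[i] - 1L
      if (p0 < lo || p0 >= lo + L) next
      len <- (si - i + 1L) * 3L
      if (len > L) next  # cannot exceed the circle
      prot <- if (si > i) translate_codons(codons[i:(si - 1L)]) else ""
      out[[length(out) + 1L]] <- list(start = p0 - lo, len = len,
                                      protein = prot, no_stop = FALSE)
    }
  }
  out
}

#' Find open reading frames on both strands of a circular genome
#'
#' Scans all six reading frames of the circle, capturing ORFs that span the
#' origin junction. An ORF runs from a start codon (ATG by default) to the
#' next in-frame stop; the stop codon is included in the interval but
#' excluded from the protein. ORFs whose start positions coincide modulo the
#' genome length are reported once. A reading frame with no in-frame stop
#' anywhere on the circle is reported with `no_stop = TRUE` and its length
#' capped at the genome length.
#'
#' @param genome A [cress_genome].
#' @param min_aa Minimum protein length in amino acids (default 101, i.e. the
#'   strictly-greater-than-100 major-ORF rule).
#' @param require_atg Require an ATG start codon (default `TRUE`); if
#'   `FALSE`, any codon following a stop can open an ORF.
#' @return A tibble sorted by `aa_len` descending (ties: smaller `start`,
#'   then `+` strand) with columns `orf_id`, `start`, `end` (0-based
#'   half-open forward-genome coordinates; `end` may exceed the genome
#'   length), `strand`, `frame`, `aa_len`, `protein`, `starts_with_atg`,
#'   `no_stop`, `spliced`.
#' @export
find_orfs <- function(genome, min_aa = 101L, require_atg = TRUE) {
  stopifnot(inherits(genome, "cress_genome"))
  if (min_aa < 1L) abort("min_aa must be >= 1")
  L <- genome_length(genome)
  fwd <- scan_strand_orfs(genome$seq, L, genome$circular, require_atg)
  rc <- revcomp_chr(genome$seq)
  rev <- scan_strand_orfs(rc, L, genome$circular, require_atg)

  rows <- list()
  for (o in fwd) {
    rows[[length(rows) + 1L]] <-
      tibble(start = o$start, end = o$start + o$len, strand = "+",
             aa_len = nchar(o$protein), protein = o$protein,
             no_stop = o$no_stop)
  }
  for (o in rev) {
    f0 <- (((L - (o$start + o$len)) %% L) + L) %% L
    rows[[length(rows) + 1L]] <-
      tibble(start = f0, end = f0 + o$len, strand = "-",
             aa_len = nchar(o$protein), protein = o$protein,
             no_stop = o$no_stop)
  }
  if (length(rows) == 0L) return(empty_orf_tbl())
  tbl <- list_rbind(rows)
  tbl <- tbl[!duplicated(tbl[, c("start", "strand")]), , drop = FALSE]
  tbl <- tbl[tbl$aa_len >= min_aa, , drop = FALSE]
  if (nrow(tbl) == 0L) return(empty_orf_tbl())
  tbl$frame <- tbl$start %% 3L
  tbl$starts_with_atg <- substr(tbl$protein, 1L, 1L) == "M" | !require_atg
  tbl$spliced <- FALSE
  tbl <- tbl[order(-tbl$aa_len, tbl$start, tbl$strand != "+"), , drop = FALSE]
  tbl$orf_id <- sprintf("%s_orf%02d", genome$id, seq_len(nrow(tbl)))
  select(tbl, "orf_id", "start", "end", "strand", "frame", "aa_len",
         "protein", "starts_with_atg", "no_stop", "spliced")
}

empty_orf_tbl <- function() {
  tibble(orf_id = character(), start = integer(), end = integer(),
         strand = character(), frame = integer(), aa_len = integer(),
         protein = character(), starts_with_atg = logical(),
         no_stop = logical(), spliced = logical())
}

#' Select the major, non-overlapping ORF set
#'
#' Greedy selection by descending protein length: an ORF is kept if its
#' circular overlap with every already-kept ORF does not exceed
#' `max_overlap_nt`. Ties in length are broken by smaller start position,
#' then by `+` strand.
#'
#' @param orfs ORF tibble from [find_orfs()].
#' @param genome_length Genome length in nt (needed for circular overlap).
#' @param max_overlap_nt Maximum tolerated pairwise overlap in nt (default 0:
#'   strictly non-overlapping).
#' @return The kept subset of `orfs`, in greedy acceptance order.
#' @export
select_major_orfs <- function(orfs, genome_length, max_overlap_nt = 0L) {
  if (nrow(orfs) == 0L) return(orfs)
  ord <- order(-orfs$aa_len, orfs$start, orfs$strand != "+")
  orfs <- orfs[ord, , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(orfs))) {
    ok <- TRUE
    for (j in keep) {
      ov <- circular_overlap(orfs$start[i], orfs$end[i],
                             orfs$start[j], orfs$end[j], genome_length)
      if (ov > max_overlap_nt) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
  }
  orfs[keep, , drop = FALSE]
}
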