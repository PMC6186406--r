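#' Circular genome objects
#'
#' A `cress_genome` is a covalently closed DNA sequence with an identifier,
#' optional metadata, and all coordinates interpreted modulo its length.
#' Internally the sequence is an uppercase character scalar over the IUPAC
#' DNA alphabet; coordinates everywhere in the package are 0-based half-open
#' (`[start, end)`), with `end` allowed to exceed the genome length to
#' represent origin-spanning features.
#'
#' @param id Record identifier (single string).
#' @param seq DNA sequence (single string; lowercase and `U` are normalised).
#' @param circular Logical; circular topology (default `TRUE`).
#' @param meta Named list of free-form metadata.
#' @param min_length Minimum accepted length in nt (pipeline entry floor).
#'
#' @return A `cress_genome` object.
#' @export
#' @examples
#' g <- cress_genome("g1", "acgtacgt")
#' genome_length(g)
cress_genome <- function(id, seq, circular = TRUE, meta = list(),
                         min_length = 0L) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- chartr("uU", "tT", seq)
  seq <- str_to_upper(seq)
  bad <- str_locate_all(seq, "[^ACGTRYSWKMBDHVN]")[[1]]
  if (nrow(bad) > 0L) {
    abort(sprintf("record '%s': non-IUPAC character '%s' at position %d",
                  id, substr(seq, bad[1, 1], bad[1, 1]), bad[1, 1]))
  }
  if (nchar(seq) < min_length) {
    abort(sprintf("record '%s': length %d below minimum %d",
                  id, nchar(seq), min_length))
  }
  structure(list(id = id, seq = seq, circular = isTRUE(circular), meta = meta),
            class = "cress_genome")
}

#' @export
print.cress_genome <- function(x, ...) {
  cat(sprintf("<cress_genome> %s: %d nt, %s\n", x$id, genome_length(x),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Genome length in nucleotides
#' @param genome A `cress_genome`.
#' @return Integer length.
#' @export
genome_length <- function(genome) nchar(genome$seq)

#' Rotate a circular genome
#'
#' Returns the genome re-originated at `offset` (0-based): the new sequence is
#' `seq[offset:] + seq[:offset]` with `offset` taken modulo the length. The
#' applied rotation is recorded in the metadata under `rotation`.
#'
#' @param genome A circular `cress_genome`.
#' @param offset Integer rotation offset (any integer; reduced mod length).
#' @return The rotated `cress_genome`.
#' @export
rotate_genome <- function(genome, offset) {
  if (!genome$circular) abort("cannot rotate a non-circular genome")
  L <- genome_length(genome)
  k <- ((as.integer(offset) %% L) + L) %% L
  if (k > 0L) {
    genome$seq <- paste0(substr(genome$seq, k + 1L, L), substr(genome$seq, 1L, k))
  }
  genome$meta$rotation <- (genome$meta$rotation %||% 0L) + k
  genome
}

#' Reverse complement of a genome or sequence string
#' @param x A `cress_genome` or a DNA string.
#' @return Object of the same type, reverse complemented.
#' @export
revcomp <- function(x) {
  if (inherits(x, "cress_genome")) {
    x$seq <- revcomp_chr(x$seq)
    return(x)
  }
  revcomp_chr(x)
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Extract a (possibly origin-spanning) subsequence [start, end) 0-based.
# `end` may exceed L; the sequence wraps. strand "-" returns the reverse
# complement of the forward-strand window.
subseq_circular <- function(genome, start, end, strand = "+") {
  L <- genome_length(genome)
  if (end <= start) abort("end must be > start")
  if (end - start > L) abort("feature longer than genome")
  len <- end - start
  start <- ((start %% L) + L) %% L
  doubled <- paste0(genome$seq, genome$seq)
  s <- substr(doubled, start + 1L, start + len)
  if (strand == "-") s <- revcomp_chr(s) else s
}

# Circular overlap (nt) between two 0-based half-open intervals on a circle
# of length L. Intervals are lists/rows with start, end (end may exceed L).
circular_overlap <- function(s1, e1, s2, e2, L) {
  # Represent each interval as a set of covered positions mod L; compare by
  # interval arithmetic on the doubled axis (each interval has length <= L).
  ov <- 0L
  a1 <- ((s1 %% L) + L) %% L; b1 <- a1 + (e1 - s1)
  a2 <- ((s2 %% L) + L) %% L; b2 <- a2 + (e2 - s2)
  for (shift in c(-L, 0L, L)) {
    lo <- max(a1, a2 + shift); hi <- min(b1, b2 + shift)
    if (hi > lo) ov <- ov + (hi - lo)
  }
  min(ov, L)
}
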