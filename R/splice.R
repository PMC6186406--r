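#' Recover an intron-interrupted (spliced) Rep gene
#'
#' Given two same-strand partial coding fragments of an interrupted gene --
#' typically two ORFs where the upstream fragment's stop falls inside a
#' suspected intron -- searches for a canonical `GT..AG` intron whose removal
#' joins the fragments into a single uninterrupted reading frame. Among valid
#' candidates the splice maximising the joined protein length is chosen; ties
#' are broken by the shortest intron, then by the leftmost donor.
#'
#' This is a minimal canonical-splice-site scan, not a trained gene model.
#'
#' @param genome A [cress_genome].
#' @param upstream,downstream Lists or single-row data frames with `start`,
#'   `end` (0-based half-open forward coordinates, `end` may exceed the
#'   genome length) and `strand`; both fragments must share a strand, with
#'   `upstream` 5' of `downstream` in gene orientation.
#' @param intron_min,intron_max Allowed intron length range in nt
#'   (defaults 50 and 300).
#' @return `NULL` if no valid splice exists, else a list with `donor_pos` and
#'   `acceptor_pos` (forward-genome 0-based positions of the first and last
#'   intron base in gene orientation), `intron_length`, `strand`,
#'   `joined_protein`, and `intron_start`/`intron_end` (forward-strand
#'   half-open interval of the intron).
#' @export
find_spliced_rep <- function(genome, upstream, downstream,
                             intron_min = 50L, intron_max = 300L) {
  stopifnot(inherits(genome, "cress_genome"))
  up <- as.list(upstream); dn <- as.list(downstream)
  if (up$strand != dn$strand) abort("fragments on different strands")
  strand <- up$strand
  L <- genome_length(genome)

  # Gene-space: position 0 is the first base of the upstream fragment, read
  # in gene orientation around the whole circle.
  if (strand == "+") {
    gs <- subseq_circular(genome, up$start, up$start + L, "+")
    off2 <- ((dn$start - up$start) %% L + L) %% L
  } else {
    gs <- subseq_circular(genome, up$end - L, up$end, "-")
    off2 <- ((up$end - dn$end) %% L + L) %% L
  }
  len1 <- up$end - up$start
  glen <- off2 + (dn$end - dn$start)   # gene-space end of downstream fragment
  if (glen > L) abort("fragments wrap past each other")

  ch <- strsplit(gs, "", fixed = TRUE)[[1]]
  dinuc <- paste0(ch[-length(ch)], ch[-1])
  donors <- which(dinuc == "GT")            # 1-based position of G
  acceptors <- which(dinuc == "AG")         # 1-based position of A
  donors <- donors[donors - 1L >= 3L & donors - 1L < glen]
  best <- NULL
  for (p1 in donors) {
    p <- p1 - 1L                            # 0-based intron start
    qs <- acceptors[acceptors + 1L - p1 + 1L >= intron_min &
                    acceptors + 1L - p1 + 1L <= intron_max]
    for (q1 in qs) {
      iend <- q1 + 1L                       # 0-based position after AG
      if (iend <= p || iend > glen - 3L) next
      ilen <- iend - p
      cds_len <- glen - ilen
      if (cds_len %% 3L != 0L) next
      cds <- paste0(substr(gs, 1L, p), substr(gs, iend + 1L, glen))
      codons <- substring(cds, seq(1L, cds_len - 2L, by = 3L),
                          seq(3L, cds_len, by = 3L))
      ncod <- length(codons)
      if (!codons[ncod] %in% c("TAA", "TAG", "TGA")) next
      if (any(codons[-ncod] %in% c("TAA", "TAG", "TGA"))) next
      prot <- translate_codons(codons[-ncod])
      if (substr(prot, 1L, 1L) != "M") next
      cand <- list(gp_donor = p, gp_intron_end = iend, ilen = ilen,
                   protein = prot)
      if (is.null(best) ||
          nchar(cand$protein) > nchar(best$protein) ||
          (nchar(cand$protein) == nchar(best$protein) && cand$ilen < best$ilen) ||
          (nchar(cand$protein) == nchar(best$protein) &&
           cand$ilen == best$ilen && cand$gp_donor < best$gp_donor)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)

  gp_to_fwd <- function(g) {
    if (strand == "+") ((up$start + g) %% L + L) %% L
    else ((up$end - 1L - g) %% L + L) %% L
  }
  donor_fwd <- gp_to_fwd(best$gp_donor)
  last_fwd <- gp_to_fwd(best$gp_intron_end - 1L)
  if (strand == "+") {
    istart <- donor_fwd; iend <- istart + best$ilen
  } else {
    istart <- last_fwd; iend <- istart + best$ilen
  }
  list(donor_pos = donor_fwd, acceptor_pos = last_fwd,
       intron_length = best$ilen, strand = strand,
       joined_protein = best$protein,
       intron_start = istart, intron_end = iend)
}
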