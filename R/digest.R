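#' Default six-cutter restriction enzyme table
#'
#' The twelve FastDigest enzymes used to linearise rolling-circle
#' amplification products into unit-length genomes. PdmI has an interrupted
#' palindrome with two free positions, written with `N` wildcards.
#'
#' @return Named character vector: enzyme name to recognition site.
#' @export
default_enzymes <- function() {
  c(BamHI = "GGATCC", EcoRV = "GATATC", HindIII = "AAGCTT", KpnI = "GGTACC",
    PstI = "CTGCAG", XhoI = "CTCGAG", SmaI = "CCCGGG", BglII = "AGATCT",
    EcoRI = "GAATTC", XbaI = "TCTAGA", NcoI = "CCATGG", PdmI = "GAANNNNTTC")
}

# All 0-based start positions of `site` (N = wildcard) on one strand of the
# circle: search the doubled prefix and deduplicate mod L.
site_positions_circular <- function(seq, site, L) {
  w <- nchar(site)
  extended <- paste0(seq, substr(seq, 1L, w - 1L))
  pat <- gsub("N", "[ACGT]", site, fixed = TRUE)
  m <- gregexpr(paste0("(?=", pat, ")"), extended, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  sort(unique((as.integer(m) - 1L) %% L))
}

#' In-silico restriction digest screen of a circular genome
#'
#' Searches both strands of the circle (including sites spanning the origin
#' junction) for each recognition site, and reports cut counts and circular
#' fragment lengths. An enzyme cutting exactly once linearises the circle to
#' unit length, mirroring the gel-excision screen used to recover complete
#' genomes; fragments between 1 and 4 kb are reported separately.
#'
#' The cut position is modelled at the first base of the recognition site.
#'
#' @param genome A [cress_genome].
#' @param enzymes Named character vector of recognition sites (default
#'   [default_enzymes()]). Sites must be 6-mers (PdmI-style interrupted sites
#'   may be longer) over `A`,`C`,`G`,`T` with `N` as the only wildcard.
#' @param window Length window (nt) for `fragments_in_window`
#'   (default `c(1000, 4000)`).
#' @return A tibble with one row per enzyme: `enzyme`, `site`, `n_cuts`,
#'   `cut_positions` (list), `fragment_lengths` (list),
#'   `unit_length_linearizer`, `fragments_in_window` (list).
#' @export
digest_screen <- function(genome, enzymes = default_enzymes(),
                          window = c(1000L, 4000L)) {
  stopifnot(inherits(genome, "cress_genome"))
  if (is.null(names(enzymes)) || any(!nzchar(names(enzymes))))
    abort("enzymes must be a named vector")
  bad <- !grepl("^[ACGTN]+$", enzymes)
  if (any(bad))
    abort(sprintf("degenerate letters other than N in site for %s",
                  names(enzymes)[bad][1]))
  L <- genome_length(genome)
  rc <- revcomp_chr(genome$seq)

  rows <- imap(enzymes, function(site, name) {
    fwd <- site_positions_circular(genome$seq, site, L)
    # Reverse-strand matches, mapped back to forward coordinates of the
    # site's first base on the forward strand.
    rev_raw <- site_positions_circular(rc, site, L)
    rev <- sort(unique((L - rev_raw - nchar(site)) %% L))
    cuts <- sort(unique(c(fwd, rev)))
    n <- length(cuts)
    frags <- if (n == 0L) integer(0)
             else if (n == 1L) L
             else diff(c(cuts, cuts[1] + L))
    tibble(enzyme = name, site = site, n_cuts = n,
           cut_positions = list(cuts), fragment_lengths = list(frags),
           unit_length_linearizer = n == 1L,
           fragments_in_window = list(frags[frags >= window[1] & frags <= window[2]]))
  })
  list_rbind(rows)
}
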