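#' Nonanucleotide motifs observed across CRESS DNA genomes
#'
#' The degenerate canonical nick-site motif is `NANTATTAC`; this extended
#' list collects distinct nonamers reported from annotated CRESS DNA genomes
#' that are matched exactly in addition to the canonical pattern.
#'
#' @return Character vector of 9-mers.
#' @export
extended_nonamers <- function() {
  c("TAGTATTAC", "TAATACTAC", "CAGTATTAC", "CATTATTAC", "TATGTGTAA",
    "TAATATTAT", "TAACATTGT", "TAACACTGT", "TAATGTTAT", "TAATACTAT",
    "TAGTGTTAC", "TATTATTAC", "TAGCACTAA", "TAATATTAC", "TAATGTTAC",
    "TAATAGTAG", "CAACCACTC")
}

CANONICAL_NONAMER_PATTERN <- "NANTATTAC"

# Mismatches of every circular 9-mer window of `s` against the canonical
# degenerate pattern (N positions free). Returns integer vector of length L.
canonical_mismatch_vector <- function(s, L) {
  ext <- paste0(s, substr(s, 1L, 8L))
  ch <- strsplit(ext, "", fixed = TRUE)[[1]]
  pat <- strsplit(CANONICAL_NONAMER_PATTERN, "", fixed = TRUE)[[1]]
  mm <- integer(L)
  for (k in seq_len(9L)) {
    if (pat[k] == "N") next
    mm <- mm + (ch[seq_len(L) + k - 1L] != pat[k])
  }
  mm
}

#' Find candidate nonanucleotide (nick-site) motifs
#'
#' Scans both strands of the circle for 9-mers matching the degenerate
#' canonical pattern `NANTATTAC` with at most `max_mismatch` mismatches at
#' the non-N positions, or exactly equal to an entry of the extended list.
#' Positions are forward-strand 0-based starts of the 9-mer window; a hit on
#' the `-` strand means the motif reads canonically on the reverse
#' complement of that window.
#'
#' @param genome A [cress_genome].
#' @param max_mismatch Maximum mismatches against the canonical pattern
#'   (default 1; values above 4 make the pattern vacuous and error).
#' @param extended_list Exact-match 9-mers (default [extended_nonamers()]).
#' @return Tibble sorted by (canonical source first, mismatches, position):
#'   `seq9`, `pos`, `strand`, `mismatches_vs_canonical`, `source`.
#' @export
find_nonamer_candidates <- function(genome, max_mismatch = 1L,
                                    extended_list = extended_nonamers()) {
  stopifnot(inherits(genome, "cress_genome"))
  if (max_mismatch > 4L) abort("max_mismatch > 4 makes the pattern vacuous")
  L <- genome_length(genome)
  rc <- revcomp_chr(genome$seq)
  ext_f <- paste0(genome$seq, substr(genome$seq, 1L, 8L))
  ext_r <- paste0(rc, substr(rc, 1L, 8L))

  scan_one <- function(s_ext, mmvec, strand) {
    hits <- list()
    can <- which(mmvec <= max_mismatch) - 1L
    for (p in can) {
      hits[[length(hits) + 1L]] <- tibble(
        seq9 = substr(s_ext, p + 1L, p + 9L), pos_native = p, strand = strand,
        mismatches_vs_canonical = mmvec[p + 1L], source = "canonical_pattern")
    }
    if (length(extended_list) > 0L) {
      for (nm in extended_list) {
        m <- gregexpr(paste0("(?=", nm, ")"), s_ext, perl = TRUE)[[1]]
        if (m[1] == -1L) next
        for (p in (as.integer(m) - 1L)) {
          if (p >= L) next
          hits[[length(hits) + 1L]] <- tibble(
            seq9 = nm, pos_native = p, strand = strand,
            mismatches_vs_canonical = mmvec[p + 1L], source = "extended_list")
        }
      }
    }
    if (length(hits) == 0L) return(NULL)
    list_rbind(hits)
  }

  fw <- scan_one(ext_f, canonical_mismatch_vector(genome$seq, L), "+")
  rv <- scan_one(ext_r, canonical_mismatch_vector(rc, L), "-")
  tbl <- bind_rows(fw, rv)
  if (is.null(tbl) || nrow(tbl) == 0L) {
    return(tibble(seq9 = character(), pos = integer(), strand = character(),
                  mismatches_vs_canonical = integer(), source = character()))
  }
  # Map reverse-strand native positions to forward-strand window starts.
  tbl$pos <- ifelse(tbl$strand == "+", tbl$pos_native,
                    ((L - tbl$pos_native - 9L) %% L + L) %% L)
  # A window can match both routes; keep one record per (pos, strand),
  # preferring the canonical source.
  tbl <- tbl[order(tbl$source != "canonical_pattern",
                   tbl$mismatches_vs_canonical, tbl$pos), , drop = FALSE]
  tbl <- tbl[!duplicated(tbl[, c("pos", "strand")]), , drop = FALSE]
  # Canonical hits beyond the tolerance exist only as extended-list matches;
  # report those with their true mismatch count but extended source.
  select(tbl, "seq9", "pos", "strand", "mismatches_vs_canonical", "source")
}

#' Detect a stem-loop (inverted repeat hairpin) around a nonamer hit
#'
#' Searches the windows flanking the motif (up to 60 nt each side) for the
#' highest-scoring inverted repeat whose loop contains the full nonamer.
#' Pair scoring: G:C pair +3, A:T pair +2, mismatch -2. Deterministic
#' tie-break: longer stem, then smaller loop. Returns `NULL` when the best
#' score is below `2 * min_stem`.
#'
#' @param genome A [cress_genome].
#' @param pos Forward-strand 0-based start of the 9-mer window.
#' @param min_stem,max_stem Stem length range in bp (defaults 5 and 14).
#' @param loop_min,loop_max Loop length range in nt (defaults 9 and 14).
#' @param max_stem_mismatch Maximum mispaired stem positions (default 1).
#' @param flank Search window each side of the motif (default 60 nt).
#' @return `NULL` or a list: `stem_len`, `mismatches_in_stem`, `score`,
#'   `loop_start`, `loop_len`, `arm5_start`, `arm3_start` (forward 0-based;
#'   positions may be negative or exceed the length, i.e. modular).
#' @export
detect_stem_loop <- function(genome, pos, min_stem = 5L, max_stem = 14L,
                             loop_min = 9L, loop_max = 14L,
                             max_stem_mismatch = 1L, flank = 60L) {
  stopifnot(inherits(genome, "cress_genome"))
  L <- genome_length(genome)
  # Local window centred on the motif; `off` maps local 1-based index of the
  # motif start.
  lo <- pos - flank - max_stem - loop_max
  hi <- pos + 9L + flank + max_stem + loop_max
  win <- subseq_circular(genome, lo, hi, "+")
  mstart <- pos - lo           # 0-based motif start within window
  ch <- strsplit(win, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  pair_score <- function(b1, b2) {
    ok <- comp[b1] == b2 & b1 %in% c("A", "C", "G", "T")
    sc <- ifelse(ok & b1 %in% c("G", "C"), 3L, ifelse(ok, 2L, -2L))
    list(score = sum(sc), mismatches = sum(!ok))
  }

  best <- NULL
  for (llen in loop_min:loop_max) {
    # Loop must contain the full nonamer: loop start from mstart+9-llen to mstart.
    for (lstart in (mstart + 9L - llen):mstart) {
      lend <- lstart + llen
      for (s in min_stem:max_stem) {
        a5 <- lstart - s; a3e <- lend + s
        if (a5 < 0L || a3e > length(ch)) next
        left <- ch[(a5 + 1L):lstart]
        right <- rev(ch[(lend + 1L):a3e])
        ps <- pair_score(left, right)
        if (ps$mismatches > max_stem_mismatch) next
        cand <- list(stem_len = s, mismatches_in_stem = ps$mismatches,
                     score = ps$score, loop_start = lo + lstart,
                     loop_len = llen, arm5_start = lo + a5,
                     arm3_start = lo + lend)
        if (is.null(best) || cand$score > best$score ||
            (cand$score == best$score && cand$stem_len > best$stem_len) ||
            (cand$score == best$score && cand$stem_len == best$stem_len &&
             cand$loop_len < best$loop_len)) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best) || best$score < 2L * min_stem) return(NULL)
  best$loop_start <- ((best$loop_start %% L) + L) %% L
  best$arm5_start <- ((best$arm5_start %% L) + L) %% L
  best$arm3_start <- ((best$arm3_start %% L) + L) %% L
  best
}

#' Call the putative origin of replication
#'
#' Chooses among nonamer candidates: apex-supported candidates (motif at the
#' apex of a detected stem-loop) are preferred, then canonical-pattern
#' matches with fewest mismatches, then highest stem-loop score, then
#' smallest position. If no candidate has apex support the best motif-only
#' hit is returned flagged `confidence = "motif_only"`.
#'
#' @param genome A [cress_genome].
#' @param candidates Tibble from [find_nonamer_candidates()]; found
#'   automatically when `NULL`.
#' @param ... Passed to [detect_stem_loop()].
#' @return `NULL` if there are no candidates, else a list with `nonamer`
#'   (`seq9`, `pos`, `strand`, `mismatches_vs_canonical`, `source`),
#'   `stemloop` (list or `NULL`) and `confidence`
#'   (`"apex_supported"`/`"motif_only"`).
#' @export
call_ori <- function(genome, candidates = NULL, ...) {
  if (is.null(candidates)) candidates <- find_nonamer_candidates(genome)
  if (nrow(candidates) == 0L) return(NULL)
  sl <- map(seq_len(nrow(candidates)),
            function(i) detect_stem_loop(genome, candidates$pos[i], ...))
  apex <- !vapply(sl, is.null, logical(1))
  score <- vapply(sl, function(x) if (is.null(x)) -Inf else x$score, double(1))
  ord <- order(!apex,
               candidates$source != "canonical_pattern",
               candidates$mismatches_vs_canonical,
               -score,
               candidates$pos)
  i <- ord[1]
  list(nonamer = as.list(candidates[i, ]),
       stemloop = sl[[i]],
       confidence = if (apex[i]) "apex_supported" else "motif_only")
}

#' Classify the genome organization genotype
#'
#' Computes the typing 4-tuple -- number of major ORFs, sense relation among
#' them, origin strand relative to Rep, and origin region relative to Rep --
#' and maps it to a genotype through the configurable type map.
#'
#' The origin region is decided by which intergenic gap (on the circle,
#' between major ORFs) contains the nonamer: the gap adjacent to Rep's 5'
#' end in Rep's reading orientation is `5prime_of_rep`, the gap adjacent to
#' its 3' end is `3prime_of_rep`, and an origin inside an ORF is
#' `within_orf`.
#'
#' @param ori Result of [call_ori()].
#' @param major_orfs Tibble from [select_major_orfs()].
#' @param rep_id `orf_id` of the Rep among `major_orfs`.
#' @param genome_length Genome length in nt.
#' @param type_map Genotype map (default [cress_type_map()]).
#' @return List: `genotype`, `n_major_orfs`, `sense_relation`,
#'   `ori_strand_rel_rep`, `ori_region`, `map_version`.
#' @export
classify_organization <- function(ori, major_orfs, rep_id, genome_length,
                                  type_map = cress_type_map()) {
  if (is.null(rep_id) || !rep_id %in% major_orfs$orf_id)
    abort("cannot type without Rep")
  if (is.null(ori)) abort("cannot type without a called ori")
  L <- genome_length
  rep <- major_orfs[major_orfs$orf_id == rep_id, ]
  n <- nrow(major_orfs)
  sense <- if (n <= 1L) "unisense"
           else if (length(unique(major_orfs$strand)) == 1L) "unisense"
           else "ambisense"
  strand_rel <- if (ori$nonamer$strand == rep$strand) "same" else "opposite"

  # Motif midpoint, then locate it relative to ORF bodies and gaps.
  mid <- (ori$nonamer$pos + 4L) %% L
  inside <- vapply(seq_len(n), function(i) {
    circular_overlap(mid, mid + 1L, major_orfs$start[i], major_orfs$end[i], L) > 0L
  }, logical(1))
  in_arc <- function(p, a, b, L) {
    # p inside the forward arc [a, b) on the circle.
    ((p - a) %% L + L) %% L < ((b - a) %% L + L) %% L
  }
  if (any(inside)) {
    region <- "within_orf"
  } else if (n == 2L) {
    # Two intergenic gaps; the one bounded by Rep's 5' terminus (its start
    # for + Reps, its end for - Reps) is the 5' region.
    other <- major_orfs[major_orfs$orf_id != rep_id, ][1, ]
    gap5 <- if (rep$strand == "+") {
      c(other$end %% L, rep$start %% L)          # ... other] --gap--> [rep 5'
    } else {
      c(rep$end %% L, other$start %% L)          # rep 5'] <--gap-- [other ...
    }
    region <- if (in_arc(mid, gap5[1], gap5[2], L)) "5prime_of_rep"
              else "3prime_of_rep"
  } else {
    # Fallback (1 or >2 ORFs): nearer Rep terminus along Rep's direction.
    if (rep$strand == "+") {
      d5 <- ((rep$start - mid) %% L + L) %% L
      d3 <- ((mid - rep$end) %% L + L) %% L
    } else {
      d5 <- ((mid - (rep$end - 1L)) %% L + L) %% L
      d3 <- (((rep$start - 1L) - mid) %% L + L) %% L
    }
    region <- if (d5 <= d3) "5prime_of_rep" else "3prime_of_rep"
  }
  gt <- genotype_from_tuple(n, sense, strand_rel, region, type_map)
  list(genotype = gt, n_major_orfs = n, sense_relation = sense,
       ori_strand_rel_rep = strand_rel, ori_region = region,
       map_version = attr(type_map, "map_version") %||% "unversioned")
}
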