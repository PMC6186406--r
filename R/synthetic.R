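# Residue pools used by the generator.
#
# The Rep background pool deliberately excludes every residue that could
# seed a spurious Rep-motif match (G, H, K, R, F, Y, W, I, L, V, M), so the
# leftmost-hit motif scan recovers exactly the planted instances.
REP_BACKGROUND_POOL <- c("A", "D", "E", "N", "P", "Q", "S", "T")
DISORDER_POOL <- c("E", "K", "S", "P", "Q", "G", "R", "A")
ORDER_POOL <- c("W", "F", "I", "L", "V", "Y", "C", "M")

# Fixed reverse-translation codon table. Codons are chosen so that shifted
# reading frames of a coding region cannot acquire start codons from
# background-residue junctions (no codon ends in AT, none starts with TG
# among the Rep background residues) and so the reverse strand of coding
# regions is peppered with TGA stops (serine = TCA).
CODON_TABLE <- c(A = "GCT", R = "CGT", N = "AAC", D = "GAC", C = "TGT",
                 Q = "CAA", E = "GAA", G = "GGT", H = "CAC", I = "ATT",
                 L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
                 S = "TCA", T = "ACT", W = "TGG", Y = "TAC", V = "GTT")

# Guard block planted immediately 5' of each gene's ATG (in gene space): it
# carries a stop codon in all three forward reading frames, so no upstream
# run-through reading frame can cross into the gene in any phase.
GENE_GUARD <- "TAACTAACTAA"

# Planted motif instances (each matches its pattern in rep_motif_patterns())
# and the 0-based amino-acid positions they occupy within the Rep protein.
REP_MOTIF_INSTANCES <- c("RCR-I" = "FTLTN", "RCR-II" = "HLH",
                         "RCR-III" = "YASK", "Walker-A" = "GPPGTGKS",
                         "Walker-B" = "IIDD", "Motif-C" = "LLSN",
                         "Arg-finger" = "R")
REP_MOTIF_POSITIONS <- c("RCR-I" = 15L, "RCR-II" = 40L, "RCR-III" = 60L,
                         "Walker-A" = 120L, "Walker-B" = 160L,
                         "Motif-C" = 190L, "Arg-finger" = 196L)

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

reverse_translate <- function(protein) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste(CODON_TABLE[aa], collapse = "")
}

#' Specification for a synthetic CRESS DNA genome
#'
#' Defines the architecture of a generated genome: total length, genome
#' organization genotype, nick-site nonamer and hairpin geometry, protein
#' lengths, capsid disorder character, and an optional Rep intron.
#'
#' @param length Genome length in nt; `NULL` draws uniformly from
#'   1700--3300.
#' @param organization_type Genotype `"I"`..`"VIII"` (default `"II"`).
#' @param nonamer Planted 9-mer (default the canonical `TAGTATTAC`).
#' @param stem_len Hairpin stem length in bp (default 8).
#' @param loop_len Hairpin loop length in nt (default 11; must hold the
#'   nonamer).
#' @param rep_len,capsid_len Protein lengths in aa, including the initial
#'   methionine (defaults 290 and 230; `rep_len` at least 220 so the
#'   motif-anchored trimmed Rep stays at or above 200 aa).
#' @param capsid_disordered Draw the capsid's first 100 residues from the
#'   disorder-promoting pool (default `TRUE`).
#' @param intron `NULL`, or `list(length =, aa_pos =)`: a `GT..AG` intron of
#'   that length inserted in the Rep before 0-based residue `aa_pos`
#'   (default position 145 when only a length is given).
#' @param seed Integer RNG seed.
#' @return A `cress_genome_spec` list.
#' @export
genome_spec <- function(length = NULL, organization_type = "II",
                        nonamer = "TAGTATTAC", stem_len = 8L, loop_len = 11L,
                        rep_len = 290L, capsid_len = 230L,
                        capsid_disordered = TRUE, intron = NULL, seed = 1L) {
  if (loop_len < 9L) abort("loop_len must be >= 9 to contain the nonamer")
  if (rep_len < 220L) abort("rep_len must be >= 220")
  if (nchar(nonamer) != 9L) abort("nonamer must be a 9-mer")
  if (!organization_type %in% cress_type_map()$genotype)
    abort("unknown organization_type")
  if (!is.null(intron)) {
    if (is.null(intron$aa_pos)) intron$aa_pos <- 145L
    if (is.null(intron$length)) abort("intron needs a length")
    if (intron$length < 50L) abort("intron length must be >= 50")
    if (intron$aa_pos < 102L || intron$aa_pos > rep_len - 102L)
      abort("intron aa_pos must leave both exon ORFs > 100 aa")
  }
  structure(list(length = length, organization_type = organization_type,
                 nonamer = toupper(nonamer), stem_len = as.integer(stem_len),
                 loop_len = as.integer(loop_len), rep_len = as.integer(rep_len),
                 capsid_len = as.integer(capsid_len),
                 capsid_disordered = isTRUE(capsid_disordered),
                 intron = intron, seed = as.integer(seed)),
            class = "cress_genome_spec")
}

make_rep_protein <- function(rep_len, split_m_at = NULL) {
  aa <- sample(REP_BACKGROUND_POOL, rep_len, replace = TRUE)
  aa[1] <- "M"
  for (nm in names(REP_MOTIF_INSTANCES)) {
    p <- REP_MOTIF_POSITIONS[[nm]]
    inst <- strsplit(REP_MOTIF_INSTANCES[[nm]], "", fixed = TRUE)[[1]]
    aa[(p + 1L):(p + length(inst))] <- inst
  }
  if (!is.null(split_m_at)) aa[split_m_at + 1L] <- "M"
  paste(aa, collapse = "")
}

make_capsid_protein <- function(capsid_len, disordered) {
  pool1 <- if (disordered) DISORDER_POOL else ORDER_POOL
  aa <- c("M", sample(pool1, min(99L, capsid_len - 1L), replace = TRUE))
  if (capsid_len > 100L)
    aa <- c(aa, sample(ORDER_POOL, capsid_len - 100L, replace = TRUE))
  paste(aa, collapse = "")
}

make_intron_seq <- function(len) {
  # GT A TAA [CT-filler] AG: the filler avoids A and G entirely, so the only
  # donor/acceptor dinucleotides are the planted ones, and the upstream
  # reading frame terminates at the planted TAA just inside the intron.
  if (len < 10L) abort("intron too short to build")
  filler <- paste(sample(c("C", "T"), len - 8L, replace = TRUE), collapse = "")
  paste0("GT", "A", "TAA", filler, "AG")
}

# Gene block in gene orientation: tri-frame stop guard, ATG.., stop.
make_gene_block <- function(protein, intron = NULL) {
  cds <- paste0(reverse_translate(protein), "TAA")
  if (!is.null(intron)) {
    cut <- 3L * intron$aa_pos
    cds <- paste0(substr(cds, 1L, cut), make_intron_seq(intron$length),
                  substr(cds, cut + 1L, nchar(cds)))
  }
  paste0(GENE_GUARD, cds)
}

GUARD_LEN <- nchar(GENE_GUARD)

#' Generate a synthetic CRESS DNA genome with ground truth
#'
#' Builds a circular genome realising the requested architecture: exactly
#' one planted nonamer at the apex of a perfect inverted repeat, a Rep CDS
#' carrying the RCR and SF3 helicase motifs in canonical order, a capsid CDS
#' placed according to the organization genotype (absent for the Rep-only
#' genotype VIII), compositionally ordered or disordered capsid N-terminus,
#' and uniform random background. The generator re-annotates its own output
#' with the package's ORF, motif and ori detectors and re-draws the random
#' background until the recovered annotation matches the planted truth
#' exactly, guaranteeing an unambiguous ground-truth channel. Deterministic
#' for a fixed seed.
#'
#' @param spec A [genome_spec()].
#' @param id Genome identifier (default derived from the seed).
#' @param max_redraw Background re-draw budget (default 50).
#' @return List: `genome` (a [cress_genome]) and `truth` (list: `ori_pos`,
#'   `ori_strand`, `nonamer`, `rep_start`, `rep_end`, `rep_strand`,
#'   `capsid_start`, `capsid_end`, `capsid_strand`, `rep_protein`,
#'   `capsid_protein`, `rep_motif_positions`, `organization_type`,
#'   `intron_start`, `intron_end`, plus the placement tuple).
#' @export
generate_genome <- function(spec, id = NULL, max_redraw = 50L) {
  stopifnot(inherits(spec, "cress_genome_spec"))
  set.seed(spec$seed)
  if (is.null(id)) id <- sprintf("syn%05d", spec$seed %% 100000L)
  tm <- cress_type_map()
  row <- tm[tm$genotype == spec$organization_type, ]
  n_orfs <- row$canonical_n_orfs
  sense <- row$canonical_sense
  ori_strand_rel <- row$canonical_ori_strand
  ori_region <- row$canonical_ori_region

  L <- spec$length %||% sample(1700:3300, 1L)
  rep_strand <- if (ori_strand_rel == "same") "+" else "-"
  cap_strand <- if (n_orfs < 2L) NA_character_
                else if (sense == "unisense") rep_strand
                else if (rep_strand == "+") "-" else "+"

  for (attempt in seq_len(max_redraw)) {
    res <- try(build_genome_once(spec, id, L, rep_strand, cap_strand,
                                 ori_region, n_orfs), silent = TRUE)
    if (inherits(res, "try-error")) {
      if (grepl("spec overflow", res)) abort("spec overflow")
      next
    }
    if (generator_truth_check(res)) return(res)
  }
  abort("generator failed to realise an unambiguous genome (redraw budget)")
}

build_genome_once <- function(spec, id, L, rep_strand, cap_strand,
                              ori_region, n_orfs) {
  # Hairpin block: GC-rich perfect stem, nonamer at the loop apex.
  arm5 <- paste(sample(c("G", "C"), spec$stem_len, replace = TRUE), collapse = "")
  lpad <- (spec$loop_len - 9L) %/% 2L
  loop <- paste0(rand_dna(lpad), spec$nonamer,
                 rand_dna(spec$loop_len - 9L - lpad))
  ori_block <- paste0(arm5, loop, revcomp_chr(arm5))
  nonamer_off <- spec$stem_len + lpad       # offset of nonamer in ori_block

  rep_gene <- make_gene_block(make_rep_protein(spec$rep_len,
                                               split_m_at = spec$intron$aa_pos),
                              spec$intron)
  cap_gene <- if (n_orfs >= 2L)
    make_gene_block(make_capsid_protein(spec$capsid_len, spec$capsid_disordered))
  else NULL

  # Canvas: S0 ORI S1 G1 S2 [G2] S3 (circular). The origin always sits in
  # the wrap gap between the last and first gene, so which slot holds Rep
  # and its orientation realise the requested ori region.
  s0 <- 6L; s1 <- 20L; s2 <- if (is.null(cap_gene)) 0L else 36L
  rep_first <- (rep_strand == "+" && ori_region == "5prime_of_rep") ||
               (rep_strand == "-" && ori_region == "3prime_of_rep")
  if (is.null(cap_gene)) rep_first <- TRUE
  g1 <- if (rep_first) rep_gene else cap_gene
  g2 <- if (rep_first) cap_gene else rep_gene
  g1_strand <- if (rep_first) rep_strand else cap_strand
  g2_strand <- if (rep_first) cap_strand else rep_strand
  g1_placed <- if (identical(g1_strand, "-")) revcomp_chr(g1) else g1
  g2_placed <- if (!is.null(g2) && identical(g2_strand, "-")) revcomp_chr(g2) else g2

  fixed <- s0 + nchar(ori_block) + s1 + nchar(g1_placed) + s2 +
           (if (is.null(g2_placed)) 0L else nchar(g2_placed))
  s3 <- L - fixed
  if (s3 < 10L) abort("spec overflow")

  seqs <- c(rand_dna(s0), ori_block, rand_dna(s1), g1_placed,
            if (!is.null(g2_placed)) c(rand_dna(s2), g2_placed), rand_dna(s3))
  genome <- cress_genome(id, paste(seqs, collapse = ""))

  # Truth coordinates. Gene blocks carry a 3-nt stop guard before the ATG;
  # the annotated ORF interval starts at the ATG and includes the stop.
  ori_pos_plus <- s0 + nonamer_off
  g1_start <- s0 + nchar(ori_block) + s1
  g2_start <- if (is.null(g2_placed)) NA_integer_
              else g1_start + nchar(g1_placed) + s2
  orf_bounds <- function(block_start, block_len, strand) {
    if (strand == "+") c(block_start + GUARD_LEN, block_start + block_len)
    else c(block_start, block_start + block_len - GUARD_LEN)
  }
  rep_block_start <- if (rep_first) g1_start else g2_start
  cap_block_start <- if (is.null(cap_gene)) NA_integer_
                     else if (rep_first) g2_start else g1_start
  rb <- orf_bounds(rep_block_start, nchar(rep_gene), rep_strand)
  cb <- if (is.null(cap_gene)) c(NA_integer_, NA_integer_)
        else orf_bounds(cap_block_start, nchar(cap_gene), cap_strand)

  # The nonamer text is planted reading canonically on the forward strand;
  # Rep's strand alone realises the same/opposite ori-strand relation.
  ori_strand <- "+"
  ori_pos <- ori_pos_plus

  intron <- spec$intron
  intron_coords <- c(NA_integer_, NA_integer_)
  if (!is.null(intron)) {
    cut_gene_space <- GUARD_LEN + 3L * intron$aa_pos  # after guard + exon1 codons
    if (rep_strand == "+") {
      istart <- rep_block_start + cut_gene_space
      intron_coords <- c(istart, istart + intron$length)
    } else {
      iend_gs <- cut_gene_space + intron$length
      istart <- rep_block_start + nchar(rep_gene) - iend_gs
      intron_coords <- c(istart, istart + intron$length)
    }
  }

  truth <- list(
    ori_pos = ori_pos, ori_strand = ori_strand, nonamer = spec$nonamer,
    rep_start = rb[1], rep_end = rb[2], rep_strand = rep_strand,
    capsid_start = cb[1], capsid_end = cb[2], capsid_strand = cap_strand,
    rep_protein = NULL, capsid_protein = NULL,
    rep_motif_positions = REP_MOTIF_POSITIONS,
    organization_type = spec$organization_type,
    capsid_disordered = spec$capsid_disordered,
    n_orfs = n_orfs, sense_relation = if (n_orfs < 2L) "unisense" else
      (if (identical(rep_strand, cap_strand)) "unisense" else "ambisense"),
    ori_strand_rel_rep = if (ori_strand == rep_strand) "same" else "opposite",
    ori_region = ori_region,
    intron_start = intron_coords[1], intron_end = intron_coords[2],
    has_intron = !is.null(intron))
  list(genome = genome, truth = truth, spec = spec)
}

# Re-annotate a generated genome and verify the planted truth is recovered
# exactly and unambiguously.
generator_truth_check <- function(res) {
  g <- res$genome; tr <- res$truth
  orfs <- find_orfs(g)
  L <- genome_length(g)
  majors <- select_major_orfs(orfs, L)
  if (!tr$has_intron) {
    want <- list(c(tr$rep_start, tr$rep_end, tr$rep_strand))
    if (!is.na(tr$capsid_start))
      want <- c(want, list(c(tr$capsid_start, tr$capsid_end, tr$capsid_strand)))
    got <- lapply(seq_len(nrow(majors)), function(i)
      c(majors$start[i], majors$end[i], majors$strand[i]))
    if (length(got) != length(want)) return(FALSE)
    key <- function(x) paste(x, collapse = ":")
    if (!setequal(vapply(got, key, ""), vapply(want, key, ""))) return(FALSE)
    # Exactly one Rep by motif scan.
    reps <- vapply(seq_len(nrow(majors)), function(i)
      scan_rep_motifs(majors$protein[i])$is_rep, logical(1))
    if (sum(reps) != 1L) return(FALSE)
    rep_i <- which(reps)
    if (majors$start[rep_i] != tr$rep_start) return(FALSE)
  }
  # Ori must be recovered exactly and without a rival apex-supported exact hit.
  cand <- find_nonamer_candidates(g)
  ori <- call_ori(g, cand)
  if (is.null(ori) || ori$confidence != "apex_supported") return(FALSE)
  if (ori$nonamer$pos != tr$ori_pos || ori$nonamer$strand != tr$ori_strand)
    return(FALSE)
  rivals <- cand[cand$pos != tr$ori_pos | cand$strand != tr$ori_strand, ,
                 drop = FALSE]
  if (nrow(rivals) > 0L) {
    for (i in seq_len(nrow(rivals))) {
      if (rivals$mismatches_vs_canonical[i] > ori$nonamer$mismatches_vs_canonical)
        next
      sl <- detect_stem_loop(g, rivals$pos[i])
      if (!is.null(sl)) return(FALSE)
    }
  }
  # Genotype via the shared map.
  if (!tr$has_intron) {
    org <- classify_organization(ori, majors, majors$orf_id[which(reps)], L)
    if (org$genotype != tr$organization_type) return(FALSE)
  }
  TRUE
}

#' Mutate a genome into an isolate
#'
#' Applies per-site independent substitutions (to a uniformly chosen
#' different base) at rate `sub_rate` and indel events at rate `indel_rate`
#' (geometric(0.5) lengths, insertion or deletion with equal probability).
#' The returned genome carries a `coord_map` attribute mapping each original
#' position (0-based) to its new position (`NA` when deleted), so planted
#' feature positions can be tracked through mutation.
#'
#' @param genome A [cress_genome].
#' @param sub_rate Substitution probability per site, in `[0, 0.6]`.
#' @param indel_rate Indel event probability per site, in `[0, 0.05]`.
#' @param seed Integer RNG seed.
#' @param id Identifier for the mutant (default parent id + suffix).
#' @return A [cress_genome] with attribute `coord_map`.
#' @export
mutate_isolate <- function(genome, sub_rate, indel_rate = 0, seed = 1L,
                           id = NULL) {
  stopifnot(inherits(genome, "cress_genome"))
  if (sub_rate < 0 || sub_rate > 0.6) abort("sub_rate out of [0, 0.6]")
  if (indel_rate < 0 || indel_rate > 0.05) abort("indel_rate out of [0, 0.05]")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(genome$seq, "", fixed = TRUE)[[1]]
  L <- length(ch)
  sub_at <- which(runif(L) < sub_rate)
  for (i in sub_at) {
    ch[i] <- sample(setdiff(bases, ch[i]), 1L)
  }
  coord <- seq_len(L) - 1L   # old 0-based -> new 0-based
  if (indel_rate > 0) {
    ev <- which(runif(L) < indel_rate)
    pieces <- as.list(ch)
    deleted <- rep(FALSE, L)
    ins_len <- rep(0L, L)
    for (i in ev) {
      if (deleted[i]) next
      len <- rgeom(1L, 0.5) + 1L
      if (runif(1) < 0.5) {
        pieces[[i]] <- paste0(paste(sample(bases, len, replace = TRUE),
                                    collapse = ""), ch[i])
        ins_len[i] <- len
      } else {
        to <- min(L, i + len - 1L)
        for (k in i:to) { pieces[[k]] <- ""; deleted[k] <- TRUE }
      }
    }
    keep_len <- ifelse(deleted, 0L, 1L) + ins_len
    newpos <- cumsum(c(0L, head(keep_len, -1L))) + ins_len
    coord <- ifelse(deleted, NA_integer_, newpos)
    seqout <- paste(unlist(pieces), collapse = "")
  } else {
    seqout <- paste(ch, collapse = "")
  }
  out <- cress_genome(id %||% paste0(genome$id, "_mut"), seqout,
                      circular = genome$circular, meta = genome$meta)
  attr(out, "coord_map") <- coord
  out
}

#' Generate a labelled reference/isolate panel at controlled identity bands
#'
#' Builds `n_families` independent synthetic families; within each family,
#' `n_species` species exemplars whose realised pairwise identities versus
#' the other exemplars fall in the `between_species` band, and
#' `isolates_per_species` isolates per species inside the `within_species`
#' band versus their exemplar. Identities are realised by rejection-sampling
#' the substitution rate against the package's own pairwise-identity
#' measurement, so the bands hold in realised (alignment) terms. Optional
#' `novel_per_family` queries are pushed into the `between_family` band,
#' below every family floor.
#'
#' @param n_species Species per family.
#' @param isolates_per_species Isolates per species (exemplar excluded).
#' @param identity_bands Named list of `c(lo, hi)` fractions:
#'   `within_species`, `between_species`, `between_family`. Defaults sit
#'   at least 3 identity points away from the default demarcation
#'   thresholds.
#' @param seed Integer seed.
#' @param n_families Number of families (default 2; labels cycle through the
#'   genome-based families of [demarcation_rules()]).
#' @param novel_per_family Extra unassignable queries per family (default 0).
#' @param spec_template A [genome_spec()] used for family ancestors.
#' @return List: `genomes` (named list of [cress_genome]), `truth` (tibble:
#'   `id`, `family`, `genus`, `species`, `role` = exemplar/isolate/novel,
#'   `ori_pos`), `bands`.
#' @export
make_reference_panel <- function(n_species, isolates_per_species,
                                 identity_bands = list(
                                   within_species = c(0.85, 0.95),
                                   between_species = c(0.60, 0.74),
                                   between_family = c(0.40, 0.50)),
                                 seed = 1L, n_families = 2L,
                                 novel_per_family = 0L,
                                 spec_template = NULL) {
  for (b in identity_bands) {
    if (b[1] > b[2]) abort("infeasible band (lo > hi)")
  }
  if (n_species == 0L || n_families == 0L) {
    return(list(genomes = list(),
                truth = tibble(id = character(), family = character(),
                               genus = character(), species = character(),
                               role = character(), ori_pos = integer()),
                bands = identity_bands))
  }
  fams <- c("Circoviridae", "Genomoviridae", "Smacoviridae")
  fams <- rep(fams, length.out = n_families)
  genomes <- list()
  rows <- list()
  counter <- 0L

  # Rejection-mutate `parent` until realised PI versus every genome in
  # `versus` lies in `band` (and below `below` versus each of `avoid`).
  mutate_to_band <- function(parent, band, versus, rng_base,
                             avoid = list(), below = 1) {
    target <- 1 - mean(band)
    p <- target
    for (it in 1:200) {
      cand <- mutate_isolate(parent, sub_rate = p, seed = rng_base + it)
      pis <- vapply(versus, function(v)
        as.numeric(pairwise_identity(cand$seq, v$seq, "nt")), double(1))
      ok <- all(pis >= band[1] & pis <= band[2])
      if (ok && length(avoid) > 0L) {
        apis <- vapply(avoid, function(v)
          as.numeric(pairwise_identity(cand$seq, v$seq, "nt")), double(1))
        ok <- all(apis < below)
      }
      if (ok) return(cand)
      if (max(pis) > band[2]) p <- min(0.6, p * 1.15 + 0.005)
      else if (min(pis) < band[1]) p <- max(0.005, p * 0.85)
    }
    abort("could not realise requested identity band")
  }

  for (f in seq_len(n_families)) {
    fam <- fams[f]
    fseed <- seed * 1000L + f
    spec <- spec_template %||% genome_spec(length = 2000L, seed = fseed)
    spec$seed <- fseed
    anc <- generate_genome(spec, id = sprintf("F%02dS01", f))
    exemplars <- list(anc$genome)
    ori_pos <- anc$truth$ori_pos
    counter <- counter + 1L
    rows[[counter]] <- tibble(id = anc$genome$id, family = fam,
                              genus = paste0(fam, "_genus1"),
                              species = sprintf("%s_sp1", fam),
                              role = "exemplar", ori_pos = ori_pos)
    genomes[[anc$genome$id]] <- anc$genome
    if (n_species > 1L) {
      for (s in 2:n_species) {
        # Band holds versus the ancestor (the nearest exemplar); the other
        # exemplars must simply stay below the band ceiling so the species
        # threshold can never fire against them.
        ex <- mutate_to_band(anc$genome, identity_bands$between_species,
                             exemplars[1], rng_base = fseed * 100L + s * 1000L,
                             avoid = exemplars[-1],
                             below = identity_bands$between_species[2])
        ex$id <- sprintf("F%02dS%02d", f, s)
        exemplars <- c(exemplars, list(ex))
        genomes[[ex$id]] <- ex
        counter <- counter + 1L
        rows[[counter]] <- tibble(id = ex$id, family = fam,
                                  genus = paste0(fam, "_genus1"),
                                  species = sprintf("%s_sp%d", fam, s),
                                  role = "exemplar", ori_pos = ori_pos)
      }
    }
    for (s in seq_len(n_species)) {
      for (k in seq_len(isolates_per_species)) {
        iso <- mutate_to_band(exemplars[[s]], identity_bands$within_species,
                              exemplars[s],
                              rng_base = fseed * 100L + s * 1000L + k * 7L)
        iso$id <- sprintf("F%02dS%02dI%02d", f, s, k)
        genomes[[iso$id]] <- iso
        counter <- counter + 1L
        rows[[counter]] <- tibble(id = iso$id, family = fam,
                                  genus = paste0(fam, "_genus1"),
                                  species = sprintf("%s_sp%d", fam, s),
                                  role = "isolate", ori_pos = ori_pos)
      }
    }
    if (novel_per_family > 0L) {
      for (k in seq_len(novel_per_family)) {
        nv <- mutate_to_band(anc$genome, identity_bands$between_family,
                             exemplars[1],
                             rng_base = fseed * 100L + 90000L + k * 11L,
                             avoid = exemplars[-1], below = 0.52)
        nv$id <- sprintf("F%02dN%02d", f, k)
        genomes[[nv$id]] <- nv
        counter <- counter + 1L
        rows[[counter]] <- tibble(id = nv$id, family = fam,
                                  genus = NA_character_,
                                  species = NA_character_,
                                  role = "novel", ori_pos = ori_pos)
      }
    }
  }
  list(genomes = genomes, truth = list_rbind(rows), bands = identity_bands)
}
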