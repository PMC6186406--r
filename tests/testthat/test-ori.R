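# Background free of canonical-pattern nonamer hits (both strands).
clean_background <- function(n, seed) {
  set.seed(seed)
  repeat {
    s <- random_dna(n)
    g <- cress_genome("bg", s, min_length = 0)
    if (nrow(find_nonamer_candidates(g)) == 0L) return(s)
  }
}

test_that("nonamer candidates match the degenerate pattern and extended list", {
  bg <- clean_background(800, 1)
  plant_at <- function(motif, at) {
    cress_genome("g", paste0(substr(bg, 1, at), motif,
                             substr(bg, at + 10, nchar(bg))))
  }
  hits <- find_nonamer_candidates(plant_at("TAGTATTAC", 200))
  expect_equal(hits$pos[1], 200L)
  expect_equal(hits$mismatches_vs_canonical[1], 0L)
  expect_equal(hits$source[1], "canonical_pattern")

  # Non-canonical motif reachable only through the extended list.
  h2 <- find_nonamer_candidates(plant_at("TATGTGTAA", 200))
  expect_true(all(h2$source == "extended_list"))
  expect_true(all(h2$mismatches_vs_canonical > 1L))
  expect_equal(h2$pos[h2$seq9 == "TATGTGTAA"], 200L)
  expect_equal(nrow(find_nonamer_candidates(plant_at("TATGTGTAA", 200),
                                            extended_list = character(0))), 0L)

  # Motif planted as reverse complement is reported on the minus strand.
  h3 <- find_nonamer_candidates(plant_at("GTAATACTA", 300))
  expect_equal(h3$strand[h3$seq9 == "TAGTATTAC"], "-")
  expect_equal(h3$pos[h3$seq9 == "TAGTATTAC"], 300L)

  expect_error(find_nonamer_candidates(plant_at("TAGTATTAC", 10),
                                       max_mismatch = 5L), "vacuous")
})

test_that("stem-loop detection scores constructed hairpins exactly", {
  bg <- clean_background(700, 3)
  hairpin <- paste0("GGCGGCGG", "C", "TAGTATTAC", "T", "CCGCCGCC")
  g <- cress_genome("h", paste0(substr(bg, 1, 300), hairpin,
                                substr(bg, 301, nchar(bg))))
  pos <- 300L + 8L + 1L
  sl <- detect_stem_loop(g, pos)
  expect_equal(sl$stem_len, 8L)
  expect_equal(sl$mismatches_in_stem, 0L)
  expect_equal(sl$score, 24L)       # 8 G:C pairs at +3 each
  expect_equal(sl$loop_len, 11L)

  # One mispaired stem position: tolerated at the default, gated at 0.
  hp2 <- paste0("GGCGGCGG", "C", "TAGTATTAC", "T", "CCGCCGAC")
  g2 <- cress_genome("h2", paste0(substr(bg, 1, 300), hp2,
                                  substr(bg, 301, nchar(bg))))
  sl2 <- detect_stem_loop(g2, pos)
  expect_equal(sl2$mismatches_in_stem, 1L)
  sl2b <- detect_stem_loop(g2, pos, max_stem_mismatch = 0L)
  expect_true(is.null(sl2b) || sl2b$mismatches_in_stem == 0L)

  # Repeat-free flank: no apex support.
  g3 <- cress_genome("h3", paste0(substr(bg, 1, 300), "TAGTATTAC",
                                  substr(bg, 310, nchar(bg))))
  expect_null(detect_stem_loop(g3, 300L, max_stem_mismatch = 0L))
})

test_that("ori calling prefers apex-supported candidates", {
  bg <- clean_background(900, 5)
  hairpin <- paste0("GGCGGCGG", "C", "TAGTATTAC", "T", "CCGCCGCC")
  with_both <- paste0(substr(bg, 1, 200), hairpin,
                      substr(bg, 201, 500), "TAGTATTAC",
                      substr(bg, 510, nchar(bg)))
  g <- cress_genome("o", with_both)
  ori <- call_ori(g)
  expect_equal(ori$confidence, "apex_supported")
  expect_equal(ori$nonamer$pos, 209L)

  expect_null(call_ori(cress_genome("none", clean_background(600, 6),
                                    min_length = 0)))

  # Motif without hairpin support is still returned, flagged.
  g2 <- cress_genome("m", paste0(substr(bg, 1, 500), "TAGTATTAC",
                                 substr(bg, 510, nchar(bg))))
  ori2 <- call_ori(g2)
  expect_equal(ori2$confidence, "motif_only")
  expect_equal(ori2$nonamer$seq9, "TAGTATTAC")
})

test_that("the genotype map is a total deterministic function of the 4-tuple", {
  regions <- c("5prime_of_rep", "3prime_of_rep", "within_orf")
  for (n in c(1L, 2L, 3L)) {
    for (sense in c("unisense", "ambisense")) {
      for (strand in c("same", "opposite")) {
        for (region in regions) {
          gt <- genotype_from_tuple(n, sense, strand, region)
          expect_length(gt, 1L)
          expect_true(gt %in% c("I", "II", "III", "IV", "V", "VI", "VII", "VIII"))
          if (n == 1L) expect_equal(gt, "VIII")
        }
      }
    }
  }
  # Anchor rows of the default map.
  expect_equal(genotype_from_tuple(2L, "ambisense", "same", "5prime_of_rep"), "II")
  expect_equal(genotype_from_tuple(2L, "unisense", "same", "5prime_of_rep"), "V")
})

test_that("classify_organization types ambisense/unisense arrangements", {
  for (gt in c("II", "V", "VIII")) {
    r <- generate_genome(genome_spec(length = 2000L, organization_type = gt,
                                     seed = 100L + match(gt, c("II", "V", "VIII"))))
    g <- r$genome
    majors <- select_major_orfs(find_orfs(g), genome_length(g))
    reps <- vapply(seq_len(nrow(majors)),
                   function(i) scan_rep_motifs(majors$protein[i])$is_rep,
                   logical(1))
    ori <- call_ori(g)
    org <- classify_organization(ori, majors, majors$orf_id[which(reps)],
                                 genome_length(g))
    expect_equal(org$genotype, gt)
  }
  r <- generate_genome(genome_spec(length = 2000L, seed = 104L))
  majors <- select_major_orfs(find_orfs(r$genome), 2000L)
  expect_error(classify_organization(call_ori(r$genome), majors, "nope", 2000L),
               "cannot type without Rep")
})

test_that("called ori is rotation and reverse-complement invariant", {
  r <- generate_genome(genome_spec(length = 2000L, seed = 51L))
  g <- r$genome
  base <- call_ori(g)
  for (k in c(37L, 1234L)) {
    rot <- call_ori(rotate_genome(g, k))
    expect_equal(rot$nonamer$pos, (base$nonamer$pos - k) %% 2000L)
    expect_equal(rot$nonamer$seq9, base$nonamer$seq9)
  }
  rc <- call_ori(revcomp(g))
  expect_equal(rc$nonamer$seq9, base$nonamer$seq9)
  expect_equal(rc$nonamer$pos, (2000L - base$nonamer$pos - 9L) %% 2000L)
  expect_equal(rc$nonamer$strand, if (base$nonamer$strand == "+") "-" else "+")
})
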