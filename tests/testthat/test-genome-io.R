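test_that("genome construction validates and normalises sequences", {
  g <- cress_genome("g1", "acgu")
  expect_equal(g$seq, "ACGT")
  expect_equal(genome_length(g), 4L)
  expect_error(cress_genome("g1", "ACJT"), "g1.*'J' at position 3")
  expect_error(cress_genome("short", "ACGT", min_length = 200L), "below minimum")
})

test_that("rotation is a group action on the circle", {
  g <- cress_genome("g", "ACGT")
  expect_equal(rotate_genome(g, 0)$seq, "ACGT")
  expect_equal(rotate_genome(g, 2)$seq, "GTAC")
  set.seed(11)
  big <- cress_genome("b", random_dna(733))
  for (k in c(1L, 100L, 732L, 733L, 1000L)) {
    back <- rotate_genome(rotate_genome(big, k), 733L - (k %% 733L))
    expect_equal(back$seq, big$seq)
  }
  lin <- cress_genome("l", "ACGT", circular = FALSE)
  expect_error(rotate_genome(lin, 1), "non-circular")
})

test_that("FASTA read/write round-trips and validates", {
  set.seed(2)
  gs <- list(cress_genome("a", random_dna(300)),
             cress_genome("b", random_dna(450)),
             cress_genome("c", random_dna(210)))
  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_genome_fasta(gs, tmp)
  back <- read_genome_fasta(tmp)
  expect_equal(names(back), c("a", "b", "c"))
  expect_equal(vapply(back, function(g) g$seq, ""),
               vapply(gs, function(g) g$seq, ""),
               ignore_attr = TRUE)

  tmp2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1", "ACGTJACGT"), tmp2)
  expect_error(read_genome_fasta(tmp2, min_length = 0), "g1")
  tmp3 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), tmp3)
  expect_error(read_genome_fasta(tmp3), "no records")
})

test_that("digest screen finds sites on both strands and across the junction", {
  set.seed(3)
  body <- random_dna(997)
  body <- gsub("GAATTC", "GAATAC", body, fixed = TRUE)
  tail <- gsub("GAATTC", "GAATAC", random_dna(997), fixed = TRUE)
  g <- cress_genome("d", paste0(body, "GAATTC", tail))
  ds <- digest_screen(g)
  eco <- ds[ds$enzyme == "EcoRI", ]
  expect_equal(eco$n_cuts, 1L)
  expect_true(eco$unit_length_linearizer)
  expect_equal(eco$fragment_lengths[[1]], genome_length(g))

  # No-site enzyme: empty fragment list.
  noc <- ds[ds$n_cuts == 0L, ]
  expect_true(all(lengths(noc$fragment_lengths) == 0L))

  # Site split across the origin junction (last 3 + first 3 nt).
  mid <- gsub("GAATTC", "GAATAC", random_dna(1994), fixed = TRUE)
  gj <- cress_genome("j", paste0("TTC", mid, "GAA"))
  dj <- digest_screen(gj)
  expect_equal(dj$n_cuts[dj$enzyme == "EcoRI"], 1L)

  expect_error(digest_screen(g, c(bad = "GARTTC")), "degenerate")
})

test_that("digest fragment multiset is rotation invariant", {
  set.seed(4)
  g <- cress_genome("r", random_dna(2100))
  base <- digest_screen(g)
  for (k in c(13L, 700L, 2099L)) {
    rot <- digest_screen(rotate_genome(g, k))
    for (i in seq_len(nrow(base))) {
      expect_equal(sort(rot$fragment_lengths[[i]]),
                   sort(base$fragment_lengths[[i]]),
                   info = base$enzyme[i])
      if (base$n_cuts[i] >= 1L) {
        expect_equal(sum(base$fragment_lengths[[i]]), genome_length(g))
      }
    }
  }
})

test_that("PdmI interrupted-palindrome site matches through N wildcards", {
  set.seed(5)
  flank <- gsub("GAA[ACGT]{4}TTC", "GAACCC", random_dna(600))
  g <- cress_genome("p", paste0(flank, "GAAGGCCTTC", flank))
  ds <- digest_screen(g)
  expect_gte(ds$n_cuts[ds$enzyme == "PdmI"], 1L)
})

test_that("GFF3 output round-trips, including split origin-spanning features", {
  g <- cress_genome("g", strrep("A", 2000))
  feats <- tibble::tibble(start = c(0L, 1950L), end = c(303L, 2050L),
                          strand = c("+", "-"), type = "CDS",
                          id = c("orf1", "wrap"), attributes = "")
  tmp <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(g, feats, tmp)
  lines <- readLines(tmp)
  expect_true(any(grepl("\t1\t303\t", lines)))          # 1-based shift
  expect_equal(sum(grepl("ID=wrap", lines)), 2L)        # two parts, same ID
  back <- read_gff3_intervals(tmp)
  back <- back[match(feats$id, back$id), ]
  expect_equal(back$start, feats$start)
  expect_equal(back$end, feats$end)
  expect_equal(back$strand, feats$strand)

  # Empty feature list: header-only file is still valid.
  tmp2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(g, feats[0, ], tmp2)
  expect_true(startsWith(readLines(tmp2)[1], "##gff-version 3"))
  expect_equal(nrow(read_gff3_intervals(tmp2)), 0L)

  expect_error(write_gff3(g, tibble::tibble(start = 0L, end = 2400L,
                                            strand = "+"), tmp),
               "longer than genome")
})
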