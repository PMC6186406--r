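# Stop-free random codons (no TAA/TAG/TGA, no internal ATG).
sense_codons <- function(n) {
  pool <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                    c("A", "C", "G", "T"),
                                    c("A", "C", "G", "T")), 1, paste,
                        collapse = ""),
                  c("TAA", "TAG", "TGA", "ATG"))
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

embed_orf <- function(n_codons, at, L = 2000L, seed = 1L) {
  set.seed(seed)
  insert <- paste0("TAA", "ATG", sense_codons(n_codons), "TAA")
  bg <- random_dna(L - nchar(insert))
  seq <- paste0(substr(bg, 1, at), insert, substr(bg, at + 1, nchar(bg)))
  cress_genome("t", seq)
}

test_that("the major-ORF length threshold is strictly greater than 100 aa", {
  g100 <- embed_orf(100, 500, seed = 7)   # ATG + 100 codons: 101 aa
  found <- find_orfs(g100, min_aa = 101L)
  expect_true(any(found$aa_len == 101L & found$strand == "+"))
  g99 <- embed_orf(99, 500, seed = 7)     # 100 aa: fails the strict filter
  expect_false(any(find_orfs(g99, min_aa = 101L)$aa_len == 100L))
  expect_true(any(find_orfs(g99, min_aa = 100L)$aa_len == 100L))
  expect_error(find_orfs(g99, min_aa = 0L), "min_aa")
})

test_that("origin-spanning ORFs are recovered with the identical protein", {
  set.seed(9)
  insert <- paste0("TAA", "ATG", sense_codons(120), "TAA")
  bg <- random_dna(2000 - nchar(insert))
  g0 <- cress_genome("lin", paste0(insert, bg))
  planted_prot <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(insert, 4, nchar(insert) - 3))))
  base <- find_orfs(g0)
  expect_true(planted_prot %in% base$protein)
  at <- genome_length(g0) - 150L  # ORF now starts 150 nt before the junction
  gw <- rotate_genome(g0, genome_length(g0) - at)
  wrapped <- find_orfs(gw)
  hit <- wrapped[wrapped$protein == planted_prot, ]
  expect_equal(nrow(hit), 1L)
  expect_gt(hit$end, genome_length(gw))  # interval crosses the origin
})

test_that("reverse-strand ORFs are found with mapped coordinates", {
  set.seed(10)
  insert <- paste0("TAA", "ATG", sense_codons(110), "TAA")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(insert)))
  bg <- random_dna(2000 - nchar(rc))
  g <- cress_genome("r", paste0(substr(bg, 1, 600), rc,
                                substr(bg, 601, nchar(bg))))
  found <- find_orfs(g)
  hit <- found[found$strand == "-" & found$aa_len == 111L, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 600L)  # block start; guard occupies the top 3 nt
  prot <- Biostrings::translate(Biostrings::DNAString(substr(insert, 4, nchar(insert) - 3)))
  expect_equal(hit$protein, as.character(prot))
})

test_that("ORF discovery is rotation and reverse-complement invariant", {
  r <- generate_genome(genome_spec(length = 2000L, seed = 31L))
  g <- r$genome
  key <- function(tbl) sort(paste(tbl$protein, tbl$strand))
  base <- find_orfs(g)
  for (k in c(17L, 901L, 1999L)) {
    expect_equal(key(find_orfs(rotate_genome(g, k))), key(base))
  }
  flipped <- find_orfs(revcomp(g))
  expect_equal(sort(flipped$protein), sort(base$protein))
  expect_equal(sort(paste(flipped$protein,
                          ifelse(flipped$strand == "+", "-", "+"))),
               key(base))
})

test_that("greedy major-ORF selection respects overlap and tie rules", {
  orfs <- tibble::tibble(
    orf_id = c("a", "b"), start = c(0L, 500L), end = c(306L, 806L),
    strand = "+", frame = 0L, aa_len = c(101L, 101L),
    protein = "x", starts_with_atg = TRUE, no_stop = FALSE, spliced = FALSE)
  expect_equal(nrow(select_major_orfs(orfs, 2000L)), 2L)

  nested <- tibble::tibble(
    orf_id = c("long", "inner"), start = c(100L, 160L), end = c(1000L, 700L),
    strand = "+", frame = 0L, aa_len = c(299L, 179L),
    protein = "x", starts_with_atg = TRUE, no_stop = FALSE, spliced = FALSE)
  kept <- select_major_orfs(nested, 2000L)
  expect_equal(kept$orf_id, "long")

  # 300 > 250 > 200 aa, mutually overlapping except overlap(300, 200) = 0:
  # greedy keeps {300, 200}.
  trio <- tibble::tibble(
    orf_id = c("a300", "b250", "c200"),
    start = c(0L, 850L, 950L), end = c(903L, 1603L, 1553L),
    strand = "+", frame = 0L, aa_len = c(300L, 250L, 200L),
    protein = "x", starts_with_atg = TRUE, no_stop = FALSE, spliced = FALSE)
  expect_equal(sort(select_major_orfs(trio, 2000L)$orf_id), c("a300", "c200"))
})

test_that("spliced Rep search recovers planted introns and applies tie-breaks", {
  r <- generate_genome(genome_spec(length = 2200L, seed = 41L,
                                   intron = list(length = 80L)))
  g <- r$genome
  majors <- select_major_orfs(find_orfs(g), genome_length(g))
  frg <- majors[majors$strand == r$truth$rep_strand, ]
  frg <- frg[order(frg$start), ]
  ord <- if (r$truth$rep_strand == "+") 1:2 else 2:1
  sp <- find_spliced_rep(g, frg[ord[1], ], frg[ord[2], ])
  expect_equal(sp$intron_start, r$truth$intron_start)
  expect_equal(sp$intron_end, r$truth$intron_end)
  expect_equal(nchar(sp$joined_protein), 290L)

  expect_error(
    find_spliced_rep(g, list(start = 0L, end = 300L, strand = "+"),
                     list(start = 400L, end = 700L, strand = "-")),
    "different strands")

  # Gap without any GT..AG pair yields nothing.
  set.seed(5)
  up <- paste0("TAA", "ATG", sense_codons(40))
  gapless <- paste(rep("C", 60), collapse = "")
  down <- paste0(sense_codons(40), "TAA")
  gg <- cress_genome("x", paste0(up, gapless, down, random_dna(1000)))
  expect_null(find_spliced_rep(gg,
                               list(start = 0L, end = nchar(up) + 3L, strand = "+"),
                               list(start = nchar(up) + nchar(gapless),
                                    end = nchar(up) + nchar(gapless) + nchar(down),
                                    strand = "+")))
})
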