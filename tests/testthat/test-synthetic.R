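test_that("generation is deterministic for a fixed seed", {
  a <- generate_genome(genome_spec(length = 2000L, seed = 5L))
  b <- generate_genome(genome_spec(length = 2000L, seed = 5L))
  expect_identical(a$genome$seq, b$genome$seq)
  expect_identical(a$truth, b$truth)
  c <- generate_genome(genome_spec(length = 2000L, seed = 6L))
  expect_false(identical(a$genome$seq, c$genome$seq))
})

test_that("generated genomes carry a consistent truth channel", {
  for (gt in c("I", "II", "III", "IV", "V", "VI", "VII", "VIII")) {
    r <- generate_genome(genome_spec(length = 2100L, organization_type = gt,
                                     seed = 200L + match(gt, c("I", "II", "III",
                                                               "IV", "V", "VI",
                                                               "VII", "VIII"))))
    g <- r$genome; tr <- r$truth
    # Planted nonamer really sits at the recorded apex position.
    win <- cressannot:::subseq_circular(g, tr$ori_pos, tr$ori_pos + 9L,
                                        tr$ori_strand)
    expect_equal(win, tr$nonamer, info = gt)
    # Rep CDS translates to a motif-complete protein.
    cds <- cressannot:::subseq_circular(g, tr$rep_start, tr$rep_end,
                                        tr$rep_strand)
    prot <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_false(grepl("\\*", substr(prot, 1, nchar(prot) - 1)), info = gt)
    sc <- scan_rep_motifs(sub("\\*$", "", prot))
    expect_true(sc$is_rep, info = gt)
    expect_equal(setNames(sc$hits$aa_pos, sc$hits$motif),
                 tr$rep_motif_positions, info = gt)
    if (gt == "VIII") {
      expect_true(is.na(tr$capsid_start))
    } else {
      expect_false(is.na(tr$capsid_start))
    }
  }
})

test_that("intron genomes splice back to a clean Rep", {
  r <- generate_genome(genome_spec(length = 2300L, seed = 77L,
                                   intron = list(length = 120L)))
  tr <- r$truth
  intron <- cressannot:::subseq_circular(r$genome, tr$intron_start,
                                         tr$intron_end, tr$rep_strand)
  expect_equal(substr(intron, 1, 2), "GT")
  expect_equal(substr(intron, nchar(intron) - 1, nchar(intron)), "AG")
  expect_equal(nchar(intron), 120L)
  # Genomic Rep span = coding length + intron length.
  expect_equal(tr$rep_end - tr$rep_start, 3L * (290L + 1L) + 120L)
})

test_that("spec validation rejects impossible architectures", {
  expect_error(genome_spec(loop_len = 8L), "loop_len")
  expect_error(genome_spec(rep_len = 100L), "rep_len")
  expect_error(genome_spec(intron = list(length = 80L, aa_pos = 10L)), "aa_pos")
  expect_error(generate_genome(genome_spec(length = 900L, seed = 1L)),
               "spec overflow")
})

test_that("mutation respects rates, bounds and the coordinate map", {
  set.seed(1)
  g <- cress_genome("m", random_dna(1500))
  expect_identical(mutate_isolate(g, 0, 0, seed = 2L)$seq, g$seq)
  expect_error(mutate_isolate(g, 0.7), "sub_rate")
  expect_error(mutate_isolate(g, 0.1, 0.2), "indel_rate")

  # Realized substitution fraction concentrates around the rate.
  p <- 0.2
  fr <- vapply(1:30, function(k) {
    m <- mutate_isolate(g, p, seed = k)
    a <- strsplit(g$seq, "")[[1]]; b <- strsplit(m$seq, "")[[1]]
    mean(a != b)
  }, double(1))
  expect_lt(abs(mean(fr) - p), 0.01)
  expect_true(all(abs(fr - p) < 4 * sqrt(p * (1 - p) / 1500)))

  # Indels shift downstream coordinates consistently.
  m <- mutate_isolate(g, 0, 0.01, seed = 3L)
  cm <- attr(m, "coord_map")
  expect_equal(length(cm), 1500L)
  live <- which(!is.na(cm))
  a <- strsplit(g$seq, "")[[1]]; b <- strsplit(m$seq, "")[[1]]
  expect_true(all(a[live] == b[cm[live] + 1L]))
})

test_that("reference panels realise the requested identity bands", {
  pan <- make_reference_panel(n_species = 2, isolates_per_species = 2,
                              seed = 11L, n_families = 1L,
                              novel_per_family = 1L)
  tt <- pan$truth
  exemplars <- tt$id[tt$role == "exemplar"]
  anc <- pan$genomes[[exemplars[1]]]
  # Within-species isolates versus their exemplar.
  for (s in 1:2) {
    ex <- pan$genomes[[exemplars[s]]]
    isos <- tt$id[tt$role == "isolate" & tt$species == tt$species[tt$id == exemplars[s]][1]]
    for (i in isos) {
      pi <- as.numeric(pairwise_identity(ex$seq, pan$genomes[[i]]$seq, "nt"))
      expect_gte(pi, pan$bands$within_species[1])
      expect_lte(pi, pan$bands$within_species[2])
    }
  }
  # Between-species exemplar pair.
  pi_bs <- as.numeric(pairwise_identity(pan$genomes[[exemplars[1]]]$seq,
                                        pan$genomes[[exemplars[2]]]$seq, "nt"))
  expect_gte(pi_bs, pan$bands$between_species[1])
  expect_lte(pi_bs, pan$bands$between_species[2])
  # Novel query sits below every family floor.
  nov <- tt$id[tt$role == "novel"]
  pi_nv <- as.numeric(pairwise_identity(anc$seq, pan$genomes[[nov]]$seq, "nt"))
  expect_lt(pi_nv, 0.52)

  empty <- make_reference_panel(0, 0, seed = 1L)
  expect_equal(length(empty$genomes), 0L)
  expect_equal(nrow(empty$truth), 0L)
  expect_error(make_reference_panel(1, 1, identity_bands = list(
    within_species = c(0.9, 0.8))), "infeasible")
})

test_that("cross-family panels stay below the family floor", {
  pan <- make_reference_panel(n_species = 1, isolates_per_species = 0,
                              identity_bands = list(
                                within_species = c(0.85, 0.95),
                                between_species = c(0.60, 0.74),
                                between_family = c(0.30, 0.50)),
                              seed = 21L, n_families = 2L,
                              novel_per_family = 1L)
  tt <- pan$truth
  a <- pan$genomes[[tt$id[tt$role == "exemplar"][1]]]
  nv <- pan$genomes[[tt$id[tt$role == "novel"][1]]]
  expect_lt(as.numeric(pairwise_identity(a$seq, nv$seq, "nt")), 0.55)
})
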