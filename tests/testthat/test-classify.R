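ref1 <- function(family, genus = NA_character_) {
  tibble::tibble(id = "ref", family = family, genus = genus,
                 species = "sp1")
}

call_at <- function(gpi, family, rep_pi = NULL, genus = NA_character_) {
  demarcate(ref1(family, genus), c(ref = gpi),
            if (is.null(rep_pi)) NULL else c(ref = rep_pi))
}

test_that("species thresholds use >= semantics at the exact family cut-offs", {
  expect_equal(call_at(0.80, "Circoviridae")$species_status, "known_species_variant")
  expect_equal(call_at(0.7999, "Circoviridae")$species_status, "new_species")
  expect_equal(call_at(0.78, "Genomoviridae")$species_status, "known_species_variant")
  expect_equal(call_at(0.7799, "Genomoviridae")$species_status, "new_species")
  expect_equal(call_at(0.77, "Smacoviridae", rep_pi = 0.5)$species_status,
               "known_species_variant")
  expect_equal(call_at(0.7699, "Smacoviridae", rep_pi = 0.5)$species_status,
               "new_species")
})

test_that("family floors use >= semantics and novelty rules are strict <", {
  expect_equal(call_at(0.55, "Circoviridae")$family, "Circoviridae")
  r <- call_at(0.5499, "Circoviridae")
  expect_equal(r$family, "unclassified")
  expect_equal(r$species_status, "unassigned")      # < 0.70
  expect_equal(call_at(0.53, "Genomoviridae")$family, "Genomoviridae")
  expect_equal(call_at(0.5299, "Genomoviridae")$family, "unclassified")

  # Between 0.70 and 0.80 with no family floor met: novel genome, not
  # unassigned (needs a reference from an un-ruled group).
  refs <- tibble::tibble(id = "ref", family = "Unrulled", genus = NA, species = NA)
  expect_equal(demarcate(refs, c(ref = 0.75))$species_status, "novel_genome")
  expect_equal(demarcate(refs, c(ref = 0.6999))$species_status, "unassigned")
  expect_equal(demarcate(refs, c(ref = 0.70))$species_status, "novel_genome")
  expect_true(demarcate(refs, c(ref = 0.7999))$novel)
  expect_false(demarcate(refs, c(ref = 0.80))$novel)

  expect_error(demarcate(ref1("Circoviridae")[0, ], c(ref = 0.9)),
               "no references")
})

test_that("worked demarcation examples land on the documented calls", {
  expect_equal(call_at(0.85, "Circoviridae")$species_status, "known_species_variant")
  r60 <- call_at(0.60, "Circoviridae")
  expect_equal(r60$family, "Circoviridae")
  expect_equal(r60$species_status, "new_species")
  expect_true(r60$novel)
  r65 <- demarcate(tibble::tibble(id = "ref", family = "Unrulled",
                                  genus = NA, species = NA), c(ref = 0.65))
  expect_equal(r65$species_status, "unassigned")
  expect_true(r65$novel)
})

test_that("Rep-based rules: smacovirus genus and bacilladnavirus species", {
  # Smacovirus genus requires Rep aa PI >= 0.40.
  hi <- call_at(0.60, "Smacoviridae", rep_pi = 0.40, genus = "Porprismacovirus")
  expect_equal(hi$family, "Smacoviridae")
  expect_equal(hi$genus, "Porprismacovirus")
  lo <- call_at(0.60, "Smacoviridae", rep_pi = 0.3999, genus = "Porprismacovirus")
  expect_equal(lo$family, "Smacoviridae")
  expect_true(is.na(lo$genus))

  # Bacilladnaviridae species demarcation on Rep amino-acid PI at 0.75.
  bac <- demarcate(ref1("Bacilladnaviridae"), c(ref = 0.5), c(ref = 0.75))
  expect_equal(bac$species_status, "known_species_variant")
  bac2 <- demarcate(ref1("Bacilladnaviridae"), c(ref = 0.5), c(ref = 0.7499))
  expect_false(bac2$species_status == "known_species_variant")
})

test_that("every demarcation decision is logged with its threshold", {
  r <- call_at(0.60, "Circoviridae")
  log <- r$rules_fired[[1]]
  expect_true(any(grepl("species", log$rule)))
  expect_true(any(grepl("family_floor", log$rule)))
  expect_true(all(c("threshold", "value") %in% names(log)))
})

test_that("barcode rank rule is strictly greater-than at 95%", {
  expect_equal(barcode_rank(0.96), "species")
  expect_equal(barcode_rank(0.95), "genus")
  expect_equal(barcode_rank(0.10), "genus")
  expect_error(barcode_rank(1.2), "out of")
})

test_that("greedy clustering: boundaries, extrema and the two-stage fallback", {
  seqs <- c(a = strrep("MKV", 60), b = strrep("MKV", 60), c = strrep("MKV", 60))
  cl <- greedy_cluster(seqs, 0.7)
  expect_equal(length(unique(cl$cluster)), 1L)

  # Pair at exactly the threshold joins (>= semantics); use a synthetic
  # identity matrix so the boundary is exact.
  pim <- structure(list(ids = c("a", "b"),
                        values = matrix(c(1, 0.7, 0.7, 1), 2, 2,
                                        dimnames = list(c("a", "b"), c("a", "b"))),
                        mode = "rep_aa"), class = "cress_pim")
  cl2 <- greedy_cluster(c(a = strrep("A", 10), b = strrep("A", 10)), 0.7,
                        pim = pim)
  expect_equal(length(unique(cl2$cluster)), 1L)
  pim$values[1, 2] <- pim$values[2, 1] <- 0.6999
  cl3 <- greedy_cluster(c(a = strrep("A", 10), b = strrep("A", 10)), 0.7,
                        pim = pim)
  expect_equal(length(unique(cl3$cluster)), 2L)

  # Two-stage fallback: 25 sequences mutually below 0.70, of which 15 join
  # representatives at 0.50; stage 1 leaves 25 clusters (> 20), stage 2
  # reduces them. Verified against a brute-force run of the greedy rule.
  ids <- sprintf("s%02d", 1:25)
  v <- matrix(0.2, 25, 25, dimnames = list(ids, ids)); diag(v) <- 1
  set.seed(9)
  for (k in 1:15) v[k, k + 10] <- v[k + 10, k] <- 0.55
  pim25 <- structure(list(ids = ids, values = v, mode = "rep_aa"),
                     class = "cress_pim")
  seqs25 <- setNames(vapply(25:1, function(n) strrep("A", 100 + n), ""), ids)
  out <- greedy_cluster(seqs25, 0.70, fallback_threshold = 0.50,
                        fallback_trigger = 20L, pim = pim25)
  expect_equal(attr(out, "stage"), 0.50)
  brute <- local({
    ord <- ids[order(-nchar(seqs25), ids)]
    reps <- character(0); assign <- integer(0)
    for (id in ord) {
      hit <- which(vapply(reps, function(r) v[id, r] >= 0.50, logical(1)))
      if (length(hit) > 0) assign[id] <- hit[1]
      else { reps <- c(reps, id); assign[id] <- length(reps) }
    }
    length(unique(assign))
  })
  expect_equal(length(unique(out$cluster)), brute)
  expect_lt(length(unique(out$cluster)), 25L)

  # Extrema: threshold 1 keeps only exact duplicates together.
  set.seed(2)
  distinct <- setNames(vapply(1:4, function(i) random_aa(80), ""),
                       paste0("d", 1:4))
  expect_equal(length(unique(greedy_cluster(distinct, 1)$cluster)), 4L)
  expect_error(greedy_cluster(distinct, 0), "threshold")
})
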