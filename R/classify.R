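#' Family demarcation rules for established CRESS DNA viral groups
#'
#' Per-family genome-wide pairwise-identity floors (the observed lower limit
#' of within-family genome-wide PI) and species demarcation thresholds.
#' Species demarcation is genome-based except for the Bacilladnaviridae,
#' whose species criterion is Rep amino-acid PI; smacovirus genus assignment
#' additionally requires at least 40% Rep amino-acid PI. Genus- or
#' subfamily-resolved species thresholds (Geminiviridae, Alphasatellitidae)
#' are carried in the `genus_thresholds` list-column.
#'
#' @return A tibble with columns `family`, `family_floor_genome_pi`,
#'   `species_threshold`, `species_basis` (`"genome_nt"`/`"rep_aa"`),
#'   `genus_rep_pi`, `genus_thresholds` (named list or `NULL`).
#' @export
demarcation_rules <- function() {
  tibble(
    family = c("Circoviridae", "Genomoviridae", "Smacoviridae",
               "Geminiviridae", "Nanoviridae", "Alphasatellitidae",
               "Bacilladnaviridae"),
    family_floor_genome_pi = c(0.55, 0.53, 0.55, 0.54, NA, 0.54, NA),
    species_threshold = c(0.80, 0.78, 0.77, NA, 0.75, NA, 0.75),
    species_basis = c("genome_nt", "genome_nt", "genome_nt", "genome_nt",
                      "genome_nt", "genome_nt", "rep_aa"),
    genus_rep_pi = c(NA, NA, 0.40, NA, NA, NA, NA),
    genus_thresholds = list(
      NULL, NULL, NULL,
      c(Becurtovirus = 0.80, Begomovirus = 0.91, Capulavirus = 0.78,
        Curtovirus = 0.77, Glabovirus = 0.80, Mastrevirus = 0.78),
      NULL,
      c(Geminialphasatellitinae = 0.88, Nanoalphasatellitinae = 0.80),
      NULL)
  )
}

# Species threshold applicable to a reference with known family (and genus /
# subfamily where the family resolves thresholds at that rank).
species_threshold_for <- function(rules, family, genus = NA) {
  r <- rules[rules$family == family, ]
  if (nrow(r) == 0L) return(NA_real_)
  gt <- r$genus_thresholds[[1]]
  if (!is.null(gt) && !is.na(genus) && genus %in% names(gt)) return(unname(gt[genus]))
  r$species_threshold
}

#' Apply the demarcation decision cascade to measured identities
#'
#' Pure decision function over pre-computed identities, so threshold
#' semantics are testable exactly. The cascade: (1) best genome-wide PI at
#' or above the matching family's species threshold (Rep amino-acid PI for
#' Rep-based families) makes the query a known-species variant; (2)
#' otherwise, genome-wide PI at or above a family's floor against any of its
#' members assigns the family as a new species (smacovirus genus assignment
#' additionally requires Rep aa PI >= the genus threshold); (3) strictly
#' below 0.80 against all references the query is a novel genome; (4)
#' strictly below 0.70 it is additionally unassigned (no family). Every
#' threshold comparison is logged in `rules_fired`.
#'
#' @param ref_taxa Tibble with one row per reference: `id`, `family`, and
#'   optionally `genus`, `species`.
#' @param genome_pi Named numeric: genome-wide PI of the query versus each
#'   reference id.
#' @param rep_pi Optional named numeric: Rep amino-acid PI versus each
#'   reference id.
#' @param rules Rules tibble (default [demarcation_rules()]).
#' @param novel_threshold,unassigned_threshold Strict upper bounds for the
#'   novelty (default 0.80) and unassignable (default 0.70) calls.
#' @return One-row tibble: `best_ref_id`, `best_genome_pi`, `best_rep_pi`,
#'   `family`, `genus`, `species_status`, `novel`, `rules_fired`
#'   (list-column of tibbles).
#' @export
demarcate <- function(ref_taxa, genome_pi, rep_pi = NULL,
                      rules = demarcation_rules(),
                      novel_threshold = 0.80, unassigned_threshold = 0.70) {
  if (nrow(ref_taxa) == 0L) abort("no references")
  ids <- ref_taxa$id
  gpi <- genome_pi[ids]
  rpi <- if (is.null(rep_pi)) setNames(rep(NA_real_, length(ids)), ids) else rep_pi[ids]
  if (is.null(ref_taxa$genus)) ref_taxa$genus <- NA_character_
  if (is.null(ref_taxa$species)) ref_taxa$species <- NA_character_

  fired <- list()
  log_rule <- function(rule, threshold, value) {
    fired[[length(fired) + 1L]] <<- tibble(rule = rule, threshold = threshold,
                                           value = value)
  }
  best_i <- which.max(gpi)
  best_ref <- ids[best_i]
  best_gpi <- unname(gpi[best_i])
  best_rpi <- unname(rpi[best_i])

  result <- function(family, genus, status) {
    tibble(best_ref_id = best_ref, best_genome_pi = best_gpi,
           best_rep_pi = best_rpi, family = family, genus = genus,
           species_status = status, novel = best_gpi < novel_threshold,
           rules_fired = list(list_rbind(fired)))
  }

  # (1) Known-species variant against the best-matching classifiable ref.
  for (i in order(-gpi)) {
    fam <- ref_taxa$family[i]
    r <- rules[rules$family == fam, ]
    if (nrow(r) == 0L) next
    basis_pi <- if (r$species_basis == "rep_aa") rpi[i] else gpi[i]
    thr <- species_threshold_for(rules, fam, ref_taxa$genus[i])
    if (is.na(thr) || is.na(basis_pi)) next
    log_rule(sprintf("species[%s,%s]", fam, r$species_basis), thr, unname(basis_pi))
    if (basis_pi >= thr) {
      return(result(fam, ref_taxa$genus[i], "known_species_variant"))
    }
    break  # only the best classifiable match decides species identity
  }

  # (2) Family floor assignment.
  fam_best <- NULL
  for (fam in unique(ref_taxa$family)) {
    r <- rules[rules$family == fam, ]
    if (nrow(r) == 0L || is.na(r$family_floor_genome_pi)) next
    in_fam <- ref_taxa$family == fam
    fam_gpi <- max(gpi[in_fam])
    log_rule(sprintf("family_floor[%s]", fam), r$family_floor_genome_pi,
             unname(fam_gpi))
    if (fam_gpi >= r$family_floor_genome_pi &&
        (is.null(fam_best) || fam_gpi > fam_best$pi)) {
      i <- which(in_fam)[which.max(gpi[in_fam])]
      fam_best <- list(family = fam, pi = fam_gpi, genus = ref_taxa$genus[i],
                       rep = unname(rpi[i]))
    }
  }
  if (!is.null(fam_best)) {
    genus <- fam_best$genus
    r <- rules[rules$family == fam_best$family, ]
    if (!is.na(r$genus_rep_pi)) {
      log_rule(sprintf("genus_rep[%s]", fam_best$family), r$genus_rep_pi,
               fam_best$rep)
      if (is.na(fam_best$rep) || fam_best$rep < r$genus_rep_pi) genus <- NA_character_
    }
    return(result(fam_best$family, genus, "new_species"))
  }

  # (3)/(4) Novelty.
  log_rule("novel_genome", novel_threshold, best_gpi)
  log_rule("unassigned", unassigned_threshold, best_gpi)
  if (best_gpi < unassigned_threshold) {
    return(result("unclassified", NA_character_, "unassigned"))
  }
  result("unclassified", NA_character_, "novel_genome")
}

#' Classify a query genome against labelled references
#'
#' Computes circular-aware genome-wide identities (and Rep amino-acid
#' identities when Rep sequences are supplied) of the query versus every
#' reference, then applies the demarcation cascade ([demarcate()]).
#'
#' @param query A [cress_genome].
#' @param refs Named list of reference [cress_genome] objects.
#' @param ref_taxa Tibble: `id`, `family`, and optionally `genus`, `species`.
#' @param query_rep,ref_reps Optional Rep amino-acid sequence(s): a single
#'   string for the query and a named character vector for the references.
#' @param oris Optional named list of [call_ori()] results keyed by genome
#'   id (query included) to anchor circular registration.
#' @param rules Rules tibble (default [demarcation_rules()]).
#' @return One-row tibble from [demarcate()] with `query_id` prepended.
#' @export
classify_taxon <- function(query, refs, ref_taxa, query_rep = NULL,
                           ref_reps = NULL, oris = NULL,
                           rules = demarcation_rules()) {
  if (length(refs) == 0L) abort("no references")
  stopifnot(all(ref_taxa$id %in% names(refs)))
  gpi <- vapply(ref_taxa$id, function(id) {
    as.numeric(circular_genome_identity(query, refs[[id]],
                                        oris[[query$id]], oris[[id]]))
  }, double(1))
  rpi <- NULL
  if (!is.null(query_rep) && !is.null(ref_reps)) {
    rpi <- vapply(ref_taxa$id, function(id) {
      if (is.na(ref_reps[id])) return(NA_real_)
      as.numeric(pairwise_identity(query_rep, ref_reps[[id]], "aa"))
    }, double(1))
  }
  out <- demarcate(ref_taxa, gpi, rpi, rules)
  out <- mutate(out, query_id = query$id, .before = 1L)
  out
}

#' Greedy identity clustering with a two-stage fallback
#'
#' Representative-based greedy clustering: sequences are sorted by length
#' descending (ties by id) and each joins the first existing representative
#' with identity at or above the threshold, else founds a new cluster. If a
#' fallback threshold is given and more than `fallback_trigger` clusters
#' remain, clustering is re-run at the fallback threshold (the 70% / 50%
#' two-stage reduction used for Rep datasets).
#'
#' @param seqs Named character vector of (amino-acid by default) sequences.
#' @param threshold Identity cut-off in `(0, 1]` (joins use `>=`).
#' @param fallback_threshold Optional second-stage cut-off.
#' @param fallback_trigger Cluster count above which the fallback stage runs
#'   (default 20).
#' @param mode Alignment mode for [pairwise_identity()] (default `"aa"`).
#' @param pim Optional precomputed [build_pi_matrix()] result to avoid
#'   re-alignment.
#' @return Tibble: `id`, `cluster`, `representative` (logical),
#'   `stage` attribute records which threshold produced the result.
#' @export
greedy_cluster <- function(seqs, threshold, fallback_threshold = NULL,
                           fallback_trigger = 20L, mode = "aa", pim = NULL) {
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  ids <- names(seqs)
  if (is.null(ids)) abort("sequences must be named")
  pi_fun <- function(a, b) {
    if (!is.null(pim)) return(pim$values[a, b])
    as.numeric(pairwise_identity(seqs[[a]], seqs[[b]], mode))
  }
  run <- function(thr) {
    ord <- ids[order(-nchar(seqs), ids)]
    reps <- character(0)
    assign <- setNames(integer(length(ids)), ids)
    for (id in ord) {
      placed <- FALSE
      for (k in seq_along(reps)) {
        if (pi_fun(id, reps[k]) >= thr) {
          assign[id] <- k; placed <- TRUE; break
        }
      }
      if (!placed) {
        reps <- c(reps, id)
        assign[id] <- length(reps)
      }
    }
    tibble(id = ids, cluster = unname(assign[ids]),
           representative = ids %in% reps)
  }
  out <- run(threshold)
  stage <- threshold
  if (!is.null(fallback_threshold) &&
      length(unique(out$cluster)) > fallback_trigger) {
    out <- run(fallback_threshold)
    stage <- fallback_threshold
  }
  attr(out, "stage") <- stage
  out
}

#' DNA-barcoding rank rule
#'
#' Barcode matches sharing strictly more than 95% nucleotide identity are
#' classified to species; anything at or below the threshold is classified
#' at genus level.
#'
#' @param identity Fraction in `[0, 1]`.
#' @param threshold Strict species cut-off (default 0.95).
#' @return `"species"` or `"genus"`.
#' @export
barcode_rank <- function(identity, threshold = 0.95) {
  if (any(identity < 0 | identity > 1)) abort("identity out of [0, 1]")
  ifelse(identity > threshold, "species", "genus")
}
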