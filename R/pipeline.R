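#' Pipeline configuration defaults
#'
#' Aggregates the tunable parameters of the annotation and classification
#' pipeline, pre-set to the demarcation-framework values: major-ORF floor of
#' strictly more than 100 aa, nonamer mismatch tolerance 1, disorder calling
#' threshold 0.5, clustering thresholds 0.70 / 0.50 with a 20-cluster
#' trigger, novelty cut-offs 0.80 / 0.70.
#'
#' @param ... Named overrides of any default field.
#' @return A named list of class `cress_config`.
#' @export
cress_config <- function(...) {
  cfg <- list(min_aa = 101L, require_atg = TRUE, max_overlap_nt = 0L,
              nonamer_max_mismatch = 1L, disorder_theta = 0.5,
              disorder_window = 15L, rep_quorum = 4L,
              cluster_threshold = 0.70, cluster_fallback = 0.50,
              cluster_trigger = 20L, novel_threshold = 0.80,
              unassigned_threshold = 0.70, min_genome_length = 200L,
              seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0L) abort(sprintf("unknown config field: %s", bad[1]))
  cfg[names(over)] <- over
  structure(cfg, class = "cress_config")
}

annotate_one <- function(genome, config) {
  L <- genome_length(genome)
  orfs <- find_orfs(genome, min_aa = config$min_aa,
                    require_atg = config$require_atg)
  majors <- select_major_orfs(orfs, L, max_overlap_nt = config$max_overlap_nt)

  scans <- map(seq_len(nrow(majors)), function(i)
    scan_rep_motifs(majors$protein[i], quorum = config$rep_quorum))
  is_rep <- vapply(scans, function(s) s$is_rep, logical(1))
  rep_i <- if (any(is_rep)) {
    cand <- which(is_rep)
    cand[order(-vapply(scans[cand], function(s) s$n_core_hits, integer(1)),
               -majors$aa_len[cand])][1]
  } else NA_integer_
  rep_id <- if (!is.na(rep_i)) majors$orf_id[rep_i] else NA_character_

  # Interrupted-gene rescue: when the best candidate is missing motifs,
  # screen same-strand ORF pairs for a joining intron; the joined gene wins
  # if it recovers strictly more core motifs.
  spliced <- NULL
  hits_best <- if (is.na(rep_i)) 0L else scans[[rep_i]]$n_core_hits
  if (hits_best < 7L && nrow(majors) >= 2L) {
    best_hits <- hits_best
    for (i in seq_len(nrow(majors))) {
      for (j in seq_len(nrow(majors))) {
        if (i == j || majors$strand[i] != majors$strand[j]) next
        sp <- tryCatch(
          find_spliced_rep(genome, majors[i, ], majors[j, ]),
          error = function(e) NULL)
        if (is.null(sp)) next
        sc <- tryCatch(scan_rep_motifs(sp$joined_protein,
                                       quorum = config$rep_quorum),
                       error = function(e) NULL)
        if (!is.null(sc) && sc$is_rep && sc$n_core_hits > best_hits) {
          best_hits <- sc$n_core_hits
          spliced <- c(sp, list(upstream = majors$orf_id[i],
                                downstream = majors$orf_id[j]))
        }
      }
    }
    if (!is.null(spliced)) {
      # Treat the joined gene as the Rep: merge the two fragment rows.
      i <- match(spliced$upstream, majors$orf_id)
      j <- match(spliced$downstream, majors$orf_id)
      rep_i <- i
      rep_id <- majors$orf_id[i]
      majors$protein[i] <- spliced$joined_protein
      majors$aa_len[i] <- nchar(spliced$joined_protein)
      majors$spliced[i] <- TRUE
      if (majors$strand[i] == "+") {
        majors$end[i] <- majors$start[i] +
          ((majors$end[j] - majors$start[i]) %% L + L) %% L
      } else {
        new_start <- majors$start[j]
        majors$end[i] <- new_start + ((majors$end[i] - new_start) %% L + L) %% L
        majors$start[i] <- new_start
      }
      majors <- majors[-j, , drop = FALSE]
    }
  }

  ori <- call_ori(genome,
                  find_nonamer_candidates(genome,
                                          max_mismatch = config$nonamer_max_mismatch))
  org <- if (!is.null(ori) && !is.na(rep_id)) {
    tryCatch(classify_organization(ori, majors, rep_id, L),
             error = function(e) NULL)
  } else NULL

  capsids <- call_capsids(majors, rep_id, theta = config$disorder_theta,
                          window = config$disorder_window)
  called_caps <- capsids$orf_id[capsids$called]
  status <- if (is.na(rep_id)) "no_rep"
            else if (length(called_caps) == 0L) "circular molecule"
            else "virus"

  row <- tibble(
    genome_id = genome$id,
    status = status,
    genome_size_nt = L,
    nonamer = if (is.null(ori)) NA_character_ else ori$nonamer$seq9,
    genotype = if (is.null(org)) NA_character_ else org$genotype,
    nonamer_genotype = if (is.null(ori) || is.null(org)) NA_character_
                       else sprintf("%s (%s)", ori$nonamer$seq9, org$genotype),
    ori_pos = if (is.null(ori)) NA_integer_ else ori$nonamer$pos,
    ori_strand = if (is.null(ori)) NA_character_ else ori$nonamer$strand,
    ori_confidence = if (is.null(ori)) NA_character_ else ori$confidence,
    n_major_orfs = nrow(majors),
    rep_orf = rep_id,
    rep_spliced = !is.na(rep_id) && isTRUE(majors$spliced[match(rep_id, majors$orf_id)]),
    capsid_orf = if (length(called_caps) > 0L) called_caps[1] else NA_character_,
    capsid_basis = if (length(called_caps) > 0L) "idp_profile" else "none")
  list(report = row, orfs = majors, capsids = capsids, ori = ori, org = org,
       spliced = spliced)
}

#' Annotate a batch of circular genomes
#'
#' Runs the full per-genome annotation chain -- ORFs, major-ORF selection,
#' Rep identification by motif scan (with a spliced-Rep rescue for
#' intron-interrupted genes), origin calling, genome-organization typing,
#' capsid calling by disorder profile -- and returns a per-genome report
#' table. Genomes carrying a Rep but no called capsid are labelled
#' `"circular molecule"`. A failure in one record is reported in its row and
#' never aborts the batch.
#'
#' @param x A FASTA path, a list of [cress_genome] objects, or a single
#'   genome.
#' @param config A [cress_config()].
#' @return Object of class `cress_annotation`: list with `report` (tibble,
#'   one row per genome) and `details` (per-genome list of `orfs`,
#'   `capsids`, `ori`, `org`).
#' @export
annotate_genomes <- function(x, config = cress_config()) {
  genomes <- if (is.character(x)) {
    read_genome_fasta(x, min_length = config$min_genome_length)
  } else if (inherits(x, "cress_genome")) list(x) else x
  if (length(genomes) == 0L) abort("no records")
  rows <- list(); details <- list()
  for (g in genomes) {
    res <- tryCatch(annotate_one(g, config), error = function(e) e)
    if (inherits(res, "error")) {
      rows[[length(rows) + 1L]] <- tibble(
        genome_id = g$id, status = "failed", genome_size_nt = genome_length(g),
        nonamer = NA_character_, genotype = NA_character_,
        nonamer_genotype = NA_character_, ori_pos = NA_integer_,
        ori_strand = NA_character_, ori_confidence = NA_character_,
        n_major_orfs = NA_integer_, rep_orf = NA_character_,
        rep_spliced = NA, capsid_orf = NA_character_,
        capsid_basis = NA_character_)
      details[[g$id]] <- list(error = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res$report
      details[[g$id]] <- res[c("orfs", "capsids", "ori", "org", "spliced")]
    }
  }
  structure(list(report = list_rbind(rows), details = details,
                 config = config),
            class = "cress_annotation")
}

#' @export
print.cress_annotation <- function(x, ...) {
  cat(sprintf("<cress_annotation> %d genomes (%d virus, %d circular molecule, %d other)\n",
              nrow(x$report), sum(x$report$status == "virus"),
              sum(x$report$status == "circular molecule"),
              sum(!x$report$status %in% c("virus", "circular molecule"))))
  print(x$report)
  invisible(x)
}

#' @describeIn annotate_genomes Per-genome report rows as a tibble.
#' @param x A `cress_annotation`.
#' @param ... Unused.
#' @export
tidy.cress_annotation <- function(x, ...) x$report

#' @describeIn annotate_genomes One-row batch summary.
#' @export
glance.cress_annotation <- function(x, ...) {
  r <- x$report
  tibble(n_genomes = nrow(r),
         n_virus = sum(r$status == "virus"),
         n_circular_molecule = sum(r$status == "circular molecule"),
         n_failed = sum(r$status == "failed"),
         n_genotypes = length(unique(r$genotype[!is.na(r$genotype)])),
         min_size_nt = min(r$genome_size_nt),
         max_size_nt = max(r$genome_size_nt))
}

#' Classify a batch of query genomes against labelled references
#'
#' @param queries Named list of [cress_genome] queries.
#' @param refs Named list of reference [cress_genome] objects.
#' @param ref_taxa Tibble: `id`, `family`, optionally `genus`, `species`.
#' @param query_reps,ref_reps Optional named character vectors of Rep
#'   amino-acid sequences.
#' @param oris Optional named list of [call_ori()] results (queries and
#'   refs) anchoring circular registration; ids absent from the list fall
#'   back to a rotation scan.
#' @param rules Demarcation rules (default [demarcation_rules()]).
#' @return Tibble of per-query [demarcate()] rows.
#' @export
classify_genomes <- function(queries, refs, ref_taxa, query_reps = NULL,
                             ref_reps = NULL, oris = NULL,
                             rules = demarcation_rules()) {
  rows <- map(queries, function(q) {
    classify_taxon(q, refs, ref_taxa,
                   query_rep = query_reps[[q$id]], ref_reps = ref_reps,
                   oris = oris, rules = rules)
  })
  list_rbind(rows)
}

#' Summarise an annotation report table
#'
#' @param report Report tibble (from [annotate_genomes()] or
#'   [read_report_tsv()]).
#' @return List: `n_genomes`, `genotypes` (sorted unique labels),
#'   `n_genotypes`, `size_range_nt`, and a printable `summary` line of the
#'   form "N genomes; K of 8 genome organizations; sizes a-b nt".
#' @export
summarize_report <- function(report) {
  gts <- sort(unique(report$genotype[!is.na(report$genotype)]))
  sizes <- report$genome_size_nt
  out <- list(n_genomes = nrow(report), genotypes = gts,
              n_genotypes = length(gts),
              size_range_nt = c(min(sizes), max(sizes)))
  out$summary <- sprintf("%d genomes; %d of 8 genome organizations; sizes %d-%d nt",
                         out$n_genomes, out$n_genotypes,
                         out$size_range_nt[1], out$size_range_nt[2])
  out
}

#' Read a report table (TSV)
#'
#' Reads a tab-separated report with at least `genome_id` and the Table-3
#' style columns (`genome_size_nt`, `nonamer`, `genotype`, identity
#' columns). The bundled transcription of the study-scale survey table ships
#' at `system.file("extdata", "table3_report.tsv", package = "cressannot")`.
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_report_tsv <- function(path) {
  as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                       check.names = FALSE, na.strings = c("NA", "n/a")))
}

#' Write a report table to TSV
#'
#' @param report Report tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  df <- as.data.frame(report)
  keep <- !vapply(df, is.list, logical(1))
  write.table(df[, keep, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
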