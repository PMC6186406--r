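#' Genome-organization genotype map
#'
#' CRESS DNA genomes are typed (genotypes I--VIII) by the arrangement of the
#' major ORFs and the position and strand of the origin of replication
#' relative to the Rep gene. The mapping is configuration data, not
#' hard-coded logic: this function returns the versioned default map, a total
#' function over the 4-tuple (`n_orfs`, `sense_relation`,
#' `ori_strand_rel_rep`, `ori_region`). Rows are matched in order and `any`
#' is a wildcard; origins falling inside an ORF are folded onto the
#' 3'-of-Rep rows. The `canonical_*` columns give the representative tuple
#' the synthetic generator uses when planting a genotype, so generator and
#' classifier share a single source of truth.
#'
#' The eight-genotype scheme is anchored to three fixed points: genotype II
#' is the ambisense arrangement with the origin on the Rep strand 5' of Rep
#' (cyclovirus/genomovirus-like), genotype V is the unisense arrangement with
#' the origin on the Rep strand (circularisvirus-like), and genotype VIII is
#' the Rep-only replicon. The remaining rows complete the domain and should
#' be re-validated against the typing scheme in use before cross-study
#' comparisons.
#'
#' @return A tibble with columns `genotype`, `n_orfs` (`"1"` or `"2+"`),
#'   `sense_relation`, `ori_strand_rel_rep`, `ori_region`, and the
#'   `canonical_*` planting columns, plus a `map_version` attribute.
#' @export
cress_type_map <- function() {
  m <- tibble::tribble(
    ~genotype, ~n_orfs, ~sense_relation, ~ori_strand_rel_rep, ~ori_region,
    "VIII", "1",  "any",       "any",      "any",
    "I",    "2+", "ambisense", "opposite", "5prime_of_rep",
    "II",   "2+", "ambisense", "same",     "5prime_of_rep",
    "III",  "2+", "ambisense", "same",     "3prime_of_rep",
    "IV",   "2+", "ambisense", "opposite", "3prime_of_rep",
    "V",    "2+", "unisense",  "same",     "5prime_of_rep",
    "VI",   "2+", "unisense",  "opposite", "5prime_of_rep",
    "VII",  "2+", "unisense",  "any",      "3prime_of_rep"
  )
  canon <- tibble::tribble(
    ~genotype, ~canonical_n_orfs, ~canonical_sense, ~canonical_ori_strand, ~canonical_ori_region,
    "VIII", 1L, "unisense",  "same",     "5prime_of_rep",
    "I",    2L, "ambisense", "opposite", "5prime_of_rep",
    "II",   2L, "ambisense", "same",     "5prime_of_rep",
    "III",  2L, "ambisense", "same",     "3prime_of_rep",
    "IV",   2L, "ambisense", "opposite", "3prime_of_rep",
    "V",    2L, "unisense",  "same",     "5prime_of_rep",
    "VI",   2L, "unisense",  "opposite", "5prime_of_rep",
    "VII",  2L, "unisense",  "same",     "3prime_of_rep"
  )
  out <- left_join(m, canon, by = "genotype")
  attr(out, "map_version") <- "cressannot-typemap-1.0"
  out
}

#' Map an organization 4-tuple to its genotype
#'
#' @param n_orfs Number of major ORFs (integer).
#' @param sense_relation `"unisense"` or `"ambisense"` (ignored for 1 ORF).
#' @param ori_strand_rel_rep `"same"` or `"opposite"`.
#' @param ori_region `"5prime_of_rep"`, `"3prime_of_rep"` or `"within_orf"`.
#' @param type_map Map tibble (default [cress_type_map()]).
#' @return Genotype label (single string).
#' @export
genotype_from_tuple <- function(n_orfs, sense_relation, ori_strand_rel_rep,
                                ori_region, type_map = cress_type_map()) {
  norf_key <- if (n_orfs <= 1L) "1" else "2+"
  # Origins inside an ORF fold onto the 3'-of-Rep rows.
  region_key <- if (ori_region == "within_orf") "3prime_of_rep" else ori_region
  for (i in seq_len(nrow(type_map))) {
    r <- type_map[i, ]
    if (r$n_orfs != norf_key) next
    if (r$sense_relation != "any" && r$sense_relation != sense_relation) next
    if (r$ori_strand_rel_rep != "any" && r$ori_strand_rel_rep != ori_strand_rel_rep) next
    if (r$ori_region != "any" && r$ori_region != region_key) next
    return(r$genotype)
  }
  abort(sprintf("type map is not total: no row for (%s, %s, %s, %s)",
                norf_key, sense_relation, ori_strand_rel_rep, region_key))
}
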