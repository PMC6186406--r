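#' Write annotated features to GFF3
#'
#' Emits features on a circular genome as GFF3 with 1-based inclusive
#' coordinates. Features whose 0-based half-open interval runs past the
#' origin (`end > genome length`) are emitted as two parts sharing the same
#' `ID`, following the GFF3 convention for circular sequences; the header
#' records the circular topology with an `##Is_circular` pragma.
#'
#' @param genome A [cress_genome].
#' @param features A data frame / tibble with columns `start`, `end`
#'   (0-based half-open, `end` may exceed the genome length for
#'   origin-spanning features), `strand` (`+`/`-`), and optionally `type`
#'   (default `"CDS"`), `id` and `attributes` (character, appended verbatim).
#' @param path Output file path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genome, features, path, source = "cressannot") {
  L <- genome_length(genome)
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", genome$id, L),
             sprintf("# circular=%s", tolower(as.character(genome$circular))))
  if (!is.null(features) && nrow(features) > 0L) {
    if (any(features$end - features$start > L))
      abort("feature longer than genome")
    if (any(features$start < 0L | features$start >= L))
      abort("feature start out of range")
    if (is.null(features$type)) features$type <- "CDS"
    if (is.null(features$id)) features$id <- sprintf("feat%03d", seq_len(nrow(features)))
    if (is.null(features$attributes)) features$attributes <- ""
    for (k in seq_len(nrow(features))) {
      f <- features[k, ]
      extra <- if (nzchar(f$attributes)) paste0(";", f$attributes) else ""
      attr1 <- sprintf("ID=%s%s", f$id, extra)
      if (f$end <= L) {
        lines <- c(lines, sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                                  genome$id, source, f$type,
                                  f$start + 1L, f$end, f$strand, attr1))
      } else {
        # Origin-spanning: two parts with the same ID.
        lines <- c(lines,
                   sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                           genome$id, source, f$type,
                           f$start + 1L, L, f$strand, attr1),
                   sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                           genome$id, source, f$type,
                           1L, f$end - L, f$strand, attr1))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read back a cressannot GFF3 file as 0-based intervals
#'
#' Inverse of [write_gff3()]: split origin-spanning parts sharing an `ID` are
#' re-joined into a single interval with `end > genome length`.
#'
#' @param path Path to a GFF3 file written by [write_gff3()].
#' @return Tibble with columns `seqid`, `type`, `start`, `end` (0-based
#'   half-open), `strand`, `id`.
#' @export
read_gff3_intervals <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) {
    return(tibble(seqid = character(), type = character(),
                  start = integer(), end = integer(),
                  strand = character(), id = character()))
  }
  parts <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  df <- tibble(seqid = parts[, 1], type = parts[, 3],
               start1 = as.integer(parts[, 4]), end1 = as.integer(parts[, 5]),
               strand = parts[, 7],
               id = sub("^ID=([^;]+).*$", "\\1", parts[, 9]))
  out <- df |>
    group_by(.data$seqid, .data$type, .data$strand, .data$id) |>
    summarise(start = max(.data$start1) - 1L,
              end = if (dplyr::n() > 1L) sum(.data$end1) else max(.data$end1),
              .groups = "drop")
  select(out, "seqid", "type", "start", "end", "strand", "id")
}
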