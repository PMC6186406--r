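#' Read circular genomes from a FASTA file
#'
#' Reads a (multi-)FASTA file into a list of [cress_genome] objects. Sequences
#' are uppercased and `U` is normalised to `T`; the FASTA description line is
#' stored in the metadata. Records containing letters outside the IUPAC DNA
#' alphabet raise an error naming the record and offending position.
#'
#' @param path Path to a FASTA file.
#' @param circular Logical; mark records as circular (default `TRUE`).
#' @param min_length Minimum accepted record length in nt (default 200, the
#'   pipeline entry floor; set to 0 to disable).
#' @return A named list of `cress_genome` objects, in file order.
#' @export
read_genome_fasta <- function(path, circular = TRUE, min_length = 200L) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort("no records")
  ids <- sub("\\s.*$", "", names(set))
  desc <- sub("^\\S+\\s*", "", names(set))
  gs <- vector("list", length(set))
  for (i in seq_along(set)) {
    meta <- list()
    if (nzchar(desc[i])) meta$description <- desc[i]
    gs[[i]] <- cress_genome(ids[i], as.character(set[[i]]), circular = circular,
                            meta = meta, min_length = min_length)
  }
  names(gs) <- ids
  gs
}

#' Write genomes (or named sequences) to FASTA
#'
#' @param x A list of [cress_genome] objects, or a named character vector of
#'   sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(x, path) {
  if (is.list(x) && all(vapply(x, inherits, logical(1), "cress_genome"))) {
    seqs <- vapply(x, function(g) g$seq, character(1))
    names(seqs) <- vapply(x, function(g) g$id, character(1))
  } else {
    seqs <- x
    if (is.null(names(seqs))) abort("sequences must be named")
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a FASTA file of protein (or aligned) sequences
#'
#' Convenience reader returning a named character vector; gap characters are
#' preserved, so aligned FASTA round-trips.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_seq_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort("no records")
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}
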