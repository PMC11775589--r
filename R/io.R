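#' Read clone sequences from a FASTA file
#'
#' Reads one record per FASTA entry in file order. Sequences are uppercased
#' and U is mapped to T (all sequenced material is cDNA-derived, so the
#' pipeline operates in DNA space). N characters from base-calling are kept.
#'
#' @param path Path to a FASTA file.
#' @param source Source label attached to every record, one of `"observed"`,
#'   `"synthetic_genuine"`, `"synthetic_contaminant"`.
#' @return A data.frame with columns `id`, `sequence`, `source` (class
#'   `clone_records`).
#' @export
read_fasta <- function(path, source = "observed") {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop("FASTA file is empty: ", path, call. = FALSE)
  first <- nonblank[1]
  if (!startsWith(lines[first], ">"))
    stop("malformed FASTA: line ", first, " does not start with '>'", call. = FALSE)
  bad <- nonblank[startsWith(lines[nonblank], ">") &
                    !nzchar(trimws(sub("^>", "", lines[nonblank])))]
  if (length(bad))
    stop("malformed FASTA: empty header at line ", bad[1], call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  ids <- sub("\\s.*$", "", names(set))
  clone_records(ids, unname(seqs), source)
}

#' Construct a set of clone records
#'
#' @param id Character vector of unique clone identifiers.
#' @param sequence Character vector of DNA sequences (N allowed).
#' @param source Single source label or vector, one of `"observed"`,
#'   `"synthetic_genuine"`, `"synthetic_contaminant"`.
#' @return A `clone_records` data.frame.
#' @export
clone_records <- function(id, sequence, source = "observed") {
  id <- as.character(id); sequence <- as.character(sequence)
  if (length(id) != length(sequence))
    stop("id and sequence lengths differ", call. = FALSE)
  if (anyDuplicated(id))
    stop("duplicate clone id: ", id[duplicated(id)][1], call. = FALSE)
  if (any(!nzchar(sequence))) stop("empty clone sequence", call. = FALSE)
  ok <- c("observed", "synthetic_genuine", "synthetic_contaminant")
  source <- rep_len(as.character(source), length(id))
  if (!all(source %in% ok))
    stop("source must be one of: ", paste(ok, collapse = ", "), call. = FALSE)
  structure(data.frame(id = id, sequence = sequence, source = source,
                       stringsAsFactors = FALSE),
            class = c("clone_records", "data.frame"))
}

#' Write clone records to FASTA
#'
#' Standard FASTA with 70-column sequence wrapping; round-trips losslessly
#' with [read_fasta()].
#'
#' @param records A `clone_records` data.frame (or any data.frame with `id`
#'   and `sequence` columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.null(records) || nrow(records) == 0)
    stop("no records to write", call. = FALSE)
  set <- Biostrings::BStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, filepath = path, width = 70L)
  invisible(path)
}

#' Reverse-complement DNA sequences
#'
#' Vectorized over a character vector; N maps to N. Clone inserts ligate into
#' the cloning vector in either orientation, so half the reads arrive
#' reverse-complemented.
#'
#' @param seq Character vector over A/C/G/T/N.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("AAG")  # "CTT"
#' @export
revcomp <- function(seq) {
  if (any(grepl("[^ACGTN]", seq)))
    stop("revcomp: sequences must be over A/C/G/T/N", call. = FALSE)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}
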