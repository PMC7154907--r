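#' Read transcripts from a FASTA file
#'
#' Reads a (possibly DNA-alphabet) FASTA file and returns RNA transcripts.
#' `T` is converted to `U` on input; the id of each transcript is the header
#' token before the first whitespace. Lowercase input is uppercased.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `sequence` (RNA alphabet
#'   `A,C,G,U`) and `length`, one row per record. An empty file yields a
#'   zero-row data.frame.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "ACGT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  if (file.size(path) == 0) {
    return(data.frame(id = character(), sequence = character(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- unname(sub("\\s.*$", "", names(set)))
  if (anyDuplicated(ids)) {
    stop("duplicate transcript ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- unname(toupper(as.character(set)))
  seqs <- chartr("T", "U", seqs)
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for id(s): ", paste(ids[nchar(seqs) == 0], collapse = ", "))
  }
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    stop("non-ACGU character (ambiguity codes are rejected) in: ",
         paste(ids[bad], collapse = ", "))
  }
  data.frame(id = ids, sequence = unname(seqs), length = nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Write transcripts to a FASTA file
#'
#' @param transcripts data.frame with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(transcripts, path) {
  set <- Biostrings::BStringSet(transcripts$sequence)
  names(set) <- transcripts$id
  Biostrings::writeXStringSet(set, path, width = 70)
  invisible(path)
}

# Vector of single bases for one transcript sequence.
seq_bases <- function(sequence) {
  strsplit(sequence, "", fixed = TRUE)[[1]]
}
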