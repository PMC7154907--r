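#' Construct a reference secondary structure
#'
#' @param transcript_id Transcript identifier.
#' @param partner Integer vector, one entry per position: 0 for unpaired,
#'   otherwise the 1-based partner position. Must be symmetric.
#' @param solvent_accessible Logical vector of the same length; positions
#'   exposed at the molecular surface (e.g. derived externally from a
#'   ribosome crystal structure). Defaults to all-accessible.
#' @param sequence Optional RNA sequence of the same length.
#' @return Object of class `reference_structure`.
#' @export
reference_structure <- function(transcript_id, partner,
                                solvent_accessible = NULL, sequence = NULL) {
  partner <- as.integer(partner)
  n <- length(partner)
  if (is.null(solvent_accessible)) solvent_accessible <- rep(TRUE, n)
  if (length(solvent_accessible) != n) {
    stop("solvent_accessible length must match partner length")
  }
  if (!is.null(sequence) && nchar(sequence) != n) {
    stop("sequence length (", nchar(sequence), ") != structure length (", n, ")")
  }
  paired <- which(partner != 0L)
  if (any(partner[paired] < 1L | partner[paired] > n)) {
    stop("partner index out of range")
  }
  if (any(partner[paired] == paired)) stop("position paired with itself")
  if (any(partner[partner[paired]] != paired)) {
    stop("partner array not symmetric")
  }
  structure(list(transcript_id = transcript_id, partner = partner,
                 solvent_accessible = as.logical(solvent_accessible),
                 sequence = sequence),
            class = "reference_structure")
}

#' Parse a dot-bracket string into a partner vector
#'
#' Nested pairs only (`(`, `)`, `.`); other characters are rejected.
#'
#' @param db Dot-bracket string.
#' @return Integer partner vector (0 = unpaired).
#' @export
parse_dotbracket <- function(db) {
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  if (any(!ch %in% c("(", ")", "."))) {
    stop("dot-bracket may contain only '(', ')' and '.'")
  }
  partner <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket: unmatched ')' at ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack)) {
    stop("unbalanced dot-bracket: ", length(stack), " unmatched '('")
  }
  partner
}

#' Read a reference structure from a CT or dot-bracket file
#'
#' CT files carry arbitrary (possibly crossing) pairs; dot-bracket supports
#' nested pairs only. An optional accessibility TSV (columns `pos`,
#' `accessible` with 0/1 or TRUE/FALSE) supplies the solvent-accessibility
#' mask; when absent every position is taken as accessible.
#'
#' Dot-bracket dialect: an optional `>id` header line, an optional sequence
#' line, then the bracket string.
#'
#' @param path Path to the structure file.
#' @param format `"ct"` or `"dotbracket"`.
#' @param accessibility Optional path to the accessibility TSV.
#' @param transcript_id Id to record; defaults to the file's own id (CT
#'   title / FASTA-style header) or the file name.
#' @return A [reference_structure()].
#' @export
read_structure <- function(path, format = c("ct", "dotbracket"),
                           accessibility = NULL, transcript_id = NULL) {
  format <- match.arg(format)
  if (format == "ct") {
    res <- read_ct_file(path)
  } else {
    res <- read_dotbracket_file(path)
  }
  id <- transcript_id %||% res$id %||% basename(path)
  acc <- NULL
  if (!is.null(accessibility)) {
    at <- utils::read.delim(accessibility, stringsAsFactors = FALSE)
    if (length(setdiff(c("pos", "accessible"), names(at)))) {
      stop("accessibility table needs columns pos, accessible")
    }
    acc <- rep(TRUE, length(res$partner))
    if (any(at$pos < 1 | at$pos > length(res$partner))) {
      stop("accessibility position out of structure bounds")
    }
    acc[at$pos] <- as.logical(as.integer(at$accessible) != 0 |
                                at$accessible %in% c("TRUE", "true"))
  }
  reference_structure(id, res$partner, solvent_accessible = acc,
                      sequence = res$sequence)
}

read_ct_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty CT file: ", path)
  head_tok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(head_tok[1]))
  if (is.na(n)) stop("CT header must start with the sequence length")
  id <- if (length(head_tok) > 1) paste(head_tok[-1], collapse = " ") else NULL
  if (length(lines) - 1L < n) stop("CT file truncated: expected ", n, " rows")
  rows <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
  idx <- as.integer(vapply(rows, `[`, "", 1))
  base <- vapply(rows, `[`, "", 2)
  partner <- as.integer(vapply(rows, `[`, "", 5))
  if (!identical(idx, seq_len(n))) stop("CT rows must be numbered 1..n")
  if (any(is.na(partner)) || any(partner < 0) || any(partner > n)) {
    stop("CT partner column out of range")
  }
  paired <- which(partner != 0L)
  bad <- paired[partner[partner[paired]] != paired]
  if (length(bad)) {
    stop("CT partner asymmetry at position(s): ", paste(bad, collapse = ", "))
  }
  seq <- paste(chartr("Tt", "Uu", toupper(base)), collapse = "")
  list(id = id, partner = partner, sequence = seq)
}

read_dotbracket_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty dot-bracket file: ", path)
  id <- NULL
  if (startsWith(lines[1], ">")) {
    id <- sub("\\s.*$", "", sub("^>", "", lines[1]))
    lines <- lines[-1]
  }
  if (!length(lines)) stop("dot-bracket file has header but no structure")
  seq <- NULL
  db <- lines[length(lines)]
  if (length(lines) >= 2 && grepl("^[ACGTUacgtu]+$", lines[1])) {
    seq <- chartr("Tt", "Uu", toupper(lines[1]))
    if (nchar(seq) != nchar(db)) {
      stop("sequence and dot-bracket lengths differ")
    }
  }
  list(id = id, partner = parse_dotbracket(db), sequence = seq)
}

#' Write a reference structure as a CT file
#'
#' @param struct A [reference_structure()]; needs a sequence.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct <- function(struct, path) {
  stopifnot(inherits(struct, "reference_structure"))
  if (is.null(struct$sequence)) stop("CT output needs the sequence")
  n <- length(struct$partner)
  bases <- seq_bases(struct$sequence)
  rows <- sprintf("%d %s %d %d %d %d", seq_len(n), bases,
                  seq_len(n) - 1L, c(seq_len(n - 1L) + 1L, 0L),
                  struct$partner, seq_len(n))
  writeLines(c(sprintf("%d %s", n, struct$transcript_id), rows), path)
  invisible(path)
}

#' Export normalized reactivities as a folding constraint file
#'
#' Writes the SHAPE-style two-column text format (`position value`) read by
#' external reactivity-constrained folding engines. Every position from 1 to
#' the transcript length appears exactly once; positions that are masked,
#' not A/C (when `ac_only`), lacking a normalized value, or absent from the
#' profile are emitted as `-999` (no data).
#'
#' @param profile A reactivity profile with normalized values
#'   (see [reactivity_pipeline()]).
#' @param path Output path.
#' @param transcript_id Transcript to export; defaults to the only
#'   transcript in the profile.
#' @param length Transcript length; defaults to the maximum position seen.
#' @param ac_only Export A/C reactivities only (G/U become `-999`).
#' @return `path`, invisibly.
#' @export
write_constraints <- function(profile, path, transcript_id = NULL,
                              length = NULL, ac_only = TRUE) {
  prof <- as.data.frame(profile)
  if (is.null(transcript_id)) {
    ids <- unique(prof$transcript_id)
    if (length(ids) != 1) stop("profile has several transcripts; pick one")
    transcript_id <- ids
  }
  prof <- prof[prof$transcript_id == transcript_id, , drop = FALSE]
  if (!"normalized" %in% names(prof) || all(is.na(prof$normalized))) {
    stop("profile lacks normalized values; run the normalization first")
  }
  n <- if (is.null(length)) max(prof$pos) else as.integer(length)
  value <- rep(-999, n)
  keep <- prof$mask_reason == "none" & !is.na(prof$normalized)
  if (ac_only) keep <- keep & prof$channel == "AC"
  value[prof$pos[keep]] <- prof$normalized[keep]
  writeLines(sprintf("%d\t%s", seq_len(n),
                     ifelse(value == -999, "-999",
                            formatC(value, digits = 6, format = "g"))), path)
  invisible(path)
}

#' Read a constraint file written by [write_constraints()]
#' @param path Path to the constraint file.
#' @return data.frame with columns `pos`, `value` (`NA` where `-999`).
#' @export
read_constraints <- function(path) {
  df <- utils::read.delim(path, header = FALSE, col.names = c("pos", "value"))
  df$value[df$value == -999] <- NA_real_
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
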