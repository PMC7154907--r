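#' Read a per-position mutation-count table
#'
#' The counts TSV dialect has a header line with columns `transcript_id`,
#' `pos` (1-based), `ref_base`, `coverage`, `sub_count`, `del_count`.
#' Extra columns are ignored. `T` in `ref_base` is converted to `U`.
#'
#' @param path Path to the TSV.
#' @return data.frame of typed position counts.
#' @export
read_counts_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("transcript_id", "pos", "ref_base", "coverage", "sub_count", "del_count")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("counts table missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[need]
  df$pos <- as.integer(df$pos)
  df$coverage <- as.integer(df$coverage)
  df$sub_count <- as.integer(df$sub_count)
  df$del_count <- as.integer(df$del_count)
  df$ref_base <- chartr("t", "u", chartr("T", "U", toupper(df$ref_base)))
  validate_counts(df)
  df
}

validate_counts <- function(df) {
  if (any(df$pos <= 0)) stop("counts table: pos must be >= 1 (1-based coordinates)")
  if (any(df$coverage < 0) || any(df$sub_count < 0) || any(df$del_count < 0)) {
    stop("counts table: negative counts")
  }
  if (any(!df$ref_base %in% c("A", "C", "G", "U"))) {
    stop("counts table: ref_base must be one of A,C,G,U")
  }
  over <- df$sub_count + df$del_count > df$coverage
  if (any(over)) {
    i <- which(over)[1]
    stop("counts table: sub_count + del_count exceeds coverage at ",
         df$transcript_id[i], ":", df$pos[i])
  }
  invisible(df)
}

#' Write a per-position mutation-count table
#' @param counts data.frame as returned by [read_counts_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' TSV dialect: columns `gene`, `transcript_id`, `start_codon_pos` (1-based
#' first nucleotide of the start codon), `cds_end_pos` (1-based inclusive,
#' last nucleotide of the stop codon).
#'
#' @param path Path to the TSV.
#' @param transcripts Optional transcript data.frame (from [read_fasta()])
#'   used to check that coordinates fall inside the transcript.
#' @return data.frame of annotations.
#' @export
read_annotation <- function(path, transcripts = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "transcript_id", "start_codon_pos", "cds_end_pos")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("annotation missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[need]
  df$start_codon_pos <- as.integer(df$start_codon_pos)
  df$cds_end_pos <- as.integer(df$cds_end_pos)
  validate_annotation(df, transcripts)
  df
}

validate_annotation <- function(df, transcripts = NULL) {
  if (any(df$start_codon_pos < 1) || any(df$start_codon_pos >= df$cds_end_pos)) {
    stop("annotation: need 1 <= start_codon_pos < cds_end_pos")
  }
  len <- df$cds_end_pos - df$start_codon_pos + 1L
  if (any(len %% 3L != 0L)) {
    stop("annotation: CDS length not divisible by 3 for gene(s): ",
         paste(df$gene[len %% 3L != 0L], collapse = ", "))
  }
  if (!is.null(transcripts)) {
    tl <- stats::setNames(transcripts$length, transcripts$id)
    unknown <- !df$transcript_id %in% names(tl)
    if (any(unknown)) {
      stop("annotation refers to unknown transcript(s): ",
           paste(unique(df$transcript_id[unknown]), collapse = ", "))
    }
    if (any(df$cds_end_pos > tl[df$transcript_id])) {
      stop("annotation: cds_end_pos beyond transcript length")
    }
  }
  invisible(df)
}

#' @rdname read_annotation
#' @param annotation data.frame of annotations.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a mask set
#'
#' Masks name positions that carry no usable probing signal: ranges covered
#' by PCR primers, RNA editing sites (apparent mutations unrelated to DMS),
#' and post-transcriptionally modified nucleotides (16S rRNA).
#'
#' @param primer_ranges data.frame with columns `transcript_id`, `start`,
#'   `end` (1-based inclusive), or NULL.
#' @param editing_sites data.frame with columns `transcript_id`, `pos`, or NULL.
#' @param modified_sites data.frame with columns `transcript_id`, `pos`, or NULL.
#' @return An object of class `mask_set`.
#' @export
mask_set <- function(primer_ranges = NULL, editing_sites = NULL,
                     modified_sites = NULL) {
  empty_rng <- data.frame(transcript_id = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
  empty_pos <- data.frame(transcript_id = character(), pos = integer(),
                          stringsAsFactors = FALSE)
  rng <- if (is.null(primer_ranges)) empty_rng else unique(primer_ranges)
  ed <- if (is.null(editing_sites)) empty_pos else unique(editing_sites)
  mo <- if (is.null(modified_sites)) empty_pos else unique(modified_sites)
  if (nrow(rng) && any(rng$end < rng$start)) stop("primer range with end < start")
  structure(list(primer_ranges = rng, editing_sites = ed, modified_sites = mo),
            class = "mask_set")
}

#' Read a mask TSV
#'
#' Dialect: columns `transcript_id`, `type` (`primer`, `editing`,
#' `modified`), `start`, `end`; for site masks `start == end`.
#'
#' @param path Path to the TSV.
#' @return A `mask_set`.
#' @export
read_masks <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "type", "start", "end")
  if (length(setdiff(need, names(df)))) {
    stop("mask table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(!df$type %in% c("primer", "editing", "modified"))) {
    stop("mask type must be primer, editing or modified")
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  expand <- function(sub) {
    if (!nrow(sub)) {
      return(data.frame(transcript_id = character(), pos = integer(),
                        stringsAsFactors = FALSE))
    }
    do.call(rbind, lapply(seq_len(nrow(sub)), function(i) {
      data.frame(transcript_id = sub$transcript_id[i],
                 pos = seq.int(sub$start[i], sub$end[i]),
                 stringsAsFactors = FALSE)
    }))
  }
  mask_set(
    primer_ranges = df[df$type == "primer", c("transcript_id", "start", "end")],
    editing_sites = expand(df[df$type == "editing", , drop = FALSE]),
    modified_sites = expand(df[df$type == "modified", , drop = FALSE])
  )
}

#' @rdname read_masks
#' @param masks A `mask_set`.
#' @export
write_masks <- function(masks, path) {
  stopifnot(inherits(masks, "mask_set"))
  rows <- list()
  if (nrow(masks$primer_ranges)) {
    rows$p <- cbind(masks$primer_ranges[, "transcript_id", drop = FALSE],
                    type = "primer", masks$primer_ranges[, c("start", "end")])
  }
  site_rows <- function(df, type) {
    if (!nrow(df)) return(NULL)
    data.frame(transcript_id = df$transcript_id, type = type,
               start = df$pos, end = df$pos, stringsAsFactors = FALSE)
  }
  rows$e <- site_rows(masks$editing_sites, "editing")
  rows$m <- site_rows(masks$modified_sites, "modified")
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(), type = character(),
                      start = integer(), end = integer())
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Positions masked for one transcript, by mask category; returns a list of
# integer vectors.
mask_positions <- function(masks, transcript_id) {
  stopifnot(inherits(masks, "mask_set"))
  rng <- masks$primer_ranges
  rng <- rng[rng$transcript_id == transcript_id, , drop = FALSE]
  primer <- if (nrow(rng)) {
    unique(unlist(lapply(seq_len(nrow(rng)),
                         function(i) seq.int(rng$start[i], rng$end[i]))))
  } else integer()
  pick <- function(df) sort(unique(df$pos[df$transcript_id == transcript_id]))
  list(primer = sort(primer),
       editing = pick(masks$editing_sites),
       modified = pick(masks$modified_sites))
}
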