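#' Resolve analysis regions from a gene annotation
#'
#' Relative coordinates are anchored at the first nucleotide of the start
#' codon (+1) and have no position 0 (-1 abuts +1). The regions are:
#' start codon (+1..+3), Shine-Dalgarno scan window (-22..-2, 21 nt),
#' translation initiation region (TIR, -25..+5, 30 nt), and coding region
#' (start codon through `cds_end_pos` inclusive). Regions reaching past the
#' transcript ends are truncated and flagged.
#'
#' @param annotation One or more annotation rows ([read_annotation()]).
#' @param transcript_length Length of the transcript, or a named vector of
#'   lengths keyed by transcript id, or a transcript data.frame from
#'   [read_fasta()].
#' @return data.frame with columns `gene`, `transcript_id`, `kind`
#'   (`start_codon`, `sd_window`, `tir`, `cds`), `start`, `end` (1-based
#'   inclusive, truncated to the transcript), `truncated`.
#' @export
resolve_regions <- function(annotation, transcript_length) {
  if (is.data.frame(transcript_length)) {
    transcript_length <- stats::setNames(transcript_length$length,
                                         transcript_length$id)
  }
  out <- lapply(seq_len(nrow(annotation)), function(i) {
    a <- annotation[i, ]
    len <- if (length(transcript_length) > 1 || !is.null(names(transcript_length))) {
      unname(transcript_length[[a$transcript_id]])
    } else {
      transcript_length
    }
    if (is.null(len) || is.na(len)) {
      stop("no transcript length for ", a$transcript_id)
    }
    s <- a$start_codon_pos
    # relative r maps to s + r - 1 for r > 0 and s + r for r < 0 (no 0)
    raw <- rbind(
      data.frame(kind = "start_codon", start = s, end = s + 2L),
      data.frame(kind = "sd_window", start = s - 22L, end = s - 2L),
      data.frame(kind = "tir", start = s - 25L, end = s + 4L),
      data.frame(kind = "cds", start = s, end = a$cds_end_pos)
    )
    raw$truncated <- raw$start < 1L | raw$end > len
    raw$start <- pmax(raw$start, 1L)
    raw$end <- pmin(raw$end, len)
    cbind(gene = a$gene, transcript_id = a$transcript_id, raw,
          stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mean normalized reactivity over a region
#'
#' Arithmetic mean of normalized reactivities over the unmasked positions of
#' the region whose reference base is in `base_set`. Masked or missing
#' positions are excluded, never imputed as zero; a region with no
#' contributing position yields `NA`, not 0.
#'
#' @param profile A normalized `reactivity_profile`.
#' @param region One row of [resolve_regions()] output, or a list/row with
#'   `start`, `end` (and optionally `transcript_id`).
#' @param base_set Character vector of reference bases to include, e.g.
#'   `"A"` for start-codon accessibility or `c("A", "C")` for SD/TIR means.
#' @return List with `mean` (NA if no positions contribute) and `n` used.
#' @export
region_mean_reactivity <- function(profile, region, base_set = c("A", "C")) {
  prof <- as.data.frame(profile)
  sel <- prof$pos >= region$start & prof$pos <= region$end &
    prof$mask_reason == "none" & !is.na(prof$normalized) &
    prof$ref_base %in% base_set
  if (!is.null(region$transcript_id)) {
    sel <- sel & prof$transcript_id == region$transcript_id
  }
  x <- prof$normalized[sel]
  list(mean = if (length(x)) mean(x) else NA_real_, n = length(x))
}
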