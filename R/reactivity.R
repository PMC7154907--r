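#' Raw per-position mutation rates with masking
#'
#' The raw DMS reactivity of a position is its mutation rate,
#' `(sub_count + del_count) / coverage`. Positions are masked (no rate)
#' when they fall inside a PCR primer range, are RNA editing sites, are
#' post-transcriptionally modified nucleotides, or have coverage below
#' `min_coverage` mapped reads. Mask precedence when several apply:
#' primer > editing_site > modified_site > low_coverage.
#'
#' @param counts Counts data.frame ([read_counts_table()] dialect).
#' @param masks A [mask_set()] (default: nothing masked).
#' @param min_coverage Minimum read coverage to report a rate.
#' @return A `reactivity_profile`: data.frame with columns `transcript_id`,
#'   `pos`, `ref_base`, `channel` (`AC` for A/C, `GU` for G/U), `coverage`,
#'   `raw_rate`, `normalized` (NA until normalization), `mask_reason`.
#' @export
compute_raw_rates <- function(counts, masks = mask_set(), min_coverage = 2500) {
  validate_counts(counts)
  if (!nrow(counts)) {
    prof <- data.frame(transcript_id = character(), pos = integer(),
                       ref_base = character(), channel = character(),
                       coverage = integer(), raw_rate = numeric(),
                       normalized = numeric(), mask_reason = character(),
                       stringsAsFactors = FALSE)
    class(prof) <- c("reactivity_profile", "data.frame")
    return(prof)
  }
  counts <- counts[order(counts$transcript_id, counts$pos), , drop = FALSE]
  dup <- duplicated(counts[c("transcript_id", "pos")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop("position present twice: ", counts$transcript_id[i], ":", counts$pos[i])
  }
  reason <- rep("none", nrow(counts))
  for (id in unique(counts$transcript_id)) {
    sel <- counts$transcript_id == id
    mp <- mask_positions(masks, id)
    pos <- counts$pos[sel]
    r <- rep("none", sum(sel))
    r[pos %in% mp$modified] <- "modified_site"
    r[pos %in% mp$editing] <- "editing_site"
    r[pos %in% mp$primer] <- "primer"
    low <- r == "none" & counts$coverage[sel] < min_coverage
    r[low] <- "low_coverage"
    reason[sel] <- r
  }
  raw <- ifelse(reason == "none",
                (counts$sub_count + counts$del_count) / counts$coverage,
                NA_real_)
  prof <- data.frame(
    transcript_id = counts$transcript_id, pos = counts$pos,
    ref_base = counts$ref_base,
    channel = ifelse(counts$ref_base %in% c("A", "C"), "AC", "GU"),
    coverage = counts$coverage, raw_rate = raw,
    normalized = NA_real_, mask_reason = reason,
    stringsAsFactors = FALSE
  )
  class(prof) <- c("reactivity_profile", "data.frame")
  prof
}

# Divisor of the percentile-window normalization: mean of the raw rates
# whose value lies strictly above the p_lo percentile and at or below the
# p_hi percentile (type-7 interpolated percentiles). When the strict window
# is empty (heavily tied channels, e.g. all rates equal), the window falls
# back to inclusive bounds so that a constant channel normalizes to 1.
norm_window_divisor <- function(x, p_lo = 0.90, p_hi = 0.99) {
  q <- stats::quantile(x, c(p_lo, p_hi), type = 7, names = FALSE)
  sel <- x > q[1] & x <= q[2]
  if (!any(sel)) sel <- x >= q[1] & x <= q[2]
  if (!any(sel)) return(NA_real_)
  mean(x[sel])
}

#' Two-channel percentile normalization of raw reactivities
#'
#' A/C and G/U reactivities are normalized separately, because DMS
#' modification of G/U is far weaker than of A/C. Within each transcript and
#' channel, every raw rate is divided by the average raw rate of the
#' 90th-99th percentile window of that transcript-channel, so the most
#' reactive (but not outlier) nucleotides average ~1.
#'
#' A transcript-channel with fewer than `min_positions` unmasked positions,
#' or whose window divisor is not strictly positive (all-zero channel), is
#' flagged unnormalizable: its `normalized` values stay `NA` and the flag is
#' recorded in the profile's `"normalization"` attribute.
#'
#' @param profile A `reactivity_profile` with raw rates.
#' @param window Percentile window `c(low, high)` as fractions.
#' @param min_positions Minimum unmasked positions per transcript-channel.
#' @return The profile with `normalized` filled in; the `"normalization"`
#'   attribute holds one row per transcript-channel (divisor, n, flag).
#' @export
normalize_two_channel <- function(profile, window = c(0.90, 0.99),
                                  min_positions = 20) {
  stopifnot(length(window) == 2, window[1] < window[2])
  prof <- profile
  groups <- unique(prof[c("transcript_id", "channel")])
  info <- NULL
  for (k in seq_len(nrow(groups))) {
    sel <- prof$transcript_id == groups$transcript_id[k] &
      prof$channel == groups$channel[k] & prof$mask_reason == "none" &
      !is.na(prof$raw_rate)
    x <- prof$raw_rate[sel]
    divisor <- NA_real_
    flag <- "ok"
    if (length(x) < min_positions) {
      flag <- "too_few_positions"
    } else {
      divisor <- norm_window_divisor(x, window[1], window[2])
      if (!is.finite(divisor) || divisor <= 0) {
        flag <- "zero_divisor"
        divisor <- NA_real_
      }
    }
    if (flag == "ok") prof$normalized[sel] <- x / divisor
    info <- rbind(info, data.frame(
      transcript_id = groups$transcript_id[k], channel = groups$channel[k],
      n_unmasked = length(x), divisor = divisor, flag = flag,
      stringsAsFactors = FALSE))
  }
  attr(prof, "normalization") <- info
  prof
}

#' Transcript-wise upper winsorization of normalized reactivities
#'
#' Caps extremely high normalized values: per transcript (both channels
#' pooled), values above the `level` percentile are replaced by that
#' percentile. The percentile is the type-1 (inverse-ECDF) order statistic,
#' which makes winsorization exactly idempotent. One-sided: low values are
#' never altered and no value is removed.
#'
#' @param profile A normalized `reactivity_profile`.
#' @param level Winsorization percentile (fraction), default 0.99.
#' @return The profile with `normalized` capped.
#' @export
winsorize_99 <- function(profile, level = 0.99) {
  prof <- profile
  for (id in unique(prof$transcript_id)) {
    sel <- prof$transcript_id == id & !is.na(prof$normalized)
    if (!any(sel)) next
    cap <- stats::quantile(prof$normalized[sel], level, type = 1, names = FALSE)
    prof$normalized[sel] <- pmin(prof$normalized[sel], cap)
  }
  prof
}

#' Full reactivity pipeline: rates, two-channel normalization, winsorization
#'
#' Fixed composition [compute_raw_rates()] then [normalize_two_channel()]
#' then [winsorize_99()].
#'
#' @inheritParams compute_raw_rates
#' @inheritParams normalize_two_channel
#' @param winsor_level Winsorization percentile (fraction).
#' @return A normalized, winsorized `reactivity_profile`.
#' @export
reactivity_pipeline <- function(counts, masks = mask_set(),
                                min_coverage = 2500, window = c(0.90, 0.99),
                                min_positions = 20, winsor_level = 0.99) {
  if (!nrow(counts)) {
    return(compute_raw_rates(counts, masks, min_coverage))
  }
  prof <- compute_raw_rates(counts, masks, min_coverage)
  prof <- normalize_two_channel(prof, window, min_positions)
  winsorize_99(prof, winsor_level)
}

#' Write a reactivity profile as TSV
#' @param profile A `reactivity_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reactivity <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
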