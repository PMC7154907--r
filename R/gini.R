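#' Gini index of reactivity values
#'
#' Dispersion statistic in `[0, 1]` used here as a structure score: a highly
#' structured RNA concentrates its normalized DMS reactivity in few
#' accessible positions (Gini near 1), while an unstructured RNA spreads
#' reactivity evenly (Gini near 0).
#'
#' Two estimator forms are provided. The default population
#' (mean-absolute-difference) form is
#' \deqn{G = \sum_i \sum_j |x_i - x_j| / (2 n^2 \bar x),}
#' the `"sample"` switch uses the bias-corrected divisor `2 n (n-1) \bar x`.
#'
#' @param values Non-negative numeric vector (NA dropped), `n >= 2`, mean > 0.
#' @param form `"population"` (default) or `"sample"`.
#' @return List of class `gini_result`: `value`, `n_used`, `form`.
#' @examples
#' gini(c(0, 1))$value  # 0.5 (population form)
#' @export
gini <- function(values, form = c("population", "sample")) {
  form <- match.arg(form)
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 2) stop("gini needs at least 2 non-missing values")
  if (any(x < 0)) stop("gini is defined for non-negative values")
  m <- mean(x)
  if (m <= 0) stop("gini undefined for zero-mean values")
  # sorted form of the pairwise-difference sum: sum_i (2i - n - 1) x_(i)
  xs <- sort(x)
  s <- sum((2 * seq_len(n) - n - 1) * xs)
  denom <- if (form == "population") n^2 * m else n * (n - 1) * m
  structure(list(value = s / denom, n_used = n, form = form),
            class = "gini_result")
}

#' Gini index of a profile region
#'
#' Convenience wrapper: Gini of the normalized reactivities of unmasked
#' positions in a region, restricted to a base set (A/C by default, the
#' reliable DMS channel; `ACGU` available for four-nucleotide variants).
#'
#' @inheritParams region_mean_reactivity
#' @param base_set Reference bases included (default A and C).
#' @param form Estimator form, see [gini()].
#' @return A `gini_result`, or `NULL` when fewer than 2 positions contribute.
#' @export
region_gini <- function(profile, region, base_set = c("A", "C"),
                        form = c("population", "sample")) {
  prof <- as.data.frame(profile)
  sel <- prof$pos >= region$start & prof$pos <= region$end &
    prof$mask_reason == "none" & !is.na(prof$normalized) &
    prof$ref_base %in% base_set
  if (!is.null(region$transcript_id)) {
    sel <- sel & prof$transcript_id == region$transcript_id
  }
  x <- prof$normalized[sel]
  if (length(x) < 2 || mean(x) <= 0) return(NULL)
  gini(x, form = match.arg(form))
}
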