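#' Ground-truth accessibility labels from a reference structure
#'
#' The positive class for validating DMS reactivity: positions that are
#' both unpaired and solvent-accessible in the reference (crystal) structure.
#' Paired or buried positions are negatives.
#'
#' @param struct A [reference_structure()].
#' @return Logical vector, one entry per position.
#' @export
accessibility_labels <- function(struct) {
  struct$partner == 0L & struct$solvent_accessible
}

#' ROC curve and AUC of reactivity against structure labels
#'
#' Sweeps a threshold over normalized reactivities of unmasked positions
#' whose reference base passes `base_filter`, scoring positions above the
#' threshold as predicted-accessible. Ties are handled by grouping equal
#' scores into one threshold step, so the AUC (trapezoidal area) equals the
#' Mann-Whitney U statistic `P(score_pos > score_neg) + 0.5 P(equal)`.
#'
#' @param profile A normalized `reactivity_profile` for one transcript.
#' @param labels Logical vector of per-position truth labels
#'   ([accessibility_labels()]), indexed by transcript position.
#' @param base_filter One of `"A"`, `"C"`, `"G"`, `"U"`, `"AC"`, `"GU"`,
#'   `"ACGU"`.
#' @return List of class `roc_result`: `auc`, `curve` (data.frame `fpr`,
#'   `tpr`, `threshold`), `n_pos`, `n_neg`, `base_filter`.
#' @export
roc_auc <- function(profile, labels, base_filter = "AC") {
  base_filter <- match.arg(base_filter,
                           c("A", "C", "G", "U", "AC", "GU", "ACGU"))
  bases <- strsplit(base_filter, "", fixed = TRUE)[[1]]
  prof <- as.data.frame(profile)
  sel <- prof$mask_reason == "none" & !is.na(prof$normalized) &
    prof$ref_base %in% bases
  pos <- prof$pos[sel]
  if (any(pos > length(labels))) stop("profile position beyond label vector")
  scores <- prof$normalized[sel]
  y <- labels[pos]
  roc_from_scores(scores, y, base_filter)
}

# Threshold-sweep ROC on raw score/label vectors.
roc_from_scores <- function(scores, y, base_filter = "ACGU") {
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC needs at least one positive and one negative")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  yy <- y[o]
  # one curve point per distinct score (tie group)
  last <- which(diff(s) != 0)
  idx <- c(last, length(s))
  tp <- cumsum(yy)[idx]
  fp <- cumsum(!yy)[idx]
  curve <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos),
                      threshold = c(Inf, s[idx]))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  structure(list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg,
                 base_filter = base_filter),
            class = "roc_result")
}

#' Write a ROC curve as TSV
#' @param roc A `roc_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roc <- function(roc, path) {
  utils::write.table(roc$curve, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
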