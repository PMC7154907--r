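#' Folding configuration for the reactivity-guided stand-in folder
#'
#' @param min_loop Minimum number of unpaired nucleotides enclosed by a pair
#'   (a pair i,j requires `j - i > min_loop`).
#' @param theta Reactivity threshold above which a paired A/C is penalized.
#' @param lambda Penalty per paired high-reactivity A/C position.
#' @param pair_bonus Score contributed by each pair.
#' @param max_span Optional maximum pairing distance `j - i` (off by
#'   default; mirrors a maximum-distance restraint in external folders).
#' @return List of class `fold_config`.
#' @export
fold_config <- function(min_loop = 3, theta = 0.4, lambda = 1,
                        pair_bonus = 1, max_span = NULL) {
  if (min_loop < 0) stop("min_loop must be >= 0")
  if (theta <= 0) stop("theta must be positive")
  if (lambda < 0) stop("lambda must be >= 0")
  structure(list(min_loop = as.integer(min_loop), theta = theta,
                 lambda = lambda, pair_bonus = pair_bonus,
                 max_span = if (is.null(max_span)) NULL else as.integer(max_span)),
            class = "fold_config")
}

can_pair_matrix <- function(bases, allow_wobble = TRUE) {
  outer(bases, bases, wc_or_wobble, allow_wobble = allow_wobble)
}

# Nested-structure DP over per-pair scores. pair_score[i, j] gives the score
# of pairing i with j (-Inf = disallowed). Tie-break in traceback: prefer
# pairing i, and with the smallest admissible partner j.
fold_dp <- function(n, pair_score, min_loop, max_span = NULL) {
  M <- matrix(0, max(n, 1), max(n, 1))
  eps <- 1e-9
  get <- function(i, j) if (i > j) 0 else M[i, j]
  if (n >= 2) {
    for (span in seq_len(n - 1)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- get(i + 1, j)  # i unpaired
        lo <- i + min_loop + 1
        if (lo <= j) {
          for (k in lo:j) {
            if (!is.null(max_span) && k - i > max_span) break
            ps <- pair_score[i, k]
            if (!is.finite(ps)) next
            cand <- ps + get(i + 1, k - 1) + get(k + 1, j)
            if (cand > best + eps) best <- cand
          }
        }
        M[i, j] <- best
      }
    }
  }
  pairs <- matrix(integer(0), ncol = 2)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (i >= j) next
    target <- get(i, j)
    placed <- FALSE
    ks <- if (i + min_loop + 1 <= j) seq.int(i + min_loop + 1, j) else integer()
    if (!is.null(max_span)) ks <- ks[ks - i <= max_span]
    for (k in ks) {
      ps <- pair_score[i, k]
      if (!is.finite(ps)) next
      if (abs(ps + get(i + 1, k - 1) + get(k + 1, j) - target) < eps) {
        pairs <- rbind(pairs, c(i, k))
        stack <- c(stack, list(c(i + 1L, k - 1L)), list(c(k + 1L, j)))
        placed <- TRUE
        break
      }
    }
    if (!placed) stack <- c(stack, list(c(i + 1L, j)))
  }
  list(score = get(1, n), pairs = pairs)
}

validate_fold <- function(pairs, n, min_loop) {
  if (!nrow(pairs)) return(invisible(TRUE))
  if (any(pairs[, 2] - pairs[, 1] <= min_loop)) stop("min_loop violated")
  used <- c(pairs[, 1], pairs[, 2])
  if (anyDuplicated(used)) stop("position in more than one pair")
  if (any(used < 1 | used > n)) stop("pair index out of range")
  for (a in seq_len(nrow(pairs))) {
    for (b in seq_len(nrow(pairs))) {
      i <- pairs[a, 1]; j <- pairs[a, 2]
      k <- pairs[b, 1]; l <- pairs[b, 2]
      if (i < k && k < j && j < l) stop("crossing pairs (pseudoknot)")
    }
  }
  invisible(TRUE)
}

#' Maximum-pairing (Nussinov) fold
#'
#' Baseline nested-structure fold maximizing the number of Watson-Crick /
#' G·U pairs subject to `j - i > min_loop`. A deterministic tie-break
#' (prefer pairing the leftmost position, with its smallest admissible
#' partner) makes output reproducible. This is a testing/visualization
#' stand-in, not a thermodynamic folder.
#'
#' @param sequence RNA sequence.
#' @param min_loop Minimum enclosed unpaired stretch (default 3).
#' @param max_span Optional maximum pairing distance.
#' @param allow_wobble Allow G·U pairs (default TRUE).
#' @return List of class `fold_result`: `pairs` (2-column matrix, i < j),
#'   `score`, `n`, `method`.
#' @examples
#' nussinov_fold("GGGAAACCC")$pairs
#' @export
nussinov_fold <- function(sequence, min_loop = 3, max_span = NULL,
                          allow_wobble = TRUE) {
  bases <- seq_bases(toupper(chartr("Tt", "Uu", sequence)))
  n <- length(bases)
  cp <- can_pair_matrix(bases, allow_wobble)
  ps <- ifelse(cp, 1, -Inf)
  res <- fold_dp(n, ps, as.integer(min_loop), max_span)
  validate_fold(res$pairs, n, min_loop)
  structure(list(pairs = res$pairs, score = res$score, n = n,
                 method = "nussinov"), class = "fold_result")
}

#' Reactivity-guided fold
#'
#' Same dynamic program as [nussinov_fold()], but each pair scores
#' `pair_bonus - lambda * (#high-reactivity A/C endpoints)`: an unmasked A
#' or C with normalized reactivity above `theta` is penalized when paired,
#' emulating soft reactivity constraints. G/U and masked positions carry no
#' penalty. With flat zero reactivity the result equals the unguided fold;
#' with very large `lambda` no high-reactivity A/C is paired.
#'
#' @param sequence RNA sequence.
#' @param profile A normalized `reactivity_profile` aligned with
#'   `sequence` (positions 1..n), or NULL for no guidance.
#' @param config A [fold_config()].
#' @param allow_wobble Allow G·U pairs.
#' @return A `fold_result` with method `"nussinov_guided"`.
#' @export
guided_fold <- function(sequence, profile = NULL, config = fold_config(),
                        allow_wobble = TRUE) {
  bases <- seq_bases(toupper(chartr("Tt", "Uu", sequence)))
  n <- length(bases)
  penal <- numeric(n)
  if (!is.null(profile)) {
    prof <- as.data.frame(profile)
    if (any(prof$pos > n)) stop("profile position beyond sequence length")
    hi <- prof$mask_reason == "none" & !is.na(prof$normalized) &
      prof$channel == "AC" & prof$normalized > config$theta
    penal[prof$pos[hi]] <- config$lambda
  }
  cp <- can_pair_matrix(bases, allow_wobble)
  ps <- ifelse(cp, config$pair_bonus - outer(penal, penal, `+`), -Inf)
  res <- fold_dp(n, ps, config$min_loop, config$max_span)
  validate_fold(res$pairs, n, config$min_loop)
  structure(list(pairs = res$pairs, score = res$score, n = n,
                 method = "nussinov_guided"), class = "fold_result")
}

#' Arc table from a fold result
#'
#' Emits one row per base pair (`i`, `j`), optionally with a per-position
#' reactivity column, in the TSV form consumed by arc-plot renderers.
#'
#' @param fold A `fold_result`.
#' @param path Optional output TSV path.
#' @param reactivity Optional numeric vector of per-position reactivities.
#' @return The arc data.frame, invisibly when written.
#' @export
pairs_to_arcs <- function(fold, path = NULL, reactivity = NULL) {
  pr <- fold$pairs
  df <- data.frame(i = if (nrow(pr)) pr[, 1] else integer(),
                   j = if (nrow(pr)) pr[, 2] else integer())
  df <- df[order(df$i), , drop = FALSE]
  if (!is.null(reactivity) && nrow(df)) {
    df$reactivity_i <- reactivity[df$i]
    df$reactivity_j <- reactivity[df$j]
  }
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Dot-bracket string from a (nested) fold result
#' @param fold A `fold_result`.
#' @return Dot-bracket string of length `fold$n`.
#' @export
pairs_to_dotbracket <- function(fold) {
  db <- rep(".", fold$n)
  if (nrow(fold$pairs)) {
    db[fold$pairs[, 1]] <- "("
    db[fold$pairs[, 2]] <- ")"
  }
  paste(db, collapse = "")
}
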