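# Independent oracles used to validate the package's implementations.
# These deliberately use the most naive formulation available.

# Gini by explicit pairwise summation.
gini_brute <- function(x, form = "population") {
  n <- length(x)
  s <- sum(abs(outer(x, x, "-")))
  denom <- if (form == "population") 2 * n^2 * mean(x) else 2 * n * (n - 1) * mean(x)
  s / denom
}

# AUC by concordant-pair counting (Mann-Whitney form).
auc_pairs <- function(scores, y) {
  sp <- scores[y]
  sn <- scores[!y]
  cmp <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
  mean(cmp)
}

# All nested pair sets over positions i..j (explicit enumeration).
# canpair: n x n logical matrix. Returns a list of 2-column matrices.
enum_structures <- function(i, j, canpair, min_loop = 3) {
  if (i >= j) return(list(matrix(integer(0), ncol = 2)))
  out <- enum_structures(i + 1, j, canpair, min_loop)
  ks <- seq.int(i + min_loop + 1, length.out = max(0, j - i - min_loop))
  for (k in ks) {
    if (!canpair[i, k]) next
    left <- enum_structures(i + 1, k - 1, canpair, min_loop)
    right <- enum_structures(k + 1, j, canpair, min_loop)
    for (L in left) for (R in right) {
      out[[length(out) + 1]] <- rbind(c(i, k), L, R)
    }
  }
  out
}

# Best achievable score over all nested structures, by enumeration.
enum_best_score <- function(bases, score_pair, min_loop = 3,
                            allow_wobble = TRUE) {
  n <- length(bases)
  canpair <- outer(bases, bases, function(a, b) {
    (a == "A" & b == "U") | (a == "U" & b == "A") |
      (a == "C" & b == "G") | (a == "G" & b == "C") |
      (allow_wobble & ((a == "G" & b == "U") | (a == "U" & b == "G")))
  })
  structs <- enum_structures(1, n, canpair, min_loop)
  best <- 0
  for (s in structs) {
    if (!nrow(s)) next
    sc <- sum(apply(s, 1, function(p) score_pair(p[1], p[2])))
    if (sc > best) best <- sc
  }
  best
}

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                              collapse = "")

# Profile builder: a single-transcript reactivity profile straight from
# given raw rates (bypassing counts), for unit tests of downstream metrics.
profile_from_values <- function(normalized, bases = NULL,
                                transcript_id = "t1",
                                mask_reason = NULL) {
  n <- length(normalized)
  if (is.null(bases)) bases <- rep("A", n)
  if (is.null(mask_reason)) mask_reason <- rep("none", n)
  structure(data.frame(
    transcript_id = transcript_id, pos = seq_len(n), ref_base = bases,
    channel = ifelse(bases %in% c("A", "C"), "AC", "GU"),
    coverage = 10000L, raw_rate = normalized, normalized = normalized,
    mask_reason = mask_reason, stringsAsFactors = FALSE),
    class = c("reactivity_profile", "data.frame"))
}

# Counts builder with uniform coverage and mutation counts giving exact
# raw rates rate = k / coverage.
counts_from_rates <- function(rates, bases = NULL, coverage = 100000L,
                              transcript_id = "t1") {
  n <- length(rates)
  if (is.null(bases)) bases <- rep("A", n)
  mut <- as.integer(round(rates * coverage))
  data.frame(transcript_id = transcript_id, pos = seq_len(n),
             ref_base = bases, coverage = coverage,
             sub_count = mut, del_count = 0L, stringsAsFactors = FALSE)
}
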