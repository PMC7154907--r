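#' Simulation configuration for synthetic DMS-MaPseq counts
#'
#' Defaults encode the qualitative behaviour of DMS probing read out by
#' mutational profiling: accessible (unpaired and solvent-exposed) A/C
#' positions are modified an order of magnitude more often than protected
#' ones, while the G/U channel separates only weakly; a small
#' sequencing/RT error floor applies everywhere; RNA editing sites show a
#' high apparent mutation rate regardless of structure.
#'
#' @param rate_unpaired_AC,rate_paired_AC Modification probability of
#'   accessible / protected A and C positions.
#' @param rate_unpaired_GU,rate_paired_GU Same for G and U (weaker signal).
#' @param error_rate Baseline mutation probability added at every position.
#' @param editing_rate Apparent mutation rate at declared editing sites.
#' @param coverage_mean,coverage_dispersion Negative-binomial coverage model
#'   (mean and `size` dispersion; larger `size` = less overdispersion).
#' @param sub_fraction Fraction of simulated mutations emitted as
#'   substitutions; the rest are deletions. Downstream analysis sums both.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(rate_unpaired_AC = 0.02, rate_paired_AC = 0.002,
                       rate_unpaired_GU = 0.006, rate_paired_GU = 0.002,
                       error_rate = 0.001, editing_rate = 0.10,
                       coverage_mean = 5000, coverage_dispersion = 10,
                       sub_fraction = 0.8) {
  cfg <- list(rate_unpaired_AC = rate_unpaired_AC,
              rate_paired_AC = rate_paired_AC,
              rate_unpaired_GU = rate_unpaired_GU,
              rate_paired_GU = rate_paired_GU,
              error_rate = error_rate, editing_rate = editing_rate,
              coverage_mean = coverage_mean,
              coverage_dispersion = coverage_dispersion,
              sub_fraction = sub_fraction)
  rates <- unlist(cfg[1:6])
  if (any(rates < 0 | rates > 1)) stop("rates must be probabilities in [0,1]")
  if (rate_unpaired_AC <= rate_paired_AC) {
    stop("rate_unpaired_AC must exceed rate_paired_AC")
  }
  if (rate_unpaired_GU <= rate_paired_GU) {
    stop("rate_unpaired_GU must exceed rate_paired_GU")
  }
  if (max(rates[1:4]) + error_rate > 1) stop("rate + error_rate exceeds 1")
  if (coverage_mean <= 0 || coverage_dispersion <= 0) {
    stop("coverage model parameters must be positive")
  }
  if (sub_fraction < 0 || sub_fraction > 1) stop("sub_fraction must be in [0,1]")
  structure(cfg, class = "sim_config")
}

#' Assign ground-truth modification rates from a structure
#'
#' A position receives its channel's "unpaired" rate iff it is both unpaired
#' and solvent-accessible in the reference structure (the positive class of
#' the ROC validation); every other position receives the channel's
#' "paired" rate. Declared RNA editing sites receive `editing_rate`
#' regardless of structure, emulating editing confounders.
#'
#' @param transcript One-row transcript data.frame or an RNA sequence string.
#' @param struct A [reference_structure()] of matching length.
#' @param config A [sim_config()].
#' @param editing_sites Integer positions of RNA editing sites.
#' @return data.frame (class `true_rate_track`) with columns `pos`, `base`,
#'   `channel`, `rate`, `positive` (unpaired AND accessible).
#' @export
assign_true_rates <- function(transcript, struct, config = sim_config(),
                              editing_sites = integer()) {
  seqs <- if (is.character(transcript)) transcript else transcript$sequence
  bases <- seq_bases(seqs)
  n <- length(bases)
  if (n != length(struct$partner)) {
    stop("structure length (", length(struct$partner),
         ") does not match transcript length (", n, ")")
  }
  positive <- struct$partner == 0L & struct$solvent_accessible
  ac <- bases %in% c("A", "C")
  rate <- ifelse(positive,
                 ifelse(ac, config$rate_unpaired_AC, config$rate_unpaired_GU),
                 ifelse(ac, config$rate_paired_AC, config$rate_paired_GU))
  if (length(editing_sites)) {
    if (any(editing_sites < 1 | editing_sites > n)) {
      stop("editing site outside transcript")
    }
    rate[editing_sites] <- config$editing_rate
  }
  structure(data.frame(pos = seq_len(n), base = bases,
                       channel = ifelse(ac, "AC", "GU"),
                       rate = rate, positive = positive,
                       stringsAsFactors = FALSE),
            class = c("true_rate_track", "data.frame"))
}

#' Simulate a mutation-count table from a true-rate track
#'
#' Coverage is negative-binomial (mean `coverage_mean`, size
#' `coverage_dispersion`); positions inside primer ranges get coverage 0
#' (primers carry no structural signal). The mutation count is binomial
#' with probability `rate + error_rate`, then split into substitutions and
#' deletions at `sub_fraction`.
#'
#' @param track A track from [assign_true_rates()].
#' @param config A [sim_config()].
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @param transcript_id Id written into the table.
#' @param masks Optional [mask_set()]; only primer ranges affect simulation.
#' @return Counts data.frame in the [read_counts_table()] dialect.
#' @export
simulate_counts <- function(track, config = sim_config(), seed = NULL,
                            transcript_id = "synthetic", masks = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(track)
  cov <- stats::rnbinom(n, size = config$coverage_dispersion,
                        mu = config$coverage_mean)
  if (!is.null(masks)) {
    primer <- mask_positions(masks, transcript_id)$primer
    cov[primer[primer <= n]] <- 0L
  }
  p <- pmin(track$rate + config$error_rate, 1)
  mut <- stats::rbinom(n, cov, p)
  sub <- as.integer(round(config$sub_fraction * mut))
  data.frame(transcript_id = transcript_id, pos = track$pos,
             ref_base = track$base, coverage = as.integer(cov),
             sub_count = sub, del_count = as.integer(mut - sub),
             stringsAsFactors = FALSE)
}

#' Simulate paired in vivo / in vitro conditions with a protein footprint
#'
#' The "in vitro" table is simulated from the structure as given (protein-free
#' refolded RNA). For the "in vivo" table, every base pair with at least one
#' endpoint inside `footprint_range` is removed and both endpoints are made
#' solvent-accessible, emulating an RNA-binding protein whose footprint
#' prevents a stem from forming and so exposes the covered region (e.g. a
#' start codon).
#'
#' @param transcript One-row transcript data.frame or sequence string.
#' @param struct A [reference_structure()].
#' @param footprint_range Integer `c(start, end)`, 1-based inclusive; may be
#'   empty (`NULL`) for identical conditions.
#' @param config A [sim_config()].
#' @param seed Integer seed; the two conditions use seeds `seed` and
#'   `seed + 1`.
#' @param transcript_id Id for the emitted tables.
#' @return List with `vivo` and `vitro` counts tables, the released
#'   `structure_vivo`, and the two rate tracks.
#' @export
make_paired_conditions <- function(transcript, struct, footprint_range,
                                   config = sim_config(), seed = NULL,
                                   transcript_id = "synthetic") {
  n <- length(struct$partner)
  sv <- struct
  if (!is.null(footprint_range) && length(footprint_range)) {
    if (length(footprint_range) != 2 || footprint_range[1] > footprint_range[2] ||
        footprint_range[1] < 1 || footprint_range[2] > n) {
      stop("footprint_range must be c(start, end) within the transcript")
    }
    fp <- seq.int(footprint_range[1], footprint_range[2])
    partner <- struct$partner
    hit <- which(partner != 0L & (seq_len(n) %in% fp | partner %in% fp))
    released <- unique(c(hit, partner[hit]))
    partner[released] <- 0L
    acc <- struct$solvent_accessible
    acc[released] <- TRUE
    acc[fp] <- TRUE
    sv <- reference_structure(struct$transcript_id, partner,
                              solvent_accessible = acc,
                              sequence = struct$sequence)
  }
  track_vitro <- assign_true_rates(transcript, struct, config)
  track_vivo <- assign_true_rates(transcript, sv, config)
  list(
    vivo = simulate_counts(track_vivo, config,
                           seed = if (is.null(seed)) NULL else seed,
                           transcript_id = transcript_id),
    vitro = simulate_counts(track_vitro, config,
                            seed = if (is.null(seed)) NULL else seed + 1L,
                            transcript_id = transcript_id),
    structure_vivo = sv,
    track_vivo = track_vivo, track_vitro = track_vitro
  )
}

#' Generate a hairpin-rich synthetic transcript with known structure
#'
#' Builds a transcript as a series of stem-loops separated by unpaired
#' spacers, the kind of locally folded architecture against which probing
#' pipelines are validated (an rRNA-like control). Unpaired positions are
#' solvent-accessible with probability `p_acc_unpaired`, paired positions
#' with `p_acc_paired`, so the positive class (unpaired AND accessible) is a
#' strict subset of unpaired positions, as in a ribosome crystal structure.
#'
#' @param target_length Approximate transcript length (nt).
#' @param stem,loop,spacer Lengths (nt) of each hairpin's stem arm, its
#'   loop, and the spacer between hairpins.
#' @param p_acc_unpaired,p_acc_paired Solvent-accessibility probabilities.
#' @param seed Integer seed.
#' @param transcript_id Id of the synthetic transcript.
#' @return List with `transcript` (one-row data.frame) and `structure`
#'   (a [reference_structure()]).
#' @export
synth_structured_transcript <- function(target_length = 1500, stem = 8,
                                        loop = 6, spacer = 10,
                                        p_acc_unpaired = 0.85,
                                        p_acc_paired = 0.5,
                                        seed = NULL,
                                        transcript_id = "synthetic_16S_like") {
  if (!is.null(seed)) set.seed(seed)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  bases <- character(0)
  partner <- integer(0)
  rand <- function(k) sample(c("A", "C", "G", "U"), k, replace = TRUE)
  add_spacer <- function(k) {
    bases <<- c(bases, rand(k))
    partner <<- c(partner, integer(k))
  }
  add_spacer(spacer)
  while (length(bases) + 2 * stem + loop + spacer <= target_length) {
    left <- rand(stem)
    lp <- rand(loop)
    right <- rev(unname(comp[left]))
    o <- length(bases)
    bases <- c(bases, left, lp, right)
    pl <- o + seq_len(stem)
    pr <- o + 2 * stem + loop + 1L - seq_len(stem)
    pp <- integer(2 * stem + loop)
    pp[seq_len(stem)] <- pr
    pp[2 * stem + loop + 1L - seq_len(stem)] <- pl
    partner <- c(partner, pp)
    add_spacer(spacer)
  }
  n <- length(bases)
  acc <- ifelse(partner == 0L,
                stats::runif(n) < p_acc_unpaired,
                stats::runif(n) < p_acc_paired)
  seqs <- paste(bases, collapse = "")
  list(
    transcript = data.frame(id = transcript_id, sequence = seqs, length = n,
                            stringsAsFactors = FALSE),
    structure = reference_structure(transcript_id, partner,
                                    solvent_accessible = acc,
                                    sequence = seqs)
  )
}

#' Fixture: a transcript whose start codon is buried in a stem under a
#' protein footprint
#'
#' Builds the scenario of a 5'-UTR RNA-binding-protein footprint that
#' prevents a stem-loop from forming: the stem's 3' arm covers the start
#' codon, the footprint covers the 5' arm. Simulating the "in vivo"
#' condition with this footprint releases the stem and exposes the start
#' codon, while the "in vitro" (protein-free) condition keeps it paired.
#' Downstream of the start codon the transcript continues with ordinary
#' hairpins so normalization has realistic context.
#'
#' @param seed Integer seed for the random flanking sequence.
#' @param utr_len Unpaired 5'-UTR length before the stem.
#' @param stem_len,loop_len Stem-loop geometry; the start codon sits at the
#'   third position of the stem's 3' arm.
#' @param tail_length Approximate length of the downstream hairpin region.
#' @return List with `transcript`, `structure`, `annotation` (one-row
#'   data.frame), and `footprint_range` covering the stem's 5' arm.
#' @export
synth_footprint_fixture <- function(seed = NULL, utr_len = 40, stem_len = 12,
                                    loop_len = 6, tail_length = 240) {
  if (!is.null(seed)) set.seed(seed)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  rand <- function(k) sample(c("A", "C", "G", "U"), k, replace = TRUE)
  utr <- rand(utr_len)
  right <- rand(stem_len)
  right[3:5] <- c("A", "U", "G")       # start codon inside the 3' arm
  left <- rev(unname(comp[right]))
  lp <- rand(loop_len)
  # downstream hairpin tail
  tail_bases <- character(0)
  tail_partner <- integer(0)
  add <- function(k) {
    tail_bases <<- c(tail_bases, rand(k))
    tail_partner <<- c(tail_partner, integer(k))
  }
  add(10)
  while (length(tail_bases) + 32 <= tail_length) {
    l2 <- rand(8); r2 <- rev(unname(comp[l2]))
    o <- length(tail_bases)
    tail_bases <- c(tail_bases, l2, rand(6), r2)
    pp <- integer(22)
    pp[1:8] <- o + 22 - (0:7)
    pp[22 - (0:7)] <- o + 1:8
    tail_partner <- c(tail_partner, pp)
    add(10)
  }
  bases <- c(utr, left, lp, right, tail_bases)
  n <- length(bases)
  partner <- integer(n)
  l_idx <- utr_len + seq_len(stem_len)
  r_idx <- utr_len + 2 * stem_len + loop_len + 1L - seq_len(stem_len)
  partner[l_idx] <- r_idx
  partner[r_idx] <- l_idx
  off <- utr_len + 2 * stem_len + loop_len
  tp <- tail_partner
  tp[tp != 0] <- tp[tp != 0] + off
  partner[off + seq_along(tp)] <- tp
  seqs <- paste(bases, collapse = "")
  start <- utr_len + stem_len + loop_len + 3L
  cds_end <- start + 3L * ((n - start + 1L) %/% 3L) - 1L
  id <- "footprint_fixture"
  list(
    transcript = data.frame(id = id, sequence = seqs, length = n,
                            stringsAsFactors = FALSE),
    structure = reference_structure(id, partner, sequence = seqs),
    annotation = data.frame(gene = "clpP_like", transcript_id = id,
                            start_codon_pos = start, cds_end_pos = cds_end,
                            stringsAsFactors = FALSE),
    footprint_range = c(utr_len + 1L, utr_len + stem_len)
  )
}
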