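#' Load the nearest-neighbor RNA-RNA helix parameter table
#'
#' Reads the versioned, human-readable parameter file shipped with the
#' package (Turner-rule stack enthalpies/entropies, duplex initiation and
#' terminal A·U/G·U penalty; see the file header for citations). Free
#' energies at any temperature are reconstructed as
#' `dG(T) = dH - T * dS / 1000` (dH kcal/mol, dS cal/(mol K)).
#'
#' @param path Parameter file; defaults to the shipped table.
#' @return List of class `nn_params`: `stacks` (data.frame keyed by
#'   `top`/`bottom`), `init`, `terminal_au` (each with `dH`, `dS`), `table`.
#' @export
load_nn_params <- function(path = system.file("extdata",
                                              "nn_stack_params.tsv",
                                              package = "chloroprobe")) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("kind", "top", "bottom", "dH_kcal", "dS_cal", "dG37_kcal")
  if (length(setdiff(need, names(tab)))) {
    stop("parameter table needs columns: ", paste(need, collapse = ", "))
  }
  st <- tab[tab$kind == "stack", ]
  if (!nrow(st)) stop("no stack entries in parameter table")
  key <- paste0(st$top, "/", st$bottom)
  if (anyDuplicated(key)) stop("duplicate stack entries")
  one <- function(kind) {
    r <- tab[tab$kind == kind, ]
    if (nrow(r) != 1) stop("parameter table needs exactly one '", kind, "' row")
    list(dH = r$dH_kcal, dS = r$dS_cal, dG37 = r$dG37_kcal)
  }
  structure(list(
    stacks = stats::setNames(st[c("dH_kcal", "dS_cal", "dG37_kcal")],
                             c("dH", "dS", "dG37")) |>
      (\(d) { rownames(d) <- key; d })(),
    init = one("init"), terminal_au = one("terminal_au"), table = tab
  ), class = "nn_params")
}

nn_dG <- function(dH, dS, temperature_K) dH - temperature_K * dS / 1000

wc_or_wobble <- function(a, b, allow_wobble = TRUE) {
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
  if (allow_wobble) {
    wc | (a == "G" & b == "U") | (a == "U" & b == "G")
  } else {
    wc
  }
}

# dG of one contiguous helix: top/bottom are equal-length base vectors,
# top 5'->3', bottom 3'->5', every column a valid pair, >= 2 pairs.
helix_dG <- function(top, bottom, params, temperature_K) {
  k <- length(top)
  keys <- paste0(top[-k], top[-1], "/", bottom[-k], bottom[-1])
  st <- params$stacks[keys, ]
  if (anyNA(st$dH)) stop("missing stack parameter for: ",
                         paste(keys[is.na(st$dH)], collapse = ", "))
  g <- sum(nn_dG(st$dH, st$dS, temperature_K)) +
    nn_dG(params$init$dH, params$init$dS, temperature_K)
  term <- function(a, b) {
    if ((a == "A" && b == "U") || (a == "U" && b == "A") ||
        (a == "G" && b == "U") || (a == "U" && b == "G")) {
      nn_dG(params$terminal_au$dH, params$terminal_au$dS, temperature_K)
    } else 0
  }
  g + term(top[1], bottom[1]) + term(top[k], bottom[k])
}

#' Hybridization free energy of an ungapped RNA-RNA duplex
#'
#' Scores the antiparallel, ungapped alignment of `probe` (5'->3') against
#' `target` (5'->3', same length): position `i` of the target pairs with
#' position `L - i + 1` of the probe. Within the alignment, the best single
#' contiguous run of complementary (Watson-Crick or, optionally, G·U
#' wobble) pairs of length >= 2 is scored as one helix: stack terms plus
#' duplex initiation plus terminal A·U/G·U penalties. No run of >= 2 pairs
#' means no duplex (`+Inf`).
#'
#' @param target Target RNA segment (5'->3'), same length as `probe`.
#' @param probe Probe RNA (5'->3'), default the anti-SD `CCUCCU`.
#' @param params An `nn_params` table ([load_nn_params()]).
#' @param temperature_K Temperature in kelvin (default 293.15, i.e. 20 C).
#' @param allow_wobble Allow G·U pairs inside the helix.
#' @return dG in kcal/mol (`+Inf` = no duplex).
#' @examples
#' p <- load_nn_params()
#' duplex_dg("AGGAGG", "CCUCCU", p, temperature_K = 310.15)
#' @export
duplex_dg <- function(target, probe = "CCUCCU", params = load_nn_params(),
                      temperature_K = 293.15, allow_wobble = TRUE) {
  t <- seq_bases(toupper(chartr("Tt", "Uu", target)))
  p <- seq_bases(toupper(chartr("Tt", "Uu", probe)))
  if (any(!c(t, p) %in% c("A", "C", "G", "U"))) {
    stop("target and probe must be ACGU RNA")
  }
  if (length(t) != length(p)) {
    stop("target and probe must have equal length (fixed ungapped alignment)")
  }
  bottom <- rev(p)
  ok <- wc_or_wobble(t, bottom, allow_wobble)
  best <- Inf
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values & r$lengths >= 2)) {
    run <- starts[i]:ends[i]
    best <- min(best, helix_dG(t[run], bottom[run], params, temperature_K))
  }
  best
}

#' Scan the anti-SD along a 5'-UTR window
#'
#' Evaluates [duplex_dg()] at every ungapped offset of the probe along the
#' window (including partial overlaps of >= 2 nt at the edges), takes the
#' minimum over offsets, and classifies the Shine-Dalgarno strength:
#' `min_dG < strong_below` kcal/mol = `strong`; `strong_below <= min_dG <
#' none_at_or_above` = `weak`; otherwise (including no duplex) = `none`.
#' Boundary values fall in the weaker class.
#'
#' @param window RNA window (5'->3'), e.g. nucleotides -22..-2 of a 5' UTR.
#' @param probe Anti-SD sequence (default `CCUCCU`).
#' @param params An `nn_params` table.
#' @param temperature_K Temperature in kelvin (default 293.15 = 20 C).
#' @param thresholds `c(strong_below, none_at_or_above)` in kcal/mol.
#' @param allow_wobble Allow G·U pairs.
#' @return List of class `sd_scan`: `min_dG`, `sd_class`, `per_offset`
#'   (data.frame `offset`, `dG`), `window`.
#' @export
scan_sd <- function(window, probe = "CCUCCU", params = load_nn_params(),
                    temperature_K = 293.15, thresholds = c(-6, 0),
                    allow_wobble = TRUE) {
  w <- toupper(chartr("Tt", "Uu", window))
  W <- nchar(w)
  if (W == 0) stop("empty scan window")
  Lp <- nchar(probe)
  wb <- seq_bases(w)
  offs <- seq.int(3L - Lp, W - 1L)
  res <- vapply(offs, function(s) {
    ti <- max(1L, s):min(W, s + Lp - 1L)
    # probe letters facing those window positions (probe 5'->3' indices)
    pi_rev <- ti - s + 1L               # indices into reversed probe
    pidx <- sort(Lp - pi_rev + 1L)
    duplex_dg(paste(wb[ti], collapse = ""),
              substr(probe, pidx[1], pidx[length(pidx)]),
              params, temperature_K, allow_wobble)
  }, 0)
  min_dG <- min(res)
  cls <- if (min_dG < thresholds[1]) "strong"
         else if (min_dG < thresholds[2]) "weak" else "none"
  structure(list(min_dG = min_dG, sd_class = cls,
                 per_offset = data.frame(offset = offs, dG = res),
                 window = w),
            class = "sd_scan")
}

#' Classify Shine-Dalgarno strength for a gene set
#'
#' For every annotated gene, scans the anti-SD against nucleotides -22..-2
#' upstream of its start codon (truncated when the 5' UTR is shorter;
#' genes with fewer than 2 nt upstream are flagged unclassifiable) and
#' reports the minimum hybridization dG and SD class, plus the class
#' fractions over classifiable genes.
#'
#' @param annotation Annotation table ([read_annotation()]).
#' @param transcripts Transcript data.frame ([read_fasta()]).
#' @inheritParams scan_sd
#' @param sd_from,sd_to Scan window bounds relative to the start codon
#'   (negative, no position 0); defaults -22 and -2.
#' @return List of class `sd_classification`: `table` (gene, min_dG,
#'   sd_class, truncated, classifiable) and `fractions` (named fractions of
#'   strong/weak/none among classifiable genes).
#' @export
classify_plastome <- function(annotation, transcripts,
                              params = load_nn_params(),
                              probe = "CCUCCU", temperature_K = 293.15,
                              thresholds = c(-6, 0), allow_wobble = TRUE,
                              sd_from = -22L, sd_to = -2L) {
  seqs <- stats::setNames(transcripts$sequence, transcripts$id)
  rows <- lapply(seq_len(nrow(annotation)), function(i) {
    a <- annotation[i, ]
    sq <- seqs[[a$transcript_id]]
    if (is.null(sq)) stop("no sequence for transcript ", a$transcript_id)
    s <- a$start_codon_pos
    from <- s + sd_from
    to <- s + sd_to
    trunc <- from < 1L
    from <- max(1L, from)
    if (to < 1L || to - from + 1L < 2L) {
      return(data.frame(gene = a$gene, min_dG = NA_real_,
                        sd_class = NA_character_, truncated = TRUE,
                        classifiable = FALSE, stringsAsFactors = FALSE))
    }
    sc <- scan_sd(substr(sq, from, to), probe, params, temperature_K,
                  thresholds, allow_wobble)
    data.frame(gene = a$gene, min_dG = sc$min_dG, sd_class = sc$sd_class,
               truncated = trunc, classifiable = TRUE,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  cl <- factor(tab$sd_class[tab$classifiable],
               levels = c("strong", "weak", "none"))
  fr <- if (length(cl)) table(cl) / length(cl) else table(cl)
  structure(list(table = tab,
                 fractions = stats::setNames(as.numeric(fr), names(fr))),
            class = "sd_classification")
}
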