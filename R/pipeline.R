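#' Read a structured run configuration (YAML)
#'
#' See the packaged example in the vignette for the layout. The file has a
#' `simulate` block (simulation parameters, transcript geometry, footprint,
#' replicate count, seed) and/or an `analyze` block (input paths per
#' condition, analysis parameters).
#'
#' @param path Path to a YAML config.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Generate a synthetic probing dataset on disk
#'
#' Writes the complete input bundle for [run_analyze()]: transcript FASTA,
#' reference-structure CT file, accessibility table, annotation TSV, mask
#' TSV, and per-condition/replicate count tables, plus a `manifest.yaml`
#' recording every parameter and derived seed.
#'
#' @param out_dir Output directory.
#' @param config A [sim_config()].
#' @param seed Master integer seed; replicate/condition seeds are derived
#'   from it and logged.
#' @param target_length,stem,loop,spacer Transcript geometry, passed to
#'   [synth_structured_transcript()].
#' @param footprint_range Optional protein footprint (see
#'   [make_paired_conditions()]); NULL simulates identical conditions.
#' @param n_replicates Replicates per condition.
#' @param start_codon_pos,cds_end_pos Annotation for the synthetic gene.
#' @param primer_len Length of the primer-masked prefix and suffix.
#' @param overwrite Allow writing into an existing directory.
#' @return List of written paths (invisibly the manifest as attribute).
#' @export
run_simulate <- function(out_dir, config = sim_config(), seed = 1L,
                         target_length = 1500, stem = 8, loop = 6,
                         spacer = 10, footprint_range = NULL,
                         n_replicates = 1L, start_codon_pos = 61L,
                         cds_end_pos = NULL, primer_len = 20L,
                         overwrite = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite) {
    stop("output directory not empty (use overwrite = TRUE): ", out_dir)
  }
  if (target_length <= 0) stop("target_length must be positive")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fx <- synth_structured_transcript(target_length, stem, loop, spacer,
                                    seed = seed)
  tr <- fx$transcript
  n <- tr$length
  if (is.null(cds_end_pos)) {
    cds_end_pos <- start_codon_pos + 3L * ((n - primer_len - start_codon_pos) %/% 3L) - 1L
  }
  ann <- data.frame(gene = "synthetic_gene", transcript_id = tr$id,
                    start_codon_pos = as.integer(start_codon_pos),
                    cds_end_pos = as.integer(cds_end_pos))
  validate_annotation(ann, tr)
  masks <- mask_set(primer_ranges = data.frame(
    transcript_id = tr$id,
    start = c(1L, n - primer_len + 1L),
    end = c(primer_len, n)))
  paths <- list(
    fasta = file.path(out_dir, "transcripts.fa"),
    ct = file.path(out_dir, "structure.ct"),
    accessibility = file.path(out_dir, "accessibility.tsv"),
    annotation = file.path(out_dir, "annotation.tsv"),
    masks = file.path(out_dir, "masks.tsv"))
  write_fasta(tr, paths$fasta)
  write_ct(fx$structure, paths$ct)
  utils::write.table(
    data.frame(pos = seq_len(n),
               accessible = as.integer(fx$structure$solvent_accessible)),
    paths$accessibility, sep = "\t", quote = FALSE, row.names = FALSE)
  write_annotation(ann, paths$annotation)
  write_masks(masks, paths$masks)
  conditions <- c("vivo", "vitro")
  counts_paths <- list()
  seeds <- list()
  for (r in seq_len(n_replicates)) {
    rep_seed <- (seed + 7919L * r) %% .Machine$integer.max
    pc <- make_paired_conditions(tr, fx$structure, footprint_range, config,
                                 seed = rep_seed, transcript_id = tr$id)
    for (cond in conditions) {
      counts <- pc[[cond]]
      # re-apply primer mask as zero coverage
      primer <- mask_positions(masks, tr$id)$primer
      counts$coverage[counts$pos %in% primer] <- 0L
      counts$sub_count[counts$pos %in% primer] <- 0L
      counts$del_count[counts$pos %in% primer] <- 0L
      p <- file.path(out_dir, sprintf("counts_%s_rep%d.tsv", cond, r))
      write_counts_table(counts, p)
      counts_paths[[cond]] <- c(counts_paths[[cond]], p)
    }
    seeds[[paste0("rep", r)]] <- rep_seed
  }
  manifest <- list(seed = seed, derived_seeds = seeds,
                   config = unclass(config),
                   geometry = list(target_length = target_length, stem = stem,
                                   loop = loop, spacer = spacer,
                                   length = n, primer_len = primer_len),
                   footprint_range = footprint_range,
                   annotation = as.list(ann),
                   files = c(lapply(paths, basename),
                             list(counts = lapply(counts_paths, basename))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(c(paths, list(counts = counts_paths,
                          manifest = file.path(out_dir, "manifest.yaml"))))
}

#' Run the full analysis on an input bundle
#'
#' Per condition and replicate: reactivity pipeline (filtering,
#' two-channel normalization, winsorization) and reactivity TSV + constraint
#' file. Across conditions: region metric comparison (means averaged over
#' replicates). If a reference structure is given: ROC/AUC per channel.
#' Always: SD classification of the annotated genes, guided-fold arc table
#' of the TIR, and a plain-text run log with every parameter and the
#' excluded-position accounting.
#'
#' @param counts_files Named list: one character vector of count TSV paths
#'   per condition (e.g. `list(vivo = ..., vitro = ...)`).
#' @param fasta,annotation,masks Paths to the input files; `masks` may be NULL.
#' @param structure_ct Optional reference CT path (enables ROC).
#' @param accessibility Optional accessibility TSV for the reference.
#' @param out_dir Output directory.
#' @param min_coverage,window,min_positions,winsor_level Reactivity
#'   parameters (see [reactivity_pipeline()]).
#' @param sd_thresholds,temperature_K SD scan parameters.
#' @param fold_cfg A [fold_config()] for the TIR arc diagrams.
#' @param overwrite Allow writing into a non-empty directory.
#' @return List with `profiles`, `region_comparison`, `roc` (or NULL),
#'   `sd`, and the run-log path.
#' @export
run_analyze <- function(counts_files, fasta, annotation, masks = NULL,
                        structure_ct = NULL, accessibility = NULL,
                        out_dir = ".", min_coverage = 2500,
                        window = c(0.90, 0.99), min_positions = 20,
                        winsor_level = 0.99, sd_thresholds = c(-6, 0),
                        temperature_K = 293.15, fold_cfg = fold_config(),
                        overwrite = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  transcripts <- stage("read_fasta", read_fasta(fasta))
  ann <- stage("read_annotation", read_annotation(annotation, transcripts))
  msk <- if (is.null(masks)) mask_set() else stage("read_masks", read_masks(masks))
  ref <- if (is.null(structure_ct)) NULL else {
    stage("read_structure",
          read_structure(structure_ct, "ct", accessibility = accessibility))
  }
  log_lines <- c(
    "chloroprobe run log",
    paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste0("min_coverage: ", min_coverage),
    paste0("normalization window: ", window[1], "-", window[2]),
    paste0("winsorization level: ", winsor_level),
    paste0("sd thresholds (kcal/mol): strong < ", sd_thresholds[1],
           ", none >= ", sd_thresholds[2]),
    paste0("temperature_K: ", temperature_K))
  profiles <- list()
  for (cond in names(counts_files)) {
    profiles[[cond]] <- list()
    for (i in seq_along(counts_files[[cond]])) {
      path <- counts_files[[cond]][i]
      counts <- stage(paste0("read_counts:", path), read_counts_table(path))
      prof <- stage(paste0("reactivity:", path),
                    reactivity_pipeline(counts, msk, min_coverage, window,
                                        min_positions, winsor_level))
      tag <- sprintf("%s_rep%d", cond, i)
      write_reactivity(prof, file.path(out_dir,
                                       sprintf("reactivity_%s.tsv", tag)))
      for (id in unique(prof$transcript_id)) {
        len <- transcripts$length[transcripts$id == id]
        write_constraints(prof, file.path(out_dir,
                                          sprintf("constraints_%s_%s.txt", id, tag)),
                          transcript_id = id, length = len)
      }
      tallies <- table(factor(prof$mask_reason,
                              levels = c("none", "low_coverage", "primer",
                                         "editing_site", "modified_site")))
      log_lines <- c(log_lines,
                     sprintf("[%s] positions total=%d analyzed=%d low_coverage=%d primer=%d editing=%d modified=%d",
                             tag, nrow(prof), tallies[["none"]],
                             tallies[["low_coverage"]], tallies[["primer"]],
                             tallies[["editing_site"]],
                             tallies[["modified_site"]]))
      profiles[[cond]][[i]] <- prof
    }
  }
  regions <- stage("resolve_regions", resolve_regions(ann, transcripts))
  comparison <- NULL
  if (all(c("vivo", "vitro") %in% names(profiles))) {
    reps <- lapply(seq_along(profiles$vivo), function(i) {
      cmp <- compare_conditions(profiles$vivo[[i]], profiles$vitro[[i]],
                                regions)
      cmp$replicate <- i
      cmp
    })
    comparison <- do.call(rbind, reps)
    agg <- stats::aggregate(
      comparison[c("mean_vivo", "mean_vitro", "mean_diff",
                   "gini_vivo", "gini_vitro", "gini_diff")],
      by = comparison[c("gene", "kind")], FUN = mean)
    utils::write.table(comparison, file.path(out_dir, "region_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(agg, file.path(out_dir, "region_metrics_mean.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    # replicate correlation per condition on shared unmasked positions
    if (length(profiles$vivo) > 1) {
      for (cond in c("vivo", "vitro")) {
        p1 <- profiles[[cond]][[1]]; p2 <- profiles[[cond]][[2]]
        ok <- p1$mask_reason == "none" & p2$mask_reason == "none" &
          !is.na(p1$normalized) & !is.na(p2$normalized)
        r <- stats::cor(p1$normalized[ok], p2$normalized[ok])
        log_lines <- c(log_lines,
                       sprintf("replicate correlation (%s, rep1 vs rep2): %.4f",
                               cond, r))
      }
    }
  }
  roc <- NULL
  if (!is.null(ref)) {
    labels <- accessibility_labels(ref)
    first_cond <- names(profiles)[1]
    prof <- profiles[[first_cond]][[1]]
    prof <- prof[prof$transcript_id == ref$transcript_id |
                   length(unique(prof$transcript_id)) == 1, ]
    roc <- list(AC = roc_auc(prof, labels, "AC"),
                GU = roc_auc(prof, labels, "GU"))
    write_roc(roc$AC, file.path(out_dir, "roc_AC.tsv"))
    write_roc(roc$GU, file.path(out_dir, "roc_GU.tsv"))
    log_lines <- c(log_lines,
                   sprintf("ROC AUC (%s): AC=%.4f GU=%.4f", first_cond,
                           roc$AC$auc, roc$GU$auc))
  } else {
    log_lines <- c(log_lines, "no reference structure: ROC skipped")
  }
  sd <- stage("sd_scan",
              classify_plastome(ann, transcripts,
                                temperature_K = temperature_K,
                                thresholds = sd_thresholds))
  utils::write.table(sd$table, file.path(out_dir, "sd_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # guided fold of each TIR, first condition/replicate
  prof1 <- profiles[[1]][[1]]
  tirs <- regions[regions$kind == "tir", , drop = FALSE]
  for (i in seq_len(nrow(tirs))) {
    rg <- tirs[i, ]
    sq <- transcripts$sequence[transcripts$id == rg$transcript_id]
    sub <- substr(sq, rg$start, rg$end)
    local_prof <- prof1[prof1$transcript_id == rg$transcript_id &
                          prof1$pos >= rg$start & prof1$pos <= rg$end, ]
    local_prof$pos <- local_prof$pos - rg$start + 1L
    fr <- guided_fold(sub, local_prof, fold_cfg)
    pairs_to_arcs(fr, file.path(out_dir,
                                sprintf("arcs_tir_%s.tsv", rg$gene)))
  }
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  list(profiles = profiles, region_comparison = comparison, roc = roc,
       sd = sd, log = log_path)
}
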