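test_that("region resolution follows the no-position-zero convention", {
  ann <- data.frame(gene = "g1", transcript_id = "t1",
                    start_codon_pos = 100L, cds_end_pos = 399L)
  rg <- resolve_regions(ann, 500L)
  get <- function(kind) rg[rg$kind == kind, ]
  expect_equal(unlist(get("tir")[c("start", "end")], use.names = FALSE),
               c(75L, 104L))
  expect_equal(unlist(get("sd_window")[c("start", "end")], use.names = FALSE),
               c(78L, 98L))
  expect_equal(unlist(get("start_codon")[c("start", "end")], use.names = FALSE),
               c(100L, 102L))
  expect_equal(unlist(get("cds")[c("start", "end")], use.names = FALSE),
               c(100L, 399L))
  expect_equal(get("tir")$end - get("tir")$start + 1L, 30L)
  expect_equal(get("sd_window")$end - get("sd_window")$start + 1L, 21L)
  expect_false(any(rg$truncated))

  # boundary: start codon at 26 -> TIR starts at 1 untruncated
  ann$start_codon_pos <- 26L; ann$cds_end_pos <- 325L
  rg26 <- resolve_regions(ann, 500L)
  expect_equal(rg26[rg26$kind == "tir", "start"], 1L)
  expect_false(rg26[rg26$kind == "tir", "truncated"])

  # degenerate: start codon at 10 -> TIR truncated to [1, 14] and flagged
  ann$start_codon_pos <- 10L; ann$cds_end_pos <- 309L
  rg10 <- resolve_regions(ann, 500L)
  tir <- rg10[rg10$kind == "tir", ]
  expect_equal(c(tir$start, tir$end), c(1L, 14L))
  expect_true(tir$truncated)
})

test_that("region means use only unmasked positions of the base set", {
  bases <- c("A", "U", "G", "A", "C", "G")
  prof <- profile_from_values(c(0.9, 2, 3, 0.2, 0.6, 4), bases = bases)
  # start codon AUG at 1..3, base set A -> just the A
  expect_equal(region_mean_reactivity(prof, list(start = 1, end = 3), "A")$mean,
               0.9)
  # two A/C values 0.2 and 0.6 -> 0.4
  got <- region_mean_reactivity(prof, list(start = 4, end = 6), c("A", "C"))
  expect_equal(got$mean, 0.4)
  expect_equal(got$n, 2L)
  # all masked -> missing, not zero
  prof$mask_reason[4:5] <- "primer"
  prof$normalized[4:5] <- NA_real_
  got2 <- region_mean_reactivity(prof, list(start = 4, end = 6), c("A", "C"))
  expect_true(is.na(got2$mean))
  expect_equal(got2$n, 0L)
})

test_that("gini matches brute force on random vectors, both forms", {
  expect_equal(gini(c(0, 1))$value, 0.5)
  expect_equal(gini(rep(3.2, 10))$value, 0)
  expect_error(gini(c(1)), "at least 2")
  expect_error(gini(c(0, 0)), "zero-mean")
  # near-maximal concentration approaches 1
  x <- c(rep(0, 999), 1)
  expect_gt(gini(x)$value, 0.99)
  set.seed(7)
  for (i in 1:50) {
    n <- sample(2:200, 1)
    x <- rexp(n)
    expect_equal(gini(x)$value, gini_brute(x), tolerance = 1e-12)
    expect_equal(gini(x, "sample")$value, gini_brute(x, "sample"),
                 tolerance = 1e-12)
  }
  # scale invariance
  x <- rexp(50)
  for (k in c(0.1, 3, 1000)) {
    expect_equal(gini(k * x)$value, gini(x)$value, tolerance = 1e-12)
  }
})

test_that("accessibility labels demand unpaired AND solvent-accessible", {
  st <- reference_structure("t", c(0L, 0L, 4L, 3L),
                            solvent_accessible = c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(accessibility_labels(st), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("roc_auc equals pair counting and behaves at the extremes", {
  # perfect separation
  prof <- profile_from_values(c(0.9, 0.8, 0.1, 0.2))
  labs <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(roc_auc(prof, labs, "ACGU")$auc, 1.0)
  # symmetry: auc(-x) = 1 - auc(x)
  set.seed(12)
  for (i in 1:30) {
    n <- sample(5:50, 1)
    scores <- round(runif(n), sample(c(1, 6), 1))  # sometimes heavy ties
    y <- runif(n) > 0.5
    if (!any(y) || all(y)) next
    r <- chloroprobe:::roc_from_scores(scores, y)
    expect_equal(r$auc, auc_pairs(scores, y), tolerance = 1e-12)
    r_neg <- chloroprobe:::roc_from_scores(-scores, y)
    expect_equal(r_neg$auc, 1 - r$auc, tolerance = 1e-12)
    # curve monotone in both axes
    expect_true(all(diff(r$curve$fpr) >= 0))
    expect_true(all(diff(r$curve$tpr) >= 0))
  }
  expect_error(roc_auc(prof, c(TRUE, TRUE, TRUE, TRUE)), "negative")
})

test_that("roc_auc agrees with pROC on a simulated profile", {
  skip_if_not_installed("pROC")
  fx <- synth_structured_transcript(600, seed = 9)
  track <- assign_true_rates(fx$transcript, fx$structure)
  prof <- reactivity_pipeline(simulate_counts(track, seed = 2))
  labs <- accessibility_labels(fx$structure)
  mine <- roc_auc(prof, labs, "AC")
  sel <- prof$mask_reason == "none" & !is.na(prof$normalized) &
    prof$ref_base %in% c("A", "C")
  ref <- pROC::roc(labs[prof$pos[sel]], prof$normalized[sel],
                   quiet = TRUE, direction = "<")
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("random scores give AUC near 0.5", {
  set.seed(99)
  scores <- runif(4000)
  y <- runif(4000) > 0.5
  r <- chloroprobe:::roc_from_scores(scores, y)
  # 3 SE band for the U statistic under the null
  se <- sqrt((sum(y) + sum(!y) + 1) / (12 * sum(y) * sum(!y)))
  expect_lt(abs(r$auc - 0.5), 3 * se)
})

test_that("condition comparison recovers constructed contrasts", {
  fx <- synth_structured_transcript(300, seed = 14)
  ann <- data.frame(gene = "g", transcript_id = fx$transcript$id,
                    start_codon_pos = 80L, cds_end_pos = 229L)
  rg <- resolve_regions(ann, fx$transcript)
  prof <- reactivity_pipeline(simulate_counts(
    assign_true_rates(fx$transcript, fx$structure), seed = 6,
    transcript_id = fx$transcript$id))
  cmp_same <- compare_conditions(prof, prof, rg)
  expect_true(all(cmp_same$mean_diff[!cmp_same$flagged] == 0))
  expect_true(all(cmp_same$gini_diff[!cmp_same$flagged] == 0))

  # unstructured (flat-rate) track is less structured than the real one
  cfg <- sim_config()
  flat_track <- assign_true_rates(fx$transcript, fx$structure, cfg)
  flat_track$rate <- ifelse(flat_track$channel == "AC",
                            cfg$rate_unpaired_AC, cfg$rate_unpaired_GU)
  flat_prof <- reactivity_pipeline(simulate_counts(
    flat_track, cfg, seed = 6, transcript_id = fx$transcript$id))
  g_flat <- region_gini(flat_prof, list(start = 1, end = 300))
  g_struct <- region_gini(prof, list(start = 1, end = 300))
  expect_lt(g_flat$value, g_struct$value)
})
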