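test_that("raw rates and mask reasons follow the filtering rules", {
  counts <- data.frame(
    transcript_id = "t1", pos = 1:6,
    ref_base = c("A", "C", "G", "A", "U", "A"),
    coverage = c(5000L, 2499L, 5000L, 5000L, 5000L, 2500L),
    sub_count = c(40L, 10L, 20L, 30L, 5L, 25L),
    del_count = c(10L, 0L, 5L, 0L, 0L, 0L))
  m <- mask_set(
    primer_ranges = data.frame(transcript_id = "t1", start = 3L, end = 3L),
    editing_sites = data.frame(transcript_id = "t1", pos = 4L),
    modified_sites = data.frame(transcript_id = "t1", pos = 5L))
  prof <- compute_raw_rates(counts, m)
  expect_equal(prof$raw_rate[1], 50 / 5000)
  expect_equal(prof$mask_reason,
               c("none", "low_coverage", "primer", "editing_site",
                 "modified_site", "none"))
  expect_true(all(is.na(prof$raw_rate[2:5])))
  expect_equal(prof$raw_rate[6], 25 / 2500)  # coverage 2500 passes
  expect_equal(prof$channel, c("AC", "AC", "GU", "AC", "GU", "AC"))

  dup <- rbind(counts, counts[1, ])
  expect_error(compute_raw_rates(dup, m), "twice")
})

test_that("percentile-window normalization matches the slice-and-average oracle", {
  # 100 A/C rates equal to 1..100 x 1e-3: divisor = mean of ranks 91..99
  rates <- (1:100) / 1000
  prof <- compute_raw_rates(counts_from_rates(rates), min_coverage = 0)
  norm <- normalize_two_channel(prof)
  divisor <- mean((91:99) / 1000)
  expect_equal(divisor, 0.095)
  expect_equal(max(norm$normalized), 0.1 / 0.095, tolerance = 1e-12)
  expect_equal(norm$normalized, rates / divisor, tolerance = 1e-12)
  info <- attr(norm, "normalization")
  expect_equal(info$divisor, divisor)

  # all rates equal -> every normalized value 1
  prof2 <- compute_raw_rates(counts_from_rates(rep(0.004, 30)), min_coverage = 0)
  norm2 <- normalize_two_channel(prof2)
  expect_equal(norm2$normalized, rep(1, 30))
})

test_that("normalization is scale-invariant and channel-separated", {
  set.seed(42)
  rates <- runif(60, 0.001, 0.05)
  bases <- sample(c("A", "C", "G", "U"), 60, TRUE)
  base_prof <- compute_raw_rates(counts_from_rates(rates, bases),
                                 min_coverage = 0)
  ref <- normalize_two_channel(base_prof)
  for (k in c(0.5, 2, 10)) {
    scaled <- base_prof
    scaled$raw_rate <- scaled$raw_rate * k
    got <- normalize_two_channel(scaled)
    expect_equal(got$normalized, ref$normalized, tolerance = 1e-12)
  }
  # permuting G/U raw rates never changes any A/C normalized value
  perm <- base_prof
  gu <- perm$channel == "GU"
  set.seed(1)
  perm$raw_rate[gu] <- sample(perm$raw_rate[gu])
  got <- normalize_two_channel(perm)
  expect_equal(got$normalized[!gu], ref$normalized[!gu])
})

test_that("channels too small or all-zero are flagged, not normalized", {
  prof <- compute_raw_rates(counts_from_rates(rep(0.01, 10)), min_coverage = 0)
  norm <- normalize_two_channel(prof)
  expect_true(all(is.na(norm$normalized)))
  expect_equal(attr(norm, "normalization")$flag, "too_few_positions")

  prof0 <- compute_raw_rates(counts_from_rates(rep(0, 30)), min_coverage = 0)
  norm0 <- normalize_two_channel(prof0)
  expect_true(all(is.na(norm0$normalized)))
  expect_equal(attr(norm0, "normalization")$flag, "zero_divisor")
})

test_that("winsorization caps only the extreme tail and is idempotent", {
  vals <- c(seq(0.1, 1.5, length.out = 99), 50)
  prof <- profile_from_values(vals)
  w <- winsorize_99(prof)
  cap <- sort(vals)[99]
  expect_equal(max(w$normalized), cap)
  expect_equal(w$normalized[1:99], vals[1:99])  # everything else unchanged
  expect_equal(winsorize_99(w)$normalized, w$normalized)  # idempotent

  flat <- profile_from_values(rep(0.7, 40))
  expect_equal(winsorize_99(flat)$normalized, rep(0.7, 40))
})

test_that("pipeline composition is deterministic and respects masks", {
  fx <- synth_structured_transcript(500, seed = 4)
  track <- assign_true_rates(fx$transcript, fx$structure)
  cnt <- simulate_counts(track, seed = 1, transcript_id = fx$transcript$id)
  m <- mask_set(primer_ranges = data.frame(
    transcript_id = fx$transcript$id, start = 1L, end = 25L))
  p1 <- reactivity_pipeline(cnt, m)
  p2 <- reactivity_pipeline(cnt, m)
  expect_identical(p1, p2)
  expect_true(all(is.na(p1$normalized[p1$mask_reason != "none"])))
  expect_true(all(p1$mask_reason[p1$pos <= 25] == "primer"))

  empty <- cnt[0, ]
  expect_equal(nrow(reactivity_pipeline(empty)), 0L)
})
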