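params <- load_nn_params()

test_that("nearest-neighbor table is internally consistent and complete", {
  tab <- params$table
  recon <- tab$dH_kcal - 310.15 * tab$dS_cal / 1000
  expect_true(all(abs(recon - tab$dG37_kcal) <= 0.1))
  # duplexes are more stable cold: dG(20C) < dG(37C) for every stack
  st <- tab[tab$kind == "stack", ]
  g20 <- st$dH_kcal - 293.15 * st$dS_cal / 1000
  g37 <- st$dH_kcal - 310.15 * st$dS_cal / 1000
  expect_true(all(g20 < g37))
  # every WC/wobble dinucleotide stack is present (6 pairs x 6 pairs)
  expect_equal(nrow(st), 36L)
  expect_equal(anyDuplicated(paste(st$top, st$bottom)), 0L)
})

test_that("duplex_dg equals hand summation from the parameter table", {
  tab <- params$table
  pick <- function(top, bottom) {
    r <- tab[tab$kind == "stack" & tab$top == top & tab$bottom == bottom, ]
    r$dH_kcal - 310.15 * r$dS_cal / 1000
  }
  special <- function(kind) {
    r <- tab[tab$kind == kind, ]
    r$dH_kcal - 310.15 * r$dS_cal / 1000
  }
  # AGGAGG paired with CCUCCU: bottom strand (3'->5') is UCCUCC;
  # stacks read off the duplex are AG/UC, GG/CC, GA/CU, AG/UC, GG/CC,
  # plus initiation and one terminal A-U (left end); right end is G-C.
  expected <- pick("AG", "UC") + pick("GG", "CC") + pick("GA", "CU") +
    pick("AG", "UC") + pick("GG", "CC") +
    special("init") + special("terminal_au")
  expect_equal(duplex_dg("AGGAGG", "CCUCCU", params, temperature_K = 310.15),
               expected, tolerance = 1e-12)
  # colder temperature stabilizes the duplex
  expect_lt(duplex_dg("AGGAGG", "CCUCCU", params, temperature_K = 293.15),
            duplex_dg("AGGAGG", "CCUCCU", params, temperature_K = 310.15))
})

test_that("duplex model scores the best single contiguous run only", {
  # AGCAGG vs CCUCCU: runs of pairs at positions 1-2 and 4-6
  both <- duplex_dg("AGCAGG", "CCUCCU", params)
  left_only <- duplex_dg("AGCAAA", "CCUCCU", params)   # kills right run
  right_only <- duplex_dg("AUCAGG", "CCUCCU", params)  # kills left run
  expect_equal(both, min(left_only, right_only))
  # no complementary positions -> no duplex
  expect_equal(duplex_dg("AAAAAA", "CCUCCU", params), Inf)
  # a single isolated pair (< 2) is not a duplex
  expect_equal(duplex_dg("AUUUUU", "CCUCCU", params), Inf)
  expect_error(duplex_dg("AGGNGG", "CCUCCU", params), "ACGU")
})

test_that("scan_sd finds strong SDs, classifies poly-A as none", {
  # GGAGG core (as in a strong plastid SD) inside a window
  sc <- scan_sd("ACAUAGGAGGUAUAACAUAAC", params = params)
  expect_equal(sc$sd_class, "strong")
  expect_lt(sc$min_dG, -6)
  expect_equal(min(sc$per_offset$dG), sc$min_dG)

  pa <- scan_sd(paste(rep("A", 21), collapse = ""), params = params)
  expect_equal(pa$sd_class, "none")
  expect_equal(pa$min_dG, Inf)

  # extension monotonicity: appending bases can only lower or keep min_dG
  set.seed(31)
  for (i in 1:20) {
    w <- rand_rna(12)
    ext <- paste0(w, rand_rna(4))
    expect_lte(scan_sd(ext, params = params)$min_dG,
               scan_sd(w, params = params)$min_dG)
  }
  expect_error(scan_sd("", params = params), "empty")
})

test_that("classification boundaries fall in the weaker class", {
  sc <- scan_sd("ACAUAGGAGGUAUAACAUAAC", params = params)
  # a min_dG exactly at the strong threshold is weak, not strong
  at_strong <- scan_sd(sc$window, params = params,
                       thresholds = c(sc$min_dG, 0))
  expect_equal(at_strong$sd_class, "weak")
  # a min_dG exactly at the none threshold is none
  at_none <- scan_sd(sc$window, params = params,
                     thresholds = c(sc$min_dG - 1, sc$min_dG))
  expect_equal(at_none$sd_class, "none")
})

test_that("classify_plastome reports per-gene classes and fractions", {
  # three genes engineered as one per class
  utr_strong <- "ACAUAGGAGGUAUAACAUAAC"   # GGAGG
  utr_weak <- "ACAUAGGUAAUAUAACAUAAC"     # short GG core
  utr_none <- paste(rep("A", 21), collapse = "")
  mk <- function(utr) paste0("G", utr, "AUGGCUGCAUAA")
  tr <- data.frame(id = c("s", "w", "n"),
                   sequence = c(mk(utr_strong), mk(utr_weak), mk(utr_none)))
  tr$length <- nchar(tr$sequence)
  ann <- data.frame(gene = c("gs", "gw", "gn"), transcript_id = c("s", "w", "n"),
                    start_codon_pos = 23L, cds_end_pos = 34L)
  cl <- classify_plastome(ann, tr, params)
  expect_equal(cl$table$sd_class, c("strong", "weak", "none"))
  expect_equal(unname(cl$fractions), rep(1 / 3, 3))

  # truncated 10-nt 5' UTR still scans, flagged as truncated
  tr2 <- data.frame(id = "t", sequence = paste0("ACAUAGGAGG", "AUGGCUUAA"))
  tr2$length <- nchar(tr2$sequence)
  ann2 <- data.frame(gene = "gt", transcript_id = "t",
                     start_codon_pos = 11L, cds_end_pos = 19L)
  cl2 <- classify_plastome(ann2, tr2, params)
  expect_true(cl2$table$truncated)
  expect_true(cl2$table$classifiable)
  expect_equal(cl2$table$sd_class, "strong")

  # fewer than 2 nt upstream -> unclassifiable
  tr3 <- data.frame(id = "u", sequence = "GAUGGCUUAA")
  tr3$length <- nchar(tr3$sequence)
  ann3 <- data.frame(gene = "gu", transcript_id = "u",
                     start_codon_pos = 2L, cds_end_pos = 10L)
  cl3 <- classify_plastome(ann3, tr3, params)
  expect_false(cl3$table$classifiable)
  expect_true(is.na(cl3$table$sd_class))
})
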