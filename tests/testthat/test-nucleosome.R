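test_that("occupancy is the per-bp fragment pileup, clipped to the region", {
  reg <- target_regions("c", 10L, 25L, "R")
  fr <- fragments("c", c(10L, 15L), c(20L, 25L))
  prof <- compute_occupancy(fr, reg)
  expect_equal(prof$values, rep(c(1, 2, 1), each = 5))

  expect_true(all(compute_occupancy(empty_fragments_for_test(), reg)$values == 0))
  expect_error(compute_occupancy(fr, target_regions("c", 5L, 6L, "z")[0, ]),
               "single region")

  set.seed(21)
  reg2 <- target_regions("c", 1000L, 3000L, "R2", "tss", 2000L)
  fr2 <- random_fragments(5000, lo = 500L, hi = 3400L)
  expect_equal(compute_occupancy(fr2, reg2)$values, bf_pileup(fr2, reg2))
})

test_that("occupancy mass equals summed fragment-overlap lengths", {
  set.seed(22)
  for (i in 1:50) {
    reg <- target_regions("c", 1000L, 3000L, "R", "tss", 2000L)
    fr <- random_fragments(sample(10:300, 1), lo = 400L, hi = 3400L)
    ov <- pmin(fr$end, reg$end) - pmax(fr$start, reg$start)
    expect_equal(sum(compute_occupancy(fr, reg)$values), sum(pmax(ov, 0)))
  }
})

test_that("normalization scales panel-wide mean occupancy to 1", {
  set.seed(23)
  regs <- target_regions("c", c(0L, 3000L), c(2000L, 5000L), c("a", "b"),
                         "tss", c(1000L, 4000L))
  fr <- random_fragments(2000, hi = 5200L)
  nf <- panel_norm_factor(fr, regs)
  tot <- sum(compute_occupancy(fr, regs[1, ], nf)$values) +
    sum(compute_occupancy(fr, regs[2, ], nf)$values)
  expect_equal(tot / 4000, 1, tolerance = 1e-12)
})

test_that("peak calling finds summits, drops flat profiles and merges close maxima", {
  reg <- target_regions("c", 0L, 1000L, "R", "tss", 500L)
  tri <- function(center, halfwidth, L = 1000) {
    pmax(0, halfwidth - abs(seq_len(L) - 1 - center))
  }
  prof <- list(region = reg, values = tri(500, 200), norm_factor = 1)
  pk <- call_peaks(prof, min_summit_occ = 1)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$summit, 500L)
  expect_equal(pk$span_end - pk$span_start, 147L)

  flat <- list(region = reg, values = rep(0, 1000), norm_factor = 1)
  expect_equal(nrow(call_peaks(flat)), 0L)

  # two bumps 100 bp apart merge, keeping the taller (right) summit
  two <- list(region = reg,
              values = 0.5 * tri(400, 80) + tri(500, 80), norm_factor = 1)
  pk2 <- call_peaks(two, min_summit_occ = 1, smooth_width = 1L)
  expect_equal(nrow(pk2), 1L)
  expect_equal(pk2$summit, 500L)

  # determinism and invariance to fragment input order
  set.seed(24)
  fr <- random_fragments(3000, lo = 0L, hi = 1000L, len_lo = 147L,
                         len_hi = 190L)
  reg2 <- target_regions("c", 0L, 1200L, "R2", "tss", 600L)
  p1 <- call_peaks(compute_occupancy(fr, reg2))
  shuffled <- fr[sample(nrow(fr)), ]
  p2 <- call_peaks(compute_occupancy(shuffled, reg2))
  expect_identical(p1, p2)
})

test_that("fuzziness is the population SD of supporting midpoints", {
  pk <- data.frame(summit = 100L, summit_occ = 5,
                   span_start = 27L, span_end = 174L)
  mk <- function(mids) fragments("c", mids - 50L, mids + 50L)  # midpoint ~ mids
  expect_equal(peak_fuzziness(mk(c(100L, 100L, 100L)), pk), 0)
  expect_equal(peak_fuzziness(mk(c(90L, 100L, 110L)), pk), sqrt(200 / 3))
  expect_true(is.na(peak_fuzziness(mk(100L), pk)))

  set.seed(25)
  mids <- sample(30:170, 1000, replace = TRUE)
  expect_equal(peak_fuzziness(mk(mids), pk), bf_pop_sd(mids),
               tolerance = 1e-9)

  # translation invariance and linear scaling
  f0 <- peak_fuzziness(mk(mids), pk)
  pk2 <- data.frame(summit = 1100L, summit_occ = 5,
                    span_start = 1027L, span_end = 1174L)
  expect_equal(peak_fuzziness(mk(mids + 1000L), pk2), f0, tolerance = 1e-9)
  mids3 <- as.integer(100 + 3 * (mids - 100))
  pk3 <- data.frame(summit = 100L, summit_occ = 5,
                    span_start = -300L, span_end = 500L)
  expect_equal(peak_fuzziness(mk(mids3), pk3), 3 * bf_pop_sd(mids - 100),
               tolerance = 1e-9)
})

test_that("midpoint convention is floor((s + e - 1) / 2)", {
  fr <- fragments("c", c(0L, 0L, 10L), c(10L, 11L, 21L))
  expect_equal(fragment_midpoints(fr), c(4L, 5L, 15L))
})

test_that("region occupancy and fuzziness features average correctly", {
  reg <- target_regions("c", 0L, 100L, "R", "tss", 50L)
  prof <- list(region = reg, values = rep(2, 100), norm_factor = 1)
  expect_equal(region_occupancy_feature(prof), 2.0)
  prof$values <- rep(c(1, 3), each = 50)
  expect_equal(region_occupancy_feature(prof), 2.0)
  set.seed(26)
  prof$values <- runif(100)
  expect_equal(region_occupancy_feature(prof), sum(prof$values) / 100)

  pks <- data.frame(summit = c(10L, 40L, 400L), fuzziness = c(6, 10, 99))
  expect_equal(region_fuzziness_feature(pks, reg), 8.0)
  expect_equal(region_fuzziness_feature(pks[1, ], reg), 6.0)
  expect_true(is.na(region_fuzziness_feature(pks[3, , drop = FALSE], reg)))
})

test_that("fragment length histogram reports exact counts and the mode", {
  fr <- fragments("c", c(0L, 0L, 0L), c(167L, 167L, 150L))
  h <- fragment_length_histogram(fr)
  expect_equal(attr(h, "mode"), 167L)
  expect_equal(h$count[h$length == 167], 2L)
  h0 <- fragment_length_histogram(empty_fragments_for_test())
  expect_equal(nrow(h0), 0L)
  expect_true(is.na(attr(h0, "mode")))
})

test_that("dinucleotide profile recovers planted 10 bp periodicity", {
  # genome with AA planted every 10 bp, phase-locked to fragment starts
  L <- 20000L
  base <- rep(c("A", "A", rep("C", 8)), length.out = L)
  genome <- Biostrings::DNAStringSet(c(g = paste(base, collapse = "")))
  starts <- seq(100L, L - 300L, by = 10L)
  fr <- fragments("g", starts, starts + 147L)
  dp <- dinucleotide_profile(fr, genome, dinucs = "AA")
  expect_equal(dp$period, 10, tolerance = 0.05)
  expect_gt(dp$snr, 15)

  # all-A genome: flat profile at fraction 1, no period call
  ga <- Biostrings::DNAStringSet(c(g = strrep("A", 5000L)))
  fra <- fragments("g", seq(100L, 4500L, by = 50L), seq(100L, 4500L, 50L) + 147L)
  dpa <- dinucleotide_profile(fra, ga, dinucs = c("AA", "AT", "TA", "TT"))
  expect_true(all(dpa$profile$fraction == 1))
  expect_true(is.na(dpa$period))

  # uniform random genome: no dominant period above the noise floor
  gu <- simulate_genome(c(g = 50000L), seed = 9)
  set.seed(9)
  su <- sample(100:49500, 400)
  fru <- fragments("g", su, su + 147L)
  dpu <- dinucleotide_profile(fru, gu)
  expect_lt(dpu$snr, 15)
  expect_true(is.na(dpu$period))

  expect_error(dinucleotide_profile(fragments("zz", 100L, 247L), gu),
               "missing from FASTA")
})
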