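test_that("cohorts are byte-identical given the same config and seed", {
  cfg <- sim_preset("null", seed = 77, n_cancer = 3, n_control = 3,
                    n_tss = 4, n_pas = 2, n_cpg_regions = 5, depth = 80)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$fragments, b$fragments)
  expect_identical(a$methylation, b$methylation)
  expect_identical(a$lambda, b$lambda)
})

test_that("zero jitter puts every midpoint exactly on a lattice center", {
  cfg <- sim_config(seed = 1)
  reg <- target_regions("c", 1000L, 3000L, "R", "tss", 2000L)
  set.seed(1)
  fr <- simulate_region_fragments(reg, 500, jitter_sd = 0, ndr_depth = 0.5,
                                  short_frac = 0, cfg = cfg)
  mids <- fragment_midpoints(fr)
  expect_true(all((mids - 2000L) %% cfg$nucleosome_spacing == 0))
  # and downstream fuzziness is exactly 0
  prof <- compute_occupancy(fr, reg)
  pks <- call_nucleosomes(fr, prof, min_summit_occ = 1)
  expect_true(all(pks$fuzziness[pks$n_support >= 2] == 0))
})

test_that("fragment lengths concentrate at the configured modal length", {
  cfg <- sim_config(seed = 2)
  reg <- target_regions("c", 1000L, 3000L, "R", "tss", 2000L)
  set.seed(2)
  fr <- simulate_region_fragments(reg, 1.2e5, jitter_sd = 4, ndr_depth = 1,
                                  short_frac = 0, cfg = cfg)
  h <- fragment_length_histogram(fr)
  expect_lte(abs(attr(h, "mode") - cfg$frag_len_mean), 2)
  expect_true(all(fr$length >= 50 & fr$length <= 250))
})

test_that("binomial methylation concentrates around the class rate", {
  sites <- data.frame(chrom = "c", pos = seq_len(10000) * 10L,
                      region = rep(sprintf("r%d", 1:100), each = 100))
  set.seed(3)
  rate <- setNames(rep(0.8, 100), sprintf("r%d", 1:100))
  calls <- simulate_methylation(sites, rate, coverage = 50,
                                dispersion = Inf)
  expect_lt(abs(sum(calls$n_meth) / sum(calls$n_total) - 0.8), 0.01)
  zero <- simulate_methylation(sites, setNames(rep(0, 100), names(rate)),
                               coverage = 50, dispersion = 150)
  expect_true(all(zero$n_meth == 0))
})

test_that("deeper NDR depletion lowers cancer anchor occupancy", {
  cfg <- sim_config(seed = 4)
  reg <- target_regions("c", 1000L, 3000L, "R", "tss", 2000L)
  set.seed(4)
  can <- simulate_region_fragments(reg, 2e4, jitter_sd = 4, ndr_depth = 0.1,
                                   short_frac = 0, cfg = cfg)
  ctl <- simulate_region_fragments(reg, 2e4, jitter_sd = 4, ndr_depth = 0.6,
                                   short_frac = 0, cfg = cfg)
  anchor_occ <- function(fr) {
    mean(bf_pileup(fr, target_regions("c", 1950L, 2050L, "a"))) /
      mean(bf_pileup(fr, reg))
  }
  expect_lt(anchor_occ(can) / anchor_occ(ctl), 1)
})

test_that("aggregate anchor occupancy is depleted under default NDR settings", {
  cfg <- sim_preset("null", seed = 5, n_cancer = 2, n_control = 2)
  coh <- simulate_cohort(cfg)
  nuc <- coh$regions[coh$regions$region_type != "cpg_marker", ]
  pooled <- do.call(rbind, coh$fragments)
  prof <- aggregate_anchor_profile(filter_fragments(pooled), nuc)
  expect_lt(prof$anchor_ratio, 0.8)
})

test_that("anchor occupancy responds linearly to the NDR depth", {
  cfg <- sim_config(seed = 6)
  reg <- target_regions("c", 1000L, 3000L, "R", "tss", 2000L)
  levels <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  set.seed(6)
  occ <- vapply(levels, function(nd) {
    fr <- simulate_region_fragments(reg, 3e4, jitter_sd = 4, ndr_depth = nd,
                                    short_frac = 0, cfg = cfg)
    mean(bf_pileup(fr, target_regions("c", 1960L, 2040L, "a")))
  }, numeric(1))
  expect_gte(summary(lm(occ ~ levels))$r.squared, 0.9)
})

test_that("ground truth lists exactly the regions with planted effects", {
  cfg <- sim_preset("complementary", seed = 7, n_cancer = 2, n_control = 2,
                    depth = 50)
  coh <- simulate_cohort(cfg)
  expect_equal(coh$ground_truth$occupancy, sprintf("nuc%02d", 1:10))
  expect_equal(coh$ground_truth$fuzziness, sprintf("nuc%02d", 11:20))
  expect_equal(coh$ground_truth$wps, sprintf("nuc%02d", 21:30))
  expect_equal(coh$ground_truth$methylation, sprintf("cpg%02d", 1:10))
  nul <- simulate_cohort(sim_preset("null", seed = 7, n_cancer = 2,
                                    n_control = 2, depth = 50))
  expect_true(all(lengths(nul$ground_truth) == 0))
})

test_that("a poorly converted spike-in fails QC downstream", {
  cfg <- sim_preset("null", seed = 8, n_cancer = 2, n_control = 2,
                    depth = 50, lambda_conversion = 0.98)
  coh <- simulate_cohort(cfg)
  qc <- cohort_qc(coh)
  expect_true(all(!qc$passed))               # 2% apparent methylation > 1%
  cfg2 <- sim_preset("null", seed = 8, n_cancer = 2, n_control = 2,
                     depth = 50)
  expect_true(all(cohort_qc(simulate_cohort(cfg2))$passed))
})

test_that("written cohorts round-trip through the file readers", {
  dir <- withr::local_tempdir()
  cfg <- sim_preset("null", seed = 9, n_cancer = 2, n_control = 2,
                    n_tss = 2, n_pas = 1, n_cpg_regions = 3, depth = 60)
  coh <- simulate_cohort(cfg, dir = dir)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- read_cohort(dir)
  s <- coh$sample_sheet$sample_id[1]
  expect_equal(back$fragments[[s]][, c("chrom", "start", "end")],
               coh$fragments[[s]][, c("chrom", "start", "end")],
               ignore_attr = TRUE)
  expect_equal(back$methylation[[s]], coh$methylation[[s]])
  expect_equal(nrow(back$regions), nrow(coh$regions))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(meth_rate = 1.2), "rates")
  expect_error(sim_config(jitter_sd = -1), "jitter_sd")
  expect_error(sim_config(ndr_width = 3000), "NDR wider")
  expect_error(simulate_cohort(
    sim_preset("null", informative = list(methylation = 99, occupancy = integer(),
                                          fuzziness = integer(), wps = integer()))),
    "out of range")
})
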