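# flat zero baseline for 5 cycles, then exponential growth to a plateau
make_curve <- function(E, f0 = 1e-5, cycles = 1:40, plateau = 50) {
  f <- pmin(f0 * (1 + E)^cycles, plateau)
  f[1:5] <- 0
  f
}

test_that("efficiency estimation recovers planted E from noiseless curves", {
  for (E in c(0.6, 0.8, 1.0)) {
    fit <- estimate_efficiency_and_ct(1:40, make_curve(E))
    expect_equal(fit$efficiency, E, tolerance = 0.02)
    # with zero baseline spread the threshold is 1% of the plateau
    expect_equal(fit$ct, log(0.01 * 50 / 1e-5) / log(1 + E), tolerance = 0.05)
  }
  # uncapped perfect doubling
  fit <- estimate_efficiency_and_ct(1:40, 0.01 * 2^(1:40))
  expect_equal(fit$efficiency, 1.0, tolerance = 0.01)
  fit18 <- estimate_efficiency_and_ct(1:40, 0.01 * 1.8^(1:40))
  expect_equal(fit18$efficiency, 0.8, tolerance = 0.02)
})

test_that("degenerate curves raise classed conditions", {
  expect_error(estimate_efficiency_and_ct(1:40, rep(0.5, 40)),
               class = "femscreen_no_amplification")
  # flat baseline followed by a decaying signal: fitted efficiency < 0
  expect_error(
    estimate_efficiency_and_ct(1:40, c(rep(0.1, 5), 100 * 0.95^(1:35))),
    class = "femscreen_quality_failure")
  expect_error(estimate_efficiency_and_ct(1:5, rep(1, 5)), "10 cycles")
  expect_error(estimate_efficiency_and_ct(c(1:39, 39), make_curve(1)),
               "strictly increasing")
})

test_that("curve tables are processed per well with flags", {
  good <- data.frame(sample_id = "s1", gene = "g1", cycle = 1:40,
                     fluorescence = make_curve(0.8))
  flat <- data.frame(sample_id = "s1", gene = "g2", cycle = 1:40,
                     fluorescence = 0.3)
  res <- process_amplification_curves(rbind(good, flat))
  expect_equal(res$flags, c("", "no_amplification"))
  expect_equal(res$efficiency[1], 0.8, tolerance = 0.02)
  expect_true(is.na(res$ct[2]))
  expect_error(process_amplification_curves(data.frame(gene = "g")),
               class = "femscreen_schema_error")
})

test_that("standard-curve inversion matches the closed form", {
  standards <- data.frame(log10_copies = c(6, 5, 4),
                          ct = c(10, 13.3219, 16.6439))
  fit <- lm(ct ~ log10_copies, data = standards)
  oracle <- 10^((20 - coef(fit)[[1]]) / coef(fit)[[2]])
  expect_equal(copies_from_standard_curve(20, standards), oracle)
  expect_equal(oracle, 1000, tolerance = 0.03)
  # a Ct equal to a standard's Ct returns that standard's copies
  expect_equal(copies_from_standard_curve(13.3219, standards), 1e5,
               tolerance = 1e-4)
  expect_error(copies_from_standard_curve(20, standards[1:2, ]), "3 standards")
  expect_error(copies_from_standard_curve(
    20, data.frame(log10_copies = c(4, 4.5, 5), ct = c(10, 12, 14))), "2 log10")
  expect_error(copies_from_standard_curve(
    20, data.frame(log10_copies = c(4, 5, 6), ct = c(10, 10, 10))), "slope")
})

test_that("Ct round-trips through a standard curve within 1%", {
  E <- 0.93
  slope <- -1 / log10(1 + E)
  standards <- data.frame(log10_copies = 3:7, ct = 38 + slope * (3:7))
  for (copies in c(5e3, 2e5, 8e6)) {
    ct <- 38 + slope * log10(copies)
    expect_equal(copies_from_standard_curve(ct, standards), copies,
                 tolerance = 0.01)
  }
})

test_that("genome bp ratios follow the marker formula", {
  sizes <- genome_sizes() # 1.7 Mb / 14 kb / 2 Gb defaults
  counts <- marker_counts(n_wsp = 1, n_coi = 0.5, n_ah = 0.2805)
  expect_equal(genome_bp_ratio(counts, sizes, "nuc"), 330, tolerance = 1e-3)
  expect_equal(genome_bp_ratio(counts, sizes, "mt"),
               14e3 * 0.5 / 1.7e6)
  # homogeneity: scaling all counts leaves ratios unchanged
  scaled <- marker_counts(7, 3.5, 1.9635)
  expect_equal(genome_bp_ratio(scaled, sizes, "nuc"),
               genome_bp_ratio(counts, sizes, "nuc"))
  expect_equal(genome_bp_ratio(marker_counts(1, 0, 1), sizes, "mt"), 0)
  expect_error(genome_bp_ratio(marker_counts(0, 1, 1), sizes, "nuc"), "wsp")
})

test_that("bp proportions normalize and handle degenerate counts", {
  sizes <- genome_sizes(g_wo = 1, g_mt = 1, g_nuc = 2)
  p <- bp_proportions(marker_counts(1, 1, 1), sizes)
  expect_equal(unname(p), c(0.25, 0.25, 0.5))
  expect_equal(sum(p), 1)
  expect_equal(unname(bp_proportions(marker_counts(3, 0, 0), sizes)), c(1, 0, 0))
  set.seed(3)
  for (i in 1:20) {
    cts <- marker_counts(runif(1), runif(1), runif(1))
    expect_equal(sum(bp_proportions(cts, genome_sizes())), 1)
  }
  expect_error(bp_proportions(marker_counts(0, 0, 0), sizes), "zero")
})

test_that("enrichment fold is the odds ratio of the endosymbiont proportion", {
  sizes <- genome_sizes(g_wo = 1, g_mt = 1, g_nuc = 1)
  before <- marker_counts(1, 500, 499)  # p_wo = 0.001
  after <- marker_counts(1, 0.5, 0.5)   # p_wo = 0.5
  expect_equal(enrichment_fold(before, before, sizes), 1)
  expect_equal(enrichment_fold(before, after, sizes), 999)
  expect_lt(enrichment_fold(after, before, sizes), 1)
  expect_error(enrichment_fold(before, marker_counts(1, 0, 0), sizes), "odds")
})
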