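quiet_noise <- function() noise_model(ct_sd = 0, latent_sd = 0, unstable_sd = 0)

test_that("generate_annotation plants the preset's category counts", {
  preset <- small_preset()
  ann <- generate_annotation(preset, seed = 1)
  a <- ann$annotation
  expect_equal(nrow(a), preset$n_genes)
  expect_equal(sum(a$is_repeat), preset$n_repeats)
  expect_equal(sum(a$is_pseudogene), preset$n_pseudogenes)
  expect_equal(sum(a$length_bp < 150), preset$n_short)
  expect_equal(sum(a$is_split_chunk), preset$n_split_chunks)
  # planted categories are disjoint
  expect_true(all(a$is_repeat + a$is_pseudogene + a$is_split_chunk +
                    (a$length_bp < 150) <= 1))
  # proteins consistent with nucleotide lengths
  expect_true(all(nchar(a$protein) * 3 == a$length_bp))
})

test_that("a minimal preset yields one unflagged gene and bad presets error", {
  p1 <- funnel_preset(n_genes = 1L, n_repeats = 0L, n_pseudogenes = 0L,
                      n_short = 0L, n_split_chunks = 0L, n_core = 0L,
                      n_identical_to_nonfeminizer = 0L, n_amplifiable = 0L,
                      n_expressed = 0L, n_under_s1 = 0L, n_over_s1 = 0L,
                      n_fail_s2 = 0L, n_regulated_both_hosts = 0L,
                      n_ccf_lag1 = 0L, n_ccf_lag0 = 0L, n_in_felement = 0L,
                      n_identical_in_felement = 0L)
  ann <- generate_annotation(p1, seed = 2)
  expect_equal(nrow(ann$annotation), 1L)
  expect_false(any(ann$annotation$is_repeat))
  expect_error(funnel_preset(n_genes = 10L, n_repeats = 11L),
               class = "femscreen_config_error")
})

test_that("generators are deterministic for a fixed seed", {
  preset <- small_preset()
  expect_identical(generate_annotation(preset, seed = 9),
                   generate_annotation(preset, seed = 9))
  expect_false(identical(generate_annotation(preset, seed = 9)$annotation$protein,
                         generate_annotation(preset, seed = 10)$annotation$protein))
  design <- sampling_design("h", 1:4, 2L, 1L)
  truth <- data.frame(gene = rep("g1", 4), stage = 1:4, fold = c(1, 1, 2, 1))
  d1 <- generate_qpcr_dataset(design, truth, noise_model(), seed = 3)
  d2 <- generate_qpcr_dataset(design, truth, noise_model(), seed = 3)
  expect_identical(d1, d2)
})

test_that("noiseless Ct values are analytically forced by the planted folds", {
  design <- sampling_design("h", 2:4, 1L, 1L)
  truth <- data.frame(gene = "g1", stage = c(2, 3, 4), fold = c(1, 2, 1))
  eff <- data.frame(gene = "g1", efficiency = 1)
  d <- generate_qpcr_dataset(design, truth, quiet_noise(), seed = 4,
                             efficiencies = eff, housekeeping = FALSE)
  avg <- average_technical_replicates(d$ct)
  ct_cal <- avg$ct[avg$stage == 2]
  expect_equal(avg$ct[avg$stage == 3], ct_cal - 1) # fold 2, E = 1: one cycle
  expect_equal(avg$ct[avg$stage == 4], ct_cal)
})

test_that("fold reconstruction from noiseless Ct recovers the truth table", {
  design <- sampling_design("h", 1:5, 3L, 1L)
  set.seed(6)
  truth <- do.call(rbind, lapply(paste0("g", 1:4), function(g) {
    f <- 2^runif(5, -2, 2)
    f[2] <- 1
    data.frame(gene = g, stage = 1:5, fold = f)
  }))
  d <- generate_qpcr_dataset(design, truth, quiet_noise(), seed = 7)
  prof <- relative_expression(d$ct, paste0("g", 1:4), STABLE_REFERENCE_GENES,
                              d$efficiencies, calibrator_stage = 2)
  merged <- merge(prof, truth, by = c("gene", "stage"))
  expect_equal(merged$ratio, merged$fold, tolerance = 1e-10)
})

test_that("dropout flags every target well as non-amplified", {
  design <- sampling_design("h", 1:3, 2L, 1L)
  truth <- data.frame(gene = "g1", stage = 1:3, fold = 1)
  d <- generate_qpcr_dataset(design, truth,
                             noise_model(dropout_rate = 1), seed = 8)
  expect_true(all(is.na(d$ct$ct[d$ct$gene == "g1"])))
  expect_false(anyNA(d$ct$ct[d$ct$gene != "g1"]))
})

test_that("design schema violations raise a schema error", {
  bad <- data.frame(sample_id = "s1", host = "h", pool = 1) # no stage/campaign
  truth <- data.frame(gene = "g1", stage = 1, fold = 1)
  expect_error(generate_qpcr_dataset(bad, truth, noise_model(), seed = 1),
               class = "femscreen_schema_error")
})

test_that("two-host generation plants exact stage-lagged profiles", {
  stages <- 1:7
  a_log2 <- c(0, 0, 2, 1, 0, 0, 0)
  folds_a <- data.frame(gene = "g1", stage = stages, fold = 2^a_log2)
  two <- generate_two_host_profiles(folds_a, c(g1 = 1L), quiet_noise(),
                                    seed = 11)
  expect_equal(log2(two$folds_b$fold), c(0, 0, 0, 2, 1, 0, 0))

  # lag 0 and no noise: identical expected profiles in both hosts
  two0 <- generate_two_host_profiles(folds_a, c(g1 = 0L), quiet_noise(),
                                     seed = 12)
  expect_equal(two0$folds_b$fold, folds_a$fold)
  # empty lag map: unassigned genes fall back to flat profiles
  twoe <- generate_two_host_profiles(folds_a, integer(0), quiet_noise(),
                                     seed = 13)
  expect_true(all(twoe$folds_b$fold == 1))
  expect_error(generate_two_host_profiles(folds_a, c(g1 = 7L), quiet_noise(),
                                          seed = 14), "lag")
})

test_that("planted housekeeping structure separates stable from unstable genes", {
  design <- sampling_design("h", 2:6, 8L, 1L)
  truth <- data.frame(gene = "g1", stage = 2:6, fold = 1)
  d <- generate_qpcr_dataset(design, truth, noise_model(), seed = 15)
  avg <- average_technical_replicates(d$ct)
  m <- sapply(HOUSEKEEPING_GENES, function(g) avg$ct[avg$gene == g])
  cors <- cor(m)
  stable <- STABLE_REFERENCE_GENES
  off <- cors[stable, stable][upper.tri(diag(length(stable)))]
  expect_true(all(off > 0.98))
  unstable <- setdiff(HOUSEKEEPING_GENES, stable)
  expect_true(all(abs(cors[unstable, stable]) < 0.8))
})
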