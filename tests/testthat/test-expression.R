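# a tiny hand-built Ct table: one host, one campaign, calibrator stage 2
tiny_ct <- function(target_ct, ref_ct, stages = c(2, 3), gene = "tgt",
                    ref = "ref") {
  rows <- expand.grid(stage = stages, replicate = 1:2)
  do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    s <- rows$stage[i]
    data.frame(sample_id = paste0("s", s), host = "h", stage = s, pool = 1,
               replicate = rows$replicate[i], campaign = 1,
               gene = c(gene, ref),
               ct = c(target_ct[as.character(s)], ref_ct[as.character(s)]))
  }))
}

test_that("with E = 1 everywhere the ratio reduces exactly to 2^ddCt", {
  ct <- tiny_ct(target_ct = c("2" = 20, "3" = 19), ref_ct = c("2" = 18, "3" = 18))
  eff <- data.frame(gene = c("tgt", "ref"), efficiency = c(1, 1))
  prof <- relative_expression(ct, "tgt", "ref", eff)
  expect_equal(prof$ratio[prof$stage == 3], 2) # ddCt = 1
  expect_equal(prof$ratio[prof$stage == 2], 1)

  # all dCt = 0 gives ratio 1
  ct0 <- tiny_ct(c("2" = 20, "3" = 20), c("2" = 18, "3" = 18))
  expect_equal(relative_expression(ct0, "tgt", "ref", eff)$ratio, c(1, 1))
})

test_that("efficiency correction follows the Pfaffl arithmetic", {
  # target dCt(cal - sample) = 2 at E = 0.8; reference dCt = 1 at E = 1:
  # ratio = 1.8^2 / 2 = 1.62
  ct <- tiny_ct(c("2" = 20, "3" = 18), c("2" = 18, "3" = 17))
  eff <- data.frame(gene = c("tgt", "ref"), efficiency = c(0.8, 1))
  prof <- relative_expression(ct, "tgt", "ref", eff)
  expect_equal(prof$ratio[prof$stage == 3], 1.8^2 / 2)
  expect_error(relative_expression(ct, "tgt", "ref",
                                   data.frame(gene = c("tgt", "ref"),
                                              efficiency = c(1.2, 1))),
               "\\[0, 1\\]")
  expect_error(relative_expression(ct, "tgt", "ref", eff,
                                   calibrator_stage = 9), "calibrator")
})

test_that("the reference geometric mean is stable under duplicated references", {
  ct <- tiny_ct(c("2" = 20, "3" = 18.3), c("2" = 18, "3" = 17.2))
  twin <- ct[ct$gene == "ref", ]
  twin$gene <- "ref2"
  eff <- data.frame(gene = c("tgt", "ref", "ref2"), efficiency = c(0.9, 1, 1))
  p1 <- relative_expression(ct, "tgt", "ref", eff)
  p2 <- relative_expression(rbind(ct, twin), "tgt", c("ref", "ref2"), eff)
  expect_equal(p1$ratio, p2$ratio)
  # a single reference with constant Ct contributes no normalization at all
  const <- ct
  const$ct[const$gene == "ref"] <- 25
  p3 <- relative_expression(const, "tgt", "ref",
                            data.frame(gene = c("tgt", "ref"),
                                       efficiency = c(0.9, 1)))
  expect_equal(p3$ratio[p3$stage == 3], 1.9^(20 - 18.3))
})

test_that("classification thresholds are inclusive and direction-resolved", {
  prof <- data.frame(gene = "g", stage = c(3, 4, 5, 6), pool = 1,
                     ratio = c(1, 2.0, 1, 1))
  call <- classify_de(prof)
  expect_equal(call$status, "over") # ratio exactly 2 counts
  expect_equal(call$stages, "4")

  none <- classify_de(data.frame(gene = "g", stage = 3:6, pool = 1, ratio = 1))
  expect_equal(none$status, "none")

  both <- classify_de(data.frame(gene = "g", stage = c(3, 4), pool = 1,
                                 ratio = c(8, 0.4)))
  expect_equal(both$status, "over") # |log2 8| > |log2 0.4|
  expect_error(classify_de(prof, stages_of_interest = integer(0)), "nonempty")
})

test_that("reference selection keeps exactly the planted stable panel", {
  design <- sampling_design("h", 2:6, c(8L, 5L, 4L, 4L, 4L), 1L)
  truth <- data.frame(gene = "g1", stage = 2:6, fold = 1)
  d <- generate_qpcr_dataset(design, truth, noise_model(), seed = 41)
  refs <- select_reference_genes(d$ct)
  expect_setequal(refs, STABLE_REFERENCE_GENES)
})

test_that("reference selection degenerate inputs are handled", {
  # all genes sharing identical Ct vectors correlate perfectly: all selected
  samples <- data.frame(sample_id = paste0("s", 1:6), host = "h",
                        stage = rep(2:4, 2), pool = rep(1:2, each = 3),
                        replicate = 1, campaign = 1)
  shared <- rnorm(6, 20)
  ct <- do.call(rbind, lapply(c("hk1", "hk2", "hk3"), function(g) {
    transform(samples, gene = g, ct = shared)
  }))
  expect_setequal(select_reference_genes(ct, c("hk1", "hk2", "hk3"),
                                         wsp_gene = NULL),
                  c("hk1", "hk2", "hk3"))
  # a constant-Ct gene has undefined correlation: dropped with a warning
  ct2 <- rbind(ct, transform(samples, gene = "flat", ct = 21))
  expect_warning(
    sel <- select_reference_genes(ct2, c("hk1", "hk2", "hk3", "flat"),
                                  wsp_gene = NULL),
    "constant")
  expect_false("flat" %in% sel)
  expect_error(select_reference_genes(ct[ct$gene == "hk1", ], "hk1",
                                      wsp_gene = NULL), "two housekeeping")
  expect_error(select_reference_genes(ct[ct$sample_id %in% c("s1", "s2"), ],
                                      c("hk1", "hk2"), wsp_gene = NULL),
               "three complete")
})

test_that("presence filter keeps genes expressed in any stage", {
  pres <- data.frame(gene = c("a", "b", "c"),
                     s3 = c(FALSE, FALSE, TRUE), s4 = FALSE,
                     s5 = FALSE, s6 = c(TRUE, FALSE, FALSE))
  expect_setequal(presence_filter(pres), c("a", "c"))
  expect_error(presence_filter(data.frame(gene = "a")), "stage")
})

test_that("the consistency rule demands a same-direction replicate crossing", {
  calls <- data.frame(gene = c("up", "down"), status = c("over", "under"))
  prof2 <- rbind(
    data.frame(gene = "up", stage = 1:7, pool = 1, ratio = 1.9),   # never >= 2
    data.frame(gene = "down", stage = 1:7, pool = 1,
               ratio = c(1, 1, 0.4, 1, 1, 1, 1)))                  # one <= 0.5
  expect_equal(consistency_filter(calls, prof2), "down")
  # an opposite-direction crossing does not rescue a gene
  prof3 <- data.frame(gene = c("up"), stage = 1:7, pool = 1, ratio = 0.2)
  expect_equal(length(consistency_filter(calls[1, ], prof3)), 0L)
  expect_error(consistency_filter(calls, prof2[prof2$gene == "up", ]), "down")
})
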