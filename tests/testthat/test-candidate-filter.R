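random_annotation <- function(n, seed) {
  set.seed(seed)
  data.frame(
    gene_id = sprintf("g%03d", seq_len(n)),
    product = rep("hypothetical protein", n),
    length_bp = sample(c(90, 120, 180, 300), n, replace = TRUE),
    is_repeat = runif(n) < 0.3,
    is_pseudogene = runif(n) < 0.2,
    is_split_chunk = runif(n) < 0.1,
    protein = vapply(seq_len(n), function(i) random_protein(30), character(1))
  )
}

test_that("filter results always partition the input gene set", {
  for (seed in 1:8) {
    ann <- random_annotation(50, seed)
    res <- filter_annotation(ann)
    parts <- c(res$survivors, unlist(res$removals, use.names = FALSE))
    expect_setequal(parts, ann$gene_id)
    expect_equal(length(parts), nrow(ann))
    expect_equal(sum(vapply(res$removals, length, integer(1))) +
                   length(res$survivors), nrow(ann))
  }
})

test_that("overlapping flags are counted once, under the first matching filter", {
  ann <- data.frame(
    gene_id = c("both", "pseudo_short", "short_split", "clean"),
    product = "p",
    length_bp = c(200, 100, 100, 200),
    is_repeat = c(TRUE, FALSE, FALSE, FALSE),
    is_pseudogene = c(TRUE, TRUE, FALSE, FALSE),
    is_split_chunk = c(FALSE, FALSE, TRUE, FALSE),
    protein = "MKV")
  res <- filter_annotation(ann)
  expect_equal(res$removals$repeats, "both")
  expect_equal(res$removals$pseudogenes, "pseudo_short")
  expect_equal(res$removals$short, "short_split")
  expect_equal(res$survivors, "clean")
})

test_that("annotation filter validates ids and handles empty input", {
  ann <- random_annotation(4, 1)
  ann$gene_id <- rep("dup", 4)
  expect_error(filter_annotation(ann), "duplicate")
  empty <- random_annotation(0, 1)
  res <- filter_annotation(empty)
  expect_length(res$survivors, 0)
})

test_that("core and conservation filters remove exactly the flagged genes", {
  survivors <- paste0("g", 1:6)
  core <- data.frame(group_id = "OG0001", genome = c("wVulC", "wVulC", "other"),
                     gene_id = c("g2", "g5", "x1"))
  res <- filter_core(survivors, core, "wVulC")
  expect_setequal(res$survivors, c("g1", "g3", "g4", "g6"))
  expect_setequal(res$removals$core_genome, c("g2", "g5"))
  none <- filter_core(survivors, core[0, ], "wVulC")
  expect_setequal(none$survivors, survivors)

  hits <- data.frame(query = c("g1", "g3", "g4"),
                     identity = c(1.0, 0.999, 1.0),
                     query_coverage = c(0.95, 1.0, 0.89))
  res2 <- filter_conserved_vs_nonfeminizer(survivors, hits)
  # only the 100%-identity hit with >= 90% coverage removes its gene
  expect_setequal(res2$removals$identical_to_nonfeminizer, "g1")
  expect_true(all(c("g3", "g4") %in% res2$survivors))
})

test_that("survivor counts never increase along the chained cascade", {
  preset <- small_preset()
  ann <- generate_annotation(preset, seed = 5)
  focal <- data.frame(genome = "wVulC", gene_id = ann$annotation$gene_id,
                      protein = ann$annotation$protein)
  r1 <- filter_annotation(ann$annotation)
  hits <- homology_hits(rbind(focal[focal$gene_id %in% r1$survivors, ],
                              ann$references))
  core <- core_genome(cluster_orthologs(hits), unique(ann$references$genome))
  nf_hits <- align_sets(focal, ann$nonfeminizer, mode = "local")
  res <- filter_cascade(ann$annotation, core, nf_hits, "wVulC")
  counts <- res$counts
  chain <- cumsum(c(0, counts[c("repeats", "pseudogenes", "short",
                                "split_chunks", "core_genome",
                                "identical_to_nonfeminizer")]))
  expect_true(all(diff(counts[["input"]] - chain) <= 0))
  expect_equal(counts[["survivors"]],
               sum(ann$truth$role == "candidate"))
  expect_equal(counts[["core_genome"]], preset$n_core)
  expect_equal(counts[["identical_to_nonfeminizer"]],
               preset$n_identical_to_nonfeminizer)
})
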