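test_that("global alignment identity reflects planted substitutions", {
  set.seed(21)
  p <- random_protein(43)
  self <- align(p, p, mode = "global")
  expect_equal(self$identity, 1)
  expect_equal(self$query_coverage, 1)
  mutated <- mutate_to_identity(p, 41 / 43, seed = 5)
  hit <- align(p, mutated, mode = "global")
  expect_equal(hit$identity, 41 / 43) # prints as 95.35%
  expect_equal(hit$alignment_length, 43L)
})

test_that("alignment scores equal the brute-force affine-gap DP oracle", {
  set.seed(22)
  for (i in 1:25) {
    a <- random_protein(sample(5:20, 1))
    b <- random_protein(sample(5:20, 1))
    for (mode in c("global", "local")) {
      expect_equal(align(a, b, mode = mode)$score,
                   oracle_align_score(a, b, mode = mode),
                   info = sprintf("%s vs %s (%s)", a, b, mode))
    }
  }
})

test_that("global identity is symmetric and inputs are validated", {
  set.seed(23)
  for (i in 1:10) {
    a <- random_protein(30)
    b <- mutate_to_identity(a, runif(1, 0.5, 0.95), seed = i)
    expect_equal(align(a, b, mode = "global")$identity,
                 align(b, a, mode = "global")$identity)
  }
  expect_error(align("", "MKV"), "nonempty")
  expect_error(align("MKV", "MKB"), "amino acids")
})

test_that("unrelated sequences score far above the significance e-value", {
  set.seed(24)
  evals <- replicate(20, {
    align(random_protein(100), random_protein(100), mode = "local")$evalue
  })
  expect_gt(min(evals), 0.001)
})

test_that("evalue follows the Karlin-Altschul form", {
  expect_equal(evalue(20, 100, 1000), 1e5 * 2^-20)
  expect_equal(evalue(0, 1, 1), 1)
  expect_equal(evalue(1e6, 100, 1000), 0)
  expect_error(evalue(10, 0, 5), "> 0")
})

test_that("ortholog clustering finds planted families as reciprocal components", {
  set.seed(25)
  genomes <- paste0("G", 1:5)
  parent1 <- random_protein(60)
  parent2 <- random_protein(60)
  fam1 <- data.frame(genome = genomes, gene_id = paste0("a_", genomes),
                     protein = vapply(1:5, function(i)
                       mutate_to_identity(parent1, 0.95, seed = i), character(1)))
  fam2 <- data.frame(genome = genomes, gene_id = paste0("b_", genomes),
                     protein = vapply(1:5, function(i)
                       mutate_to_identity(parent2, 0.95, seed = 10 + i), character(1)))
  hits <- homology_hits(rbind(fam1, fam2))
  groups <- cluster_orthologs(hits)
  expect_equal(length(unique(groups$group_id)), 2L)
  expect_setequal(groups$gene_id[groups$group_id == groups$group_id[
    groups$gene_id == "a_G1"]], fam1$gene_id)

  # oracle: brute-force components over threshold-passing reciprocal edges
  pass <- hits[hits$identity >= 0.7 & hits$evalue <= 1e-6, ]
  edges <- as.matrix(pass[pass$query < pass$subject, c("query", "subject")])
  comp <- oracle_components(unique(c(edges)), edges)
  expect_equal(length(unique(comp)), 2L)
  split_oracle <- unname(lapply(split(names(comp), comp), sort))
  split_pkg <- unname(lapply(split(groups$gene_id, groups$group_id), sort))
  expect_setequal(split_pkg, split_oracle)
})

test_that("clustering respects thresholds and input row order", {
  set.seed(26)
  parent <- random_protein(60)
  prot <- data.frame(
    genome = paste0("G", 1:3), gene_id = paste0("g", 1:3),
    protein = c(parent,
                mutate_to_identity(parent, 0.95, seed = 1),
                mutate_to_identity(parent, 0.60, seed = 2)))
  hits <- homology_hits(prot)
  groups <- cluster_orthologs(hits)
  expect_setequal(groups$gene_id, c("g1", "g2")) # g3 below the identity floor
  expect_identical(cluster_orthologs(hits[sample(nrow(hits)), ]), groups)
  expect_equal(nrow(cluster_orthologs(hits, min_identity = 0.99)), 0L)
  expect_error(cluster_orthologs(hits, min_identity = 1.2),
               class = "femscreen_config_error")
})

test_that("core genome keeps only groups spanning the whole panel", {
  groups <- data.frame(
    group_id = c("OG0001", "OG0001", "OG0001", "OG0002", "OG0002"),
    genome = c("A", "B", "C", "A", "B"),
    gene_id = paste0("x", 1:5))
  expect_equal(unique(core_genome(groups, c("A", "B", "C"))$group_id), "OG0001")
  expect_equal(unique(core_genome(groups, c("A", "B"))$group_id),
               c("OG0001", "OG0002"))
  expect_error(core_genome(groups, character(0)), "nonempty")
})

test_that("planted core families are recovered exactly from a synthetic genome", {
  preset <- small_preset()
  ann <- generate_annotation(preset, seed = 31)
  focal <- data.frame(genome = "wVulC", gene_id = ann$annotation$gene_id,
                      protein = ann$annotation$protein)
  hits <- homology_hits(rbind(focal, ann$references))
  groups <- cluster_orthologs(hits)
  core <- core_genome(groups, unique(ann$references$genome))
  core_focal <- core$gene_id[core$genome == "wVulC"]
  expect_setequal(core_focal, ann$truth$gene_id[ann$truth$role == "core"])
})
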