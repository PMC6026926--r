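# End-to-end orchestration: fixture generation, the full screen, and the
# funnel report.

#' Default run configuration
#'
#' All thresholds of the screen in one place, each defaulting to the
#' published value: 150 bp annotation length cut; 70% identity and 1e-6
#' e-value for ortholog clustering; 100% identity over >= 90% length for
#' the non-feminizer conservation filter; r > 0.95 for reference-gene
#' selection; 0.5/2 fold thresholds calibrated to stage 2 over stages 3-6
#' (native host) and 2-5 (heterologous host, one stage earlier); 0.001
#' e-value and 90% identity for the f-element search.
#'
#' @param ... Overrides of individual fields.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    focal_genome = FOCAL_GENOME,
    min_length_bp = 150L,
    cluster_min_identity = 0.70,
    cluster_max_evalue = 1e-6,
    conserved_min_coverage = 0.90,
    word_size = 10L,
    reference_r_min = 0.95,
    reference_alpha = 0.05,
    wsp_gene = "wsp",
    calibrator_stage = 2L,
    stages_of_interest_native = 3:6,
    stages_of_interest_hetero = 2:5,
    de_low = 0.5,
    de_high = 2.0,
    ccf_max_lag = 2L,
    felement_max_evalue = 0.001,
    felement_min_identity = 0.90,
    output_dir = NULL,
    # input paths, filled in by make_paper_fixture() or by the user
    annotation = NULL, reference_proteomes = NULL, nonfeminizer = NULL,
    presence = NULL, qpcr_s1 = NULL, qpcr_s2 = NULL, qpcr_s3 = NULL,
    efficiencies = NULL, felement = NULL
  )
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg
}

#' Write the full synthetic study dataset to disk
#'
#' Generates every input the screen consumes under the given preset --
#' annotation and proteome files, the three qPCR sampling campaigns, the
#' presence matrix, per-gene efficiencies, and the f element -- together
#' with the truth tables naming all planted roles, and a ready-to-run
#' `config.yaml`. Byte-identical for a fixed seed.
#'
#' @param outdir Output directory (must be empty unless `force`).
#' @param seed Integer seed driving every generator.
#' @param preset A [funnel_preset()].
#' @param noise A [noise_model()].
#' @param force Overwrite an existing nonempty directory?
#' @return The configuration list (invisibly), with paths filled in.
#' @export
make_paper_fixture <- function(outdir, seed, preset = paper_funnel_preset(),
                               noise = noise_model(), force = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir, all.files = TRUE, no.. = TRUE)) &&
      !force) {
    stop("output directory exists and is not empty (use force = TRUE): ", outdir)
  }
  for (d in c("", "annotation", "proteomes", "qpcr", "felement", "truth")) {
    dir.create(file.path(outdir, d), showWarnings = FALSE, recursive = TRUE)
  }

  ann <- generate_annotation(preset, seed)
  write_annotation_tsv(ann$annotation, file.path(outdir, "annotation", "focal_annotation.tsv"))
  utils::write.table(ann$truth, file.path(outdir, "truth", "annotation_roles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ref_paths <- list()
  for (g in unique(ann$references$genome)) {
    sub <- ann$references[ann$references$genome == g, ]
    p <- file.path(outdir, "proteomes", paste0(g, ".faa"))
    write_protein_fasta(stats::setNames(sub$protein, sub$gene_id), p)
    ref_paths[[g]] <- p
  }
  nonfem_path <- file.path(outdir, "proteomes", paste0(NONFEM_GENOME, ".faa"))
  write_protein_fasta(stats::setNames(ann$nonfeminizer$protein,
                                      ann$nonfeminizer$gene_id), nonfem_path)

  candidates <- ann$truth$gene_id[ann$truth$role == "candidate"]
  truth <- plant_funnel_truth(candidates, preset, seed + 1L)
  utils::write.csv(truth$presence, file.path(outdir, "qpcr", "presence.csv"),
                   row.names = FALSE, quote = FALSE)

  designs <- paper_designs()
  s1 <- generate_qpcr_dataset(designs$s1, truth$folds_s1, noise, seed = seed + 2L)
  two <- generate_two_host_profiles(truth$folds_s2, truth$lags, noise,
                                    seed = seed + 3L,
                                    design_a = designs$s2, design_b = designs$s3,
                                    folds_b = truth$folds_b,
                                    efficiencies = s1$efficiencies)
  write_ct_csv(s1$ct, file.path(outdir, "qpcr", "sampling1.csv"))
  write_ct_csv(two$host_a$ct, file.path(outdir, "qpcr", "sampling2.csv"))
  write_ct_csv(two$host_b$ct, file.path(outdir, "qpcr", "sampling3.csv"))
  utils::write.table(s1$efficiencies, file.path(outdir, "qpcr", "efficiencies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  final_prot <- ann$annotation[match(truth$final, ann$annotation$gene_id),
                               c("gene_id", "protein")]
  fel <- generate_felement(final_prot, preset, seed = seed + 4L)
  fel_path <- file.path(outdir, "felement", "felement_synthetic.faa")
  write_protein_fasta(stats::setNames(fel$proteins$protein, fel$proteins$gene_id),
                      fel_path)

  for (nm in c("folds_s1", "folds_s2", "folds_b")) {
    utils::write.table(truth[[nm]], file.path(outdir, "truth", paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(fel$truth, file.path(outdir, "truth", "felement_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  roles <- truth[c("amplifiable", "expressed", "under_s1", "over_s1", "fail_s2",
                   "final", "regulated_b")]
  roles$lags <- as.list(truth$lags)
  jsonlite::write_json(roles, file.path(outdir, "truth", "expression_roles.json"),
                       auto_unbox = FALSE, pretty = TRUE)

  cfg <- default_config(
    annotation = file.path(outdir, "annotation", "focal_annotation.tsv"),
    reference_proteomes = ref_paths,
    nonfeminizer = nonfem_path,
    presence = file.path(outdir, "qpcr", "presence.csv"),
    qpcr_s1 = file.path(outdir, "qpcr", "sampling1.csv"),
    qpcr_s2 = file.path(outdir, "qpcr", "sampling2.csv"),
    qpcr_s3 = file.path(outdir, "qpcr", "sampling3.csv"),
    efficiencies = file.path(outdir, "qpcr", "efficiencies.tsv"),
    felement = fel_path,
    output_dir = file.path(outdir, "results")
  )
  yaml::write_yaml(cfg, file.path(outdir, "config.yaml"))
  invisible(cfg)
}

stage_error <- function(stage, e) {
  stop(errorCondition(
    sprintf("screen stage '%s' failed: %s", stage, conditionMessage(e)),
    class = c("femscreen_stage_error", "error")))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) stage_error(stage, e))
}

read_proteome <- function(path, genome) {
  seqs <- read_protein_fasta(path)
  data.frame(genome = genome, gene_id = names(seqs), protein = unname(seqs))
}

#' Run the full candidate screen
#'
#' Executes the screen in published order -- annotation filter cascade,
#' core-genome filter, non-feminizer conservation filter, amplification and
#' presence filters, sampling-1 differential-expression classification,
#' sampling-2 consistency rule, heterologous-host classification, lagged
#' cross-correlation, f-element search -- writing every intermediate
#' artifact to `output_dir` and returning the funnel report. Fully
#' deterministic given the configuration and input files.
#'
#' @param config A configuration list ([default_config()]) or the path to a
#'   YAML file with the same fields.
#' @return An object of class `funnel_report`.
#' @export
run_screen <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config[!vapply(config, is.null, logical(1))])
  outdir <- cfg$output_dir
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(name, writer) if (!is.null(outdir)) writer(file.path(outdir, name))

  annotation <- run_stage("annotation", read_annotation_tsv(cfg$annotation))
  n_annotated <- nrow(annotation)
  if (n_annotated == 0L) {
    return(empty_funnel_report())
  }

  cascade <- run_stage("filter_cascade", {
    r1 <- filter_annotation(annotation, cfg$min_length_bp)
    refs <- do.call(rbind, lapply(names(cfg$reference_proteomes), function(g) {
      read_proteome(cfg$reference_proteomes[[g]], g)
    }))
    focal_prot <- data.frame(genome = cfg$focal_genome,
                             gene_id = annotation$gene_id,
                             protein = annotation$protein)
    survivors_prot <- focal_prot[focal_prot$gene_id %in% r1$survivors, ]
    hits <- homology_hits(rbind(survivors_prot, refs), word_size = cfg$word_size)
    groups <- cluster_orthologs(hits, cfg$cluster_min_identity, cfg$cluster_max_evalue)
    core <- core_genome(groups, names(cfg$reference_proteomes))
    r2 <- chain_filters(r1, filter_core(r1$survivors, core, cfg$focal_genome))
    nonfem <- read_proteome(cfg$nonfeminizer, "nonfeminizer")
    nf_hits <- align_sets(focal_prot[focal_prot$gene_id %in% r2$survivors, ],
                          nonfem, mode = "local")
    res <- chain_filters(r2, filter_conserved_vs_nonfeminizer(
      r2$survivors, nf_hits, cfg$conserved_min_coverage))
    emit("ortholog_groups.tsv", function(p) utils::write.table(
      groups, p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("filter_audit.json", function(p) jsonlite::write_json(
      list(counts = as.list(res$counts), removals = res$removals), p,
      auto_unbox = TRUE, pretty = TRUE))
    res
  })
  candidates <- cascade$survivors

  presence <- run_stage("presence_filter", utils::read.csv(cfg$presence))
  amplifiable <- intersect(candidates, presence$gene)
  expressed <- run_stage("presence_filter",
                         intersect(amplifiable, presence_filter(presence)))

  eff <- run_stage("expression", utils::read.delim(cfg$efficiencies))
  ct1 <- run_stage("expression", read_ct_csv(cfg$qpcr_s1))
  references <- run_stage("reference_selection", select_reference_genes(
    ct1, r_min = cfg$reference_r_min, wsp_gene = cfg$wsp_gene,
    alpha = cfg$reference_alpha))
  profiles1 <- run_stage("expression", relative_expression(
    ct1, expressed, references, eff, cfg$calibrator_stage))
  calls1 <- run_stage("expression", classify_de(
    profiles1, cfg$stages_of_interest_native, cfg$de_low, cfg$de_high))
  under1 <- calls1$gene[calls1$status == "under"]
  over1 <- calls1$gene[calls1$status == "over"]
  emit("expression_sampling1.tsv",
       function(p) write_expression_tsv(profiles1, p, calls1))

  ct2 <- run_stage("consistency", read_ct_csv(cfg$qpcr_s2))
  profiles2 <- run_stage("consistency", relative_expression(
    ct2, c(under1, over1), references, eff, cfg$calibrator_stage))
  final <- run_stage("consistency", consistency_filter(
    calls1, profiles2, cfg$de_low, cfg$de_high))
  emit("expression_sampling2.tsv", function(p) write_expression_tsv(profiles2, p))

  ct3 <- run_stage("crosshost", read_ct_csv(cfg$qpcr_s3))
  profiles3 <- run_stage("crosshost", relative_expression(
    ct3, final, references, eff, cfg$calibrator_stage))
  calls_b <- run_stage("crosshost", classify_de(
    profiles3, cfg$stages_of_interest_hetero, cfg$de_low, cfg$de_high))
  regulated_both <- intersect(final, calls_b$gene[calls_b$status != "none"])
  cross <- run_stage("crosshost", crosshost_analysis(
    profiles2[profiles2$gene %in% final, ], profiles3, genes = final,
    max_lag = cfg$ccf_max_lag))
  emit("crosshost.tsv", function(p) utils::write.table(
    cross, p, sep = "\t", quote = FALSE, row.names = FALSE))

  fel_hits <- run_stage("felement", {
    fel <- read_proteome(cfg$felement, "felement")
    cand_prot <- data.frame(genome = cfg$focal_genome,
                            gene_id = final,
                            protein = annotation$protein[match(final, annotation$gene_id)])
    search_felement(cand_prot, fel, cfg$felement_max_evalue,
                    cfg$felement_min_identity)
  })
  emit("felement_hits.tsv", function(p) utils::write.table(
    fel_hits, p, sep = "\t", quote = FALSE, row.names = FALSE))

  report <- funnel_report(
    annotated = n_annotated,
    post_annotation_filters = n_annotated -
      length(cascade$removals$repeats) - length(cascade$removals$pseudogenes) -
      length(cascade$removals$short) - length(cascade$removals$split_chunks),
    candidates = length(candidates),
    amplifiable = length(amplifiable),
    expressed = length(expressed),
    de_sampling1_under = length(under1),
    de_sampling1_over = length(over1),
    final_candidates = length(final),
    regulated_both_hosts = length(regulated_both),
    crosscorr_significant = sum(cross$significant),
    crosscorr_lag1 = sum(cross$significant & cross$best_lag == 1L),
    in_felement = nrow(fel_hits),
    identical_in_felement = sum(fel_hits$max_identity >= 100 - 1e-6),
    details = list(
      reference_genes = references,
      under_genes = under1, over_genes = over1, final_genes = final,
      regulated_both = regulated_both,
      crosscorr = cross, felement_hits = fel_hits,
      filter_counts = as.list(cascade$counts)
    )
  )
  emit("funnel_report.json", function(p) jsonlite::write_json(
    report[setdiff(names(report), "details")], p, auto_unbox = TRUE, pretty = TRUE))
  emit("funnel_report.txt", function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    sink(con)
    print(report)
    sink()
  })
  report
}

funnel_report <- function(..., details = list()) {
  counts <- list(...)
  main_chain <- c("annotated", "post_annotation_filters", "candidates",
                  "amplifiable", "expressed", "final_candidates")
  vals <- unlist(counts[main_chain])
  if (any(diff(vals) > 0)) {
    stop("funnel report is not nonincreasing along the main chain")
  }
  if (counts$in_felement > counts$final_candidates) {
    stop("more genes in the f element than final candidates")
  }
  structure(c(counts, list(details = details)), class = "funnel_report")
}

empty_funnel_report <- function() {
  funnel_report(annotated = 0L, post_annotation_filters = 0L, candidates = 0L,
                amplifiable = 0L, expressed = 0L, de_sampling1_under = 0L,
                de_sampling1_over = 0L, final_candidates = 0L,
                regulated_both_hosts = 0L, crosscorr_significant = 0L,
                crosscorr_lag1 = 0L, in_felement = 0L,
                identical_in_felement = 0L)
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Candidate screen funnel\n")
  fmt <- function(label, value) cat(sprintf("  %-34s %6d\n", label, value))
  fmt("annotated genes", x$annotated)
  fmt("after annotation filters", x$post_annotation_filters)
  fmt("candidates (after cascade)", x$candidates)
  fmt("amplifiable", x$amplifiable)
  fmt("expressed (stages 3-6)", x$expressed)
  fmt("under-expressed, sampling 1", x$de_sampling1_under)
  fmt("over-expressed, sampling 1", x$de_sampling1_over)
  fmt("final candidates (consistent)", x$final_candidates)
  fmt("regulated in both hosts", x$regulated_both_hosts)
  fmt("cross-correlation significant", x$crosscorr_significant)
  fmt("  of which one-stage shift", x$crosscorr_lag1)
  fmt("in f element", x$in_felement)
  fmt("  of which identical copies", x$identical_in_felement)
  if (length(x$details$reference_genes)) {
    cat("  reference genes:", paste(x$details$reference_genes, collapse = ", "), "\n")
  }
  invisible(x)
}
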