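# Synthetic qPCR data with planted expression structure.
#
# The generative model works in log2 template units. Every biological sample
# carries a latent loading offset lambda ~ N(0, latent_sd) shared by the
# target genes and the planted-stable housekeeping genes; the remaining
# housekeeping genes fluctuate independently. A gene with true per-stage
# fold f (relative to the calibrator stage) and amplification efficiency E
# yields
#
#   Ct = base - (log2 f + lambda) / log2(1 + E) + N(0, ct_sd)
#
# per technical replicate, so efficiency-corrected calibration against the
# calibrator stage recovers f exactly when ct_sd = 0 (the references cancel
# the latent term whatever their efficiencies are).

#' Housekeeping panel used by the synthetic qPCR generator
#'
#' The 15-gene housekeeping panel measured for reference-gene selection; the
#' first element (`wsp`, the endosymbiont single-copy marker) anchors the
#' stage-invariance verification. `STABLE_REFERENCE_GENES` are the six genes
#' the generator plants on the common stability signal, i.e. the expected
#' output of [select_reference_genes()].
#'
#' @format Character vectors.
#' @export
HOUSEKEEPING_GENES <- c("wsp", "coxA", "atpD", "sucB", "gatB", "gltA", "L2",
                        "L20", "S4", "fabF", "pyrB", "purF", "tkt", "hcpA",
                        "fbpA")

#' @rdname HOUSEKEEPING_GENES
#' @export
STABLE_REFERENCE_GENES <- c("gltA", "L2", "L20", "S4", "fabF", "purF")

#' Build a qPCR sampling design table
#'
#' One row per biological sample (a pool of juveniles at a developmental
#' stage); the paired technical replicates are added by the generator.
#'
#' @param host Host identifier (e.g. `"Avulgare"`, `"Cconvexus"`).
#' @param stages Integer vector of sampled intermolt stages.
#' @param pools_per_stage Number of pools at each stage (recycled).
#' @param campaign Sampling campaign index (1, 2 or 3).
#' @return Data frame with columns `sample_id`, `host`, `stage`, `pool`,
#'   `campaign`.
#' @export
sampling_design <- function(host, stages, pools_per_stage, campaign) {
  pools_per_stage <- rep_len(pools_per_stage, length(stages))
  rows <- do.call(rbind, lapply(seq_along(stages), function(i) {
    data.frame(host = host, stage = stages[i], pool = seq_len(pools_per_stage[i]),
               campaign = campaign)
  }))
  rows$sample_id <- sprintf("%s_c%d_s%d_p%02d", rows$host, rows$campaign,
                            rows$stage, rows$pool)
  rows[, c("sample_id", "host", "stage", "pool", "campaign")]
}

#' The study's three sampling campaigns
#'
#' Campaign 1: native-host pools at stages 2-6 (40, 24, 16, 16 and 16 pools
#' respectively). Campaign 2: triplicated native-host pools at stages 1-7.
#' Campaign 3: triplicated heterologous-host pools at stages 1-7.
#'
#' @param host_a,host_b Host identifiers for the native and heterologous
#'   host.
#' @return Named list of three design tables (`s1`, `s2`, `s3`).
#' @export
paper_designs <- function(host_a = "Avulgare", host_b = "Cconvexus") {
  list(
    s1 = sampling_design(host_a, 2:6, c(40L, 24L, 16L, 16L, 16L), campaign = 1L),
    s2 = sampling_design(host_a, 1:7, 3L, campaign = 2L),
    s3 = sampling_design(host_b, 1:7, 3L, campaign = 3L)
  )
}

check_design <- function(design) {
  needed <- c("sample_id", "host", "stage", "pool", "campaign")
  if (!is.data.frame(design) || !all(needed %in% names(design))) {
    stop(errorCondition(
      paste("design table must have columns", paste(needed, collapse = ", ")),
      class = c("femscreen_schema_error", "error")))
  }
  invisible(design)
}

#' Generate a synthetic qPCR Ct dataset
#'
#' Emits per-well Ct values (two technical replicates per well) for the
#' target genes in `truth` and, optionally, the 15-gene housekeeping panel
#' of which exactly the six [STABLE_REFERENCE_GENES] track a common
#' per-sample stability signal while the other nine fluctuate independently.
#'
#' @param design Sampling design table (see [sampling_design()]).
#' @param truth Per-gene per-stage fold table: data frame with columns
#'   `gene`, `stage`, `fold` (fold relative to the calibrator stage; must
#'   cover every stage in `design`).
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param efficiencies Optional data frame `gene`, `efficiency`; genes not
#'   listed get an efficiency drawn uniformly from the noise model's range.
#' @param housekeeping Emit the housekeeping panel as well?
#' @return A list of class `qpcr_dataset`: `ct` (long data frame
#'   `sample_id, host, stage, pool, replicate, campaign, gene, ct`, `ct` is
#'   `NA` for dropped-out wells), `efficiencies` (`gene`, `efficiency`),
#'   and `truth` (the fold table, the planted reference for recovery tests).
#' @export
generate_qpcr_dataset <- function(design, truth, noise, seed,
                                  efficiencies = NULL, housekeeping = TRUE) {
  check_design(design)
  if (!all(c("gene", "stage", "fold") %in% names(truth))) {
    stop("truth table must have columns gene, stage, fold")
  }
  withr::with_seed(seed, {
    generate_qpcr_impl(design, truth, noise, efficiencies, housekeeping)
  })
}

generate_qpcr_impl <- function(design, truth, noise, efficiencies, housekeeping) {
  genes <- unique(truth$gene)
  stages <- sort(unique(design$stage))
  if (!all(design$stage %in% truth$stage)) {
    stop("truth table does not cover every design stage")
  }
  fold <- matrix(NA_real_, nrow = length(genes), ncol = length(stages),
                 dimnames = list(genes, stages))
  fold[cbind(match(truth$gene, genes), match(truth$stage, stages))] <- truth$fold
  if (anyNA(fold)) stop("truth table must give a fold for every gene at every stage")

  hk <- if (housekeeping) HOUSEKEEPING_GENES else character(0)
  all_genes <- c(genes, hk)
  eff <- stats::runif(length(all_genes), noise$efficiency_range[1],
                      noise$efficiency_range[2])
  names(eff) <- all_genes
  if (!is.null(efficiencies)) {
    known <- intersect(efficiencies$gene, all_genes)
    eff[known] <- efficiencies$efficiency[match(known, efficiencies$gene)]
  }
  base_ct <- stats::setNames(stats::runif(length(all_genes), 18, 26), all_genes)

  ns <- nrow(design)
  lambda <- stats::rnorm(ns, 0, noise$latent_sd)
  # log2 template quantity per gene x sample
  log2q <- matrix(NA_real_, nrow = length(all_genes), ncol = ns,
                  dimnames = list(all_genes, design$sample_id))
  log2q[genes, ] <- log2(fold[, as.character(design$stage), drop = FALSE]) +
    rep(lambda, each = length(genes))
  if (housekeeping) {
    stable <- intersect(hk, STABLE_REFERENCE_GENES)
    unstable <- setdiff(hk, stable)
    log2q[stable, ] <- rep(lambda, each = length(stable))
    log2q[unstable, ] <- stats::rnorm(length(unstable) * ns, 0, noise$unstable_sd)
  }
  ct_true <- base_ct - log2q / log2(1 + eff)

  dropped <- matrix(FALSE, nrow = length(all_genes), ncol = ns,
                    dimnames = dimnames(log2q))
  if (noise$dropout_rate > 0) {
    dropped[genes, ] <- stats::runif(length(genes) * ns) < noise$dropout_rate
  }

  long <- do.call(rbind, lapply(1:2, function(rep_i) {
    df <- design[rep(seq_len(ns), each = length(all_genes)),
                 c("sample_id", "host", "stage", "pool", "campaign")]
    df$replicate <- rep_i
    df$gene <- rep(all_genes, ns)
    df$ct <- as.vector(ct_true) + stats::rnorm(length(ct_true), 0, noise$ct_sd)
    df$ct[as.vector(dropped)] <- NA_real_
    df
  }))
  long <- long[order(long$sample_id, long$gene, long$replicate), ]
  rownames(long) <- NULL
  structure(
    list(ct = long[, c("sample_id", "host", "stage", "pool", "replicate",
                       "campaign", "gene", "ct")],
         efficiencies = data.frame(gene = all_genes, efficiency = unname(eff)),
         truth = truth),
    class = "qpcr_dataset"
  )
}

#' @export
print.qpcr_dataset <- function(x, ...) {
  cat(sprintf("Synthetic qPCR dataset: %d wells (%d genes x %d samples x 2 technical replicates)\n",
              nrow(x$ct), length(unique(x$ct$gene)),
              length(unique(x$ct$sample_id))))
  invisible(x)
}

# shift a per-stage log2 profile by an integer lag, clamping at the edges
shift_profile <- function(values, lag) {
  n <- length(values)
  idx <- pmin(pmax(seq_len(n) - lag, 1L), n)
  values[idx]
}

#' Generate paired developmental Ct datasets for two hosts
#'
#' For genes with a planted lag L, the heterologous-host (host B) expected
#' log2 ratio at stage s equals the native-host (host A) expected log2 ratio
#' at stage s - L (edges clamped), emulating a shared expression program
#' shifted by the hosts' one-stage offset in sexual differentiation. Genes
#' without a lag assignment get independent profiles: the ones listed in
#' `folds_b` use those planted folds, the rest are flat (fold 1 at every
#' stage).
#'
#' @param folds_a Host-A fold table (`gene`, `stage`, `fold`).
#' @param lag_assignments Named integer vector, gene -> lag.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param design_a,design_b Sampling designs for the two hosts (equal stage
#'   grids; default the study's campaigns 2 and 3).
#' @param folds_b Optional host-B fold table for unassigned genes.
#' @param efficiencies Optional shared `gene`, `efficiency` table (the same
#'   primer pairs are used in both hosts).
#' @return List with `host_a` and `host_b` (two `qpcr_dataset` objects) and
#'   `folds_b` (the complete host-B truth table).
#' @export
generate_two_host_profiles <- function(folds_a, lag_assignments, noise, seed,
                                       design_a = paper_designs()$s2,
                                       design_b = paper_designs()$s3,
                                       folds_b = NULL, efficiencies = NULL) {
  stages_a <- sort(unique(design_a$stage))
  stages_b <- sort(unique(design_b$stage))
  if (!identical(stages_a, stages_b)) {
    stop("the two hosts must be sampled on the same stage grid")
  }
  if (length(lag_assignments) &&
      any(abs(lag_assignments) >= length(stages_b))) {
    stop("planted lag magnitude must be smaller than the number of stages")
  }
  genes <- unique(folds_a$gene)
  unknown <- setdiff(names(lag_assignments), genes)
  if (length(unknown)) {
    stop("lag assignments for genes absent from the host-A truth: ",
         paste(unknown, collapse = ", "))
  }
  wide_a <- matrix(NA_real_, nrow = length(genes), ncol = length(stages_a),
                   dimnames = list(genes, stages_a))
  wide_a[cbind(match(folds_a$gene, genes), match(folds_a$stage, stages_a))] <-
    folds_a$fold
  rows_b <- lapply(genes, function(g) {
    if (g %in% names(lag_assignments)) {
      f <- 2^shift_profile(log2(wide_a[g, ]), lag_assignments[[g]])
    } else if (!is.null(folds_b) && g %in% folds_b$gene) {
      sub <- folds_b[folds_b$gene == g, ]
      f <- sub$fold[match(stages_b, sub$stage)]
    } else {
      f <- rep(1, length(stages_b))
    }
    data.frame(gene = g, stage = stages_b, fold = unname(f))
  })
  full_b <- do.call(rbind, rows_b)
  host_a <- generate_qpcr_dataset(design_a, folds_a, noise, seed = seed,
                                  efficiencies = efficiencies)
  host_b <- generate_qpcr_dataset(design_b, full_b, noise, seed = seed + 1L,
                                  efficiencies = if (is.null(efficiencies))
                                    host_a$efficiencies else efficiencies)
  list(host_a = host_a, host_b = host_b, folds_b = full_b)
}

#' Read and write the qPCR CSV schema
#'
#' Header `sample_id,host,stage,pool,replicate,campaign,gene,ct`.
#'
#' @param ct Long Ct data frame.
#' @param path File path.
#' @export
write_ct_csv <- function(ct, path) {
  utils::write.csv(ct, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ct_csv
#' @export
read_ct_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
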