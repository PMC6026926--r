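# Reference-gene selection, efficiency-corrected relative expression
# calibrated to a developmental stage, differential-expression
# classification and the two-sampling consistency rule.

#' Average technical replicates at the Ct level
#'
#' @param ct Long Ct data frame (`sample_id, host, stage, pool, replicate,
#'   campaign, gene, ct`).
#' @return One row per biological sample and gene, with `ct` the mean over
#'   technical replicates (`NA` if all replicates failed to amplify).
#' @export
average_technical_replicates <- function(ct) {
  key <- interaction(ct$sample_id, ct$gene, drop = TRUE)
  first <- !duplicated(key)
  out <- ct[first, setdiff(names(ct), c("replicate", "ct"))]
  means <- tapply(ct$ct, key, mean, na.rm = TRUE)
  out$ct <- as.numeric(means[as.character(key[first])])
  out$ct[is.nan(out$ct)] <- NA_real_
  rownames(out) <- NULL
  out
}

# sample x gene Ct matrix from averaged long data
ct_wide <- function(ct_avg, genes = NULL) {
  if (is.null(genes)) genes <- sort(unique(ct_avg$gene))
  samples <- unique(ct_avg$sample_id)
  m <- matrix(NA_real_, nrow = length(samples), ncol = length(genes),
              dimnames = list(samples, genes))
  sub <- ct_avg[ct_avg$gene %in% genes, ]
  m[cbind(match(sub$sample_id, samples), match(sub$gene, genes))] <- sub$ct
  m
}

#' Select stable reference genes (BestKeeper-style)
#'
#' Computes the BestKeeper stability index (per-sample geometric mean of Ct
#' across the whole housekeeping panel), keeps the genes whose Ct is
#' Pearson-correlated with the index above `r_min`, and then verifies that
#' each kept gene's Ct relative to the endosymbiont single-copy marker
#' (`wsp`) is stage-invariant (one-way ANOVA on `Ct_gene - Ct_wsp` by
#' stage; genes with `p <= alpha` are dropped). Genes with constant Ct
#' (undefined correlation) are excluded with a warning.
#'
#' @param ct Long Ct data frame (technical replicates are averaged
#'   internally).
#' @param housekeeping Candidate reference gene names present in `ct`.
#' @param r_min Correlation floor against the stability index.
#' @param wsp_gene Name of the marker gene anchoring the stage-invariance
#'   check; set to `NULL` to skip the check.
#' @param alpha Significance level of the stage-invariance ANOVA.
#' @param pairwise Use the minimum pairwise inter-gene correlation instead
#'   of the gene-vs-index correlation.
#' @return Character vector of selected reference genes.
#' @export
select_reference_genes <- function(ct, housekeeping = HOUSEKEEPING_GENES,
                                   r_min = 0.95, wsp_gene = "wsp",
                                   alpha = 0.05, pairwise = FALSE) {
  avg <- average_technical_replicates(ct)
  housekeeping <- intersect(housekeeping, unique(avg$gene))
  candidates <- setdiff(housekeeping, wsp_gene)
  if (length(candidates) < 2L) stop("at least two housekeeping genes are required")
  m <- ct_wide(avg, housekeeping)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L) stop("at least three complete samples are required")
  constant <- apply(m[, candidates, drop = FALSE], 2, stats::sd) == 0
  if (any(constant)) {
    warning("excluding constant-Ct genes: ",
            paste(candidates[constant], collapse = ", "))
    candidates <- candidates[!constant]
  }
  if (pairwise) {
    cors <- stats::cor(m[, candidates, drop = FALSE])
    diag(cors) <- NA
    r <- apply(cors, 1, max, na.rm = TRUE)
  } else {
    index <- exp(rowMeans(log(m[, housekeeping, drop = FALSE])))
    r <- vapply(candidates, function(g) stats::cor(m[, g], index), numeric(1))
  }
  selected <- candidates[r > r_min]
  if (!is.null(wsp_gene) && wsp_gene %in% colnames(m) && length(selected)) {
    stage <- avg$stage[match(rownames(m), avg$sample_id)]
    keep <- vapply(selected, function(g) {
      delta <- m[, g] - m[, wsp_gene]
      p <- stats::anova(stats::aov(delta ~ factor(stage)))[["Pr(>F)"]][1]
      p > alpha
    }, logical(1))
    selected <- selected[keep]
  }
  selected
}

#' Efficiency-corrected relative expression calibrated to a stage
#'
#' Implements the efficiency-corrected ratio (the Pfaffl model generalized
#' to several reference genes): for each biological sample,
#' `ratio = (1+E_t)^(Ct_t,cal - Ct_t,sample) /
#' geomean_r (1+E_r)^(Ct_r,cal - Ct_r,sample)`, where `Ct_.,cal` is the
#' mean Ct over the calibrator-stage samples of the same host and campaign.
#' With all efficiencies equal to 1 this reduces exactly to `2^ddCt`.
#'
#' @param ct Long Ct data frame (technical replicates are averaged
#'   internally).
#' @param targets Target gene(s).
#' @param references Reference gene set (from [select_reference_genes()]).
#' @param efficiencies Data frame `gene`, `efficiency` covering targets and
#'   references, each in `[0, 1]`.
#' @param calibrator_stage Calibrator stage (default 2, the earliest stage
#'   amplified in all samplings).
#' @return Data frame `gene, host, campaign, stage, pool, sample_id, ratio`
#'   with one row per target gene and biological sample (`NA` ratio where
#'   the target well dropped out).
#' @export
relative_expression <- function(ct, targets, references, efficiencies,
                                calibrator_stage = 2L) {
  avg <- average_technical_replicates(ct)
  genes <- c(targets, references)
  missing <- setdiff(genes, unique(avg$gene))
  if (length(missing)) {
    stop("genes absent from the Ct data: ", paste(missing, collapse = ", "))
  }
  eff <- stats::setNames(efficiencies$efficiency, efficiencies$gene)[genes]
  if (anyNA(eff)) {
    stop("efficiencies missing for: ", paste(genes[is.na(eff)], collapse = ", "))
  }
  if (any(eff < 0 | eff > 1)) stop("efficiencies must lie in [0, 1]")
  out <- lapply(split(avg, list(avg$host, avg$campaign), drop = TRUE), function(block) {
    m <- ct_wide(block, genes)
    info <- block[match(rownames(m), block$sample_id), ]
    cal <- info$stage == calibrator_stage
    if (!any(cal)) {
      stop(sprintf("calibrator stage %d absent from host %s campaign %s",
                   calibrator_stage, info$host[1], info$campaign[1]))
    }
    ct_cal <- colMeans(m[cal, , drop = FALSE], na.rm = TRUE)
    if (anyNA(ct_cal) || any(is.nan(ct_cal))) {
      stop("missing calibrator Ct for some gene")
    }
    # log2 of the efficiency-corrected amount, per gene and sample
    dlog2 <- sweep(-m, 2, ct_cal, `+`) # Ct_cal - Ct_sample
    dlog2 <- sweep(dlog2, 2, log2(1 + eff[colnames(m)]), `*`)
    ref_term <- rowMeans(dlog2[, references, drop = FALSE])
    do.call(rbind, lapply(targets, function(g) {
      data.frame(gene = g, host = info$host, campaign = info$campaign,
                 stage = info$stage, pool = info$pool,
                 sample_id = info$sample_id,
                 ratio = 2^(dlog2[, g] - ref_term))
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Classify differential expression against fold thresholds
#'
#' A gene is over-expressed when its per-stage mean ratio is at least
#' `high` at one or more stages of interest, under-expressed when it is at
#' most `low`; thresholds are inclusive. If both occur, the status with the
#' larger absolute log2 departure wins.
#'
#' @param profile Expression profile data frame (`gene, stage, pool,
#'   ratio`).
#' @param stages_of_interest Stages scanned for threshold crossings.
#' @param low,high Fold thresholds (defaults 0.5 and 2).
#' @return Data frame `gene, status, stages` (`status` in
#'   `over`/`under`/`none`; `stages` a comma-separated list of supporting
#'   stages).
#' @export
classify_de <- function(profile, stages_of_interest = 3:6, low = 0.5, high = 2.0) {
  if (length(stages_of_interest) == 0L) stop("stages_of_interest must be nonempty")
  sub <- profile[profile$stage %in% stages_of_interest & !is.na(profile$ratio), ]
  rows <- lapply(split(sub, sub$gene), function(d) {
    means <- tapply(d$ratio, d$stage, mean)
    over_stages <- names(means)[means >= high]
    under_stages <- names(means)[means <= low]
    status <- if (length(over_stages) && length(under_stages)) {
      if (max(abs(log2(means[over_stages]))) >=
          max(abs(log2(means[under_stages])))) "over" else "under"
    } else if (length(over_stages)) "over"
    else if (length(under_stages)) "under"
    else "none"
    support <- switch(status, over = over_stages, under = under_stages,
                      character(0))
    data.frame(gene = d$gene[1], status = status,
               stages = paste(support, collapse = ","))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expression presence filter
#'
#' Retains genes called expressed (by qualitative RT-PCR) in at least one
#' of the gonad differentiation stages.
#'
#' @param presence Data frame with a `gene` column and one logical/0-1
#'   column per stage (e.g. `s3`..`s6`).
#' @return Character vector of retained genes.
#' @export
presence_filter <- function(presence) {
  stage_cols <- setdiff(names(presence), "gene")
  if (length(stage_cols) == 0L) stop("presence matrix has no stage columns")
  any_pos <- rowSums(as.matrix(presence[, stage_cols, drop = FALSE]) > 0) > 0
  presence$gene[any_pos]
}

#' Two-sampling consistency filter
#'
#' A gene differentially expressed in sampling 1 is retained only if at
#' least one sampling-2 replicate crosses the fold threshold in the same
#' direction at one or more stages (ratio >= `high` for an `over` call,
#' <= `low` for an `under` call).
#'
#' @param calls_s1 Sampling-1 DE calls (data frame `gene`, `status`, with
#'   statuses `over`/`under`).
#' @param profiles_s2 Sampling-2 expression profile with per-replicate rows
#'   (`gene, stage, pool, ratio`).
#' @param low,high Fold thresholds.
#' @return Character vector of consistently regulated genes.
#' @export
consistency_filter <- function(calls_s1, profiles_s2, low = 0.5, high = 2.0) {
  calls <- calls_s1[calls_s1$status %in% c("over", "under"), ]
  missing <- setdiff(calls$gene, unique(profiles_s2$gene))
  if (length(missing)) {
    stop("genes from sampling 1 missing in sampling 2: ",
         paste(missing, collapse = ", "))
  }
  keep <- vapply(seq_len(nrow(calls)), function(i) {
    g <- calls$gene[i]
    r <- profiles_s2$ratio[profiles_s2$gene == g]
    r <- r[!is.na(r)]
    if (calls$status[i] == "over") any(r >= high) else any(r <= low)
  }, logical(1))
  calls$gene[keep]
}

#' Write an expression profile TSV
#'
#' Header `gene host stage ratio_mean ratio_reps status`.
#'
#' @param profile Expression profile data frame.
#' @param calls Optional DE calls merged in by gene.
#' @param path Output path.
#' @export
write_expression_tsv <- function(profile, path, calls = NULL) {
  agg <- do.call(rbind, lapply(split(profile, list(profile$gene, profile$host,
                                                   profile$stage), drop = TRUE),
    function(d) {
      data.frame(gene = d$gene[1], host = d$host[1], stage = d$stage[1],
                 ratio_mean = mean(d$ratio, na.rm = TRUE),
                 ratio_reps = paste(sprintf("%.4g", d$ratio), collapse = ","))
    }))
  agg <- agg[order(agg$gene, agg$host, agg$stage), ]
  agg$status <- if (is.null(calls)) NA_character_ else
    calls$status[match(agg$gene, calls$gene)]
  utils::write.table(agg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
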