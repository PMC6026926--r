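#' Funnel preset: planted counts for every stage of the candidate screen
#'
#' A `funnel_preset` fixes how many genes the synthetic-data generators plant
#' in each category of the screen: annotation categories removed by the
#' in-silico filter cascade (repeats, pseudogenes, short genes, split-CDS
#' chunks, core-genome orthologs, genes identical to the non-feminizing
#' strain), the expression funnel (amplifiable, expressed, under/over-expressed
#' in sampling 1, failing the sampling-2 consistency check, regulated in both
#' hosts, significant in the lagged cross-correlation), and f-element
#' membership. The default values reproduce the published screen funnel for
#' the feminizing strain wVulC (1888 annotated genes down to 35 final
#' candidates, 27 of which lie in the f element).
#'
#' Removal categories are disjoint by construction: a planted repeat is never
#' also a planted pseudogene, so the per-category counts sum exactly through
#' the cascade.
#'
#' @param n_genes Number of annotated coding sequences in the focal genome.
#' @param n_repeats,n_pseudogenes,n_short,n_split_chunks Annotation categories
#'   removed by the first filter (counts of genes flagged repeat, pseudogene,
#'   shorter than the length cutoff, or small CDS of a gene split in two CDS).
#' @param n_core Genes planted as members of core-genome ortholog groups
#'   spanning all five reference genomes.
#' @param n_identical_to_nonfeminizer Genes planted with a 100%-identical
#'   homolog covering at least 90% of their length in the non-feminizing
#'   strain.
#' @param n_amplifiable Candidates for which PCR amplification succeeds.
#' @param n_expressed Amplifiable candidates expressed in at least one of the
#'   gonad differentiation stages (3 to 6).
#' @param n_under_s1,n_over_s1 Genes planted at least 2-fold under/over the
#'   calibrator in at least one of stages 3 to 6 in the first sampling.
#' @param n_fail_s2 Differentially expressed genes planted to stay inside the
#'   fold thresholds for all sampling-2 replicates (dropped by the
#'   consistency rule).
#' @param n_regulated_both_hosts Final candidates planted to cross the fold
#'   thresholds in the heterologous host as well.
#' @param n_ccf_lag1,n_ccf_lag0 Genes planted with a shared cross-host
#'   expression profile at a one-stage shift / no shift.
#' @param n_in_felement Final candidates represented in the synthetic
#'   f element.
#' @param n_identical_in_felement Represented candidates whose f-element
#'   copies are 100% identical at the amino-acid level.
#' @param copy_number_range Integer interval for per-gene f-element copy
#'   numbers.
#' @return An object of class `funnel_preset` (a validated named list).
#' @seealso [generate_annotation()], [make_paper_fixture()]
#' @examples
#' preset <- funnel_preset() # the published funnel
#' preset$n_genes
#' @export
funnel_preset <- function(n_genes = 1888L,
                          n_repeats = 792L,
                          n_pseudogenes = 26L,
                          n_short = 52L,
                          n_split_chunks = 16L,
                          n_core = 721L,
                          n_identical_to_nonfeminizer = 16L,
                          n_amplifiable = 216L,
                          n_expressed = 139L,
                          n_under_s1 = 13L,
                          n_over_s1 = 29L,
                          n_fail_s2 = 7L,
                          n_regulated_both_hosts = 29L,
                          n_ccf_lag1 = 2L,
                          n_ccf_lag0 = 1L,
                          n_in_felement = 27L,
                          n_identical_in_felement = 20L,
                          copy_number_range = c(1L, 5L)) {
  preset <- list(
    n_genes = as.integer(n_genes),
    n_repeats = as.integer(n_repeats),
    n_pseudogenes = as.integer(n_pseudogenes),
    n_short = as.integer(n_short),
    n_split_chunks = as.integer(n_split_chunks),
    n_core = as.integer(n_core),
    n_identical_to_nonfeminizer = as.integer(n_identical_to_nonfeminizer),
    n_amplifiable = as.integer(n_amplifiable),
    n_expressed = as.integer(n_expressed),
    n_under_s1 = as.integer(n_under_s1),
    n_over_s1 = as.integer(n_over_s1),
    n_fail_s2 = as.integer(n_fail_s2),
    n_regulated_both_hosts = as.integer(n_regulated_both_hosts),
    n_ccf_lag1 = as.integer(n_ccf_lag1),
    n_ccf_lag0 = as.integer(n_ccf_lag0),
    n_in_felement = as.integer(n_in_felement),
    n_identical_in_felement = as.integer(n_identical_in_felement),
    copy_number_range = as.integer(copy_number_range)
  )
  class(preset) <- "funnel_preset"
  validate_funnel_preset(preset)
  preset
}

#' @rdname funnel_preset
#' @export
paper_funnel_preset <- function() funnel_preset()

config_error <- function(msg) {
  stop(errorCondition(msg, class = c("femscreen_config_error", "error")))
}

validate_funnel_preset <- function(p) {
  counts <- p[setdiff(names(p), "copy_number_range")]
  for (nm in names(counts)) {
    if (length(counts[[nm]]) != 1L || is.na(counts[[nm]]) || counts[[nm]] < 0L) {
      config_error(sprintf("preset count '%s' must be a single nonnegative integer", nm))
    }
  }
  removals <- p$n_repeats + p$n_pseudogenes + p$n_short + p$n_split_chunks +
    p$n_core + p$n_identical_to_nonfeminizer
  if (removals > p$n_genes) {
    config_error(sprintf(
      "removal categories sum to %d which exceeds n_genes = %d", removals, p$n_genes
    ))
  }
  survivors <- p$n_genes - removals
  if (p$n_amplifiable > survivors) {
    config_error(sprintf("n_amplifiable = %d exceeds the %d cascade survivors",
                         p$n_amplifiable, survivors))
  }
  if (p$n_expressed > p$n_amplifiable) {
    config_error("n_expressed exceeds n_amplifiable")
  }
  if (p$n_under_s1 + p$n_over_s1 > p$n_expressed) {
    config_error("n_under_s1 + n_over_s1 exceeds n_expressed")
  }
  if (p$n_under_s1 + p$n_over_s1 < p$n_fail_s2) {
    config_error("n_fail_s2 exceeds n_under_s1 + n_over_s1")
  }
  n_final <- p$n_under_s1 + p$n_over_s1 - p$n_fail_s2
  if (p$n_regulated_both_hosts > n_final) {
    config_error(sprintf("n_regulated_both_hosts = %d exceeds the %d final candidates",
                         p$n_regulated_both_hosts, n_final))
  }
  if (p$n_ccf_lag1 + p$n_ccf_lag0 > p$n_regulated_both_hosts) {
    config_error("n_ccf_lag1 + n_ccf_lag0 exceeds n_regulated_both_hosts")
  }
  if (p$n_in_felement > n_final) {
    config_error(sprintf("n_in_felement = %d exceeds the %d final candidates",
                         p$n_in_felement, n_final))
  }
  if (p$n_identical_in_felement > p$n_in_felement) {
    config_error("n_identical_in_felement exceeds n_in_felement")
  }
  cr <- p$copy_number_range
  if (length(cr) != 2L || any(is.na(cr)) || cr[1] < 1L || cr[2] < cr[1]) {
    config_error("copy_number_range must be an integer interval [lo, hi] with lo >= 1")
  }
  invisible(p)
}

#' @export
print.funnel_preset <- function(x, ...) {
  cat("Funnel preset (planted counts)\n")
  n_final <- x$n_under_s1 + x$n_over_s1 - x$n_fail_s2
  cat(sprintf("  genes %d | removed: %d repeats, %d pseudogenes, %d short, %d split, %d core, %d identical\n",
              x$n_genes, x$n_repeats, x$n_pseudogenes, x$n_short,
              x$n_split_chunks, x$n_core, x$n_identical_to_nonfeminizer))
  cat(sprintf("  amplifiable %d -> expressed %d -> DE %d+%d -> final %d (both hosts %d, ccf %d+%d)\n",
              x$n_amplifiable, x$n_expressed, x$n_under_s1, x$n_over_s1,
              n_final, x$n_regulated_both_hosts, x$n_ccf_lag1, x$n_ccf_lag0))
  cat(sprintf("  f element: %d genes (%d identical), copies in [%d, %d]\n",
              x$n_in_felement, x$n_identical_in_felement,
              x$copy_number_range[1], x$copy_number_range[2]))
  invisible(x)
}

#' Noise model for synthetic qPCR data
#'
#' Gaussian per-well Ct noise, the range from which true per-gene
#' amplification efficiencies are drawn, and the probability that a truly
#' expressed gene fails amplification. The published study states no noise
#' magnitudes; the defaults are the package's own choice of a realistic
#' LightCycler-grade setting (0.1 cycles of technical noise, efficiencies
#' between 0.8 and 1.0, no dropout).
#'
#' @param ct_sd Standard deviation of per-well Ct noise, in cycles.
#' @param efficiency_range Interval in `[0, 1]` for true per-gene
#'   amplification efficiency E (amplification factor `1 + E`).
#' @param dropout_rate Probability that a target well fails to amplify.
#' @param latent_sd Standard deviation, in log2 template units, of the shared
#'   per-sample loading signal tracked by the stable housekeeping genes.
#' @param unstable_sd Standard deviation, in log2 template units, of the
#'   independent fluctuation of non-stable housekeeping genes.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(ct_sd = 0.1, efficiency_range = c(0.8, 1.0),
                        dropout_rate = 0, latent_sd = 2.5, unstable_sd = 1.0) {
  if (ct_sd < 0) config_error("ct_sd must be >= 0")
  if (length(efficiency_range) != 2L || any(efficiency_range < 0) ||
      any(efficiency_range > 1) || efficiency_range[2] < efficiency_range[1]) {
    config_error("efficiency_range must be an interval within [0, 1]")
  }
  if (dropout_rate < 0 || dropout_rate > 1) {
    config_error("dropout_rate must be a probability")
  }
  if (latent_sd < 0 || unstable_sd < 0) {
    config_error("latent_sd and unstable_sd must be >= 0")
  }
  structure(list(ct_sd = ct_sd, efficiency_range = efficiency_range,
                 dropout_rate = dropout_rate, latent_sd = latent_sd,
                 unstable_sd = unstable_sd),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf(
    "qPCR noise model: ct_sd %.3g cycles, E in [%.2f, %.2f], dropout %.3g, latent sd %.3g, unstable sd %.3g\n",
    x$ct_sd, x$efficiency_range[1], x$efficiency_range[2], x$dropout_rate,
    x$latent_sd, x$unstable_sd))
  invisible(x)
}
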