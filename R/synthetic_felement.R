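# Synthetic f element: a protein set containing planted copies of a subset
# of the final candidate genes plus decoys that must fail the search
# thresholds.

#' Generate a synthetic f-element protein set
#'
#' Represents exactly `preset$n_in_felement` of the supplied candidate
#' genes, each by a number of copies drawn uniformly from
#' `preset$copy_number_range`. `preset$n_identical_in_felement` of the
#' represented genes get 100%-identical copies; the copies of the remaining
#' represented genes are mutated to identities in `[0.90, 1)` (interior
#' substitutions only, so local alignment reports the full-length
#' identity). Every unrepresented candidate contributes one decoy copy
#' mutated to `decoy_identity`, below the 90% search floor, and a few
#' unrelated random proteins are added.
#'
#' @param candidates Protein set of the final candidate genes (data frame
#'   `genome, gene_id, protein` or named character vector).
#' @param preset A [funnel_preset()].
#' @param decoy_identity Target identity of the planted decoy copies
#'   (must be below 0.90).
#' @param seed Integer seed.
#' @param n_random_decoys Unrelated random proteins appended to the set.
#' @return List of class `synthetic_felement`: `proteins` (data frame
#'   `genome, gene_id, protein` with anonymized f-element ids) and `truth`
#'   (data frame `gene, in_felement, copies, identical`), plus the per-copy
#'   map `copy_map` (`fel_id, source_gene, planted_identity`).
#' @export
generate_felement <- function(candidates, preset, decoy_identity = 0.70, seed,
                              n_random_decoys = 12L) {
  validate_funnel_preset(preset)
  cand <- as_protein_df(candidates, genome = FOCAL_GENOME)
  if (preset$n_in_felement > nrow(cand)) {
    config_error(sprintf("n_in_felement = %d exceeds the %d supplied candidates",
                         preset$n_in_felement, nrow(cand)))
  }
  if (decoy_identity >= 0.90) {
    config_error("decoy_identity must be below the 0.90 search floor")
  }
  withr::with_seed(seed, {
    represented <- sample(cand$gene_id, preset$n_in_felement)
    identical_set <- sample(represented, preset$n_identical_in_felement)
    cr <- preset$copy_number_range
    seqs <- character(0)
    map <- data.frame(fel_id = character(0), source_gene = character(0),
                      planted_identity = numeric(0))
    add <- function(seq, source, identity) {
      seqs <<- c(seqs, seq)
      map <<- rbind(map, data.frame(fel_id = NA_character_, source_gene = source,
                                    planted_identity = identity))
    }
    for (g in represented) {
      seq <- cand$protein[cand$gene_id == g]
      len <- nchar(seq)
      n_copies <- cr[1] + sample.int(cr[2] - cr[1] + 1L, 1L) - 1L
      for (ci in seq_len(n_copies)) {
        if (g %in% identical_set) {
          add(seq, g, 1)
        } else {
          # 1-2 interior substitutions: identity in [0.90, 1), above the
          # highest identity floor printed for a real f-element copy
          n_sub <- sample(1:2, 1L)
          add(mutate_interior(seq, n_sub, left_margin = 6L), g, (len - n_sub) / len)
        }
      }
    }
    for (g in setdiff(cand$gene_id, represented)) {
      seq <- cand$protein[cand$gene_id == g]
      n_sub <- round(nchar(seq) * (1 - decoy_identity))
      add(mutate_interior(seq, n_sub, left_margin = 6L), g,
          (nchar(seq) - n_sub) / nchar(seq))
    }
    if (n_random_decoys > 0L) {
      for (s in random_proteins(n_random_decoys, NORMAL_PROTEIN_LEN)) {
        add(s, NA_character_, NA_real_)
      }
    }
    ord <- sample.int(length(seqs)) # anonymize copy order
    seqs <- seqs[ord]
    map <- map[ord, , drop = FALSE]
    map$fel_id <- sprintf("fel_%04d", seq_along(seqs))
    truth <- data.frame(
      gene = cand$gene_id,
      in_felement = cand$gene_id %in% represented,
      copies = as.integer(table(factor(map$source_gene,
                                       levels = cand$gene_id))[cand$gene_id] *
                            (cand$gene_id %in% represented)),
      identical = cand$gene_id %in% identical_set
    )
    structure(
      list(proteins = data.frame(genome = "felement", gene_id = map$fel_id,
                                 protein = seqs),
           truth = truth, copy_map = map[, c("fel_id", "source_gene",
                                             "planted_identity")]),
      class = "synthetic_felement"
    )
  })
}

#' @export
print.synthetic_felement <- function(x, ...) {
  cat(sprintf("Synthetic f element: %d proteins; %d candidate genes represented (%d with identical copies)\n",
              nrow(x$proteins), sum(x$truth$in_felement), sum(x$truth$identical)))
  invisible(x)
}
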