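# Ordered in-silico filter cascade producing the first candidate set.
#
# Every filter returns a `filter_result` that partitions its input: the
# survivors plus the per-filter removal lists always reconstruct the input
# gene set exactly, which is what makes the published funnel counts auditable.

#' Filter result: survivors plus an ordered removal audit
#'
#' @param survivors Character vector of surviving gene ids.
#' @param removals Named list of character vectors, in filter application
#'   order, of the gene ids removed by each filter.
#' @param input Character vector of the input gene ids (used to check the
#'   partition invariant).
#' @return An object of class `filter_result` with fields `survivors`,
#'   `removals` and `counts`.
#' @export
filter_result <- function(survivors, removals, input) {
  all_removed <- unlist(removals, use.names = FALSE)
  parts <- c(survivors, all_removed)
  if (length(parts) != length(input) || !setequal(parts, input) ||
      anyDuplicated(parts) > 0L) {
    stop("filter bookkeeping violated: survivors and removals do not partition the input")
  }
  structure(
    list(survivors = survivors, removals = removals,
         counts = c(input = length(input),
                    vapply(removals, length, integer(1)),
                    survivors = length(survivors))),
    class = "filter_result"
  )
}

#' @export
print.filter_result <- function(x, ...) {
  cat("Filter cascade result\n")
  cat(sprintf("  input: %d genes\n", x$counts[["input"]]))
  for (nm in names(x$removals)) {
    cat(sprintf("  - %-28s removed %d\n", nm, length(x$removals[[nm]])))
  }
  cat(sprintf("  survivors: %d\n", length(x$survivors)))
  invisible(x)
}

# merge two filter_results applied in sequence
chain_filters <- function(first, second) {
  filter_result(second$survivors, c(first$removals, second$removals),
                c(first$survivors, unlist(first$removals, use.names = FALSE)))
}

#' Annotation-based filters: repeats, pseudogenes, short genes, split chunks
#'
#' Removes, in fixed precedence order, genes flagged as repeats (transposable
#' elements, prophage genes and other repeated genes), pseudogenes, genes
#' shorter than `min_length_bp` (equivalently, proteins under 50 residues at
#' the default 150 bp cut), and small CDS of genes split in two CDS. A gene
#' matching several flags is counted only under the first matching filter, so
#' the per-category counts are disjoint and sum exactly.
#'
#' @param genes Data frame with columns `gene_id`, `length_bp`, `is_repeat`,
#'   `is_pseudogene`, `is_split_chunk` (annotation schema).
#' @param min_length_bp Nucleotide length cutoff.
#' @return A [filter_result()] with removals `repeats`, `pseudogenes`,
#'   `short`, `split_chunks`.
#' @export
filter_annotation <- function(genes, min_length_bp = 150L) {
  needed <- c("gene_id", "length_bp", "is_repeat", "is_pseudogene", "is_split_chunk")
  if (!all(needed %in% names(genes))) {
    stop("annotation must have columns ", paste(needed, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id) > 0L) {
    stop("duplicate gene ids in annotation: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  remaining <- genes
  take <- function(mask) {
    hit <- remaining[mask, "gene_id"]
    remaining <<- remaining[!mask, , drop = FALSE]
    hit
  }
  removals <- list(
    repeats = take(as.logical(remaining$is_repeat)),
    pseudogenes = take(as.logical(remaining$is_pseudogene)),
    short = take(remaining$length_bp < min_length_bp),
    split_chunks = take(as.logical(remaining$is_split_chunk))
  )
  filter_result(remaining$gene_id, removals, genes$gene_id)
}

#' Core-genome filter
#'
#' Removes focal-genome genes that are members of any core ortholog group
#' (groups spanning the whole reference-genome panel, see [core_genome()]).
#'
#' @param survivors Character vector of focal gene ids still in play.
#' @param core Core ortholog groups (data frame with `genome`, `gene_id`).
#' @param focal_genome Identifier of the focal genome inside `core`.
#' @return A [filter_result()] with removal `core_genome`.
#' @export
filter_core <- function(survivors, core, focal_genome) {
  core_focal <- core$gene_id[core$genome == focal_genome]
  removed <- intersect(survivors, core_focal)
  filter_result(setdiff(survivors, removed), list(core_genome = removed), survivors)
}

#' Conservation filter against the non-feminizing strain
#'
#' Removes genes with at least one local alignment at 100% amino-acid
#' identity covering at least `min_coverage` of the query length in the
#' closely related non-feminizing genome: such genes are unlikely to explain
#' a phenotype the other strain does not induce. A hit at 99.9% identity, or
#' at 100% identity but 89% coverage, leaves the gene in play.
#'
#' @param survivors Character vector of focal gene ids still in play.
#' @param hits Local hit table of focal genes vs the non-feminizer proteome
#'   (see [align_sets()]).
#' @param min_coverage Query-coverage floor for the identity-1 hits.
#' @return A [filter_result()] with removal `identical_to_nonfeminizer`.
#' @export
filter_conserved_vs_nonfeminizer <- function(survivors, hits, min_coverage = 0.90) {
  conserved <- hits$query[hits$identity >= 1 - 1e-9 &
                            hits$query_coverage >= min_coverage]
  removed <- intersect(survivors, unique(conserved))
  filter_result(setdiff(survivors, removed),
                list(identical_to_nonfeminizer = removed), survivors)
}

#' Full in-silico filter cascade
#'
#' Applies, in published order, the annotation filters, the core-genome
#' filter and the non-feminizer conservation filter, and returns a single
#' combined audit trail.
#'
#' @inheritParams filter_annotation
#' @param core Core ortholog groups (see [core_genome()]).
#' @param nonfem_hits Local hit table of focal genes vs the non-feminizer
#'   proteome.
#' @param focal_genome Focal genome identifier.
#' @param min_length_bp Nucleotide length cutoff for the short-gene filter.
#' @return A [filter_result()] with all six removal categories.
#' @export
filter_cascade <- function(genes, core, nonfem_hits, focal_genome,
                           min_length_bp = 150L) {
  r1 <- filter_annotation(genes, min_length_bp)
  r2 <- chain_filters(r1, filter_core(r1$survivors, core, focal_genome))
  chain_filters(r2, filter_conserved_vs_nonfeminizer(r2$survivors, nonfem_hits))
}
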