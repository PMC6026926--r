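# Locate candidate genes in the f element (the Wolbachia genome fragment
# horizontally transferred into the host nuclear genome), count copies,
# summarize identities and test enrichment.

#' Search candidate proteins against the f element
#'
#' Aligns every candidate locally against every f-element protein (exact
#' Smith-Waterman, see [align_sets()]). An f-element protein counts as a
#' copy of a candidate when the alignment passes both the e-value ceiling
#' and the identity floor; candidates with no passing copy are omitted from
#' the result.
#'
#' @param candidates,felement Protein sets (data frames `genome, gene_id,
#'   protein` or named character vectors).
#' @param max_evalue E-value ceiling (default 0.001).
#' @param min_identity Identity floor as a fraction (default 0.90).
#' @return Data frame `gene, copies, max_identity, identities` with
#'   identities in percent (`identities` comma-separated per copy), one row
#'   per candidate with at least one passing copy.
#' @export
search_felement <- function(candidates, felement, max_evalue = 0.001,
                            min_identity = 0.90) {
  fel <- as_protein_df(felement, genome = "felement")
  if (nrow(fel) == 0L) stop("the f-element protein set is empty")
  hits <- align_sets(candidates, fel, mode = "local")
  pass <- hits[hits$evalue <= max_evalue & hits$identity >= min_identity, ]
  if (nrow(pass) == 0L) {
    return(data.frame(gene = character(0), copies = integer(0),
                      max_identity = numeric(0), identities = character(0)))
  }
  rows <- lapply(split(pass, pass$query), function(d) {
    ident <- sort(100 * d$identity, decreasing = TRUE)
    data.frame(gene = d$query[1], copies = nrow(d),
               max_identity = ident[1],
               identities = paste(sprintf("%.2f", ident), collapse = ","))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene), ]
  rownames(out) <- NULL
  out
}

#' Exact two-sided Fisher test on a 2x2 table
#'
#' Sums, over the hypergeometric support at fixed margins, the
#' probabilities of all tables at most as probable as the observed one
#' (with the customary `1 + 1e-7` relative tolerance on the comparison).
#' Used to test whether differentially expressed candidates are enriched in
#' the f element.
#'
#' @param a Candidates in the f element.
#' @param b Candidates not in the f element.
#' @param c Background genes in the f element.
#' @param d Background genes not in the f element.
#' @return Two-sided p-value in `[0, 1]`.
#' @examples
#' fisher_exact(5, 5, 5, 5) # 1: no association
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("contingency cells must be nonnegative")
  if (any(cells != round(cells))) stop("contingency cells must be integers")
  m <- a + b # candidates
  n <- c + d # background
  k <- a + c # genes in the f element
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Candidate/background enrichment in the f element
#'
#' Builds the 2x2 table (candidates vs background, in vs not in the
#' f element) and runs [fisher_exact()]. The background set must be
#' supplied explicitly.
#'
#' @param candidate_genes Final candidate gene ids.
#' @param background_genes Background gene ids (disjoint from the
#'   candidates).
#' @param in_felement Gene ids with at least one passing f-element copy.
#' @return List with the `table` (named counts) and the two-sided
#'   `p_value`.
#' @export
felement_enrichment <- function(candidate_genes, background_genes, in_felement) {
  a <- sum(candidate_genes %in% in_felement)
  b <- length(candidate_genes) - a
  cc <- sum(background_genes %in% in_felement)
  d <- length(background_genes) - cc
  list(table = c(a = a, b = b, c = cc, d = d),
       p_value = fisher_exact(a, b, cc, d))
}
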