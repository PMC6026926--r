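# Pairwise protein alignment, hit tables, ortholog clustering, core genome.
#
# Alignments are exact dynamic programming (Needleman-Wunsch / Smith-Waterman
# via Biostrings::pairwiseAlignment) with BLOSUM62, gap open 11, gap extend 1.
# E-values use the Karlin-Altschul form with fixed gapped-BLOSUM62 constants
# (lambda = 0.267, K = 0.041); they only gate thresholds here.

KA_LAMBDA <- 0.267
KA_K <- 0.041
AA_REGEX <- "^[ACDEFGHIKLMNPQRSTVWYX]+$"

check_protein <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop(sprintf("%s must be a nonempty residue string", what))
  }
  if (!grepl(AA_REGEX, seq)) {
    stop(sprintf("%s contains characters outside the 20 amino acids + X", what))
  }
  invisible(seq)
}

bits_from_score <- function(score) (KA_LAMBDA * score - log(KA_K)) / log(2)

#' Karlin-Altschul expectation for a bit score
#'
#' `E = m * n * 2^(-bit_score)` for a query of length `m` searched against a
#' database of `n` residues.
#'
#' @param bit_score Normalized alignment score in bits.
#' @param m Query length in residues.
#' @param n Database length in residues.
#' @return The expectation value.
#' @examples
#' evalue(20, m = 100, n = 1000) # ~0.0954
#' @export
evalue <- function(bit_score, m, n) {
  if (any(m <= 0) || any(n <= 0)) stop("m and n must be > 0")
  m * n * 2^(-bit_score)
}

#' Exact pairwise protein alignment
#'
#' Global (Needleman-Wunsch) or local (Smith-Waterman) alignment with
#' BLOSUM62, gap open 11, gap extend 1 (a gap of length L costs
#' `11 + L`). Identity is `matches / alignment columns`; query coverage is
#' the fraction of query residues inside the aligned region. The bit score is
#' `(lambda * S - ln K) / ln 2` with lambda = 0.267, K = 0.041, and the
#' reported e-value treats the subject as a single-sequence database.
#'
#' @param a,b Residue strings (query and subject).
#' @param mode `"global"` or `"local"`.
#' @param query,subject Identifiers carried into the result.
#' @return A one-row data.frame with columns `query`, `subject`, `identity`
#'   (fraction), `query_coverage`, `alignment_length`, `matches`, `score`,
#'   `bit_score`, `evalue`.
#' @examples
#' align("MKVLATNSGF", "MKVLATNSGF", mode = "global")$identity # 1
#' @export
align <- function(a, b, mode = c("local", "global"),
                  query = "query", subject = "subject") {
  mode <- match.arg(mode)
  check_protein(a, "query sequence")
  check_protein(b, "subject sequence")
  align_many(stats::setNames(a, query), b, subject = subject, mode = mode)
}

# Align a named vector of queries against one subject sequence in a single
# vectorized DP call. Returns one row per query.
align_many <- function(queries, subject_seq, subject, mode = c("local", "global")) {
  mode <- match.arg(mode)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(queries), Biostrings::AAString(subject_seq),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = mode
  )
  qlen <- nchar(queries)
  slen <- nchar(subject_seq)
  matches <- Biostrings::nmatch(pa)
  cols <- Biostrings::nchar(pa)
  if (mode == "global") {
    covered_q <- qlen
    covered_s <- rep(slen, length(queries))
  } else {
    pat <- Biostrings::pattern(pa)
    sub <- Biostrings::subject(pa)
    covered_q <- Biostrings::end(pat) - Biostrings::start(pat) + 1L
    covered_s <- Biostrings::end(sub) - Biostrings::start(sub) + 1L
  }
  bits <- bits_from_score(Biostrings::score(pa))
  data.frame(
    query = names(queries),
    subject = subject,
    identity = matches / cols,
    query_coverage = covered_q / qlen,
    subject_coverage = covered_s / slen,
    alignment_length = cols,
    matches = matches,
    score = Biostrings::score(pa),
    bit_score = bits,
    evalue = evalue(bits, m = qlen, n = slen),
    row.names = NULL
  )
}

as_protein_df <- function(x, genome = NA_character_) {
  if (is.data.frame(x)) {
    stopifnot(all(c("gene_id", "protein") %in% names(x)))
    if (!"genome" %in% names(x)) x$genome <- rep(genome, nrow(x))
    return(x[, c("genome", "gene_id", "protein")])
  }
  if (length(x) && is.null(names(x))) stop("protein vectors must be named by gene id")
  data.frame(genome = rep(genome, length(x)), gene_id = names(x) %||% character(0),
             protein = unname(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Align every query against every subject
#'
#' Exact local (or global) DP alignment of all query/subject pairs; no
#' prescreening. E-values use the total subject-set residue count as the
#' database length. Intended for query-vs-database searches such as the
#' non-feminizer conservation filter and the f-element search.
#'
#' @param query,subject Data frames with columns `genome`, `gene_id`,
#'   `protein`, or named character vectors of residue strings.
#' @param mode Alignment mode, `"local"` (default) or `"global"`.
#' @return A hit table: one row per pair with the columns of [align()] plus
#'   `query_genome` and `subject_genome`.
#' @export
align_sets <- function(query, subject, mode = c("local", "global")) {
  mode <- match.arg(mode)
  qdf <- as_protein_df(query)
  sdf <- as_protein_df(subject)
  if (nrow(qdf) == 0L || nrow(sdf) == 0L) stop("query and subject sets must be nonempty")
  db_len <- sum(nchar(sdf$protein))
  queries <- stats::setNames(qdf$protein, qdf$gene_id)
  rows <- lapply(seq_len(nrow(sdf)), function(j) {
    h <- align_many(queries, sdf$protein[j], subject = sdf$gene_id[j], mode = mode)
    h$subject_genome <- sdf$genome[j]
    h
  })
  hits <- do.call(rbind, rows)
  hits$query_genome <- qdf$genome[match(hits$query, qdf$gene_id)]
  hits$evalue <- evalue(hits$bit_score, m = nchar(qdf$protein[match(hits$query, qdf$gene_id)]),
                        n = db_len)
  rownames(hits) <- NULL
  hits[, c("query", "subject", "query_genome", "subject_genome", "identity",
           "query_coverage", "subject_coverage", "alignment_length", "matches",
           "score", "bit_score", "evalue")]
}

# Candidate unordered pairs sharing at least one exact k-mer.
kmer_pairs <- function(seqs, word_size) {
  n <- length(seqs)
  ids <- seq_len(n)
  kmers <- lapply(seqs, function(s) {
    len <- nchar(s)
    if (len < word_size) return(character(0))
    unique(substring(s, 1:(len - word_size + 1L), word_size:len))
  })
  idx <- rep.int(ids, lengths(kmers))
  buckets <- split(idx, unlist(kmers, use.names = FALSE))
  buckets <- buckets[lengths(buckets) > 1L]
  if (length(buckets) == 0L) return(matrix(integer(0), ncol = 2))
  pairs <- do.call(rbind, lapply(buckets, function(b) {
    b <- sort(unique(b))
    if (length(b) < 2L) return(NULL)
    t(utils::combn(b, 2L))
  }))
  unique(pairs)
}

#' All-vs-all homology hit table
#'
#' Builds the hit table consumed by [cluster_orthologs()]. Sequence pairs are
#' preselected by exact shared words of `word_size` residues (a pair is
#' aligned only if the two sequences share at least one identical k-mer, the
#' word-hit idea behind BLAST seeding); each selected pair is then aligned by
#' exact DP and reported in both orientations. Pairs of unrelated random
#' sequences essentially never share a word, while homologs above the
#' clustering thresholds share conserved stretches, so at the identity levels
#' the screen operates on the preselection loses no hits.
#'
#' @param proteins Data frame with columns `genome`, `gene_id`, `protein`.
#' @param word_size Word length for pair preselection.
#' @param mode Alignment mode passed to the DP engine.
#' @return A hit table with both ordered orientations of every aligned pair;
#'   e-values use the total residue count of `proteins` as the database
#'   length.
#' @export
homology_hits <- function(proteins, word_size = 10L, mode = c("local", "global")) {
  mode <- match.arg(mode)
  proteins <- as_protein_df(proteins)
  if (anyDuplicated(proteins$gene_id)) stop("gene ids must be unique across genomes")
  pairs <- kmer_pairs(proteins$protein, word_size)
  empty <- data.frame(query = character(0), subject = character(0),
                      query_genome = character(0), subject_genome = character(0),
                      identity = numeric(0), query_coverage = numeric(0),
                      subject_coverage = numeric(0), alignment_length = integer(0),
                      matches = integer(0), score = numeric(0),
                      bit_score = numeric(0), evalue = numeric(0))
  if (nrow(pairs) == 0L) return(empty)
  db_len <- sum(nchar(proteins$protein))
  # group by subject so each DP call is vectorized over its queries
  by_subject <- split(pairs[, 1L], pairs[, 2L])
  rows <- lapply(names(by_subject), function(j) {
    j <- as.integer(j)
    qi <- by_subject[[as.character(j)]]
    h <- align_many(stats::setNames(proteins$protein[qi], proteins$gene_id[qi]),
                    proteins$protein[j], subject = proteins$gene_id[j], mode = mode)
    h$query_genome <- proteins$genome[qi]
    h$subject_genome <- proteins$genome[j]
    h$qlen <- nchar(proteins$protein[qi])
    h$slen <- nchar(proteins$protein[j])
    h
  })
  hits <- do.call(rbind, rows)
  # report both orientations; identity and score are shared, coverage and
  # evalue follow the respective query
  fwd <- hits
  fwd$evalue <- evalue(fwd$bit_score, m = fwd$qlen, n = db_len)
  rev <- hits
  rev[, c("query", "subject")] <- hits[, c("subject", "query")]
  rev[, c("query_genome", "subject_genome")] <- hits[, c("subject_genome", "query_genome")]
  rev[, c("query_coverage", "subject_coverage")] <-
    hits[, c("subject_coverage", "query_coverage")]
  rev$evalue <- evalue(rev$bit_score, m = hits$slen, n = db_len)
  out <- rbind(fwd, rev)
  rownames(out) <- NULL
  out[, c("query", "subject", "query_genome", "subject_genome", "identity",
          "query_coverage", "subject_coverage", "alignment_length", "matches",
          "score", "bit_score", "evalue")]
}

#' Cluster genes into ortholog groups
#'
#' Builds an undirected graph with an edge between two genes when a
#' reciprocal hit pair passes both thresholds (identity and e-value in both
#' orientations); ortholog groups are the connected components of size at
#' least two. Group ids are assigned in lexicographic order of each group's
#' smallest member, so the output is invariant under input row order.
#'
#' @param hits Hit table as produced by [homology_hits()] (deduplicated per
#'   ordered pair).
#' @param min_identity Identity floor (fraction of aligned columns).
#' @param max_evalue E-value ceiling.
#' @return A data.frame with columns `group_id`, `genome`, `gene_id`.
#' @export
cluster_orthologs <- function(hits, min_identity = 0.70, max_evalue = 1e-6) {
  if (min_identity < 0 || min_identity > 1) {
    config_error("min_identity must be in [0, 1]")
  }
  if (max_evalue < 0) config_error("max_evalue must be >= 0")
  pass <- hits[hits$identity >= min_identity & hits$evalue <= max_evalue, , drop = FALSE]
  empty <- data.frame(group_id = character(0), genome = character(0),
                      gene_id = character(0))
  if (nrow(pass) == 0L) return(empty)
  key <- function(q, s) paste(q, s, sep = "\r")
  reciprocal <- key(pass$subject, pass$query) %in% key(pass$query, pass$subject)
  edges <- pass[reciprocal & pass$query < pass$subject, c("query", "subject"), drop = FALSE]
  if (nrow(edges) == 0L) return(empty)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- members[vapply(members, length, integer(1)) >= 2L]
  members <- lapply(members, sort)
  members <- members[order(vapply(members, `[`, character(1), 1L))]
  genome_of <- c(stats::setNames(hits$query_genome, hits$query),
                 stats::setNames(hits$subject_genome, hits$subject))
  out <- do.call(rbind, lapply(seq_along(members), function(i) {
    data.frame(group_id = sprintf("OG%04d", i), genome = unname(genome_of[members[[i]]]),
               gene_id = members[[i]])
  }))
  rownames(out) <- NULL
  out
}

#' Core-genome ortholog groups
#'
#' Retains the ortholog groups containing at least one member from every
#' genome of the given panel.
#'
#' @param groups Output of [cluster_orthologs()].
#' @param genomes Character vector of genome identifiers defining the panel.
#' @return The subset of `groups` whose group ids span all `genomes`.
#' @export
core_genome <- function(groups, genomes) {
  if (length(genomes) == 0L) stop("the genome panel must be nonempty")
  covered <- tapply(groups$genome, groups$group_id,
                    function(g) all(genomes %in% g))
  keep <- names(covered)[covered]
  groups[groups$group_id %in% keep, , drop = FALSE]
}

#' Write a hit table as TSV
#'
#' Columns `query subject identity query_coverage bit_score evalue`, with
#' identity as a percentage with two decimals.
#'
#' @param hits Hit table.
#' @param path Output path.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- data.frame(
    query = hits$query, subject = hits$subject,
    identity = sprintf("%.2f", 100 * hits$identity),
    query_coverage = sprintf("%.4f", hits$query_coverage),
    bit_score = sprintf("%.2f", hits$bit_score),
    evalue = format(hits$evalue, digits = 4)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
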