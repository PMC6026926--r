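# Synthetic genome annotation with planted filter-cascade structure.
#
# The generator emits the focal-genome annotation plus the five
# reference-genome proteomes (carrying the planted core ortholog families)
# and the non-feminizing strain proteome (carrying the planted
# 100%-identical homologs), together with a truth table naming every
# planted role.

REFERENCE_GENOMES <- c("wMel", "wRi", "wHa", "wNo", "wPip")
FOCAL_GENOME <- "wVulC"
NONFEM_GENOME <- "wCon"

# Ortholog family members are derived from a common parent with interior
# substitutions only: the first ANCHOR_LEN residues are conserved (the
# family's shared motif, which also guarantees the word-based pair
# preselection sees every true pair) and terminal residues are left intact
# so local alignment reports the full-length identity.
ANCHOR_LEN <- 12L
CORE_MEMBER_IDENTITY <- 0.92
NONFEM_PARTIAL_IDENTITY <- 0.95
NORMAL_PROTEIN_LEN <- 60L

#' Generate a synthetic annotated genome with a planted filter funnel
#'
#' Builds an annotation of `preset$n_genes` coding sequences in which every
#' removal category of the in-silico filter cascade is planted disjointly
#' with the preset's counts: flagged repeats, pseudogenes, genes under
#' 150 bp, split-CDS chunks, members of core ortholog families shared with
#' all five reference genomes (at roughly 85% pairwise member identity,
#' comfortably above the 70% clustering floor), and genes with a
#' 100%-identical full-length homolog in the non-feminizing strain. All
#' remaining genes are unrelated random proteins. The reference and
#' non-feminizer proteomes needed by the downstream homology steps are
#' emitted alongside, as is a truth table naming each gene's planted role.
#'
#' @param preset A [funnel_preset()].
#' @param seed Integer seed; output is deterministic for a fixed seed.
#' @param n_ref_decoys Unrelated proteins added to each reference proteome.
#' @param n_nonfem_decoys Unrelated proteins added to the non-feminizer
#'   proteome.
#' @param n_nonfem_partial Candidate genes given a near-identical (but not
#'   100%) non-feminizer homolog, exercising the strictness of the
#'   conservation filter.
#' @return A list of class `synthetic_annotation` with elements
#'   `annotation` (data frame: `gene_id`, `product`, `length_bp`,
#'   `is_repeat`, `is_pseudogene`, `is_split_chunk`, `protein`),
#'   `references` (data frame of reference-genome proteins), `nonfeminizer`
#'   (data frame of non-feminizer proteins), and `truth` (data frame:
#'   `gene_id`, `role`).
#' @export
generate_annotation <- function(preset, seed, n_ref_decoys = 20L,
                                n_nonfem_decoys = 50L, n_nonfem_partial = 40L) {
  validate_funnel_preset(preset)
  withr::with_seed(seed, generate_annotation_impl(preset, n_ref_decoys,
                                                  n_nonfem_decoys,
                                                  n_nonfem_partial))
}

generate_annotation_impl <- function(preset, n_ref_decoys, n_nonfem_decoys,
                                     n_nonfem_partial) {
  n <- preset$n_genes
  ids <- sprintf("%s_%04d", FOCAL_GENOME, seq_len(n))
  role <- rep("candidate", n)
  pool <- sample.int(n) # random placement of planted roles along the genome
  take <- function(k) {
    if (k == 0L) return(integer(0))
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  idx <- list(
    repeats = take(preset$n_repeats),
    pseudogene = take(preset$n_pseudogenes),
    short = take(preset$n_short),
    split_chunk = take(preset$n_split_chunks),
    core = take(preset$n_core),
    identical_nonfem = take(preset$n_identical_to_nonfeminizer)
  )
  role[idx$repeats] <- "repeat"
  role[idx$pseudogene] <- "pseudogene"
  role[idx$short] <- "short"
  role[idx$split_chunk] <- "split_chunk"
  role[idx$core] <- "core"
  role[idx$identical_nonfem] <- "identical_nonfem"

  plen <- rep(NORMAL_PROTEIN_LEN, n)
  plen[idx$short] <- sample(20:49, preset$n_short, replace = TRUE)
  protein <- random_proteins(n, plen)

  # core families: overwrite each planted core gene with a family member
  n_sub <- round(NORMAL_PROTEIN_LEN * (1 - CORE_MEMBER_IDENTITY))
  parents <- random_proteins(preset$n_core, NORMAL_PROTEIN_LEN)
  ref_rows <- vector("list", preset$n_core)
  for (f in seq_len(preset$n_core)) {
    protein[idx$core[f]] <- mutate_interior(parents[f], n_sub, ANCHOR_LEN)
    members <- vapply(REFERENCE_GENOMES, function(g) {
      mutate_interior(parents[f], n_sub, ANCHOR_LEN)
    }, character(1))
    ref_rows[[f]] <- data.frame(
      genome = REFERENCE_GENOMES,
      gene_id = sprintf("%s_%04d", REFERENCE_GENOMES, f),
      protein = unname(members)
    )
  }
  references <- do.call(rbind, ref_rows)
  if (n_ref_decoys > 0L) {
    decoys <- do.call(rbind, lapply(REFERENCE_GENOMES, function(g) {
      data.frame(genome = g,
                 gene_id = sprintf("%s_d%03d", g, seq_len(n_ref_decoys)),
                 protein = random_proteins(n_ref_decoys, NORMAL_PROTEIN_LEN))
    }))
    references <- rbind(references, decoys)
  }
  rownames(references) <- NULL

  # non-feminizer proteome: exact full-length copies of the planted
  # identical genes, near-identical homologs for some candidates, decoys
  nonfem <- data.frame(genome = character(0), gene_id = character(0),
                       protein = character(0))
  k <- 0L
  add_nonfem <- function(seqs) {
    k <<- k + length(seqs)
    data.frame(genome = NONFEM_GENOME,
               gene_id = sprintf("%s_%04d", NONFEM_GENOME, seq.int(k - length(seqs) + 1L, k)),
               protein = seqs)
  }
  if (preset$n_identical_to_nonfeminizer > 0L) {
    nonfem <- rbind(nonfem, add_nonfem(protein[idx$identical_nonfem]))
  }
  candidates <- which(role == "candidate")
  n_partial <- min(n_nonfem_partial, length(candidates))
  if (n_partial > 0L) {
    partial_idx <- sample(candidates, n_partial)
    n_sub_p <- round(NORMAL_PROTEIN_LEN * (1 - NONFEM_PARTIAL_IDENTITY))
    partial <- vapply(protein[partial_idx], function(s) {
      mutate_interior(s, n_sub_p, ANCHOR_LEN)
    }, character(1), USE.NAMES = FALSE)
    nonfem <- rbind(nonfem, add_nonfem(partial))
  }
  if (n_nonfem_decoys > 0L) {
    nonfem <- rbind(nonfem, add_nonfem(random_proteins(n_nonfem_decoys,
                                                       NORMAL_PROTEIN_LEN)))
  }
  rownames(nonfem) <- NULL

  product <- ifelse(role == "repeat", "transposase (repeat region)",
             ifelse(role == "pseudogene", "pseudogene",
             ifelse(role == "split_chunk", "split CDS chunk",
             ifelse(role == "core", "conserved core protein",
                    "hypothetical protein"))))
  annotation <- data.frame(
    gene_id = ids,
    product = product,
    length_bp = 3L * plen,
    is_repeat = role == "repeat",
    is_pseudogene = role == "pseudogene",
    is_split_chunk = role == "split_chunk",
    protein = protein
  )
  structure(
    list(annotation = annotation,
         references = references,
         nonfeminizer = nonfem,
         truth = data.frame(gene_id = ids, role = role)),
    class = "synthetic_annotation"
  )
}

#' @export
print.synthetic_annotation <- function(x, ...) {
  cat(sprintf("Synthetic annotation: %d genes (%s)\n", nrow(x$annotation),
              paste(sprintf("%s=%d", names(table(x$truth$role)),
                            as.integer(table(x$truth$role))), collapse = ", ")))
  cat(sprintf("  reference proteins: %d across %d genomes; non-feminizer proteins: %d\n",
              nrow(x$references), length(unique(x$references$genome)),
              nrow(x$nonfeminizer)))
  invisible(x)
}

#' Read and write the annotation TSV schema
#'
#' Header `gene_id product length_bp is_repeat is_pseudogene is_split_chunk
#' protein`.
#'
#' @param annotation Annotation data frame.
#' @param path File path.
#' @export
write_annotation_tsv <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
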