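# Protein sequence helpers shared by the synthetic-data generators.

AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# uniform random proteins over the 20 standard residues
random_proteins <- function(n, length) {
  if (length(length) == 1L) length <- rep(length, n)
  vapply(seq_len(n), function(i) {
    paste(sample(AA_ALPHABET20, length[i], replace = TRUE), collapse = "")
  }, character(1))
}

# substitute residues at the given positions, always to a different residue
substitute_at <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1]]
  for (p in positions) {
    chars[p] <- sample(setdiff(AA_ALPHABET20, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Mutate a protein to a target ungapped identity
#'
#' Applies exactly `round(length * (1 - target_identity))` substitutions at
#' uniformly sampled positions (no indels); every substitution changes the
#' residue, so the realized ungapped identity is exactly
#' `matches / length`. Used to construct homolog pairs at controlled percent
#' identity, e.g. a 43-residue protein at target 41/43 gives the 95.35%
#' identity floor observed among f-element copies.
#'
#' @param protein Residue string over the 20 standard amino acids.
#' @param target_identity Fraction in `(0, 1]`.
#' @param seed Integer seed; the result is deterministic for a fixed seed.
#' @return The mutated residue string.
#' @examples
#' mutate_to_identity("MKVLINGKTLKGEITVDGAKNAALPILFAALLAEEPVEIQNVPKLKDIDTS",
#'                    0.9, seed = 1)
#' @export
mutate_to_identity <- function(protein, target_identity, seed) {
  if (!nzchar(protein)) config_error("protein sequence must be nonempty")
  if (target_identity <= 0 || target_identity > 1) {
    config_error("target_identity must be in (0, 1]")
  }
  len <- nchar(protein)
  if (target_identity < 1 && target_identity * len < 0.5) {
    config_error(sprintf(
      "target_identity %.4g is below the 1/length resolution of a %d-residue sequence",
      target_identity, len))
  }
  n_sub <- round(len * (1 - target_identity))
  if (n_sub == 0L) return(protein)
  withr::with_seed(seed, {
    positions <- sample.int(len, n_sub)
    substitute_at(protein, positions)
  })
}

# Mutate away from both ends so that local alignment keeps the full length
# (a terminal mismatch is trimmed by Smith-Waterman; an interior one is not).
# Assumes an RNG is already established by the caller.
mutate_interior <- function(seq, n_sub, left_margin = 12L, right_margin = 6L) {
  len <- nchar(seq)
  lo <- left_margin + 1L
  hi <- len - right_margin
  if (n_sub == 0L) return(seq)
  if (hi - lo + 1L < n_sub) {
    config_error("sequence too short for the requested interior substitutions")
  }
  substitute_at(seq, sample(seq.int(lo, hi), n_sub))
}

#' Read and write protein FASTA
#'
#' Thin wrappers around [Biostrings::readAAStringSet()] and
#' [Biostrings::writeXStringSet()] (wrapped at 60 columns) returning and
#' accepting named character vectors.
#'
#' @param x Named character vector of residue strings.
#' @param path File path.
#' @return `read_protein_fasta` returns a named character vector.
#' @export
write_protein_fasta <- function(x, path) {
  set <- Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' @rdname write_protein_fasta
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}
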