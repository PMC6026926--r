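# Independent oracles used by the unit tests. These deliberately do not
# share code with the package implementation.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Gotoh affine-gap DP written directly from the recurrences: a gap of
# length L costs open + L * ext. Returns the optimal score.
oracle_align_score <- function(a, b, mode = c("global", "local"),
                               open = 11, ext = 1) {
  mode <- match.arg(mode)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1) # gap in b (a aligned to gap)
  Y <- matrix(NEG, n + 1, m + 1) # gap in a
  if (mode == "global") {
    M[1, 1] <- 0
    for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
    for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  } else {
    M[, 1] <- 0
    M[1, ] <- 0
  }
  best_local <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- blosum62[av[i], bv[j]]
      diag_best <- max(M[i, j], X[i, j], Y[i, j])
      if (mode == "local") diag_best <- max(diag_best, 0)
      M[i + 1, j + 1] <- diag_best + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
      if (mode == "local") best_local <- max(best_local, M[i + 1, j + 1])
    }
  }
  if (mode == "global") max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  else best_local
}

# connected components by breadth-first search over an edge list
oracle_components <- function(nodes, edges) {
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  for (v in nodes) {
    if (!is.na(comp[v])) next
    cid <- cid + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[u])) next
      comp[u] <- cid
      queue <- c(queue, setdiff(adj[[u]], names(comp)[!is.na(comp)]))
    }
  }
  comp
}

# two-sided Fisher p by direct enumeration with choose()
oracle_fisher <- function(a, b, c, d) {
  N <- a + b + c + d
  row1 <- a + b
  col1 <- a + c
  prob <- function(x) {
    choose(row1, x) * choose(N - row1, col1 - x) / choose(N, col1)
  }
  support <- max(0, col1 - (N - row1)):min(col1, row1)
  p_obs <- prob(a)
  sum(vapply(support, prob, numeric(1))[
    vapply(support, prob, numeric(1)) <= p_obs * (1 + 1e-7)])
}

random_protein <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), len, replace = TRUE),
        collapse = "")
}

# a small but complete funnel preset for fast end-to-end tests
small_preset <- function(...) {
  args <- utils::modifyList(list(
    n_genes = 60L, n_repeats = 5L, n_pseudogenes = 3L, n_short = 4L,
    n_split_chunks = 2L, n_core = 6L, n_identical_to_nonfeminizer = 2L,
    n_amplifiable = 30L, n_expressed = 20L, n_under_s1 = 4L, n_over_s1 = 6L,
    n_fail_s2 = 2L, n_regulated_both_hosts = 6L, n_ccf_lag1 = 2L,
    n_ccf_lag0 = 1L, n_in_felement = 6L, n_identical_in_felement = 4L,
    copy_number_range = c(1L, 3L)
  ), list(...))
  do.call(funnel_preset, args)
}
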