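# Cross-host comparison of developmental expression profiles:
# autocorrelation pre-check, lagged cross-correlation, eta-squared.
#
# Conventions (stated because they differ between software): both the ACF
# and the CCF center on the full-series mean and normalize by the lag-0
# standard deviations with n in the denominator, so values shrink toward
# zero at large lags. Significance bounds use 1.96/sqrt(n) at every lag.

#' Sample autocorrelation of a short stage series
#'
#' Sample ACF with overall-mean centering and lag-0 variance normalization;
#' a lag `l >= 1` is flagged significant when `|acf(l)| > 1.96 / sqrt(n)`.
#' Used as a pre-check before the cross-correlation test: series with
#' substantial autocorrelation inflate the CCF null.
#'
#' @param values Ordered per-stage values (length `n >= max_lag + 3`).
#' @param max_lag Largest lag to report.
#' @return Data frame with columns `lag`, `acf`, `significant`.
#' @export
autocorrelation <- function(values, max_lag = 2L) {
  n <- length(values)
  if (n < max_lag + 3L) stop("series too short for the requested max_lag")
  v <- mean((values - mean(values))^2)
  if (v == 0) stop("constant series: autocorrelation is undefined")
  m <- mean(values)
  acf_l <- vapply(0:max_lag, function(l) {
    sum((values[seq_len(n - l)] - m) * (values[seq_len(n - l) + l] - m)) / (n * v)
  }, numeric(1))
  data.frame(lag = 0:max_lag, acf = acf_l,
             significant = c(FALSE, abs(acf_l[-1]) > 1.96 / sqrt(n)))
}

#' Lagged cross-correlation of two stage series
#'
#' `ccf(l) = sum_t (a_t - mean(a)) (b_{t+l} - mean(b)) / (n s_a s_b)` over
#' the overlapping stages, for lags in `[-max_lag, max_lag]`; `s` are
#' full-series standard deviations with `n` in the denominator. A lag is
#' significant when `|ccf(l)| > 1.96 / sqrt(n)`; the best lag maximizes
#' `|ccf|`, with ties broken toward smaller `|l|` and then the positive lag.
#' A positive best lag means `b` trails `a` by that many stages.
#'
#' @param a,b Ordered per-stage values on equal stage grids (`n >= 5`).
#' @param max_lag Largest lag magnitude to scan.
#' @return List with `ccf` (data frame `lag`, `ccf`, `significant`),
#'   `best_lag`, `ccf_at_best` and `significant`.
#' @export
cross_correlation <- function(a, b, max_lag = 2L) {
  n <- length(a)
  if (length(b) != n) stop("the two series must share one stage grid")
  if (n < 5L) stop("at least 5 stages are required")
  sa <- sqrt(mean((a - mean(a))^2))
  sb <- sqrt(mean((b - mean(b))^2))
  if (sa == 0 || sb == 0) stop("constant series: cross-correlation is undefined")
  ma <- mean(a)
  mb <- mean(b)
  lags <- seq.int(-max_lag, max_lag)
  ccf_l <- vapply(lags, function(l) {
    t_idx <- seq_len(n)
    keep <- t_idx + l >= 1L & t_idx + l <= n
    sum((a[t_idx[keep]] - ma) * (b[t_idx[keep] + l] - mb)) / (n * sa * sb)
  }, numeric(1))
  bound <- 1.96 / sqrt(n)
  # ties toward smaller |l|, then the positive lag
  ord <- order(-abs(ccf_l), abs(lags), -sign(lags))
  best <- ord[1]
  list(
    ccf = data.frame(lag = lags, ccf = ccf_l, significant = abs(ccf_l) > bound),
    best_lag = lags[best],
    ccf_at_best = ccf_l[best],
    significant = abs(ccf_l[best]) > bound
  )
}

#' Proportion of variance explained by stage (eta squared)
#'
#' One-way decomposition of per-stage replicate values:
#' `eta^2 = SS_between / SS_total`. Reported alongside the
#' cross-correlation test to verify that within-stage variance is not
#' driving it; invariant under affine transformation of all values.
#'
#' @param values Numeric replicate values.
#' @param stage Stage label per value (>= 2 stages, >= 2 replicates in at
#'   least one stage).
#' @return `eta^2` in `[0, 1]`.
#' @export
eta_squared <- function(values, stage) {
  if (length(values) != length(stage)) stop("values and stage must align")
  keep <- !is.na(values)
  values <- values[keep]
  stage <- stage[keep]
  if (length(unique(stage)) < 2L) stop("at least two stages are required")
  grand <- mean(values)
  ss_total <- sum((values - grand)^2)
  if (ss_total == 0) stop("all values identical: eta squared is undefined")
  means <- tapply(values, stage, mean)
  counts <- tapply(values, stage, length)
  ss_between <- sum(counts * (means[names(counts)] - grand)^2)
  unname(ss_between / ss_total)
}

#' Cross-host analysis of candidate gene profiles
#'
#' For each gene, builds the per-stage mean log2 ratio series in each host,
#' runs the autocorrelation pre-check (genes failing it are flagged, not
#' dropped), the lagged cross-correlation test and the per-host eta-squared.
#'
#' @param profiles_a,profiles_b Expression profiles (data frames with
#'   columns `gene`, `stage`, `ratio`; replicate rows are averaged on the
#'   log2 scale) for the native and heterologous host.
#' @param genes Genes to test (default: those present in both).
#' @param max_lag Largest lag magnitude to scan.
#' @param eta_flag Informational flag bound: genes with `eta^2` under this
#'   value in either host are marked `low_eta2`.
#' @return Data frame `gene, best_lag, ccf_at_best, significant, eta_sq_hostA,
#'   eta_sq_hostB, flags`.
#' @export
crosshost_analysis <- function(profiles_a, profiles_b, genes = NULL,
                               max_lag = 2L, eta_flag = 0.5) {
  if (is.null(genes)) genes <- intersect(unique(profiles_a$gene),
                                         unique(profiles_b$gene))
  series <- function(profiles, g) {
    sub <- profiles[profiles$gene == g & !is.na(profiles$ratio), ]
    means <- tapply(log2(sub$ratio), sub$stage, mean)
    means[order(as.numeric(names(means)))]
  }
  rows <- lapply(genes, function(g) {
    a <- series(profiles_a, g)
    b <- series(profiles_b, g)
    sub_a <- profiles_a[profiles_a$gene == g & !is.na(profiles_a$ratio), ]
    sub_b <- profiles_b[profiles_b$gene == g & !is.na(profiles_b$ratio), ]
    flags <- character(0)
    ac_fail <- function(x) {
      tryCatch(any(autocorrelation(as.numeric(x), max_lag)$significant),
               error = function(e) NA)
    }
    if (isTRUE(ac_fail(a)) || isTRUE(ac_fail(b))) flags <- c(flags, "autocorrelated")
    cc <- tryCatch(cross_correlation(as.numeric(a), as.numeric(b), max_lag),
                   error = function(e) NULL)
    eta_a <- tryCatch(eta_squared(log2(sub_a$ratio), sub_a$stage),
                      error = function(e) NA_real_)
    eta_b <- tryCatch(eta_squared(log2(sub_b$ratio), sub_b$stage),
                      error = function(e) NA_real_)
    if ((!is.na(eta_a) && eta_a < eta_flag) ||
        (!is.na(eta_b) && eta_b < eta_flag)) {
      flags <- c(flags, "low_eta2")
    }
    data.frame(
      gene = g,
      best_lag = if (is.null(cc)) NA_integer_ else cc$best_lag,
      ccf_at_best = if (is.null(cc)) NA_real_ else cc$ccf_at_best,
      significant = if (is.null(cc)) FALSE else cc$significant,
      eta_sq_hostA = eta_a,
      eta_sq_hostB = eta_b,
      flags = paste(flags, collapse = ";")
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
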