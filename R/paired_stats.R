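# Paired comparisons on WT/KO value tables: paired t-test and exact paired
# Wilcoxon signed-rank test.

#' Paired Student's t-test
#'
#' One-sample t-test on the KO minus WT differences, two-sided.
#'
#' @param wt,ko Numeric vectors of paired values (same length, n >= 2); or a
#'   data.frame with columns `wt` and `ko` as the first argument.
#' @return List: `statistic` (t), `df`, `p_value`, `mean_diff`.
#' @export
#' @examples
#' paired_t(c(0, 0, 0), c(1, 2, 3))  # t = 3.4641, p = 0.0742
paired_t <- function(wt, ko = NULL) {
  if (is.data.frame(wt)) { ko <- wt$ko; wt <- wt$wt }
  stopifnot(length(wt) == length(ko), all(is.finite(wt)), all(is.finite(ko)))
  if (length(wt) < 2L) stop("paired t-test needs at least 2 pairs")
  d <- ko - wt
  if (stats::sd(d) == 0)
    stop("zero variance of differences; t statistic undefined")
  ht <- stats::t.test(d)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_diff = mean(d))
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided exact test on KO minus WT differences. Zero differences are
#' dropped before ranking; ties among absolute differences get midranks.
#' The null distribution of the positive-rank sum is enumerated exactly over
#' all 2^n sign assignments (computed by dynamic programming over doubled
#' midranks, equivalent to full enumeration), and the two-sided p-value is
#' twice the smaller tail, capped at 1. Exact enumeration is supported for
#' up to 25 non-zero differences, covering small-cohort designs.
#'
#' @param wt,ko Numeric vectors of paired values; or a data.frame with
#'   columns `wt` and `ko` as the first argument.
#' @return List: `statistic` (V, sum of positive ranks), `p_value`,
#'   `n_used` (non-zero differences).
#' @export
#' @examples
#' paired_wilcoxon_exact(rep(0, 7), 1:7)$p_value  # 2/128 = 0.015625
paired_wilcoxon_exact <- function(wt, ko = NULL) {
  if (is.data.frame(wt)) { ko <- wt$ko; wt <- wt$wt }
  stopifnot(length(wt) == length(ko), all(is.finite(wt)), all(is.finite(ko)))
  d <- ko - wt
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L)
    return(list(statistic = 0, p_value = 1, n_used = 0L))
  if (m > 25L)
    stop("exact enumeration supported for at most 25 non-zero differences")
  r2 <- as.integer(round(2 * rank(abs(d))))  # doubled midranks are integers
  v2 <- sum(r2[d > 0])
  total <- sum(r2)
  ## counts over all sign assignments of the doubled positive-rank sum
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), f[seq_len(total + 1L - r)])
    f <- f + shifted
  }
  denom <- 2^m
  p_le <- sum(f[seq_len(v2 + 1L)]) / denom
  p_ge <- sum(f[(v2 + 1L):(total + 1L)]) / denom
  list(statistic = v2 / 2, p_value = min(1, 2 * min(p_le, p_ge)),
       n_used = m)
}

#' Run both paired tests on a WT/KO table
#'
#' @param tbl data.frame with columns `pair`, `wt`, `ko` (or just `wt`/`ko`).
#' @return data.frame with one row per test: test, statistic, p_value, n.
#' @export
paired_tests <- function(tbl) {
  tt <- paired_t(tbl)
  wt_ <- paired_wilcoxon_exact(tbl)
  data.frame(test = c("paired_t", "paired_wilcoxon_exact"),
             statistic = c(tt$statistic, wt_$statistic),
             p_value = c(tt$p_value, wt_$p_value),
             n = c(length(tbl$wt), wt_$n_used),
             stringsAsFactors = FALSE)
}
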