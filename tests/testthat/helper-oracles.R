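# Independent oracles used across tests. These deliberately avoid the code
# paths they check: direct summation, exhaustive enumeration, per-base loops.

## binomial tail P(X >= k) by direct summation of the mass function
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(stats::dbinom(k:n, n, p))
}

## exact two-sided signed-rank p by full enumeration over all 2^n sign
## assignments (midranks; zeros dropped by the caller)
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(1)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  v_all <- as.numeric(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

## per-base coverage/depth accumulator (protein of length `len`; psms is a
## data.frame with start, end, one row per scan)
oracle_coverage_depth <- function(psms, len) {
  counts <- integer(len)
  for (i in seq_len(nrow(psms))) {
    for (pos in psms$start[i]:psms$end[i]) counts[pos] <- counts[pos] + 1L
  }
  covered <- counts > 0
  list(coverage = 100 * sum(covered) / len,
       depth = if (any(covered)) mean(counts[covered]) else 0)
}

## brute-force count of peptidoforms: every assignment of at most one
## applicable variable mod per site, <= max_var variable mods, <= 1
## arginylation; fixed mods do not count against the cap
oracle_count_forms <- function(sequence, registry, max_var,
                               protein_nterm = FALSE) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  var <- registry[registry$mode == "variable", , drop = FALSE]
  site_opts <- list()
  positions <- c(0L, seq_along(aa))
  for (pos in positions) {
    opts <- list(NULL)
    for (i in seq_len(nrow(var))) {
      spec <- var$specificity[i]
      hit <- if (spec == "peptide N-term") pos == 0L
      else if (spec == "protein N-term") pos == 0L && protein_nterm
      else pos > 0L && aa[pos] %in% strsplit(spec, "", fixed = TRUE)[[1]]
      if (hit) opts <- c(opts, list(var[i, ]))
    }
    site_opts[[as.character(pos)]] <- opts
  }
  idx <- lapply(site_opts, seq_along)
  grid <- expand.grid(idx)
  count <- 0L
  for (g in seq_len(nrow(grid))) {
    chosen <- Map(function(opts, j) opts[[j]], site_opts, unlist(grid[g, ]))
    chosen <- Filter(Negate(is.null), chosen)
    nv <- length(chosen)
    narg <- sum(vapply(chosen, function(x) x$is_arginylation, TRUE))
    if (nv <= max_var && narg <= 1L) count <- count + 1L
  }
  count
}

## random peptide of given length (guaranteed valid residues)
random_peptide <- function(len, alphabet = names(argsite::residue_masses())) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

## I/L mass-equivalence normalization for truth comparisons
norm_il <- function(s) chartr("I", "L", s)

## noise-free spectrum containing exactly the singly/doubly charged b/y
## ladder of a peptidoform (built independently via exported fragment_ladder)
ladder_spectrum <- function(pf, z, scan = "s1") {
  charges <- if (z >= 2) c(1L, 2L) else 1L
  mz <- unlist(lapply(charges, function(zc)
    c(fragment_ladder(pf, "b", zc), fragment_ladder(pf, "y", zc))))
  spectrum(scan, precursor_mz(pf, z), z, mz, rep(100, length(mz)))
}
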