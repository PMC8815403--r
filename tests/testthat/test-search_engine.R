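make_tiny_db <- function(seed = 71, n = 12) {
  mp <- make_proteome(seed, n_proteins = n, length_range = c(120, 200))
  build_search_db(mp$proteome, default_modifications(), digest_config())
}

test_that("precursor candidate matching equals a linear-scan oracle", {
  db <- make_tiny_db()
  pf <- db$peptidoforms
  expect_gt(nrow(pf), 1000)
  set.seed(72)
  for (i in 1:25) {
    z <- sample(2:3, 1)
    row <- pf[sample(nrow(pf), 1), ]
    obs <- (row$neutral_mass + z * 1.007276) / z *
      (1 + runif(1, -8, 8) * 1e-6)
    s <- spectrum("q", obs, z)
    tol <- sample(c(0, 3, 6, 10), 1)
    got <- match_candidates(s, db, tol)
    theo <- (pf$neutral_mass + z * 1.007276) / z
    want <- which(abs((obs - theo) / theo * 1e6) <= tol)
    expect_setequal(
      paste(got$protein, got$start, got$mods),
      paste(pf$protein[want], pf$start[want], pf$mods[want]))
  }

  ## a spectrum at exactly a candidate's m/z finds it even at tolerance 0
  row <- pf[100, ]
  s <- spectrum("exact", (row$neutral_mass + 2 * 1.007276) / 2, 2)
  got <- match_candidates(s, db, 0)
  expect_true(any(got$neutral_mass == row$neutral_mass))
})

test_that("binomial survival score matches direct tail summation", {
  pf <- peptidoform("AVEDLKTTPGYR")
  z <- 2L
  full <- ladder_spectrum(pf, z)

  ## full ladder and nothing else: k = n
  sc <- score_psm(full, pf, 0.02)
  expect_equal(sc$matched, sc$n_theoretical)
  expect_gt(sc$score, 0)

  ## no peaks within tolerance: k = 0, score 0 (P(X>=0) = 1)
  grid <- seq(150, 1200, by = 13.7)
  grid <- grid[vapply(grid, function(g) min(abs(g - full$mz)) > 0.5, TRUE)]
  far <- spectrum("far", precursor_mz(pf, z), z,
                  mz = grid, intensity = rep(1, length(grid)))
  sc0 <- score_psm(far, pf, 0.02)
  expect_equal(sc0$matched, 0)
  expect_equal(sc0$score, 0)

  ## empty peak list scores 0
  expect_equal(score_psm(spectrum("e", precursor_mz(pf, z), z), pf)$score, 0)

  ## partial match: score equals -10 log10 of the independent tail sum
  keep <- full$mz[seq(1, length(full$mz), by = 2)]
  noise <- seq(min(keep) + 0.5, max(keep) - 0.5, length.out = 30)
  part <- spectrum("p", precursor_mz(pf, z), z,
                   mz = c(keep, noise), intensity = rep(1, length(keep) + 30))
  sc2 <- score_psm(part, pf, 0.02)
  p <- min(1, 2 * 0.02 * length(part$mz) / diff(range(part$mz)))
  expect_equal(sc2$score,
               -10 * log10(oracle_binom_tail(sc2$matched,
                                             sc2$n_theoretical, p)),
               tolerance = 1e-8)

  ## survival evaluation for fixed (n = 20, k = 12, p = 0.05)
  expect_equal(-10 * log10(oracle_binom_tail(12, 20, 0.05)),
               -10 * stats::pbinom(11, 20, 0.05, lower.tail = FALSE,
                                   log.p = TRUE) / log(10))

  ## determinism
  expect_identical(score_psm(part, pf, 0.02), score_psm(part, pf, 0.02))
})

test_that("localization separates or ties placements as evidence dictates", {
  cfg <- search_config()
  reg <- default_modifications()
  db <- list(registry = reg)  # localize only needs the registry
  seqc <- "TTPEQDVLKK"        # E4 and D6 candidate sites
  z <- 2L
  pf_true <- peptidoform(seqc, mods = "Arg (DE)@4")
  pf_alt <- peptidoform(seqc, mods = "Arg (DE)@6")
  psm <- data.frame(scan = "s", protein = "P", start = 10, end = 19,
                    sequence = seqc, mods = "Arg (DE)@4", arg_pos = 4,
                    stringsAsFactors = FALSE)

  ## full ladder of the true placement contains site-discriminating ions
  s_full <- ladder_spectrum(pf_true, z)
  loc <- localize(s_full, psm, db, cfg)
  expect_equal(loc$sites, 4)
  expect_false(loc$ambiguous)
  expect_equal(loc$protein_sites, 13)  # start 10 + pos 4 - 1

  ## only ions on which both placements agree: a forced tie
  b1 <- c(fragment_ladder(pf_true, "b", 1), fragment_ladder(pf_true, "y", 1))
  b2 <- c(fragment_ladder(pf_alt, "b", 1), fragment_ladder(pf_alt, "y", 1))
  shared <- b1[abs(b1 - b2) < 1e-9]
  s_tie <- spectrum("t", precursor_mz(pf_true, z), z, shared,
                    rep(1, length(shared)))
  loc2 <- localize(s_tie, psm, db, cfg)
  expect_true(loc2$ambiguous)
  expect_setequal(loc2$sites, c(4, 6))
})

test_that("an E/D pair two residues apart with no discriminating ions is
          reported as an ambiguous pair", {
  ## mirrors the reported 'arginylated at E167 or D169' ambiguity
  cfg <- search_config()
  db <- list(registry = default_modifications())
  seqc <- "LVTPGYVPTEQDVLR"
  pf_e <- peptidoform(seqc, mods = "Arg (DE)@10")
  pf_d <- peptidoform(seqc, mods = "Arg (DE)@12")
  lad <- function(pf) unlist(lapply(1:2, function(zc)
    c(fragment_ladder(pf, "b", zc), fragment_ladder(pf, "y", zc))))
  l1 <- lad(pf_e); l2 <- lad(pf_d)
  shared <- l1[abs(l1 - l2) < 1e-9]
  s <- spectrum("fig1", precursor_mz(pf_e, 3), 3, shared,
                rep(1, length(shared)))
  psm <- data.frame(scan = "fig1", protein = "GNAT1", start = 158, end = 172,
                    sequence = seqc, mods = "Arg (DE)@10", arg_pos = 10,
                    stringsAsFactors = FALSE)
  loc <- localize(s, psm, db, cfg)
  expect_true(loc$ambiguous)
  expect_setequal(loc$sites, c(10, 12))
  expect_setequal(loc$protein_sites, c(167, 169))
})

test_that("q-values equal a hand-computed running-ratio table", {
  ## 10 PSMs, interleaved target/decoy scores
  psms <- data.frame(
    score = c(100, 90, 80, 70, 60, 50, 40, 30, 20, 10),
    decoy = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE,
              FALSE, FALSE))
  got <- compute_qvalues(psms)
  ## oracle: FDR_i = decoys-at-or-above / targets-at-or-above; q = min over
  ## all accepting sets containing PSM i
  fdr <- cumsum(psms$decoy) / cumsum(!psms$decoy)
  q_want <- rev(cummin(rev(fdr)))
  expect_equal(got$q, q_want)
  expect_equal(got$q[1:2], c(0, 0))

  ## all targets above all decoys: every target accepted at q = 0
  clean <- data.frame(score = 10:1,
                      decoy = c(rep(FALSE, 5), rep(TRUE, 5)))
  acc <- fdr_filter(clean, 0)
  expect_equal(nrow(acc), 5)
  expect_true(all(acc$q == 0))

  ## monotone: raising the threshold never shrinks the accepted set
  sizes <- vapply(c(0, 0.1, 0.25, 0.5, 1),
                  function(thr) nrow(fdr_filter(psms, thr)), 1L)
  expect_true(all(diff(sizes) >= 0))

  ## zero targets -> empty output
  only_decoys <- data.frame(score = c(5, 4), decoy = c(TRUE, TRUE))
  expect_equal(nrow(fdr_filter(only_decoys, 0.5)), 0)
})

test_that("decoy reversal is an involution preserving masses", {
  mp <- make_proteome(81, n_proteins = 5, length_range = c(80, 120))
  twice <- reverse_proteome(reverse_proteome(mp$proteome))
  expect_equal(unname(twice), unname(mp$proteome))
  expect_equal(names(twice), paste0("REV_REV_", names(mp$proteome)))
})

test_that("noise-free spectra are top-ranked to their true peptidoform", {
  db <- make_tiny_db(91, n = 10)
  pf <- db$peptidoforms
  pool <- pf[!pf$decoy & pf$n_var_mods == 0, ]
  set.seed(92)
  pool <- pool[sample(nrow(pool), 100), ]
  pool$charge <- 2L
  sim <- simulate_spectra(pool, seed = 93)
  psms <- search_spectra(sim$spectra, db, search_config())
  expect_equal(nrow(psms), 100)
  key_true <- paste(norm_il(sim$ledger$sequence), sim$ledger$mods)
  names(key_true) <- sim$ledger$scan
  ok <- paste(norm_il(psms$sequence), psms$mods) == key_true[psms$scan]
  expect_gte(mean(ok), 0.99)
})

test_that("search config round-trips through a key = value file", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# engine settings", "ppm_tol = 10", "frag_tol_da = 0.05",
               "q_threshold = 0.05", "localization_epsilon = 2",
               "min_matched = 4", "decoy_mode = reverse"), path)
  cfg <- read_search_config(path)
  expect_equal(cfg$ppm_tol, 10)
  expect_equal(cfg$frag_tol_da, 0.05)
  expect_equal(cfg$min_matched, 4L)
})
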