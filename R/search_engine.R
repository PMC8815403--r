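# Peptide-spectrum matching, binomial-survival scoring, site localization,
# and target-decoy FDR control.

#' Search configuration
#'
#' @param ppm_tol Precursor tolerance in ppm (signed window).
#' @param frag_tol_da Fragment matching tolerance in Da.
#' @param q_threshold q-value acceptance threshold.
#' @param localization_epsilon Score difference within which alternative
#'   modification placements are considered tied.
#' @param min_matched Minimum matched fragment ions for a candidate to
#'   produce a PSM at all (applied identically to targets and decoys). A
#'   fixed evidence floor is the standard guard against chance few-peak
#'   matches outranking a sparse decoy tail: under the binomial null with a
#'   typical ladder (n ~ 100, per-ion match probability ~ 1e-3), six matched
#'   ions have chance probability ~ 1e-10 per comparison — far below one
#'   event per run — while any true identification of a minimum-length
#'   tryptic peptide retains at least six matchable ions.
#' @param decoy_mode Decoy construction; only `"reverse"` (full-protein
#'   sequence reversal) is implemented.
#' @return List of class `search_config`.
#' @export
search_config <- function(ppm_tol = 6, frag_tol_da = 0.02,
                          q_threshold = 0.01, localization_epsilon = 1,
                          min_matched = 6L, decoy_mode = "reverse") {
  stopifnot(ppm_tol >= 0, frag_tol_da > 0, q_threshold >= 0,
            localization_epsilon >= 0, min_matched >= 0,
            decoy_mode == "reverse")
  structure(list(ppm_tol = ppm_tol, frag_tol_da = frag_tol_da,
                 q_threshold = q_threshold,
                 localization_epsilon = localization_epsilon,
                 min_matched = as.integer(min_matched),
                 decoy_mode = decoy_mode),
            class = "search_config")
}

#' Read a key = value text configuration file
#'
#' Recognized keys: ppm_tol, frag_tol_da, q_threshold, localization_epsilon,
#' decoy_mode. Lines starting with `#` are comments.
#'
#' @param path Config file path.
#' @return A [search_config()].
#' @export
read_search_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  args <- list()
  for (k in c("ppm_tol", "frag_tol_da", "q_threshold", "localization_epsilon",
              "min_matched"))
    if (k %in% keys) args[[k]] <- as.numeric(vals[match(k, keys)])
  if ("decoy_mode" %in% keys) args$decoy_mode <- vals[match("decoy_mode", keys)]
  do.call(search_config, args)
}

# ---------------------------------------------------------------------------
# Database
# ---------------------------------------------------------------------------

#' Reverse a proteome for decoy generation
#'
#' Full-protein sequence reversal; ids are prefixed `REV_`. Reversal is an
#' involution: reversing a reversed database recovers the target sequences.
#'
#' @param proteome Named character vector of protein sequences.
#' @return Named character vector of reversed sequences.
#' @export
reverse_proteome <- function(proteome) {
  rev_one <- function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                               collapse = "")
  out <- vapply(proteome, rev_one, "")
  names(out) <- paste0("REV_", names(proteome))
  out
}

#' Build a peptidoform search database
#'
#' Digests every protein with trypsin/P, enumerates peptidoforms under the
#' modification registry, and (by default) appends an identically processed
#' decoy database built by full-protein sequence reversal. The result is
#' indexed by neutral mass for precursor lookups.
#'
#' @param proteome Named character vector of protein sequences.
#' @param registry Modification registry (see [default_modifications()]).
#' @param digest_cfg A [digest_config()].
#' @param decoy Append reversed-sequence decoys?
#' @return Object of class `search_db`: a list with the peptidoform table
#'   (`$peptidoforms`, sorted by neutral mass), the registry, the digest
#'   configuration, and the proteome.
#' @export
build_search_db <- function(proteome, registry = default_modifications(),
                            digest_cfg = digest_config(), decoy = TRUE) {
  if (!length(proteome)) stop("empty proteome")
  full <- proteome
  is_decoy <- rep(FALSE, length(full))
  if (decoy) {
    dec <- reverse_proteome(proteome)
    full <- c(full, dec)
    is_decoy <- c(is_decoy, rep(TRUE, length(dec)))
  }
  tabs <- vector("list", length(full))
  for (i in seq_along(full)) {
    pep <- digest_trypsin_p(full[[i]], digest_cfg)
    if (!nrow(pep)) next
    forms <- vector("list", nrow(pep))
    for (j in seq_len(nrow(pep))) {
      forms[[j]] <- enumerate_peptidoforms(pep$sequence[j], pep$start[j],
                                           registry, digest_cfg,
                                           protein = names(full)[i])
    }
    tab <- do.call(rbind, forms)
    tab$decoy <- is_decoy[i]
    tabs[[i]] <- tab
  }
  tabs <- tabs[!vapply(tabs, is.null, TRUE)]
  if (!length(tabs)) stop("digestion produced no peptides")
  db <- do.call(rbind, tabs)
  db <- db[order(db$neutral_mass, db$protein, db$start, db$mods), ,
           drop = FALSE]
  rownames(db) <- NULL
  structure(list(peptidoforms = db, registry = registry,
                 digest_cfg = digest_cfg, proteome = proteome),
            class = "search_db")
}

#' @export
print.search_db <- function(x, ...) {
  cat(sprintf("<search_db> %d peptidoforms (%d decoy) from %d proteins\n",
              nrow(x$peptidoforms), sum(x$peptidoforms$decoy),
              length(x$proteome)))
  invisible(x)
}

#' Precursor-matching candidates for a spectrum
#'
#' All and only database peptidoforms whose theoretical precursor m/z at the
#' spectrum's charge lies within `ppm_tol` of the observed precursor.
#'
#' @param spec A [spectrum()].
#' @param db A [build_search_db()] result.
#' @param ppm_tol Precursor tolerance in ppm.
#' @return Subset of the peptidoform table with a `ppm_error` column
#'   (signed, observed minus theoretical, ppm).
#' @export
match_candidates <- function(spec, db, ppm_tol) {
  pf <- db$peptidoforms
  z <- spec$charge
  obs <- spec$precursor_mz
  lo_mz <- obs / (1 + ppm_tol * 1e-6)
  hi_mz <- obs / (1 - ppm_tol * 1e-6)
  lo_m <- lo_mz * z - z * PROTON_MASS
  hi_m <- hi_mz * z - z * PROTON_MASS
  i0 <- findInterval(lo_m, pf$neutral_mass, left.open = TRUE) + 1L
  i1 <- findInterval(hi_m, pf$neutral_mass)
  if (i1 < i0)
    return(cbind(pf[0L, , drop = FALSE], ppm_error = numeric()))
  cand <- pf[i0:i1, , drop = FALSE]
  theo <- (cand$neutral_mass + z * PROTON_MASS) / z
  cand$ppm_error <- (obs - theo) / theo * 1e6
  cand <- cand[abs(cand$ppm_error) <= ppm_tol, , drop = FALSE]
  cand
}

# ---------------------------------------------------------------------------
# Scoring
# ---------------------------------------------------------------------------

## fragment charges modeled for a precursor charge z: 1+, and 2+ when z >= 2
.frag_charges <- function(z) if (z >= 2L) c(1L, 2L) else 1L

## internal scorer on raw pieces; returns c(score, matched, n_theoretical)
.score_raw <- function(obs_mz, rmass, dvec, nterm_delta, z, frag_tol_da) {
  theo <- .ladder_mz(rmass, dvec, nterm_delta, .frag_charges(z))
  n <- length(theo)
  if (n == 0L || length(obs_mz) == 0L) return(c(0, 0, n))
  ## greedy nearest observed peak within tolerance for each theoretical ion
  idx <- findInterval(theo, obs_mz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(obs_mz))
  d_lo <- abs(theo - obs_mz[lo])
  d_hi <- abs(theo - obs_mz[hi])
  k <- sum(pmin(d_lo, d_hi) <= frag_tol_da)
  span <- obs_mz[length(obs_mz)] - obs_mz[1L]
  p <- if (span <= 0) 1 else min(1, 2 * frag_tol_da * length(obs_mz) / span)
  if (k == 0L || p >= 1) return(c(0, k, n))
  logp <- stats::pbinom(k - 1L, n, p, lower.tail = FALSE, log.p = TRUE)
  score <- max(0, -10 * logp / log(10))
  c(score, k, n)
}

#' Score a peptide-spectrum match
#'
#' The score is `-10 * log10` of the binomial survival probability
#' `P(X >= k)` with `n` the theoretical b/y ladder size (singly charged ions,
#' plus doubly charged for precursors of charge >= 2), `k` the number of
#' theoretical ions with an observed peak within `frag_tol_da` (greedy
#' nearest match, each theoretical ion matched at most once), and
#' `p = min(1, 2 * frag_tol_da * peak count / observed m/z span)`. An empty
#' peak list scores 0. Deterministic.
#'
#' @param spec A [spectrum()].
#' @param pf A [peptidoform()].
#' @param frag_tol_da Fragment tolerance in Da (> 0).
#' @return List with `score`, `matched`, and `n_theoretical`.
#' @export
score_psm <- function(spec, pf, frag_tol_da = 0.02) {
  if (frag_tol_da <= 0) stop("frag_tol_da must be > 0")
  rmass <- .residue_mass_vec(pf$sequence)
  dvec <- numeric(length(rmass))
  nterm <- 0
  if (nrow(pf$mods)) {
    side <- pf$mods$pos > 0L
    if (any(side)) dvec[pf$mods$pos[side]] <- dvec[pf$mods$pos[side]] +
        pf$mods$delta[side]
    nterm <- sum(pf$mods$delta[!side])
  }
  r <- .score_raw(spec$mz, rmass, dvec, nterm, spec$charge, frag_tol_da)
  list(score = r[1L], matched = as.integer(r[2L]),
       n_theoretical = as.integer(r[3L]))
}

## score one db row against a spectrum (returns c(score, matched, n))
.score_db_row <- function(spec, row, registry, frag_tol_da) {
  rmass <- .residue_mass_vec(row$sequence)
  dvec <- numeric(length(rmass))
  nterm <- 0
  md <- parse_mods(row$mods, registry)
  if (nrow(md)) {
    side <- md$pos > 0L
    if (any(side)) dvec[md$pos[side]] <- dvec[md$pos[side]] + md$delta[side]
    nterm <- sum(md$delta[!side])
  }
  .score_raw(spec$mz, rmass, dvec, nterm, spec$charge, frag_tol_da)
}

# ---------------------------------------------------------------------------
# Search
# ---------------------------------------------------------------------------

.empty_psms <- function() {
  data.frame(scan = character(), precursor_mz = numeric(), charge = integer(),
             protein = character(), start = integer(), end = integer(),
             sequence = character(), mods = character(), n_mods = integer(),
             arg_pos = integer(), arg_name = character(),
             score = numeric(), ppm_error = numeric(), matched = integer(),
             n_theoretical = integer(), decoy = logical(),
             stringsAsFactors = FALSE)
}

#' Search spectra against a peptidoform database
#'
#' For each spectrum, scores every precursor-matching candidate (targets and
#' decoys competing) and keeps the single best PSM. Ties are broken by fewer
#' modifications, then lexicographic peptide sequence, then the canonical
#' modification string, then target before decoy — fully deterministic.
#'
#' @param spectra List of [spectrum()] objects.
#' @param db A [build_search_db()] result.
#' @param cfg A [search_config()].
#' @return data.frame of best-per-scan PSMs.
#' @export
search_spectra <- function(spectra, db, cfg = search_config()) {
  out <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    cand <- match_candidates(s, db, cfg$ppm_tol)
    if (!nrow(cand)) next
    sc <- matrix(0, nrow(cand), 3L)
    for (j in seq_len(nrow(cand)))
      sc[j, ] <- .score_db_row(s, cand[j, , drop = FALSE], db$registry,
                               cfg$frag_tol_da)
    enough <- sc[, 2L] >= cfg$min_matched
    if (!any(enough)) next
    cand <- cand[enough, , drop = FALSE]
    sc <- sc[enough, , drop = FALSE]
    n_mods <- vapply(strsplit(cand$mods, ";", fixed = TRUE), length, 1L)
    n_mods[!nzchar(cand$mods)] <- 0L
    o <- order(-sc[, 1L], n_mods, cand$sequence, cand$mods, cand$decoy)
    b <- o[1L]
    out[[i]] <- data.frame(
      scan = s$scan, precursor_mz = s$precursor_mz, charge = s$charge,
      protein = cand$protein[b], start = cand$start[b], end = cand$end[b],
      sequence = cand$sequence[b], mods = cand$mods[b], n_mods = n_mods[b],
      arg_pos = cand$arg_pos[b], arg_name = cand$arg_name[b],
      score = sc[b, 1L], ppm_error = cand$ppm_error[b],
      matched = as.integer(sc[b, 2L]), n_theoretical = as.integer(sc[b, 3L]),
      decoy = cand$decoy[b], stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(.empty_psms())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---------------------------------------------------------------------------
# Localization
# ---------------------------------------------------------------------------

#' Localize an arginylation site
#'
#' Rescores the PSM's peptidoform with the arginylation moved to every
#' alternative legal placement (every D/E side chain, and the peptide
#' N-terminus when the registry contains an N-terminal variant of the same
#' delta). Placements within `localization_epsilon` of the best score form
#' the localization set; the match is flagged ambiguous when that set has
#' more than one member.
#'
#' @param spec The [spectrum()] behind the PSM.
#' @param psm One PSM row (from [search_spectra()]) carrying an arginylation.
#' @param db The search database used.
#' @param cfg A [search_config()].
#' @return List: `sites` (peptide positions, 0 = N-terminus), `protein_sites`
#'   (protein coordinates; NA for the N-terminus entry), `scores`,
#'   `best_site`, and `ambiguous`.
#' @export
localize <- function(spec, psm, db, cfg = search_config()) {
  if (is.na(psm$arg_pos)) stop("PSM carries no arginylation")
  registry <- db$registry
  md <- parse_mods(psm$mods, registry)
  arg_row <- md[md$is_arginylation, , drop = FALSE]
  other <- md[!md$is_arginylation, , drop = FALSE]
  delta <- arg_row$delta[1L]
  aa <- .residues(psm$sequence)
  placements <- which(aa %in% c("D", "E"))
  arg_reg <- registry[registry$is_arginylation &
                        abs(registry$delta - delta) < 1e-9, , drop = FALSE]
  side_name <- arg_reg$name[arg_reg$specificity == "DE"][1L]
  nterm_name <- arg_reg$name[arg_reg$specificity %in%
                               c("protein N-term", "peptide N-term")]
  nterm_ok <- if (any(arg_reg$specificity == "peptide N-term")) TRUE
              else psm$start <= 2L
  sites <- placements
  names_at <- rep(side_name, length(placements))
  if (length(nterm_name) && nterm_ok && !(0L %in% other$pos)) {
    sites <- c(0L, sites)
    names_at <- c(nterm_name[1L], names_at)
  }
  keep <- !(sites %in% other$pos)
  sites <- sites[keep]; names_at <- names_at[keep]
  if (!length(sites)) stop("no legal arginylation placements")
  scores <- numeric(length(sites))
  for (i in seq_along(sites)) {
    row <- psm
    row$mods <- .mods_string(c(other$pos, sites[i]),
                             c(other$name, names_at[i]))
    scores[i] <- .score_db_row(spec, row, registry, cfg$frag_tol_da)[1L]
  }
  best <- max(scores)
  in_set <- scores >= best - cfg$localization_epsilon
  list(sites = sites[in_set],
       protein_sites = ifelse(sites[in_set] == 0L, NA_integer_,
                              psm$start + sites[in_set] - 1L),
       scores = scores[in_set],
       best_site = sites[which.max(scores)],
       ambiguous = sum(in_set) > 1L)
}

# ---------------------------------------------------------------------------
# FDR
# ---------------------------------------------------------------------------

#' Target-decoy q-values for a set of PSMs
#'
#' PSMs are ranked by score (ties broken deterministically as in
#' [search_spectra()]); at each rank the estimated FDR is the number of
#' decoys at or above that rank divided by the number of targets at or above
#' it, and each PSM's q-value is the minimum estimated FDR over all accepting
#' sets that contain it.
#'
#' @param psms PSM data.frame with `score` and `decoy` columns.
#' @return The input with a `q` column appended (decoys get q too).
#' @export
compute_qvalues <- function(psms) {
  if (!nrow(psms)) { psms$q <- numeric(); return(psms) }
  keys <- list(-psms$score)
  for (k in c("n_mods", "sequence", "mods"))
    if (k %in% names(psms)) keys <- c(keys, list(psms[[k]]))
  keys <- c(keys, list(psms$decoy))
  o <- do.call(order, keys)
  d <- cumsum(psms$decoy[o])
  t <- cumsum(!psms$decoy[o])
  fdr <- ifelse(t == 0L, Inf, d / t)
  q <- rev(cummin(rev(fdr)))
  psms$q <- NA_real_
  psms$q[o] <- q
  psms
}

#' Filter PSMs at a q-value threshold
#'
#' Returns the accepted target PSMs (q <= threshold), with q-values.
#' Acceptance is monotone in the threshold: raising it never shrinks the
#' accepted set. With zero targets the output is empty.
#'
#' @param psms PSM data.frame.
#' @param q_threshold Acceptance threshold (e.g. 0.01 for 1% FDR).
#' @return Accepted target PSMs with a `q` column.
#' @export
fdr_filter <- function(psms, q_threshold = 0.01) {
  psms <- compute_qvalues(psms)
  res <- psms[!psms$decoy & psms$q <= q_threshold, , drop = FALSE]
  rownames(res) <- NULL
  res
}
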