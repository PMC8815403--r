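# Two-run restricted-database search strategy with exclusion filters and
# coverage/depth reporting.

#' Scan-exclusion filter against first-pass identifications
#'
#' An arginylated second-pass PSM is dropped iff its scan id appears among
#' the accepted first-pass PSMs: a scan that already has a confident
#' unmodified explanation provides no independent evidence for arginylation.
#'
#' @param pass2_psms Arginylated second-pass PSMs.
#' @param pass1_psms Accepted first-pass PSMs.
#' @return List: `kept` and `dropped` (the latter with a `reason` column).
#' @export
exclude_by_pass1 <- function(pass2_psms, pass1_psms) {
  hit <- pass2_psms$scan %in% pass1_psms$scan
  dropped <- pass2_psms[hit, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- "scan-identified-in-pass-1"
  list(kept = pass2_psms[!hit, , drop = FALSE], dropped = dropped)
}

#' Terminal-arginine missed-cleavage confound flag
#'
#' A side-chain arginylated peptide is mass-isobaric with the unmodified
#' peptide extended by one literal Arg through an extra missed cleavage.
#' The match is therefore confounded whenever the residue immediately
#' preceding the peptide in its protein, or the residue immediately
#' following it, is R. Peptides at the protein boundary have no neighbor on
#' that side and cannot be confounded there.
#'
#' @param psm One PSM row (protein, start, end, sequence).
#' @param proteome Named character vector including the PSM's protein.
#' @return TRUE if the arginylated form could be mistaken for a terminal
#'   arginine left by a missed cleavage.
#' @export
terminal_arg_confound <- function(psm, proteome) {
  if (!psm$protein %in% names(proteome))
    stop("protein not found: ", psm$protein)
  prot <- proteome[[psm$protein]]
  if (substring(prot, psm$start, psm$end) != psm$sequence)
    stop("peptide does not match protein ", psm$protein,
         " at ", psm$start, "-", psm$end)
  before <- if (psm$start > 1L) substring(prot, psm$start - 1L,
                                          psm$start - 1L) else ""
  after <- if (psm$end < nchar(prot)) substring(prot, psm$end + 1L,
                                                psm$end + 1L) else ""
  identical(before, "R") || identical(after, "R")
}

#' Per-protein coverage and depth from first-pass identifications
#'
#' Coverage is the percentage of residues covered by at least one accepted
#' first-pass peptide. Depth is the average, over covered residues, of the
#' number of MS/MS scans whose identified peptides span that residue
#' (repeat identifications of the same peptide all count).
#'
#' @param pass1_psms Accepted first-pass PSMs (one row per scan).
#' @param protein Protein id.
#' @param proteome Named character vector with the protein's sequence.
#' @return data.frame row: protein, length, coverage (percent), depth
#'   (0 when nothing is covered).
#' @export
coverage_depth <- function(pass1_psms, protein, proteome) {
  len <- nchar(proteome[[protein]])
  counts <- integer(len)
  hits <- pass1_psms[pass1_psms$protein == protein, , drop = FALSE]
  for (i in seq_len(nrow(hits))) {
    span <- hits$start[i]:hits$end[i]
    counts[span] <- counts[span] + 1L
  }
  covered <- counts > 0L
  data.frame(protein = protein, length = len,
             coverage = 100 * sum(covered) / len,
             depth = if (any(covered)) mean(counts[covered]) else 0,
             stringsAsFactors = FALSE)
}

#' Run the two-pass arginylation search
#'
#' Pass 1 searches all spectra against the full database with arginylation
#' disabled; pass 2 searches against the restricted database of proteins of
#' interest with the arginylation modifications enabled. Both passes are
#' FDR-filtered independently at `cfg$q_threshold`. Arginylated pass-2 PSMs
#' are then excluded — each with exactly one reason, in the precedence
#' `fdr`, `scan-identified-in-pass-1`, `terminal-Arg-confound` — and the
#' survivors are site-localized. Coverage/depth is reported for the
#' restricted proteins from pass-1 identifications only.
#'
#' @param spectra List of [spectrum()] objects.
#' @param full_proteome Named character vector (whole database, e.g. a
#'   proteome plus contaminants).
#' @param restricted_proteome Named character vector: the proteins of
#'   interest. Must be non-empty.
#' @param cfg A [search_config()].
#' @param digest_cfg A [digest_config()].
#' @param nterm_arginylation Allow peptide-N-terminal arginylation in pass 2?
#' @return Object of class `two_pass_result`: pass1 (accepted PSMs), pass2
#'   (all arginylated target pass-2 PSMs with q-values), surviving
#'   (arginylated PSMs passing every filter, with localization columns
#'   `loc_sites`, `loc_protein_sites`, `ambiguous`), exclusions (scan,
#'   sequence, reason), sites (unique surviving protein sites), coverage.
#' @export
run_two_pass <- function(spectra, full_proteome, restricted_proteome,
                         cfg = search_config(),
                         digest_cfg = digest_config(),
                         nterm_arginylation = TRUE) {
  if (!length(restricted_proteome)) stop("empty restricted protein list")

  reg1 <- default_modifications(arginylation = FALSE)
  reg2 <- default_modifications(arginylation = TRUE,
                                nterm_arginylation = nterm_arginylation)

  db1 <- build_search_db(full_proteome, reg1, digest_cfg)
  psms1 <- search_spectra(spectra, db1, cfg)
  accepted1 <- fdr_filter(psms1, cfg$q_threshold)

  db2 <- build_search_db(restricted_proteome, reg2, digest_cfg)
  psms2 <- compute_qvalues(search_spectra(spectra, db2, cfg))
  arg2 <- psms2[!psms2$decoy & !is.na(psms2$arg_pos), , drop = FALSE]

  reason <- rep(NA_character_, nrow(arg2))
  for (i in seq_len(nrow(arg2))) {
    if (arg2$q[i] > cfg$q_threshold) {
      reason[i] <- "fdr"
    } else if (arg2$scan[i] %in% accepted1$scan) {
      reason[i] <- "scan-identified-in-pass-1"
    } else if (terminal_arg_confound(arg2[i, ], restricted_proteome)) {
      reason[i] <- "terminal-Arg-confound"
    }
  }
  exclusions <- cbind(arg2[!is.na(reason), c("scan", "protein", "sequence",
                                             "mods", "score", "q"),
                           drop = FALSE],
                      reason = reason[!is.na(reason)])
  rownames(exclusions) <- NULL
  surviving <- arg2[is.na(reason), , drop = FALSE]

  ## localize survivors
  scan_index <- match(surviving$scan,
                      vapply(spectra, `[[`, "", "scan"))
  loc_sites <- character(nrow(surviving))
  loc_prot <- character(nrow(surviving))
  ambiguous <- logical(nrow(surviving))
  best_prot_site <- rep(NA_integer_, nrow(surviving))
  for (i in seq_len(nrow(surviving))) {
    lc <- localize(spectra[[scan_index[i]]], surviving[i, ], db2, cfg)
    loc_sites[i] <- paste(lc$sites, collapse = "|")
    loc_prot[i] <- paste(lc$protein_sites, collapse = "|")
    ambiguous[i] <- lc$ambiguous
    best_prot_site[i] <- if (lc$best_site == 0L) NA_integer_ else
      surviving$start[i] + lc$best_site - 1L
  }
  surviving$loc_sites <- loc_sites
  surviving$loc_protein_sites <- loc_prot
  surviving$ambiguous <- ambiguous
  surviving$best_protein_site <- best_prot_site
  rownames(surviving) <- NULL

  sites <- unique(surviving[!is.na(surviving$best_protein_site),
                            c("protein", "best_protein_site", "arg_name")])
  rownames(sites) <- NULL

  coverage <- do.call(rbind, lapply(names(restricted_proteome), function(p)
    coverage_depth(accepted1, p, restricted_proteome)))

  structure(list(pass1 = accepted1, pass2 = arg2, surviving = surviving,
                 exclusions = exclusions, sites = sites, coverage = coverage,
                 config = cfg),
            class = "two_pass_result")
}

#' @export
print.two_pass_result <- function(x, ...) {
  cat(sprintf(paste0("<two_pass_result> pass1 accepted: %d | pass2 ",
                     "arginylated: %d | surviving: %d (excluded: %d)\n"),
              nrow(x$pass1), nrow(x$pass2), nrow(x$surviving),
              nrow(x$exclusions)))
  invisible(x)
}

#' Write the result tables of a two-pass run
#'
#' Writes evidence.tsv (surviving arginylated PSMs), sites.tsv,
#' coverage.tsv, and exclusions.tsv into a directory.
#'
#' @param result A [run_two_pass()] result.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_two_pass <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_id_tsv(result$surviving, file.path(dir, "evidence.tsv"))
  write_id_tsv(result$sites, file.path(dir, "sites.tsv"))
  write_id_tsv(result$coverage, file.path(dir, "coverage.tsv"))
  write_id_tsv(result$exclusions, file.path(dir, "exclusions.tsv"))
  invisible(dir)
}
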