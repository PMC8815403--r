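# In-silico trypsin/P digestion and peptidoform enumeration.

#' Digestion / enumeration configuration
#'
#' @param missed_cleavages Maximum missed cleavages per peptide.
#' @param min_length,max_length Peptide length bounds (residues).
#' @param max_var_mods Maximum variable modifications per peptidoform.
#' @return List of class `digest_config`.
#' @export
digest_config <- function(missed_cleavages = 2L, min_length = 7L,
                          max_length = 30L, max_var_mods = 5L) {
  stopifnot(missed_cleavages >= 0L, min_length >= 1L,
            max_length >= min_length, max_var_mods >= 0L)
  structure(list(missed_cleavages = as.integer(missed_cleavages),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 max_var_mods = as.integer(max_var_mods)),
            class = "digest_config")
}

#' Trypsin/P in-silico digestion
#'
#' Cleaves C-terminal to every K or R, with no suppression before proline
#' (the trypsin/P rule). Returns every product with at most
#' `cfg$missed_cleavages` internal missed cleavages and a length within the
#' configured range.
#'
#' @param sequence Protein sequence (standard residues).
#' @param cfg A [digest_config()].
#' @return data.frame with columns start, end (1-based inclusive), sequence,
#'   missed. Empty input gives a zero-row frame.
#' @export
#' @examples
#' digest_trypsin_p("MKAVEDLRK", digest_config(0, min_length = 1))$sequence
digest_trypsin_p <- function(sequence, cfg = digest_config()) {
  empty <- data.frame(start = integer(), end = integer(),
                      sequence = character(), missed = integer(),
                      stringsAsFactors = FALSE)
  if (!nzchar(sequence)) return(empty)
  aa <- .residues(sequence)
  n <- length(aa)
  cuts <- which(aa %in% c("K", "R"))          # cleave after these positions
  bounds <- unique(c(0L, cuts, n))            # segment boundaries
  nb <- length(bounds)
  out <- vector("list", nb - 1L)
  for (i in seq_len(nb - 1L)) {
    jmax <- min(nb, i + 1L + cfg$missed_cleavages)
    js <- (i + 1L):jmax
    st <- bounds[i] + 1L
    en <- bounds[js]
    len <- en - st + 1L
    keep <- len >= cfg$min_length & len <= cfg$max_length
    if (!any(keep)) next
    out[[i]] <- data.frame(start = st, end = en[keep],
                           sequence = substring(sequence, st, en[keep]),
                           missed = (js - i - 1L)[keep],
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$start, res$end), , drop = FALSE]
}

## Candidate variable-modification placements for one peptide.
## Returns data.frame(pos, name, delta, is_arginylation).
.var_placements <- function(aa, registry, protein_nterm) {
  var <- registry[registry$mode == "variable", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(var))) {
    spec <- var$specificity[i]
    if (spec == "peptide N-term") {
      pos <- 0L
    } else if (spec == "protein N-term") {
      if (!protein_nterm) next  # start <= 2: initiator-Met cleavage counts
      pos <- 0L
    } else {
      pos <- which(aa %in% strsplit(spec, "", fixed = TRUE)[[1L]])
      if (!length(pos)) next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(pos = pos, name = var$name[i], delta = var$delta[i],
                 is_arginylation = var$is_arginylation[i],
                 stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(pos = integer(), name = character(), delta = numeric(),
                      is_arginylation = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Enumerate peptidoforms of a digested peptide
#'
#' Applies fixed modifications everywhere their specificity matches, then
#' enumerates all combinations of variable modifications up to
#' `cfg$max_var_mods`, with at most one modification per position and at most
#' one arginylation per peptidoform (side chains of D/E, or the peptide
#' N-terminus when the registry allows it). Ordering is deterministic:
#' by number of variable modifications, then by canonical mods string.
#'
#' @param sequence Peptide sequence.
#' @param start 1-based start of the peptide in its protein (position 1 makes
#'   protein-N-terminal modifications eligible).
#' @param registry Modification registry (see [default_modifications()]).
#' @param cfg A [digest_config()] (only `max_var_mods` is used).
#' @param protein Protein id to stamp on each row.
#' @return data.frame: protein, start, end, sequence, mods (canonical string),
#'   n_var_mods, arg_pos (0 = N-terminal arginylation, NA = none), arg_name,
#'   neutral_mass. One row per peptidoform.
#' @export
enumerate_peptidoforms <- function(sequence, start = 1L,
                                   registry = default_modifications(),
                                   cfg = digest_config(),
                                   protein = NA_character_) {
  aa <- .residues(sequence)
  n <- length(aa)
  base_mass <- sum(residue_masses()[aa]) + WATER_MASS

  fixed <- registry[registry$mode == "fixed", , drop = FALSE]
  fpos <- integer(); fname <- character(); fdelta <- 0
  for (i in seq_len(nrow(fixed))) {
    hits <- which(aa %in% strsplit(fixed$specificity[i], "", fixed = TRUE)[[1L]])
    fpos <- c(fpos, hits)
    fname <- c(fname, rep(fixed$name[i], length(hits)))
  }
  fdelta <- if (length(fpos)) sum(.mod_delta(fname, registry)) else 0

  pl <- .var_placements(aa, registry, protein_nterm = (start <= 2L))
  arg_pl <- pl[pl$is_arginylation, , drop = FALSE]
  oth_pl <- pl[!pl$is_arginylation, , drop = FALSE]

  ## subsets of non-arginylation placements, <= 1 per position
  subsets <- list(integer(0))
  if (nrow(oth_pl)) {
    kmax <- min(cfg$max_var_mods, nrow(oth_pl))
    for (k in seq_len(kmax)) {
      cmb <- utils::combn(nrow(oth_pl), k, simplify = FALSE)
      cmb <- Filter(function(ix) !anyDuplicated(oth_pl$pos[ix]), cmb)
      subsets <- c(subsets, cmb)
    }
  }

  rows <- list()
  add_row <- function(pos, name, delta_extra, n_var, arg_pos, arg_name) {
    rows[[length(rows) + 1L]] <<- list(
      mods = .mods_string(c(fpos, pos), c(fname, name)),
      n_var = n_var, arg_pos = arg_pos, arg_name = arg_name,
      mass = base_mass + fdelta + delta_extra)
  }
  for (s in subsets) {
    pos <- oth_pl$pos[s]; name <- oth_pl$name[s]
    dsum <- sum(oth_pl$delta[s])
    add_row(pos, name, dsum, length(s), NA_integer_, NA_character_)
    if (length(s) < cfg$max_var_mods && nrow(arg_pl)) {
      for (j in seq_len(nrow(arg_pl))) {
        if (arg_pl$pos[j] %in% pos) next
        add_row(c(pos, arg_pl$pos[j]), c(name, arg_pl$name[j]),
                dsum + arg_pl$delta[j], length(s) + 1L,
                arg_pl$pos[j], arg_pl$name[j])
      }
    }
  }

  res <- data.frame(
    protein = protein, start = as.integer(start),
    end = as.integer(start + n - 1L), sequence = sequence,
    mods = vapply(rows, `[[`, "", "mods"),
    n_var_mods = vapply(rows, `[[`, 1L, "n_var"),
    arg_pos = vapply(rows, `[[`, 1L, "arg_pos"),
    arg_name = vapply(rows, `[[`, "", "arg_name"),
    neutral_mass = vapply(rows, `[[`, 1, "mass"),
    stringsAsFactors = FALSE)
  res <- res[order(res$n_var_mods, res$mods), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Convert one enumeration row to a peptidoform object
#'
#' @param row One row of the frame returned by [enumerate_peptidoforms()].
#' @param registry Modification registry used for the enumeration.
#' @return A [peptidoform()].
#' @export
peptidoform_from_row <- function(row, registry = default_modifications()) {
  peptidoform(row$sequence, mods = row$mods, protein = row$protein,
              start = row$start, end = row$end, registry = registry)
}

# ---------------------------------------------------------------------------
# FASTA
# ---------------------------------------------------------------------------

#' Read a protein FASTA file
#'
#' Multi-record, wrapped lines; record ids are truncated at the first
#' whitespace. Optionally appends a contaminants FASTA.
#'
#' @param path FASTA path.
#' @param contaminants Optional second FASTA whose records are appended with
#'   a `CON_` id prefix.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, contaminants = NULL) {
  ss <- Biostrings::readAAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (!is.null(contaminants)) {
    con <- read_fasta(contaminants)
    names(con) <- paste0("CON_", names(con))
    seqs <- c(seqs, con)
  }
  if (anyDuplicated(names(seqs))) stop("duplicate FASTA record ids")
  seqs
}

#' Write a protein FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
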