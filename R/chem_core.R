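## Monoisotopic constants (Da). 5-decimal standard values; the printed
## precursor m/z of the worked peptide examples reproduce at this precision.
PROTON_MASS <- 1.007276
WATER_MASS  <- 18.01056

#' Monoisotopic residue mass table
#'
#' Returns the monoisotopic residue (not amino-acid) masses in Da for the 20
#' standard residues, keyed by one-letter code. I and L are isobaric.
#'
#' @return Named numeric vector of length 20.
#' @export
#' @examples
#' residue_masses()[["G"]]  # 57.02146
residue_masses <- function() {
  c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
    D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
    H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
}

## split a sequence into residues, rejecting unknown codes
.residues <- function(sequence) {
  rm <- residue_masses()
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(aa, names(rm))
  if (length(bad))
    stop("unknown_residue: residue code(s) not in the standard table: ",
         paste(unique(bad), collapse = ", "))
  aa
}

.residue_mass_vec <- function(sequence) {
  unname(residue_masses()[.residues(sequence)])
}

# ---------------------------------------------------------------------------
# Modifications
# ---------------------------------------------------------------------------

#' Construct a modification definition
#'
#' A modification is a mass delta with a placement rule. `specificity` is a
#' string of residue one-letter codes (side-chain placement), or one of
#' `"peptide N-term"` / `"protein N-term"` for terminal placement.
#'
#' @param name Unique modification name (no `;` or `@` characters).
#' @param delta Monoisotopic mass delta in Da.
#' @param specificity Residue codes, `"peptide N-term"`, or `"protein N-term"`.
#' @param mode `"fixed"` (always applied) or `"variable"`.
#' @param is_arginylation Logical; arginyl additions get at most one placement
#'   per peptidoform.
#' @return One-row data.frame.
#' @export
modification <- function(name, delta, specificity,
                         mode = c("variable", "fixed"),
                         is_arginylation = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.character(name), length(name) == 1L, nchar(name) > 0L)
  if (grepl("[;@]", name)) stop("modification name must not contain ';' or '@'")
  if (!is.finite(delta)) stop("modification delta must be finite")
  data.frame(name = name, delta = delta, specificity = specificity,
             mode = mode, is_arginylation = is_arginylation,
             stringsAsFactors = FALSE)
}

#' Default modification registry
#'
#' Fixed carbamidomethyl on Cys (iodoacetamide alkylation), variable protein
#' N-terminal acetylation and Met oxidation, and — when `arginylation = TRUE`
#' — variable addition of Arg, monomethyl-Arg, and dimethyl-Arg restricted to
#' D/E side chains and (when `nterm_arginylation = TRUE`) to the peptide
#' N-terminus. Arginyl deltas are the Arg residue mass plus 0, 1, or 2 CH2
#' (14.01565 Da each).
#'
#' Arginylation occurs in vivo, before digestion, so the N-terminal variants
#' are restricted to the protein N-terminus: an internal tryptic peptide's
#' N-terminus did not exist when the transferase acted, and a free-floating
#' peptide-N-term placement would be fragment-indistinguishable from a
#' side-chain placement on residue 1.
#'
#' @param arginylation Include the arginylation modifications?
#' @param nterm_arginylation Also allow arginylation on the protein N-terminus?
#' @return data.frame registry (one row per modification).
#' @export
default_modifications <- function(arginylation = TRUE,
                                  nterm_arginylation = TRUE) {
  regs <- list(
    modification("Carbamidomethyl (C)", 57.02146, "C", mode = "fixed"),
    modification("Acetyl (Protein N-term)", 42.01057, "protein N-term"),
    modification("Oxidation (M)", 15.99491, "M")
  )
  if (arginylation) {
    regs <- c(regs, list(
      modification("Arg (DE)",        156.10111, "DE", is_arginylation = TRUE),
      modification("MethylArg (DE)",  170.11676, "DE", is_arginylation = TRUE),
      modification("DimethylArg (DE)", 184.13241, "DE", is_arginylation = TRUE)))
    if (nterm_arginylation) {
      regs <- c(regs, list(
        modification("Arg (N-term)",        156.10111, "protein N-term",
                     is_arginylation = TRUE),
        modification("MethylArg (N-term)",  170.11676, "protein N-term",
                     is_arginylation = TRUE),
        modification("DimethylArg (N-term)", 184.13241, "protein N-term",
                     is_arginylation = TRUE)))
    }
  }
  do.call(rbind, regs)
}

#' Read / write a modification registry as TSV
#'
#' Columns: name, delta, specificity, mode, is_arginylation.
#'
#' @param path File path.
#' @param registry Registry data.frame (see [default_modifications()]).
#' @return `read_modifications` returns the registry data.frame.
#' @export
read_modifications <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "delta", "specificity", "mode", "is_arginylation")
  if (!all(need %in% names(df)))
    stop("modification TSV must have columns: ", paste(need, collapse = ", "))
  df$is_arginylation <- as.logical(df$is_arginylation)
  df
}

#' @rdname read_modifications
#' @export
write_modifications <- function(registry, path) {
  utils::write.table(registry, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## delta lookup by name
.mod_delta <- function(names, registry) {
  idx <- match(names, registry$name)
  if (anyNA(idx)) stop("unknown modification name(s): ",
                       paste(names[is.na(idx)], collapse = ", "))
  registry$delta[idx]
}

## canonical mods string: "name@pos;name@pos" sorted by position then name.
## Position 0 denotes the peptide N-terminus.
.mods_string <- function(pos, name) {
  if (length(pos) == 0L) return("")
  o <- order(pos, name)
  paste(sprintf("%s@%d", name[o], pos[o]), collapse = ";")
}

#' Parse a canonical modification string
#'
#' The canonical form is `"name@pos"` entries joined by `";"`, position 0
#' meaning the peptide N-terminus.
#'
#' @param mods Canonical string (may be `""`).
#' @param registry Modification registry for delta lookup.
#' @return data.frame with columns pos, name, delta, is_arginylation.
#' @export
parse_mods <- function(mods, registry) {
  if (is.na(mods) || !nzchar(mods))
    return(data.frame(pos = integer(), name = character(), delta = numeric(),
                      is_arginylation = logical(), stringsAsFactors = FALSE))
  parts <- strsplit(mods, ";", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^(.*)@(\\d+)$", parts))
  if (any(vapply(m, length, 1L) != 3L))
    stop("malformed modification string: ", mods)
  name <- vapply(m, `[`, "", 2L)
  pos <- as.integer(vapply(m, `[`, "", 3L))
  idx <- match(name, registry$name)
  if (anyNA(idx)) stop("unknown modification name(s): ",
                       paste(name[is.na(idx)], collapse = ", "))
  data.frame(pos = pos, name = name, delta = registry$delta[idx],
             is_arginylation = registry$is_arginylation[idx],
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Peptidoform
# ---------------------------------------------------------------------------

#' Construct a peptidoform
#'
#' A peptide from a named protein with positioned modifications — the unit of
#' identification. Modification positions are 1-based within the peptide;
#' position 0 is the peptide N-terminus. At most one arginylation is allowed,
#' and side-chain arginylation must sit on D or E.
#'
#' @param sequence Peptide residue sequence (standard one-letter codes).
#' @param mods data.frame with columns pos, name, delta and optionally
#'   is_arginylation; or a canonical string plus `registry`.
#' @param protein Protein identifier (optional bookkeeping).
#' @param start,end 1-based inclusive span in the protein.
#' @param registry Registry used when `mods` is given as a string.
#' @return Object of class `peptidoform`.
#' @export
#' @examples
#' pf <- peptidoform("GIADPEESSPNMIVYCK",
#'                   mods = "MethylArg (DE)@4;Carbamidomethyl (C)@16",
#'                   registry = default_modifications())
#' neutral_mass(pf)
peptidoform <- function(sequence, mods = NULL, protein = NA_character_,
                        start = 1L, end = start + nchar(sequence) - 1L,
                        registry = default_modifications()) {
  aa <- .residues(sequence)
  n <- length(aa)
  if (is.null(mods)) {
    mods <- data.frame(pos = integer(), name = character(), delta = numeric(),
                       is_arginylation = logical(), stringsAsFactors = FALSE)
  } else if (is.character(mods)) {
    mods <- parse_mods(mods, registry)
  }
  if (is.null(mods$is_arginylation))
    mods$is_arginylation <- grepl("Arg", mods$name) &
      !grepl("^Carbamidomethyl", mods$name)
  if (any(mods$pos < 0L | mods$pos > n))
    stop("modification position outside 0..", n)
  n_arg <- sum(mods$is_arginylation)
  if (n_arg > 1L) stop("at most one arginylation per peptidoform")
  if (n_arg == 1L) {
    ap <- mods$pos[mods$is_arginylation]
    if (ap > 0L && !(aa[ap] %in% c("D", "E")))
      stop("side-chain arginylation only on D or E residues (position ", ap,
           " is ", aa[ap], ")")
  }
  if (end - start + 1L != n) stop("start/end span does not match sequence length")
  structure(list(protein = protein, start = as.integer(start),
                 end = as.integer(end), sequence = sequence,
                 mods = mods[order(mods$pos, mods$name), , drop = FALSE]),
            class = "peptidoform")
}

#' @export
print.peptidoform <- function(x, ...) {
  ms <- .mods_string(x$mods$pos, x$mods$name)
  cat(sprintf("<peptidoform> %s [%s %d-%d]%s\n", x$sequence,
              x$protein, x$start, x$end,
              if (nzchar(ms)) paste0(" + ", ms) else ""))
  invisible(x)
}

#' Neutral monoisotopic mass of a peptidoform
#'
#' Sum of residue masses plus one water plus all modification deltas.
#' Additive in modifications (bit-exact).
#'
#' @param pf A [peptidoform()], or a plain sequence string (no modifications).
#' @return Mass in Da.
#' @export
neutral_mass <- function(pf) {
  if (is.character(pf)) pf <- peptidoform(pf)
  sum(.residue_mass_vec(pf$sequence)) + WATER_MASS + sum(pf$mods$delta)
}

#' Precursor m/z of a peptidoform at a given charge
#'
#' @param pf A [peptidoform()] (or plain sequence).
#' @param z Positive integer charge.
#' @return (neutral mass + z * 1.007276) / z.
#' @export
precursor_mz <- function(pf, z) {
  z <- as.integer(z)
  if (length(z) != 1L || is.na(z) || z < 1L) stop("charge z must be >= 1")
  (neutral_mass(pf) + z * PROTON_MASS) / z
}

#' b/y fragment ion ladder of a peptidoform
#'
#' Singly or doubly protonated b and y ions. Modifications contribute to
#' exactly the ions containing the modified residue; N-terminal modifications
#' (position 0) travel with the b series prefix ions.
#'
#' @param pf A [peptidoform()].
#' @param series `"b"` or `"y"`.
#' @param z Fragment charge (>= 1).
#' @return Numeric vector of length `nchar(sequence) - 1` (b1..b(n-1) or
#'   y1..y(n-1)).
#' @export
fragment_ladder <- function(pf, series = c("b", "y"), z = 1L) {
  series <- match.arg(series)
  z <- as.integer(z)
  if (is.na(z) || z < 1L) stop("fragment charge must be >= 1")
  if (is.character(pf)) pf <- peptidoform(pf)
  rm <- .residue_mass_vec(pf$sequence)
  n <- length(rm)
  dv <- numeric(n)
  nterm <- 0
  if (nrow(pf$mods)) {
    side <- pf$mods$pos > 0L
    if (any(side)) dv[pf$mods$pos[side]] <- dv[pf$mods$pos[side]] +
        pf$mods$delta[side]
    nterm <- sum(pf$mods$delta[!side])
  }
  if (series == "b") {
    prefix <- cumsum(rm + dv)[seq_len(n - 1L)] + nterm
    (prefix + z * PROTON_MASS) / z
  } else {
    ## suffix sums over the last i residues, i = 1..n-1
    suffix <- cumsum(rev(rm + dv))[seq_len(n - 1L)]
    (suffix + WATER_MASS + z * PROTON_MASS) / z
  }
}

## fast internal ladder for scoring: both series, given charges, one numeric
## vector; seq given as residue-mass vector plus per-position deltas.
.ladder_mz <- function(rmass, dvec, nterm_delta, charges) {
  n <- length(rmass)
  if (n < 2L) return(numeric())
  tot <- rmass + dvec
  prefix <- cumsum(tot)[seq_len(n - 1L)] + nterm_delta
  suffix <- cumsum(rev(tot))[seq_len(n - 1L)]
  out <- numeric(0)
  for (z in charges) {
    out <- c(out, (prefix + z * PROTON_MASS) / z,
             (suffix + WATER_MASS + z * PROTON_MASS) / z)
  }
  out
}
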