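# Ground-truth synthetic data: proteomes, tryptic MS/MS spectra, retinal
# section image pairs, and paired value tables. Every generator is
# deterministic for a given seed and returns a truth ledger alongside the
# artifact.

.rand_protein <- function(len, de_density, kr_spacing) {
  other <- setdiff(names(residue_masses()), c("K", "R", "D", "E"))
  u <- stats::runif(len)
  aa <- character(len)
  is_kr <- u < 1 / kr_spacing
  is_de <- !is_kr & u < 1 / kr_spacing + de_density
  aa[is_kr] <- sample(c("K", "R"), sum(is_kr), replace = TRUE)
  aa[is_de] <- sample(c("D", "E"), sum(is_de), replace = TRUE)
  aa[!is_kr & !is_de] <- sample(other, sum(!is_kr & !is_de), replace = TRUE)
  paste(aa, collapse = "")
}

#' Generate a synthetic proteome with known composition
#'
#' Random proteins with controllable D/E frequency (arginylatable side-chain
#' density) and mean K/R spacing (tryptic peptide length). Optionally embeds
#' given peptides into carrier proteins at tryptic boundaries so they are
#' recovered exactly by trypsin/P digestion; the flanking residue before an
#' internal embed is configurable (use `"R"` to construct terminal-Arg
#' confound cases).
#'
#' @param seed Integer seed.
#' @param n_proteins Number of random proteins.
#' @param length_range Protein length range (residues).
#' @param de_density Per-residue probability of D or E.
#' @param kr_spacing Mean residues between K/R sites.
#' @param embed Optional data.frame with columns `sequence`, `where`
#'   (`"internal"` or `"nterm"`), and optionally `flank_before` (default
#'   `"K"`); each row is planted in its own carrier protein.
#' @return List: `proteome` (named character vector) and `ledger`
#'   (data.frame protein, start, end, sequence for the embedded peptides).
#' @export
make_proteome <- function(seed, n_proteins = 20L,
                          length_range = c(200L, 400L), de_density = 0.12,
                          kr_spacing = 12, embed = NULL) {
  stopifnot(de_density >= 0, de_density <= 1)
  set.seed(seed)
  proteome <- character(0)
  if (n_proteins > 0L) {
    lens <- sample(length_range[1L]:length_range[2L], n_proteins,
                   replace = TRUE)
    proteome <- vapply(lens, .rand_protein, "", de_density = de_density,
                       kr_spacing = kr_spacing)
    names(proteome) <- sprintf("SYN%03d", seq_len(n_proteins))
  }
  ledger <- data.frame(protein = character(), start = integer(),
                       end = integer(), sequence = character(),
                       stringsAsFactors = FALSE)
  if (!is.null(embed) && nrow(embed)) {
    if (is.null(embed$flank_before)) embed$flank_before <- "K"
    for (i in seq_len(nrow(embed))) {
      pep <- embed$sequence[i]
      id <- sprintf("CARRIER%02d", i)
      if (identical(embed$where[i], "nterm")) {
        tail_seq <- .rand_protein(150L, de_density, kr_spacing)
        prot <- paste0(pep, "A", tail_seq)
        start <- 1L
      } else {
        head_seq <- .rand_protein(80L, de_density, kr_spacing)
        tail_seq <- .rand_protein(80L, de_density, kr_spacing)
        prot <- paste0(head_seq, embed$flank_before[i], pep, "A", tail_seq)
        start <- nchar(head_seq) + 2L
      }
      proteome[[id]] <- prot
      ledger <- rbind(ledger, data.frame(
        protein = id, start = start, end = start + nchar(pep) - 1L,
        sequence = pep, stringsAsFactors = FALSE))
    }
  }
  list(proteome = proteome, ledger = ledger)
}

#' Simulate tryptic MS/MS spectra of known peptidoforms
#'
#' Each spectrum carries the full (or subsampled) singly/doubly charged b/y
#' ladder of its true peptidoform with log-normal fragment intensities,
#' plus uniform noise peaks over the ladder's m/z span, with the precursor
#' m/z jittered uniformly within the given ppm. Deterministic per seed; the
#' same seed reproduces byte-identical spectra.
#'
#' @param pfs data.frame with columns `sequence`, `mods` (canonical string,
#'   may be ""), `charge`, and optionally `protein`, `start`, `end`.
#' @param seed Integer seed.
#' @param ladder_fraction Fraction of theoretical ions retained (0, 1].
#' @param n_noise_peaks Uniform noise peaks per spectrum.
#' @param ppm_jitter Half-width of the uniform precursor jitter (ppm).
#' @param intensity_meanlog,intensity_sdlog Log-normal fragment intensity
#'   parameters.
#' @param noise_intensity_meanlog Log-normal meanlog for noise peaks.
#' @param registry Modification registry for the `mods` strings.
#' @return List: `spectra` (list of [spectrum()]) and `ledger` (one row per
#'   spectrum: scan, protein, start, end, sequence, mods, charge, arg_pos,
#'   arg_site_protein).
#' @export
simulate_spectra <- function(pfs, seed, ladder_fraction = 1,
                             n_noise_peaks = 0L, ppm_jitter = 0,
                             intensity_meanlog = log(1e4),
                             intensity_sdlog = 0.5,
                             noise_intensity_meanlog = log(5e2),
                             registry = default_modifications()) {
  stopifnot(ladder_fraction > 0, ladder_fraction <= 1)
  set.seed(seed)
  n <- nrow(pfs)
  spectra <- vector("list", n)
  led <- vector("list", n)
  for (i in seq_len(n)) {
    seqc <- pfs$sequence[i]
    z <- as.integer(pfs$charge[i])
    md <- parse_mods(if (is.null(pfs$mods)) "" else pfs$mods[i], registry)
    rmass <- .residue_mass_vec(seqc)
    dvec <- numeric(length(rmass))
    nterm <- 0
    if (nrow(md)) {
      side <- md$pos > 0L
      if (any(side)) dvec[md$pos[side]] <- dvec[md$pos[side]] +
          md$delta[side]
      nterm <- sum(md$delta[!side])
    }
    ladder <- .ladder_mz(rmass, dvec, nterm, .frag_charges(z))
    nkeep <- max(1L, round(ladder_fraction * length(ladder)))
    keep <- sort(sample(seq_along(ladder), nkeep))
    mz <- ladder[keep]
    it <- stats::rlnorm(nkeep, intensity_meanlog, intensity_sdlog)
    if (n_noise_peaks > 0L) {
      span <- range(ladder)
      nz <- stats::runif(n_noise_peaks, 0.9 * span[1L], 1.1 * span[2L])
      mz <- c(mz, nz)
      it <- c(it, stats::rlnorm(n_noise_peaks, noise_intensity_meanlog,
                                intensity_sdlog))
    }
    neutral <- sum(rmass) + WATER_MASS + sum(md$delta)
    prec <- (neutral + z * PROTON_MASS) / z
    if (ppm_jitter > 0)
      prec <- prec * (1 + stats::runif(1, -ppm_jitter, ppm_jitter) * 1e-6)
    scan <- sprintf("scan_%05d", i)
    spectra[[i]] <- spectrum(scan, prec, z, mz, it)
    arg_pos <- if (nrow(md) && any(md$is_arginylation))
      md$pos[md$is_arginylation][1L] else NA_integer_
    start <- if (is.null(pfs$start)) NA_integer_ else pfs$start[i]
    led[[i]] <- data.frame(
      scan = scan,
      protein = if (is.null(pfs$protein)) NA_character_ else pfs$protein[i],
      start = start,
      end = if (is.null(pfs$end)) NA_integer_ else pfs$end[i],
      sequence = seqc,
      mods = if (is.null(pfs$mods)) "" else pfs$mods[i],
      charge = z, arg_pos = arg_pos,
      arg_site_protein = if (!is.na(arg_pos) && arg_pos > 0L &&
                             !is.na(start)) start + arg_pos - 1L
                         else NA_integer_,
      stringsAsFactors = FALSE)
  }
  list(spectra = spectra, ledger = do.call(rbind, led))
}

#' Simulate a WT/KO pair of retinal section images
#'
#' Emulates the quantified geometry: two bright bands of synaptic processes
#' (Gaussian cross-section along horizontal centerlines, standing in for the
#' two SAC bands in the inner plexiform layer) over a uniform non-specific
#' background, with a designated ONL background region below them and
#' additive Gaussian noise. Band amplitudes are in raw counts above
#' background.
#'
#' @param seed Integer seed.
#' @param wt_amplitude,ko_amplitude Peak band intensity above background.
#' @param band_sigma_um Gaussian band cross-section sigma (micrometres).
#' @param band_separation_um Distance between the two band centerlines.
#' @param background Raw background level (also the ONL level).
#' @param noise_sd Additive Gaussian noise sd (raw counts).
#' @param scale_um_per_px Pixel size.
#' @param width_um Image width.
#' @return List: `wt` and `ko` ([section_image()]s with bands and ONL mask
#'   attached) and `ledger`.
#' @export
simulate_section_pair <- function(seed, wt_amplitude = 300,
                                  ko_amplitude = 300, band_sigma_um = 0.6,
                                  band_separation_um = 10, background = 40,
                                  noise_sd = 4, scale_um_per_px = 0.2,
                                  width_um = 40) {
  stopifnot(wt_amplitude > 0, ko_amplitude > 0, background > 0)
  set.seed(seed)
  px <- scale_um_per_px
  band_y <- c(12, 12 + band_separation_um)           # um
  onl_top <- band_y[2L] + 10; onl_bot <- onl_top + 15
  height_um <- onl_bot + 5
  nr <- round(height_um / px); nc <- round(width_um / px)
  y_um <- (seq_len(nr) - 0.5) * px

  make_one <- function(amp) {
    prof <- background +
      amp * exp(-(y_um - band_y[1L])^2 / (2 * band_sigma_um^2)) +
      amp * exp(-(y_um - band_y[2L])^2 / (2 * band_sigma_um^2))
    img <- matrix(prof, nr, nc) +
      matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
    img[img < 0] <- 0
    mask <- matrix(FALSE, nr, nc)
    onl_rows <- which(y_um >= onl_top & y_um <= onl_bot)
    mask[onl_rows, ] <- TRUE
    attr(mask, "polygon") <- cbind(
      x = c(1, nc, nc, 1),
      y = c(min(onl_rows), min(onl_rows), max(onl_rows), max(onl_rows)))
    xs <- seq(3 / px, (width_um - 3) / px, length.out = 50L)
    bands <- lapply(band_y, function(b)
      cbind(x = xs, y = rep(b / px + 0.5, length(xs))))
    section_image(img, px, mask, bands)
  }
  wt <- make_one(wt_amplitude)
  ko <- make_one(ko_amplitude)
  ledger <- data.frame(genotype = c("WT", "KO"),
                       amplitude = c(wt_amplitude, ko_amplitude),
                       background = background,
                       band_sigma_um = band_sigma_um,
                       noise_sd = noise_sd, seed = seed,
                       stringsAsFactors = FALSE)
  list(wt = wt, ko = ko, ledger = ledger)
}

#' Simulate a paired WT/KO value table
#'
#' Log-normal pair baselines with a multiplicative KO effect; used to
#' exercise the paired statistics on known effect sizes.
#'
#' @param seed Integer seed.
#' @param n_pairs Number of littermate pairs.
#' @param effect True KO/WT ratio.
#' @param cv Within-pair coefficient of variation.
#' @return data.frame: pair, wt, ko; attribute `effect` carries the truth.
#' @export
simulate_paired_table <- function(seed, n_pairs = 7L, effect = 1.5,
                                  cv = 0.1) {
  set.seed(seed)
  base <- stats::rlnorm(n_pairs, 0, 0.3)
  wt <- base * stats::rlnorm(n_pairs, 0, cv)
  ko <- base * effect * stats::rlnorm(n_pairs, 0, cv)
  out <- data.frame(pair = seq_len(n_pairs), wt = wt, ko = ko)
  attr(out, "effect") <- effect
  out
}

# ---------------------------------------------------------------------------
# Worked peptide examples
# ---------------------------------------------------------------------------

#' The published worked peptide examples
#'
#' The arginylated peptidoforms whose precursor m/z values are printed in
#' the source figures: sequence, canonical modification string, charge, the
#' printed m/z, and the printed mass error. One entry (the dimethyl-
#' arginylated RGS7 peptide) ships without a residue sequence: its capped
#' residues were typeset as graphics and the sequence is not recoverable
#' from text, so only its printed precursor and sites are recorded.
#'
#' @return data.frame of worked examples.
#' @export
worked_examples <- function() {
  path <- system.file("extdata", "worked_examples.tsv", package = "argsite")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  df
}

#' Recompute the worked-example precursors
#'
#' Builds each worked-example peptidoform and compares its theoretical
#' precursor m/z with the printed value.
#'
#' @param examples Output of [worked_examples()] (default).
#' @return data.frame with computed m/z and signed ppm deviation from the
#'   printed value; entries without a sequence are dropped.
#' @export
verify_worked_examples <- function(examples = worked_examples()) {
  examples <- examples[!is.na(examples$sequence), , drop = FALSE]
  reg <- default_modifications()
  mz <- vapply(seq_len(nrow(examples)), function(i) {
    pf <- peptidoform(examples$sequence[i], mods = examples$mods[i],
                      registry = reg)
    precursor_mz(pf, examples$charge[i])
  }, 1)
  out <- examples
  out$computed_mz <- mz
  out$ppm_vs_printed <- (mz - out$printed_mz) / out$printed_mz * 1e6
  out
}
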