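# Spectrum container and MGF interchange.

#' Construct an MS/MS spectrum
#'
#' @param scan Scan identifier, unique within a run (MGF TITLE, verbatim).
#' @param precursor_mz Precursor m/z.
#' @param charge Precursor charge (>= 1).
#' @param mz,intensity Fragment peak list; stored sorted ascending by m/z.
#' @return Object of class `spectrum`.
#' @export
spectrum <- function(scan, precursor_mz, charge, mz = numeric(),
                     intensity = numeric()) {
  stopifnot(length(mz) == length(intensity))
  if (length(intensity) && any(intensity < 0)) stop("intensities must be >= 0")
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("charge must be >= 1")
  o <- order(mz)
  structure(list(scan = as.character(scan),
                 precursor_mz = as.numeric(precursor_mz),
                 charge = charge, mz = mz[o], intensity = intensity[o]),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s  precursor %.5f (%d+), %d peaks\n",
              x$scan, x$precursor_mz, x$charge, length(x$mz)))
  invisible(x)
}

#' Read an MGF peak-list file
#'
#' Dialect: `BEGIN IONS`/`END IONS` blocks with `TITLE` (used verbatim as the
#' scan id), `PEPMASS` (first token), `CHARGE` (`3+` or `3`), and one
#' `m/z intensity` pair per line. Scan ids must be unique.
#'
#' @param path MGF path.
#' @return List of [spectrum()] objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS")
  spectra <- vector("list", length(begins))
  for (b in seq_along(begins)) {
    block <- lines[(begins[b] + 1L):(ends[b] - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- sub("=.*$", "", block[kv])
    vals <- sub("^[^=]*=", "", block[kv])
    title <- vals[match("TITLE", keys)]
    pepmass <- vals[match("PEPMASS", keys)]
    charge <- vals[match("CHARGE", keys)]
    if (is.na(title) || is.na(pepmass) || is.na(charge))
      stop("malformed MGF block ", b, ": missing TITLE, PEPMASS or CHARGE")
    pepmass <- suppressWarnings(as.numeric(strsplit(pepmass, "\\s+")[[1L]][1L]))
    z <- suppressWarnings(as.integer(sub("\\+$", "", charge)))
    if (is.na(pepmass) || is.na(z))
      stop("malformed MGF block ", b, ": unparseable PEPMASS or CHARGE")
    peaks <- block[!kv]
    if (length(peaks)) {
      fields <- strsplit(peaks, "\\s+")
      if (any(vapply(fields, length, 1L) < 2L))
        stop("malformed MGF block ", b, ": bad peak line")
      mz <- as.numeric(vapply(fields, `[`, "", 1L))
      it <- as.numeric(vapply(fields, `[`, "", 2L))
      if (anyNA(mz) || anyNA(it))
        stop("malformed MGF block ", b, ": non-numeric peak")
    } else {
      mz <- numeric(); it <- numeric()
    }
    spectra[[b]] <- spectrum(title, pepmass, z, mz, it)
  }
  ids <- vapply(spectra, `[[`, "", "scan")
  if (anyDuplicated(ids))
    stop("duplicate scan ids in MGF: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  spectra
}

#' Write spectra to MGF
#'
#' Floats are written with 5 decimals; `write_mgf` then `read_mgf` is the
#' identity on scan id, precursor m/z, charge, and peaks at that precision.
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  ids <- vapply(spectra, `[[`, "", "scan")
  if (anyDuplicated(ids)) stop("duplicate scan ids")
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", s$scan),
                 sprintf("PEPMASS=%.5f", s$precursor_mz),
                 sprintf("CHARGE=%d+", s$charge),
                 if (length(s$mz)) sprintf("%.5f %.5f", s$mz, s$intensity),
                 "END IONS"), con)
  }
  invisible(path)
}

#' Write an identification table as TSV
#'
#' Used for the evidence, site, coverage, and exclusion tables.
#'
#' @param df data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_id_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_id_tsv
#' @export
read_id_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
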