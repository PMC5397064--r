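# Plain-text readers and writers for the standard interchange formats:
# radial profiles and fit tables as TSV, maps as TSV and float TIFF,
# spectra and TEM profiles as two-column text.

#' Write / read a radial profile as TSV
#'
#' Columns: `q_nm_inv`, `I`, `sd`, `n_pixels`.
#'
#' @param profile a [RadialProfile-class].
#' @param path file path.
#' @return `readRadialProfile` returns a [RadialProfile-class].
#' @export
writeRadialProfile <- function(profile, path) {
  df <- data.frame(q_nm_inv = profile@q, I = profile@intensity,
                   sd = profile@sd, n_pixels = profile@nPixels)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeRadialProfile
#' @export
readRadialProfile <- function(path) {
  df <- read.delim(path)
  RadialProfile(df$q_nm_inv, df$I, sd = df$sd, nPixels = df$n_pixels)
}

#' Write a parameter map as long-format TSV and/or float TIFF
#'
#' @param map a [ParamMap-class].
#' @param path output path; `.tsv` writes columns `x_um`, `y_um`, `value`,
#'   `valid`; `.tif`/`.tiff` writes a 32-bit float image with invalid cells
#'   as `NA` replaced by `fill`.
#' @param fill value written into invalid cells of a TIFF (default 0).
#' @return The path, invisibly.
#' @export
writeParamMap <- function(map, path, fill = 0) {
  stopifnot(is(map, "ParamMap"))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    vals <- map@values
    vals[!map@valid] <- fill
    rng <- range(vals)
    # tiff::writeTIFF stores [0,1] floats; keep scale in a sidecar-free way
    # by writing the raw values when the range allows, else normalized
    tiff::writeTIFF(vals / max(1, max(abs(rng))), path,
                    bits.per.sample = 32L)
  } else {
    ny <- nrow(map@values); nx <- ncol(map@values)
    df <- data.frame(
      x_um = map@origin[1] + (rep(seq_len(nx), each = ny) - 1) * map@pitch[1],
      y_um = map@origin[2] + (rep(seq_len(ny), nx) - 1) * map@pitch[2],
      value = as.vector(map@values),
      valid = as.vector(map@valid))
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a two-column text file as a spectrum or TEM profile
#'
#' Whitespace- or tab-separated, optional header; first column is the
#' abscissa (wavenumber in cm^-1 or position in nm), second the intensity.
#'
#' @param path file path.
#' @param label label attached to a spectrum.
#' @return `readSpectrum` returns a [RamanSpectrum-class]; `readTEMProfile`
#'   a [TEMProfile-class].
#' @export
readSpectrum <- function(path, label = basename(path)) {
  df <- .read_two_col(path)
  RamanSpectrum(df[[1]], df[[2]], label = label)
}

#' @rdname readSpectrum
#' @export
readTEMProfile <- function(path) {
  df <- .read_two_col(path)
  TEMProfile(df[[1]], df[[2]])
}

.read_two_col <- function(path) {
  first <- readLines(path, n = 1)
  hasHeader <- !grepl("^\\s*[-0-9.eE+]+[\\s,\t]+[-0-9.eE+]+\\s*$", first,
                      perl = TRUE)
  df <- read.table(path, header = hasHeader)
  if (ncol(df) < 2) stop("expected two columns in ", path)
  df
}

#' Write a spectrum as two-column text
#' @param spectrum a [RamanSpectrum-class].
#' @param path file path.
#' @export
writeSpectrum <- function(spectrum, path) {
  write.table(data.frame(wavenumber_cm_1 = spectrum@wavenumber,
                         intensity = spectrum@intensity),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fitted scan table as TSV
#' @param fitTable data.frame from [fitScan()].
#' @param path file path.
#' @export
writeFitTable <- function(fitTable, path) {
  write.table(fitTable, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFitTable
#' @export
readFitTable <- function(path) read.delim(path)
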