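## Spectrum file I/O and grid resampling.

#' Default analysis energy grid
#'
#' XANES fits typically use an energy range of about 150-200 eV above the
#' absorption edge; the default grid runs 0-200 eV in 1 eV steps, relative
#' to the edge (edge = 0).
#'
#' @param from,to,by Grid limits and step, eV.
#' @return Numeric energy grid.
#' @export
#' @examples
#' head(analysisGrid())
analysisGrid <- function(from = 0, to = 200, by = 1) seq(from, to, by = by)

#' Read a two- or three-column spectrum file
#'
#' Parses plain-text spectra: columns are energy (eV relative to the edge),
#' normalized absorption, and optionally a per-point error.  Lines starting
#' with `#` are comments; whitespace and commas both delimit.  By the
#' constant-error convention the third column, when present, is collapsed to
#' its arithmetic mean unless `constantEpsilon = FALSE`; without a third
#' column `epsilonDefault` is used.
#'
#' @param path File path.
#' @param epsilonDefault Error applied when the file has no error column.
#' @param constantEpsilon Collapse a per-point error column to its mean
#'   (default TRUE, the convention for normalized edge spectra).
#' @return An [ExperimentalSpectrum-class].  When `constantEpsilon = FALSE`
#'   and a third column is present, the per-point errors are kept in
#'   `meta$epsilonPerPoint` while `epsilon` holds their mean.
#' @export
readSpectrum <- function(path, epsilonDefault = 0.01, constantEpsilon = TRUE) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) stop("no data rows in ", path)
  rows <- lapply(keep, function(i) {
    parts <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (any(is.na(vals)))
      stop(sprintf("non-numeric value on line %d of %s: '%s'",
                   i, path, lines[i]))
    if (!length(vals) %in% c(2L, 3L))
      stop(sprintf("line %d of %s has %d columns; expected 2 or 3",
                   i, path, length(vals)))
    vals
  })
  ncols <- unique(vapply(rows, length, 1L))
  if (length(ncols) != 1L)
    stop("mixed column counts in ", path)
  m <- do.call(rbind, rows)
  e <- m[, 1L]
  if (any(diff(e) <= 0))
    stop("energies must be strictly increasing in ", path)
  meta <- list(source = path)
  if (ncols == 3L) {
    err <- m[, 3L]
    if (any(err <= 0)) stop("error column must be positive in ", path)
    eps <- mean(err)
    if (!constantEpsilon) meta$epsilonPerPoint <- err
  } else {
    eps <- epsilonDefault
  }
  ExperimentalSpectrum(e, m[, 2L], epsilon = eps, meta = meta)
}

#' Write a spectrum as plain text
#'
#' Emits a `#`-commented header naming the units and then two columns
#' (energy_eV, absorption_norm), plus a third constant error column for
#' [ExperimentalSpectrum-class] input.  Values round-trip through
#' [readSpectrum()] to better than 1e-9 relative.
#'
#' @param spec A [Spectrum-class] or [ExperimentalSpectrum-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(spec, path) {
  e <- spec@energies; v <- spec@values
  if (is(spec, "ExperimentalSpectrum")) {
    header <- "# energy_eV absorption_norm error_norm"
    body <- sprintf("%.15g %.15g %.15g", e, v, rep(spec@epsilon, length(e)))
  } else {
    header <- "# energy_eV absorption_norm"
    body <- sprintf("%.15g %.15g", e, v)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Export spectra as CSV
#'
#' Writes aligned curves with unit-bearing column names
#' (`energy_eV`, one column per curve).
#'
#' @param specs Named list of [Spectrum-class] objects on a common grid.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeSpectraCSV <- function(specs, path) {
  stopifnot(length(specs) >= 1L)
  e <- specs[[1L]]@energies
  for (s in specs)
    if (!isTRUE(all.equal(s@energies, e)))
      stop("all spectra must share one grid for CSV export")
  df <- data.frame(energy_eV = e)
  nm <- names(specs)
  if (is.null(nm)) nm <- paste0("curve", seq_along(specs))
  for (i in seq_along(specs)) df[[nm[i]]] <- specs[[i]]@values
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Resample a spectrum onto a target grid
#'
#' Linear interpolation; the target grid must lie within the source grid
#' (no extrapolation).  Exact on piecewise-linear inputs and the identity on
#' the spectrum's own grid.
#'
#' @param spec A [Spectrum-class].
#' @param grid Target energies, strictly increasing, within the source range.
#' @return A [Spectrum-class] on `grid`.
#' @export
resampleSpectrum <- function(spec, grid) {
  e <- spec@energies
  out <- grid[grid < min(e) - 1e-12 | grid > max(e) + 1e-12]
  if (length(out))
    stop(sprintf("cannot extrapolate: target energy %g outside source range [%g, %g]",
                 out[1L], min(e), max(e)))
  v <- approx(e, spec@values, xout = grid, method = "linear",
              ties = "ordered")$y
  Spectrum(grid, v, meta = spec@meta)
}

# Trapezoidal cumulative integral on possibly non-uniform grids.
.cumtrapz <- function(x, y) as.numeric(pracma::cumtrapz(x, y))
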