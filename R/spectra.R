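#' Construct a spectrum
#'
#' A spectrum is a single wavelength-indexed trace with acquisition
#' metadata: fluorescence emission, acceptor molar extinction, a
#' synchronous scan at fixed wavelength offset, a resonance light
#' scattering (RLS) scan, or a circular dichroism trace.
#'
#' @param wavelength numeric, wavelengths in nm; strictly increasing.
#' @param intensity numeric, same length as `wavelength`. Arbitrary
#'   fluorescence units for emission/synchronous/RLS scans, molar
#'   extinction (M^-1 cm^-1) for absorption, ellipticity (mdeg) for CD.
#' @param kind one of `"emission"`, `"absorption"`, `"synchronous"`,
#'   `"rls"`, `"cd"`.
#' @param excitation excitation wavelength in nm, or `NA` if not
#'   applicable.
#' @param delta_lambda excitation-emission offset in nm for synchronous
#'   and RLS scans, or `NA`.
#' @return An object of class `"spectrum"`.
#' @examples
#' s <- spectrum(330:350, dnorm(330:350, 340, 5), kind = "emission",
#'               excitation = 280)
#' emission_maximum(s)
#' @export
spectrum <- function(wavelength, intensity,
                     kind = c("emission", "absorption", "synchronous",
                              "rls", "cd"),
                     excitation = NA_real_, delta_lambda = NA_real_) {
  kind <- match.arg(kind)
  wavelength <- as.numeric(wavelength)
  intensity <- as.numeric(intensity)
  if (length(wavelength) != length(intensity))
    stop("wavelength and intensity must have equal length")
  if (length(wavelength) < 2L)
    stop("a spectrum needs at least two samples")
  if (!all(is.finite(wavelength)) || !all(is.finite(intensity)))
    stop("all wavelengths and intensities must be finite")
  if (any(diff(wavelength) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (kind == "absorption" && any(intensity < 0))
    stop("extinction coefficients must be nonnegative")
  structure(list(wavelength = wavelength, intensity = intensity,
                 kind = kind, excitation = as.numeric(excitation),
                 delta_lambda = as.numeric(delta_lambda)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d points, %.6g-%.6g nm>\n", x$kind,
              length(x$wavelength), min(x$wavelength), max(x$wavelength)))
  if (is.finite(x$excitation))
    cat(sprintf("  excitation: %g nm\n", x$excitation))
  if (is.finite(x$delta_lambda))
    cat(sprintf("  delta-lambda: %g nm\n", x$delta_lambda))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength, intensity = x$intensity)
}

#' Construct a titration series
#'
#' A titration series holds one spectrum per quencher concentration; the
#' first point must be the quencher-free reference, which defines F0 for
#' every quenching analysis.
#'
#' @param spectra list of [spectrum()] objects, one per concentration.
#' @param concentrations numeric, nondecreasing, first element exactly 0.
#' @param unit concentration unit the grid is expressed in (`"M"`,
#'   `"mM"`, `"uM"` or `"nM"`). Fitted constants are reported in the
#'   reciprocal of this unit.
#' @param protein_concentration protein concentration, mM (optional).
#' @param ph,temperature solution pH and temperature in K (optional).
#' @param initial_volume cell volume before titration, mL (optional).
#' @param added_volumes cumulative added titrant volume per point, mL
#'   (optional; used by [correct_dilution()]).
#' @return An object of class `"titration_series"`.
#' @export
titration_series <- function(spectra, concentrations, unit = "mM",
                             protein_concentration = NA_real_,
                             ph = NA_real_, temperature = NA_real_,
                             initial_volume = NA_real_,
                             added_volumes = NULL) {
  if (!is.list(spectra) || !all(vapply(spectra, inherits, logical(1),
                                       "spectrum")))
    stop("spectra must be a list of spectrum objects")
  concentrations <- as.numeric(concentrations)
  if (length(spectra) != length(concentrations))
    stop("need exactly one spectrum per concentration")
  if (length(concentrations) < 2L)
    stop("a titration needs the reference plus at least one addition")
  if (concentrations[1L] != 0)
    stop("first titration point must be at concentration exactly 0 ",
         "(the quencher-free reference that defines F0)")
  if (any(diff(concentrations) < 0))
    stop("concentrations must be nondecreasing")
  unit <- match_conc_unit(unit)
  if (!is.null(added_volumes)) {
    added_volumes <- as.numeric(added_volumes)
    if (length(added_volumes) != length(concentrations))
      stop("added_volumes must align with concentrations")
  }
  structure(list(spectra = spectra, concentrations = concentrations,
                 unit = unit,
                 protein_concentration = as.numeric(protein_concentration),
                 ph = as.numeric(ph), temperature = as.numeric(temperature),
                 initial_volume = as.numeric(initial_volume),
                 added_volumes = added_volumes),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration series: %d points, [Q] %.6g-%.6g %s>\n",
              length(x$concentrations), min(x$concentrations),
              max(x$concentrations), x$unit))
  invisible(x)
}

#' @export
length.titration_series <- function(x) length(x$concentrations)

# canonical concentration units and their size in molar
.conc_units <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)

match_conc_unit <- function(unit) {
  if (!is.character(unit) || length(unit) != 1L ||
      !unit %in% names(.conc_units))
    stop("unit must be one of: ", paste(names(.conc_units), collapse = ", "))
  unit
}

#' Concentration unit conversions
#'
#' `conc_to_molar()` converts a concentration expressed in `unit` to
#' molar; `per_conc_to_per_molar()` converts a reciprocal-concentration
#' constant (such as a Stern-Volmer constant fitted against a mM grid)
#' to reciprocal molar. Conversions are explicit everywhere because
#' quenching constants are conventionally reported in M^-1 while
#' titration grids are commonly recorded in mM.
#'
#' @param x numeric value(s) to convert.
#' @param unit source concentration unit (`"M"`, `"mM"`, `"uM"`, `"nM"`).
#' @return Converted numeric values.
#' @examples
#' per_conc_to_per_molar(2.4e9, "mM")  # 2.4e12 M^-1
#' @export
conc_to_molar <- function(x, unit) {
  unit <- match_conc_unit(unit)
  x * .conc_units[[unit]]
}

#' @rdname conc_to_molar
#' @export
per_conc_to_per_molar <- function(x, unit) {
  unit <- match_conc_unit(unit)
  x / .conc_units[[unit]]
}

#' Inner-filter correction
#'
#' Corrects an observed fluorescence intensity for primary and secondary
#' inner-filter attenuation using the standard half-absorbance form
#' F_corr = F_obs * 10^((A_ex + A_em) / 2).
#'
#' @param f observed intensity (vectorized).
#' @param a_ex absorbance at the excitation wavelength.
#' @param a_em absorbance at the emission wavelength.
#' @return Corrected intensity.
#' @examples
#' correct_inner_filter(100, 0.2, 0.1)  # 141.25
#' @export
correct_inner_filter <- function(f, a_ex, a_em) {
  if (any(a_ex < 0) || any(a_em < 0))
    stop("absorbances must be nonnegative")
  f * 10^((a_ex + a_em) / 2)
}

#' Dilution correction
#'
#' Rescales an intensity for the titrant volume added to the cell:
#' F_corr = F_obs * (v0 + v_added) / v0.
#'
#' @param f observed intensity (vectorized).
#' @param v0 initial cell volume, mL; must be positive.
#' @param v_added cumulative added volume, mL; nonnegative.
#' @return Corrected intensity.
#' @export
correct_dilution <- function(f, v0, v_added) {
  if (any(v0 <= 0)) stop("initial volume must be positive")
  if (any(v_added < 0)) stop("added volume must be nonnegative")
  f * (v0 + v_added) / v0
}

#' Locate the emission maximum of a spectrum
#'
#' Finds the peak wavelength by parabolic interpolation through the
#' maximal sample and its two neighbours, which resolves sub-nm shifts
#' on an integer-nm grid. When the maximal intensity is attained at more
#' than one grid point the lowest such wavelength is returned without
#' interpolation, and when the maximum sits on the grid boundary the
#' boundary wavelength is returned flagged (attribute `"boundary"`).
#'
#' @param s a [spectrum()].
#' @return Peak wavelength in nm, with logical attribute `"boundary"`.
#' @export
emission_maximum <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  y <- s$intensity
  x <- s$wavelength
  n <- length(y)
  if (n < 3L) stop("need at least 3 points to locate a maximum")
  i <- which.max(y)
  ymax <- y[i]
  ties <- which(y == ymax)
  if (length(ties) > 1L)      # plateau: lowest wavelength, no interpolation
    return(structure(x[ties[1L]], boundary = FALSE))
  if (i == 1L || i == n)
    return(structure(x[i], boundary = TRUE))
  # vertex of the parabola through (x[i-1],y[i-1]), (x[i],y[i]), (x[i+1],y[i+1])
  d1 <- x[i] - x[i - 1L]; d2 <- x[i] - x[i + 1L]
  g1 <- y[i] - y[i - 1L]; g2 <- y[i] - y[i + 1L]
  den <- d1 * g2 - d2 * g1
  if (den == 0) return(structure(x[i], boundary = FALSE))
  vx <- x[i] - 0.5 * (d1^2 * g2 - d2^2 * g1) / den
  structure(vx, boundary = FALSE)
}

#' Read and write spectrum CSV files
#'
#' Spectra are exchanged as two-column CSV files with header
#' `wavelength_nm,intensity`.
#'
#' @param path file path.
#' @param kind,excitation,delta_lambda metadata passed to [spectrum()]
#'   (not stored in the CSV itself; carried by the titration manifest).
#' @return `read_spectrum()` returns a [spectrum()]; `write_spectrum()`
#'   returns `path` invisibly.
#' @export
read_spectrum <- function(path, kind = "emission", excitation = NA_real_,
                          delta_lambda = NA_real_) {
  if (!file.exists(path)) stop("no such spectrum file: ", path)
  d <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "intensity") %in% names(d)))
    stop("spectrum CSV must have columns wavelength_nm,intensity: ", path)
  spectrum(d$wavelength_nm, d$intensity, kind = kind,
           excitation = excitation, delta_lambda = delta_lambda)
}

#' @rdname read_spectrum
#' @param s a [spectrum()] to write.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  # 17 significant digits so that values survive a write/read round trip
  # bit-identically
  d <- data.frame(wavelength_nm = sprintf("%.17g", s$wavelength),
                  intensity = sprintf("%.17g", s$intensity))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a titration series from a manifest
#'
#' The manifest is a CSV with columns
#' `concentration,unit,file,excitation_nm,delta_lambda_nm,added_volume_ml`;
#' each row references one spectrum CSV (paths relative to the manifest's
#' directory). Rows are sorted by concentration on load (with a message
#' when reordering was needed); a missing zero-concentration row is a
#' hard error because nothing then defines F0.
#'
#' @param manifest_path path to the manifest CSV.
#' @param kind spectrum kind for every loaded trace.
#' @return A [titration_series()].
#' @export
read_titration <- function(manifest_path, kind = "emission") {
  if (!file.exists(manifest_path))
    stop("no such manifest: ", manifest_path)
  m <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("concentration", "unit", "file", "excitation_nm",
            "delta_lambda_nm", "added_volume_ml")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ","))
  bad <- which(!is.finite(m$concentration) | m$concentration < 0 |
                 is.na(m$file) | m$file == "")
  if (length(bad))
    stop("malformed manifest rows: ", paste(bad, collapse = ", "))
  base <- dirname(manifest_path)
  paths <- file.path(base, m$file)
  missing <- which(!file.exists(paths))
  if (length(missing))
    stop("manifest rows reference missing spectrum files: ",
         paste(missing, collapse = ", "))
  if (is.unsorted(m$concentration)) {
    message("manifest concentrations were not sorted; sorting on load")
    ord <- order(m$concentration)
    m <- m[ord, , drop = FALSE]
    paths <- paths[ord]
  }
  if (m$concentration[1L] != 0)
    stop("manifest has no zero-concentration reference point; ",
         "the first titration point must be at [Q] = 0 to define F0")
  unit <- unique(m$unit)
  if (length(unit) != 1L)
    stop("manifest mixes concentration units: ",
         paste(unit, collapse = ", "))
  spectra <- lapply(seq_len(nrow(m)), function(i)
    read_spectrum(paths[i], kind = kind,
                  excitation = m$excitation_nm[i],
                  delta_lambda = m$delta_lambda_nm[i]))
  titration_series(spectra, m$concentration, unit = unit,
                   added_volumes = m$added_volume_ml)
}

#' Write a titration series as spectrum CSVs plus a manifest
#'
#' @param series a [titration_series()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix for the per-point spectrum CSVs.
#' @return Path of the written manifest, invisibly.
#' @export
write_titration <- function(series, dir, prefix = "point") {
  stopifnot(inherits(series, "titration_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(series$concentrations)
  files <- sprintf("%s_%02d.csv", prefix, seq_len(n))
  for (i in seq_len(n))
    write_spectrum(series$spectra[[i]], file.path(dir, files[i]))
  av <- series$added_volumes
  if (is.null(av)) av <- rep(0, n)
  m <- data.frame(
    concentration = sprintf("%.17g", series$concentrations),
    unit = series$unit,
    file = files,
    excitation_nm = vapply(series$spectra, function(s) s$excitation,
                           numeric(1)),
    delta_lambda_nm = vapply(series$spectra, function(s) s$delta_lambda,
                             numeric(1)),
    added_volume_ml = av)
  manifest <- file.path(dir, paste0(prefix, "_manifest.csv"))
  utils::write.csv(m, manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Per-point fluorescence readout of a titration
#'
#' Reduces every spectrum of a series to one intensity, either the peak
#' intensity (default) or the intensity at a fixed wavelength (linear
#' interpolation).
#'
#' @param series a [titration_series()].
#' @param readout `"peak"` or `"at"`.
#' @param wavelength wavelength in nm, required when `readout = "at"`.
#' @return Numeric vector of intensities, one per titration point.
#' @export
titration_intensities <- function(series, readout = c("peak", "at"),
                                  wavelength = NULL) {
  stopifnot(inherits(series, "titration_series"))
  readout <- match.arg(readout)
  if (readout == "peak")
    return(vapply(series$spectra, function(s) max(s$intensity), numeric(1)))
  if (is.null(wavelength))
    stop("readout = \"at\" requires a wavelength")
  vapply(series$spectra, function(s) {
    if (wavelength < min(s$wavelength) || wavelength > max(s$wavelength))
      stop("readout wavelength ", wavelength, " nm outside scan range")
    stats::approx(s$wavelength, s$intensity, xout = wavelength)$y
  }, numeric(1))
}
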