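#' Resonance light scattering curve
#'
#' Intensity-versus-concentration curve read from a set of
#' delta-lambda = 0 synchronous scans at one wavelength.
#'
#' @param concentrations nondecreasing quencher concentrations.
#' @param intensities scattering intensities, one per concentration.
#' @param unit concentration unit.
#' @param readout_wavelength scan wavelength the intensities were read
#'   at, nm.
#' @return An object of class `"rls_curve"`.
#' @export
rls_curve <- function(concentrations, intensities, unit = "mM",
                      readout_wavelength = NA_real_) {
  concentrations <- as.numeric(concentrations)
  intensities <- as.numeric(intensities)
  if (length(concentrations) != length(intensities))
    stop("concentrations and intensities must align")
  if (any(diff(concentrations) < 0))
    stop("concentrations must be nondecreasing")
  if (!all(is.finite(concentrations)) || !all(is.finite(intensities)))
    stop("all values must be finite")
  structure(list(concentrations = concentrations,
                 intensities = intensities,
                 unit = match_conc_unit(unit),
                 readout_wavelength = as.numeric(readout_wavelength)),
            class = "rls_curve")
}

#' @export
print.rls_curve <- function(x, ...) {
  cat(sprintf("<RLS curve: %d points, [Q] %.4g-%.4g %s>\n",
              length(x$concentrations), min(x$concentrations),
              max(x$concentrations), x$unit))
  invisible(x)
}

#' Extract an RLS curve from a titration of delta-lambda = 0 scans
#'
#' Reads the scattering intensity at one wavelength (linear
#' interpolation) out of every scan of the series. The default readout
#' wavelength is the position of the global scattering maximum of the
#' highest-concentration scan, where aggregation-driven enhancement is
#' largest.
#'
#' @param series a [titration_series()] whose spectra are all of kind
#'   `"rls"`.
#' @param readout_wavelength wavelength in nm, or `NULL` for the
#'   default.
#' @return An [rls_curve()].
#' @export
extract_rls_curve <- function(series, readout_wavelength = NULL) {
  stopifnot(inherits(series, "titration_series"))
  kinds <- vapply(series$spectra, function(s) s$kind, character(1))
  if (!all(kinds == "rls"))
    stop("all spectra must be RLS (delta-lambda = 0) scans")
  last <- series$spectra[[length(series$spectra)]]
  if (is.null(readout_wavelength))
    readout_wavelength <- last$wavelength[which.max(last$intensity)]
  ints <- vapply(series$spectra, function(s) {
    if (readout_wavelength < min(s$wavelength) ||
        readout_wavelength > max(s$wavelength))
      stop("readout wavelength ", readout_wavelength,
           " nm outside the scan range")
    stats::approx(s$wavelength, s$intensity,
                  xout = readout_wavelength)$y
  }, numeric(1))
  rls_curve(series$concentrations, ints, unit = series$unit,
            readout_wavelength = readout_wavelength)
}

# hinge model I(q) = b + m * max(0, q - knot), OLS for fixed knot
hinge_sse <- function(knot, q, i) {
  x <- pmax(0, q - knot)
  fit <- stats::lm.fit(cbind(1, x), i)
  list(sse = sum(fit$residuals^2),
       baseline = fit$coefficients[[1L]],
       slope = fit$coefficients[[2L]])
}

#' Detect the critical induced aggregation concentration
#'
#' Fits a continuous flat-then-linear hinge to an RLS curve: intensity
#' equal to a baseline up to the knot, rising linearly above it. The
#' knot is located by an exhaustive grid search over candidate
#' positions at and between the observed concentrations, refined by
#' local optimisation within the best candidate's bracket, minimising
#' the squared error. The knot of the best model is the critical
#' induced aggregation concentration (C_CIAC): the smallest drug
#' concentration at which scattering - and hence aggregate volume -
#' starts to grow.
#'
#' The hinge is only accepted when it beats the flat-only model by an
#' F-ratio of at least `f_threshold` (default 4.0); otherwise the
#' result is flagged as no onset detected (`detected = FALSE`,
#' `cciac = NA`).
#'
#' @param curve an [rls_curve()] with at least 6 points.
#' @param f_threshold F-ratio acceptance gate for the hinge versus the
#'   flat model.
#' @return An object of class `"cciac_result"`: `cciac`, `baseline`,
#'   `slope_above`, `sse`, `f_ratio`, `detected`, `unit`.
#' @export
detect_cciac <- function(curve, f_threshold = 4.0) {
  stopifnot(inherits(curve, "rls_curve"))
  q <- curve$concentrations
  i <- curve$intensities
  n <- length(q)
  if (n < 6L) stop("C_CIAC detection needs at least 6 points")

  sse_flat <- sum((i - mean(i))^2)
  scale2 <- max(mean(i^2), 1e-300)
  no_onset <- function(f_ratio) structure(
    list(cciac = NA_real_, baseline = mean(i), slope_above = 0,
         sse = sse_flat, f_ratio = f_ratio, detected = FALSE,
         unit = curve$unit), class = "cciac_result")
  if (sse_flat <= n * scale2 * 1e-20)   # strictly flat curve
    return(no_onset(NA_real_))

  qs <- sort(unique(q))
  interior <- qs[qs > qs[1L] & qs < qs[length(qs)]]
  mids <- (qs[-1L] + qs[-length(qs)]) / 2
  cand <- sort(unique(c(interior, mids)))
  sses <- vapply(cand, function(k) hinge_sse(k, q, i)$sse, numeric(1))
  best <- which.min(sses)
  # refine inside the bracket around the best candidate
  lo <- if (best > 1L) cand[best - 1L] else qs[1L]
  hi <- if (best < length(cand)) cand[best + 1L] else qs[length(qs)]
  knot <- cand[best]
  sse <- sses[best]
  if (hi > lo) {
    # tolerance must scale with the bracket: concentrations can be ~1e-7
    opt <- stats::optimize(function(k) hinge_sse(k, q, i)$sse, c(lo, hi),
                           tol = (hi - lo) * 1e-10)
    if (opt$objective < sse) {
      knot <- opt$minimum
      sse <- opt$objective
    }
  }
  fit <- hinge_sse(knot, q, i)
  f_ratio <- if (sse <= sse_flat * 1e-15) Inf else
    ((sse_flat - sse) / 2) / (sse / max(n - 3L, 1L))
  if (!is.finite(f_ratio) && !is.infinite(f_ratio)) f_ratio <- 0
  if (f_ratio < f_threshold) return(no_onset(f_ratio))
  structure(list(cciac = knot, baseline = fit$baseline,
                 slope_above = fit$slope, sse = sse, f_ratio = f_ratio,
                 detected = TRUE, unit = curve$unit),
            class = "cciac_result")
}

#' @export
print.cciac_result <- function(x, ...) {
  if (!x$detected) {
    cat("No aggregation onset detected (flat RLS curve)\n")
  } else {
    cat(sprintf("C_CIAC = %.4g %s (baseline %.4g, slope above %.4g)\n",
                x$cciac, x$unit, x$baseline, x$slope_above))
  }
  invisible(x)
}

#' Read and write RLS curve CSVs
#'
#' Two-column CSV with header `concentration,intensity`.
#'
#' @param path file path.
#' @param unit concentration unit of the stored values.
#' @param readout_wavelength metadata carried onto the curve.
#' @return `read_rls_curve()` returns an [rls_curve()].
#' @export
read_rls_curve <- function(path, unit = "mM",
                           readout_wavelength = NA_real_) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path)
  if (!all(c("concentration", "intensity") %in% names(d)))
    stop("RLS CSV must have columns concentration,intensity")
  rls_curve(d$concentration, d$intensity, unit = unit,
            readout_wavelength = readout_wavelength)
}

#' @rdname read_rls_curve
#' @param curve an [rls_curve()] to write.
#' @export
write_rls_curve <- function(curve, path) {
  stopifnot(inherits(curve, "rls_curve"))
  utils::write.csv(data.frame(concentration = sprintf("%.17g",
                                                      curve$concentrations),
                              intensity = sprintf("%.17g",
                                                  curve$intensities)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
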