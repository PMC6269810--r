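#' Red-edge excitation shift (REES)
#'
#' The REES is the difference between the emission maximum under
#' red-edge excitation (305 nm) and under normal tryptophan excitation
#' (295 nm). A positive REES reports slow solvent relaxation around the
#' Trp residues, i.e. a motionally restricted microenvironment; its
#' decrease upon ligand binding indicates a less congested Trp
#' surrounding.
#'
#' @param s295 emission spectrum excited at the normal wavelength
#'   (295 nm); must carry excitation metadata.
#' @param s305 emission spectrum excited at the red edge (305 nm).
#' @param mode `"raw"` keeps sub-nm peak positions; `"table"` rounds
#'   each maximum to integer nm before differencing, matching how REES
#'   values are conventionally tabulated.
#' @return An object of class `"rees_result"` with elements
#'   `lam_max_295`, `lam_max_305` and `rees = lam_max_305 - lam_max_295`
#'   (nm).
#' @export
rees <- function(s295, s305, mode = c("raw", "table")) {
  mode <- match.arg(mode)
  stopifnot(inherits(s295, "spectrum"), inherits(s305, "spectrum"))
  if (s295$kind != "emission" || s305$kind != "emission")
    stop("REES needs two emission spectra")
  if (!is.finite(s295$excitation) || !is.finite(s305$excitation))
    stop("both spectra must carry excitation metadata")
  l295 <- as.numeric(emission_maximum(s295))
  l305 <- as.numeric(emission_maximum(s305))
  if (mode == "table") {
    l295 <- round(l295)
    l305 <- round(l305)
  }
  structure(list(lam_max_295 = l295, lam_max_305 = l305,
                 rees = l305 - l295), class = "rees_result")
}

#' @export
print.rees_result <- function(x, ...) {
  cat(sprintf("REES: %g nm (lambda_max %g nm @295 -> %g nm @305)\n",
              x$rees, x$lam_max_295, x$lam_max_305))
  invisible(x)
}

#' Synchronous-fluorescence quenching slope
#'
#' For a titration of synchronous scans at one fixed offset
#' (delta-lambda = 15 nm isolates tyrosine, 60 nm tryptophan), fits a
#' straight line of F/F0 (peak readout) against quencher concentration.
#' A steeper negative slope means the corresponding residue class
#' contributes more to the quenched fluorescence. Curvature is not
#' modelled; it is surfaced as the residual RMS. The peak-position
#' shift over the titration is reported as well.
#'
#' @param series a [titration_series()] of synchronous scans sharing a
#'   single delta-lambda.
#' @return An object of class `"synchronous_result"` with elements
#'   `delta_lambda`, `slope` (per concentration unit), `intercept`,
#'   `residual_rms`, `lam_max_shift` (nm, last minus first) and `unit`.
#' @export
synchronous_slope <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  dl <- vapply(series$spectra, function(s) s$delta_lambda, numeric(1))
  kinds <- vapply(series$spectra, function(s) s$kind, character(1))
  if (!all(kinds == "synchronous"))
    stop("series must contain synchronous scans")
  if (length(unique(dl)) != 1L || any(!is.finite(dl)))
    stop("series mixes delta-lambda values: ",
         paste(unique(dl), collapse = ", "))
  f <- titration_intensities(series, "peak")
  ratio <- f / f[1L]
  q <- series$concentrations
  fit <- stats::lm(ratio ~ q)
  lam <- vapply(series$spectra,
                function(s) as.numeric(emission_maximum(s)), numeric(1))
  structure(list(delta_lambda = dl[1L],
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 residual_rms = sqrt(mean(stats::resid(fit)^2)),
                 lam_max_shift = lam[length(lam)] - lam[1L],
                 unit = series$unit),
            class = "synchronous_result")
}

#' @export
print.synchronous_result <- function(x, ...) {
  cat(sprintf(paste0("Synchronous scan (delta-lambda %g nm): ",
                     "slope %.4g per %s, peak shift %.3g nm\n"),
              x$delta_lambda, x$slope, x$unit, x$lam_max_shift))
  invisible(x)
}

#' Track the emission maximum across a titration
#'
#' Locates the emission maximum of every titration point and reports
#' the total red (positive) or blue (negative) shift over the series.
#'
#' @param series an emission [titration_series()].
#' @return An object of class `"red_shift_track"`: a list with
#'   `concentration`, `lambda_max` (nm per point) and `total_shift`
#'   (last minus first, nm).
#' @export
red_shift_track <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  lam <- vapply(series$spectra,
                function(s) as.numeric(emission_maximum(s)), numeric(1))
  structure(list(concentration = series$concentrations,
                 lambda_max = lam,
                 total_shift = lam[length(lam)] - lam[1L],
                 unit = series$unit),
            class = "red_shift_track")
}

#' @export
print.red_shift_track <- function(x, ...) {
  cat(sprintf("Emission-maximum track: total shift %.3g nm over %d points\n",
              x$total_shift, length(x$lambda_max)))
  invisible(x)
}

#' Mean residue ellipticity
#'
#' Converts an observed circular dichroism ellipticity to the molar
#' residue ellipticity [theta] = 100 * theta_obs / (c l), with c the
#' residue concentration in mol cm^-3 and l the path length in cm.
#'
#' @param theta_obs observed ellipticity, degrees (vectorized).
#' @param conc residue concentration, mol cm^-3; positive.
#' @param path path length, cm; positive.
#' @return Mean residue ellipticity, deg cm^2 dmol^-1.
#' @examples
#' mean_residue_ellipticity(0.01, 1e-6, 0.1)  # 1e7
#' @export
mean_residue_ellipticity <- function(theta_obs, conc, path) {
  if (any(conc <= 0)) stop("residue concentration must be positive")
  if (any(path <= 0)) stop("path length must be positive")
  100 * theta_obs / (conc * path)
}

# canonical secondary-structure class labels:
# regular/distorted helix, regular/distorted sheet, turn, unordered
.ss_classes <- c("H_r", "H_d", "S_r", "S_d", "Tr", "Un")

#' Circular dichroism record
#'
#' Bundles an observed ellipticity, its mean-residue-ellipticity
#' conversion and (optionally) externally computed secondary-structure
#' fractions for the six canonical classes: regular and distorted
#' alpha-helix (`H_r`, `H_d`), regular and distorted beta-sheet
#' (`S_r`, `S_d`), turn (`Tr`) and unordered (`Un`), in percent.
#' When fractions are present they must sum to 100 within 0.5.
#'
#' @param fractions named numeric of percents for
#'   `H_r, H_d, S_r, S_d, Tr, Un`, or `NULL`.
#' @param theta_obs observed ellipticity, degrees (optional).
#' @param mre mean residue ellipticity (optional).
#' @param label sample label.
#' @return An object of class `"cd_record"`.
#' @export
cd_record <- function(fractions = NULL, theta_obs = NA_real_,
                      mre = NA_real_, label = NA_character_) {
  if (!is.null(fractions)) {
    if (!all(.ss_classes %in% names(fractions)))
      stop("fractions must be named with: ",
           paste(.ss_classes, collapse = ", "))
    fractions <- fractions[.ss_classes]
    s <- sum(fractions)
    if (abs(s - 100) > 0.5)
      stop(sprintf("secondary-structure fractions sum to %.2f, not 100 +/- 0.5",
                   s))
  }
  structure(list(fractions = fractions, theta_obs = theta_obs,
                 mre = mre, label = label), class = "cd_record")
}

#' Secondary-structure change between two CD records
#'
#' Differences the per-class secondary-structure percentages of a
#' treated sample against the native one and reports whether the change
#' follows the destabilisation pattern expected for ligand-induced
#' partial unfolding: helix and sheet content (regular and distorted)
#' down, unordered content up.
#'
#' @param native,treated [cd_record()]s carrying fractions.
#' @return An object of class `"structure_delta"`: `deltas` (named,
#'   treated minus native, percent points), and logicals `helix_down`,
#'   `sheet_down`, `unordered_up`.
#' @export
structure_delta <- function(native, treated) {
  stopifnot(inherits(native, "cd_record"), inherits(treated, "cd_record"))
  for (r in list(native, treated)) {
    if (is.null(r$fractions))
      stop("both records must carry secondary-structure fractions")
    s <- sum(r$fractions)
    if (abs(s - 100) > 0.5)
      stop(sprintf("fractions sum to %.2f, violating the 100 +/- 0.5 invariant",
                   s))
  }
  d <- treated$fractions - native$fractions
  structure(list(deltas = d,
                 helix_down = all(d[c("H_r", "H_d")] <= 0),
                 sheet_down = all(d[c("S_r", "S_d")] <= 0),
                 unordered_up = d[["Un"]] >= 0,
                 native_label = native$label,
                 treated_label = treated$label),
            class = "structure_delta")
}

#' @export
print.structure_delta <- function(x, ...) {
  cat("Secondary-structure change (treated - native, percent points):\n")
  print(round(x$deltas, 2))
  cat(sprintf("  helix down: %s; sheet down: %s; unordered up: %s\n",
              x$helix_down, x$sheet_down, x$unordered_up))
  invisible(x)
}

#' Read a secondary-structure fraction table
#'
#' Reads a CSV with columns `system,H_r,H_d,S_r,S_d,Tr,Un` (percent)
#' into a named list of [cd_record()]s. Such tables come from external
#' CD deconvolution software; this package only book-keeps them.
#'
#' @param path CSV path.
#' @return Named list of [cd_record()]s.
#' @export
read_structure_fractions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("system", .ss_classes)
  if (!all(need %in% names(d)))
    stop("fraction table must have columns: ", paste(need, collapse = ","))
  recs <- lapply(seq_len(nrow(d)), function(i) {
    fr <- as.numeric(d[i, .ss_classes])
    names(fr) <- .ss_classes
    cd_record(fractions = fr, label = d$system[i])
  })
  names(recs) <- d$system
  recs
}
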