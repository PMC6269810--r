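#' Physical constants for a Forster analysis
#'
#' @param phi donor fluorescence quantum yield. No default: unlike the
#'   orientation factor and refractive index, no universal value is
#'   defensible - it must come from the experiment or the literature
#'   for the specific protein (hen lysozyme Trp yields of roughly
#'   0.06-0.14 have been reported, depending on conditions).
#' @param k2 dipole orientation factor K^2; 2/3 is the isotropic
#'   dynamic-averaging value. Must lie in (0, 4].
#' @param n_ri refractive index of the medium; 1.336 for dilute
#'   aqueous buffer.
#' @return An object of class `"fret_constants"`.
#' @export
fret_constants <- function(phi, k2 = 2 / 3, n_ri = 1.336) {
  if (missing(phi) || is.null(phi) || !is.finite(phi))
    stop("the donor quantum yield phi must be supplied; ",
         "no default is scientifically defensible")
  if (phi <= 0 || k2 <= 0 || n_ri <= 0)
    stop("all Forster constants must be strictly positive")
  if (k2 > 4) stop("the orientation factor K^2 cannot exceed 4")
  structure(list(phi = phi, k2 = k2, n_ri = n_ri),
            class = "fret_constants")
}

# trapezoid rule on an irregular grid
trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

#' Spectral overlap integral
#'
#' Computes J = int F(lambda) eps(lambda) lambda^4 dlambda /
#' int F(lambda) dlambda over the wavelength interval where the donor
#' emission and the acceptor extinction spectra overlap. Both integrals
#' are trapezoidal sums on the donor grid restricted to the overlap,
#' with the acceptor extinction linearly interpolated onto it;
#' wavelengths enter the lambda^4 weight in cm so that J carries units
#' of cm^3 M^-1. The donor normalisation cancels any uniform scaling of
#' the emission spectrum.
#'
#' @param donor_emission donor emission [spectrum()].
#' @param acceptor_extinction acceptor molar extinction [spectrum()]
#'   (M^-1 cm^-1).
#' @return Overlap integral J in cm^3 M^-1.
#' @export
overlap_integral <- function(donor_emission, acceptor_extinction) {
  stopifnot(inherits(donor_emission, "spectrum"),
            inherits(acceptor_extinction, "spectrum"))
  lo <- max(min(donor_emission$wavelength),
            min(acceptor_extinction$wavelength))
  hi <- min(max(donor_emission$wavelength),
            max(acceptor_extinction$wavelength))
  idx <- donor_emission$wavelength >= lo & donor_emission$wavelength <= hi
  if (hi <= lo || sum(idx) < 2L)
    stop("donor and acceptor spectra have no overlapping wavelength ",
         "interval")
  lam_nm <- donor_emission$wavelength[idx]
  f <- donor_emission$intensity[idx]
  eps <- stats::approx(acceptor_extinction$wavelength,
                       acceptor_extinction$intensity,
                       xout = lam_nm)$y
  lam_cm <- lam_nm * 1e-7
  den <- trapz(lam_nm, f)
  if (den <= 0) stop("donor emission integrates to zero on the overlap")
  trapz(lam_nm, f * eps * lam_cm^4) / den
}

#' Forster radius
#'
#' Computes the critical transfer distance from
#' R0^6 = 8.8e-25 K^2 n^-4 phi J (cm^6). The sixth power is required
#' dimensionally: with J in cm^3 M^-1 the right-hand side carries cm^6,
#' and its sixth root is the distance at which transfer efficiency is
#' 50%.
#'
#' @param j overlap integral, cm^3 M^-1; nonnegative.
#' @param constants a [fret_constants()].
#' @return Forster radius R0 in nm.
#' @export
forster_radius <- function(j, constants) {
  stopifnot(inherits(constants, "fret_constants"))
  if (j < 0) stop("the overlap integral cannot be negative")
  r0_6 <- 8.8e-25 * constants$k2 * constants$n_ri^-4 * constants$phi * j
  (r0_6)^(1 / 6) * 1e7     # cm -> nm
}

#' Energy transfer efficiency
#'
#' E = 1 - F/F0, the fraction of donor excitations transferred to the
#' acceptor, from the donor intensity with (`f`) and without (`f0`) the
#' acceptor present.
#'
#' @param f donor intensity with acceptor; must satisfy 0 < f <= f0.
#' @param f0 donor intensity without acceptor.
#' @return Efficiency in [0, 1).
#' @export
transfer_efficiency <- function(f, f0) {
  if (any(f0 <= 0)) stop("reference intensity must be positive")
  if (any(f <= 0)) stop("donor intensity must be positive")
  if (any(f > f0))
    stop("f > f0 implies negative transfer efficiency; check inputs")
  1 - f / f0
}

#' Donor-acceptor distance
#'
#' Inverts E = R0^6 / (R0^6 + r^6) to r = R0 ((1 - E)/E)^(1/6). At
#' E = 0.5 the distance equals the Forster radius exactly; the formula
#' is undefined at E = 0 (infinite distance) and E = 1 (zero
#' distance), which are refused.
#'
#' @param e transfer efficiency, strictly inside (0, 1).
#' @param r0 Forster radius, nm; positive.
#' @return Distance r in nm.
#' @export
donor_acceptor_distance <- function(e, r0) {
  if (any(e <= 0) || any(e >= 1))
    stop("efficiency must lie strictly between 0 and 1")
  if (any(r0 <= 0)) stop("the Forster radius must be positive")
  r0 * ((1 - e) / e)^(1 / 6)
}

#' Full Forster resonance energy transfer analysis
#'
#' Chains [overlap_integral()], [forster_radius()],
#' [transfer_efficiency()] and [donor_acceptor_distance()] into one
#' result bundle.
#'
#' @param donor_emission donor emission [spectrum()] (corrected).
#' @param acceptor_extinction acceptor extinction [spectrum()].
#' @param f,f0 donor intensities with and without acceptor.
#' @param constants a [fret_constants()].
#' @return An object of class `"fret_result"` with elements `j`
#'   (cm^3 M^-1), `e`, `r0` (nm), `r` (nm) and `constants`.
#' @export
fret_analysis <- function(donor_emission, acceptor_extinction, f, f0,
                          constants) {
  j <- overlap_integral(donor_emission, acceptor_extinction)
  r0 <- forster_radius(j, constants)
  e <- transfer_efficiency(f, f0)
  r <- donor_acceptor_distance(e, r0)
  structure(list(j = j, e = e, r0 = r0, r = r, constants = constants),
            class = "fret_result")
}

#' @export
print.fret_result <- function(x, ...) {
  cat("Forster energy-transfer analysis\n")
  cat(sprintf("  J  = %.4g cm^3 M^-1\n", x$j))
  cat(sprintf("  E  = %.4g\n", x$e))
  cat(sprintf("  R0 = %.4g nm\n", x$r0))
  cat(sprintf("  r  = %.4g nm\n", x$r))
  invisible(x)
}
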