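#' Stern-Volmer quenching fit
#'
#' Fits the Stern-Volmer law F0/F = 1 + Ksv [Q] to a titration. Because
#' the law fixes the intercept at 1, Ksv is estimated by least squares
#' with the intercept pinned to 1 (Ksv = sum((y-1) q) / sum(q^2) over
#' the nonzero-concentration points); the correlation coefficient of the
#' unconstrained regression is reported alongside as a linearity
#' diagnostic. The apparent bimolecular quenching rate constant
#' kq = Ksv / tau0 is filled in from the fluorophore lifetime.
#'
#' With `two_regime = TRUE` the points (ordered by concentration) are
#' split at every contiguous boundary leaving at least `min_points` per
#' side; each side is fitted with the intercept pinned to 1 and the
#' split minimising the total squared residual is returned, with the
#' second constant in `ksv2`/`kq2` and the boundary in `regime_split`.
#' This handles quenchers that address two binding-site classes of
#' different affinity.
#'
#' @param series a [titration_series()].
#' @param readout `"peak"` (default) or `"at"`; see
#'   [titration_intensities()].
#' @param wavelength fixed readout wavelength when `readout = "at"`.
#' @param tau0 unquenched fluorophore lifetime in seconds (default
#'   1e-8 s, the canonical biopolymer value).
#' @param two_regime search for two Stern-Volmer regimes?
#' @param min_points minimum points per regime side.
#' @return An object of class `"quenching_fit"` with elements `ksv`,
#'   `kq` (reciprocal of the series' concentration unit, per second for
#'   kq), `tau0`, `intercept` and `r` (free-intercept diagnostics),
#'   `unit`, `sse`, and when a split was fitted `ksv2`, `kq2`,
#'   `regime_split`, `r2`.
#' @export
stern_volmer_fit <- function(series, readout = c("peak", "at"),
                             wavelength = NULL, tau0 = 1e-8,
                             two_regime = FALSE, min_points = 3L) {
  stopifnot(inherits(series, "titration_series"))
  readout <- match.arg(readout)
  f <- titration_intensities(series, readout, wavelength)
  if (any(f <= 0))
    stop("nonpositive intensities: cannot form F0/F")
  f0 <- f[1L]
  q <- series$concentrations[-1L]
  fq <- f[-1L]
  keep <- fq <= f0
  if (!all(keep)) {
    warning(sum(!keep), " point(s) with F > F0 excluded from the ",
            "Stern-Volmer fit")
    q <- q[keep]; fq <- fq[keep]
  }
  if (length(q) < min_points)
    stop("need at least ", min_points, " nonzero-concentration points")
  y <- f0 / fq

  pinned <- function(qi, yi) {
    ksv <- sum((yi - 1) * qi) / sum(qi^2)
    sse <- sum((yi - 1 - ksv * qi)^2)
    list(ksv = ksv, sse = sse)
  }
  diag_r <- function(qi, yi)
    if (length(qi) >= 3L && stats::sd(yi) > 0) stats::cor(qi, yi) else NA_real_

  if (!two_regime) {
    fit <- pinned(q, y)
    free <- stats::lm(y ~ q)
    out <- list(ksv = fit$ksv, kq = fit$ksv / check_tau0(tau0),
                tau0 = tau0,
                intercept = unname(stats::coef(free)[1L]),
                r = diag_r(q, y), unit = series$unit, sse = fit$sse,
                n_points = length(q), two_regime = FALSE,
                ksv2 = NA_real_, kq2 = NA_real_,
                regime_split = NA_real_, r2 = NA_real_)
    return(structure(out, class = "quenching_fit"))
  }

  n <- length(q)
  if (n < 2L * min_points)
    stop("two-regime fit needs at least ", 2L * min_points, " points")
  best <- NULL
  for (k in seq(min_points, n - min_points)) {
    lo <- pinned(q[1:k], y[1:k])
    hi <- pinned(q[(k + 1):n], y[(k + 1):n])
    sse <- lo$sse + hi$sse
    if (is.null(best) || sse < best$sse)
      best <- list(k = k, sse = sse, lo = lo, hi = hi)
  }
  k <- best$k
  out <- list(ksv = best$lo$ksv, kq = best$lo$ksv / check_tau0(tau0),
              tau0 = tau0, intercept = 1,
              r = diag_r(q[1:k], y[1:k]), unit = series$unit,
              sse = best$sse, n_points = n, two_regime = TRUE,
              ksv2 = best$hi$ksv, kq2 = best$hi$ksv / tau0,
              regime_split = q[k],
              r2 = diag_r(q[(k + 1):n], y[(k + 1):n]))
  structure(out, class = "quenching_fit")
}

check_tau0 <- function(tau0) {
  if (!is.numeric(tau0) || length(tau0) != 1L || tau0 <= 0)
    stop("tau0 must be a positive lifetime in seconds")
  tau0
}

#' @export
print.quenching_fit <- function(x, ...) {
  cat("Stern-Volmer fit\n")
  cat(sprintf("  Ksv = %.4g %s^-1   kq = %.4g %s^-1 s^-1 (tau0 = %g s)\n",
              x$ksv, x$unit, x$kq, x$unit, x$tau0))
  if (isTRUE(x$two_regime))
    cat(sprintf("  regime 2: Ksv = %.4g %s^-1 above [Q] = %.4g %s\n",
                x$ksv2, x$unit, x$regime_split, x$unit))
  cat(sprintf("  free-intercept diagnostic: intercept %.4g, r = %.4f\n",
              x$intercept, x$r))
  invisible(x)
}

#' Bimolecular quenching rate constant
#'
#' kq = Ksv / tau0, with tau0 the average unquenched lifetime of the
#' biopolymer (1e-8 s by convention).
#'
#' @param ksv Stern-Volmer constant, reciprocal concentration;
#'   nonnegative.
#' @param tau0 lifetime in seconds; positive.
#' @return kq in the same reciprocal-concentration unit per second.
#' @examples
#' quenching_rate_constant(2.4e12)  # 2.4e20
#' @export
quenching_rate_constant <- function(ksv, tau0 = 1e-8) {
  if (any(ksv < 0)) stop("ksv must be nonnegative")
  ksv / check_tau0(tau0)
}

#' Classify the quenching mechanism
#'
#' Compares the apparent bimolecular quenching rate constant with the
#' maximum diffusion-collision (dynamic) quenching rate constant of a
#' biopolymer, 2e10 M^-1 s^-1. A kq strictly above that limit cannot
#' arise from collisional quenching alone, so the mechanism is declared
#' static (ground-state complex formation); at or below the limit
#' dynamic quenching remains possible.
#'
#' @param kq quenching rate constant. Must be expressed in M^-1 s^-1;
#'   pass the unit the constant was fitted in via `unit` and the value
#'   is checked (fits against mM grids must be converted first, see
#'   [per_conc_to_per_molar()]).
#' @param unit concentration unit kq's reciprocal refers to; anything
#'   but `"M"` is refused with a conversion hint.
#' @param diffusion_limit the diffusion-collision ceiling, M^-1 s^-1.
#' @return `"static"` or `"dynamic_possible"`.
#' @examples
#' classify_mechanism(2.4e20)  # static
#' @export
classify_mechanism <- function(kq, unit = "M", diffusion_limit = 2e10) {
  unit <- match_conc_unit(unit)
  if (unit != "M")
    stop("kq is expressed per ", unit,
         "; convert with per_conc_to_per_molar(kq, \"", unit,
         "\") before classifying against the M^-1 s^-1 diffusion limit")
  if (kq < 0) stop("kq must be nonnegative")
  if (kq > diffusion_limit) "static" else "dynamic_possible"
}

#' Modified Stern-Volmer (accessible-fraction) fit
#'
#' Fits F0/(F0 - F) = 1/fa + 1/(fa ka [Q]): a regression of
#' F0/(F0 - F) on 1/[Q] whose intercept is 1/fa (fa = fraction of the
#' total fluorescence accessible to the quencher) and whose slope gives
#' ka = intercept/slope (the effective quenching constant of the
#' accessible fluorophores). A nonpositive intercept, fa > 1 or
#' ka <= 0 is physically impossible; the raw parameters are still
#' returned, flagged `unphysical`, rather than clamped.
#'
#' With `two_regime = TRUE` every contiguous split of the
#' concentration-ordered points with at least `min_points` per side is
#' scored by the total squared residual of two independent straight
#' lines in the (1/[Q], F0/(F0-F)) plane, and the minimising split is
#' returned as a pair of fits.
#'
#' @inheritParams stern_volmer_fit
#' @return An object of class `"accessibility_fit"` (elements `fa`,
#'   `ka`, `intercept`, `slope`, `r`, `unit`, `sse`, `unphysical`), or
#'   for `two_regime = TRUE` an `"accessibility_fit2"`: a list with
#'   elements `low`, `high` (two accessibility fits), `split`
#'   (boundary concentration), `split_index` and `sse`.
#' @export
modified_stern_volmer_fit <- function(series, readout = c("peak", "at"),
                                      wavelength = NULL,
                                      two_regime = FALSE,
                                      min_points = 3L) {
  stopifnot(inherits(series, "titration_series"))
  readout <- match.arg(readout)
  f <- titration_intensities(series, readout, wavelength)
  f0 <- f[1L]
  q <- series$concentrations[-1L]
  fq <- f[-1L]
  keep <- fq < f0 & q > 0
  if (sum(!keep) > 0)
    warning(sum(!keep), " unquenched point(s) (F >= F0) dropped from ",
            "the modified Stern-Volmer fit")
  q <- q[keep]; fq <- fq[keep]
  if (length(q) < min_points)
    stop("need at least ", min_points, " quenched points")
  x <- 1 / q
  y <- f0 / (f0 - fq)

  msv_line <- function(xi, yi, unit) {
    fit <- stats::lm(yi ~ xi)
    a <- unname(stats::coef(fit)[1L])
    b <- unname(stats::coef(fit)[2L])
    fa <- 1 / a
    ka <- a / b
    bad <- character(0)
    if (a <= 0) bad <- c(bad, "intercept <= 0")
    if (is.finite(fa) && fa > 1) bad <- c(bad, "fa > 1")
    if (!is.finite(ka) || ka <= 0) bad <- c(bad, "ka <= 0")
    structure(list(fa = fa, ka = ka, intercept = a, slope = b,
                   r = if (length(xi) >= 3L) stats::cor(xi, yi) else NA_real_,
                   unit = unit, sse = sum(stats::resid(fit)^2),
                   n_points = length(xi),
                   unphysical = length(bad) > 0,
                   unphysical_reason = paste(bad, collapse = "; ")),
              class = "accessibility_fit")
  }

  if (!two_regime) return(msv_line(x, y, series$unit))

  n <- length(q)
  if (n < 2L * min_points)
    stop("two-regime fit needs at least ", 2L * min_points, " points")
  best <- NULL
  for (k in seq(min_points, n - min_points)) {
    lo <- msv_line(x[1:k], y[1:k], series$unit)
    hi <- msv_line(x[(k + 1):n], y[(k + 1):n], series$unit)
    sse <- lo$sse + hi$sse
    if (is.null(best) || sse < best$sse)
      best <- list(k = k, sse = sse, lo = lo, hi = hi)
  }
  structure(list(low = best$lo, high = best$hi, split = q[best$k],
                 split_index = best$k, sse = best$sse,
                 unit = series$unit),
            class = "accessibility_fit2")
}

#' @export
print.accessibility_fit <- function(x, ...) {
  cat("Modified Stern-Volmer fit\n")
  cat(sprintf("  fa = %.4g   ka = %.4g %s^-1   r = %.4f\n",
              x$fa, x$ka, x$unit, x$r))
  if (isTRUE(x$unphysical))
    cat("  WARNING: unphysical parameters (", x$unphysical_reason, ")\n",
        sep = "")
  invisible(x)
}

#' @export
print.accessibility_fit2 <- function(x, ...) {
  cat(sprintf("Two-regime modified Stern-Volmer fit (split at [Q] = %.4g %s)\n",
              x$split, x$unit))
  cat(sprintf("  low regime:  fa = %.4g, ka = %.4g %s^-1\n",
              x$low$fa, x$low$ka, x$unit))
  cat(sprintf("  high regime: fa = %.4g, ka = %.4g %s^-1\n",
              x$high$fa, x$high$ka, x$unit))
  invisible(x)
}

#' Double-logarithmic binding-sites fit
#'
#' Fits log10((F0 - F)/F) = log10(KA) + n log10([Q]): the slope
#' estimates the number of binding sites n and the intercept the
#' association constant KA. Only quenched points (0 < F < F0) enter;
#' unquenched points are dropped with a warning because (F0 - F)/F is
#' zero there.
#'
#' @inheritParams stern_volmer_fit
#' @param min_points minimum usable quenched points.
#' @return An object of class `"binding_sites_fit"` with elements `n`,
#'   `log_ka` (log10 of KA in reciprocal-unit^n), `ka`, `r`, `unit`.
#' @export
double_log_fit <- function(series, readout = c("peak", "at"),
                           wavelength = NULL, min_points = 3L) {
  stopifnot(inherits(series, "titration_series"))
  readout <- match.arg(readout)
  f <- titration_intensities(series, readout, wavelength)
  f0 <- f[1L]
  q <- series$concentrations[-1L]
  fq <- f[-1L]
  keep <- fq > 0 & fq < f0 & q > 0
  if (sum(!keep) > 0)
    warning(sum(!keep), " point(s) with F outside (0, F0) dropped from ",
            "the double-log fit")
  q <- q[keep]; fq <- fq[keep]
  if (length(q) < min_points)
    stop("need at least ", min_points, " points with 0 < F < F0")
  x <- log10(q)
  y <- log10((f0 - fq) / fq)
  fit <- stats::lm(y ~ x)
  structure(list(n = unname(stats::coef(fit)[2L]),
                 log_ka = unname(stats::coef(fit)[1L]),
                 ka = 10^unname(stats::coef(fit)[1L]),
                 r = if (length(x) >= 3L) stats::cor(x, y) else NA_real_,
                 unit = series$unit, n_points = length(x),
                 sse = sum(stats::resid(fit)^2)),
            class = "binding_sites_fit")
}

#' @export
print.binding_sites_fit <- function(x, ...) {
  cat("Double-log binding-sites fit\n")
  cat(sprintf("  n = %.4g   log10(KA) = %.4g (KA = %.4g %s^-n)   r = %.4f\n",
              x$n, x$log_ka, x$ka, x$unit, x$r))
  invisible(x)
}
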