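#' Emission band model
#'
#' Parametric Gaussian model of a protein emission band. Tryptophan
#' emission of a globular protein peaks near 340 nm and red-shifts by a
#' few nm as a bound quencher makes the fluorophore microenvironment
#' more hydrophilic; the shift is modelled as linear in quencher
#' concentration, which matches the small (at most ~3 nm) shifts this
#' package is designed to resolve.
#'
#' @param center band center, nm.
#' @param width Gaussian sigma, nm; must be positive.
#' @param amplitude peak intensity, arbitrary units; nonnegative.
#' @param shift_rate red shift of the center per unit concentration
#'   (nm per concentration unit of the titration grid).
#' @return An object of class `"band_model"`.
#' @export
band_model <- function(center = 340, width = 20, amplitude = 100,
                       shift_rate = 0) {
  if (width <= 0) stop("band width must be positive")
  if (amplitude < 0) stop("band amplitude must be nonnegative")
  structure(list(center = center, width = width, amplitude = amplitude,
                 shift_rate = shift_rate), class = "band_model")
}

#' Generator configuration for synthetic quenching titrations
#'
#' Bundles the emission band, the quencher grid and the quenching law
#' used by [gen_quenching_titration()]. Four mechanisms are supported:
#' \describe{
#'   \item{`simple_static`}{F0/F = 1 + Ksv [Q] (single Stern-Volmer
#'     constant `ksv`).}
#'   \item{`accessible_fraction`}{F = F0 (1 - fa ka [Q] / (1 + ka [Q])),
#'     whose linearisation is the modified Stern-Volmer plot
#'     F0/(F0-F) = 1/fa + 1/(fa ka [Q]).}
#'   \item{`two_regime`}{Stern-Volmer law with constant `ksv[1]` for
#'     [Q] <= `split` and `ksv[2]` above, emulating a quencher that sees
#'     two binding-site classes of different affinity.}
#'   \item{`hill`}{(F0-F)/F = ka [Q]^n_hill, the double-logarithmic
#'     binding-site law with association constant `ka` and `n_hill`
#'     binding sites.}
#' }
#'
#' @param band a [band_model()].
#' @param quencher_grid nondecreasing concentrations starting at exactly
#'   0, in `unit`.
#' @param unit concentration unit of the grid.
#' @param mechanism one of `"simple_static"`, `"accessible_fraction"`,
#'   `"two_regime"`, `"hill"`.
#' @param ksv Stern-Volmer constant(s), reciprocal `unit`; length 1
#'   (`simple_static`) or 2 (`two_regime`).
#' @param split regime-change concentration for `two_regime`, strictly
#'   inside the grid.
#' @param fa accessible fluorophore fraction, dimensionless.
#' @param ka effective/association quenching constant, reciprocal `unit`
#'   (raised to `n_hill` for the `hill` mechanism).
#' @param n_hill number of binding sites (Hill exponent).
#' @param noise_sd Gaussian noise standard deviation as a fraction of
#'   the band amplitude; 0 for noiseless data.
#' @param seed integer RNG seed; the same configuration and seed always
#'   reproduce the same series.
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(band, quencher_grid, unit = "mM",
                             mechanism = c("simple_static",
                                           "accessible_fraction",
                                           "two_regime", "hill"),
                             ksv = NULL, split = NULL, fa = NULL,
                             ka = NULL, n_hill = NULL,
                             noise_sd = 0, seed = 1L) {
  mechanism <- match.arg(mechanism)
  stopifnot(inherits(band, "band_model"))
  quencher_grid <- as.numeric(quencher_grid)
  if (length(quencher_grid) < 2L)
    stop("quencher grid needs the reference point plus additions")
  if (quencher_grid[1L] != 0)
    stop("quencher grid must start at exactly 0")
  if (any(diff(quencher_grid) < 0))
    stop("quencher grid must be nondecreasing")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  unit <- match_conc_unit(unit)
  switch(mechanism,
    simple_static = {
      if (is.null(ksv) || length(ksv) != 1L || ksv < 0)
        stop("simple_static requires a single nonnegative ksv")
    },
    two_regime = {
      if (is.null(ksv) || length(ksv) != 2L || any(ksv < 0))
        stop("two_regime requires ksv of length 2")
      if (is.null(split) || split <= min(quencher_grid) ||
          split >= max(quencher_grid))
        stop("two_regime requires a split strictly inside the grid")
    },
    accessible_fraction = {
      if (is.null(fa) || is.null(ka) || fa <= 0 || ka <= 0)
        stop("accessible_fraction requires positive fa and ka")
    },
    hill = {
      if (is.null(ka) || is.null(n_hill) || ka <= 0 || n_hill <= 0)
        stop("hill requires positive ka and n_hill")
    })
  structure(list(band = band, quencher_grid = quencher_grid, unit = unit,
                 mechanism = mechanism, ksv = ksv, split = split, fa = fa,
                 ka = ka, n_hill = n_hill, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# evaluate F/F0 scale factors for a config on its grid (noiseless)
quench_scale <- function(cfg, q = cfg$quencher_grid) {
  switch(cfg$mechanism,
    simple_static = 1 / (1 + cfg$ksv * q),
    two_regime = ifelse(q <= cfg$split,
                        1 / (1 + cfg$ksv[1L] * q),
                        1 / (1 + cfg$ksv[2L] * q)),
    accessible_fraction = {
      bound <- cfg$fa * cfg$ka * q / (1 + cfg$ka * q)
      if (any(bound >= 1))
        stop("unphysical accessible_fraction request: ",
             "fa*ka*[Q]/(1+ka*[Q]) >= 1 leaves no fluorescence")
      1 - bound
    },
    hill = 1 / (1 + cfg$ka * q^cfg$n_hill))
}

# run expr with a private RNG stream; global .Random.seed is untouched
with_private_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate one Gaussian emission band
#'
#' Samples amplitude * exp(-(lambda - c')^2 / (2 width^2)) on the given
#' wavelength grid, where c' = center + shift_rate * concentration is
#' the red-shifted band center at the given quencher concentration.
#'
#' @param band a [band_model()].
#' @param grid wavelength grid in nm (numeric vector, strictly
#'   increasing); must cover the shifted center +/- 3 widths.
#' @param concentration quencher concentration (same unit as
#'   `shift_rate`'s denominator).
#' @param excitation excitation wavelength recorded on the spectrum.
#' @param kind spectrum kind for the generated trace.
#' @param delta_lambda offset metadata for synchronous-type traces.
#' @return A [spectrum()].
#' @examples
#' s <- gen_emission_band(band_model(340, 20, 100), seq(260, 420, 1), 0)
#' max(s$intensity)  # 100 at 340 nm
#' @export
gen_emission_band <- function(band, grid, concentration = 0,
                              excitation = NA_real_, kind = "emission",
                              delta_lambda = NA_real_) {
  stopifnot(inherits(band, "band_model"))
  grid <- as.numeric(grid)
  center <- band$center + band$shift_rate * concentration
  lo <- center - 3 * band$width
  hi <- center + 3 * band$width
  if (min(grid) > lo || max(grid) < hi)
    stop(sprintf(paste0("wavelength grid [%g, %g] nm too narrow: must ",
                        "cover the band center %g nm +/- 3 widths ",
                        "([%g, %g] nm)"),
                 min(grid), max(grid), center, lo, hi))
  y <- band$amplitude * exp(-(grid - center)^2 / (2 * band$width^2))
  spectrum(grid, y, kind = kind, excitation = excitation,
           delta_lambda = delta_lambda)
}

#' Generate a synthetic quenching titration
#'
#' For each concentration on the configured grid the emission band is
#' scaled by the noiseless F/F0 dictated by the configured quenching
#' mechanism (see [generator_config()]), then Gaussian noise of sd
#' `noise_sd * amplitude` is added reproducibly from the seed. The
#' reference point ([Q] = 0) is always the unquenched band.
#'
#' @param cfg a [generator_config()].
#' @param grid wavelength grid in nm; defaults to the band center +/- 4
#'   widths at 1 nm steps (widened to cover the largest red shift).
#' @param excitation excitation wavelength recorded on every spectrum.
#' @param kind,delta_lambda spectrum metadata (use `kind =
#'   "synchronous"` with `delta_lambda` 15 or 60 for synchronous scans).
#' @return A [titration_series()].
#' @export
gen_quenching_titration <- function(cfg, grid = NULL,
                                    excitation = 280, kind = "emission",
                                    delta_lambda = NA_real_) {
  stopifnot(inherits(cfg, "generator_config"))
  b <- cfg$band
  q <- cfg$quencher_grid
  if (is.null(grid)) {
    shift <- b$shift_rate * max(q)
    grid <- seq(floor(b$center - 4 * b$width + min(0, shift)),
                ceiling(b$center + 4 * b$width + max(0, shift)), by = 1)
  }
  scale <- quench_scale(cfg)
  spectra <- with_private_seed(cfg$seed, lapply(seq_along(q), function(i) {
    s <- gen_emission_band(b, grid, q[i], excitation = excitation,
                           kind = kind, delta_lambda = delta_lambda)
    y <- s$intensity * scale[i]
    if (cfg$noise_sd > 0)
      y <- y + stats::rnorm(length(y), sd = cfg$noise_sd * b$amplitude)
    s$intensity <- y
    s
  }))
  titration_series(spectra, q, unit = cfg$unit)
}

#' Generate an acceptor absorption spectrum
#'
#' Produces a nonnegative molar-extinction trace (M^-1 cm^-1), either
#' flat or Gaussian, for use as the acceptor side of an overlap-integral
#' calculation.
#'
#' @param shape `"gaussian"` or `"flat"`.
#' @param grid wavelength grid in nm.
#' @param eps0 peak (or constant) extinction coefficient, M^-1 cm^-1;
#'   must be nonnegative.
#' @param center,width Gaussian parameters in nm (ignored for flat).
#' @return A [spectrum()] of kind `"absorption"`.
#' @export
gen_absorption_spectrum <- function(shape = c("gaussian", "flat"), grid,
                                    eps0, center = NULL, width = NULL) {
  shape <- match.arg(shape)
  if (eps0 < 0) stop("extinction coefficient must be nonnegative")
  grid <- as.numeric(grid)
  y <- if (shape == "flat") {
    rep(eps0, length(grid))
  } else {
    if (is.null(center) || is.null(width) || width <= 0)
      stop("gaussian shape requires a center and a positive width")
    eps0 * exp(-(grid - center)^2 / (2 * width^2))
  }
  spectrum(grid, y, kind = "absorption")
}

#' Generate a synthetic RLS intensity curve
#'
#' Emulates a resonance light scattering titration: intensity stays at
#' the baseline while the drug concentration is below the critical
#' induced aggregation concentration (C_CIAC), then rises linearly as
#' growing aggregates scatter more light.
#'
#' @param cciac aggregation onset concentration; must lie strictly
#'   inside the concentration grid.
#' @param baseline scattering intensity below the onset.
#' @param slope intensity increase per unit concentration above the
#'   onset.
#' @param grid concentration grid (nondecreasing).
#' @param unit concentration unit.
#' @param noise_sd Gaussian noise sd in intensity units.
#' @param seed integer RNG seed.
#' @param readout_wavelength scan wavelength the curve was read at
#'   (metadata).
#' @return An [rls_curve()].
#' @export
gen_rls_series <- function(cciac, baseline, slope, grid, unit = "mM",
                           noise_sd = 0, seed = 1L,
                           readout_wavelength = NA_real_) {
  grid <- as.numeric(grid)
  if (any(diff(grid) < 0)) stop("concentration grid must be nondecreasing")
  if (cciac <= min(grid) || cciac >= max(grid))
    stop("cciac must lie strictly inside the concentration grid")
  y <- baseline + slope * pmax(0, grid - cciac)
  if (noise_sd > 0)
    y <- with_private_seed(seed,
                           y + stats::rnorm(length(y), sd = noise_sd))
  rls_curve(grid, y, unit = unit, readout_wavelength = readout_wavelength)
}

#' Write a generator configuration as a flat key-value file
#'
#' @param cfg a [generator_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_generator_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "generator_config"))
  kv <- c(
    sprintf("mechanism=%s", cfg$mechanism),
    sprintf("unit=%s", cfg$unit),
    sprintf("band.center=%.17g", cfg$band$center),
    sprintf("band.width=%.17g", cfg$band$width),
    sprintf("band.amplitude=%.17g", cfg$band$amplitude),
    sprintf("band.shift_rate=%.17g", cfg$band$shift_rate),
    sprintf("quencher_grid=%s",
            paste(sprintf("%.17g", cfg$quencher_grid), collapse = ",")),
    sprintf("noise_sd=%.17g", cfg$noise_sd),
    sprintf("seed=%d", cfg$seed))
  for (p in c("ksv", "split", "fa", "ka", "n_hill"))
    if (!is.null(cfg[[p]]))
      kv <- c(kv, sprintf("%s=%s", p,
                          paste(sprintf("%.17g", cfg[[p]]), collapse = ",")))
  writeLines(kv, path)
  invisible(path)
}

#' Read a generator configuration written by [write_generator_config()]
#'
#' @param path key-value file path.
#' @return A [generator_config()].
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), character(1))
  get1 <- function(k, num = TRUE) {
    if (!k %in% keys) return(NULL)
    v <- strsplit(vals[match(k, keys)], ",", fixed = TRUE)[[1L]]
    if (num) as.numeric(v) else v
  }
  generator_config(
    band = band_model(get1("band.center"), get1("band.width"),
                      get1("band.amplitude"), get1("band.shift_rate")),
    quencher_grid = get1("quencher_grid"),
    unit = get1("unit", num = FALSE),
    mechanism = get1("mechanism", num = FALSE),
    ksv = get1("ksv"), split = get1("split"), fa = get1("fa"),
    ka = get1("ka"), n_hill = get1("n_hill"),
    noise_sd = get1("noise_sd"), seed = as.integer(get1("seed")))
}
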