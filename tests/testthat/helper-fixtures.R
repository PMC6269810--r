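# shared fixture builders: everything is generated in code at test time

# a Gaussian emission spectrum with a peak at `center`
make_emission <- function(center = 340, width = 15, amplitude = 100,
                          excitation = 295,
                          grid = seq(280, 420, by = 1)) {
  gen_emission_band(band_model(center, width, amplitude), grid, 0,
                    excitation = excitation)
}

# noiseless simple Stern-Volmer titration with Ksv[Q] spanning ~[0, 4.6]
make_sv_series <- function(ksv = 2.3e12, unit = "M", n = 11,
                           qmax = 2e-12, noise_sd = 0, seed = 1L) {
  cfg <- generator_config(band_model(), seq(0, qmax, length.out = n),
                          unit = unit, mechanism = "simple_static",
                          ksv = ksv, noise_sd = noise_sd, seed = seed)
  gen_quenching_titration(cfg)
}

# noiseless modified-Stern-Volmer titration
make_msv_series <- function(fa = 0.8, ka = 1e12, unit = "M", n = 10,
                            qmax = 4e-12) {
  cfg <- generator_config(band_model(),
                          c(0, seq(qmax / n, qmax, length.out = n)),
                          unit = unit, mechanism = "accessible_fraction",
                          fa = fa, ka = ka)
  gen_quenching_titration(cfg)
}

# noiseless double-log (Hill-type) titration on a log-spaced grid
make_hill_series <- function(ka = 1e6, n_hill = 1.21, unit = "M",
                             n = 10, lo = 1e-7, hi = 10^-5.5) {
  grid <- c(0, 10^seq(log10(lo), log10(hi), length.out = n))
  cfg <- generator_config(band_model(), grid, unit = unit,
                          mechanism = "hill", ka = ka, n_hill = n_hill)
  gen_quenching_titration(cfg)
}

# noiseless two-regime titration split at `split`
make_two_regime_series <- function(ksv = c(2.3e12, 1.1e12),
                                   split = 5e-13, unit = "M", n = 11,
                                   qmax = 1e-12) {
  cfg <- generator_config(band_model(),
                          c(0, seq(qmax / n, qmax, length.out = n)),
                          unit = unit, mechanism = "two_regime",
                          ksv = ksv, split = split)
  gen_quenching_titration(cfg)
}

ss_fixture_path <- function() {
  system.file("extdata", "secondary_structure_fractions.csv",
              package = "specbind", mustWork = TRUE)
}
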