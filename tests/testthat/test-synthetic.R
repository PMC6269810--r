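# synthetic-spectra generator: band shapes, quenching laws, RLS hinges

test_that("gen_emission_band samples the Gaussian profile with the red shift", {
  grid <- seq(260, 430, by = 1)
  s0 <- gen_emission_band(band_model(340, 20, 100), grid, 0)
  expect_equal(max(s0$intensity), 100)
  expect_equal(grid[which.max(s0$intensity)], 340)

  # closed form: shifted center = center + shift_rate * concentration
  b <- band_model(340, 20, 100, shift_rate = 2.4e5)
  s1 <- gen_emission_band(b, grid, 8.33e-6)
  expect_equal(as.numeric(emission_maximum(s1)), 340 + 2.4e5 * 8.33e-6,
               tolerance = 1e-6)
  expect_equal(round(as.numeric(emission_maximum(s1))), 342)

  # null band
  sz <- gen_emission_band(band_model(340, 20, 0), grid, 0)
  expect_true(all(sz$intensity == 0))

  # grid narrower than center +/- 3 widths is refused
  expect_error(gen_emission_band(band_model(340, 20, 100), 330:350, 0),
               "too narrow")
})

test_that("quenching titrations realise their generating law exactly", {
  # F0/F = 2 when Ksv[Q] = 1
  cfg <- generator_config(band_model(), c(0, 5e-13), unit = "M",
                          mechanism = "simple_static", ksv = 2e12)
  ser <- gen_quenching_titration(cfg)
  f <- titration_intensities(ser)
  expect_equal(f[1] / f[2], 2, tolerance = 1e-12)

  # [Q] = 0 point is the unquenched band for every mechanism
  for (ser in list(make_sv_series(), make_msv_series(),
                   make_hill_series(), make_two_regime_series())) {
    ref <- ser$spectra[[1]]
    expect_equal(max(ref$intensity), 100, tolerance = 1e-12)
  }
})

test_that("same config and seed reproduce the identical noisy series", {
  a <- make_sv_series(noise_sd = 0.05, seed = 42L)
  b <- make_sv_series(noise_sd = 0.05, seed = 42L)
  expect_identical(lapply(a$spectra, `[[`, "intensity"),
                   lapply(b$spectra, `[[`, "intensity"))
  c <- make_sv_series(noise_sd = 0.05, seed = 43L)
  expect_false(identical(a$spectra[[2]]$intensity,
                         c$spectra[[2]]$intensity))
})

test_that("generation does not disturb the global RNG stream", {
  set.seed(7)
  before <- .Random.seed
  invisible(make_sv_series(noise_sd = 0.1, seed = 9L))
  expect_identical(.Random.seed, before)
})

test_that("unphysical accessible-fraction requests are refused", {
  cfg <- generator_config(band_model(), c(0, 1, 10, 100, 1000),
                          unit = "mM", mechanism = "accessible_fraction",
                          fa = 1.5, ka = 10)
  expect_error(gen_quenching_titration(cfg), "unphysical")
})

test_that("absorption spectra honour their shape parameters", {
  grid <- seq(250, 450, by = 1)
  flat <- gen_absorption_spectrum("flat", grid, eps0 = 1000)
  expect_true(all(flat$intensity == 1000))
  expect_identical(flat$kind, "absorption")

  zero <- gen_absorption_spectrum("flat", grid, eps0 = 0)
  expect_true(all(zero$intensity == 0))

  expect_error(gen_absorption_spectrum("flat", grid, eps0 = -5),
               "nonnegative")

  # an acceptor far below the donor band yields a negligible overlap
  donor <- make_emission(center = 340, width = 10,
                         grid = seq(300, 420, 1))
  acc <- gen_absorption_spectrum("gaussian", grid, eps0 = 1000,
                                 center = 270, width = 1)
  j <- overlap_integral(donor, acc)
  j_scale <- 1000 * (420e-7)^4          # eps0 * lambda^4 at the red end
  expect_lt(j, j_scale * 1e-10)
})

test_that("RLS generator produces the hinge it was asked for", {
  grid <- seq(0, 1e-6, length.out = 20)
  flat <- gen_rls_series(5e-7, 100, 0, grid)
  expect_true(all(flat$intensities == 100))

  a <- gen_rls_series(3.7e-7, 100, 5e8, grid, noise_sd = 2, seed = 11L)
  b <- gen_rls_series(3.7e-7, 100, 5e8, grid, noise_sd = 2, seed = 11L)
  expect_identical(a$intensities, b$intensities)

  expect_error(gen_rls_series(2e-6, 100, 5e8, grid), "strictly inside")
})

test_that("noiseless generation round-trips through the matching fit", {
  # each mechanism's parameters are recovered to <= 1e-6 relative error
  sv <- stern_volmer_fit(make_sv_series(ksv = 2.3e12))
  expect_equal(sv$ksv, 2.3e12, tolerance = 1e-6)

  msv <- modified_stern_volmer_fit(make_msv_series(fa = 0.8, ka = 1e12))
  expect_equal(msv$fa, 0.8, tolerance = 1e-6)
  expect_equal(msv$ka, 1e12, tolerance = 1e-6)

  dl <- double_log_fit(make_hill_series(ka = 1e6, n_hill = 1.21))
  expect_equal(dl$n, 1.21, tolerance = 1e-6)
  expect_equal(dl$ka, 1e6, tolerance = 1e-6)

  tr <- stern_volmer_fit(make_two_regime_series(ksv = c(2.3e12, 1.1e12),
                                                split = 5e-13),
                         two_regime = TRUE)
  expect_equal(tr$ksv, 2.3e12, tolerance = 1e-6)
  expect_equal(tr$ksv2, 1.1e12, tolerance = 1e-6)

  hinge <- detect_cciac(gen_rls_series(4e-7, 50, 1e9,
                                       seq(0, 1e-6, length.out = 12)))
  expect_equal(hinge$cciac, 4e-7, tolerance = 1e-6)
})

test_that("noiseless F is nonincreasing in [Q] for every mechanism", {
  series <- list(
    make_sv_series(),
    make_msv_series(),
    make_hill_series(),
    # regimes ordered so affinity grows with concentration
    make_two_regime_series(ksv = c(0.7e12, 2.9e12), split = 5e-13))
  for (ser in series) {
    f <- titration_intensities(ser)
    expect_true(all(diff(f) <= 1e-12 * f[1]))
  }
})

test_that("config files round-trip through the key-value format", {
  cfg <- generator_config(band_model(341.5, 18, 250, 2.4e5),
                          c(0, 1e-13, 5e-13, 2e-12), unit = "M",
                          mechanism = "two_regime",
                          ksv = c(2.3e12, 1.1e12), split = 5e-13,
                          noise_sd = 0.02, seed = 17L)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_generator_config(cfg, path)
  back <- read_generator_config(path)
  expect_equal(back[setdiff(names(back), "band")],
               cfg[setdiff(names(cfg), "band")])
  expect_equal(unclass(back$band), unclass(cfg$band))
})
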