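# REES, synchronous slopes, red-shift tracking, CD bookkeeping

test_that("REES is the 305-minus-295 emission-maximum difference", {
  s295 <- make_emission(center = 339, excitation = 295)
  s305 <- make_emission(center = 343, excitation = 305)
  r <- rees(s295, s305, mode = "table")
  expect_equal(r$rees, 4)
  expect_equal(r$lam_max_295, 339)
  expect_equal(r$lam_max_305, 343)

  r1 <- rees(make_emission(342, excitation = 295),
             make_emission(343, excitation = 305), mode = "table")
  expect_equal(r1$rees, 1)

  # identical spectra: zero shift
  s <- make_emission(center = 341, excitation = 295)
  expect_equal(rees(s, s)$rees, 0)
})

test_that("REES is antisymmetric and table mode rounds first", {
  a <- make_emission(center = 339.4, excitation = 295)
  b <- make_emission(center = 342.6, excitation = 305)
  expect_equal(rees(a, b)$rees, -rees(b, a)$rees, tolerance = 1e-9)
  # 342.6 -> 343 and 339.4 -> 339 before differencing
  expect_equal(rees(a, b, mode = "table")$rees, 4)
})

test_that("REES refuses spectra without excitation metadata", {
  a <- make_emission(center = 339)
  b <- make_emission(center = 343)
  b$excitation <- NA_real_
  expect_error(rees(a, b), "excitation metadata")
})

test_that("synchronous slope fits F/F0 against [Q]", {
  grid <- seq(240, 340, by = 1)
  mk_sync <- function(scales, dl) {
    sp <- lapply(scales, function(sc)
      gen_emission_band(band_model(290, 10, 100 * sc), grid, 0,
                        kind = "synchronous", delta_lambda = dl))
    titration_series(sp, seq(0, 8e-6, length.out = length(scales)),
                     unit = "mM")
  }
  # no quenching: slope 0
  s0 <- synchronous_slope(mk_sync(rep(1, 6), 15))
  # slope is per concentration unit; with [Q] ~ 1e-6 floating-point noise
  # in the constant ratios amplifies to ~1e-10, still negligible vs 5e4
  expect_equal(s0$slope, 0, tolerance = 1e-6)

  # exact linear decay F/F0 = 1 - 5e4 [Q]
  q <- seq(0, 8e-6, length.out = 6)
  s1 <- synchronous_slope(mk_sync(1 - 5e4 * q, 60))
  expect_equal(s1$slope, -5e4, tolerance = 1e-9)
  expect_lt(s1$residual_rms, 1e-9)

  # Trp-dominated quenching: |slope| at 60 nm exceeds 15 nm
  s15 <- synchronous_slope(mk_sync(1 - 3e4 * q, 15))
  s60 <- synchronous_slope(mk_sync(1 - 9e4 * q, 60))
  expect_gt(abs(s60$slope), abs(s15$slope))

  # mixed offsets in one series are refused
  mixed <- mk_sync(rep(1, 6), 15)
  mixed$spectra[[2]]$delta_lambda <- 60
  expect_error(synchronous_slope(mixed), "mixes delta-lambda")
})

test_that("red-shift tracking follows the generator's linear shift", {
  cfg <- generator_config(band_model(340, 15, 100, shift_rate = 2.4e5),
                          seq(0, 8.33e-6, length.out = 6), unit = "mM",
                          mechanism = "simple_static", ksv = 1e5)
  ser <- gen_quenching_titration(cfg)
  tr <- red_shift_track(ser)
  expected <- 340 + 2.4e5 * ser$concentrations
  expect_equal(tr$lambda_max, expected, tolerance = 1e-3)
  expect_equal(tr$total_shift, 2.4e5 * 8.33e-6, tolerance = 1e-3)

  # zero shift rate: all maxima equal
  cfg0 <- generator_config(band_model(340, 15, 100),
                           seq(0, 8.33e-6, length.out = 6), unit = "mM",
                           mechanism = "simple_static", ksv = 1e5)
  tr0 <- red_shift_track(gen_quenching_titration(cfg0))
  expect_true(all(abs(tr0$lambda_max - 340) < 1e-9))

  # reversing the series negates the total shift
  rev_ser <- ser
  rev_ser$spectra <- rev(ser$spectra)
  rev_tr <- red_shift_track(rev_ser)
  expect_equal(rev_tr$total_shift, -tr$total_shift, tolerance = 1e-9)
})

test_that("mean residue ellipticity follows 100 theta / (c l)", {
  expect_equal(mean_residue_ellipticity(0, 1e-6, 0.1), 0)
  expect_equal(mean_residue_ellipticity(0.01, 1e-6, 0.1), 1e7)
  expect_equal(mean_residue_ellipticity(0.01, 1e-6, 0.2),
               mean_residue_ellipticity(0.01, 1e-6, 0.1) / 2)
  expect_error(mean_residue_ellipticity(0.01, 0, 0.1), "positive")
  expect_error(mean_residue_ellipticity(0.01, 1e-6, -1), "positive")
})

test_that("secondary-structure fixture rows satisfy the sum invariant", {
  recs <- read_structure_fractions(ss_fixture_path())
  expect_length(recs, 5)
  for (r in recs) expect_lt(abs(sum(r$fractions) - 100), 0.5)
  expect_equal(sum(recs$native$fractions), 100)
})

test_that("structure deltas book-keep the unfolding pattern", {
  recs <- read_structure_fractions(ss_fixture_path())
  d <- structure_delta(recs$native, recs$binary)
  expect_equal(unname(d$deltas["Un"]), 41.14 - 33.37, tolerance = 1e-9)
  expect_true(d$helix_down)
  expect_true(d$unordered_up)
  # deltas are pure redistribution: they sum to ~0
  expect_lt(abs(sum(d$deltas)), 1.0)

  same <- structure_delta(recs$native, recs$native)
  expect_true(all(same$deltas == 0))

  ok <- cd_record(c(H_r = 50, H_d = 10, S_r = 10, S_d = 10, Tr = 10,
                    Un = 10))
  expect_s3_class(ok, "cd_record")
  expect_error(cd_record(c(H_r = 50, H_d = 10, S_r = 10, S_d = 10,
                           Tr = 10, Un = 30)), "sum to")
})
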