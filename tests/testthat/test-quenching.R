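# Stern-Volmer, modified Stern-Volmer and double-log fits

test_that("Stern-Volmer fit pins the intercept and recovers Ksv", {
  # no quenching -> Ksv = 0
  flat <- titration_series(replicate(5, make_emission(), simplify = FALSE),
                           c(0, 1e-13, 2e-13, 3e-13, 4e-13), unit = "M")
  expect_equal(stern_volmer_fit(flat)$ksv, 0, tolerance = 1e-12)

  # noiseless synthetic recovered to machine-level relative error
  fit <- stern_volmer_fit(make_sv_series(ksv = 2e12))
  expect_equal(fit$ksv, 2e12, tolerance = 1e-10)
  expect_equal(fit$kq, 2e12 / 1e-8, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-6)
  expect_gt(fit$r, 0.999999)

  # cross-check against the closed-form pinned-intercept least squares
  f <- titration_intensities(make_sv_series(ksv = 2e12, noise_sd = 0.01,
                                            seed = 3L))
  q <- make_sv_series()$concentrations[-1]
  y <- f[1] / f[-1]
  oracle <- sum((y - 1) * q) / sum(q^2)
  noisy <- stern_volmer_fit(make_sv_series(ksv = 2e12, noise_sd = 0.01,
                                           seed = 3L))
  expect_equal(noisy$ksv, oracle, tolerance = 1e-12)
})

test_that("Stern-Volmer fit guards its inputs", {
  ser <- make_sv_series()
  ser$spectra[[3]]$intensity <- -ser$spectra[[3]]$intensity
  expect_error(stern_volmer_fit(ser), "nonpositive")

  ser2 <- make_sv_series()
  ser2$spectra[[3]]$intensity <- ser2$spectra[[1]]$intensity * 1.5
  expect_warning(fit <- stern_volmer_fit(ser2), "F > F0")
  expect_equal(fit$n_points, 9)
})

test_that("quenching rate constant is Ksv / tau0 and linear in Ksv", {
  expect_equal(quenching_rate_constant(2.4e12), 2.4e20)
  expect_equal(quenching_rate_constant(3.6e12), 3.6e20)
  expect_equal(quenching_rate_constant(0), 0)
  k <- 1.7e11
  expect_equal(quenching_rate_constant(5 * k),
               5 * quenching_rate_constant(k))
  expect_equal(quenching_rate_constant(2e12, tau0 = 2e-8), 1e20)
  expect_error(quenching_rate_constant(1e12, tau0 = 0), "positive")
  expect_error(quenching_rate_constant(-1), "nonnegative")
})

test_that("mechanism classification is strict at the diffusion limit", {
  expect_identical(classify_mechanism(2.4e20), "static")
  expect_identical(classify_mechanism(1e9), "dynamic_possible")
  # exactly at the limit: dynamic quenching cannot be excluded
  expect_identical(classify_mechanism(2e10), "dynamic_possible")
  # constants fitted against a mM grid must be converted first
  expect_error(classify_mechanism(2.4e17, unit = "mM"),
               "per_conc_to_per_molar")
})

test_that("modified Stern-Volmer fit recovers fa and ka", {
  # fully accessible fluorophore: intercept 1, fa 1
  m1 <- modified_stern_volmer_fit(make_msv_series(fa = 1, ka = 5e11))
  expect_equal(m1$intercept, 1, tolerance = 1e-9)
  expect_equal(m1$fa, 1, tolerance = 1e-9)
  expect_false(m1$unphysical)

  m2 <- modified_stern_volmer_fit(make_msv_series(fa = 0.8, ka = 1e12))
  expect_equal(m2$fa, 0.8, tolerance = 1e-9)
  expect_equal(m2$ka, 1e12, tolerance = 1e-9)

  # fa > 1 is returned raw but flagged unphysical
  grid <- c(0, seq(2e-6, 2e-5, length.out = 10))
  cfg <- generator_config(band_model(), grid, unit = "M",
                          mechanism = "accessible_fraction",
                          fa = 1.23, ka = 1e5)
  m3 <- modified_stern_volmer_fit(gen_quenching_titration(cfg))
  expect_equal(m3$fa, 1.23, tolerance = 1e-9)
  expect_true(m3$unphysical)
  expect_match(m3$unphysical_reason, "fa > 1")
})

test_that("two-regime modified fit finds the generating split", {
  ser <- make_two_regime_series(ksv = c(2.3e12, 1.1e12), split = 5e-13)
  m <- modified_stern_volmer_fit(ser, two_regime = TRUE)
  expect_s3_class(m, "accessibility_fit2")
  expect_equal(m$split, 5e-13)
  # each regime is a pure Stern-Volmer law: fa = 1, ka = that Ksv
  expect_equal(m$low$ka, 2.3e12, tolerance = 1e-6)
  expect_equal(m$high$ka, 1.1e12, tolerance = 1e-6)

  # exhaustive-split oracle: no other split scores better
  f <- titration_intensities(ser)
  q <- ser$concentrations[-1]
  x <- 1 / q
  y <- f[1] / (f[1] - f[-1])
  n <- length(q)
  sse_all <- sapply(3:(n - 3), function(k) {
    lo <- lm(y[1:k] ~ x[1:k])
    hi <- lm(y[(k + 1):n] ~ x[(k + 1):n])
    sum(resid(lo)^2) + sum(resid(hi)^2)
  })
  expect_equal(q[(3:(n - 3))[which.min(sse_all)]], m$split)

  # the best split beats the single-line fit on two-regime data
  single <- modified_stern_volmer_fit(ser)
  expect_lt(m$sse, single$sse)
})

test_that("double-log fit recovers KA and n from the exact log-line", {
  d <- double_log_fit(make_hill_series(ka = 1e6, n_hill = 1.21))
  expect_equal(d$n, 1.21, tolerance = 1e-6)
  expect_equal(d$ka, 1e6, tolerance = 1e-6)
  expect_equal(d$log_ka, 6, tolerance = 1e-6)

  # single-site generator gives n = 1 exactly
  d1 <- double_log_fit(make_hill_series(ka = 1e12, n_hill = 1,
                                        lo = 1e-13, hi = 1e-12))
  expect_equal(d1$n, 1, tolerance = 1e-9)

  # unquenched points are dropped with a warning
  ser <- make_hill_series()
  ser$spectra[[2]]$intensity <- ser$spectra[[1]]$intensity
  expect_warning(double_log_fit(ser), "dropped")
})

test_that("binding-site exponents near 1 come out of Stern-Volmer-like data", {
  # regenerated single-site parameter sets: n must land in (0.9, 1.6)
  for (ksv in c(2.4e12, 3.6e12, 2.5e12, 2.7e12)) {
    ser <- make_sv_series(ksv = ksv, qmax = 2 / ksv)
    d <- double_log_fit(ser)
    expect_gt(d$n, 0.9)
    expect_lt(d$n, 1.6)
  }
})

test_that("fit families agree on simple static data", {
  ser <- make_sv_series(ksv = 2e12)
  sv <- stern_volmer_fit(ser)
  dl <- double_log_fit(ser)
  # F0/F = 1 + K[Q] is (F0-F)/F = K[Q]: a Hill law with n = 1, KA = Ksv
  expect_equal(dl$n, 1, tolerance = 1e-4)
  expect_equal(dl$ka, sv$ksv, tolerance = 1e-4)

  # accessible-fraction law with fa = 1 degenerates to Stern-Volmer
  ser2 <- make_msv_series(fa = 1, ka = 7e11)
  expect_equal(modified_stern_volmer_fit(ser2)$ka,
               stern_volmer_fit(ser2)$ksv, tolerance = 1e-6)
})

test_that("fits report constants in the unit of the concentration grid", {
  # the same physical data expressed in mM gives Ksv in mM^-1
  ser_m <- make_sv_series(ksv = 2.3e12, unit = "M")
  ser_mm <- titration_series(ser_m$spectra,
                             ser_m$concentrations * 1e3, unit = "mM")
  fit_m <- stern_volmer_fit(ser_m)
  fit_mm <- stern_volmer_fit(ser_mm)
  expect_equal(per_conc_to_per_molar(fit_mm$ksv, "mM"), fit_m$ksv,
               tolerance = 1e-9)
})
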