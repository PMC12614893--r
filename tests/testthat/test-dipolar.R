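test_that("dipolar kernel matches its physical definition", {
  tg <- seq(0, 2000, by = 20)
  rg <- seq(2, 6, by = 0.1)
  K <- dipolar_kernel(tg, rg)

  # zero-time row is exactly 1 for every distance column
  expect_equal(unname(K[1, ]), rep(1, length(rg)))

  # dipolar frequency constant agrees with CODATA first principles
  expect_equal(52.04, codata_dipolar_mhz(1), tolerance = 2e-4)

  # spot values agree with the Fresnel closed form and dense quadrature
  i <- match(500, tg); j <- match(3, rg)
  expect_equal(K[i, j], kernel_fresnel_oracle(500, 3), tolerance = 1e-8)
  expect_equal(K[i, j], kernel_quadrature(500, 3), tolerance = 1e-6)
  for (t in c(120, 1500)) for (r in c(2.2, 4.6)) {
    expect_equal(dipolar_kernel(c(0, t), c(r, r + 0.1))[2, 1],
                 kernel_fresnel_oracle(t, r), tolerance = 1e-8)
  }

  # powder average of a cosine is bounded: [-0.5, 1]
  Kd <- dipolar_kernel(seq(0, 8000, by = 8), seq(1.5, 8, by = 0.02))
  expect_true(all(Kd <= 1 + 1e-12))
  expect_true(all(Kd >= -0.5 - 1e-12))

  expect_error(dipolar_kernel(c(0, 10, 15), c(2, 3)), "uniform")
  expect_error(dipolar_kernel(c(0, 10), c(0.5, 1.5)), "1, 12")
})

test_that("stretched-exponential background behaves analytically", {
  fit <- background_fit(dim = 3, k = 2e-4, lambda_mod = 0.4)
  expect_equal(background_decay(0, fit), 1)
  expect_equal(background_decay(c(0, 100, 5000),
                                background_fit(k = 0, lambda_mod = 0.3)),
               rep(1, 3))
  t <- c(13, 250, 999, 1500, 2200, 3100, 4000, 4700, 55, 5000)
  expect_equal(background_decay(t, fit), exp(-2e-4 * t))
  fit2 <- background_fit(dim = 2, k = 1e-3, lambda_mod = 0.2)
  expect_equal(background_decay(t, fit2), exp(-1e-3 * t^(2 / 3)))
  expect_error(background_decay(-5, fit), "non-negative")
  expect_error(background_fit(lambda_mod = 0), "lambda")
  expect_error(background_fit(dim = 8), "dim")
})

test_that("trace simulation is deterministic and linear in the distribution", {
  bg <- background_fit(dim = 3, k = 5e-5, lambda_mod = 0.3)
  acq <- acquisition_params(tau2 = 2000, dt = 8)
  g1 <- gaussian_mixture(data.frame(modal = 3.5, sigma = 0.4, weight = 1))
  g2 <- gaussian_mixture(data.frame(modal = 4.5, sigma = 0.5, weight = 1))

  # lambda -> 0 limit: the trace is the bare background
  bg0 <- background_fit(dim = 3, k = 5e-5, lambda_mod = 1e-9)
  v0 <- simulate_trace(g1, bg0, acq, noise_sd = 0)
  expect_equal(v0$real, background_decay(v0$time, bg0), tolerance = 1e-6)

  # identical seed implies byte-identical traces
  a <- simulate_trace(g1, bg, acq, noise_sd = 0.02, seed = 42)
  b <- simulate_trace(g1, bg, acq, noise_sd = 0.02, seed = 42)
  expect_identical(a, b)
  c2 <- simulate_trace(g1, bg, acq, noise_sd = 0.02, seed = 43)
  expect_false(identical(a$real, c2$real))

  # linearity in P at fixed lambda and B (noise off); the mixture density is
  # built from the already-normalised components so the identity is exact
  mix <- distance_distribution(g1$r, 0.3 * g1$p + 0.7 * g2$p)
  v_mix <- simulate_trace(mix, bg, acq, noise_sd = 0)$real
  v_lin <- 0.3 * simulate_trace(g1, bg, acq, noise_sd = 0)$real +
    0.7 * simulate_trace(g2, bg, acq, noise_sd = 0)$real
  # the two pure-component traces each contain the unmodulated background,
  # which is itself linear, so the combination matches directly
  expect_equal(v_mix, v_lin, tolerance = 1e-9)
})

test_that("noiseless simulate/invert round trip recovers the modal distance", {
  tt <- make_test_trace(modal = 3.8, sigma = 0.60, noise_sd = 0)
  inv <- invert_trace(tt$trace, t_cut = 4000, start_frac = 0.5, alpha = 10)
  expect_lt(abs(distribution_stats(inv$dist)$modal - 3.8), 0.1)
})

test_that("ASCII trace files round-trip including metadata", {
  tt <- make_test_trace(noise_sd = 0.01, tau2 = 2000, dt = 8)
  path <- withr::local_tempfile(fileext = ".dat")
  write_trace(tt$trace, path)
  back <- load_trace(path)
  expect_equal(back$time, tt$trace$time)
  expect_equal(back$real, tt$trace$real, tolerance = 1e-8)
  expect_equal(back$imag, tt$trace$imag, tolerance = 1e-8)
  expect_equal(back$acq$tau2, tt$trace$acq$tau2)

  # two-column file loads with no quadrature channel
  writeLines(c("# comment", paste(seq(0, 792, by = 8),
                                  exp(-seq(0, 792, by = 8) / 1000))),
             path)
  two <- load_trace(path)
  expect_null(two$imag)
})

test_that("Bruker BES3T pair loads identically to its ASCII twin", {
  tt <- make_test_trace(noise_sd = 0.005, tau2 = 2000, dt = 8)
  stem <- withr::local_tempfile(fileext = ".DTA")
  write_trace(tt$trace, stem, dialect = "bruker")
  back <- load_trace(stem, dialect = "bruker")
  expect_equal(back$time, tt$trace$time, tolerance = 1e-9)
  expect_identical(back$real, tt$trace$real)   # float64 is exact
  expect_identical(back$imag, tt$trace$imag)
  expect_error(load_trace(withr::local_tempfile(fileext = ".DTA"),
                          dialect = "bruker"), "descriptor")
})
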