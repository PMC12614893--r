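test_that("phase correction recovers a rotated signal and is a no-op on real data", {
  tt <- make_test_trace(noise_sd = 0, tau2 = 2000, dt = 8)
  real_only <- dipolar_trace(tt$trace$time, tt$trace$real, acq = tt$trace$acq,
                             normalise = FALSE)
  expect_identical(phase_correct(real_only), real_only)

  # rotate a real trace by 0.7 rad, correct, recover the original real part
  phi <- 0.7
  z <- complex(real = tt$trace$real, imaginary = 0) * exp(1i * phi)
  rotated <- dipolar_trace(tt$trace$time, Re(z), imag = Im(z),
                           acq = tt$trace$acq, normalise = FALSE)
  fixed <- phase_correct(rotated)
  expect_equal(fixed$real, tt$trace$real, tolerance = 1e-9)

  # the tail imaginary RMS never increases
  noisy <- make_test_trace(noise_sd = 0.02, tau2 = 2000, dt = 8, seed = 9)$trace
  zn <- complex(real = noisy$real, imaginary = noisy$imag) * exp(1i * 0.4)
  rot <- dipolar_trace(noisy$time, Re(zn), imag = Im(zn), acq = noisy$acq,
                       normalise = FALSE)
  fix <- phase_correct(rot)
  n <- length(rot$time); tail_idx <- seq.int(floor(n / 2), n)
  expect_lte(sqrt(mean(fix$imag[tail_idx]^2)),
             sqrt(mean(rot$imag[tail_idx]^2)) + 1e-12)
})

test_that("truncation keeps the right samples and preserves the inversion", {
  tt <- make_test_trace(noise_sd = 0, tau2 = 5000, dt = 4)
  full <- tt$trace
  expect_equal(truncate_trace(full, max(full$time))$real, full$real)
  cut <- truncate_trace(full, 4000)
  expect_length(cut$time, floor(4000 / 4) + 1)
  expect_equal(cut$acq$t_max, 4000)
  expect_error(truncate_trace(full, 30), "degenerate")

  inv_full <- invert_trace(full, start_frac = 0.5, alpha = 100)
  inv_cut <- invert_trace(cut, start_frac = 0.5, alpha = 100)
  expect_lt(abs(distribution_stats(inv_full$dist)$modal -
                  distribution_stats(inv_cut$dist)$modal), 0.05 + 1e-9)
})

test_that("background fitting recovers known decay parameters", {
  # long window so the dipolar modulation has fully dephased in the fit tail
  tt <- make_test_trace(modal = 3.8, sigma = 0.60, noise_sd = 0,
                        lambda = 0.3, k = 5e-5, tau2 = 8000, dt = 8)
  tr <- tt$trace
  fit <- fit_background(tr, start_frac = 0.5)
  expect_lt(abs(fit$k - 5e-5) / 5e-5, 0.01)
  expect_lt(abs(fit$lambda_mod - 0.3) / 0.3, 0.01)

  # modulation-free trace: fitted depth collapses
  t <- seq(0, 4000, by = 8)
  flat <- dipolar_trace(t, exp(-5e-5 * t), normalise = FALSE)
  expect_lte(fit_background(flat, start_frac = 0.4)$lambda_mod, 0.02)

  tr <- truncate_trace(make_test_trace(noise_sd = 0)$trace, 4000)
  # automated mode minimises its tail criterion over the scanned grid
  tail_sel <- tr$time >= 0.75 * max(tr$time)
  v <- tr$real / tr$real[1]
  tail_mis <- function(f) {
    pred <- (1 - f$lambda_mod) * background_decay(tr$time[tail_sel], f)
    mean((v[tail_sel] - pred)^2)
  }
  auto <- fit_background(tr)
  scan <- seq(0.1, 0.8, by = 0.05)
  expect_true(auto$start_frac %in% scan)
  fixed_mis <- vapply(scan, function(sf)
    tail_mis(fit_background(tr, start_frac = sf)), numeric(1))
  expect_lte(tail_mis(auto), min(fixed_mis) + 1e-15)

  expect_error(fit_background(tr, start_frac = 0.9), "start_frac")
})

test_that("background correction yields the form factor exactly", {
  tt <- make_test_trace(modal = 4.0, sigma = 0.5, noise_sd = 0,
                        tau2 = 3000, dt = 8)
  corr <- form_factor(tt$trace, tt$background)
  K <- dipolar_kernel(corr$time, tt$truth$r)
  dr <- tt$truth$r[2] - tt$truth$r[1]
  expect_equal(corr$real, as.vector(K %*% tt$truth$p) * dr, tolerance = 1e-9)
  expect_equal(corr$real[1], 1, tolerance = 1e-9)

  # modulation-free trace: the corrected signal is flat 1 whatever depth
  # the background model assumes
  bg0 <- background_fit(dim = 3, k = 5e-5, lambda_mod = 1e-9)
  g0 <- gaussian_mixture(data.frame(modal = 4, sigma = 0.5, weight = 1))
  v0 <- simulate_trace(g0, bg0, acquisition_params(tau2 = 2000, dt = 8))
  fit03 <- background_fit(dim = 3, k = 5e-5, lambda_mod = 0.3)
  expect_equal(form_factor(v0, fit03)$real, rep(1, length(v0$time)),
               tolerance = 1e-5)
})

test_that("non-negative Tikhonov inversion matches the reference NNLS solver", {
  set.seed(11)
  for (i in 1:5) {
    m <- 40; n <- 15
    A <- matrix(rnorm(m * n), m, n)
    b <- rnorm(m)
    ours <- fnnls(crossprod(A), as.vector(crossprod(A, b)))
    ref <- pracma::lsqnonneg(A, b)$x
    expect_equal(as.vector(ours), ref, tolerance = 1e-8)
  }
})

test_that("Tikhonov solutions are non-negative, normalised, and alpha-monotone", {
  tt <- make_test_trace(modal = 3.8, sigma = 0.6, noise_sd = 0,
                        tau2 = 3000, dt = 8)
  corr <- form_factor(tt$trace, tt$background)
  sol <- tikhonov(corr, alpha = 10)
  expect_true(all(sol$dist$p >= 0))
  dr <- sol$dist$r[2] - sol$dist$r[1]
  expect_equal(sum(sol$dist$p) * dr, 1, tolerance = 1e-9)

  # round trip: overlap with the generating distribution
  expect_gte(bhattacharyya(sol$dist, tt$truth), 0.99)

  # roughness decreases monotonically with alpha; huge alpha flattens
  pens <- vapply(c(1, 10, 100, 1e4, 1e6), function(a)
    tikhonov(corr, alpha = a)$pen_norm, numeric(1))
  expect_true(all(diff(pens) <= 1e-12))
  expect_lt(pens[5] / pens[1], 1e-2)

  expect_error(tikhonov(corr, alpha = -1), "positive")
})

test_that("L-curve corner selection is stable and close to the oracle alpha", {
  tt <- make_test_trace(modal = 4.0, sigma = 0.45, noise_sd = 1 / 30,
                        tau2 = 3000, dt = 8, seed = 3)
  tr <- phase_correct(tt$trace)
  corr <- form_factor(tr, tt$background)
  alphas <- 10^seq(-1, 4, by = 0.5)
  a <- lcurve_alpha(corr, alpha_list = alphas)
  expect_true(as.numeric(a) %in% alphas)

  # oracle: alpha minimising the error against the generating distribution
  errs <- vapply(attr(a, "solutions"), function(s)
    1 - bhattacharyya(s$dist, tt$truth), numeric(1))
  a_oracle <- attr(a, "alphas")[which.min(errs)]
  expect_lte(abs(log10(as.numeric(a)) - log10(a_oracle)), 1)

  # appending extreme candidates does not move the corner
  a2 <- lcurve_alpha(corr, alpha_list = c(1e-6, alphas, 1e6))
  expect_equal(as.numeric(a2), as.numeric(a))

  expect_error(lcurve_alpha(corr, alpha_list = c(1, 10)), "at least 3")
})

test_that("distribution statistics follow the FWHM definitions", {
  # exact Gaussians reproduce the FWHM = 2 sqrt(2 ln 2) sigma identity
  for (sg in c(0.60, 0.34)) {
    d <- gaussian_mixture(data.frame(modal = 4.5, sigma = sg, weight = 1))
    st <- distribution_stats(d)
    expect_equal(st$fwhm, 2 * sqrt(2 * log(2)) * sg, tolerance = 1e-3)
    expect_equal(st$sigma, sg, tolerance = 1e-3)
    expect_equal(st$modal, 4.5, tolerance = 0.011)
  }

  # bimodal with a genuine dip below half-maximum: mode and FWHM refer to
  # the taller (global) peak only
  rg <- default_r_grid()
  p <- dnorm(rg, 3.6, 0.12) + 1.1 * dnorm(rg, 4.3, 0.12)
  bi <- distance_distribution(rg, p)
  st <- distribution_stats(bi)
  expect_equal(st$modal, 4.3, tolerance = 0.011)
  # brute-force half-max interval around the 4.3 peak
  half <- max(bi$p) / 2
  above <- rg[bi$p >= half & abs(rg - 4.3) < 0.4]
  expect_equal(st$fwhm, max(above) - min(above), tolerance = 0.05)
  expect_lt(st$fwhm, 0.8)        # does not bridge to the 3.6 nm mode

  expect_error(distance_distribution(rg, rep(0, length(rg))), "zero")
})

test_that("reliability zones scale as the cube root of the time window", {
  z <- reliability_zones(4000)
  expect_true(all(diff(z) > 0))
  expect_named(z, c("shape", "width", "mean", "detect"))
  expect_gte(z[["shape"]], 4)          # 4 us certifies shape out to >= 4 nm
  expect_equal(unname(reliability_zones(8000) / z), rep(2^(1 / 3), 4),
               tolerance = 1e-12)
  expect_error(reliability_zones(0), "positive")
})

test_that("validation ensemble follows the two-round protocol", {
  tt <- make_test_trace(modal = 3.8, sigma = 0.6, noise_sd = 0.01,
                        tau2 = 3000, dt = 12, seed = 5)
  tr <- phase_correct(tt$trace)
  ens <- validate_trace(tr, n_bg = 16, n_noise = 50, seed = 2)
  expect_equal(sum(ens$trials$type == "background"), 16)
  expect_equal(sum(ens$trials$type == "noise"), 50)
  starts <- ens$trials$start_frac[ens$trials$type == "background"]
  expect_equal(range(starts), c(0.05, 0.80))
  # the unperturbed best-start trial survives pruning
  base_row <- ens$trials$type == "background" &
    abs(ens$trials$start_frac - ens$best_start) < 1e-12
  expect_true(all(ens$trials$kept[base_row]))
  # band sanity: encloses its own point estimate
  expect_true(all(ens$consensus$ci_lower <= ens$consensus$p + 1e-12))
  expect_true(all(ens$consensus$ci_upper >= ens$consensus$p - 1e-12))

  # degenerate protocol: no noise, single start -> all trials identical,
  # zero-width band
  ens0 <- validate_trace(tr, n_bg = 3, bg_range = c(0.4, 0.4),
                         noise_level = 0, n_noise = 4, seed = 2)
  expect_equal(max(ens0$consensus$ci_upper - ens0$consensus$ci_lower), 0,
               tolerance = 1e-12)
})
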