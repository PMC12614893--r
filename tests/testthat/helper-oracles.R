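# Independent oracles used across the suite.

# Dipolar frequency at r nm from CODATA constants: mu0 g^2 beta_e^2 / (4 pi h r^3)
codata_dipolar_mhz <- function(r_nm) {
  mu0 <- 4 * pi * 1e-7          # N A^-2
  g <- 2.00231930436            # free-electron g
  beta_e <- 9.2740100783e-24    # J T^-1
  h <- 6.62607015e-34           # J s
  mu0 * g^2 * beta_e^2 / (4 * pi * h * (r_nm * 1e-9)^3) / 1e6
}

# brute-force powder average by dense quadrature (trapezoid, n points)
kernel_quadrature <- function(t_ns, r_nm, n = 2e5) {
  x <- seq(0, 1, length.out = n)
  phi <- 2 * pi * 52.04e-3 * t_ns / r_nm^3
  y <- cos((1 - 3 * x^2) * phi)
  sum((y[-1] + y[-n]) / 2) / (n - 1)
}

# closed-form kernel via Fresnel integrals (independent of the package's
# Gauss-Legendre evaluation path)
kernel_fresnel_oracle <- function(t_ns, r_nm) {
  phi <- 2 * pi * 52.04e-3 * t_ns / r_nm^3
  if (phi < 1e-8) return(1)
  z <- sqrt(6 * phi / pi)
  sqrt(pi / (6 * phi)) *
    (cos(phi) * pracma::fresnelC(z) + sin(phi) * pracma::fresnelS(z))
}

# Horn's quaternion method for optimal superposition RMSD: an independent
# check on the Kabsch/SVD route
quaternion_rmsd <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  A <- sweep(X, 2, cx); B <- sweep(Y, 2, cy)
  M <- crossprod(A, B)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(X)
  sqrt(max(msd, 0))
}

# small noiseless / noisy single-Gaussian trace factory shared by tests
make_test_trace <- function(modal = 3.8, sigma = 0.60, noise_sd = 0,
                            dt = 4, tau2 = 5000, lambda = 0.3, k = 5e-5,
                            seed = 1L, r_grid = default_r_grid()) {
  truth <- gaussian_mixture(data.frame(modal = modal, sigma = sigma,
                                       weight = 1), r_grid)
  trace <- simulate_trace(truth,
                          background_fit(dim = 3, k = k, lambda_mod = lambda),
                          acquisition_params(tau2 = tau2, dt = dt),
                          noise_sd = noise_sd, seed = seed)
  list(trace = trace, truth = truth,
       background = background_fit(dim = 3, k = k, lambda_mod = lambda))
}

# directory holding locally fetched structure/EPR accessions, if any
accession_dir <- function() {
  getOption("deerens.accession_dir",
            file.path(testthat::test_path(), "accessions"))
}
accession_path <- function(...) file.path(accession_dir(), ...)
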