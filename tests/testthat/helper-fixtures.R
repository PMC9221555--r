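# Small randomized model states and data sets used across the unit tests.
# Everything is generated in code under a caller-controlled seed.

# a handful of stochastic end-to-end checks are allowed to fail without
# cutting the run short; keep reporting everything
options(testthat.progress.max_fails = 1000L)

random_state <- function(p = 4, r = 2, r1 = 2, r2 = 2, K = 6, kappa_sd = 0.5) {
  model_state(
    Lambda = matrix(rnorm(p * r), p, r),
    Gamma1 = matrix(rnorm(p * r1), p, r1),
    Gamma2 = matrix(rnorm(p * r2), p, r2),
    Xi1 = rnorm(r), Xi2 = rnorm(r),
    beta = matrix(rnorm(r * K), r, K),
    beta1 = matrix(rnorm(r1 * K), r1, K),
    beta2 = matrix(rnorm(r2 * K), r2, K),
    kappa = rnorm(K - 1, 0, kappa_sd),
    sig1sq = runif(p, 0.5, 2), sig2sq = runif(p, 0.5, 2),
    phi1 = matrix(rgamma(p * r, 3, 3), p, r),
    phi11 = matrix(rgamma(p * r1, 3, 3), p, r1),
    phi12 = matrix(rgamma(p * r2, 3, 3), p, r2),
    delta1 = rgamma(r, 2, 1), delta11 = rgamma(r1, 2, 1),
    delta12 = rgamma(r2, 2, 1))
}

random_instance <- function(p = 4, Tn = 20, r = 2, r1 = 2, r2 = 2, K = 6,
                            noise_sd = 1) {
  bases <- tacifa_bases(K)
  tg <- seq_len(Tn) / Tn
  state <- random_state(p, r, r1, r2, K)
  mu <- mean_curves(state, bases, tg)
  data <- paired_series(mu$mu_X + noise_sd * matrix(rnorm(p * Tn), p, Tn),
                        mu$mu_Y + noise_sd * matrix(rnorm(p * Tn), p, Tn),
                        tg, rescale = "never")
  list(state = state, data = data, bases = bases, t = tg)
}

# numeric central-difference gradient of f at x
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# random orthonormal matrix (QR of a Gaussian, sign-fixed)
random_rotation <- function(r) {
  qr_ <- qr(matrix(rnorm(r * r), r, r))
  Q <- qr.Q(qr_)
  Q %*% diag(sign(diag(qr.R(qr_))), r, r)
}

fast_config <- function(...) {
  sampler_config(hmc = hmc_settings(leapfrog_steps = 10), ...)
}
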