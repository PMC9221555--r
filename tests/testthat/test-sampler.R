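# HMC gradients against finite differences, conjugate-block oracles, the
# adaptation and pruning rules, and the run loop contract.

test_that("warp-block gradient matches centered finite differences", {
  set.seed(31)
  inst <- random_instance(p = 3, Tn = 20, r = 2, K = 6)
  cfg <- sampler_config(K = 6)
  cd <- tacifa:::as_cpp_data(inst$data)
  cb <- tacifa:::as_cpp_bases(inst$bases)
  st <- inst$state
  pot <- tacifa:::cpp_kappa_potential(unclass(st), cd, cb, cfg$hyper)
  f <- function(k) {
    s <- st; s$kappa <- k
    tacifa:::cpp_kappa_potential(unclass(s), cd, cb, cfg$hyper)$value
  }
  fd <- fd_gradient(f, st$kappa)
  expect_lt(max(abs(pot$grad - fd) / pmax(abs(fd), 1e-6)), 1e-5)
})

test_that("loading-column gradient matches finite differences (projector algebra)", {
  set.seed(32)
  inst <- random_instance(p = 5, Tn = 15, r = 3, K = 6)
  cfg <- sampler_config(K = 6)
  cd <- tacifa:::as_cpp_data(inst$data)
  cb <- tacifa:::as_cpp_bases(inst$bases)
  st <- inst$state
  for (j in 1:3) {
    lam <- st$Lambda[, j]
    pot <- tacifa:::cpp_lambda_potential(unclass(st), cd, cb, cfg$hyper, j, lam)
    f <- function(l) tacifa:::cpp_lambda_potential(unclass(st), cd, cb,
                                                   cfg$hyper, j, l)$value
    fd <- fd_gradient(f, lam)
    expect_lt(max(abs(pot$grad - fd) / pmax(abs(fd), 1e-6)), 1e-5)
  }
})

test_that("block-matrix projector identity (1-P1)(1-P2)(1-P1) = Psi", {
  set.seed(33)
  for (i in 1:20) {
    p <- sample(4:8, 1); r <- sample(2:(p - 1), 1)
    Lam <- matrix(rnorm(p * r), p, r)
    j <- sample(r, 1)
    Lm <- Lam[, -j, drop = FALSE]; lj <- Lam[, j, drop = FALSE]
    P1 <- Lm %*% solve(crossprod(Lm), t(Lm))
    IP1 <- diag(p) - P1
    P2 <- lj %*% solve(t(lj) %*% IP1 %*% lj, t(lj))
    expect_lt(max(abs(IP1 %*% (diag(p) - P2) %*% IP1 - projection(Lam))), 1e-10)
  }
})

test_that("zero step size leaves the state unchanged", {
  set.seed(34)
  inst <- random_instance()
  cfg <- sampler_config(K = 6)
  cfg$hmc$step_size_kappa <- 0
  cfg$hmc$step_size_lambda <- 0
  out <- hmc_update_kappa(inst$state, inst$data, inst$bases, cfg)
  expect_equal(out$state$kappa, inst$state$kappa)
  expect_equal(out$accept, 0)
  out2 <- hmc_update_lambda_column(inst$state, inst$data, inst$bases, cfg, 1)
  expect_equal(out2$state$Lambda, inst$state$Lambda)
})

test_that("factor-coefficient full conditional matches the Bayesian regression posterior", {
  set.seed(35)
  # r = 1 so the beta block is a single Bayesian linear regression with
  # design [a1 (x) B; a2 (x) B~] and prior N(0, omega I); compare the
  # Monte Carlo mean/covariance of repeated Gibbs draws to the closed form.
  inst <- random_instance(p = 3, Tn = 25, r = 1, K = 5)
  st <- inst$state; dat <- inst$data; bases <- inst$bases
  cfg <- sampler_config(K = 5)
  omega <- cfg$hyper$omega
  B <- eval_basis(bases$shared, dat$t)
  M <- eval_warp(warp_spec(st$kappa), bases$warp, dat$t)
  BM <- eval_basis(bases$shared, M)
  Psi <- projection(st$Lambda)
  a1 <- st$Lambda[, 1] * st$Xi1
  a2 <- st$Lambda[, 1] * st$Xi2
  X1 <- dat$X - Psi %*% st$Gamma1 %*% (st$beta1 %*% t(eval_basis(bases$ind1, dat$t)))
  Y1 <- dat$Y - Psi %*% st$Gamma2 %*% (st$beta2 %*% t(eval_basis(bases$ind2, dat$t)))
  P <- sum(a1^2 / st$sig1sq) * crossprod(B) +
    sum(a2^2 / st$sig2sq) * crossprod(BM) + diag(5) / omega
  ell <- t(B) %*% (t(X1) %*% (a1 / st$sig1sq)) +
    t(BM) %*% (t(Y1) %*% (a2 / st$sig2sq))
  mu_closed <- solve(P, ell)
  draws <- t(replicate(4000, {
    gibbs_update_linear_blocks(st, dat, bases, cfg, blocks = "beta")$beta[1, ]
  }))
  expect_equal(colMeans(draws), drop(mu_closed), tolerance = 0.05)
  expect_equal(cov(draws), solve(P), tolerance = 0.15)
})

test_that("an (effectively) infinitely tight prior collapses the coefficient draw", {
  set.seed(36)
  inst <- random_instance(p = 3, Tn = 20, r = 2, K = 5)
  cfg <- sampler_config(K = 5, hyper = list(omega = 1e-12))
  out <- gibbs_update_linear_blocks(inst$state, inst$data, inst$bases, cfg,
                                    blocks = "beta")
  expect_lt(max(abs(out$beta)), 1e-3)
})

test_that("likelihood-free limit: loading column HMC samples its prior", {
  set.seed(37)
  inst <- random_instance(p = 4, Tn = 10, r = 2, K = 5)
  st <- inst$state
  st$sig1sq <- rep(1e8, 4)   # drown the likelihood
  st$sig2sq <- rep(1e8, 4)
  st$phi1[] <- 1
  st$delta1 <- c(1, 1)       # prior on each entry is then N(0, 1)
  cfg <- sampler_config(K = 5, hmc = hmc_settings(step_size_lambda = 0.5,
                                                  leapfrog_steps = 10))
  draws <- matrix(NA_real_, 800, 4)
  acc <- 0
  for (i in seq_len(800)) {
    out <- hmc_update_lambda_column(st, inst$data, inst$bases, cfg, 2)
    st <- out$state
    acc <- acc + out$accept
    draws[i, ] <- st$Lambda[, 2]
  }
  expect_gt(acc / 800, 0.5)
  expect_lt(max(abs(colMeans(draws))), 0.25)
  expect_equal(mean(apply(draws, 2, sd)), 1, tolerance = 0.25)
})

test_that("step-size adaptation follows the acceptance-band rule", {
  s <- hmc_settings(step_size_kappa = 0.1, step_size_lambda = 0.2)
  low <- adapt_step_sizes(s, list(kappa = 0.5, lambda = 0.5))
  expect_lt(low$step_size_kappa, 0.1)
  expect_lt(low$step_size_lambda, 0.2)
  mid <- adapt_step_sizes(s, list(kappa = 0.7, lambda = 0.7))
  expect_equal(mid$step_size_kappa, 0.1)
  expect_equal(mid$step_size_lambda, 0.2)
  high <- adapt_step_sizes(s, list(kappa = 1.0, lambda = 1.0))
  expect_gt(high$step_size_kappa, 0.1)
  expect_gt(high$step_size_lambda, 0.2)
})

test_that("pruning removes all-small columns with their bookkeeping, never below rank 1", {
  set.seed(38)
  st <- random_state(p = 4, r = 3, r1 = 2, r2 = 2, K = 6)
  st$Lambda[, 2] <- runif(4, -5e-4, 5e-4)
  st2 <- prune_columns(st, threshold = 1e-3)
  expect_equal(ncol(st2$Lambda), 2)
  expect_equal(st2$Lambda, st$Lambda[, c(1, 3)])
  expect_equal(st2$Xi1, st$Xi1[c(1, 3)])
  expect_equal(st2$beta, st$beta[c(1, 3), ])
  expect_equal(st2$phi1, st$phi1[, c(1, 3)])
  expect_equal(st2$delta1, st$delta1[c(1, 3)])
  # all columns above threshold: unchanged
  st3 <- prune_columns(st2, threshold = 1e-3)
  expect_equal(st3$Lambda, st2$Lambda)
  # rank floor at 1
  st$Lambda[] <- 1e-6
  st4 <- prune_columns(st, threshold = 1e-3)
  expect_equal(ncol(st4$Lambda), 1)
})

test_that("run_mcmc is reproducible under a fixed seed and tolerates zero iterations", {
  sim <- generate_sim1(T = 60, p = 6, seed = 39)
  cfg <- fast_config(n_iter = 60, n_burnin = 30, K = 6, seed = 5)
  c1 <- run_mcmc(sim$data, cfg)
  c2 <- run_mcmc(sim$data, cfg)
  expect_identical(c1$draws, c2$draws)
  expect_identical(c1$rank_history, c2$rank_history)
  c0 <- run_mcmc(sim$data, fast_config(n_iter = 0, n_burnin = 0, K = 6, seed = 5))
  expect_length(c0$draws, 0)
})

test_that("joint prior-data and conditional sampling agree on the noise scale (Geweke-style)", {
  # marginal-conditional vs successive-conditional simulation at toy size:
  # if every full conditional is correct, alternating parameter updates with
  # data regeneration leaves the prior invariant. Compared on log sigma^2
  # (the inverse-gamma(0.1, .) mean does not exist).
  set.seed(40)
  p <- 2; Tn <- 10; K <- 5
  bases <- tacifa_bases(K)
  tg <- seq_len(Tn) / Tn
  cfg <- sampler_config(K = K,
                        hyper = list(a_sigma = 2, b_sigma = 2, omega = 1,
                                     nu1 = 3, a_delta1 = 2, a_delta2 = 2),
                        hmc = hmc_settings(step_size_kappa = 0.2,
                                           step_size_lambda = 0.2,
                                           leapfrog_steps = 8))
  draw_prior_state <- function() {
    r <- 1
    delta1 <- rgamma(r, cfg$hyper$a_delta1, 1)
    phi1 <- matrix(rgamma(p * r, 3, 3), p, r)
    model_state(
      Lambda = matrix(rnorm(p * r), p, r) / sqrt(phi1 * delta1),
      Gamma1 = matrix(rnorm(p, 0, 1), p, 1), Gamma2 = matrix(rnorm(p, 0, 1), p, 1),
      Xi1 = rnorm(1, 0, 1), Xi2 = rnorm(1, 0, 1),
      beta = matrix(rnorm(K, 0, 1), 1, K), beta1 = matrix(rnorm(K, 0, 1), 1, K),
      beta2 = matrix(rnorm(K, 0, 1), 1, K), kappa = rnorm(K - 1, 0, 1),
      sig1sq = 1 / rgamma(p, 2, 2), sig2sq = 1 / rgamma(p, 2, 2),
      phi1 = phi1, delta1 = delta1)
  }
  gen_data <- function(st) {
    mu <- mean_curves(st, bases, tg)
    paired_series(mu$mu_X + rnorm(p * Tn) * sqrt(st$sig1sq),
                  mu$mu_Y + rnorm(p * Tn) * sqrt(st$sig2sq),
                  tg, rescale = "never")
  }
  n_mc <- 2000
  prior_stat <- replicate(n_mc, mean(log(draw_prior_state()$sig1sq)))
  st <- draw_prior_state()
  succ_stat <- numeric(n_mc)
  for (i in seq_len(n_mc)) {
    dat <- gen_data(st)
    st <- gibbs_update_linear_blocks(st, dat, bases, cfg)
    st <- hmc_update_kappa(st, dat, bases, cfg)$state
    st <- hmc_update_lambda_column(st, dat, bases, cfg, 1)$state
    succ_stat[i] <- mean(log(st$sig1sq))
  }
  # conservative z-test; the successive chain is thinned for autocorrelation
  thin <- succ_stat[seq(10, n_mc, by = 5)]
  z <- (mean(thin) - mean(prior_stat)) /
    sqrt(var(thin) / length(thin) + var(prior_stat) / n_mc)
  expect_lt(abs(z), 5)
  expect_equal(sd(thin), sd(prior_stat), tolerance = 0.3)
})
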