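# Containers, projector, mean/likelihood machinery and the Syn statistic.

test_that("projection is the coordinate projector for identity-column loadings", {
  p <- 5; r <- 2
  Lam <- diag(p)[, 1:r]
  Psi <- projection(Lam)
  expect_equal(Psi, diag(c(rep(0, r), rep(1, p - r))))
})

test_that("projection is symmetric, idempotent, annihilating, with trace p - r", {
  set.seed(21)
  for (i in 1:100) {
    p <- sample(4:8, 1); r <- sample(1:(p - 1), 1)
    Lam <- matrix(rnorm(p * r), p, r)
    Psi <- projection(Lam)
    expect_lt(max(abs(Psi - t(Psi))), 1e-10)
    expect_lt(max(abs(Psi %*% Psi - Psi)), 1e-10)
    expect_lt(max(abs(Psi %*% Lam)), 1e-10)
    expect_equal(sum(diag(Psi)), p - r, tolerance = 1e-10)
  }
})

test_that("rank-deficient loadings fall back to a pseudo-inverse with warning", {
  Lam <- cbind(1:4, 2 * (1:4))
  expect_warning(Psi <- projection(Lam), "rank deficient")
  expect_lt(max(abs(Psi %*% Lam)), 1e-8)
  expect_equal(sum(diag(Psi)), 3, tolerance = 1e-8)  # rank is 1
})

test_that("paired_series validates and rescales grids", {
  X <- matrix(rnorm(15), 3, 5)
  ps <- paired_series(X, X)
  expect_equal(ps$t, seq(0, 1, length.out = 5))
  ps2 <- paired_series(X, X, t = 10 + 1:5)
  expect_equal(ps2$t, (0:4) / 4)
  expect_error(paired_series(X, X[, 1:4]), "share dimensions|must share")
  expect_error(paired_series(X, X, t = c(1, 2, 2, 3, 4) / 4), "increasing")
})

test_that("mean curves: identical shared parts with identity warp give mu_X = mu_Y", {
  set.seed(22)
  K <- 6
  bases <- tacifa_bases(K)
  st <- random_state(p = 5, r = 2, K = K)
  st$Gamma1[] <- 0
  st$Gamma2[] <- 0
  st$Xi2 <- st$Xi1
  # softmax-cumulative coefficients equal to Greville abscissae make M(t) = t,
  # achievable because the Greville increments are positive
  gv <- greville_abscissae(bases$warp)
  st$kappa <- log(diff(gv))
  mu <- mean_curves(st, bases, seq(0, 1, length.out = 40))
  expect_lt(max(abs(mu$M - seq(0, 1, length.out = 40))), 1e-10)
  expect_equal(mu$mu_X, mu$mu_Y, tolerance = 1e-10)
})

test_that("zero shared coefficients leave the pure individual space", {
  set.seed(23)
  bases <- tacifa_bases(6)
  st <- random_state(p = 5, r = 2, K = 6)
  st$beta[] <- 0
  tt <- seq(0, 1, length.out = 30)
  mu <- mean_curves(st, bases, tt)
  Psi <- projection(st$Lambda)
  zeta1 <- st$beta1 %*% t(eval_basis(bases$ind1, tt))
  expect_equal(mu$mu_X, Psi %*% st$Gamma1 %*% zeta1, tolerance = 1e-12)
})

test_that("shared and individual mean components are orthogonal at every t", {
  set.seed(24)
  bases <- tacifa_bases(6)
  st <- random_state(p = 6, r = 2, K = 6)
  tt <- seq(0, 1, length.out = 25)
  Psi <- projection(st$Lambda)
  cu <- tacifa:::state_curves(st, bases, tt)
  shared <- st$Lambda %*% (st$Xi1 * cu$eta)
  individual <- Psi %*% st$Gamma1 %*% cu$zeta1
  expect_lt(max(abs(colSums(shared * individual))), 1e-8)
})

test_that("log-likelihood equals the closed form at zero residuals", {
  set.seed(25)
  bases <- tacifa_bases(6)
  st <- random_state(p = 4, r = 2, K = 6)
  st$sig1sq <- rep(1, 4); st$sig2sq <- rep(1, 4)
  tt <- seq_len(10) / 10
  mu <- mean_curves(st, bases, tt)
  dat <- paired_series(mu$mu_X, mu$mu_Y, tt, rescale = "never")
  expect_equal(log_likelihood(st, dat, bases), -4 * 10 * log(2 * pi))
})

test_that("log-likelihood is separable across features and matches a naive sum", {
  set.seed(26)
  inst <- random_instance(p = 4, Tn = 10)
  st <- inst$state; dat <- inst$data; bases <- inst$bases
  mu <- mean_curves(st, bases, dat$t)
  naive <- sum(dnorm(dat$X, mu$mu_X, sqrt(st$sig1sq), log = TRUE)) +
    sum(dnorm(dat$Y, mu$mu_Y, sqrt(st$sig2sq), log = TRUE))
  expect_equal(log_likelihood(st, dat, bases), naive, tolerance = 1e-10)
  # doubling one feature's variance changes only that feature's terms
  st2 <- st
  st2$sig1sq[2] <- 2 * st$sig1sq[2]
  delta <- log_likelihood(st2, dat, bases) - log_likelihood(st, dat, bases)
  R1 <- dat$X - mu$mu_X
  expected <- sum(dnorm(R1[2, ], 0, sqrt(st2$sig1sq[2]), log = TRUE)) -
    sum(dnorm(R1[2, ], 0, sqrt(st$sig1sq[2]), log = TRUE))
  expect_equal(delta, expected, tolerance = 1e-10)
  st_bad <- st
  st_bad$sig1sq[1] <- -1
  expect_error(log_likelihood(st_bad, dat, bases), "positive")
})

test_that("Syn is 1 for two identical series and solvable by hand at p = T = 1", {
  set.seed(27)
  K <- 6
  bases <- tacifa_bases(K)
  st <- random_state(p = 5, r = 2, K = K)
  st$Gamma2 <- st$Gamma1
  st$beta2 <- st$beta1
  st$Xi2 <- st$Xi1
  st$sig2sq <- st$sig1sq
  gv <- greville_abscissae(bases$warp)
  st$kappa <- log(diff(gv))  # identity warp
  tt <- seq(0, 1, length.out = 40)
  expect_equal(syn_similarity(st, bases, tt), 1, tolerance = 1e-10)

  # hand instance: contributions 0.8 vs 0.3 -> Syn = 1 - |0.8 - 0.3| = 0.5
  # p = r = 1 so Psi = 0 and the individual terms vanish; constant shared
  # factor eta(t) = 1 via equal spline coefficients (partition of unity);
  # contribution a^2/(a^2 + 1) = 0.8 at a = 2, b^2/(b^2 + 1) = 0.3.
  st1 <- model_state(Lambda = matrix(1), Gamma1 = matrix(1), Gamma2 = matrix(1),
                     Xi1 = 2, Xi2 = sqrt(3 / 7),
                     beta = matrix(1, 1, K), beta1 = matrix(0, 1, K),
                     beta2 = matrix(0, 1, K), kappa = rep(0, K - 1),
                     sig1sq = 1, sig2sq = 1)
  expect_equal(syn_similarity(st1, bases, 0.5), 0.5, tolerance = 1e-10)
})

test_that("Syn is invariant to sign flips and column permutations preserving contributions", {
  set.seed(28)
  bases <- tacifa_bases(6)
  st <- random_state(p = 5, r = 3, K = 6)
  s0 <- syn_similarity(st, bases, seq(0, 1, length.out = 20))
  # flip signs of a column of Lambda together with its scale entries
  st2 <- st
  st2$Lambda[, 2] <- -st2$Lambda[, 2]
  st2$Xi1[2] <- -st2$Xi1[2]
  st2$Xi2[2] <- -st2$Xi2[2]
  expect_equal(syn_similarity(st2, bases, seq(0, 1, length.out = 20)), s0,
               tolerance = 1e-12)
  # permute columns together with scales and factor rows
  perm <- c(3, 1, 2)
  st3 <- st
  st3$Lambda <- st$Lambda[, perm]
  st3$Xi1 <- st$Xi1[perm]; st3$Xi2 <- st$Xi2[perm]
  st3$beta <- st$beta[perm, ]
  expect_equal(syn_similarity(st3, bases, seq(0, 1, length.out = 20)), s0,
               tolerance = 1e-12)
})
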