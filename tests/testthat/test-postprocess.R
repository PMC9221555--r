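# Procrustes alignment, SP importance, predictive and warp summaries.

test_that("procrustes_rotation recovers exact rotations and the r = 1 sign", {
  set.seed(51)
  A <- matrix(rnorm(8 * 3), 8, 3)
  expect_equal(procrustes_rotation(A, A), diag(3), tolerance = 1e-10)
  for (i in 1:20) {
    R0 <- random_rotation(3)
    B <- A %*% R0
    R <- procrustes_rotation(A, B)
    expect_lt(max(abs(R - t(R0))), 1e-10)
    expect_lt(max(abs(A - B %*% R)), 1e-10)
  }
  # r = 1: exhaustive oracle over {-1, +1}
  for (i in 1:20) {
    a <- matrix(rnorm(6), 6, 1)
    b <- matrix(rnorm(6), 6, 1)
    signs <- c(-1, 1)
    best <- signs[which.min(sapply(signs, function(s) sum((a - b * s)^2)))]
    expect_equal(drop(procrustes_rotation(a, b)), best)
  }
  expect_warning(procrustes_rotation(matrix(0, 4, 2), matrix(rnorm(8), 4, 2)),
                 "undefined")
})

test_that("procrustes solution beats random orthonormal rotations", {
  set.seed(52)
  A <- matrix(rnorm(10 * 3), 10, 3)
  B <- A %*% random_rotation(3) + 0.1 * matrix(rnorm(30), 10, 3)
  R <- procrustes_rotation(A, B)
  obj <- sum((A - B %*% R)^2)
  for (i in 1:1000) {
    expect_lte(obj, sum((A - B %*% random_rotation(3))^2) + 1e-12)
  }
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-10)
})

# a tiny chain fixture built by running the sampler briefly
make_small_chain <- function(seed = 53, n_iter = 80, n_burnin = 40) {
  sim <- generate_sim1(T = 60, p = 6, seed = seed)
  run_mcmc(sim$data, fast_config(n_iter = n_iter, n_burnin = n_burnin,
                                 K = 6, seed = seed))
}

test_that("aligning a chain of identical draws changes nothing (up to the initial transform)", {
  chain <- make_small_chain()
  d <- chain$draws[[length(chain$draws)]]
  chain$draws <- rep(list(d), 5)
  al <- align_chain(chain)
  for (m in 2:5) {
    expect_equal(al$Lambda1[[m]], al$Lambda1[[1]], tolerance = 1e-8)
    expect_equal(al$PsiGamma1[[m]], al$PsiGamma1[[1]], tolerance = 1e-8)
    expect_equal(al$beta[[m]], al$beta[[1]], tolerance = 1e-8)
  }
})

test_that("rotation-injected chains collapse back to a single loading", {
  set.seed(54)
  chain <- make_small_chain()
  d <- chain$draws[[length(chain$draws)]]
  r <- ncol(d$Lambda)
  # whiten the base draw so its factor curves are orthonormal on the grid;
  # rotations then preserve the curves' norms and the aligned chain must
  # collapse onto a single loading
  B <- eval_basis(chain$bases$shared, chain$data$t)
  eta <- d$beta %*% t(B)
  W <- solve(chol(tcrossprod(eta)))           # eta' = t(W) eta is orthonormal
  L1w <- d$Lambda %*% diag(d$Xi1, r, r) %*% t(solve(W))
  betaw <- t(W) %*% d$beta
  inject <- function(R) {
    d2 <- d
    d2$Lambda <- L1w %*% R
    d2$Xi1 <- rep(1, r)
    d2$Xi2 <- rep(1, r)
    d2$beta <- crossprod(R, betaw)
    d2
  }
  base <- inject(diag(r))
  chain$draws <- c(list(base), lapply(1:4, function(i) inject(random_rotation(r))))
  al <- align_chain(chain)
  for (m in 2:5) expect_equal(al$Lambda1[[m]], al$Lambda1[[1]], tolerance = 1e-6)
})

test_that("alignment leaves every draw's likelihood unchanged", {
  chain <- make_small_chain(seed = 55)
  keep <- seq(1, length(chain$draws), by = 8)
  chain$draws <- chain$draws[keep]
  al <- align_chain(chain)
  dat <- chain$data
  bases <- chain$bases
  B <- eval_basis(bases$shared, dat$t)
  B1 <- eval_basis(bases$ind1, dat$t)
  B2 <- eval_basis(bases$ind2, dat$t)
  BJ <- eval_basis(bases$warp, dat$t)
  ll_blocks <- function(L1, L2, P1, P2, be, be1, be2, kap, s1, s2) {
    M <- pmin(pmax(drop(BJ %*% gamma_from_kappa(kap)), 0), 1)
    muX <- P1 %*% (be1 %*% t(B1)) + L1 %*% (be %*% t(B))
    muY <- P2 %*% (be2 %*% t(B2)) + L2 %*% (be %*% t(eval_basis(bases$shared, M)))
    sum(dnorm(dat$X, muX, sqrt(s1), log = TRUE)) +
      sum(dnorm(dat$Y, muY, sqrt(s2), log = TRUE))
  }
  for (m in seq_along(al$Lambda1)) {
    d <- chain$draws[[m]]
    raw <- ll_blocks(d$Lambda %*% diag(d$Xi1, ncol(d$Lambda)),
                     d$Lambda %*% diag(d$Xi2, ncol(d$Lambda)),
                     projection(d$Lambda) %*% d$Gamma1,
                     projection(d$Lambda) %*% d$Gamma2,
                     d$beta, d$beta1, d$beta2, d$kappa, d$sig1sq, d$sig2sq)
    aligned <- ll_blocks(al$Lambda1[[m]], al$Lambda2[[m]],
                         al$PsiGamma1[[m]], al$PsiGamma2[[m]],
                         al$beta[[m]], al$beta1[[m]], al$beta2[[m]],
                         al$kappa[[m]], al$sig1sq[[m]], al$sig2sq[[m]])
    expect_equal(aligned, raw, tolerance = 1e-8)
  }
  # stored rotations are orthonormal
  for (R in al$rotations$shared)
    expect_lt(max(abs(crossprod(R) - diag(ncol(R)))), 1e-10)
})

test_that("SP importance scores sign-determination", {
  pos <- lapply(1:10, function(i) matrix(abs(rnorm(6)), 3, 2))
  expect_equal(importance(pos), matrix(1, 3, 2))
  half <- lapply(1:10, function(i) matrix(ifelse(i %% 2 == 0, 1, -1), 3, 2))
  expect_equal(importance(half), matrix(0, 3, 2))
  expect_error(importance(pos[1]), "at least 2")
  mixed <- lapply(1:10, function(i) cbind(c(1, 1, 1), c(if (i <= 5) 1 else -1, -1, 1)))
  sp <- importance(mixed)
  expect_equal(n_important_factors(sp), 2)  # column max criterion
  expect_equal(sp[1, 2], 0)
})

test_that("noiseless self-prediction at the true state has zero error", {
  set.seed(56)
  sim <- generate_sim1(T = 50, p = 6, noise_sd = 1, seed = 56)
  tr <- sim$truth
  # build a chain whose draws are all the exact generative state
  K <- 8
  bases <- tacifa_bases(K)
  B <- eval_basis(bases$shared, sim$data$t)
  # represent the true polynomial factors exactly in the spline basis (degree
  # 3 basis reproduces cubics)
  beta_true <- t(solve(crossprod(B) + 1e-10 * diag(K), crossprod(B, t(tr$eta))))
  gv <- greville_abscissae(bases$warp)
  st <- model_state(Lambda = tr$Lambda, Gamma1 = matrix(0, 6, 1),
                    Gamma2 = matrix(0, 6, 1),
                    Xi1 = rep(1, 3), Xi2 = rep(1, 3), beta = beta_true,
                    beta1 = matrix(0, 1, K), beta2 = matrix(0, 1, K),
                    kappa = log(diff(gv)), sig1sq = rep(1e-12, 6),
                    sig2sq = rep(1e-12, 6))
  chain <- structure(list(draws = rep(list(unclass(st)), 3),
                          bases = bases, data = sim$data,
                          rank_history = matrix(c(3, 1, 1), 1)),
                     class = "tacifa_chain")
  pred <- predict_heldout(chain, sim$data$t[1:10], include_noise = FALSE)
  target <- tr$Lambda %*% tr$eta[, 1:10]
  expect_lt(max(abs(pred$X$mean - target)), 1e-6)
  expect_lt(max(abs(pred$X$upper - pred$X$lower)), 1e-6)
  expect_error(predict_heldout(chain, c(0.5, 1.5)), "\\[0, 1\\]")
})

test_that("warp summary has pinned endpoints and degenerate bands for identical warps", {
  chain <- make_small_chain(seed = 57)
  d <- chain$draws[[1]]
  chain$draws <- rep(list(d), 4)
  grid <- seq(0, 1, length.out = 21)
  ws <- warp_summary(chain, grid = grid)
  expect_equal(ws$lower, ws$upper, tolerance = 1e-12)
  expect_identical(ws$mean[1], 0)
  expect_identical(ws$mean[21], 1)
  expect_identical(ws$lower[1], 0)
  expect_identical(ws$upper[21], 1)
})
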