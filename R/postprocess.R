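# Identifiability post-processing (orthogonal Procrustes alignment of the
# loading chains), SP importance scores, warp and posterior-predictive
# summaries.

#' Orthogonal Procrustes rotation
#'
#' Returns the orthonormal R minimizing ||A - B R||_F: with the SVD
#' Q1 D Q2' of A'B, the minimizer is R = Q2 Q1'.
#'
#' @param A,B matrices of equal dimension (p x r).
#' @return r x r orthonormal rotation. When A'B is (numerically) zero the
#'   optimum is undefined and the identity is returned with a warning.
#' @export
procrustes_rotation <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("A and B must have equal dimensions")
  Cx <- crossprod(A, B)
  if (max(abs(Cx)) < 1e-12) {
    warning("A'B is numerically zero; rotation undefined, returning identity")
    return(diag(ncol(A)))
  }
  s <- svd(Cx)
  s$v %*% t(s$u)
}

# as procrustes_rotation, but silently returns the identity for blocks that
# are (numerically) zero, e.g. individual loadings while Psi is null
rotation_or_identity <- function(A, B) {
  if (max(abs(crossprod(A, B))) < 1e-12) return(diag(ncol(A)))
  procrustes_rotation(A, B)
}

#' Align a chain of loading draws
#'
#' Resolves the scale and rotational non-identifiability of the factor
#' loadings. Each draw's factor curves are first normalized to unit norm on
#' the training grid, absorbing their scale into the loading columns (the
#' likelihood is unchanged; loading magnitudes then reflect actual
#' contributions). The
#' first draw of the shared loading Lambda1 = Lambda Xi1 is pre-rotated by the
#' right singular vectors of the residual cross-product
#' (X - Psi Gamma1 zeta1)' Lambda1, ordering columns by decreasing
#' significance; every later draw is then rotated toward its aligned
#' predecessor by [procrustes_rotation()], walking the chain front to back.
#' The same rotation is applied to Lambda2 = Lambda Xi2 and (transposed) to
#' the shared factor coefficients, so each draw's likelihood is untouched.
#' The individual-loading chains Psi Gamma1 and Psi Gamma2 are aligned the
#' same way with their own rotations. Draws whose ranks differ from the
#' terminal ranks are discarded (with a message).
#'
#' @param chain a `tacifa_chain` from [run_mcmc()].
#' @return An object of class `tacifa_aligned`: lists of aligned draws
#'   `Lambda1`, `Lambda2`, `PsiGamma1`, `PsiGamma2`, counter-rotated
#'   coefficient draws `beta`, `beta1`, `beta2`, untouched `kappa`,
#'   `sig1sq`, `sig2sq`, rotation logs, and the indices of the retained draws.
#' @export
align_chain <- function(chain) {
  stopifnot(inherits(chain, "tacifa_chain"))
  draws <- chain$draws
  if (length(draws) == 0L) stop("chain has no stored draws")
  last <- draws[[length(draws)]]
  r <- ncol(last$Lambda); r1 <- ncol(last$Gamma1); r2 <- ncol(last$Gamma2)
  keep <- vapply(draws, function(d)
    ncol(d$Lambda) == r && ncol(d$Gamma1) == r1 && ncol(d$Gamma2) == r2,
    logical(1))
  if (!all(keep))
    message("discarding ", sum(!keep),
            " draws whose ranks differ from the terminal ranks")
  idx <- which(keep)
  draws <- draws[idx]
  M <- length(draws)

  B1 <- eval_basis(chain$bases$ind1, chain$data$t)
  B2 <- eval_basis(chain$bases$ind2, chain$data$t)
  Bsh <- eval_basis(chain$bases$shared, chain$data$t)
  Psi_m <- lapply(draws, function(d) projection(d$Lambda))
  L1 <- lapply(seq_len(M), function(m)
    draws[[m]]$Lambda %*% diag(draws[[m]]$Xi1, r, r))
  L2 <- lapply(seq_len(M), function(m)
    draws[[m]]$Lambda %*% diag(draws[[m]]$Xi2, r, r))
  PG1 <- lapply(seq_len(M), function(m) Psi_m[[m]] %*% draws[[m]]$Gamma1)
  PG2 <- lapply(seq_len(M), function(m) Psi_m[[m]] %*% draws[[m]]$Gamma2)
  beta <- lapply(draws, `[[`, "beta")
  beta1 <- lapply(draws, `[[`, "beta1")
  beta2 <- lapply(draws, `[[`, "beta2")

  # scale identification: factor curves are normalized to unit norm on the
  # training grid, absorbing their scale into the loading columns (the
  # likelihood is untouched); loading magnitudes then reflect actual
  # contributions rather than an arbitrary loading/curve scale split
  unit_scale <- function(load_cols, coef, Bmat, extra = NULL) {
    cs <- sqrt(rowSums((coef %*% t(Bmat))^2))
    cs[!is.finite(cs) | cs < 1e-12] <- 1
    k <- length(cs)
    out <- list(load = lapply(load_cols, function(A) A %*% diag(cs, k, k)),
                coef = coef / cs)
    out
  }
  for (m in seq_len(M)) {
    u <- unit_scale(list(L1[[m]], L2[[m]]), beta[[m]], Bsh)
    L1[[m]] <- u$load[[1]]; L2[[m]] <- u$load[[2]]; beta[[m]] <- u$coef
    u1 <- unit_scale(list(PG1[[m]]), beta1[[m]], B1)
    PG1[[m]] <- u1$load[[1]]; beta1[[m]] <- u1$coef
    u2 <- unit_scale(list(PG2[[m]]), beta2[[m]], B2)
    PG2[[m]] <- u2$load[[1]]; beta2[[m]] <- u2$coef
  }

  # initial transform of the first shared-loading draw: SVD of the residual
  # cross-product puts the dominant directions in the leading columns
  zeta1_1 <- beta1[[1]] %*% t(B1)
  resid <- t(chain$data$X - PG1[[1]] %*% zeta1_1) %*% L1[[1]]
  U2 <- svd(resid)$v
  rot_shared <- vector("list", M)
  L1[[1]] <- L1[[1]] %*% U2
  L2[[1]] <- L2[[1]] %*% U2
  beta[[1]] <- t(U2) %*% beta[[1]]
  rot_shared[[1]] <- U2

  align_block <- function(blocks, counter, rot1 = NULL) {
    rots <- vector("list", length(blocks))
    rots[[1]] <- if (is.null(rot1)) diag(ncol(blocks[[1]])) else rot1
    if (length(blocks) > 1) {
      for (m in 2:length(blocks)) {
        R <- rotation_or_identity(blocks[[m - 1]], blocks[[m]])
        blocks[[m]] <- blocks[[m]] %*% R
        counter[[m]] <- crossprod(R, counter[[m]])
        rots[[m]] <- R
      }
    }
    list(blocks = blocks, counter = counter, rots = rots)
  }

  # shared block: one rotation per draw applied to both Lambda1 and Lambda2
  rots <- rot_shared
  if (M > 1) {
    for (m in 2:M) {
      R <- rotation_or_identity(L1[[m - 1]], L1[[m]])
      L1[[m]] <- L1[[m]] %*% R
      L2[[m]] <- L2[[m]] %*% R
      beta[[m]] <- crossprod(R, beta[[m]])
      rots[[m]] <- R
    }
  }
  a1 <- align_block(PG1, beta1)
  a2 <- align_block(PG2, beta2)

  structure(list(Lambda1 = L1, Lambda2 = L2,
                 PsiGamma1 = a1$blocks, PsiGamma2 = a2$blocks,
                 beta = beta, beta1 = a1$counter, beta2 = a2$counter,
                 kappa = lapply(draws, `[[`, "kappa"),
                 sig1sq = lapply(draws, `[[`, "sig1sq"),
                 sig2sq = lapply(draws, `[[`, "sig2sq"),
                 rotations = list(shared = rots, ind1 = a1$rots, ind2 = a2$rots),
                 kept = idx),
            class = "tacifa_aligned")
}

#' SP importance scores of a loading chain
#'
#' SP(i, j) = |0.5 - P(A\[i, j\] > 0)| / 0.5, the posterior sign-determination
#' of each entry across aligned draws: 1 when the posterior mass is entirely
#' one-signed, 0 when perfectly sign-balanced.
#'
#' @param block_draws list of aligned loading draws (equal dimensions), e.g.
#'   `aligned$Lambda1`.
#' @return matrix of scores in \[0,1\].
#' @export
importance <- function(block_draws) {
  if (length(block_draws) < 2L) stop("need at least 2 draws")
  pos <- Reduce(`+`, lapply(block_draws, function(A) (A > 0) + 0))
  abs(0.5 - pos / length(block_draws)) / 0.5
}

#' Count important factors in an SP table
#'
#' A column (factor) counts as important when its largest SP entry reaches the
#' threshold. The loading columns in the simulation designs are sparse, so the
#' column maximum, not the column mean, carries the signal.
#'
#' @param sp an [importance()] table.
#' @param threshold SP threshold, default 0.9.
#' @return integer count.
#' @export
n_important_factors <- function(sp, threshold = 0.9) {
  sum(apply(sp, 2, max) >= threshold)
}

# per-draw mean curves at arbitrary times, from the raw draws of a chain
draw_means <- function(draw, bases, t_new) {
  r <- ncol(draw$Lambda)
  Psi <- projection(draw$Lambda)
  M <- eval_warp(warp_spec(draw$kappa), bases$warp, t_new)
  eta <- draw$beta %*% t(eval_basis(bases$shared, t_new))
  etaM <- draw$beta %*% t(eval_basis(bases$shared, M))
  zeta1 <- draw$beta1 %*% t(eval_basis(bases$ind1, t_new))
  zeta2 <- draw$beta2 %*% t(eval_basis(bases$ind2, t_new))
  list(mu_X = Psi %*% draw$Gamma1 %*% zeta1 + draw$Lambda %*% (draw$Xi1 * eta),
       mu_Y = Psi %*% draw$Gamma2 %*% zeta2 + draw$Lambda %*% (draw$Xi2 * etaM))
}

#' Posterior-predictive summaries at held-out time points
#'
#' Evaluates each retained draw's mean curves at the new time points (the
#' spline bases extend to any t in \[0,1\]) and adds observation noise to form
#' the posterior predictive. Prediction uses the posterior-predictive mean;
#' bands are pointwise quantiles across draws.
#'
#' @param chain a `tacifa_chain`.
#' @param t_test time points in \[0,1\].
#' @param probs band quantiles (default a central 95% interval).
#' @param include_noise add observation noise to the band draws (the posterior
#'   predictive proper); the reported `mean` is always the mean of the mean
#'   curves.
#' @return list with elements `X` and `Y`, each holding p x length(t_test)
#'   matrices `mean`, `lower`, `upper`.
#' @export
predict_heldout <- function(chain, t_test, probs = c(0.025, 0.975),
                            include_noise = TRUE) {
  stopifnot(inherits(chain, "tacifa_chain"))
  if (any(t_test < 0) || any(t_test > 1)) stop("t_test must lie in [0, 1]")
  draws <- chain$draws
  M <- length(draws)
  if (M < 2L) stop("need at least 2 stored draws")
  p <- chain$data$p; nt <- length(t_test)
  accX <- array(NA_real_, c(p, nt, M))
  accY <- array(NA_real_, c(p, nt, M))
  sampX <- array(NA_real_, c(p, nt, M))
  sampY <- array(NA_real_, c(p, nt, M))
  for (m in seq_len(M)) {
    mu <- draw_means(draws[[m]], chain$bases, t_test)
    accX[, , m] <- mu$mu_X
    accY[, , m] <- mu$mu_Y
    if (include_noise) {
      sampX[, , m] <- mu$mu_X + rnorm(p * nt) * sqrt(draws[[m]]$sig1sq)
      sampY[, , m] <- mu$mu_Y + rnorm(p * nt) * sqrt(draws[[m]]$sig2sq)
    } else {
      sampX[, , m] <- mu$mu_X
      sampY[, , m] <- mu$mu_Y
    }
  }
  band <- function(a, pr) apply(a, c(1, 2), quantile, probs = pr)
  list(X = list(mean = apply(accX, c(1, 2), mean),
                lower = band(sampX, probs[1]), upper = band(sampX, probs[2])),
       Y = list(mean = apply(accY, c(1, 2), mean),
                lower = band(sampY, probs[1]), upper = band(sampY, probs[2])))
}

#' Held-out mean squared error
#'
#' @param pred output of [predict_heldout()].
#' @param X_true,Y_true held-out data columns.
#' @return named vector with the per-series MSEs.
#' @export
heldout_mse <- function(pred, X_true, Y_true) {
  c(X = mean((pred$X$mean - X_true)^2), Y = mean((pred$Y$mean - Y_true)^2))
}

#' Empirical coverage of predictive bands
#'
#' Fraction of held-out entries inside the pointwise predictive interval.
#'
#' @inheritParams heldout_mse
#' @return named vector of coverages (proportions).
#' @export
heldout_coverage <- function(pred, X_true, Y_true) {
  c(X = mean(X_true >= pred$X$lower & X_true <= pred$X$upper),
    Y = mean(Y_true >= pred$Y$lower & Y_true <= pred$Y$upper))
}

#' Posterior summary of the warping function
#'
#' Pointwise posterior mean and credible band of M(t). The construction pins
#' M(0) = 0 and M(1) = 1 exactly, so bands are degenerate at the endpoints.
#'
#' @param chain a `tacifa_chain`.
#' @param grid evaluation grid; defaults to the training grid.
#' @param probs band quantiles.
#' @return data.frame with columns `t`, `mean`, `lower`, `upper`.
#' @export
warp_summary <- function(chain, grid = NULL, probs = c(0.025, 0.975)) {
  stopifnot(inherits(chain, "tacifa_chain"))
  if (length(chain$draws) < 2L) stop("need at least 2 stored draws")
  if (is.null(grid)) grid <- chain$data$t
  BJ <- eval_basis(chain$bases$warp, grid)
  Ms <- vapply(chain$draws,
               function(d) pmin(pmax(drop(BJ %*% gamma_from_kappa(d$kappa)), 0), 1),
               numeric(length(grid)))
  data.frame(t = grid,
             mean = rowMeans(Ms),
             lower = apply(Ms, 1, quantile, probs = probs[1]),
             upper = apply(Ms, 1, quantile, probs = probs[2]))
}

#' Syn similarity from a fitted chain
#'
#' Evaluates the Syn statistic either at the posterior mean of the aligned
#' loading blocks, factor coefficients, warp curve and noise variances
#' (default), or averaged over the aligned draws.
#'
#' @param aligned a `tacifa_aligned` from [align_chain()].
#' @param chain the `tacifa_chain` the alignment came from.
#' @param method "mean" (posterior-mean state) or "draws" (average of
#'   per-draw Syn values).
#' @return scalar in \[0,1\].
#' @export
posterior_syn <- function(aligned, chain, method = c("mean", "draws")) {
  method <- match.arg(method)
  stopifnot(inherits(aligned, "tacifa_aligned"), inherits(chain, "tacifa_chain"))
  t <- chain$data$t
  bases <- chain$bases
  B <- eval_basis(bases$shared, t)
  B1 <- eval_basis(bases$ind1, t)
  B2 <- eval_basis(bases$ind2, t)
  BJ <- eval_basis(bases$warp, t)
  syn_of <- function(L1, L2, P1, P2, be, be1, be2, kap, s1, s2) {
    M <- pmin(pmax(drop(BJ %*% gamma_from_kappa(kap)), 0), 1)
    eta <- be %*% t(B)
    etaM <- be %*% t(eval_basis(bases$shared, M))
    syn_core(L1 %*% eta, L2 %*% etaM, P1 %*% (be1 %*% t(B1)),
             P2 %*% (be2 %*% t(B2)), s1, s2)
  }
  if (method == "draws") {
    vals <- vapply(seq_along(aligned$Lambda1), function(m)
      syn_of(aligned$Lambda1[[m]], aligned$Lambda2[[m]],
             aligned$PsiGamma1[[m]], aligned$PsiGamma2[[m]],
             aligned$beta[[m]], aligned$beta1[[m]], aligned$beta2[[m]],
             aligned$kappa[[m]], aligned$sig1sq[[m]], aligned$sig2sq[[m]]),
      numeric(1))
    return(mean(vals))
  }
  avg <- function(xs) Reduce(`+`, xs) / length(xs)
  # the warp curve is averaged on the M(t) scale, then Syn is evaluated once
  Ms <- vapply(aligned$kappa,
               function(k) pmin(pmax(drop(BJ %*% gamma_from_kappa(k)), 0), 1),
               numeric(length(t)))
  Mbar <- rowMeans(Ms)
  be <- avg(aligned$beta)
  eta <- be %*% t(B)
  etaM <- be %*% t(eval_basis(bases$shared, Mbar))
  syn_core(avg(aligned$Lambda1) %*% eta,
           avg(aligned$Lambda2) %*% etaM,
           avg(aligned$PsiGamma1) %*% (avg(aligned$beta1) %*% t(B1)),
           avg(aligned$PsiGamma2) %*% (avg(aligned$beta2) %*% t(B2)),
           avg(aligned$sig1sq), avg(aligned$sig2sq))
}
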