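# Posterior computation: HMC-within-Gibbs with multiplicative-gamma shrinkage
# and adaptive column pruning. The iteration loop and all block updates live
# in compiled code; this file provides configuration, initialization, the
# run loop wrapper and single-block entry points used for verification.

#' HMC settings
#'
#' The leapfrog length is fixed (30 steps by default); the step sizes are
#' tuned every `adapt_interval` iterations during burn-in so that acceptance
#' stays within `target_accept_band` (reduced when below, increased when
#' above). Adaptation is frozen after burn-in so retained draws satisfy
#' detailed balance.
#'
#' @param leapfrog_steps number of leapfrog steps per proposal.
#' @param step_size_kappa initial step size for the warp block.
#' @param step_size_lambda initial step size for the shared-loading columns.
#' @param target_accept_band acceptance band, default \[0.6, 0.8\].
#' @param adapt_interval iterations between step-size adjustments.
#' @export
hmc_settings <- function(leapfrog_steps = 30L, step_size_kappa = 0.01,
                         step_size_lambda = 0.01,
                         target_accept_band = c(0.6, 0.8),
                         adapt_interval = 100L) {
  stopifnot(leapfrog_steps >= 1L, step_size_kappa > 0, step_size_lambda > 0,
            length(target_accept_band) == 2L,
            target_accept_band[1] < target_accept_band[2],
            adapt_interval >= 1L)
  structure(list(leapfrog_steps = as.integer(leapfrog_steps),
                 step_size_kappa = step_size_kappa,
                 step_size_lambda = step_size_lambda,
                 target_accept_band = target_accept_band,
                 adapt_interval = as.integer(adapt_interval)),
            class = "hmc_settings")
}

#' Sampler configuration
#'
#' @param n_iter total MCMC iterations.
#' @param n_burnin burn-in iterations (must be < `n_iter`).
#' @param K,K1,K2,J basis sizes (the simulation protocol ties them to K).
#' @param r_init,r1_init,r2_init initial ranks; default is the conservative
#'   upper bound r = p, set when the data are seen.
#' @param prune enable adaptive column pruning during burn-in.
#' @param prune_threshold columns whose entries all lie within +-threshold are
#'   deleted (with their factor rows, scales and shrinkage parameters).
#' @param prune_start first iteration at which pruning may be attempted;
#'   attempts then occur with probability exp(-1 - 5e-4 * iteration), never
#'   after burn-in.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param hmc an [hmc_settings()].
#' @param hyper hyperparameters: `nu1` (local shrinkage Gamma(nu1, nu1)),
#'   `a_delta1`/`a_delta2` (first/later multiplicative-gamma shapes; larger
#'   later shapes give increasing shrinkage with column index), `a_sigma`,
#'   `b_sigma` (inverse-gamma for the noise variances) and `omega` (prior
#'   variance of the scale, warp and factor-spline coefficients).
#' @param init_search run a short bracketing search for workable initial step
#'   sizes before sampling.
#' @param seed optional integer seed applied at the start of [run_mcmc()].
#' @export
sampler_config <- function(n_iter = 6000L, n_burnin = 3000L,
                           K = 10L, K1 = K, K2 = K, J = K,
                           r_init = NULL, r1_init = NULL, r2_init = NULL,
                           prune = TRUE, prune_threshold = 1e-3,
                           prune_start = 300L, thin = 1L,
                           hmc = hmc_settings(),
                           hyper = list(nu1 = 3, a_delta1 = 5, a_delta2 = 5,
                                        a_sigma = 0.1, b_sigma = 0.1,
                                        omega = 100),
                           init_search = TRUE, seed = NULL) {
  stopifnot(n_burnin < n_iter || n_iter == 0L, prune_threshold > 0, thin >= 1L)
  defaults <- list(nu1 = 3, a_delta1 = 5, a_delta2 = 5,
                   a_sigma = 0.1, b_sigma = 0.1, omega = 100)
  hyper <- utils::modifyList(defaults, hyper)
  structure(list(n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
                 K = as.integer(K), K1 = as.integer(K1), K2 = as.integer(K2),
                 J = as.integer(J),
                 r_init = r_init, r1_init = r1_init, r2_init = r2_init,
                 prune = prune, prune_threshold = prune_threshold,
                 prune_start = as.integer(prune_start), thin = as.integer(thin),
                 hmc = hmc, hyper = hyper, init_search = init_search,
                 seed = seed),
            class = "sampler_config")
}

#' Initial model state
#'
#' Ranks start at the conservative upper bound r = r1 = r2 = p (unless
#' overridden); loadings are drawn from their shrinkage priors, the factor
#' spline coefficients come from ridge fits of the data onto the basis, the
#' warp starts at (near) identity (kappa = 0) and the noise variances at 1.
#'
#' @param data a [paired_series()].
#' @param config a [sampler_config()].
#' @param bases a [tacifa_bases()]; built from `config` if missing.
#' @return a [model_state()].
#' @export
init_state <- function(data, config, bases = NULL) {
  stopifnot(inherits(data, "paired_series"))
  if (is.null(bases)) bases <- tacifa_bases(config$K, config$K1, config$K2, config$J)
  p <- data$p
  r <- if (is.null(config$r_init)) p else config$r_init
  r1 <- if (is.null(config$r1_init)) p else config$r1_init
  r2 <- if (is.null(config$r2_init)) p else config$r2_init
  hy <- config$hyper

  draw_loading <- function(p, r) {
    delta <- c(rgamma(1, hy$a_delta1, 1), rgamma(max(r - 1, 0), hy$a_delta2, 1))
    delta <- pmax(delta, 1e-3)
    tau <- cumprod(delta)
    phi <- matrix(rgamma(p * r, hy$nu1, hy$nu1), p, r)
    A <- matrix(rnorm(p * r), p, r) / sqrt(phi * rep(tau, each = p))
    list(A = A, phi = phi, delta = delta)
  }
  L <- draw_loading(p, r); G1 <- draw_loading(p, r1); G2 <- draw_loading(p, r2)

  ridge_fit <- function(targets, B) {
    # targets: q x T curves; returns q x K coefficients
    BtB <- crossprod(B) + 1e-6 * diag(ncol(B))
    t(solve(BtB, t(targets %*% B)))
  }
  B <- eval_basis(bases$shared, data$t)
  B1 <- eval_basis(bases$ind1, data$t)
  B2 <- eval_basis(bases$ind2, data$t)
  Lam <- L$A
  F_shared <- solve(crossprod(Lam) + 1e-6 * diag(r), t(Lam) %*%
                      (data$X + data$Y) / 2)
  beta <- ridge_fit(F_shared, B)
  Psi <- projection(Lam)
  F1 <- solve(crossprod(G1$A) + 1e-6 * diag(r1), t(G1$A) %*% (Psi %*% data$X))
  F2 <- solve(crossprod(G2$A) + 1e-6 * diag(r2), t(G2$A) %*% (Psi %*% data$Y))
  beta1 <- ridge_fit(F1, B1)
  beta2 <- ridge_fit(F2, B2)

  model_state(Lambda = Lam, Gamma1 = G1$A, Gamma2 = G2$A,
              Xi1 = rep(1, r), Xi2 = rep(1, r),
              beta = beta, beta1 = beta1, beta2 = beta2,
              kappa = rep(0, bases$J - 1L),
              sig1sq = rep(1, p), sig2sq = rep(1, p),
              phi1 = L$phi, phi11 = G1$phi, phi12 = G2$phi,
              delta1 = L$delta, delta11 = G1$delta, delta12 = G2$delta)
}

as_state <- function(lst) {
  do.call(model_state, lst[c("Lambda", "Gamma1", "Gamma2", "Xi1", "Xi2",
                             "beta", "beta1", "beta2", "kappa",
                             "sig1sq", "sig2sq", "phi1", "phi11", "phi12",
                             "delta1", "delta11", "delta12")])
}

#' Run the MCMC sampler
#'
#' One iteration updates, in order: all linear Gaussian blocks (shared and
#' individual factor coefficients, Gamma loadings, diagonal scales) by exact
#' conjugate draws; the noise precisions and multiplicative-gamma shrinkage
#' parameters by their Gamma full conditionals; each column of the shared
#' loading Lambda by Metropolis-corrected leapfrog HMC (the projector Psi is
#' recomputed consistently); the warp coefficients kappa by HMC; then an
#' optional pruning attempt. Step sizes adapt during burn-in only.
#'
#' @param data a [paired_series()].
#' @param config a [sampler_config()].
#' @param init optional initial [model_state()].
#' @return An object of class `tacifa_chain`: post-burn-in `draws`, the
#'   `final_state`, per-iteration `rank_history` (r, r1, r2), acceptance and
#'   step-size histories, pruning iterations, and the `config`, `bases` and
#'   training `data` used.
#' @export
run_mcmc <- function(data, config = sampler_config(), init = NULL) {
  stopifnot(inherits(data, "paired_series"))
  if (!is.null(config$seed)) set.seed(config$seed)
  bases <- tacifa_bases(config$K, config$K1, config$K2, config$J)
  if (is.null(init)) init <- init_state(data, config, bases)
  ctrl <- list(n_iter = config$n_iter, n_burnin = config$n_burnin,
               thin = config$thin,
               leapfrog_steps = config$hmc$leapfrog_steps,
               adapt_interval = config$hmc$adapt_interval,
               accept_lo = config$hmc$target_accept_band[1],
               accept_hi = config$hmc$target_accept_band[2],
               prune = isTRUE(config$prune),
               prune_threshold = config$prune_threshold,
               prune_start = config$prune_start,
               init_search = isTRUE(config$init_search),
               step_size_kappa = config$hmc$step_size_kappa,
               step_size_lambda = config$hmc$step_size_lambda)
  res <- cpp_run_mcmc(as_cpp_data(data), as_cpp_bases(bases), unclass(init),
                      config$hyper, ctrl)
  vecfields <- c("Xi1", "Xi2", "kappa", "sig1sq", "sig2sq",
                 "delta1", "delta11", "delta12")
  normalize <- function(d) {
    for (f in intersect(names(d), vecfields)) d[[f]] <- as.numeric(d[[f]])
    d
  }
  structure(list(draws = lapply(res$draws, normalize),
                 final_state = normalize(res$final_state),
                 rank_history = res$rank_history,
                 accept = list(kappa = unlist(res$accept_kappa),
                               lambda = unlist(res$accept_lambda)),
                 step_sizes = list(kappa = unlist(res$step_kappa),
                                   lambda = unlist(res$step_lambda)),
                 prune_iterations = unlist(res$prune_iterations),
                 config = config, bases = bases, data = data),
            class = "tacifa_chain")
}

#' @export
print.tacifa_chain <- function(x, ...) {
  rh <- x$rank_history
  cat("tacifa_chain:", length(x$draws), "stored draws\n")
  if (nrow(rh) > 0) {
    cat("  terminal ranks: r =", rh[nrow(rh), 1], " r1 =", rh[nrow(rh), 2],
        " r2 =", rh[nrow(rh), 3], "\n")
    if (length(x$accept$kappa))
      cat("  last acceptance (kappa, lambda):",
          round(utils::tail(x$accept$kappa, 1), 2),
          round(utils::tail(x$accept$lambda, 1), 2), "\n")
  }
  invisible(x)
}

#' One sweep of the conjugate Gibbs blocks
#'
#' Redraws the requested blocks from their exact full conditionals:
#' `beta`, `beta1`, `beta2` (factor spline coefficients), `Gamma1`, `Gamma2`,
#' `Xi1`, `Xi2` (Gaussian), `sigma` (noise precisions) and `shrinkage`
#' (multiplicative-gamma locals and globals).
#'
#' @param state a [model_state()].
#' @param data a [paired_series()].
#' @param bases a [tacifa_bases()].
#' @param config a [sampler_config()] (hyperparameters).
#' @param blocks character vector of blocks; `NULL` updates all.
#' @return updated [model_state()].
#' @export
gibbs_update_linear_blocks <- function(state, data, bases, config,
                                       blocks = NULL) {
  lin <- c("beta", "beta1", "beta2", "Gamma1", "Gamma2", "Xi1", "Xi2")
  sc <- c("sigma", "shrinkage")
  if (is.null(blocks)) blocks <- c(lin, sc)
  bad <- setdiff(blocks, c(lin, sc))
  if (length(bad)) stop("unknown blocks: ", paste(bad, collapse = ", "))
  st <- unclass(state)
  if (length(intersect(blocks, lin)))
    st <- cpp_gibbs_linear(st, as_cpp_data(data), as_cpp_bases(bases),
                           config$hyper, intersect(blocks, lin))
  if (length(intersect(blocks, sc)))
    st <- cpp_gibbs_scales(st, as_cpp_data(data), as_cpp_bases(bases),
                           config$hyper, intersect(blocks, sc))
  as_state(st)
}

#' HMC update of the warp coefficients
#'
#' @inheritParams gibbs_update_linear_blocks
#' @param settings an [hmc_settings()]; the kappa step size is used.
#' @return list with the updated `state` and `accept` (0/1).
#' @export
hmc_update_kappa <- function(state, data, bases, config,
                             settings = config$hmc) {
  res <- cpp_hmc_kappa(unclass(state), as_cpp_data(data), as_cpp_bases(bases),
                       config$hyper, settings$step_size_kappa,
                       settings$leapfrog_steps)
  list(state = as_state(res$state), accept = res$accept)
}

#' HMC update of one column of the shared loading matrix
#'
#' The remaining columns are held fixed; the projector is written through its
#' rank-one update so the potential and gradient account for the dependence of
#' Psi on the moving column.
#'
#' @inheritParams hmc_update_kappa
#' @param j column index (1-based).
#' @return list with the updated `state` and `accept` (0/1).
#' @export
hmc_update_lambda_column <- function(state, data, bases, config, j,
                                     settings = config$hmc) {
  stopifnot(j >= 1, j <= ncol(state$Lambda))
  res <- cpp_hmc_lambda(unclass(state), as_cpp_data(data), as_cpp_bases(bases),
                        config$hyper, as.integer(j),
                        settings$step_size_lambda, settings$leapfrog_steps)
  list(state = as_state(res$state), accept = res$accept)
}

#' Step-size adaptation rule
#'
#' Multiplicative tuning toward the acceptance band: decrease (factor 0.8, or
#' 0.5 when acceptance is far below) when below the band, increase (1.25, or
#' 2 when essentially everything is accepted) when above, no change inside.
#'
#' @param settings an [hmc_settings()].
#' @param accept_history named list or vector with elements `kappa` and
#'   `lambda`: acceptance rates over the last adaptation window.
#' @return updated [hmc_settings()].
#' @export
adapt_step_sizes <- function(settings, accept_history) {
  tune <- function(eps, rate) {
    lo <- settings$target_accept_band[1]
    hi <- settings$target_accept_band[2]
    if (rate < lo) eps * (if (rate < 0.2) 0.5 else 0.8)
    else if (rate > hi) eps * (if (rate > 0.95) 2.0 else 1.25)
    else eps
  }
  if (!is.null(accept_history$kappa))
    settings$step_size_kappa <- tune(settings$step_size_kappa,
                                     accept_history$kappa)
  if (!is.null(accept_history$lambda))
    settings$step_size_lambda <- tune(settings$step_size_lambda,
                                      accept_history$lambda)
  settings
}

#' Prune near-zero loading columns
#'
#' Deletes every column of Lambda, Gamma1 or Gamma2 whose entries all lie
#' within +-threshold of zero, together with the matching factor row, diagonal
#' scale entry and shrinkage parameters. Ranks never fall below 1.
#'
#' @param state a [model_state()].
#' @param threshold pruning threshold.
#' @return updated [model_state()] (possibly with reduced ranks).
#' @export
prune_columns <- function(state, threshold = 1e-3) {
  res <- cpp_prune(unclass(state), threshold)
  as_state(res$state)
}

#' Choose the basis size by held-out prediction
#'
#' Fits the model for each candidate basis size (with K1 = K2 = J = K) on a
#' random 90/10 column split and returns the candidate with the smallest total
#' held-out prediction MSE.
#'
#' @param data a [paired_series()].
#' @param candidates integer vector of basis sizes.
#' @param config a [sampler_config()] used for every candidate (its K fields
#'   are overridden).
#' @param fraction held-out fraction of time columns.
#' @param seed seed for the split and the fits.
#' @return the selected basis size, with the per-candidate MSE table in
#'   attribute `"scores"`.
#' @export
select_basis_size <- function(data, candidates, config = sampler_config(),
                              fraction = 0.1, seed = NULL) {
  stopifnot(length(candidates) >= 1L)
  if (length(candidates) == 1L) return(as.integer(candidates))
  if (!is.null(seed)) set.seed(seed)
  split <- heldout_split(data$T, fraction)
  train <- subset_columns(data, split$train)
  t_test <- data$t[split$test]
  scores <- vapply(candidates, function(K) {
    cfg <- config
    cfg$K <- cfg$K1 <- cfg$K2 <- cfg$J <- as.integer(K)
    cfg$seed <- NULL
    chain <- run_mcmc(train, cfg)
    pred <- predict_heldout(chain, t_test)
    mean((pred$X$mean - data$X[, split$test])^2) +
      mean((pred$Y$mean - data$Y[, split$test])^2)
  }, numeric(1))
  out <- as.integer(candidates[which.min(scores)])
  attr(out, "scores") <- setNames(scores, candidates)
  out
}
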