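# Programmatic simulation designs: a factor-model design with a known warp
# and sparse shared loadings, and a geometric design (ellipse landmarks) with
# no inherent connection to the model.

#' True warping functions used in the simulation designs
#'
#' `warp_sqrt` is M0(t) = t^0.5 (the second series leads); `warp_turn` is
#' M0(t) = ((0.33 sin 2 pi t)^2 + t^2)^0.5, which crosses the identity and so
#' encodes a change in the direction of the lag.
#' @param t times in \[0,1\].
#' @return warped times in \[0,1\].
#' @export
warp_sqrt <- function(t) sqrt(t)

#' @rdname warp_sqrt
#' @export
warp_turn <- function(t) pmin(sqrt((0.33 * sin(2 * pi * t))^2 + t^2), 1)

#' Factor-model simulation with warped shared factors
#'
#' Generates a pair of p x T series from the model itself: shared factors are
#' the first three orthogonal polynomials on the grid (via `poly`), the shared
#' loading is block-diagonal (columns load 5 features each, nonzero entries
#' N(15, 0.1^2)), individual loadings Gamma1, Gamma2 have N(0, 0.1^2) entries,
#' and the individual factor curves are zeta_1k(t) = sin(kt) and
#' zeta_2k(t) = cos(kt), k = 1..n_ind. The second series' shared factors are
#' evaluated at M0(t) (t^0.5 by default) and unit-variance Gaussian noise is
#' added. The grid is t = 1/T, 2/T, ..., 1.
#'
#' `generate_sim1_variant` swaps the first series' individual factor family:
#' `"sin"` reproduces `generate_sim1` exactly (same seed, same draws),
#' `"linear"` uses kt, `"quadratic"` uses (kt)^2 — increasingly dissimilar
#' individual structure, which lowers the fitted Syn similarity.
#'
#' @param T number of time points.
#' @param p number of features (a multiple of the 3 shared factors works
#'   best for the block-diagonal truth).
#' @param noise_sd observation noise standard deviation.
#' @param warp true warping function M0.
#' @param n_ind number of individual-specific factors.
#' @param seed optional seed.
#' @return list with `data` (a [paired_series()]) and `truth` (loadings,
#'   factor curves, warped times, noiseless means).
#' @export
generate_sim1 <- function(T = 500L, p = 15L, noise_sd = 1, warp = warp_sqrt,
                          n_ind = 10L, seed = NULL) {
  generate_sim1_variant("sin", T = T, p = p, noise_sd = noise_sd, warp = warp,
                        n_ind = n_ind, seed = seed)
}

#' @rdname generate_sim1
#' @param family individual-factor family for the first series.
#' @export
generate_sim1_variant <- function(family = c("sin", "linear", "quadratic"),
                                  T = 500L, p = 15L, noise_sd = 1,
                                  warp = warp_sqrt, n_ind = 10L, seed = NULL) {
  family <- match.arg(family)
  if (!is.null(seed)) set.seed(seed)
  T <- as.integer(T); p <- as.integer(p)
  stopifnot(T >= 2L, noise_sd >= 0)
  t <- seq_len(T) / T
  r <- 3L
  po <- poly(t, degree = r)
  eta <- t(unclass(po))                      # r x T, orthonormal columns
  Mt <- warp(t)
  etaM <- t(unclass(predict(po, Mt)))        # same polynomials at M0(t)

  block <- ceiling(p / r)
  Lambda <- matrix(0, p, r)
  for (j in seq_len(r)) {
    rows <- ((j - 1) * block + 1):min(j * block, p)
    Lambda[rows, j] <- rnorm(length(rows), mean = 15, sd = 0.1)
  }
  Gamma1 <- matrix(rnorm(p * n_ind, 0, 0.1), p, n_ind)
  Gamma2 <- matrix(rnorm(p * n_ind, 0, 0.1), p, n_ind)

  k <- seq_len(n_ind)
  zeta1 <- switch(family,
                  sin = outer(k, t, function(k, t) sin(k * t)),
                  linear = outer(k, t, function(k, t) k * t),
                  quadratic = outer(k, t, function(k, t) (k * t)^2))
  zeta2 <- outer(k, t, function(k, t) cos(k * t))

  Psi <- projection(Lambda)
  muX <- Psi %*% Gamma1 %*% zeta1 + Lambda %*% eta
  muY <- Psi %*% Gamma2 %*% zeta2 + Lambda %*% etaM
  X <- muX + noise_sd * matrix(rnorm(p * T), p, T)
  Y <- muY + noise_sd * matrix(rnorm(p * T), p, T)

  truth <- list(Lambda = Lambda, Gamma1 = Gamma1, Gamma2 = Gamma2,
                eta = eta, etaM = etaM, zeta1 = zeta1, zeta2 = zeta2,
                M = Mt, warp = warp, muX = muX, muY = muY,
                noise_sd = noise_sd, family = family)
  list(data = paired_series(X, Y, t, rescale = "never"), truth = truth)
}

#' Geometric simulation: a circle flattening into an ellipse
#'
#' Each series records the Cartesian coordinates of 12 equidistant landmarks
#' (angles theta_i in \[0, 2 pi)) on an ellipse whose axes change over time
#' while the area stays fixed (ax bx = 4): for the first series
#' ax(t) = 2(t + 1), bx(t) = 2/(t + 1); the second series follows the same
#' deformation on the warped clock, ay(t) = 2(t^0.5 + 1), by(t) = 2/(t^0.5+1),
#' i.e. a true warp M0(t) = t^0.5. Rows alternate x- and y-coordinates per
#' landmark (24 features). Landmarks at theta = 0, pi/2, pi, 3 pi/2 have one
#' coordinate identically zero; the remaining 20 features form 10 mirror
#' pairs, so the shared space has about 10 independent factors. The base
#' design is noiseless; `noise_sd` of 1 or 1.5 gives the low signal-to-noise
#' variants.
#'
#' @param T number of time points (grid 1/T, ..., 1).
#' @param noise_sd added Gaussian noise (0 = the noiseless design).
#' @param n_landmarks landmarks on the perimeter.
#' @param seed optional seed (used only when noise is added).
#' @return list with `data` (a [paired_series()]) and the geometric `truth`.
#' @export
generate_sim2 <- function(T = 500L, noise_sd = 0, n_landmarks = 12L,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  T <- as.integer(T)
  t <- seq_len(T) / T
  theta <- 2 * pi * (seq_len(n_landmarks) - 1) / n_landmarks
  ax <- 2 * (t + 1); bx <- 2 / (t + 1)
  ay <- 2 * (sqrt(t) + 1); by <- 2 / (sqrt(t) + 1)
  p <- 2L * n_landmarks
  X <- matrix(0, p, T); Y <- matrix(0, p, T)
  for (i in seq_len(n_landmarks)) {
    X[2L * i - 1L, ] <- ax * sin(theta[i])
    X[2L * i, ] <- bx * cos(theta[i])
    Y[2L * i - 1L, ] <- ay * sin(theta[i])
    Y[2L * i, ] <- by * cos(theta[i])
  }
  muX <- X; muY <- Y
  if (noise_sd > 0) {
    X <- X + noise_sd * matrix(rnorm(p * T), p, T)
    Y <- Y + noise_sd * matrix(rnorm(p * T), p, T)
  }
  truth <- list(theta = theta, ax = ax, bx = bx, ay = ay, by = by,
                M = sqrt(t), warp = warp_sqrt, muX = muX, muY = muY,
                noise_sd = noise_sd)
  list(data = paired_series(X, Y, t, rescale = "never"), truth = truth)
}

#' Random train/test split of time columns
#'
#' Reserves a random fraction of the time points (columns of both series) as
#' a test set for posterior-predictive evaluation.
#'
#' @param T number of time columns.
#' @param fraction held-out fraction (0 < fraction < 1).
#' @param seed optional seed.
#' @return list with sorted integer vectors `train` and `test` (disjoint,
#'   exhaustive; `length(test) == round(fraction * T)`).
#' @export
heldout_split <- function(T, fraction = 0.1, seed = NULL) {
  stopifnot(fraction > 0, fraction < 1, T >= 2)
  if (!is.null(seed)) set.seed(seed)
  n_test <- max(1L, round(fraction * T))
  test <- sort(sample.int(T, n_test))
  list(train = setdiff(seq_len(T), test), test = test)
}
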