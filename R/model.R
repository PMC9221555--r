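# Model containers, mean/likelihood machinery, the orthogonal projector and
# the Syn similarity statistic.

#' Paired multivariate time series
#'
#' Container for two p x T data matrices observed on a common time grid.
#' Columns are time points; rows are features. The grid must be strictly
#' increasing and is mapped into \[0,1\]: grids already inside \[0,1\] are
#' kept as-is (`rescale = "auto"`), otherwise (or with `rescale = "always"`)
#' the affine map (t - t_1)/(t_T - t_1) is applied.
#'
#' @param X,Y numeric p x T matrices (same dimensions).
#' @param t optional time grid of length T; defaults to a uniform grid on
#'   \[0,1\].
#' @param rescale one of "auto", "always", "never".
#' @return An object of class `paired_series` with fields `X`, `Y`, `t`, `p`,
#'   `T`.
#' @export
paired_series <- function(X, Y, t = NULL, rescale = c("auto", "always", "never")) {
  rescale <- match.arg(rescale)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y)))
    stop("X is ", nrow(X), "x", ncol(X), " but Y is ", nrow(Y), "x", ncol(Y),
         "; the two series must share dimensions")
  if (!is.numeric(X) || !is.numeric(Y) || anyNA(X) || anyNA(Y))
    stop("X and Y must be numeric without missing values")
  Tn <- ncol(X)
  if (Tn < 2L) stop("need at least 2 time points")
  if (is.null(t)) t <- seq(0, 1, length.out = Tn)
  t <- as.numeric(t)
  if (length(t) != Tn) stop("time grid length ", length(t),
                            " does not match T = ", Tn)
  if (any(diff(t) <= 0)) stop("time grid must be strictly increasing")
  if (rescale == "always" || (rescale == "auto" && (min(t) < 0 || max(t) > 1)))
    t <- (t - t[1]) / (t[Tn] - t[1])
  if (min(t) < 0 || max(t) > 1) stop("time grid must lie in [0, 1]")
  structure(list(X = unname(X), Y = unname(Y), t = t, p = nrow(X), T = Tn),
            class = "paired_series")
}

#' @export
print.paired_series <- function(x, ...) {
  cat("paired_series: p =", x$p, "features, T =", x$T,
      "time points on [", format(min(x$t), digits = 3), ",",
      format(max(x$t), digits = 3), "]\n")
  invisible(x)
}

#' Restrict a paired series to a subset of time columns
#'
#' @param data a [paired_series()].
#' @param idx column indices (kept in increasing order).
#' @export
subset_columns <- function(data, idx) {
  stopifnot(inherits(data, "paired_series"))
  idx <- sort(unique(as.integer(idx)))
  if (any(idx < 1L) || any(idx > data$T)) stop("column index out of range")
  paired_series(data$X[, idx, drop = FALSE], data$Y[, idx, drop = FALSE],
                t = data$t[idx], rescale = "never")
}

#' Basis set for the model
#'
#' The shared factors use K bases, the two individual factor sets K1 and K2,
#' and the warp J (all cubic with clamped equidistant knots by default). The
#' simulation studies tie K1 = K2 = J = K.
#'
#' @param K bases for the shared factor curves.
#' @param K1,K2 bases for the individual-specific factor curves.
#' @param J bases for the warping function.
#' @param degree spline degree.
#' @return Object of class `tacifa_bases` holding one [bspline_spec()] per
#'   block.
#' @export
tacifa_bases <- function(K, K1 = K, K2 = K, J = K, degree = 3L) {
  structure(list(shared = bspline_spec(K, degree),
                 ind1 = bspline_spec(K1, degree),
                 ind2 = bspline_spec(K2, degree),
                 warp = bspline_spec(J, degree),
                 K = K, K1 = K1, K2 = K2, J = J, degree = degree),
            class = "tacifa_bases")
}

# knots-only view passed to the compiled sampler
as_cpp_bases <- function(bases) {
  list(degree = bases$degree,
       knotsK = bases$shared$knots, knots1 = bases$ind1$knots,
       knots2 = bases$ind2$knots, knotsJ = bases$warp$knots)
}

as_cpp_data <- function(data) list(X = data$X, Y = data$Y, t = data$t)

#' Orthogonal projector onto the complement of a loading space
#'
#' Psi = I - Lambda (Lambda' Lambda)^-1 Lambda', the projector onto the
#' orthogonal complement of the columns of Lambda. It carries the
#' individual-specific loadings so that the shared and individual spaces are
#' orthogonal by construction.
#'
#' @param Lambda p x r loading matrix with full column rank; if the smallest
#'   singular value is below 1e-10 a Moore-Penrose pseudo-inverse is used and
#'   a warning is emitted (this signals a near-degenerate column).
#' @return symmetric idempotent p x p matrix with trace p - rank(Lambda).
#' @export
projection <- function(Lambda) {
  Lambda <- as.matrix(Lambda)
  p <- nrow(Lambda)
  # I - U U' over the numerically nonzero singular directions; equals the
  # pseudo-inverse form and stays stable when columns are nearly collinear
  s <- svd(Lambda, nv = 0)
  pos <- s$d > 1e-10 * max(s$d, .Machine$double.eps)
  if (!all(pos))
    warning("Lambda is (near) rank deficient; using a pseudo-inverse")
  U <- s$u[, pos, drop = FALSE]
  diag(p) - tcrossprod(U)
}

#' Construct a full model state
#'
#' Bundles all model unknowns: loadings (`Lambda`, `Gamma1`, `Gamma2`),
#' diagonal shared scales (`Xi1`, `Xi2`), spline coefficient blocks for the
#' shared (`beta`, r x K), and individual factors (`beta1`, `beta2`), the warp
#' coefficients `kappa`, feature-specific noise variances and the
#' multiplicative-gamma shrinkage locals/globals.
#'
#' @param Lambda,Gamma1,Gamma2 loading matrices (p rows each).
#' @param Xi1,Xi2 length-r diagonal scale vectors.
#' @param beta,beta1,beta2 factor spline coefficients.
#' @param kappa warp coefficients (length J - 1).
#' @param sig1sq,sig2sq length-p noise variances (strictly positive).
#' @param phi1,phi11,phi12 local shrinkage precisions (match loading shapes).
#' @param delta1,delta11,delta12 multiplicative gamma increments.
#' @return Object of class `tacifa_state`.
#' @export
model_state <- function(Lambda, Gamma1, Gamma2, Xi1, Xi2,
                        beta, beta1, beta2, kappa, sig1sq, sig2sq,
                        phi1 = NULL, phi11 = NULL, phi12 = NULL,
                        delta1 = NULL, delta11 = NULL, delta12 = NULL) {
  Lambda <- as.matrix(Lambda); Gamma1 <- as.matrix(Gamma1); Gamma2 <- as.matrix(Gamma2)
  beta <- as.matrix(beta); beta1 <- as.matrix(beta1); beta2 <- as.matrix(beta2)
  p <- nrow(Lambda)
  r <- ncol(Lambda); r1 <- ncol(Gamma1); r2 <- ncol(Gamma2)
  stopifnot(nrow(Gamma1) == p, nrow(Gamma2) == p,
            length(Xi1) == r, length(Xi2) == r,
            nrow(beta) == r, nrow(beta1) == r1, nrow(beta2) == r2,
            length(sig1sq) == p, length(sig2sq) == p)
  if (any(sig1sq <= 0) || any(sig2sq <= 0)) stop("noise variances must be positive")
  if (is.null(phi1)) phi1 <- matrix(1, p, r)
  if (is.null(phi11)) phi11 <- matrix(1, p, r1)
  if (is.null(phi12)) phi12 <- matrix(1, p, r2)
  if (is.null(delta1)) delta1 <- rep(1, r)
  if (is.null(delta11)) delta11 <- rep(1, r1)
  if (is.null(delta12)) delta12 <- rep(1, r2)
  structure(list(Lambda = Lambda, Gamma1 = Gamma1, Gamma2 = Gamma2,
                 Xi1 = as.numeric(Xi1), Xi2 = as.numeric(Xi2),
                 beta = beta, beta1 = beta1, beta2 = beta2,
                 kappa = as.numeric(kappa),
                 sig1sq = as.numeric(sig1sq), sig2sq = as.numeric(sig2sq),
                 phi1 = phi1, phi11 = phi11, phi12 = phi12,
                 delta1 = as.numeric(delta1), delta11 = as.numeric(delta11),
                 delta12 = as.numeric(delta12)),
            class = "tacifa_state")
}

# factor curves of a state on a grid; the shared factors of the second series
# are evaluated at the warped times M(t)
state_curves <- function(state, bases, t) {
  warp <- warp_spec(state$kappa)
  M <- eval_warp(warp, bases$warp, t)
  list(eta = state$beta %*% t(eval_basis(bases$shared, t)),
       etaM = state$beta %*% t(eval_basis(bases$shared, M)),
       zeta1 = state$beta1 %*% t(eval_basis(bases$ind1, t)),
       zeta2 = state$beta2 %*% t(eval_basis(bases$ind2, t)),
       M = M)
}

#' Mean curves of the two series under a model state
#'
#' mu_X(t) = Psi Gamma1 zeta1(t) + Lambda Xi1 eta(t);
#' mu_Y(t) = Psi Gamma2 zeta2(t) + Lambda Xi2 eta(M(t)).
#' The second series' shared factors are time-aligned through the warp.
#'
#' @param state a [model_state()].
#' @param bases a [tacifa_bases()].
#' @param t evaluation grid in \[0,1\].
#' @return list with p x length(t) matrices `mu_X` and `mu_Y` plus the warped
#'   times `M`.
#' @export
mean_curves <- function(state, bases, t) {
  cu <- state_curves(state, bases, t)
  Psi <- projection(state$Lambda)
  mu_X <- Psi %*% state$Gamma1 %*% cu$zeta1 +
    state$Lambda %*% (state$Xi1 * cu$eta)
  mu_Y <- Psi %*% state$Gamma2 %*% cu$zeta2 +
    state$Lambda %*% (state$Xi2 * cu$etaM)
  list(mu_X = mu_X, mu_Y = mu_Y, M = cu$M)
}

#' Gaussian log-likelihood of a state
#'
#' Sum over both series of independent Gaussian log-densities with
#' feature-specific variances.
#'
#' @param state a [model_state()].
#' @param data a [paired_series()].
#' @param bases a [tacifa_bases()].
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(state, data, bases) {
  if (any(state$sig1sq <= 0) || any(state$sig2sq <= 0))
    stop("noise variances must be positive")
  mu <- mean_curves(state, bases, data$t)
  Tn <- data$T
  R1 <- data$X - mu$mu_X
  R2 <- data$Y - mu$mu_Y
  ll1 <- -0.5 * sum(Tn * log(2 * pi * state$sig1sq)) -
    0.5 * sum(rowSums(R1^2) / state$sig1sq)
  ll2 <- -0.5 * sum(Tn * log(2 * pi * state$sig2sq)) -
    0.5 * sum(rowSums(R2^2) / state$sig2sq)
  ll1 + ll2
}

# shared-variance-contribution core of Syn: all arguments p x T (variances
# recycled per feature row)
syn_core <- function(shared1, shared2, ind1, ind2, sig1sq, sig2sq) {
  c1 <- shared1^2 / (ind1^2 + shared1^2 + sig1sq)
  c2 <- shared2^2 / (ind2^2 + shared2^2 + sig2sq)
  p <- nrow(shared1); Tn <- ncol(shared1)
  1 - sum(abs(rowSums(c1 - c2))) / (p * Tn)
}

#' Syn: similarity of the shared structure of the two series
#'
#' For each feature l and time t the relative shared-variance contribution of
#' each series is
#' (Lambda_l Xi eta)^2 / ((Psi_l Gamma zeta)^2 + (Lambda_l Xi eta)^2 + sigma_l^2);
#' Syn is one minus the average (over features and time) absolute difference of
#' the two contributions. It lies in \[0,1\]; 1 means the warped shared
#' structure explains the same relative variance in both series feature by
#' feature.
#'
#' @param state a [model_state()].
#' @param bases a [tacifa_bases()].
#' @param t evaluation grid.
#' @return scalar in \[0,1\].
#' @export
syn_similarity <- function(state, bases, t) {
  cu <- state_curves(state, bases, t)
  Psi <- projection(state$Lambda)
  shared1 <- state$Lambda %*% (state$Xi1 * cu$eta)
  shared2 <- state$Lambda %*% (state$Xi2 * cu$etaM)
  ind1 <- Psi %*% state$Gamma1 %*% cu$zeta1
  ind2 <- Psi %*% state$Gamma2 %*% cu$zeta2
  syn_core(shared1, shared2, ind1, ind2, state$sig1sq, state$sig2sq)
}
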