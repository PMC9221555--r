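# B-spline bases on [0,1] and the monotone warping-function construction.

#' B-spline basis specification on [0,1]
#'
#' Defines `n_bases` B-spline basis functions of the given degree with clamped
#' (repeated) boundary knots and equidistant interior knots, so that the basis
#' is a non-negative partition of unity on \[0,1\] and interpolates at the
#' endpoints (first basis equals 1 at t = 0, last equals 1 at t = 1).
#'
#' @param n_bases number of basis functions (at least `degree + 1`).
#' @param degree polynomial degree; cubic by default.
#' @return An object of class `bspline_spec` with fields `n_bases`, `degree`
#'   and the full (clamped) `knots` vector.
#' @examples
#' sp <- bspline_spec(10)
#' B <- eval_basis(sp, seq(0, 1, 0.1))
#' rowSums(B)  # all 1
#' @export
bspline_spec <- function(n_bases, degree = 3L) {
  n_bases <- as.integer(n_bases)
  degree <- as.integer(degree)
  if (degree < 0L) stop("degree must be non-negative")
  if (n_bases < degree + 1L)
    stop("n_bases must be at least degree + 1 (got ", n_bases, ")")
  n_int <- n_bases - degree - 1L
  interior <- if (n_int > 0L) seq(0, 1, length.out = n_int + 2L)[-c(1L, n_int + 2L)] else numeric(0)
  knots <- c(rep(0, degree + 1L), interior, rep(1, degree + 1L))
  structure(list(n_bases = n_bases, degree = degree, knots = knots),
            class = "bspline_spec")
}

#' Evaluate a B-spline basis (or its derivative)
#'
#' @param spec a [bspline_spec()].
#' @param t evaluation points, all within \[0,1\].
#' @param deriv derivative order (0 = values).
#' @return A `length(t) x n_bases` matrix. Rows of the value matrix sum to 1.
#' @export
eval_basis <- function(spec, t, deriv = 0L) {
  stopifnot(inherits(spec, "bspline_spec"))
  if (any(!is.finite(t)) || any(t < 0) || any(t > 1))
    stop("evaluation points must lie in [0, 1]")
  B <- splines::splineDesign(spec$knots, t, ord = spec$degree + 1L,
                             derivs = rep(deriv, length(t)))
  dimnames(B) <- NULL
  B
}

#' Greville abscissae of a basis
#'
#' Knot averages; using them as spline coefficients reproduces the identity
#' function, which is how the warp reduces to M(t) = t.
#' @param spec a [bspline_spec()].
#' @return numeric vector of length `n_bases`.
#' @export
greville_abscissae <- function(spec) {
  stopifnot(inherits(spec, "bspline_spec"))
  d <- spec$degree
  vapply(seq_len(spec$n_bases),
         function(j) mean(spec$knots[(j + 1):(j + d)]), numeric(1))
}

#' Monotone warp coefficients from unconstrained parameters
#'
#' Maps a free vector kappa = (kappa_2, ..., kappa_J) to cumulative softmax
#' weights gamma = (0, gamma_2, ..., gamma_J = 1):
#' gamma_j = sum_{l <= j} exp(kappa_l) / sum_k exp(kappa_k).
#' Used as B-spline coefficients these force M(0) = 0, M(1) = 1 and
#' monotonicity of the warp.
#'
#' @param kappa real vector (length J - 1), all finite.
#' @return non-decreasing vector of length `length(kappa) + 1` starting at 0
#'   and ending at 1.
#' @examples
#' gamma_from_kappa(c(0, 0, 0))            # 0, 1/3, 2/3, 1
#' gamma_from_kappa(log(1:3))              # 0, 1/6, 1/2, 1
#' @export
gamma_from_kappa <- function(kappa) {
  if (length(kappa) < 1L) stop("kappa must have length >= 1")
  if (any(!is.finite(kappa))) stop("kappa must be finite")
  w <- exp(kappa - max(kappa))
  w <- w / sum(w)
  gamma <- c(0, cumsum(w))
  gamma[length(gamma)] <- 1
  gamma
}

#' Warping-function specification
#'
#' @param kappa free coefficients (length J - 1).
#' @return An object of class `warp_spec` with fields `kappa` and the induced
#'   monotone coefficients `gamma` (length J).
#' @export
warp_spec <- function(kappa) {
  structure(list(kappa = as.numeric(kappa), gamma = gamma_from_kappa(kappa)),
            class = "warp_spec")
}

#' Evaluate the warping function M(t)
#'
#' M(t) = sum_j gamma_j B_j(t) with monotone coefficients, so M maps \[0,1\]
#' onto itself with M(0) = 0, M(1) = 1 and M non-decreasing. Values are
#' clamped into \[0,1\] to guard against floating-point overshoot.
#'
#' @param warp a [warp_spec()].
#' @param spec the warp basis, a [bspline_spec()] with
#'   `n_bases == length(warp$gamma)`.
#' @param t evaluation points in \[0,1\].
#' @return numeric vector of warped times.
#' @export
eval_warp <- function(warp, spec, t) {
  stopifnot(inherits(warp, "warp_spec"), inherits(spec, "bspline_spec"))
  if (spec$n_bases != length(warp$gamma))
    stop("warp has ", length(warp$gamma), " coefficients but basis has ",
         spec$n_bases, " functions")
  M <- drop(eval_basis(spec, t) %*% warp$gamma)
  pmin(pmax(M, 0), 1)
}
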