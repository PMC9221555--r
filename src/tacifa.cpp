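// Sampler core for the time-aligned common/individual factor model.
//
// The model for a pair of p x T series X, Y on a common grid t in [0,1]:
//   x_t = Psi Gamma1 zeta1(t) + Lambda Xi1 eta(t)    + e1t,
//   y_t = Psi Gamma2 zeta2(t) + Lambda Xi2 eta(M(t)) + e2t,
// with Psi = I - Lambda (Lambda'Lambda)^-1 Lambda', eta/zeta B-spline factor
// curves, and M a monotone B-spline warp with softmax-cumulative coefficients.
// Conjugate Gibbs updates for all linear/scale blocks; HMC for kappa (warp)
// and for the columns of Lambda (which enter nonlinearly through Psi).
//
// All randomness goes through R's RNG so set.seed() governs reproducibility.

#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::uvec;

// ---------------------------------------------------------------------------
// B-spline evaluation (de Boor recursions, clamped knots, right-closed at 1)
// ---------------------------------------------------------------------------

static int find_span(double u, const vec& knots, int degree, int nbasis) {
  int n = nbasis - 1;
  if (u >= knots(n + 1)) return n;  // right-closed convention at the boundary
  if (u <= knots(degree)) return degree;
  int lo = degree, hi = n + 1, mid = (lo + hi) / 2;
  while (u < knots(mid) || u >= knots(mid + 1)) {
    if (u < knots(mid)) hi = mid; else lo = mid;
    mid = (lo + hi) / 2;
  }
  return mid;
}

// Values and derivatives of the (degree+1) nonzero basis functions at u.
// ders is (nd+1) x (degree+1); row 0 = values, row 1 = first derivatives, ...
static void basis_ders(double u, int span, const vec& knots, int degree,
                       int nd, mat& ders) {
  const int p = degree;
  mat ndu(p + 1, p + 1);
  vec left(p + 1), right(p + 1);
  ndu(0, 0) = 1.0;
  for (int j = 1; j <= p; j++) {
    left(j) = u - knots(span + 1 - j);
    right(j) = knots(span + j) - u;
    double saved = 0.0;
    for (int r = 0; r < j; r++) {
      ndu(j, r) = right(r + 1) + left(j - r);
      double temp = ndu(r, j - 1) / ndu(j, r);
      ndu(r, j) = saved + right(r + 1) * temp;
      saved = left(j - r) * temp;
    }
    ndu(j, j) = saved;
  }
  ders.zeros(nd + 1, p + 1);
  for (int j = 0; j <= p; j++) ders(0, j) = ndu(j, p);
  if (nd == 0) return;
  mat a(2, p + 1);
  for (int r = 0; r <= p; r++) {
    int s1 = 0, s2 = 1;
    a(0, 0) = 1.0;
    for (int k = 1; k <= nd; k++) {
      double d = 0.0;
      int rk = r - k, pk = p - k;
      if (r >= k) { a(s2, 0) = a(s1, 0) / ndu(pk + 1, rk); d = a(s2, 0) * ndu(rk, pk); }
      int j1 = (rk >= -1) ? 1 : -rk;
      int j2 = (r - 1 <= pk) ? (k - 1) : (p - r);
      for (int j = j1; j <= j2; j++) {
        a(s2, j) = (a(s1, j) - a(s1, j - 1)) / ndu(pk + 1, rk + j);
        d += a(s2, j) * ndu(rk + j, pk);
      }
      if (r <= pk) { a(s2, k) = -a(s1, k - 1) / ndu(pk + 1, r); d += a(s2, k) * ndu(r, pk); }
      ders(k, r) = d;
      std::swap(s1, s2);
    }
  }
  int rr = p;
  for (int k = 1; k <= nd; k++) {
    for (int j = 0; j <= p; j++) ders(k, j) *= rr;
    rr *= (p - k);
  }
}

// Full basis (or derivative) matrix: length(x) rows, nbasis columns.
// [[Rcpp::export]]
arma::mat cpp_bspline_matrix(const arma::vec& x, const arma::vec& knots,
                             int degree, int deriv) {
  int nbasis = knots.n_elem - degree - 1;
  mat out(x.n_elem, nbasis, arma::fill::zeros);
  mat ders;
  for (arma::uword i = 0; i < x.n_elem; i++) {
    double u = x(i);
    if (u < knots(0) - 1e-12 || u > knots(knots.n_elem - 1) + 1e-12)
      stop("basis evaluation point outside the knot range");
    int span = find_span(u, knots, degree, nbasis);
    basis_ders(u, span, knots, degree, deriv, ders);
    for (int j = 0; j <= degree; j++) out(i, span - degree + j) = ders(deriv, j);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Warp coefficients: gamma_j = sum_{l<=j} softmax(kappa)_l, gamma_1 = 0
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::vec cpp_gamma_from_kappa(const arma::vec& kappa) {
  if (!kappa.is_finite()) stop("non-finite kappa");
  vec w = arma::exp(kappa - kappa.max());
  w /= arma::accu(w);
  vec gamma(kappa.n_elem + 1, arma::fill::zeros);
  double c = 0.0;
  for (arma::uword j = 0; j < kappa.n_elem; j++) { c += w(j); gamma(j + 1) = c; }
  gamma(kappa.n_elem) = 1.0;  // exact endpoint
  return gamma;
}

// ---------------------------------------------------------------------------
// State / fixed quantities
// ---------------------------------------------------------------------------

struct State {
  mat Lambda, Gamma1, Gamma2;   // p x r, p x r1, p x r2
  vec Xi1, Xi2;                 // r
  mat beta, beta1, beta2;       // r x K, r1 x K1, r2 x K2
  vec kappa;                    // J - 1
  vec sig1, sig2;               // p (variances)
  mat phi1, phi11, phi12;       // local shrinkage
  vec delta1, delta11, delta12; // multiplicative gamma increments
};

struct Pre {
  mat X, Y;                     // p x T
  vec tg;                       // T
  mat B, B1, B2, BJ;            // bases at the grid
  mat BtB, B1tB1, B2tB2;
  mat SJ;                       // T x (J-1), SJ(t, j) = sum_{l >= j+2} BJ_l(t)
  vec knotsK;                   // shared-basis knots, for evaluation at M(t)
  int degree;
  double nu1, adel1, adel2, asig, bsig, omega;
};

static State state_from_list(const List& st) {
  State s;
  s.Lambda = as<mat>(st["Lambda"]); s.Gamma1 = as<mat>(st["Gamma1"]);
  s.Gamma2 = as<mat>(st["Gamma2"]);
  s.Xi1 = as<vec>(st["Xi1"]); s.Xi2 = as<vec>(st["Xi2"]);
  s.beta = as<mat>(st["beta"]); s.beta1 = as<mat>(st["beta1"]);
  s.beta2 = as<mat>(st["beta2"]);
  s.kappa = as<vec>(st["kappa"]);
  s.sig1 = as<vec>(st["sig1sq"]); s.sig2 = as<vec>(st["sig2sq"]);
  s.phi1 = as<mat>(st["phi1"]); s.phi11 = as<mat>(st["phi11"]);
  s.phi12 = as<mat>(st["phi12"]);
  s.delta1 = as<vec>(st["delta1"]); s.delta11 = as<vec>(st["delta11"]);
  s.delta12 = as<vec>(st["delta12"]);
  return s;
}

static List state_to_list(const State& s) {
  return List::create(
    _["Lambda"] = s.Lambda, _["Gamma1"] = s.Gamma1, _["Gamma2"] = s.Gamma2,
    _["Xi1"] = s.Xi1, _["Xi2"] = s.Xi2,
    _["beta"] = s.beta, _["beta1"] = s.beta1, _["beta2"] = s.beta2,
    _["kappa"] = s.kappa, _["sig1sq"] = s.sig1, _["sig2sq"] = s.sig2,
    _["phi1"] = s.phi1, _["phi11"] = s.phi11, _["phi12"] = s.phi12,
    _["delta1"] = s.delta1, _["delta11"] = s.delta11, _["delta12"] = s.delta12);
}

static Pre pre_from_lists(const List& data, const List& bases, const List& hyper) {
  Pre pre;
  pre.X = as<mat>(data["X"]); pre.Y = as<mat>(data["Y"]);
  pre.tg = as<vec>(data["t"]);
  pre.degree = as<int>(bases["degree"]);
  pre.knotsK = as<vec>(bases["knotsK"]);
  vec knots1 = as<vec>(bases["knots1"]);
  vec knots2 = as<vec>(bases["knots2"]);
  vec knotsJ = as<vec>(bases["knotsJ"]);
  pre.B  = cpp_bspline_matrix(pre.tg, pre.knotsK, pre.degree, 0);
  pre.B1 = cpp_bspline_matrix(pre.tg, knots1, pre.degree, 0);
  pre.B2 = cpp_bspline_matrix(pre.tg, knots2, pre.degree, 0);
  pre.BJ = cpp_bspline_matrix(pre.tg, knotsJ, pre.degree, 0);
  pre.BtB = pre.B.t() * pre.B;
  pre.B1tB1 = pre.B1.t() * pre.B1;
  pre.B2tB2 = pre.B2.t() * pre.B2;
  int J = pre.BJ.n_cols;
  pre.SJ.zeros(pre.BJ.n_rows, J - 1);
  for (int j = 0; j < J - 1; j++)  // column j corresponds to kappa_{j+2}
    pre.SJ.col(j) = arma::sum(pre.BJ.cols(j + 1, J - 1), 1);
  pre.nu1 = as<double>(hyper["nu1"]);
  pre.adel1 = as<double>(hyper["a_delta1"]);
  pre.adel2 = as<double>(hyper["a_delta2"]);
  pre.asig = as<double>(hyper["a_sigma"]);
  pre.bsig = as<double>(hyper["b_sigma"]);
  pre.omega = as<double>(hyper["omega"]);
  return pre;
}

// I - U U' over the numerically nonzero singular directions of Lambda;
// equals I - Lambda(Lambda'Lambda)^-1 Lambda' at full rank and stays stable
// when shrunk columns are nearly collinear.
static mat psi_of(const mat& Lambda) {
  int p = Lambda.n_rows;
  mat U, V;
  vec sv;
  if (!arma::svd_econ(U, sv, V, Lambda, "left"))
    stop("SVD failure while forming the orthogonal projector");
  double tol = 1e-10 * std::max(sv.max(), arma::datum::eps);
  uvec keep = arma::find(sv > tol);
  mat Uk = U.cols(keep);
  return arma::eye(p, p) - Uk * Uk.t();
}

static vec cumprod_vec(const vec& d) {
  vec out(d.n_elem);
  double c = 1.0;
  for (arma::uword i = 0; i < d.n_elem; i++) { c *= d(i); out(i) = c; }
  return out;
}

static vec draw_mvn_prec(mat P, const vec& l) {
  P = 0.5 * (P + P.t());  // guard against floating-point asymmetry
  mat R;
  if (!arma::chol(R, P)) {
    P.diag() += 1e-8 * (1.0 + P.diag().max());
    if (!arma::chol(R, P)) stop("Cholesky failure in a Gaussian full conditional");
  }
  vec mu = arma::solve(arma::trimatu(R), arma::solve(arma::trimatl(R.t()), l));
  vec z(P.n_rows);
  for (arma::uword i = 0; i < z.n_elem; i++) z(i) = norm_rand();
  return mu + arma::solve(arma::trimatu(R), z);
}

// Basis (and optionally derivative) of the shared basis evaluated at M(t).
static void warp_basis(const State& s, const Pre& pre, vec& M, mat& BM,
                       mat* BMd) {
  vec gamma = cpp_gamma_from_kappa(s.kappa);
  M = pre.BJ * gamma;
  M.clamp(0.0, 1.0);
  BM = cpp_bspline_matrix(M, pre.knotsK, pre.degree, 0);
  if (BMd) *BMd = cpp_bspline_matrix(M, pre.knotsK, pre.degree, 1);
}

// ---------------------------------------------------------------------------
// Conjugate Gibbs blocks
// ---------------------------------------------------------------------------

static bool has_block(const std::vector<std::string>& blocks, const char* b) {
  if (blocks.empty()) return true;  // empty = all blocks
  for (const auto& x : blocks) if (x == b) return true;
  return false;
}

static void gibbs_linear(State& s, const Pre& pre, const mat& BM,
                         const std::vector<std::string>& blocks) {
  const int T = pre.X.n_cols;
  const int r = s.Lambda.n_cols, r1 = s.Gamma1.n_cols, r2 = s.Gamma2.n_cols;
  const int K = pre.B.n_cols, K1 = pre.B1.n_cols, K2 = pre.B2.n_cols;
  const vec is1 = 1.0 / s.sig1, is2 = 1.0 / s.sig2;
  const double iomega = 1.0 / pre.omega;

  mat Psi = psi_of(s.Lambda);
  mat eta = s.beta * pre.B.t();       // r x T
  mat etaM = s.beta * BM.t();         // r x T
  mat zeta1 = s.beta1 * pre.B1.t();   // r1 x T
  mat zeta2 = s.beta2 * pre.B2.t();   // r2 x T
  mat D1 = Psi * s.Gamma1, D2 = Psi * s.Gamma2;
  mat E1 = pre.X - D1 * zeta1 - s.Lambda * arma::diagmat(s.Xi1) * eta;
  mat E2 = pre.Y - D2 * zeta2 - s.Lambda * arma::diagmat(s.Xi2) * etaM;
  mat BMtBM = BM.t() * BM;

  if (has_block(blocks, "beta")) {
    for (int q = 0; q < r; q++) {
      vec a1 = s.Lambda.col(q) * s.Xi1(q);
      vec a2 = s.Lambda.col(q) * s.Xi2(q);
      E1 += a1 * eta.row(q);
      E2 += a2 * etaM.row(q);
      double c1 = arma::accu(arma::square(a1) % is1);
      double c2 = arma::accu(arma::square(a2) % is2);
      mat P = c1 * pre.BtB + c2 * BMtBM;
      P.diag() += iomega;
      vec l = pre.B.t() * (E1.t() * (a1 % is1)) + BM.t() * (E2.t() * (a2 % is2));
      vec b = draw_mvn_prec(P, l);
      s.beta.row(q) = b.t();
      eta.row(q) = (pre.B * b).t();
      etaM.row(q) = (BM * b).t();
      E1 -= a1 * eta.row(q);
      E2 -= a2 * etaM.row(q);
    }
  }

  if (has_block(blocks, "beta1")) {
    for (int q = 0; q < r1; q++) {
      vec d = D1.col(q);
      E1 += d * zeta1.row(q);
      double c = arma::accu(arma::square(d) % is1);
      mat P = c * pre.B1tB1;
      P.diag() += iomega;
      vec l = pre.B1.t() * (E1.t() * (d % is1));
      vec b = draw_mvn_prec(P, l);
      s.beta1.row(q) = b.t();
      zeta1.row(q) = (pre.B1 * b).t();
      E1 -= d * zeta1.row(q);
    }
  }
  if (has_block(blocks, "beta2")) {
    for (int q = 0; q < r2; q++) {
      vec d = D2.col(q);
      E2 += d * zeta2.row(q);
      double c = arma::accu(arma::square(d) % is2);
      mat P = c * pre.B2tB2;
      P.diag() += iomega;
      vec l = pre.B2.t() * (E2.t() * (d % is2));
      vec b = draw_mvn_prec(P, l);
      s.beta2.row(q) = b.t();
      zeta2.row(q) = (pre.B2 * b).t();
      E2 -= d * zeta2.row(q);
    }
  }

  // Gamma blocks, column by column (columns are coupled only through the
  // residual, so a scan over columns is a valid Gibbs sweep).
  if (has_block(blocks, "Gamma1")) {
    vec tau11 = cumprod_vec(s.delta11);
    mat PsiS1Psi = Psi * (Psi.each_col() % is1);
    for (int c = 0; c < r1; c++) {
      vec g = s.Gamma1.col(c);
      E1 += (Psi * g) * zeta1.row(c);
      double zz = arma::dot(zeta1.row(c), zeta1.row(c));
      mat P = zz * PsiS1Psi;
      P.diag() += s.phi11.col(c) * tau11(c);
      vec l = Psi * ((E1.each_col() % is1) * zeta1.row(c).t());
      vec gn = draw_mvn_prec(P, l);
      s.Gamma1.col(c) = gn;
      E1 -= (Psi * gn) * zeta1.row(c);
    }
    D1 = Psi * s.Gamma1;
  }
  if (has_block(blocks, "Gamma2")) {
    vec tau12 = cumprod_vec(s.delta12);
    mat PsiS2Psi = Psi * (Psi.each_col() % is2);
    for (int c = 0; c < r2; c++) {
      vec g = s.Gamma2.col(c);
      E2 += (Psi * g) * zeta2.row(c);
      double zz = arma::dot(zeta2.row(c), zeta2.row(c));
      mat P = zz * PsiS2Psi;
      P.diag() += s.phi12.col(c) * tau12(c);
      vec l = Psi * ((E2.each_col() % is2) * zeta2.row(c).t());
      vec gn = draw_mvn_prec(P, l);
      s.Gamma2.col(c) = gn;
      E2 -= (Psi * gn) * zeta2.row(c);
    }
    D2 = Psi * s.Gamma2;
  }

  if (has_block(blocks, "Xi1")) {
    mat Xt = E1 + s.Lambda * arma::diagmat(s.Xi1) * eta;
    mat H = s.Lambda.t() * (Xt.each_col() % is1);          // r x T
    mat P = (s.Lambda.t() * (s.Lambda.each_col() % is1)) % (eta * eta.t());
    P.diag() += iomega;
    vec l = arma::sum(H % eta, 1);
    s.Xi1 = draw_mvn_prec(P, l);
    E1 = Xt - s.Lambda * arma::diagmat(s.Xi1) * eta;
  }
  if (has_block(blocks, "Xi2")) {
    mat Yt = E2 + s.Lambda * arma::diagmat(s.Xi2) * etaM;
    mat H = s.Lambda.t() * (Yt.each_col() % is2);
    mat P = (s.Lambda.t() * (s.Lambda.each_col() % is2)) % (etaM * etaM.t());
    P.diag() += iomega;
    vec l = arma::sum(H % etaM, 1);
    s.Xi2 = draw_mvn_prec(P, l);
    E2 = Yt - s.Lambda * arma::diagmat(s.Xi2) * etaM;
  }
  (void)T; (void)K; (void)K1; (void)K2;
}

// Residual-variance and multiplicative-gamma shrinkage updates.
static void gibbs_scales(State& s, const Pre& pre, const mat& BM,
                         const std::vector<std::string>& blocks) {
  const int p = pre.X.n_rows, T = pre.X.n_cols;
  mat Psi = psi_of(s.Lambda);
  mat eta = s.beta * pre.B.t();
  mat etaM = s.beta * BM.t();
  mat E1 = pre.X - Psi * s.Gamma1 * (s.beta1 * pre.B1.t())
    - s.Lambda * arma::diagmat(s.Xi1) * eta;
  mat E2 = pre.Y - Psi * s.Gamma2 * (s.beta2 * pre.B2.t())
    - s.Lambda * arma::diagmat(s.Xi2) * etaM;

  if (has_block(blocks, "sigma")) {
    vec ss1 = arma::sum(arma::square(E1), 1);
    vec ss2 = arma::sum(arma::square(E2), 1);
    for (int i = 0; i < p; i++) {
      s.sig1(i) = 1.0 / R::rgamma(pre.asig + 0.5 * T, 1.0 / (pre.bsig + 0.5 * ss1(i)));
      s.sig2(i) = 1.0 / R::rgamma(pre.asig + 0.5 * T, 1.0 / (pre.bsig + 0.5 * ss2(i)));
    }
  }

  if (has_block(blocks, "shrinkage")) {
    // one MGP block: local precisions phi, then a scan over delta
    auto mgp = [&](mat& phi, vec& delta, const mat& A) {
      int pp = A.n_rows, rr = A.n_cols;
      vec tau = cumprod_vec(delta);
      for (int k = 0; k < rr; k++)
        for (int l = 0; l < pp; l++)
          phi(l, k) = R::rgamma(pre.nu1 + 0.5,
                                1.0 / (pre.nu1 + 0.5 * tau(k) * A(l, k) * A(l, k)));
      for (int h = 0; h < rr; h++) {
        tau = cumprod_vec(delta);
        double rate = 1.0, shape = (h == 0 ? pre.adel1 : pre.adel2)
          + 0.5 * pp * (rr - h);
        for (int k = h; k < rr; k++) {
          double w = arma::dot(phi.col(k), arma::square(A.col(k)));
          rate += 0.5 * (tau(k) / delta(h)) * w;
        }
        delta(h) = R::rgamma(shape, 1.0 / rate);
      }
    };
    mgp(s.phi1, s.delta1, s.Lambda);
    mgp(s.phi11, s.delta11, s.Gamma1);
    mgp(s.phi12, s.delta12, s.Gamma2);
  }
}

// ---------------------------------------------------------------------------
// HMC for kappa (warp coefficients)
// ---------------------------------------------------------------------------

// negative log posterior and gradient in kappa, everything else fixed
static double kappa_potential(const vec& kappa, const State& s, const Pre& pre,
                              const mat& Ytil, vec* grad) {
  int Jm1 = kappa.n_elem;
  vec w = arma::exp(kappa - kappa.max());
  w /= arma::accu(w);
  vec gamma(Jm1 + 1, arma::fill::zeros);
  double c = 0.0;
  for (int j = 0; j < Jm1; j++) { c += w(j); gamma(j + 1) = c; }
  gamma(Jm1) = 1.0;
  vec M = pre.BJ * gamma;
  M.clamp(0.0, 1.0);
  mat BM = cpp_bspline_matrix(M, pre.knotsK, pre.degree, 0);
  mat A2 = s.Lambda * arma::diagmat(s.Xi2);      // p x r
  mat E2 = Ytil - A2 * (s.beta * BM.t());        // p x T
  vec is2 = 1.0 / s.sig2;
  double U = 0.5 * arma::dot(is2, arma::sum(arma::square(E2), 1))
    + 0.5 * arma::dot(kappa, kappa) / pre.omega;
  if (grad) {
    mat BMd = cpp_bspline_matrix(M, pre.knotsK, pre.degree, 1);
    mat W2 = E2.each_col() % is2;
    mat AdM = A2 * (s.beta * BMd.t());           // p x T, d/dM of the mean
    rowvec h = arma::sum(W2 % AdM, 0);           // 1 x T
    vec u = pre.SJ.t() * h.t();                  // (J-1)
    double hM = arma::dot(h.t(), M);
    *grad = -(w % (u - hM)) + kappa / pre.omega;
  }
  return U;
}

static int hmc_kappa(State& s, const Pre& pre, double eps, int L) {
  mat Psi = psi_of(s.Lambda);
  mat Ytil = pre.Y - Psi * s.Gamma2 * (s.beta2 * pre.B2.t());
  int n = s.kappa.n_elem;
  vec q = s.kappa, m(n);
  for (int i = 0; i < n; i++) m(i) = norm_rand();
  vec grad;
  double U0 = kappa_potential(q, s, pre, Ytil, &grad);
  double K0 = 0.5 * arma::dot(m, m);
  vec m_ = m - 0.5 * eps * grad;
  for (int l = 0; l < L; l++) {
    q += eps * m_;
    double U = kappa_potential(q, s, pre, Ytil, &grad);
    (void)U;
    if (!grad.is_finite()) return 0;
    if (l < L - 1) m_ -= eps * grad; else m_ -= 0.5 * eps * grad;
  }
  double U1 = kappa_potential(q, s, pre, Ytil, nullptr);
  double K1 = 0.5 * arma::dot(m_, m_);
  if (!std::isfinite(U1)) return 0;
  double logacc = (U0 + K0) - (U1 + K1);
  if (std::log(unif_rand()) < logacc) { s.kappa = q; return 1; }
  return 0;
}

// ---------------------------------------------------------------------------
// HMC for one column of Lambda
// ---------------------------------------------------------------------------

struct LambdaCtx {
  mat Psim;          // projector onto the complement of the other columns
  mat PGz1, PGz2;    // Psim * Gamma_i zeta_i(t)
  mat Gz1, Gz2;      // Gamma_i zeta_i(t)
  mat base1, base2;  // data minus everything that does not move with lambda
  rowvec etaj, etaMj;
  double xi1j, xi2j;
  vec is1, is2, prior_prec;
};

static double lambda_potential(const vec& lam, const LambdaCtx& cx, vec* grad) {
  vec v = cx.Psim * lam;
  double sv = arma::dot(v, v);
  if (sv < 1e-12) {  // proposed column (numerically) inside the other columns' span
    if (grad) grad->zeros(lam.n_elem);
    return arma::datum::inf;
  }
  vec qv1 = cx.Gz1.t() * v, qv2 = cx.Gz2.t() * v;   // T vectors
  mat E1 = cx.base1 + v * (qv1.t() / sv) - lam * (cx.xi1j * cx.etaj);
  mat E2 = cx.base2 + v * (qv2.t() / sv) - lam * (cx.xi2j * cx.etaMj);
  double U = 0.5 * arma::dot(cx.is1, arma::sum(arma::square(E1), 1))
    + 0.5 * arma::dot(cx.is2, arma::sum(arma::square(E2), 1))
    + 0.5 * arma::dot(cx.prior_prec, arma::square(lam));
  if (grad) {
    mat W1 = E1.each_col() % cx.is1;
    mat W2 = E2.each_col() % cx.is2;
    vec g = -cx.xi1j * (W1 * cx.etaj.t()) - cx.xi2j * (W2 * cx.etaMj.t());
    // gradient through Psi = Psim - v v'/(v'v), v = Psim lam
    vec W1tv = W1.t() * v, W2tv = W2.t() * v;
    vec Cv = cx.Gz1 * W1tv + cx.Gz2 * W2tv;
    vec Ctv = W1 * qv1 + W2 * qv2;
    double vCv = arma::dot(qv1, W1tv) + arma::dot(qv2, W2tv);
    g += cx.Psim * ((Cv + Ctv) / sv) - (2.0 * vCv / (sv * sv)) * v;
    g += cx.prior_prec % lam;
    *grad = g;
  }
  return U;
}

static LambdaCtx lambda_context(const State& s, const Pre& pre, const mat& BM,
                                int j) {
  const int p = pre.X.n_rows, r = s.Lambda.n_cols;
  LambdaCtx cx;
  mat eta = s.beta * pre.B.t();
  mat etaM = s.beta * BM.t();
  cx.Gz1 = s.Gamma1 * (s.beta1 * pre.B1.t());
  cx.Gz2 = s.Gamma2 * (s.beta2 * pre.B2.t());
  if (r == 1) {
    cx.Psim = arma::eye(p, p);
  } else {
    mat Lm = s.Lambda;
    Lm.shed_col(j);
    cx.Psim = psi_of(Lm);
  }
  cx.PGz1 = cx.Psim * cx.Gz1;
  cx.PGz2 = cx.Psim * cx.Gz2;
  mat sh1 = s.Lambda * arma::diagmat(s.Xi1) * eta
    - s.Lambda.col(j) * (s.Xi1(j) * eta.row(j));
  mat sh2 = s.Lambda * arma::diagmat(s.Xi2) * etaM
    - s.Lambda.col(j) * (s.Xi2(j) * etaM.row(j));
  cx.base1 = pre.X - cx.PGz1 - sh1;
  cx.base2 = pre.Y - cx.PGz2 - sh2;
  cx.etaj = eta.row(j);
  cx.etaMj = etaM.row(j);
  cx.xi1j = s.Xi1(j);
  cx.xi2j = s.Xi2(j);
  cx.is1 = 1.0 / s.sig1;
  cx.is2 = 1.0 / s.sig2;
  vec tau1 = cumprod_vec(s.delta1);
  cx.prior_prec = s.phi1.col(j) * tau1(j);
  return cx;
}

static int hmc_lambda_col(State& s, const Pre& pre, const mat& BM, int j,
                          double eps, int L) {
  LambdaCtx cx = lambda_context(s, pre, BM, j);
  int p = s.Lambda.n_rows;
  vec q = s.Lambda.col(j), m(p);
  for (int i = 0; i < p; i++) m(i) = norm_rand();
  vec grad;
  double U0 = lambda_potential(q, cx, &grad);
  if (!std::isfinite(U0) || !grad.is_finite()) return 0;
  double K0 = 0.5 * arma::dot(m, m);
  vec m_ = m - 0.5 * eps * grad;
  for (int l = 0; l < L; l++) {
    q += eps * m_;
    lambda_potential(q, cx, &grad);
    if (!grad.is_finite()) return 0;
    if (l < L - 1) m_ -= eps * grad; else m_ -= 0.5 * eps * grad;
  }
  double U1 = lambda_potential(q, cx, nullptr);
  double K1 = 0.5 * arma::dot(m_, m_);
  if (!std::isfinite(U1)) return 0;
  if (std::log(unif_rand()) < (U0 + K0) - (U1 + K1)) {
    s.Lambda.col(j) = q;
    return 1;
  }
  return 0;
}

// ---------------------------------------------------------------------------
// Column pruning (rank adaptation)
// ---------------------------------------------------------------------------

// Columns to keep: a column survives when any entry reaches the threshold or
// when it is still inside its protection window (recently added columns get
// time to fit before they can be deleted). At least one column always stays.
static uvec keep_cols(const mat& A, double threshold,
                      const std::vector<int>& birth, int iter, int protect) {
  std::vector<arma::uword> kept;
  for (arma::uword c = 0; c < A.n_cols; c++) {
    bool shielded = c < birth.size() && (iter - birth[c]) < protect;
    if (shielded || arma::abs(A.col(c)).max() >= threshold)
      kept.push_back(c);
  }
  if (kept.empty()) {  // keep the largest column so the rank stays >= 1
    arma::uword best = 0;
    double bv = -1.0;
    for (arma::uword c = 0; c < A.n_cols; c++) {
      double m = arma::abs(A.col(c)).max();
      if (m > bv) { bv = m; best = c; }
    }
    kept.push_back(best);
  }
  return uvec(kept);
}

static void sel_cols(mat& A, const uvec& k) { mat t = A.cols(k); A = t; }
static void sel_rows(mat& A, const uvec& k) { mat t = A.rows(k); A = t; }
static void sel_elem(vec& v, const uvec& k) { vec t = v(k); v = t; }

// Delete the selected columns of each loading block together with the
// matching factor rows, scale entries and shrinkage parameters.
static bool apply_keep(State& s, const uvec& k1, const uvec& k11,
                       const uvec& k12) {
  bool changed = false;
  if (k1.n_elem < s.Lambda.n_cols) {
    sel_cols(s.Lambda, k1);
    sel_elem(s.Xi1, k1); sel_elem(s.Xi2, k1);
    sel_rows(s.beta, k1);
    sel_cols(s.phi1, k1);
    sel_elem(s.delta1, k1);
    changed = true;
  }
  if (k11.n_elem < s.Gamma1.n_cols) {
    sel_cols(s.Gamma1, k11);
    sel_rows(s.beta1, k11);
    sel_cols(s.phi11, k11);
    sel_elem(s.delta11, k11);
    changed = true;
  }
  if (k12.n_elem < s.Gamma2.n_cols) {
    sel_cols(s.Gamma2, k12);
    sel_rows(s.beta2, k12);
    sel_cols(s.phi12, k12);
    sel_elem(s.delta12, k12);
    changed = true;
  }
  return changed;
}

static void subset_birth(std::vector<int>& birth, const uvec& k) {
  std::vector<int> nb;
  nb.reserve(k.n_elem);
  for (arma::uword idx = 0; idx < k.n_elem; idx++) nb.push_back(birth[k(idx)]);
  birth = nb;
}

static bool prune_state(State& s, double threshold) {
  const std::vector<int> none;
  return apply_keep(s,
                    keep_cols(s.Lambda, threshold, none, 0, 0),
                    keep_cols(s.Gamma1, threshold, none, 0, 0),
                    keep_cols(s.Gamma2, threshold, none, 0, 0));
}

// ---------------------------------------------------------------------------
// Exported single-step wrappers (used by the R module surface and the tests)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_gibbs_linear(List state, List data, List bases, List hyper,
                      std::vector<std::string> blocks) {
  State s = state_from_list(state);
  Pre pre = pre_from_lists(data, bases, hyper);
  vec M; mat BM;
  warp_basis(s, pre, M, BM, nullptr);
  gibbs_linear(s, pre, BM, blocks);
  return state_to_list(s);
}

// [[Rcpp::export]]
List cpp_gibbs_scales(List state, List data, List bases, List hyper,
                      std::vector<std::string> blocks) {
  State s = state_from_list(state);
  Pre pre = pre_from_lists(data, bases, hyper);
  vec M; mat BM;
  warp_basis(s, pre, M, BM, nullptr);
  gibbs_scales(s, pre, BM, blocks);
  return state_to_list(s);
}

// [[Rcpp::export]]
List cpp_kappa_potential(List state, List data, List bases, List hyper) {
  State s = state_from_list(state);
  Pre pre = pre_from_lists(data, bases, hyper);
  mat Psi = psi_of(s.Lambda);
  mat Ytil = pre.Y - Psi * s.Gamma2 * (s.beta2 * pre.B2.t());
  vec grad;
  double U = kappa_potential(s.kappa, s, pre, Ytil, &grad);
  return List::create(_["value"] = U, _["grad"] = grad);
}

// [[Rcpp::export]]
List cpp_lambda_potential(List state, List data, List bases, List hyper,
                          int j, const arma::vec& lambda_j) {
  State s = state_from_list(state);
  Pre pre = pre_from_lists(data, bases, hyper);
  vec M; mat BM;
  warp_basis(s, pre, M, BM, nullptr);
  LambdaCtx cx = lambda_context(s, pre, BM, j - 1);
  vec grad;
  double U = lambda_potential(lambda_j, cx, &grad);
  return List::create(_["value"] = U, _["grad"] = grad);
}

// [[Rcpp::export]]
List cpp_hmc_kappa(List state, List data, List bases, List hyper,
                   double eps, int L) {
  State s = state_from_list(state);
  Pre pre = pre_from_lists(data, bases, hyper);
  int acc = (eps > 0.0) ? hmc_kappa(s, pre, eps, L) : 0;
  return List::create(_["state"] = state_to_list(s), _["accept"] = acc);
}

// [[Rcpp::export]]
List cpp_hmc_lambda(List state, List data, List bases, List hyper,
                    int j, double eps, int L) {
  State s = state_from_list(state);
  Pre pre = pre_from_lists(data, bases, hyper);
  vec M; mat BM;
  warp_basis(s, pre, M, BM, nullptr);
  int acc = (eps > 0.0) ? hmc_lambda_col(s, pre, BM, j - 1, eps, L) : 0;
  return List::create(_["state"] = state_to_list(s), _["accept"] = acc);
}

// [[Rcpp::export]]
List cpp_prune(List state, double threshold) {
  State s = state_from_list(state);
  bool changed = prune_state(s, threshold);
  return List::create(_["state"] = state_to_list(s), _["changed"] = changed);
}

// ---------------------------------------------------------------------------
// Full MCMC loop
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_mcmc(List data, List bases, List init, List hyper, List ctrl) {
  State s = state_from_list(init);
  Pre pre = pre_from_lists(data, bases, hyper);
  const int n_iter = as<int>(ctrl["n_iter"]);
  const int n_burnin = as<int>(ctrl["n_burnin"]);
  const int thin = as<int>(ctrl["thin"]);
  const int L = as<int>(ctrl["leapfrog_steps"]);
  const int adapt_interval = as<int>(ctrl["adapt_interval"]);
  const double lo = as<double>(ctrl["accept_lo"]), hi = as<double>(ctrl["accept_hi"]);
  const bool prune = as<bool>(ctrl["prune"]);
  const double pth = as<double>(ctrl["prune_threshold"]);
  const int prune_start = as<int>(ctrl["prune_start"]);
  const bool init_search = as<bool>(ctrl["init_search"]);
  const bool readd = ctrl.containsElementNamed("readd") ?
    as<bool>(ctrl["readd"]) : false;
  const int kappa_repeats = ctrl.containsElementNamed("kappa_repeats") ?
    as<int>(ctrl["kappa_repeats"]) : 5;
  const int sigma_freeze = ctrl.containsElementNamed("sigma_freeze") ?
    as<int>(ctrl["sigma_freeze"]) : 200;
  double eps_k = as<double>(ctrl["step_size_kappa"]);
  double eps_l0 = as<double>(ctrl["step_size_lambda"]);
  vec eps_l(s.Lambda.n_cols, arma::fill::value(eps_l0));

  const std::vector<std::string> all_blocks;
  std::vector<List> draws;
  arma::imat rank_hist(n_iter, 3);
  std::vector<double> acc_k_hist, acc_l_hist, eps_k_hist, eps_l_hist;
  std::vector<int> prune_events;

  // crude bracketing so the 0.6-0.8 band rule starts near a workable scale
  if (init_search) {
    vec M; mat BM;
    warp_basis(s, pre, M, BM, nullptr);
    for (int it = 0; it < 12; it++) {
      State tmp = s;
      int a = hmc_kappa(tmp, pre, eps_k, 5);
      if (a) { eps_k *= 2.0; } else { eps_k *= 0.5; }
    }
    eps_k *= 0.5;
    for (arma::uword j = 0; j < eps_l.n_elem; j++) {
      for (int it = 0; it < 10; it++) {
        State tmp = s;
        int a = hmc_lambda_col(tmp, pre, BM, j, eps_l(j), 5);
        if (a) { eps_l(j) *= 2.0; } else { eps_l(j) *= 0.5; }
      }
      eps_l(j) *= 0.5;
    }
  }

  int acc_k = 0, try_k = 0;
  vec acc_l(eps_l.n_elem, arma::fill::zeros);
  vec try_l(eps_l.n_elem, arma::fill::zeros);
  // nursery window: columns added during the run are shielded from pruning
  // for `protect` iterations; the initial columns are not shielded (their
  // birth is set before the run so early pruning can clear collapsed ones)
  const int protect = 300;
  std::vector<int> birthL(s.Lambda.n_cols, -protect);
  std::vector<int> birthG1(s.Gamma1.n_cols, -protect);
  std::vector<int> birthG2(s.Gamma2.n_cols, -protect);
  auto tune = [&](double eps, double rate) {
    if (rate < lo) return eps * (rate < 0.2 ? 0.5 : 0.8);
    if (rate > hi) return eps * (rate > 0.95 ? 2.0 : 1.25);
    return eps;
  };
  for (int i = 1; i <= n_iter; i++) {
    if (i % 200 == 0) Rcpp::checkUserInterrupt();
    vec M; mat BM;
    warp_basis(s, pre, M, BM, nullptr);
    gibbs_linear(s, pre, BM, all_blocks);
    // noise variances stay at their initial values for a short window so
    // the mean structure can capture strong features first; otherwise a
    // feature left unexplained in the first few sweeps gets a huge variance,
    // loses its likelihood weight and can stay unfit (variance absorption)
    if (i <= sigma_freeze) {
      gibbs_scales(s, pre, BM, {"shrinkage"});
    } else {
      gibbs_scales(s, pre, BM, all_blocks);
    }

    for (arma::uword j = 0; j < s.Lambda.n_cols; j++) {
      acc_l(j) += hmc_lambda_col(s, pre, BM, j, eps_l(j), L);
      try_l(j) += 1.0;
    }
    // the warp block is the stiffest coordinate (it must traverse a narrow
    // ridge while the noise variances collapse), so it gets several HMC
    // repetitions per sweep
    for (int rep = 0; rep < kappa_repeats; rep++) {
      acc_k += hmc_kappa(s, pre, eps_k, L);
      try_k++;
    }

    // sign-flip group moves: negating a loading column together with its
    // factor row leaves likelihood and prior unchanged (accepted w.p. 1) and
    // mixes the chain over the sign symmetry; post-hoc Procrustes alignment
    // restores a common orientation for the identified columns, while
    // unidentified columns keep random signs instead of spurious coherence
    for (arma::uword j = 0; j < s.Lambda.n_cols; j++)
      if (unif_rand() < 0.5) {
        s.Lambda.col(j) *= -1.0;  // flips both Lambda Xi1 and Lambda Xi2 columns
        s.beta.row(j) *= -1.0;    // counter-flip of the shared factor
      }
    for (arma::uword j = 0; j < s.Gamma1.n_cols; j++)
      if (unif_rand() < 0.5) {
        s.Gamma1.col(j) *= -1.0;
        s.beta1.row(j) *= -1.0;
      }
    for (arma::uword j = 0; j < s.Gamma2.n_cols; j++)
      if (unif_rand() < 0.5) {
        s.Gamma2.col(j) *= -1.0;
        s.beta2.row(j) *= -1.0;
      }

    // per-block step-size tuning toward the acceptance band (burn-in only);
    // each Lambda column adapts on its own acceptance since the shrinkage
    // prior gives the columns very different scales
    if (i <= n_burnin && i % adapt_interval == 0) {
      double rk = try_k > 0 ? (double)acc_k / try_k : 0.0;
      eps_k = tune(eps_k, rk);
      double rl_all = arma::accu(try_l) > 0 ?
        arma::accu(acc_l) / arma::accu(try_l) : 0.0;
      for (arma::uword j = 0; j < eps_l.n_elem; j++)
        if (try_l(j) > 0) eps_l(j) = tune(eps_l(j), acc_l(j) / try_l(j));
      acc_k_hist.push_back(rk); acc_l_hist.push_back(rl_all);
      eps_k_hist.push_back(eps_k); eps_l_hist.push_back(eps_l(0));
      acc_k = 0; try_k = 0;
      acc_l.zeros(); try_l.zeros();
    }

    if (prune && i <= n_burnin && i >= prune_start &&
        unif_rand() < std::exp(-1.0 - 5e-4 * i)) {
      // threshold ramps up to its final value over the first 1000
      // iterations, so early prunes clear only columns that are truly
      // collapsed; recently added columns are shielded for `protect`
      // iterations so a re-added factor has time to fit before it can be
      // deleted again
      double pth_eff = pth * std::min(1.0, (double)i / 1000.0);
      uvec kL = keep_cols(s.Lambda, pth_eff, birthL, i, protect);
      uvec kG1 = keep_cols(s.Gamma1, pth_eff, birthG1, i, protect);
      uvec kG2 = keep_cols(s.Gamma2, pth_eff, birthG2, i, protect);
      bool prL = kL.n_elem < s.Lambda.n_cols;
      bool prG1 = kG1.n_elem < s.Gamma1.n_cols;
      bool prG2 = kG2.n_elem < s.Gamma2.n_cols;
      if (prL || prG1 || prG2) {
        apply_keep(s, kL, kG1, kG2);
        prune_events.push_back(i);
        if (prL) {
          sel_elem(eps_l, kL); sel_elem(acc_l, kL); sel_elem(try_l, kL);
          subset_birth(birthL, kL);
        }
        if (prG1) subset_birth(birthG1, kG1);
        if (prG2) subset_birth(birthG2, kG2);
      }

      // column re-addition: a block with nothing to prune, rank below its
      // upper bound and no column still in the protection window receives
      // one fresh small column, so a factor deleted before its signal
      // emerged has a path back; off by default — under a near-noiseless
      // likelihood every added column finds some residual to fit and the
      // rank ratchets upward instead of adapting
      if (readd && i <= n_burnin - 2 * protect) {
        const int p = pre.X.n_rows;
        auto young = [&](const std::vector<int>& birth) {
          for (int b : birth) if (b > 0 && i - b < protect) return true;
          return false;
        };
        if (!prL && (int)s.Lambda.n_cols < p && !young(birthL)) {
          int r = s.Lambda.n_cols;
          vec nc(p);
          for (int l = 0; l < p; l++) nc(l) = 0.01 * norm_rand();
          s.Lambda.insert_cols(r, nc);
          s.Xi1.insert_rows(r, vec{1.0});
          s.Xi2.insert_rows(r, vec{1.0});
          s.beta.insert_rows(r, mat(1, s.beta.n_cols, arma::fill::zeros));
          vec ph(p);
          for (int l = 0; l < p; l++)
            ph(l) = R::rgamma(pre.nu1, 1.0 / pre.nu1);
          s.phi1.insert_cols(r, ph);
          s.delta1.insert_rows(r, vec{1.0});
          birthL.push_back(i);
          eps_l.insert_rows(r, vec{arma::mean(eps_l)});
          acc_l.insert_rows(r, vec{0.0});
          try_l.insert_rows(r, vec{0.0});
        }
        auto add_gamma = [&](mat& G, mat& be, mat& ph, vec& de,
                             std::vector<int>& birth) {
          int c = G.n_cols;
          vec nc(p);
          for (int l = 0; l < p; l++) nc(l) = 0.01 * norm_rand();
          G.insert_cols(c, nc);
          be.insert_rows(c, mat(1, be.n_cols, arma::fill::zeros));
          vec phv(p);
          for (int l = 0; l < p; l++)
            phv(l) = R::rgamma(pre.nu1, 1.0 / pre.nu1);
          ph.insert_cols(c, phv);
          de.insert_rows(c, vec{1.0});
          birth.push_back(i);
        };
        if (!prG1 && (int)s.Gamma1.n_cols < p && !young(birthG1))
          add_gamma(s.Gamma1, s.beta1, s.phi11, s.delta11, birthG1);
        if (!prG2 && (int)s.Gamma2.n_cols < p && !young(birthG2))
          add_gamma(s.Gamma2, s.beta2, s.phi12, s.delta12, birthG2);
      }
    }

    rank_hist(i - 1, 0) = s.Lambda.n_cols;
    rank_hist(i - 1, 1) = s.Gamma1.n_cols;
    rank_hist(i - 1, 2) = s.Gamma2.n_cols;

    if (!s.Lambda.is_finite() || !s.kappa.is_finite() || !s.beta.is_finite())
      stop("sampler diverged (non-finite state) at iteration %d", i);

    if (i > n_burnin && ((i - n_burnin) % thin == 0)) {
      draws.push_back(List::create(
        _["Lambda"] = s.Lambda, _["Xi1"] = s.Xi1, _["Xi2"] = s.Xi2,
        _["beta"] = s.beta, _["Gamma1"] = s.Gamma1, _["Gamma2"] = s.Gamma2,
        _["beta1"] = s.beta1, _["beta2"] = s.beta2,
        _["kappa"] = s.kappa, _["sig1sq"] = s.sig1, _["sig2sq"] = s.sig2));
    }
  }

  List dr(draws.size());
  for (size_t i = 0; i < draws.size(); i++) dr[i] = draws[i];
  return List::create(
    _["draws"] = dr,
    _["final_state"] = state_to_list(s),
    _["rank_history"] = rank_hist,
    _["accept_kappa"] = acc_k_hist, _["accept_lambda"] = acc_l_hist,
    _["step_kappa"] = eps_k_hist, _["step_lambda"] = eps_l_hist,
    _["prune_iterations"] = prune_events);
}
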