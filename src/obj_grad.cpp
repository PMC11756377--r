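// Log-posterior and analytic gradient for the heterogeneous attributed
// multilayer mixed-membership model.
//
// Latent state Theta = (U, V, W, H) is passed packed as a single vector:
//   U (N x K, column-major), V (N x K, only when directed), W (L blocks of
//   K x K, column-major), H (K x Pstar, column-major).  Pstar expands each
//   categorical attribute into Z columns, every other attribute into one.
//
// Expected values: lambda_{ijl} = f(U_i)' g_l(W_l) f(V_j) with f = row
// softmax and g_l the per-family link (logistic / exp / identity) applied
// entrywise to W_l; pi_{ix} = mbar_i' g_x(H-block) with mbar = (f(U)+f(V))/2
// (categorical blocks are row-softmaxed across categories).
//
// All likelihood sums run over mask == 1 entries only.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

// numerically stable row softmax
static mat softmax_rows_cpp(const mat& M) {
  mat S = M;
  S.each_col() -= max(M, 1);
  S = exp(S);
  S.each_col() /= sum(S, 1);
  return S;
}

// [[Rcpp::export(name = ".obj_grad_cpp")]]
Rcpp::List obj_grad_cpp(const arma::vec& theta,
                        int N, int K, bool directed,
                        const arma::cube& A, const arma::ucube& M,
                        const arma::ivec& layer_fam, const arma::vec& layer_s2,
                        const arma::mat& X, const arma::umat& XM,
                        const arma::ivec& attr_fam, const arma::ivec& attr_Z,
                        const arma::vec& attr_s2,
                        const arma::vec& prior_mean, const arma::vec& prior_var,
                        bool want_grad) {
  const int L = A.n_slices;
  const int P = X.n_cols;
  int Pstar = 0;
  for (int p = 0; p < P; ++p) Pstar += (attr_fam[p] == 0) ? attr_Z[p] : 1;

  // unpack
  size_t off = 0;
  const mat U(theta.memptr() + off, N, K);           off += (size_t)N * K;
  mat Vm;
  if (directed) { Vm = mat(theta.memptr() + off, N, K); off += (size_t)N * K; }
  const size_t w_off = off;
  std::vector<mat> W(L);
  for (int l = 0; l < L; ++l) { W[l] = mat(theta.memptr() + off, K, K); off += (size_t)K * K; }
  const size_t h_off = off;
  mat H;
  if (Pstar > 0) H = mat(theta.memptr() + h_off, K, Pstar);

  const mat mU = softmax_rows_cpp(U);
  const mat mV = directed ? softmax_rows_cpp(Vm) : mU;

  double value = 0.0;
  mat SU(N, K, fill::zeros), SV(N, K, fill::zeros);   // dL/dm accumulators
  vec grad(theta.n_elem, fill::zeros);

  // ---- network layers ----
  for (int l = 0; l < L; ++l) {
    mat G(K, K), Gp(K, K);
    const int fam = layer_fam[l];
    if (fam == 0) {            // bernoulli: logistic
      G = 1.0 / (1.0 + exp(-W[l]));
      Gp = G % (1.0 - G);
    } else if (fam == 1) {     // poisson: exp
      G = exp(W[l]);
      Gp = G;
    } else {                   // gaussian: identity
      G = W[l];
      Gp.ones();
    }

    const mat Lam = mU * G * mV.t();
    mat D(N, N, fill::zeros);
    const double s2 = layer_s2[l];
    for (int j = 0; j < N; ++j) {
      for (int i = 0; i < N; ++i) {
        if (!M(i, j, l)) continue;
        const double a = A(i, j, l), lam = Lam(i, j);
        if (fam == 0) {
          value += a * std::log(lam) + (1.0 - a) * std::log1p(-lam);
          D(i, j) = a / lam - (1.0 - a) / (1.0 - lam);
        } else if (fam == 1) {
          value += a * std::log(lam) - lam - std::lgamma(a + 1.0);
          D(i, j) = a / lam - 1.0;
        } else {
          const double r = a - lam;
          value += -0.5 * (LOG2PI + std::log(s2)) - r * r / (2.0 * s2);
          D(i, j) = r / s2;
        }
      }
    }
    if (want_grad) {
      const mat gW = (mU.t() * D * mV) % Gp;
      grad.subvec(w_off + (size_t)l * K * K, w_off + (size_t)(l + 1) * K * K - 1) =
        vectorise(gW);
      SU += D * (mV * G.t());
      SV += D.t() * (mU * G);
    }
  }

  // ---- node attributes ----
  mat Smbar(N, K, fill::zeros);
  int col0 = 0;
  for (int p = 0; p < P; ++p) {
    const mat mbar = directed ? mat(0.5 * (mU + mV)) : mU;
    const int fam = attr_fam[p];
    if (fam == 0) {            // categorical, Z columns, row softmax
      const int Z = attr_Z[p];
      const mat B = H.cols(col0, col0 + Z - 1);
      const mat C = softmax_rows_cpp(B);
      const mat Pi = mbar * C;                    // N x Z
      mat gradC(K, Z, fill::zeros);
      for (int i = 0; i < N; ++i) {
        if (!XM(i, p)) continue;
        const int z = (int)X(i, p);               // 0-based label
        const double pi = Pi(i, z);
        value += std::log(pi);
        if (want_grad) {
          gradC.col(z) += mbar.row(i).t() / pi;
          Smbar.row(i) += C.col(z).t() / pi;
        }
      }
      if (want_grad) {
        mat gB(K, Z);
        for (int k = 0; k < K; ++k) {
          const double dotkc = dot(gradC.row(k), C.row(k));
          gB.row(k) = C.row(k) % (gradC.row(k) - dotkc);
        }
        grad.subvec(h_off + (size_t)col0 * K, h_off + (size_t)(col0 + Z) * K - 1) =
          vectorise(gB);
      }
      col0 += Z;
    } else {                   // poisson or gaussian, single column
      const vec h = H.col(col0);
      const vec c = (fam == 1) ? vec(exp(h)) : h;
      const vec Pi = mbar * c;
      vec d(N, fill::zeros);
      const double s2 = attr_s2[p];
      for (int i = 0; i < N; ++i) {
        if (!XM(i, p)) continue;
        const double x = X(i, p), pi = Pi(i);
        if (fam == 1) {
          value += x * std::log(pi) - pi - std::lgamma(x + 1.0);
          d(i) = x / pi - 1.0;
        } else {
          const double r = x - pi;
          value += -0.5 * (LOG2PI + std::log(s2)) - r * r / (2.0 * s2);
          d(i) = r / s2;
        }
      }
      if (want_grad) {
        vec gh = mbar.t() * d;
        if (fam == 1) gh %= c;
        grad.subvec(h_off + (size_t)col0 * K, h_off + (size_t)(col0 + 1) * K - 1) = gh;
        Smbar += d * c.t();
      }
      col0 += 1;
    }
  }

  if (want_grad) {
    if (directed) { SU += 0.5 * Smbar; SV += 0.5 * Smbar; }
    else          { SU += SV + Smbar; }   // mV and mbar both alias mU

    // back-propagate through the row softmax
    mat gU(N, K);
    for (int i = 0; i < N; ++i) {
      const double doti = dot(SU.row(i), mU.row(i));
      gU.row(i) = mU.row(i) % (SU.row(i) - doti);
    }
    grad.subvec(0, (size_t)N * K - 1) = vectorise(gU);
    if (directed) {
      mat gV(N, K);
      for (int i = 0; i < N; ++i) {
        const double doti = dot(SV.row(i), mV.row(i));
        gV.row(i) = mV.row(i) % (SV.row(i) - doti);
      }
      grad.subvec((size_t)N * K, (size_t)2 * N * K - 1) = vectorise(gV);
    }
  }

  // ---- Gaussian priors over every packed entry ----
  const vec resid = theta - prior_mean;
  value += accu(-0.5 * (LOG2PI + log(prior_var)) - square(resid) / (2.0 * prior_var));
  if (want_grad) grad -= resid / prior_var;

  if (want_grad)
    return Rcpp::List::create(Rcpp::Named("value") = value,
                              Rcpp::Named("grad") = grad);
  return Rcpp::List::create(Rcpp::Named("value") = value);
}
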