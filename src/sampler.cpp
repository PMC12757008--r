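// Blocked Gibbs sampler for the hierarchical bivariate VAR(1) with person
// random intercepts, a moderated contemporaneous disturbance correlation
// (inverse Fisher-z link on standardized exercise identity) and
// full-information handling of missing responses.
//
// Update scheme per iteration:
//   1. latent missing responses      : bivariate-normal full conditionals
//   2. regression coefficients delta : multivariate normal with the random
//      effects integrated out (partially collapsed block update)
//   3. random intercepts m           : conjugate bivariate normals
//   4. beta (4), sigma (2), alpha (2): stepping-out slice sampling on the
//      full conditional (likelihood over all rows + prior)
//   5. tau (2)                       : slice sampling (random-effect density
//                                      + half-normal prior)
//
// All randomness is drawn through R's RNG, so set.seed() in R makes a chain
// byte-reproducible.  Burst-first days either contribute the stationary
// marginal (mode 0) or are conditioned on (mode 1).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const double LOG2PI = std::log(2.0 * M_PI);

struct PersonCov {
  vec rho;
  mat Einv;     // np x 3: (11, 12, 22) entries of E^{-1}
  vec logdetE;
  mat Sinv;     // np x 3
  vec logdetS;
  mat Smat;     // np x 3
  bool ok;
  bool nonstationary;
};

inline double spec_radius2(const mat22 &B) {
  double tr = B(0, 0) + B(1, 1);
  double det = B(0, 0) * B(1, 1) - B(0, 1) * B(1, 0);
  double disc = tr * tr - 4.0 * det;
  if (disc >= 0.0) {
    double s = std::sqrt(disc);
    return std::max(std::abs((tr + s) / 2.0), std::abs((tr - s) / 2.0));
  }
  return std::sqrt(std::max(det, 0.0));
}

PersonCov person_cov(const mat22 &B, double sL, double sP,
                     double a0, double a1, const vec &ez) {
  PersonCov pc;
  pc.ok = false;
  pc.nonstationary = false;
  if (sL <= 0.0 || sP <= 0.0) return pc;
  if (spec_radius2(B) >= 1.0 - 1e-10) {
    pc.nonstationary = true;
    return pc;
  }
  const uword np = ez.n_elem;
  pc.rho = tanh(a0 + a1 * ez);
  pc.Einv.set_size(np, 3);
  pc.logdetE.set_size(np);
  pc.Sinv.set_size(np, 3);
  pc.logdetS.set_size(np);
  pc.Smat.set_size(np, 3);

  // vec(S) = (I4 - B kron B)^{-1} vec(E), column-major vec convention.
  mat44 K;
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j)
      for (int k = 0; k < 2; ++k)
        for (int l = 0; l < 2; ++l)
          K(i + 2 * j, k + 2 * l) = B(i, k) * B(j, l);
  mat44 A = eye(4, 4) - K;
  mat44 Ainv;
  if (!inv(Ainv, A)) return pc;
  vec4 e0 = {sL * sL, 0.0, 0.0, sP * sP};
  vec4 e1 = {0.0, sL * sP, sL * sP, 0.0};
  vec4 g0 = Ainv * e0;
  vec4 g1 = Ainv * e1;

  for (uword i = 0; i < np; ++i) {
    double r = pc.rho(i);
    double e11 = sL * sL, e22 = sP * sP, e12 = sL * sP * r;
    double detE = e11 * e22 - e12 * e12;
    if (detE <= 0.0) return pc;
    pc.Einv(i, 0) = e22 / detE;
    pc.Einv(i, 1) = -e12 / detE;
    pc.Einv(i, 2) = e11 / detE;
    pc.logdetE(i) = std::log(detE);
    double s11 = g0(0) + r * g1(0);
    double s12 = g0(1) + r * g1(1);
    double s22 = g0(3) + r * g1(3);
    double detS = s11 * s22 - s12 * s12;
    if (s11 <= 0.0 || s22 <= 0.0 || detS <= 0.0) return pc;
    pc.Smat(i, 0) = s11; pc.Smat(i, 1) = s12; pc.Smat(i, 2) = s22;
    pc.Sinv(i, 0) = s22 / detS;
    pc.Sinv(i, 1) = -s12 / detS;
    pc.Sinv(i, 2) = s11 / detS;
    pc.logdetS(i) = std::log(detS);
  }
  pc.ok = true;
  return pc;
}

double loglik_rows(const mat &W, const ivec &person, const ivec &prevrow,
                   const PersonCov &pc, const mat22 &B, int mode) {
  double ll = 0.0;
  const uword N = W.n_rows;
  for (uword r = 0; r < N; ++r) {
    int i = person(r);
    if (prevrow(r) < 0) {
      if (mode == 1) continue;
      double u1 = W(r, 0), u2 = W(r, 1);
      double q = pc.Sinv(i, 0) * u1 * u1 + 2.0 * pc.Sinv(i, 1) * u1 * u2 +
                 pc.Sinv(i, 2) * u2 * u2;
      ll += -LOG2PI - 0.5 * pc.logdetS(i) - 0.5 * q;
    } else {
      uword pr = (uword)prevrow(r);
      double u1 = W(r, 0) - (B(0, 0) * W(pr, 0) + B(0, 1) * W(pr, 1));
      double u2 = W(r, 1) - (B(1, 0) * W(pr, 0) + B(1, 1) * W(pr, 1));
      double q = pc.Einv(i, 0) * u1 * u1 + 2.0 * pc.Einv(i, 1) * u1 * u2 +
                 pc.Einv(i, 2) * u2 * u2;
      ll += -LOG2PI - 0.5 * pc.logdetE(i) - 0.5 * q;
    }
  }
  return ll;
}

// Cholesky with a ridge retry; degenerate conditionals can arise on
// near-empty datasets where a block is informed only by the weak prior.
inline mat chol_safe(mat A, const char *what) {
  A = symmatu(A);
  mat R;
  if (chol(R, A)) return R;
  double ridge = 1e-10 * std::max(A.diag().max(), 1.0);
  for (int k = 0; k < 8; ++k) {
    if (chol(R, A + ridge * eye(size(A)))) return R;
    ridge *= 100.0;
  }
  Rcpp::stop(std::string("conditional precision not positive definite (") +
             what + ")");
}

inline double half_normal_lp(double x, double scale) {
  if (x < 0.0) return -datum::inf;
  return -0.5 * (x / scale) * (x / scale) - std::log(scale);
}

// Stepping-out slice sampler (Neal 2003) on [lo, hi].
template <typename F>
double slice_sample(F logf, double x0, double w, double lo, double hi) {
  double f0 = logf(x0);
  if (!std::isfinite(f0)) return x0;  // defensive: stay put
  double logy = f0 - R::exp_rand();
  double u = R::unif_rand() * w;
  double L = x0 - u;
  double Rr = L + w;
  for (int s = 0; s < 50 && L > lo && logf(L) > logy; ++s) L -= w;
  for (int s = 0; s < 50 && Rr < hi && logf(Rr) > logy; ++s) Rr += w;
  if (L < lo) L = lo;
  if (Rr > hi) Rr = hi;
  for (int s = 0; s < 100; ++s) {
    double x1 = L + R::unif_rand() * (Rr - L);
    if (logf(x1) > logy) return x1;
    if (x1 < x0) L = x1; else Rr = x1;
  }
  return x0;
}

}  // namespace

// Likelihood of the model given residuals W = Y - X delta - m[person]
// (reference hook for cross-checking the R implementation).
// [[Rcpp::export(name = ".bvb_loglik_resid")]]
double bvb_loglik_resid(const arma::mat &W, const arma::ivec &person,
                        const arma::ivec &prevrow, const arma::vec &ez,
                        const arma::mat &beta, double sigma_L, double sigma_P,
                        double alpha0, double alpha1, int mode) {
  mat22 B;
  B(0, 0) = beta(0, 0); B(0, 1) = beta(0, 1);
  B(1, 0) = beta(1, 0); B(1, 1) = beta(1, 1);
  PersonCov pc = person_cov(B, sigma_L, sigma_P, alpha0, alpha1, ez);
  if (!pc.ok) return -datum::inf;
  return loglik_rows(W, person, prevrow, pc, B, mode);
}

// [[Rcpp::export(name = ".bvb_gibbs")]]
Rcpp::List bvb_gibbs(arma::mat Y,            // N x 2, missings pre-filled
                     const arma::mat &X,     // N x p standardized covariates
                     const arma::ivec &person,   // 0-based person index
                     const arma::ivec &prevrow,  // 0-based predecessor row, -1
                     const arma::vec &ez,        // np standardized moderator
                     const arma::uvec &miss_rows,    // rows with any missing
                     const arma::ivec &miss_which,   // 1 = L, 2 = P, 3 = both
                     const Rcpp::List &prior,
                     int mode, int n_warmup, int n_save,
                     const Rcpp::List &init) {
  const uword N = Y.n_rows;
  const uword p = X.n_cols;
  const uword np = ez.n_elem;
  const double sigma_scale = prior["sigma_scale"];
  const double tau_scale = prior["tau_scale"];
  const double coef_sd = prior["coef_sd"];
  const double coef_prec = std::isfinite(coef_sd) ? 1.0 / (coef_sd * coef_sd) : 0.0;

  // ---- state ----
  vec delta = Rcpp::as<vec>(init["delta"]);       // length 2p (L block, P block)
  mat m = Rcpp::as<mat>(init["m"]);               // np x 2
  mat22 B;
  {
    vec b0 = Rcpp::as<vec>(init["beta"]);         // (LL, LP, PL, PP)
    B(0, 0) = b0(0); B(0, 1) = b0(1); B(1, 0) = b0(2); B(1, 1) = b0(3);
  }
  double sL = init["sigma_L"], sP = init["sigma_P"];
  double tL = init["tau_L"], tP = init["tau_P"];
  double a0 = init["alpha0"], a1 = init["alpha1"];

  // ---- data-fixed per-person accumulators for the collapsed delta update ----
  // first-day rows: F = sum x x', sf = sum x, nf = count
  // transitions:    Ccc = sum xc xc', Ccl = sum xc xl', Cll = sum xl xl',
  //                 sc = sum xc, sl = sum xl, nt = count
  cube Fc(p, p, np, fill::zeros), Ccc(p, p, np, fill::zeros),
       Ccl(p, p, np, fill::zeros), Cll(p, p, np, fill::zeros);
  mat sf(p, np, fill::zeros), sc(p, np, fill::zeros), sl(p, np, fill::zeros);
  vec nf(np, fill::zeros), nt(np, fill::zeros);
  ivec nextrow(N);
  nextrow.fill(-1);
  for (uword r = 0; r < N; ++r) {
    int i = person(r);
    rowvec x = X.row(r);
    if (prevrow(r) < 0) {
      if (mode == 0) {
        Fc.slice(i) += x.t() * x;
        sf.col(i) += x.t();
        nf(i) += 1.0;
      }
    } else {
      uword pr = (uword)prevrow(r);
      rowvec xl = X.row(pr);
      Ccc.slice(i) += x.t() * x;
      Ccl.slice(i) += x.t() * xl;
      Cll.slice(i) += xl.t() * xl;
      sc.col(i) += x.t();
      sl.col(i) += xl.t();
      nt(i) += 1.0;
      nextrow(pr) = (int)r;
    }
  }

  PersonCov pc = person_cov(B, sL, sP, a0, a1, ez);
  if (!pc.ok) Rcpp::stop("initial parameter values are not stationary");

  mat mu(N, 2);
  auto update_mu = [&]() {
    mu.col(0) = X * delta.subvec(0, p - 1);
    mu.col(1) = X * delta.subvec(p, 2 * p - 1);
  };
  update_mu();

  mat W(N, 2);
  auto update_W = [&]() {
    for (uword r = 0; r < N; ++r) {
      int i = person(r);
      W(r, 0) = Y(r, 0) - mu(r, 0) - m(i, 0);
      W(r, 1) = Y(r, 1) - mu(r, 1) - m(i, 1);
    }
  };
  update_W();

  long nonstat_hits = 0;
  const uword K = 2 * p + 4 + 2 + 2 + 2 + 2 * np;
  mat draws(n_save, K);
  // one recorded column per missing scalar (two for a fully missing day)
  std::vector<uword> val_row;
  std::vector<uword> val_comp;
  for (uword k = 0; k < miss_rows.n_elem; ++k) {
    if (miss_which(k) == 1 || miss_which(k) == 3) {
      val_row.push_back(miss_rows(k));
      val_comp.push_back(0);
    }
    if (miss_which(k) == 2 || miss_which(k) == 3) {
      val_row.push_back(miss_rows(k));
      val_comp.push_back(1);
    }
  }
  mat miss_draws(n_save, val_row.size());

  const int n_total = n_warmup + n_save;
  for (int iter = 0; iter < n_total; ++iter) {
    if (iter % 256 == 0) Rcpp::checkUserInterrupt();

    // ---------- 1. impute missing responses ----------
    for (uword k = 0; k < miss_rows.n_elem; ++k) {
      uword r = miss_rows(k);
      int i = person(r);
      mat22 Q(fill::zeros);
      vec2 l(fill::zeros);
      bool have_term = false;
      if (prevrow(r) < 0) {
        if (mode == 0) {
          mat22 Qs = {{pc.Sinv(i, 0), pc.Sinv(i, 1)},
                      {pc.Sinv(i, 1), pc.Sinv(i, 2)}};
          vec2 c1 = {mu(r, 0) + m(i, 0), mu(r, 1) + m(i, 1)};
          Q += Qs;
          l += Qs * c1;
          have_term = true;
        }
      } else {
        uword pr = (uword)prevrow(r);
        mat22 Qe = {{pc.Einv(i, 0), pc.Einv(i, 1)},
                    {pc.Einv(i, 1), pc.Einv(i, 2)}};
        vec2 wprev = {Y(pr, 0) - mu(pr, 0) - m(i, 0),
                      Y(pr, 1) - mu(pr, 1) - m(i, 1)};
        vec2 c1 = {mu(r, 0) + m(i, 0) + B(0, 0) * wprev(0) + B(0, 1) * wprev(1),
                   mu(r, 1) + m(i, 1) + B(1, 0) * wprev(0) + B(1, 1) * wprev(1)};
        Q += Qe;
        l += Qe * c1;
        have_term = true;
      }
      if (nextrow(r) >= 0) {
        uword nx = (uword)nextrow(r);
        mat22 Qe = {{pc.Einv(i, 0), pc.Einv(i, 1)},
                    {pc.Einv(i, 1), pc.Einv(i, 2)}};
        // residual_{r+1} = (y_nx - mu_nx - m) - B (y_r - mu_r - m)
        vec2 g = {Y(nx, 0) - mu(nx, 0) - m(i, 0) +
                      B(0, 0) * (mu(r, 0) + m(i, 0)) + B(0, 1) * (mu(r, 1) + m(i, 1)),
                  Y(nx, 1) - mu(nx, 1) - m(i, 1) +
                      B(1, 0) * (mu(r, 0) + m(i, 0)) + B(1, 1) * (mu(r, 1) + m(i, 1))};
        Q += B.t() * Qe * B;
        l += B.t() * (Qe * g);
        have_term = true;
      }
      if (!have_term || det(Q) < 1e-300) {
        // isolated day (can only happen in the conditioning variant):
        // fall back to the stationary marginal for imputation
        mat22 Qs = {{pc.Sinv(i, 0), pc.Sinv(i, 1)},
                    {pc.Sinv(i, 1), pc.Sinv(i, 2)}};
        vec2 c1 = {mu(r, 0) + m(i, 0), mu(r, 1) + m(i, 1)};
        Q = Qs;
        l = Qs * c1;
      }
      vec2 mean = solve(Q, l);
      int which = miss_which(k);
      if (which == 3) {
        mat Rq = chol_safe(Q, "missing responses");
        vec2 z = {R::norm_rand(), R::norm_rand()};
        vec2 y = mean + solve(trimatu(Rq), z);
        Y(r, 0) = y(0);
        Y(r, 1) = y(1);
      } else {
        int j = which - 1;       // missing component
        int o = 1 - j;           // observed component
        double cmean = mean(j) - (Q(j, o) / Q(j, j)) * (Y(r, o) - mean(o));
        Y(r, j) = cmean + R::norm_rand() / std::sqrt(Q(j, j));
      }
    }

    // ---------- 2. collapsed delta update ----------
    {
      vec w11(np), w12(np), w22(np), wS11(np), wS12(np), wS22(np);
      for (uword i = 0; i < np; ++i) {
        w11(i) = pc.Einv(i, 0); w12(i) = pc.Einv(i, 1); w22(i) = pc.Einv(i, 2);
        if (mode == 0) {
          wS11(i) = pc.Sinv(i, 0); wS12(i) = pc.Sinv(i, 1); wS22(i) = pc.Sinv(i, 2);
        } else {
          wS11(i) = wS12(i) = wS22(i) = 0.0;
        }
      }
      auto wsum = [&](const cube &Cb, const vec &w) {
        mat out(p, p, fill::zeros);
        for (uword i = 0; i < np; ++i)
          if (w(i) != 0.0 && (nt(i) > 0 || nf(i) > 0)) out += w(i) * Cb.slice(i);
        return out;
      };
      mat F11 = wsum(Fc, wS11), F12 = wsum(Fc, wS12), F22 = wsum(Fc, wS22);
      mat A11 = wsum(Ccc, w11), B11m = wsum(Ccl, w11), C11 = wsum(Cll, w11);
      mat A12 = wsum(Ccc, w12), B12m = wsum(Ccl, w12), C12 = wsum(Cll, w12);
      mat A22 = wsum(Ccc, w22), B22m = wsum(Ccl, w22), C22 = wsum(Cll, w22);

      double b11 = B(0, 0), b12 = B(0, 1), b21 = B(1, 0), b22 = B(1, 1);
      mat LL = F11 + A11 - b11 * (B11m + B11m.t()) + b11 * b11 * C11
               - b21 * (B12m + B12m.t() - 2.0 * b11 * C12) + b21 * b21 * C22;
      mat PP = F22 + b12 * b12 * C11
               - b12 * (B12m + B12m.t() - 2.0 * b22 * C12)
               + A22 - b22 * (B22m + B22m.t()) + b22 * b22 * C22;
      mat LP = F12 - b12 * (B11m - b11 * C11) + A12 - b22 * B12m - b11 * B12m.t()
               + (b11 * b22 + b12 * b21) * C12 - b21 * (B22m.t() - b22 * C22);

      mat H(2 * p, 2 * p);
      H.submat(0, 0, p - 1, p - 1) = LL;
      H.submat(0, p, p - 1, 2 * p - 1) = LP;
      H.submat(p, 0, 2 * p - 1, p - 1) = LP.t();
      H.submat(p, p, 2 * p - 1, 2 * p - 1) = PP;
      H.diag() += coef_prec;

      // RHS over rows and per-person v = sum A' Omega d
      vec bvec(2 * p, fill::zeros);
      mat vper(2, np, fill::zeros);
      mat22 ImB = eye(2, 2) - B;
      for (uword r = 0; r < N; ++r) {
        int i = person(r);
        if (prevrow(r) < 0) {
          if (mode == 1) continue;
          vec2 d = {Y(r, 0), Y(r, 1)};  // m is marginalized, not subtracted
          vec2 e = {pc.Sinv(i, 0) * d(0) + pc.Sinv(i, 1) * d(1),
                    pc.Sinv(i, 1) * d(0) + pc.Sinv(i, 2) * d(1)};
          bvec.subvec(0, p - 1) += e(0) * X.row(r).t();
          bvec.subvec(p, 2 * p - 1) += e(1) * X.row(r).t();
          vper.col(i) += e;
        } else {
          uword pr = (uword)prevrow(r);
          vec2 d = {Y(r, 0) - (B(0, 0) * Y(pr, 0) + B(0, 1) * Y(pr, 1)),
                    Y(r, 1) - (B(1, 0) * Y(pr, 0) + B(1, 1) * Y(pr, 1))};
          vec2 e = {pc.Einv(i, 0) * d(0) + pc.Einv(i, 1) * d(1),
                    pc.Einv(i, 1) * d(0) + pc.Einv(i, 2) * d(1)};
          bvec.subvec(0, p - 1) +=
              e(0) * X.row(r).t() - (e(0) * b11 + e(1) * b21) * X.row(pr).t();
          bvec.subvec(p, 2 * p - 1) +=
              e(1) * X.row(r).t() - (e(0) * b12 + e(1) * b22) * X.row(pr).t();
          vper.col(i) += ImB.t() * e;
        }
      }

      // subtract the marginalized random-effect contribution
      for (uword i = 0; i < np; ++i) {
        mat22 Os = {{pc.Sinv(i, 0), pc.Sinv(i, 1)}, {pc.Sinv(i, 1), pc.Sinv(i, 2)}};
        mat22 Oe = {{pc.Einv(i, 0), pc.Einv(i, 1)}, {pc.Einv(i, 1), pc.Einv(i, 2)}};
        mat22 OA = Oe * ImB;
        mat22 Pm = nt(i) * (ImB.t() * OA);
        if (mode == 0) Pm += nf(i) * Os;
        Pm(0, 0) += 1.0 / (tL * tL);
        Pm(1, 1) += 1.0 / (tP * tP);

        mat U(2 * p, 2, fill::zeros);
        if (mode == 0 && nf(i) > 0) {
          U.submat(0, 0, p - 1, 0) += Os(0, 0) * sf.col(i);
          U.submat(0, 1, p - 1, 1) += Os(0, 1) * sf.col(i);
          U.submat(p, 0, 2 * p - 1, 0) += Os(1, 0) * sf.col(i);
          U.submat(p, 1, 2 * p - 1, 1) += Os(1, 1) * sf.col(i);
        }
        if (nt(i) > 0) {
          vec Sa = sc.col(i) - b11 * sl.col(i);
          vec Sc = -b21 * sl.col(i);
          vec Sb = -b12 * sl.col(i);
          vec Sd = sc.col(i) - b22 * sl.col(i);
          U.submat(0, 0, p - 1, 0) += Sa * OA(0, 0) + Sc * OA(1, 0);
          U.submat(0, 1, p - 1, 1) += Sa * OA(0, 1) + Sc * OA(1, 1);
          U.submat(p, 0, 2 * p - 1, 0) += Sb * OA(0, 0) + Sd * OA(1, 0);
          U.submat(p, 1, 2 * p - 1, 1) += Sb * OA(0, 1) + Sd * OA(1, 1);
        }
        mat22 Pinv;
        if (!inv_sympd(Pinv, symmatu(Pm))) {
          Pinv = inv(symmatu(Pm) + 1e-10 * Pm.diag().max() * eye(2, 2));
        }
        H -= U * Pinv * U.t();
        bvec -= U * (Pinv * vper.col(i));
      }

      mat R = chol_safe(H, "regression coefficients");  // H = R'R
      vec mean = solve(trimatu(R), solve(trimatl(R.t()), bvec));
      vec z(2 * p);
      for (uword j = 0; j < 2 * p; ++j) z(j) = R::norm_rand();
      delta = mean + solve(trimatu(R), z);
      update_mu();
    }

    // ---------- 3. random intercepts ----------
    {
      mat22 ImB = eye(2, 2) - B;
      mat racc(2, np, fill::zeros);
      for (uword r = 0; r < N; ++r) {
        int i = person(r);
        if (prevrow(r) < 0) {
          if (mode == 1) continue;
          vec2 d = {Y(r, 0) - mu(r, 0), Y(r, 1) - mu(r, 1)};
          racc.col(i) += vec2{pc.Sinv(i, 0) * d(0) + pc.Sinv(i, 1) * d(1),
                              pc.Sinv(i, 1) * d(0) + pc.Sinv(i, 2) * d(1)};
        } else {
          uword pr = (uword)prevrow(r);
          vec2 yp = {Y(pr, 0) - mu(pr, 0), Y(pr, 1) - mu(pr, 1)};
          vec2 d = {Y(r, 0) - mu(r, 0) - (B(0, 0) * yp(0) + B(0, 1) * yp(1)),
                    Y(r, 1) - mu(r, 1) - (B(1, 0) * yp(0) + B(1, 1) * yp(1))};
          vec2 e = {pc.Einv(i, 0) * d(0) + pc.Einv(i, 1) * d(1),
                    pc.Einv(i, 1) * d(0) + pc.Einv(i, 2) * d(1)};
          racc.col(i) += ImB.t() * e;
        }
      }
      for (uword i = 0; i < np; ++i) {
        mat22 Os = {{pc.Sinv(i, 0), pc.Sinv(i, 1)}, {pc.Sinv(i, 1), pc.Sinv(i, 2)}};
        mat22 Oe = {{pc.Einv(i, 0), pc.Einv(i, 1)}, {pc.Einv(i, 1), pc.Einv(i, 2)}};
        mat22 Pm = nt(i) * (ImB.t() * (Oe * ImB));
        if (mode == 0) Pm += nf(i) * Os;
        Pm(0, 0) += 1.0 / (tL * tL);
        Pm(1, 1) += 1.0 / (tP * tP);
        mat Rm = chol_safe(Pm, "random intercepts");
        vec2 mean = solve(trimatu(Rm), solve(trimatl(Rm.t()), racc.col(i)));
        vec2 z = {R::norm_rand(), R::norm_rand()};
        vec2 mi = mean + solve(trimatu(Rm), z);
        m(i, 0) = mi(0);
        m(i, 1) = mi(1);
      }
      update_W();
    }

    // ---------- 4. slice updates for beta, sigma, alpha ----------
    {
      auto cond_lp = [&](const mat22 &Bc, double sLc, double sPc,
                         double a0c, double a1c) {
        PersonCov pcc = person_cov(Bc, sLc, sPc, a0c, a1c, ez);
        if (!pcc.ok) {
          if (pcc.nonstationary) ++nonstat_hits;
          return -datum::inf;
        }
        return loglik_rows(W, person, prevrow, pcc, Bc, mode);
      };

      for (int bi = 0; bi < 4; ++bi) {
        int rI = bi / 2, cI = bi % 2;
        double cur = B(rI, cI);
        double nb = slice_sample(
            [&](double x) {
              mat22 Bc = B;
              Bc(rI, cI) = x;
              return cond_lp(Bc, sL, sP, a0, a1);
            },
            cur, 0.15, -1.0 + 1e-9, 1.0 - 1e-9);
        B(rI, cI) = nb;
      }
      sL = slice_sample(
          [&](double x) {
            return cond_lp(B, x, sP, a0, a1) + half_normal_lp(x, sigma_scale);
          },
          sL, 0.2, 1e-8, datum::inf);
      sP = slice_sample(
          [&](double x) {
            return cond_lp(B, sL, x, a0, a1) + half_normal_lp(x, sigma_scale);
          },
          sP, 0.2, 1e-8, datum::inf);
      auto alpha_prior = [&](double x) {
        return coef_prec > 0.0 ? -0.5 * coef_prec * x * x : 0.0;
      };
      a0 = slice_sample(
          [&](double x) { return cond_lp(B, sL, sP, x, a1) + alpha_prior(x); },
          a0, 0.2, -datum::inf, datum::inf);
      a1 = slice_sample(
          [&](double x) { return cond_lp(B, sL, sP, a0, x) + alpha_prior(x); },
          a1, 0.2, -datum::inf, datum::inf);
      pc = person_cov(B, sL, sP, a0, a1, ez);
      if (!pc.ok) Rcpp::stop("internal error: accepted non-stationary state");
    }

    // ---------- 5. tau ----------
    {
      double ssL = dot(m.col(0), m.col(0));
      double ssP = dot(m.col(1), m.col(1));
      double n_d = (double)np;
      tL = slice_sample(
          [&](double x) {
            return -n_d * std::log(x) - 0.5 * ssL / (x * x) +
                   half_normal_lp(x, tau_scale);
          },
          tL, 0.2, 1e-8, datum::inf);
      tP = slice_sample(
          [&](double x) {
            return -n_d * std::log(x) - 0.5 * ssP / (x * x) +
                   half_normal_lp(x, tau_scale);
          },
          tP, 0.2, 1e-8, datum::inf);
    }

    // ---------- record ----------
    if (iter >= n_warmup) {
      uword s = iter - n_warmup;
      uword pos = 0;
      for (uword j = 0; j < 2 * p; ++j) draws(s, pos++) = delta(j);
      draws(s, pos++) = B(0, 0);
      draws(s, pos++) = B(0, 1);
      draws(s, pos++) = B(1, 0);
      draws(s, pos++) = B(1, 1);
      draws(s, pos++) = sL;
      draws(s, pos++) = sP;
      draws(s, pos++) = a0;
      draws(s, pos++) = a1;
      draws(s, pos++) = tL;
      draws(s, pos++) = tP;
      for (uword i = 0; i < np; ++i) draws(s, pos++) = m(i, 0);
      for (uword i = 0; i < np; ++i) draws(s, pos++) = m(i, 1);
      for (uword k = 0; k < val_row.size(); ++k)
        miss_draws(s, k) = Y(val_row[k], val_comp[k]);
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("draws") = draws,
      Rcpp::Named("miss_draws") = miss_draws,
      Rcpp::Named("nonstationary_hits") = (double)nonstat_hits);
}
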