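// Gibbs sampler core for the bivariate threshold-linear animal model.
//
// Trait 1 is either a latent liability behind an ordinal 3-category score
// (residual variance fixed at 1, first threshold fixed at 0) or an observed
// Gaussian trait; trait 2 is Gaussian. Univariate models are the nt == 1
// special case. Additive genetic effects have prior N(0, A (x) G) and are
// updated animal-wise through the sparse A-inverse; missing records are
// handled by data augmentation. All random numbers come from R's RNG, so
// runs are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double rtruncnorm1(double m, double s, double lo, double hi,
                          int &nclamp) {
  double a = (lo == R_NegInf) ? 0.0 : R::pnorm(lo, m, s, 1, 0);
  double b = (hi == R_PosInf) ? 1.0 : R::pnorm(hi, m, s, 1, 0);
  if (b - a < 1e-14) {
    // far-tail interval: fall back to the nearest admissible point
    ++nclamp;
    if (lo == R_NegInf) return hi - 1e-8 * s;
    if (hi == R_PosInf) return lo + 1e-8 * s;
    return 0.5 * (lo + hi);
  }
  double u = a + R::unif_rand() * (b - a);
  if (u < 1e-16) u = 1e-16;
  if (u > 1.0 - 1e-16) u = 1.0 - 1e-16;
  double x = R::qnorm(u, m, s, 1, 0);
  if (!std::isfinite(x)) {
    ++nclamp;
    x = std::min(std::max(m, lo == R_NegInf ? m : lo),
                 hi == R_PosInf ? m : hi);
  }
  return x;
}

// [[Rcpp::export(name = ".rtruncnorm_vec")]]
NumericVector rtruncnorm_vec(int n, double m, double s, double lo,
                             double hi) {
  NumericVector out(n);
  int ncl = 0;
  for (int i = 0; i < n; ++i) out[i] = rtruncnorm1(m, s, lo, hi, ncl);
  return out;
}

// inverse-Wishart draw via Bartlett decomposition of the Wishart on S^{-1}
static arma::mat riwish(double df, const arma::mat &S) {
  int p = S.n_rows;
  arma::mat Sinv = arma::inv_sympd(arma::symmatu(S));
  arma::mat L = arma::chol(Sinv, "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat W = L * A * A.t() * L.t();
  return arma::inv_sympd(arma::symmatu(W));
}

static double rscinvchisq(double df, double scale_sum) {
  // draw from scaled-inverse-chi-squared given df and total scale sum
  return scale_sum / R::rchisq(df);
}

// [[Rcpp::export(name = ".gibbs_core")]]
List gibbs_core(const arma::sp_mat &ainv,
                int nt, bool liability,
                IntegerVector cat1,        // -1 missing, 0/1/2 (liability)
                NumericVector y1_init,     // initial liabilities / observed y1
                LogicalVector y1_observed, // gaussian trait1: observed mask
                NumericVector y2_obs,      // NaN = missing (nt == 2)
                IntegerVector rec_animal,  // 0-based animal per record
                IntegerMatrix fidx1, int nbeta1,
                IntegerMatrix fidx2, int nbeta2,
                int mat_trait,             // 0 none, else trait index (1/2)
                IntegerVector dam_idx, int n_dams,
                int niter, int burnin, int thin,
                List priors, List inits, List fixed,
                double t2_init) {
  const int n = rec_animal.size();
  const int q = ainv.n_rows;

  // --- state -------------------------------------------------------------
  arma::mat G = as<arma::mat>(inits["G"]);
  arma::mat R = as<arma::mat>(inits["R"]);
  double sigma2_c = as<double>(inits["sigma2_c"]);
  arma::vec beta1 = as<arma::vec>(inits["beta1"]);
  arma::vec beta2 = (nt == 2) ? as<arma::vec>(inits["beta2"]) : arma::vec();
  arma::mat a(q, nt, arma::fill::zeros);
  arma::vec cmat(std::max(n_dams, 1), arma::fill::zeros);
  double t2 = t2_init;

  const bool fix_G = as<bool>(fixed["G"]);
  const bool fix_R = as<bool>(fixed["R"]);
  const bool fix_c = as<bool>(fixed["sigma2_c"]);

  const double nu_g = as<double>(priors["nu_g"]);
  const arma::mat S_g = as<arma::mat>(priors["S_g"]);
  const double nu_r = as<double>(priors["nu_r"]);
  const arma::mat S_r = as<arma::mat>(priors["S_r"]);
  const double nu_c = as<double>(priors["nu_c"]);
  const double s2_c0 = as<double>(priors["s2_c0"]);

  // working response and residuals
  arma::vec y1(n), y2(nt == 2 ? n : 0);
  for (int i = 0; i < n; ++i) y1(i) = y1_init(i);
  if (nt == 2)
    for (int i = 0; i < n; ++i)
      y2(i) = R_finite(y2_obs(i)) ? y2_obs(i) : 0.0;

  // per-coefficient record lists
  std::vector<std::vector<int>> rl1(nbeta1), rl2(nbeta2);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < fidx1.ncol(); ++c) {
      int k = fidx1(i, c);
      if (k >= 0) rl1[k].push_back(i);
    }
  if (nt == 2)
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < fidx2.ncol(); ++c) {
        int k = fidx2(i, c);
        if (k >= 0) rl2[k].push_back(i);
      }
  std::vector<std::vector<int>> dam_rl(std::max(n_dams, 1));
  if (mat_trait > 0)
    for (int i = 0; i < n; ++i)
      if (dam_idx(i) >= 0) dam_rl[dam_idx(i)].push_back(i);

  // record index per animal (at most one record per animal)
  arma::ivec rec_of(q); rec_of.fill(-1);
  for (int i = 0; i < n; ++i) rec_of(rec_animal(i)) = i;

  // fitted parts: residuals e = y - (X beta + W c + Z a)
  arma::vec e1(n), e2(nt == 2 ? n : 0);
  auto fitted = [&](int i, int t) {
    double f = 0.0;
    if (t == 0) {
      for (int c = 0; c < fidx1.ncol(); ++c) {
        int k = fidx1(i, c);
        if (k >= 0) f += beta1(k);
      }
      if (mat_trait == 1 && dam_idx(i) >= 0) f += cmat(dam_idx(i));
      f += a(rec_animal(i), 0);
    } else {
      for (int c = 0; c < fidx2.ncol(); ++c) {
        int k = fidx2(i, c);
        if (k >= 0) f += beta2(k);
      }
      if (mat_trait == 2 && dam_idx(i) >= 0) f += cmat(dam_idx(i));
      f += a(rec_animal(i), 1);
    }
    return f;
  };
  for (int i = 0; i < n; ++i) {
    e1(i) = y1(i) - fitted(i, 0);
    if (nt == 2) e2(i) = y2(i) - fitted(i, 1);
  }

  const int nkeep = (niter - burnin) / thin;
  const int npar = 8; // g11 g12 g22 e11 e12 e22 c t2
  arma::mat out(nkeep, npar, arma::fill::zeros);
  arma::vec beta1_sum(nbeta1, arma::fill::zeros);
  arma::vec beta2_sum(std::max(nbeta2, 1), arma::fill::zeros);
  arma::mat a_sum(q, nt, arma::fill::zeros);
  arma::vec c_sum(std::max(n_dams, 1), arma::fill::zeros);
  int nclamp = 0;
  int kept = 0;

  for (int it = 1; it <= niter; ++it) {
    if (it % 1000 == 0) Rcpp::checkUserInterrupt();
    // residual precision pieces
    double r11 = R(0, 0), r12 = (nt == 2) ? R(0, 1) : 0.0,
           r22 = (nt == 2) ? R(1, 1) : 0.0;
    double det2 = (nt == 2) ? (r11 * r22 - r12 * r12) : 0.0;
    double p11 = (nt == 2) ? r22 / det2 : 1.0 / r11;
    double p12 = (nt == 2) ? -r12 / det2 : 0.0;
    double p22 = (nt == 2) ? r11 / det2 : 0.0;

    // (1) data augmentation: liabilities / missing records ---------------
    for (int i = 0; i < n; ++i) {
      bool need1 = liability || !y1_observed(i);
      if (need1) {
        double fit1 = y1(i) - e1(i); // unchanged by redrawing y1
        double m = fit1, v = r11;
        if (nt == 2) { // condition on the co-trait residual
          m += (r12 / r22) * e2(i);
          v = r11 - r12 * r12 / r22;
        }
        double s = std::sqrt(v), draw;
        if (liability && cat1(i) >= 0) {
          double lo = R_NegInf, hi = R_PosInf;
          if (cat1(i) == 0)      { hi = 0.0; }
          else if (cat1(i) == 1) { lo = 0.0; hi = t2; }
          else                   { lo = t2; }
          draw = rtruncnorm1(m, s, lo, hi, nclamp);
        } else {
          draw = m + s * R::norm_rand();
        }
        y1(i) = draw;
        e1(i) = draw - fit1;
      }
      if (nt == 2 && !R_finite(y2_obs(i))) {
        double fit2 = y2(i) - e2(i);
        double m = fit2 + (r12 / r11) * e1(i);
        double v = r22 - r12 * r12 / r11;
        y2(i) = m + std::sqrt(v) * R::norm_rand();
        e2(i) = y2(i) - fit2;
      }
    }

    // (2) threshold update ------------------------------------------------
    if (liability) {
      double lo = R_NegInf, hi = R_PosInf;
      for (int i = 0; i < n; ++i) {
        if (cat1(i) == 1 && y1(i) > lo) lo = y1(i);
        if (cat1(i) == 2 && y1(i) < hi) hi = y1(i);
      }
      if (std::isfinite(lo) && std::isfinite(hi) && hi > lo)
        t2 = lo + R::unif_rand() * (hi - lo);
    }

    // (3) fixed effects ---------------------------------------------------
    for (int k = 0; k < nbeta1; ++k) {
      const std::vector<int> &S = rl1[k];
      if (S.empty()) continue;
      double prec = S.size() * p11, rhs = 0.0;
      for (int i : S) {
        rhs += p11 * (e1(i) + beta1(k));
        if (nt == 2) rhs += p12 * e2(i);
      }
      double bnew = rhs / prec + R::norm_rand() / std::sqrt(prec);
      double d = bnew - beta1(k);
      beta1(k) = bnew;
      for (int i : S) e1(i) -= d;
    }
    if (nt == 2) {
      for (int k = 0; k < nbeta2; ++k) {
        const std::vector<int> &S = rl2[k];
        if (S.empty()) continue;
        double prec = S.size() * p22, rhs = 0.0;
        for (int i : S) rhs += p22 * (e2(i) + beta2(k)) + p12 * e1(i);
        double bnew = rhs / prec + R::norm_rand() / std::sqrt(prec);
        double d = bnew - beta2(k);
        beta2(k) = bnew;
        for (int i : S) e2(i) -= d;
      }
    }

    // (4) maternal environment -------------------------------------------
    if (mat_trait > 0) {
      double rmm = (mat_trait == 1) ? p11 : (nt == 2 ? p22 : p11);
      double rms = (nt == 2) ? p12 : 0.0;
      double ssc = 0.0;
      for (int j = 0; j < n_dams; ++j) {
        const std::vector<int> &S = dam_rl[j];
        double prec = S.size() * rmm + 1.0 / sigma2_c, rhs = 0.0;
        for (int i : S) {
          if (mat_trait == 2) rhs += rmm * (e2(i) + cmat(j)) + rms * e1(i);
          else rhs += rmm * (e1(i) + cmat(j)) + rms * (nt == 2 ? e2(i) : 0.0);
        }
        double cnew = rhs / prec + R::norm_rand() / std::sqrt(prec);
        double d = cnew - cmat(j);
        cmat(j) = cnew;
        for (int i : S) {
          if (mat_trait == 2) e2(i) -= d; else e1(i) -= d;
        }
        ssc += cnew * cnew;
      }
      if (!fix_c)
        sigma2_c = rscinvchisq(nu_c + n_dams, nu_c * s2_c0 + ssc);
    }

    // (5) animal effects and G -------------------------------------------
    arma::mat Ginv = (nt == 2) ? arma::inv_sympd(arma::symmatu(G))
                               : arma::mat(1, 1, arma::fill::value(1.0 / G(0, 0)));
    for (int i = 0; i < q; ++i) {
      // u = sum_{j != i} ainv(i,j) a_j ; aii = ainv(i,i)
      double u1 = 0.0, u2 = 0.0, aii = 0.0;
      for (arma::sp_mat::const_col_iterator jt = ainv.begin_col(i);
           jt != ainv.end_col(i); ++jt) {
        int j = jt.row();
        double v = *jt;
        if (j == i) { aii = v; continue; }
        u1 += v * a(j, 0);
        if (nt == 2) u2 += v * a(j, 1);
      }
      int r = rec_of(i);
      if (nt == 1) {
        double prec = aii * Ginv(0, 0) + (r >= 0 ? p11 : 0.0);
        double rhs = -Ginv(0, 0) * u1;
        if (r >= 0) rhs += p11 * (e1(r) + a(i, 0));
        double anew = rhs / prec + R::norm_rand() / std::sqrt(prec);
        double d = anew - a(i, 0);
        a(i, 0) = anew;
        if (r >= 0) e1(r) -= d;
      } else {
        double P11 = aii * Ginv(0, 0), P12 = aii * Ginv(0, 1),
               P22 = aii * Ginv(1, 1);
        double rhs1 = -(Ginv(0, 0) * u1 + Ginv(0, 1) * u2);
        double rhs2 = -(Ginv(0, 1) * u1 + Ginv(1, 1) * u2);
        if (r >= 0) {
          P11 += p11; P12 += p12; P22 += p22;
          double t1r = e1(r) + a(i, 0), t2r = e2(r) + a(i, 1);
          rhs1 += p11 * t1r + p12 * t2r;
          rhs2 += p12 * t1r + p22 * t2r;
        }
        // 2x2 Cholesky solve + sample
        double l11 = std::sqrt(P11), l21 = P12 / l11,
               l22 = std::sqrt(P22 - l21 * l21);
        // mean: solve L w = rhs, L' mu = w
        double w1 = rhs1 / l11, w2 = (rhs2 - l21 * w1) / l22;
        double mu2 = w2 / l22, mu1 = (w1 - l21 * mu2) / l11;
        // noise: solve L' z = eps
        double eps1 = R::norm_rand(), eps2 = R::norm_rand();
        double z2 = eps2 / l22, z1 = (eps1 - l21 * z2) / l11;
        double d1 = (mu1 + z1) - a(i, 0), d2 = (mu2 + z2) - a(i, 1);
        a(i, 0) += d1; a(i, 1) += d2;
        if (r >= 0) { e1(r) -= d1; e2(r) -= d2; }
      }
    }
    if (!fix_G) {
      // Sa = a' Ainv a accumulated over non-zeros
      double s11 = 0.0, s12 = 0.0, s22 = 0.0;
      for (arma::sp_mat::const_iterator itm = ainv.begin();
           itm != ainv.end(); ++itm) {
        int i = itm.row(), j = itm.col();
        double v = *itm;
        s11 += v * a(i, 0) * a(j, 0);
        if (nt == 2) {
          s12 += v * a(i, 0) * a(j, 1);
          s22 += v * a(i, 1) * a(j, 1);
        }
      }
      if (nt == 1) {
        G(0, 0) = rscinvchisq(nu_g + q, nu_g * S_g(0, 0) + s11);
      } else {
        arma::mat Sa = {{s11, s12}, {s12, s22}};
        G = riwish(nu_g + q, S_g + Sa);
      }
    }

    // (6) residual covariance --------------------------------------------
    if (!fix_R) {
      if (nt == 2) {
        double Se11 = arma::dot(e1, e1), Se12 = arma::dot(e1, e2),
               Se22 = arma::dot(e2, e2);
        if (liability) {
          // sigma2_e1 constrained to 1: Gibbs on the residual regression
          // b = sigma_e12 and conditional variance tau2
          double b = R(0, 1);
          double SSEb = Se22 - 2.0 * b * Se12 + b * b * Se11;
          double tau2 = rscinvchisq(nu_r + n, nu_r * S_r(1, 1) + SSEb);
          double bhat = Se12 / Se11;
          b = bhat + R::norm_rand() * std::sqrt(tau2 / Se11);
          R(0, 0) = 1.0; R(0, 1) = R(1, 0) = b;
          R(1, 1) = tau2 + b * b;
        } else {
          arma::mat Se = {{Se11, Se12}, {Se12, Se22}};
          R = riwish(nu_r + n, S_r + Se);
        }
      } else if (!liability) {
        double Se11 = arma::dot(e1, e1);
        R(0, 0) = rscinvchisq(nu_r + n, nu_r * S_r(0, 0) + Se11);
      } // nt == 1 with liability: residual variance fixed at 1
    }

    // (7) store -----------------------------------------------------------
    if (it > burnin) {
      beta1_sum += beta1;
      if (nt == 2) beta2_sum += beta2;
      a_sum += a;
      if (mat_trait > 0) c_sum += cmat;
      if ((it - burnin) % thin == 0 && kept < nkeep) {
        out(kept, 0) = G(0, 0);
        out(kept, 1) = (nt == 2) ? G(0, 1) : NA_REAL;
        out(kept, 2) = (nt == 2) ? G(1, 1) : NA_REAL;
        out(kept, 3) = R(0, 0);
        out(kept, 4) = (nt == 2) ? R(0, 1) : NA_REAL;
        out(kept, 5) = (nt == 2) ? R(1, 1) : NA_REAL;
        out(kept, 6) = (mat_trait > 0) ? sigma2_c : NA_REAL;
        out(kept, 7) = liability ? t2 : NA_REAL;
        ++kept;
      }
    }
  }

  double denom = std::max(niter - burnin, 1);
  return List::create(
    _["samples"] = out,
    _["kept"] = kept,
    _["beta1_mean"] = beta1_sum / denom,
    _["beta2_mean"] = (nt == 2) ? NumericVector(wrap(beta2_sum / denom))
                                : NumericVector(0),
    _["a_mean"] = a_sum / denom,
    _["c_mean"] = c_sum / denom,
    _["n_clamped"] = nclamp);
}
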