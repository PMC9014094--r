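#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Meuwissen-Luo recursion for inbreeding coefficients.
// sire/dam are 1-based row indices into the (parents-first) pedigree,
// 0 = unknown.  Equivalent to diag(A) - 1 from the tabular method.
// [[Rcpp::export]]
NumericVector ml_inbreeding(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector F(n);
  std::vector<double> L(n, 0.0), D(n, 0.0);
  std::vector<int> point(n, -1);

  for (int i = 0; i < n; ++i) {
    const int is = sire[i] - 1, id = dam[i] - 1;
    const double fs = (is >= 0) ? F[is] : -1.0;
    const double fd = (id >= 0) ? F[id] : -1.0;
    D[i] = 0.5 - 0.25 * (fs + fd);
    if (is < 0 || id < 0) { F[i] = 0.0; continue; }
    double fi = -1.0;
    L[i] = 1.0;
    point[i] = -1;
    int j = i;
    while (j >= 0) {
      const double r = 0.5 * L[j];
      const int ks = sire[j] - 1, kd = dam[j] - 1;
      if (ks >= 0) {
        int k = j;
        while (point[k] > ks) k = point[k];
        L[ks] += r;
        if (point[k] != ks) { point[ks] = point[k]; point[k] = ks; }
      }
      if (kd >= 0) {
        int k = j;
        while (point[k] > kd) k = point[k];
        L[kd] += r;
        if (point[k] != kd) { point[kd] = point[k]; point[k] = kd; }
      }
      fi += L[j] * L[j] * D[j];
      L[j] = 0.0;
      const int next = point[j];
      point[j] = -1;
      j = next;
    }
    F[i] = fi;
  }
  return F;
}

// ---------------------------------------------------------------------------

static double rtnorm1(double mu, double sd, double lo, double hi) {
  const double a = (lo - mu) / sd, b = (hi - mu) / sd;
  const double pa = R::pnorm(a, 0.0, 1.0, 1, 0);
  const double pb = R::pnorm(b, 0.0, 1.0, 1, 0);
  if (pb - pa < 1e-14) {  // interval numerically in a far tail
    double z;
    if (b <= 0.0) z = b; else if (a >= 0.0) z = a + 1e-10; else z = 0.0;
    return mu + sd * z;
  }
  double u = R::runif(pa, pb);
  if (u < 1e-15) u = 1e-15;
  if (u > 1.0 - 1e-15) u = 1.0 - 1e-15;
  return mu + sd * R::qnorm(u, 0.0, 1.0, 1, 0);
}

// Inverse-Wishart draw for the 2x2 direct/maternal covariance matrix:
// Sigma = W^-1 with W ~ Wishart(df, inv(S)).  Returns false when the
// scale matrix is not positive definite (caller jitters and retries).
static bool draw_sigma2(double S11, double S12, double S22, double df,
                        double &s_u, double &s_um, double &s_m) {
  const double det = S11 * S22 - S12 * S12;
  if (det <= 0.0 || S11 <= 0.0) return false;
  const double i11 = S22 / det, i12 = -S12 / det, i22 = S11 / det;
  const double l11 = std::sqrt(i11);
  const double l21 = i12 / l11;
  const double l22sq = i22 - l21 * l21;
  if (l22sq <= 0.0) return false;
  const double l22 = std::sqrt(l22sq);
  const double c11 = std::sqrt(R::rchisq(df));
  const double c21 = R::rnorm(0.0, 1.0);
  const double c22 = std::sqrt(R::rchisq(df - 1.0));
  const double w11 = l11 * c11;
  const double w21 = l21 * c11 + l22 * c21;
  const double w22 = l22 * c22;
  const double W11 = w11 * w11;
  const double W12 = w11 * w21;
  const double W22 = w21 * w21 + w22 * w22;
  const double detW = W11 * W22 - W12 * W12;
  if (detW <= 0.0) return false;
  s_u = W22 / detW;
  s_um = -W12 / detW;
  s_m = W11 / detW;
  return true;
}

// Group records by an index vector (1-based, 0 = no level): CSR layout.
static void build_groups(const IntegerVector &idx, int nlev,
                         std::vector<int> &off, std::vector<int> &recs) {
  const int n = idx.size();
  std::vector<int> cnt(nlev, 0);
  int total = 0;
  for (int i = 0; i < n; ++i) if (idx[i] > 0) { ++cnt[idx[i] - 1]; ++total; }
  off.assign(nlev + 1, 0);
  for (int k = 0; k < nlev; ++k) off[k + 1] = off[k] + cnt[k];
  std::vector<int> cur(off.begin(), off.end() - 1);
  recs.assign(total, 0);
  for (int i = 0; i < n; ++i) {
    if (idx[i] > 0) recs[cur[idx[i] - 1]++] = i;
  }
}

// Single-site Gibbs sampler for the threshold (liability) animal model
// with optional maternal genetic and maternal environmental effects.
// The genetic precision structure Kinv (A^-1 or H^-1) is passed in CSC
// form (Ki/Kp/Kx) over q animals in pedigree order, which is also the
// fixed solve order.
// [[Rcpp::export]]
List threshold_gibbs_cpp(IntegerVector y, NumericVector y_cont, bool gaussian,
                         NumericMatrix X, IntegerVector cg, int ncg,
                         IntegerVector uidx, IntegerVector midx,
                         IntegerVector pidx, int npe,
                         bool use_m, bool use_pe,
                         IntegerVector Ki, IntegerVector Kp, NumericVector Kx,
                         int q, int C, int n_iter, int burn_in, int thin,
                         List priors, NumericVector fixed_vals,
                         NumericVector init_vals) {
  const int n = gaussian ? y_cont.size() : y.size();
  const int p = X.ncol();

  // --- grouping structures -------------------------------------------------
  std::vector<int> cg_off, cg_rec, u_off, u_rec, m_off, m_rec, pe_off, pe_rec;
  build_groups(cg, ncg, cg_off, cg_rec);
  build_groups(uidx, q, u_off, u_rec);
  if (use_m) build_groups(midx, q, m_off, m_rec);
  if (use_pe) build_groups(pidx, npe, pe_off, pe_rec);

  // --- priors and fixed/free pattern --------------------------------------
  const double nu_cg = as<double>(priors["nu_cg"]);
  const double s2_cg = as<double>(priors["s2_cg"]);
  const double nu_pe = as<double>(priors["nu_pe"]);
  const double s2_pe = as<double>(priors["s2_pe"]);
  const double nu_e = as<double>(priors["nu_e"]);
  const double s2_e = as<double>(priors["s2_e"]);
  const double nu_u = as<double>(priors["nu_u"]);
  const double s2_u = as<double>(priors["s2_u"]);
  const double nu_sig = as<double>(priors["nu_sig"]);
  NumericMatrix V_sig = as<NumericMatrix>(priors["V_sig"]);

  // fixed_vals order: var_cg, var_u, cov_um, var_m, var_pe, var_e (NA = free)
  const bool fix_cg = !NumericVector::is_na(fixed_vals[0]);
  const bool fix_u = !NumericVector::is_na(fixed_vals[1]);
  const bool fix_pe = !NumericVector::is_na(fixed_vals[4]);
  const bool fix_e = !NumericVector::is_na(fixed_vals[5]);

  // --- state ---------------------------------------------------------------
  double var_cg = fix_cg ? fixed_vals[0] : init_vals[0];
  double var_u = fix_u ? fixed_vals[1] : init_vals[1];
  double cov_um = use_m ? (fix_u ? fixed_vals[2] : init_vals[2]) : 0.0;
  double var_m = use_m ? (fix_u ? fixed_vals[3] : init_vals[3]) : 0.0;
  double var_pe = use_pe ? (fix_pe ? fixed_vals[4] : init_vals[4]) : 0.0;
  double var_e = fix_e ? fixed_vals[5] : init_vals[5];

  std::vector<double> b(p, 0.0), w(ncg, 0.0), u(q, 0.0), m(q, 0.0),
      pe(npe > 0 ? npe : 1, 0.0);

  const int n_thr = C - 1;
  std::vector<double> t(n_thr, 0.0);
  for (int k = 0; k < n_thr; ++k) t[k] = (double)k;  // 0, 1, 2, ...
  const int first_free_t = 2;  // t[0]=0 and (when C>=3) t[1]=1 stay fixed
  const int n_free_t = std::max(0, n_thr - first_free_t);

  std::vector<double> l(n, 0.0);
  if (gaussian) {
    for (int i = 0; i < n; ++i) l[i] = y_cont[i];
  } else {
    for (int i = 0; i < n; ++i) {
      const int c = y[i];
      if (c == 1) l[i] = t[0] - 0.5;
      else if (c == C) l[i] = t[n_thr - 1] + 0.5;
      else l[i] = 0.5 * (t[c - 2] + t[c - 1]);
    }
  }

  // residuals e = l - eta with all effects initialized at zero
  std::vector<double> e(l);

  std::vector<double> kdiag(q, 0.0);
  for (int a = 0; a < q; ++a) {
    for (int ptr = Kp[a]; ptr < Kp[a + 1]; ++ptr) {
      if (Ki[ptr] == a) { kdiag[a] = Kx[ptr]; break; }
    }
  }

  std::vector<double> xtx(p, 0.0);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }

  // --- output --------------------------------------------------------------
  const int n_save = (n_iter - burn_in + thin - 1) / thin;
  NumericMatrix samples(n_save, 6 + n_free_t);
  std::vector<double> su(q, 0.0), su2(q, 0.0), sm(q, 0.0), sm2(q, 0.0);
  std::vector<double> sb(p, 0.0), sw(ncg, 0.0), spe(npe > 0 ? npe : 1, 0.0);
  int saved = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    const double sde = std::sqrt(var_e);

    // 1. liabilities -------------------------------------------------------
    if (!gaussian) {
      for (int i = 0; i < n; ++i) {
        const int c = y[i];
        const double lo = (c == 1) ? R_NegInf : t[c - 2];
        const double hi = (c == C) ? R_PosInf : t[c - 1];
        const double mu = l[i] - e[i];
        const double lnew = rtnorm1(mu, sde, lo, hi);
        e[i] += lnew - l[i];
        l[i] = lnew;
      }
      // 2. free thresholds -------------------------------------------------
      for (int k = first_free_t; k < n_thr; ++k) {
        double lo = t[k - 1], hi = (k + 1 < n_thr) ? t[k + 1] : R_PosInf;
        for (int i = 0; i < n; ++i) {
          if (y[i] == k + 1 && l[i] > lo) lo = l[i];
          if (y[i] == k + 2 && l[i] < hi) hi = l[i];
        }
        if (!R_finite(hi)) hi = lo + 3.0 * sde;
        if (hi > lo) t[k] = R::runif(lo, hi);
      }
    }

    // 3. fixed effects (flat prior) ---------------------------------------
    for (int j = 0; j < p; ++j) {
      if (xtx[j] <= 0.0) continue;
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += X(i, j) * (e[i] + X(i, j) * b[j]);
      const double lhs = xtx[j];
      const double bn = R::rnorm(rhs / lhs, sde / std::sqrt(lhs));
      const double d = bn - b[j];
      if (d != 0.0) for (int i = 0; i < n; ++i) e[i] -= X(i, j) * d;
      b[j] = bn;
    }

    // 4. contemporary-group effects ---------------------------------------
    {
      const double lam = var_e / var_cg;
      for (int k = 0; k < ncg; ++k) {
        const int a0 = cg_off[k], a1 = cg_off[k + 1];
        double rhs = 0.0;
        for (int r = a0; r < a1; ++r) rhs += e[cg_rec[r]] + w[k];
        const double lhs = (a1 - a0) + lam;
        const double wn = R::rnorm(rhs / lhs, sde / std::sqrt(lhs));
        const double d = wn - w[k];
        for (int r = a0; r < a1; ++r) e[cg_rec[r]] -= d;
        w[k] = wn;
      }
    }

    // 5/6. genetic effects (direct, then maternal) ------------------------
    double lam11, lam12 = 0.0, lam22 = 0.0;
    if (use_m) {
      const double det = var_u * var_m - cov_um * cov_um;
      lam11 = var_m / det; lam12 = -cov_um / det; lam22 = var_u / det;
    } else {
      lam11 = 1.0 / var_u;
    }
    const double inv_ve = 1.0 / var_e;
    for (int a = 0; a < q; ++a) {
      double s_u = 0.0, s_m = 0.0;
      const int p0 = Kp[a], p1 = Kp[a + 1];
      if (use_m) {
        for (int ptr = p0; ptr < p1; ++ptr) {
          s_u += Kx[ptr] * u[Ki[ptr]];
          s_m += Kx[ptr] * m[Ki[ptr]];
        }
      } else {
        for (int ptr = p0; ptr < p1; ++ptr) s_u += Kx[ptr] * u[Ki[ptr]];
      }
      const double kaa = kdiag[a];
      s_u -= kaa * u[a];
      const int a0 = u_off[a], a1 = u_off[a + 1];
      double rhs = 0.0;
      for (int r = a0; r < a1; ++r) rhs += e[u_rec[r]];
      rhs = (rhs + (a1 - a0) * u[a]) * inv_ve;
      rhs -= lam11 * s_u + lam12 * s_m;
      const double lhs = (a1 - a0) * inv_ve + lam11 * kaa;
      const double un = R::rnorm(rhs / lhs, 1.0 / std::sqrt(lhs));
      const double d = un - u[a];
      for (int r = a0; r < a1; ++r) e[u_rec[r]] -= d;
      u[a] = un;
    }
    if (use_m) {
      for (int a = 0; a < q; ++a) {
        double s_m = 0.0, s_u = 0.0;
        for (int ptr = Kp[a]; ptr < Kp[a + 1]; ++ptr) {
          s_m += Kx[ptr] * m[Ki[ptr]];
          s_u += Kx[ptr] * u[Ki[ptr]];
        }
        const double kaa = kdiag[a];
        s_m -= kaa * m[a];
        const int a0 = m_off[a], a1 = m_off[a + 1];
        double rhs = 0.0;
        for (int r = a0; r < a1; ++r) rhs += e[m_rec[r]];
        rhs = (rhs + (a1 - a0) * m[a]) * inv_ve;
        rhs -= lam22 * s_m + lam12 * s_u;
        const double lhs = (a1 - a0) * inv_ve + lam22 * kaa;
        const double mn = R::rnorm(rhs / lhs, 1.0 / std::sqrt(lhs));
        const double d = mn - m[a];
        for (int r = a0; r < a1; ++r) e[m_rec[r]] -= d;
        m[a] = mn;
      }
    }

    // 7. maternal environmental effects -----------------------------------
    if (use_pe) {
      const double lam = var_e / var_pe;
      for (int k = 0; k < npe; ++k) {
        const int a0 = pe_off[k], a1 = pe_off[k + 1];
        double rhs = 0.0;
        for (int r = a0; r < a1; ++r) rhs += e[pe_rec[r]] + pe[k];
        const double lhs = (a1 - a0) + lam;
        const double pn = R::rnorm(rhs / lhs, sde / std::sqrt(lhs));
        const double d = pn - pe[k];
        for (int r = a0; r < a1; ++r) e[pe_rec[r]] -= d;
        pe[k] = pn;
      }
    }

    // 8. variance components ----------------------------------------------
    if (!fix_cg) {
      double ss = 0.0;
      for (int k = 0; k < ncg; ++k) ss += w[k] * w[k];
      var_cg = (ss + nu_cg * s2_cg) / R::rchisq(ncg + nu_cg);
    }
    if (!fix_u) {
      if (use_m) {
        // quadratic forms u'Ku, u'Km, m'Km over the sparse precision
        double S11 = 0.0, S12 = 0.0, S22 = 0.0;
        for (int a = 0; a < q; ++a) {
          double ku = 0.0, km = 0.0;
          for (int ptr = Kp[a]; ptr < Kp[a + 1]; ++ptr) {
            ku += Kx[ptr] * u[Ki[ptr]];
            km += Kx[ptr] * m[Ki[ptr]];
          }
          S11 += u[a] * ku;
          S12 += u[a] * km;
          S22 += m[a] * km;
        }
        S11 += V_sig(0, 0); S12 += V_sig(0, 1); S22 += V_sig(1, 1);
        const double df = q + nu_sig;
        double su_, sum_, sm_;
        int tries = 0;
        while (!draw_sigma2(S11, S12, S22, df, su_, sum_, sm_)) {
          S11 += 1e-8; S22 += 1e-8;  // jitter non-PD scale
          if (++tries > 50) stop("covariance scale matrix not positive definite");
        }
        var_u = su_; cov_um = sum_; var_m = sm_;
      } else {
        double ss = 0.0;
        for (int a = 0; a < q; ++a) {
          double ku = 0.0;
          for (int ptr = Kp[a]; ptr < Kp[a + 1]; ++ptr)
            ku += Kx[ptr] * u[Ki[ptr]];
          ss += u[a] * ku;
        }
        var_u = (ss + nu_u * s2_u) / R::rchisq(q + nu_u);
      }
    }
    if (use_pe && !fix_pe) {
      double ss = 0.0;
      for (int k = 0; k < npe; ++k) ss += pe[k] * pe[k];
      var_pe = (ss + nu_pe * s2_pe) / R::rchisq(npe + nu_pe);
    }
    if (!fix_e) {
      double ss = 0.0;
      for (int i = 0; i < n; ++i) ss += e[i] * e[i];
      var_e = (ss + nu_e * s2_e) / R::rchisq(n + nu_e);
    }
    if (var_e > 1e8 || var_u > 1e8 || var_cg > 1e8) {
      stop("divergent chain: a variance component exceeded 1e8 at iteration %d",
           iter + 1);
    }

    // 9. save --------------------------------------------------------------
    if (iter >= burn_in && (iter - burn_in) % thin == 0) {
      samples(saved, 0) = var_cg;
      samples(saved, 1) = var_u;
      samples(saved, 2) = cov_um;
      samples(saved, 3) = var_m;
      samples(saved, 4) = var_pe;
      samples(saved, 5) = var_e;
      for (int k = 0; k < n_free_t; ++k)
        samples(saved, 6 + k) = t[first_free_t + k];
      for (int a = 0; a < q; ++a) {
        su[a] += u[a]; su2[a] += u[a] * u[a];
        if (use_m) { sm[a] += m[a]; sm2[a] += m[a] * m[a]; }
      }
      for (int j = 0; j < p; ++j) sb[j] += b[j];
      for (int k = 0; k < ncg; ++k) sw[k] += w[k];
      if (use_pe) for (int k = 0; k < npe; ++k) spe[k] += pe[k];
      ++saved;
    }
    if (iter % 512 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector mu(q), vu(q), mm(q), vm(q);
  for (int a = 0; a < q; ++a) {
    mu[a] = su[a] / saved;
    vu[a] = su2[a] / saved - mu[a] * mu[a];
    if (use_m) { mm[a] = sm[a] / saved; vm[a] = sm2[a] / saved - mm[a] * mm[a]; }
  }
  NumericVector bm(p), wm(ncg), pem(npe > 0 ? npe : 1);
  for (int j = 0; j < p; ++j) bm[j] = sb[j] / saved;
  for (int k = 0; k < ncg; ++k) wm[k] = sw[k] / saved;
  for (int k = 0; k < (npe > 0 ? npe : 1); ++k) pem[k] = spe[k] / saved;

  return List::create(_["samples"] = samples, _["n_saved"] = saved,
                      _["u_mean"] = mu, _["u_var"] = vu,
                      _["m_mean"] = mm, _["m_var"] = vm,
                      _["b_mean"] = bm, _["w_mean"] = wm,
                      _["pe_mean"] = pem,
                      _["liab_final"] = NumericVector(l.begin(), l.end()),
                      _["thresholds"] = NumericVector(t.begin(), t.end()));
}
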