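// Fast loss/gradient evaluation for texture synthesis.
//
// This mirrors the reference R implementation (.synth_eval in
// R/synthesis-grad.R) operation for operation; the R path is kept as the
// cross-validation oracle in the test suite.  See that file for the
// derivation of the statistics and their adjoints.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static cx_mat spec_crop(const cx_mat& M) {   // n -> n/2, value convention
  const uword n = M.n_rows, h = n / 4;
  cx_mat out(n / 2, n / 2);
  out.submat(0, 0, h - 1, h - 1) = M.submat(0, 0, h - 1, h - 1);
  out.submat(h, 0, 2 * h - 1, h - 1) = M.submat(n - h, 0, n - 1, h - 1);
  out.submat(0, h, h - 1, 2 * h - 1) = M.submat(0, n - h, h - 1, n - 1);
  out.submat(h, h, 2 * h - 1, 2 * h - 1) = M.submat(n - h, n - h, n - 1, n - 1);
  return out / 4.0;
}

static cx_mat spec_pad(const cx_mat& M) {    // n -> 2n, value convention
  const uword n = M.n_rows, h = n / 2;
  cx_mat out(2 * n, 2 * n, fill::zeros);
  out.submat(0, 0, h - 1, h - 1) = M.submat(0, 0, h - 1, h - 1);
  out.submat(2 * n - h, 0, 2 * n - 1, h - 1) = M.submat(n - h, 0, n - 1, h - 1);
  out.submat(0, 2 * n - h, h - 1, 2 * n - 1) = M.submat(0, n - h, h - 1, n - 1);
  out.submat(2 * n - h, 2 * n - h, 2 * n - 1, 2 * n - 1) =
      M.submat(n - h, n - h, n - 1, n - 1);
  return out * 4.0;
}

static cx_mat spec_crop_idx(const cx_mat& M) {  // plain index crop
  return spec_crop(M) * 4.0;
}

static cx_mat spec_pad_idx(const cx_mat& M) {   // plain index pad
  return spec_pad(M) / 4.0;
}

static cx_mat flip_freq(const cx_mat& M) {      // T(-omega)
  const uword n = M.n_rows;
  uvec idx(n);
  idx(0) = 0;
  for (uword i = 1; i < n; i++) idx(i) = n - i;
  return M(idx, idx);
}


// elementwise product of a complex matrix with a real mask (no temporaries)
static cx_mat rmul(const cx_mat& Z, const mat& m) {
  cx_mat out(Z.n_rows, Z.n_cols);
  const std::complex<double>* z = Z.memptr();
  const double* r = m.memptr();
  std::complex<double>* o = out.memptr();
  const uword N = Z.n_elem;
  for (uword i = 0; i < N; i++) o[i] = z[i] * r[i];
  return out;
}

static void rmul_inplace(cx_mat& Z, const mat& m) {
  std::complex<double>* z = Z.memptr();
  const double* r = m.memptr();
  for (uword i = 0; i < Z.n_elem; i++) z[i] *= r[i];
}

static mat abs_sq(const cx_mat& Z) {
  mat out(Z.n_rows, Z.n_cols);
  const std::complex<double>* z = Z.memptr();
  double* o = out.memptr();
  for (uword i = 0; i < Z.n_elem; i++) o[i] = std::norm(z[i]);
  return out;
}

static mat cshift2(const mat& q, int dy, int dx) {
  const int n = q.n_rows, m = q.n_cols;
  int sy = ((-dy) % n + n) % n, sx = ((-dx) % m + m) % m;
  return shift(shift(q, sy, 0), sx, 1);
}

// linear index (column-major) of offset (dy, dx) in an n x n FFT map
static uword off_index(int n, int dy, int dx) {
  int r = ((dy % n) + n) % n;
  int c = ((dx % n) + n) % n;
  return (uword)c * n + r;
}

// [[Rcpp::export(name = ".synth_eval_cpp")]]
Rcpp::List synth_eval_cpp(const arma::mat& x, const Rcpp::List& masks,
                          const arma::imat& off, const arma::vec& target,
                          const arma::ivec& gstart, const arma::ivec& gend,
                          const arma::vec& gden, double gfloor, int K, int O) {
  const int n = x.n_rows;
  const int no = off.n_rows;
  const std::complex<double> I1(0.0, 1.0);

  // masks[[k]] is list(lo, hi, ang=list(...)); masks[[K+1]] = list(lo0, hi0)
  Rcpp::List m0 = masks[K];
  mat lo0 = Rcpp::as<mat>(m0["lo0"]);
  // hi0 unused: no highpass statistics

  // ---- forward pyramid ----
  std::vector<cx_mat> S(K + 1);
  std::vector<std::vector<cx_mat>> Bs(K), bsp(K), Mh(K);
  std::vector<std::vector<mat>> msp(K);
  S[0] = fft2(x); rmul_inplace(S[0], lo0);
  for (int k = 0; k < K; k++) {
    Rcpp::List mk = masks[k];
    mat lo = Rcpp::as<mat>(mk["lo"]);
    mat hi = Rcpp::as<mat>(mk["hi"]);
    Rcpp::List ang = mk["ang"];
    cx_mat HS = rmul(S[k], hi);
    Bs[k].resize(O); bsp[k].resize(O); msp[k].resize(O); Mh[k].resize(O);
    for (int o = 0; o < O; o++) {
      mat a = Rcpp::as<mat>(ang[o]);
      Bs[k][o] = rmul(HS, a);
      bsp[k][o] = ifft2(Bs[k][o]);
      msp[k][o] = abs(bsp[k][o]);
      Mh[k][o] = fft2(msp[k][o]);
    }
    S[k + 1] = spec_crop(rmul(S[k], lo));
  }

  // derived coarse-resolution cross-scale maps
  std::vector<std::vector<mat>> dmf(std::max(K - 1, 0));
  std::vector<std::vector<cx_mat>> dbf(std::max(K - 1, 0)), pdc(std::max(K - 1, 0));
  for (int k = 0; k + 1 < K; k++) {
    dmf[k].resize(O); dbf[k].resize(O); pdc[k].resize(O);
    for (int o = 0; o < O; o++) {
      dmf[k][o] = real(ifft2(spec_crop_idx(Mh[k][o])));
      dbf[k][o] = ifft2(spec_crop_idx(Bs[k][o]));
      const cx_mat& b = bsp[k + 1][o];
      const mat& m = msp[k + 1][o];
      cx_mat pd(b.n_rows, b.n_cols, fill::zeros);
      for (uword i = 0; i < b.n_elem; i++)
        if (m(i) > 0) pd(i) = b(i) * b(i) / m(i);
      pdc[k][o] = pd;
    }
  }

  vec mu_p(K);
  mat mu_m(K, O);
  for (int k = 0; k < K; k++) {
    double Nk = (double)(n / (1 << k)) * (n / (1 << k));
    mu_p(k) = S[k](0, 0).real() / Nk;
    for (int o = 0; o < O; o++) mu_m(k, o) = accu(msp[k][o]) / Nk;
  }

  // ---- statistics ----
  const int nlin = K * no, nmag = K * O * no, nmcs = (K - 1) * O * O;
  const int nmco = K * O * (O - 1) / 2, nphs = (K - 1) * O * O * 2;
  const int nbmm = K * O;
  const int ntot = nlin + nmag + nmcs + nmco + nphs + nbmm + 4;
  vec s(ntot, fill::zeros);

  std::vector<std::vector<uword>> oidx(K);
  for (int k = 0; k < K; k++) {
    int nk = n / (1 << k);
    oidx[k].resize(no);
    for (int i = 0; i < no; i++)
      oidx[k][i] = off_index(nk, off(i, 0), off(i, 1));
  }

  std::vector<mat> ac_p(K);                 // autocorrelation maps (reused in bwd)
  std::vector<std::vector<mat>> ac_m(K);
  int pos = 0;
  for (int k = 0; k < K; k++) {
    int nk = n / (1 << k); double Nk = (double)nk * nk;
    ac_p[k] = real(ifft2(cx_mat(abs_sq(S[k]), mat(nk, nk, fill::zeros)))) / Nk;
    for (int i = 0; i < no; i++)
      s(pos++) = ac_p[k](oidx[k][i]) - mu_p(k) * mu_p(k);
  }
  for (int k = 0; k < K; k++) {
    int nk = n / (1 << k); double Nk = (double)nk * nk;
    ac_m[k].resize(O);
    for (int o = 0; o < O; o++) {
      ac_m[k][o] = real(ifft2(cx_mat(abs_sq(Mh[k][o]), mat(nk, nk, fill::zeros)))) / Nk;
      for (int i = 0; i < no; i++)
        s(pos++) = ac_m[k][o](oidx[k][i]) - mu_m(k, o) * mu_m(k, o);
    }
  }
  for (int k = 0; k + 1 < K; k++) {
    double Nf = (double)(n / (1 << k)) * (n / (1 << k));
    for (int of = 0; of < O; of++)
      for (int oc = 0; oc < O; oc++)
        s(pos++) = accu(dmf[k][of] % msp[k + 1][oc]) / Nf -
                   mu_m(k, of) * mu_m(k + 1, oc);
  }
  for (int k = 0; k < K; k++) {
    double Nk = (double)(n / (1 << k)) * (n / (1 << k));
    for (int o1 = 0; o1 < O - 1; o1++)
      for (int o2 = o1 + 1; o2 < O; o2++)
        s(pos++) = accu(msp[k][o1] % msp[k][o2]) / Nk -
                   mu_m(k, o1) * mu_m(k, o2);
  }
  for (int k = 0; k + 1 < K; k++) {
    double Nf = (double)(n / (1 << k)) * (n / (1 << k));
    for (int of = 0; of < O; of++)
      for (int oc = 0; oc < O; oc++) {
        std::complex<double> z = accu(dbf[k][of] % conj(pdc[k][oc])) / Nf;
        s(pos++) = z.real();
        s(pos++) = z.imag();
      }
  }
  for (int k = 0; k < K; k++)
    for (int o = 0; o < O; o++) s(pos++) = mu_m(k, o);

  double mu = accu(x) / ((double)n * n);
  mat xc = x - mu;
  double N = (double)n * n;
  double m2 = accu(square(xc)) / N;
  double m3 = accu(pow(xc, 3)) / N;
  double m4 = accu(square(square(xc))) / N;
  s(pos++) = mu;
  s(pos++) = m2;
  s(pos++) = m2 > 0 ? m3 / std::pow(m2, 1.5) : datum::nan;
  s(pos++) = m2 > 0 ? m4 / (m2 * m2) : datum::nan;

  // ---- loss and error signal ----
  vec d = s - target;
  double loss = 0.0;
  vec e(ntot, fill::zeros);
  const int ng = gstart.n_elem;
  vec gerr(ng);
  for (int g = 0; g < ng; g++) {
    double sq = 0.0, tq = 0.0;
    for (int j = gstart(g); j <= gend(g); j++) {
      sq += d(j) * d(j);
      tq += target(j) * target(j);
      e(j) = 2.0 * d(j) / gden(g);
    }
    loss += sq / gden(g);
    gerr(g) = std::sqrt(sq) / (std::sqrt(tq) + gfloor);
  }
  // degenerate marginals: no gradient through NaN stats
  for (int j = 0; j < ntot; j++) if (!std::isfinite(e(j))) e(j) = 0.0;

  // ---- backward ----
  int p_lin = 0, p_mag = nlin, p_mcs = nlin + nmag;
  int p_mco = p_mcs + nmcs, p_phs = p_mco + nmco, p_bmm = p_phs + nphs;
  int p_mar = p_bmm + nbmm;

  std::vector<std::vector<cx_mat>> Gb(K), Gm(K);
  std::vector<std::vector<mat>> gms(K);
  std::vector<std::vector<cx_mat>> gbs(K);
  for (int k = 0; k < K; k++) {
    int nk = n / (1 << k);
    Gb[k].assign(O, cx_mat(nk, nk, fill::zeros));
    Gm[k].assign(O, cx_mat(nk, nk, fill::zeros));
    gms[k].assign(O, mat(nk, nk, fill::zeros));
    gbs[k].assign(O, cx_mat(nk, nk, fill::zeros));
  }

  // kernel spectrum for the autocorrelation gradient convolution
  auto acker_fft = [&](int k, const vec& ev) {
    int nk = n / (1 << k);
    mat kern(nk, nk, fill::zeros);
    for (int i = 0; i < no; i++) {
      kern(off_index(nk, off(i, 0), off(i, 1))) += ev(i);
      kern(off_index(nk, -off(i, 0), -off(i, 1))) += ev(i);
    }
    return fft2(kern);
  };

  // magnitude autocorrelation + band means + cross orientation
  int ico = p_mco;
  for (int k = 0; k < K; k++) {
    int nk = n / (1 << k); double Nk = (double)nk * nk;
    for (int o = 0; o < O; o++) {
      vec ev(no);
      bool nz = false;
      for (int i = 0; i < no; i++) {
        ev(i) = e(p_mag + ((k * O + o) * no) + i);
        nz = nz || ev(i) != 0.0;
      }
      if (nz) {
        Gm[k][o] += Mh[k][o] % acker_fft(k, ev) / Nk;
        gms[k][o] -= 2.0 * mu_m(k, o) * accu(ev) / Nk;
      }
      gms[k][o] += e(p_bmm + k * O + o) / Nk;
    }
    for (int o1 = 0; o1 < O - 1; o1++)
      for (int o2 = o1 + 1; o2 < O; o2++) {
        double ev = e(ico++);
        if (ev != 0.0) {
          gms[k][o1] += ev * (msp[k][o2] - mu_m(k, o2)) / Nk;
          gms[k][o2] += ev * (msp[k][o1] - mu_m(k, o1)) / Nk;
        }
      }
  }

  // cross-scale magnitude and phase
  for (int k = 0; k + 1 < K; k++) {
    int nf = n / (1 << k);
    double Nf = (double)nf * nf, Nc = (double)(nf / 2) * (nf / 2);
    for (int of = 0; of < O; of++) {
      mat gc_m(nf / 2, nf / 2, fill::zeros);
      cx_mat gc_b(nf / 2, nf / 2, fill::zeros);
      bool any_m = false, any_b = false;
      for (int oc = 0; oc < O; oc++) {
        double ev = e(p_mcs + ((k * O + of) * O) + oc);
        if (ev != 0.0) {
          gms[k + 1][oc] += ev * (dmf[k][of] / Nf - mu_m(k, of) / Nc);
          gms[k][of] -= ev * mu_m(k + 1, oc) / Nf;
          gc_m += ev * msp[k + 1][oc] / Nf;
          any_m = true;
        }
        double er = e(p_phs + (((k * O + of) * O) + oc) * 2);
        double ei = e(p_phs + (((k * O + of) * O) + oc) * 2 + 1);
        if (er != 0.0 || ei != 0.0) {
          std::complex<double> ez(er, ei);
          gc_b += ez * pdc[k][oc] / Nf;
          any_b = true;
          cx_mat gpd = std::conj(ez) * dbf[k][of] / Nf;
          const cx_mat& b = bsp[k + 1][oc];
          const mat& m = msp[k + 1][oc];
          cx_mat& acc = gbs[k + 1][oc];
          for (uword i = 0; i < b.n_elem; i++) {
            if (m(i) > 0) {
              std::complex<double> eit = b(i) / m(i);
              acc(i) += 1.5 * std::conj(eit) * gpd(i) -
                        0.5 * eit * eit * eit * std::conj(gpd(i));
            }
          }
        }
      }
      if (any_m) Gm[k][of] += 4.0 * spec_pad_idx(fft2(gc_m));
      if (any_b) Gb[k][of] += 4.0 * spec_pad_idx(fft2(gc_b));
    }
  }

  // adjoint pyramid recursion
  int nK = n / (1 << K);
  cx_mat Sadj(nK, nK, fill::zeros);
  for (int k = K - 1; k >= 0; k--) {
    int nk = n / (1 << k); double Nk = (double)nk * nk;
    Rcpp::List mk = masks[k];
    mat lo = Rcpp::as<mat>(mk["lo"]);
    mat hi = Rcpp::as<mat>(mk["hi"]);
    Rcpp::List ang = mk["ang"];
    Sadj = spec_pad(Sadj); rmul_inplace(Sadj, lo);
    double w = std::pow(4.0, -k);
    cx_mat Tacc(nk, nk, fill::zeros);
    for (int o = 0; o < O; o++) {
      mat gm = real(ifft2(Gm[k][o])) + gms[k][o];
      cx_mat gb = gbs[k][o];
      const cx_mat& b = bsp[k][o];
      const mat& m = msp[k][o];
      for (uword i = 0; i < b.n_elem; i++)
        if (m(i) > 0) gb(i) += gm(i) * b(i) / m(i);
      cx_mat Gf = fft2(gb) + Gb[k][o];
      mat a = Rcpp::as<mat>(ang[o]);
      Tacc += rmul(Gf, a);
    }
    rmul_inplace(Tacc, hi); Tacc *= w;
    Sadj += (Tacc + conj(flip_freq(Tacc))) / 2.0;
    vec ev(no);
    bool nz = false;
    for (int i = 0; i < no; i++) {
      ev(i) = e(p_lin + k * no + i);
      nz = nz || ev(i) != 0.0;
    }
    if (nz) {
      cx_mat Gp = S[k] % acker_fft(k, ev) / Nk;
      Gp(0, 0) -= 2.0 * mu_p(k) * accu(ev);
      Sadj += Gp * w;
    }
  }
  rmul_inplace(Sadj, lo0);
  mat gx = real(ifft2(Sadj));

  // marginal gradients
  double e_mean = e(p_mar), e_var = e(p_mar + 1);
  double e_skew = e(p_mar + 2), e_kurt = e(p_mar + 3);
  if (e_mean != 0 || e_var != 0 || e_skew != 0 || e_kurt != 0) {
    gx += e_mean / N;
    mat d2 = 2.0 * xc / N;
    gx += e_var * d2;
    if (m2 > 0) {
      mat d3 = (3.0 / N) * (square(xc) - m2);
      mat d4 = (4.0 / N) * (pow(xc, 3) - m3);
      gx += e_skew * (d3 / std::pow(m2, 1.5) -
                      1.5 * m3 / std::pow(m2, 2.5) * d2);
      gx += e_kurt * (d4 / (m2 * m2) - 2.0 * m4 / std::pow(m2, 3) * d2);
    }
  }

  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = gx,
                            Rcpp::Named("stats") = s,
                            Rcpp::Named("group_err") = gerr);
}
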