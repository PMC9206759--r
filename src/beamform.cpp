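// Compiled kernels for the STA pipeline: point-scatterer simulation,
// delay-compensated receive synthesis, and the per-pixel beamformers.
// Per-pixel results are pure functions of their inputs; loops are plain
// serial so output is independent of evaluation order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Gaussian-enveloped cosine echoes summed per (tx, rx) trace.
// pos: S x 3 scatterer positions (m); amp: length S; elem_x: length N.
// Returns cube (n_samp, N_rx, N_tx); reciprocity rf[i][j] == rf[j][i].
// [[Rcpp::export]]
arma::cube sim_sta_cpp(const arma::mat& pos, const arma::vec& amp,
                       const arma::vec& elem_x, double fs, double t0,
                       int n_samp, double c, double f0, double bw_frac,
                       bool spreading, int oversamp) {
  const int N = elem_x.n_elem;
  const int S = pos.n_rows;
  const double sigma_f = bw_frac * f0 / (2.0 * std::sqrt(2.0 * std::log(2.0)));
  const double sigma_t = 1.0 / (2.0 * datum::pi * sigma_f);
  const double half = 4.0 * sigma_t;

  // oversampled pulse table on [-half, half]
  const double dtab = 1.0 / (fs * oversamp);
  const int n_tab = (int)std::ceil(2.0 * half / dtab) + 2;
  vec tab(n_tab);
  for (int k = 0; k < n_tab; ++k) {
    double t = -half + k * dtab;
    tab(k) = std::exp(-t * t / (2.0 * sigma_t * sigma_t)) *
             std::cos(2.0 * datum::pi * f0 * t);
  }

  // element-to-scatterer distances
  mat D(N, S);
  for (int s = 0; s < S; ++s) {
    double px = pos(s, 0), py = pos(s, 1), pz = pos(s, 2);
    for (int i = 0; i < N; ++i) {
      double dx = elem_x(i) - px;
      D(i, s) = std::sqrt(dx * dx + py * py + pz * pz);
    }
  }

  cube out(n_samp, N, N, fill::zeros);  // (t, rx, tx)
  const double inv_c = 1.0 / c;
  for (int i = 0; i < N; ++i) {
    for (int j = i; j < N; ++j) {
      double* tr = out.slice(i).colptr(j);
      for (int s = 0; s < S; ++s) {
        double d1 = D(i, s), d2 = D(j, s);
        double tau = (d1 + d2) * inv_c;
        double a = spreading ? amp(s) / (d1 * d2) : amp(s);
        int k0 = (int)std::ceil(((tau - half) - t0) * fs);
        int k1 = (int)std::floor(((tau + half) - t0) * fs);
        if (k0 < 0) k0 = 0;
        if (k1 > n_samp - 1) k1 = n_samp - 1;
        for (int k = k0; k <= k1; ++k) {
          double tt = t0 + k / fs - tau;          // in [-half, half]
          double u = (tt + half) / dtab;
          int m = (int)u;
          if (m < 0 || m >= n_tab - 1) continue;
          double fr = u - m;
          tr[k] += a * (tab(m) + fr * (tab(m + 1) - tab(m)));
        }
      }
      if (j != i) out.slice(j).col(i) = out.slice(i).col(j);
    }
  }
  return out;
}

// Receive-synthesized analytic aperture vectors for every grid pixel.
// data: complex cube (T, rx, tx); px, pz: grid axes; rxw: base receive
// window (used when f_number <= 0); window_type 0 = rectangular, 1 = hamming
// (built over the active run when f_number > 0).
// Returns A (N x Pz*Px, axial index fastest) and the zero-fill count.
// [[Rcpp::export]]
Rcpp::List afield_cpp(const arma::cx_cube& data, const arma::vec& elem_x,
                      double fs, double t0, double c,
                      const arma::vec& px, const arma::vec& pz,
                      const arma::vec& rxw, double f_number,
                      int window_type) {
  const int N = elem_x.n_elem;
  const int T = data.n_rows;
  const int Pz = pz.n_elem, Px = px.n_elem;
  cx_mat A(N, (size_t)Pz * Px, fill::zeros);
  long long n_zero = 0;
  vec d(N), w(N);

  for (int ix = 0; ix < Px; ++ix) {
    double x = px(ix);
    for (int iz = 0; iz < Pz; ++iz) {
      double z = pz(iz);
      size_t p = (size_t)ix * Pz + iz;
      for (int k = 0; k < N; ++k) {
        double dx = elem_x(k) - x;
        d(k) = std::sqrt(dx * dx + z * z);
      }
      if (f_number > 0) {
        // active run and window over it
        double lim = z / (2.0 * f_number);
        int first = -1, last = -1;
        for (int k = 0; k < N; ++k)
          if (std::abs(elem_x(k) - x) <= lim) { if (first < 0) first = k; last = k; }
        w.zeros();
        if (first >= 0) {
          int m = last - first + 1;
          for (int k = 0; k < m; ++k)
            w(first + k) = (window_type == 1 && m > 1)
              ? 0.54 - 0.46 * std::cos(2.0 * datum::pi * k / (m - 1))
              : 1.0;
        }
      } else {
        w = rxw;
      }
      for (int i = 0; i < N; ++i) {
        std::complex<double> acc(0.0, 0.0);
        for (int j = 0; j < N; ++j) {
          if (w(j) == 0.0) continue;
          double s = ((d(i) + d(j)) / c - t0) * fs;   // 0-based index
          int k0 = (int)std::floor(s);
          if (k0 < 0 || k0 > T - 2) { ++n_zero; continue; }
          double fr = s - k0;
          const std::complex<double>* v = data.slice(i).colptr(j);
          acc += w(j) * (v[k0] + fr * (v[k0 + 1] - v[k0]));
        }
        A(i, p) = acc;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("A") = A,
                            Rcpp::Named("n_zero_filled") = (double)n_zero);
}

// Non-adaptive per-pixel pass: DAS, CF, GCF, aperture ASD.
// [[Rcpp::export]]
Rcpp::List pass1_cpp(const arma::cx_mat& A, const arma::vec& txw, int M0) {
  const int N = A.n_rows;
  const size_t P = A.n_cols;
  cx_vec das(P);
  vec cf(P), gcf(P), sigma(P);
  std::vector<int> bins;
  for (int k = -M0; k <= M0; ++k) {
    int b = ((k % N) + N) % N;
    if (std::find(bins.begin(), bins.end(), b) == bins.end()) bins.push_back(b);
  }
  for (size_t p = 0; p < P; ++p) {
    cx_vec x = A.col(p);
    das(p) = accu(txw % x);
    double den = accu(square(abs(x)));
    std::complex<double> sm = accu(x);
    cf(p) = den == 0.0 ? 0.0 : std::min(1.0, std::norm(sm) / (N * den));
    cx_vec s = fft(x);
    vec s2 = square(abs(s)) / N;
    double tot = accu(s2);
    double num = 0.0;
    for (int b : bins) num += s2(b);
    gcf(p) = tot == 0.0 ? 0.0 : std::min(1.0, num / tot);
    std::complex<double> mu = sm / (double)N;
    sigma(p) = std::sqrt(accu(square(abs(x - mu))) / N);
  }
  return Rcpp::List::create(Rcpp::Named("das") = das, Rcpp::Named("cf") = cf,
                            Rcpp::Named("gcf") = gcf,
                            Rcpp::Named("sigma") = sigma);
}

static double msr_real(const cx_mat& M, double cap) {
  mat v = real(M);
  double m = accu(v) / v.n_elem;
  double s = std::sqrt(accu(square(v - m)) / v.n_elem);
  if (s <= 1e-12 * std::abs(m)) return m == 0.0 ? 0.0 : cap;
  return m / s;
}

// printed four-term rotary average: (R + J R^T + J R J + R^T J) / 4
static cx_mat rotary_printed(const cx_mat& R) {
  cx_mat Rt = R.st();
  return 0.25 * (R + flipud(Rt) + flipud(fliplr(R)) + fliplr(Rt));
}

static cx_mat rotary_fb(const cx_mat& R) {
  return 0.5 * (R + flipud(fliplr(conj(R))));
}

// Adaptive per-pixel pass: MV, ESBMV, CMSF and CMSAW weights.
// A: aperture vectors (N x Pz*Px, axial fastest); sigma_prime, cf: per pixel.
// Temporal window shrinks symmetrically at axial edges.
// [[Rcpp::export]]
Rcpp::List pass2_cpp(const arma::cx_mat& A, int Pz, int Px,
                     const arma::vec& sigma_prime, const arma::vec& cf,
                     int L, int K, double delta_load, double gamma_thr,
                     int L_max, double delta_cmsf, double delta_max,
                     double msr_cap, bool printed_rotary,
                     bool do_esbmv, bool do_cmsf, bool do_cmsaw) {
  const int N = A.n_rows;
  const size_t P = (size_t)Pz * Px;
  const int ns = N - L + 1;
  cx_vec mv(P, fill::zeros), esbmv(P, fill::zeros);
  vec wcmsf(P, fill::zeros), wcmsaw(P, fill::zeros);
  vec lp_map(P, fill::zeros), dac_map(P, fill::zeros);
  long long n_fallback = 0, n_clamped = 0, n_capped = 0;
  cx_vec ones_v(L, fill::ones);

  for (int ix = 0; ix < Px; ++ix) {
    for (int iz = 0; iz < Pz; ++iz) {
      size_t p = (size_t)ix * Pz + iz;
      int kmax = std::min(K, std::min(iz, Pz - 1 - iz));
      int nt = 2 * kmax + 1;
      cx_mat S(L, (size_t)nt * ns);
      size_t col = 0;
      for (int k = -kmax; k <= kmax; ++k) {
        const cx_vec xk = A.col(p + k);
        for (int l = 0; l < ns; ++l, ++col)
          S.col(col) = xk.subvec(l, l + L - 1);
      }
      cx_mat R = (S * S.t()) / (double)(nt * ns);
      double tr = std::real(trace(R));
      cx_mat Rhat = R;
      Rhat.diag() += delta_load * tr;

      cx_vec sol;
      bool ok = solve(sol, Rhat, ones_v, solve_opts::no_approx);
      cx_vec w;
      if (!ok || !sol.is_finite()) {
        w = ones_v / (double)L;
        ++n_fallback;
      } else {
        w = sol / accu(sol);
      }
      const cx_vec x = A.col(p);
      cx_vec mbar(L, fill::zeros);
      for (int l = 0; l < ns; ++l) mbar += x.subvec(l, l + L - 1);
      mbar /= (double)ns;
      mv(p) = cdot(w, mbar);

      if (do_esbmv) {
        vec eval;
        cx_mat evec;
        if (eig_sym(eval, evec, Rhat)) {      // ascending
          double lmax = eval(L - 1);
          int first = L - 1;
          while (first > 0 && eval(first - 1) >= gamma_thr * lmax) --first;
          if (first == 0) {
            esbmv(p) = mv(p);                  // full subspace: projector = I
          } else {
            cx_mat Es = evec.cols(first, L - 1);
            cx_vec wes = Es * (Es.t() * w);
            esbmv(p) = cdot(wes, mbar);
          }
        } else {
          esbmv(p) = mv(p);
          ++n_fallback;
        }
      }

      if (do_cmsf || do_cmsaw) {
        double sp = sigma_prime(p);
        int Lp = (int)std::floor(sp * L_max);
        if (Lp < 2) { Lp = 2; ++n_clamped; }
        lp_map(p) = Lp;
        int nsp = N - Lp + 1;
        cx_mat Sp(Lp, nsp);
        for (int l = 0; l < nsp; ++l) Sp.col(l) = x.subvec(l, l + Lp - 1);
        cx_mat Rc = (Sp * Sp.t()) / (double)nsp;
        cx_mat Rr = printed_rotary ? rotary_printed(Rc) : rotary_fb(Rc);
        if (do_cmsf) {
          cx_mat M = Rr;
          M.diag() -= delta_cmsf * Rr.diag();
          double v = msr_real(M, msr_cap);
          if (v == msr_cap) ++n_capped;
          wcmsf(p) = v;
        }
        if (do_cmsaw) {
          double wcf = cf(p);
          double dac = wcf <= 0.0 ? 0.0
            : std::pow(wcf, std::max(sp, 1e-6)) * delta_max;
          dac_map(p) = dac;
          cx_mat M = Rr;
          M.diag() -= dac * Rr.diag();
          double v = msr_real(M, msr_cap);
          if (v == msr_cap) ++n_capped;
          wcmsaw(p) = v;
        }
      }
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("mv") = mv, Rcpp::Named("esbmv") = esbmv,
    Rcpp::Named("w_cmsf") = wcmsf, Rcpp::Named("w_cmsaw") = wcmsaw,
    Rcpp::Named("l_prime") = lp_map, Rcpp::Named("delta_ac") = dac_map,
    Rcpp::Named("n_solve_fallback") = (double)n_fallback,
    Rcpp::Named("n_lprime_clamped") = (double)n_clamped,
    Rcpp::Named("n_msr_capped") = (double)n_capped);
}
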