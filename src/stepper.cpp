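// Core time integrators.
//
// pf_run: phase-field model on a periodic grid.  The state is the triplet of
// weighted fields (B*u, phi*v, phi*f).  Weighted diffusion D div(w grad c),
// c = W / max(w, floor), is integrated with a conservative centered flux form
// sub-stepped to its explicit stability limit; because the face weights
// vanish outside the cell support, no mass leaks out of the cell and the
// total of each weighted field is conserved exactly by the diffusion terms.
// When a field's weight is spatially uniform the operator is constant-
// coefficient and is instead advanced with the exponential Fourier-spectral
// factor exp(-D k^2 dt), which is exact per mode.  Reactions are explicit.
//
// trad_run: flat 2D model (membrane overlaps cytosol) on a binary disk mask
// with the same conservative zero-flux flux form.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat hill2(const mat& x, double K) {
  mat x2 = square(x);
  return x2 / (x2 + K * K);
}

// conservative divergence of w * grad(c) with periodic wrap, arithmetic face
// mean of w; second order, sums to zero exactly over the grid
static mat div_w_grad(const mat& w, const mat& c, double h) {
  const uword n = w.n_rows, m = w.n_cols;
  mat out(n, m);
  const double h2 = h * h;
  for (uword j = 0; j < m; ++j) {
    uword jp = (j + 1) % m, jm = (j + m - 1) % m;
    for (uword i = 0; i < n; ++i) {
      uword ip = (i + 1) % n, im = (i + n - 1) % n;
      double fE = 0.5 * (w(i, jp) + w(i, j)) * (c(i, jp) - c(i, j));
      double fW = 0.5 * (w(i, j) + w(i, jm)) * (c(i, j) - c(i, jm));
      double fS = 0.5 * (w(ip, j) + w(i, j)) * (c(ip, j) - c(i, j));
      double fN = 0.5 * (w(i, j) + w(im, j)) * (c(i, j) - c(im, j));
      out(i, j) = (fE - fW + fS - fN) / h2;
    }
  }
  return out;
}

// masked divergence with min-face weights: no flux crosses a binary mask
// boundary (zero-flux), so the masked totals are conserved exactly
static mat div_w_grad_min(const mat& w, const mat& c, double h) {
  const uword n = w.n_rows, m = w.n_cols;
  mat out(n, m);
  const double h2 = h * h;
  for (uword j = 0; j < m; ++j) {
    uword jp = (j + 1) % m, jm = (j + m - 1) % m;
    for (uword i = 0; i < n; ++i) {
      uword ip = (i + 1) % n, im = (i + n - 1) % n;
      double fE = std::min(w(i, jp), w(i, j)) * (c(i, jp) - c(i, j));
      double fW = std::min(w(i, j), w(i, jm)) * (c(i, j) - c(i, jm));
      double fS = std::min(w(ip, j), w(i, j)) * (c(ip, j) - c(i, j));
      double fN = std::min(w(i, j), w(im, j)) * (c(i, j) - c(im, j));
      out(i, j) = (fE - fW + fS - fN) / h2;
    }
  }
  return out;
}

// one weighted-diffusion macro step of length dt, sub-stepped for stability
static void diffuse_weighted(mat& W, const mat& w, const mat& wt,
                             double D, double dt, double h, double cfl) {
  if (D <= 0.0) return;
  int nsub = std::max(1, (int)std::ceil(dt * D / (cfl * h * h)));
  const double dts = dt / nsub;
  for (int q = 0; q < nsub; ++q)
    W += dts * D * div_w_grad(w, W / wt, h);
}

// exact spectral diffusion update for a uniform weight
static void diffuse_spectral(mat& W, const mat& E) {
  const uword N = W.n_rows;
  cx_mat H = fft2(cx_mat(W, zeros<mat>(N, N)));
  W = real(ifft2(cx_mat(E % real(H), E % imag(H))));
}

static bool is_uniform(const mat& w) {
  return (w.max() - w.min()) < 1e-12;
}

// [[Rcpp::export(name = ".pf_run_cpp")]]
Rcpp::List pf_run(const arma::mat& Wu0, const arma::mat& Wv0, const arma::mat& Wf0,
                  const arma::mat& wu, const arma::mat& phi, const arma::mat& gphi,
                  const arma::mat& Bt, const arma::mat& phit,
                  const arma::mat& ks,
                  const arma::mat& xc, const arma::mat& yc,
                  Rcpp::List par,
                  double dt, int nsteps, double h, double dA,
                  int record_every,
                  double mt_override,       // < 0 : dynamic mt(f)
                  bool matched_measure,
                  int snap_every,           // 0 : no field snapshots
                  double stab) {            // CFL safety divisor (>= 1)
  const double Du = par["D_u"], Dv = par["D_v"], Df = par["D_f"];
  const double b = par["b"], r = par["r"];
  const double c1 = par["c1"], c2 = par["c2"], c3 = par["c3"];
  const double K1 = par["K1"], K2 = par["K2"], K3 = par["K3"];
  const double df = par["d_f"], mt0 = par["mt0"], lam = par["lam"], KF = par["K_F"];
  const double cfl = 0.2 / stab;

  const uword N = Wu0.n_rows;
  const bool spec_u = is_uniform(wu), spec_v = is_uniform(phi),
             spec_f = is_uniform(phi);

  // spectral decay factors (only used on uniform-weight fields)
  mat Eu, Ev, Ef;
  if (spec_u || spec_v || spec_f) {
    const double L = h * static_cast<double>(N);
    vec k1(N);
    for (uword i = 0; i < N; ++i) {
      double ki = (i <= N / 2) ? (double)i : (double)i - (double)N;
      k1(i) = 2.0 * M_PI * ki / L;
    }
    mat ksq(N, N);
    for (uword j = 0; j < N; ++j)
      for (uword i = 0; i < N; ++i)
        ksq(i, j) = k1(i) * k1(i) + k1(j) * k1(j);
    Eu = exp(-dt * Du * ksq);
    Ev = exp(-dt * Dv * ksq);
    Ef = exp(-dt * Df * ksq);
  }

  const mat& w_u_exch = wu;                          // u-side exchange weight
  const mat& w_v_exch = matched_measure ? wu : gphi; // matched: exact conservation

  // membrane support for max-u reporting
  umat memmask = wu > (wu.max() * 1e-3);

  const int nrec = nsteps / record_every + 2;
  mat rec(nrec, 10);
  int irec = 0;
  long clipped = 0;

  int nsnap = (snap_every > 0) ? (nsteps / snap_every + 1) : 0;
  cube snap_u, snap_f;
  vec snap_t;
  if (nsnap > 0) {
    snap_u.set_size(N, N, nsnap);
    snap_f.set_size(N, N, nsnap);
    snap_t.set_size(nsnap);
  }
  int isnap = 0;

  mat Wu = Wu0, Wv = Wv0, Wf = Wf0;
  double mt = 0.0;

  for (int s = 0; s <= nsteps; ++s) {
    mat u = Wu / Bt, v = Wv / phit, f = Wf / phit;
    // clip negative concentrations for reaction evaluation (positivity guard)
    clipped += accu(u < -1e-12) + accu(v < -1e-12) + accu(f < -1e-12);
    mat ur = clamp(u, 0.0, datum::inf);
    mat vr = clamp(v, 0.0, datum::inf);
    mat fr = clamp(f, 0.0, datum::inf);

    double ftot = accu(phi % fr) * dA;
    mt = (mt_override >= 0.0) ? mt_override : mt0 * (1.0 + lam * ftot);

    if (s % record_every == 0 || s == nsteps) {
      double maxu = ur.elem(find(memmask)).max();
      rec(irec, 0) = dt * s;
      rec(irec, 1) = maxu;
      rec(irec, 2) = accu(Wu) * dA;            // total Rac-GTP (membrane mass)
      rec(irec, 3) = ftot;                     // total F-actin
      rec(irec, 4) = mt;
      rec(irec, 5) = accu(wu % ur % xc) * dA;  // polarity moment components
      rec(irec, 6) = accu(wu % ur % yc) * dA;
      rec(irec, 7) = accu(Wu) * dA;            // membrane Rac mass  (int wu u)
      rec(irec, 8) = accu(Wv) * dA;            // cytosolic Rac mass (int phi v)
      rec(irec, 9) = static_cast<double>(clipped);
      ++irec;
    }
    if (nsnap > 0 && (s % snap_every == 0) && isnap < nsnap) {
      snap_u.slice(isnap) = ur;
      snap_f.slice(isnap) = fr;
      snap_t(isnap) = dt * s;
      ++isnap;
    }
    if (s == nsteps) break;

    mat prodr = b + c1 * hill2(ur, K1) + c2 * hill2(fr, K2) + ks; // activation
    mat X = prodr % vr - r * ur;                                  // net GDP->GTP
    mat Rf_w = gphi % (c3 * hill2(ur, K3) * (KF / (KF + mt))) - phi % (df * fr);

    // diffusion
    if (spec_u) diffuse_spectral(Wu, Eu);
    else diffuse_weighted(Wu, wu, Bt, Du, dt, h, cfl);
    if (spec_v) diffuse_spectral(Wv, Ev);
    else diffuse_weighted(Wv, phi, phit, Dv, dt, h, cfl);
    if (spec_f) diffuse_spectral(Wf, Ef);
    else diffuse_weighted(Wf, phi, phit, Df, dt, h, cfl);

    // reactions
    Wu += dt * (w_u_exch % X);
    Wv -= dt * (w_v_exch % X);
    Wf += dt * Rf_w;

    if (!Wu.is_finite() || !Wv.is_finite() || !Wf.is_finite())
      Rcpp::stop("integration failure: non-finite field at step %d (t = %g)",
                 s + 1, dt * (s + 1));
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("metrics") = rec.rows(0, irec - 1),
    Rcpp::Named("Wu") = Wu, Rcpp::Named("Wv") = Wv, Rcpp::Named("Wf") = Wf,
    Rcpp::Named("mt") = mt,
    Rcpp::Named("clipped") = static_cast<double>(clipped));
  if (nsnap > 0) {
    out["snap_u"] = cube(snap_u.slices(0, isnap - 1));
    out["snap_f"] = cube(snap_f.slices(0, isnap - 1));
    out["snap_t"] = vec(snap_t.subvec(0, isnap - 1));
  }
  return out;
}

// [[Rcpp::export(name = ".trad_run_cpp")]]
Rcpp::List trad_run(const arma::mat& u0, const arma::mat& v0, const arma::mat& f0,
                    const arma::mat& mask,
                    const arma::mat& ks,
                    const arma::mat& xc, const arma::mat& yc,
                    Rcpp::List par,
                    double dt, int nsteps, double h, double dA,
                    int record_every,
                    double mt_override,
                    int snap_every) {
  const double Du = par["D_u"], Dv = par["D_v"], Df = par["D_f"];
  const double b = par["b"], r = par["r"];
  const double c1 = par["c1"], c2 = par["c2"], c3 = par["c3"];
  const double K1 = par["K1"], K2 = par["K2"], K3 = par["K3"];
  const double df = par["d_f"], mt0 = par["mt0"], lam = par["lam"];
  const double delta = par["delta"], kBT = par["kBT"];
  const double c3f = par.containsElementNamed("c3_flat") ? double(par["c3_flat"]) : c3;

  const uword N = u0.n_rows;
  mat u = u0, v = v0, f = f0;
  umat inmask = mask > 0.5;

  // explicit diffusion sub-stepping (stability limit dt_sub <= 0.2 h^2 / D)
  auto nsub_for = [&](double D) {
    if (D <= 0.0) return 1;
    int m = static_cast<int>(std::ceil(dt / (0.2 * h * h / D)));
    return std::max(1, m);
  };
  const int nsu = nsub_for(Du), nsv = nsub_for(Dv), nsf = nsub_for(Df);

  const int nrec = nsteps / record_every + 2;
  mat rec(nrec, 10);
  int irec = 0;
  long clipped = 0;
  double mt = 0.0;

  int nsnap = (snap_every > 0) ? (nsteps / snap_every + 1) : 0;
  cube snap_u, snap_f;
  vec snap_t;
  if (nsnap > 0) {
    snap_u.set_size(N, N, nsnap);
    snap_f.set_size(N, N, nsnap);
    snap_t.set_size(nsnap);
  }
  int isnap = 0;

  for (int s = 0; s <= nsteps; ++s) {
    clipped += accu(u < -1e-12) + accu(v < -1e-12) + accu(f < -1e-12);
    u = clamp(u, 0.0, datum::inf) % mask;
    v = clamp(v, 0.0, datum::inf) % mask;
    f = clamp(f, 0.0, datum::inf) % mask;

    double ftot = accu(f) * dA;
    mt = (mt_override >= 0.0) ? mt_override : mt0 * (1.0 + lam * ftot);

    if (s % record_every == 0 || s == nsteps) {
      rec(irec, 0) = dt * s;
      rec(irec, 1) = u.elem(find(inmask)).max();
      rec(irec, 2) = accu(u) * dA;
      rec(irec, 3) = ftot;
      rec(irec, 4) = mt;
      rec(irec, 5) = accu(u % xc) * dA;
      rec(irec, 6) = accu(u % yc) * dA;
      rec(irec, 7) = accu(u) * dA;
      rec(irec, 8) = accu(v) * dA;
      rec(irec, 9) = static_cast<double>(clipped);
      ++irec;
    }
    if (nsnap > 0 && (s % snap_every == 0) && isnap < nsnap) {
      snap_u.slice(isnap) = u;
      snap_f.slice(isnap) = f;
      snap_t(isnap) = dt * s;
      ++isnap;
    }
    if (s == nsteps) break;

    mat prod = b + c1 * hill2(u, K1) + c2 * hill2(f, K2) + ks;
    mat X = prod % v - r * u;
    double ratchet = std::exp(-mt * delta / kBT);
    mat Rf = c3f * hill2(u, K3) * ratchet - df * f;

    // diffusion (sub-stepped), then reactions
    for (int q = 0; q < nsu; ++q) u += (dt / nsu) * Du * div_w_grad_min(mask, u, h);
    for (int q = 0; q < nsv; ++q) v += (dt / nsv) * Dv * div_w_grad_min(mask, v, h);
    for (int q = 0; q < nsf; ++q) f += (dt / nsf) * Df * div_w_grad_min(mask, f, h);
    u += dt * (X % mask);
    v -= dt * (X % mask);
    f += dt * (Rf % mask);

    if (!u.is_finite() || !v.is_finite() || !f.is_finite())
      Rcpp::stop("integration failure: non-finite field at step %d (t = %g)",
                 s + 1, dt * (s + 1));
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("metrics") = rec.rows(0, irec - 1),
    Rcpp::Named("u") = u, Rcpp::Named("v") = v, Rcpp::Named("f") = f,
    Rcpp::Named("mt") = mt,
    Rcpp::Named("clipped") = static_cast<double>(clipped));
  if (nsnap > 0) {
    out["snap_u"] = cube(snap_u.slices(0, isnap - 1));
    out["snap_f"] = cube(snap_f.slices(0, isnap - 1));
    out["snap_t"] = vec(snap_t.subvec(0, isnap - 1));
  }
  return out;
}
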