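// Compiled GPSR core for the three-dictionary sparse component analysis.
//
// Coefficient layout (must match the R-side dictionary stack):
//   [ nuclei: h*w | muscle DCT: h*w | adipose: nw wedge subbands of p*p ]
// all column-major. The curvelet windows are symmetric under frequency
// negation, so each wedge subband of a real image is real.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Ops {
  uword h, w, p, nw, m;
  const cube &win;
  const uvec &dec;     // per-window spectrum fold factor
  const mat &Dr, &Dc;  // orthonormal DCT-II matrices (rows, cols)
  uvec off, grid;      // per-window coefficient offset and grid size

  Ops(uword h_, uword w_, const cube &win_, const uvec &dec_,
      const mat &Dr_, const mat &Dc_)
      : h(h_), w(w_), p(win_.n_rows), nw(win_.n_slices), win(win_),
        dec(dec_), Dr(Dr_), Dc(Dc_) {
    off.set_size(nw);
    grid.set_size(nw);
    uword pos = 2 * h * w;
    for (uword s = 0; s < nw; s++) {
      grid(s) = p / dec(s);
      off(s) = pos;
      pos += grid(s) * grid(s);
    }
    m = pos;
  }

  // fold a p x p spectrum onto a q x q grid (aliasing-free by window
  // construction); unfold replicates it back
  static cx_mat fold(const cx_mat &M, uword D) {
    if (D == 1) return M;
    uword q = M.n_rows / D;
    cx_mat out(q, q, fill::zeros);
    for (uword a = 0; a < D; a++)
      for (uword b = 0; b < D; b++)
        out += M.submat(a * q, b * q, (a + 1) * q - 1, (b + 1) * q - 1);
    return out;
  }
  static cx_mat unfold(const cx_mat &M, uword D) {
    if (D == 1) return M;
    return repmat(M, D, D);
  }

  // A theta: synthesize the image-domain sum of the three components.
  mat synth(const vec &theta) const {
    mat out(h, w);
    std::memcpy(out.memptr(), theta.memptr(), h * w * sizeof(double));
    mat dctc(theta.memptr() + h * w, h, w);
    out += Dr.t() * dctc * Dc;
    cx_mat Z(p, p, fill::zeros);
    for (uword s = 0; s < nw; s++) {
      uword q = grid(s);
      cx_mat cw(mat(theta.memptr() + off(s), q, q),
                mat(q, q, fill::zeros));
      Z += unfold(fft2(cw) / (double)q, dec(s)) % win.slice(s);
    }
    cx_mat back = ifft2(Z) * (double)p;
    out += real(back.submat(0, 0, h - 1, w - 1));
    return out;
  }

  // A' r: stack the adjoints (pixel, DCT analysis, wedge analysis).
  void analyze(const mat &r, vec &g) const {
    std::memcpy(g.memptr(), r.memptr(), h * w * sizeof(double));
    mat d = Dr * r * Dc.t();
    std::memcpy(g.memptr() + h * w, d.memptr(), h * w * sizeof(double));
    cx_mat pad(p, p, fill::zeros);
    pad.submat(0, 0, h - 1, w - 1) = cx_mat(r, mat(h, w, fill::zeros));
    cx_mat X = fft2(pad) / (double)p;
    for (uword s = 0; s < nw; s++) {
      uword q = grid(s);
      cx_mat cw = ifft2(fold(X % win.slice(s), dec(s))) * (double)q;
      mat re = real(cw);
      std::memcpy(g.memptr() + off(s), re.memptr(), q * q * sizeof(double));
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".gpsr_core")]]
Rcpp::List gpsr_core(const arma::mat &y, const arma::cube &windows,
                     const arma::uvec &decimation,
                     const arma::mat &Dr, const arma::mat &Dc,
                     const arma::vec &tau_seg, const arma::uvec &seg_len,
                     int max_iterations, double rel_tolerance, bool bb) {
  Ops A(y.n_rows, y.n_cols, windows, decimation, Dr, Dc);
  const uword m = A.m;
  vec tau(m);
  uword pos = 0;
  for (uword k = 0; k < seg_len.n_elem; k++) {
    tau.subvec(pos, pos + seg_len(k) - 1).fill(tau_seg(k));
    pos += seg_len(k);
  }

  vec u(m, fill::zeros), v(m, fill::zeros);
  vec g(m), du(m), dv(m), d(m);
  mat resid = -y;  // A(u - v) - y at the zero initializer
  A.analyze(resid, g);
  double obj = 0.5 * accu(resid % resid);
  std::vector<double> trace{obj};
  double alpha = 1.0;
  bool converged = false;

  for (int it = 0; it < max_iterations; it++) {
    double taudot = 0.0, maxstep = 0.0;
    for (uword i = 0; i < m; i++) {
      double dui = std::max(u(i) - alpha * (g(i) + tau(i)), 0.0) - u(i);
      double dvi = std::max(v(i) - alpha * (-g(i) + tau(i)), 0.0) - v(i);
      du(i) = dui; dv(i) = dvi; d(i) = dui - dvi;
      taudot += tau(i) * (dui + dvi);
      maxstep = std::max(maxstep, std::max(std::fabs(dui), std::fabs(dvi)));
    }
    if (maxstep == 0.0) { converged = true; break; }
    mat Ad = A.synth(d);
    double quad = accu(Ad % Ad);
    double slope = accu(resid % Ad) + taudot;
    double lambda = quad > 0 ? std::min(std::max(-slope / quad, 0.0), 1.0)
                             : (slope < 0 ? 1.0 : 0.0);
    if (lambda == 0.0) { converged = true; break; }
    double s_norm = 0.0, l1 = 0.0;
    for (uword i = 0; i < m; i++) {
      double ui = u(i) + lambda * du(i);
      double vi = v(i) + lambda * dv(i);
      double ov = std::min(ui, vi);  // shrink: keep u, v complementary
      if (ov > 0) { ui -= ov; vi -= ov; }
      u(i) = ui; v(i) = vi;
      s_norm += lambda * lambda * (du(i) * du(i) + dv(i) * dv(i));
      l1 += tau(i) * (ui + vi);
    }
    resid += lambda * Ad;
    vec g_new(m);
    A.analyze(resid, g_new);
    if (bb) {
      double sy = lambda * dot(d, g_new - g);
      alpha = sy > 0 ? std::min(std::max(s_norm / sy, 1e-6), 1e6) : 1e6;
    }
    g = g_new;
    double obj_new = 0.5 * accu(resid % resid) + l1;
    trace.push_back(obj_new);
    bool done = std::fabs(obj - obj_new) <=
                rel_tolerance * std::max(obj, 1e-12);
    obj = obj_new;
    if (done) { converged = true; break; }
  }

  vec theta = u - v;
  return Rcpp::List::create(
      Rcpp::Named("theta") = Rcpp::NumericVector(theta.begin(), theta.end()),
      Rcpp::Named("trace") = trace,
      Rcpp::Named("converged") = converged);
}
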