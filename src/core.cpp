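// Compiled inner loops of the imaging model: bead-model projection, CTF
// filtering, and the pose-marginalized image likelihood. Conventions are
// shared with the R reference implementations (see R/forward.R and
// R/likelihood.R); the R side is the documentation of record.
//
// FFTs go through FFTW (double precision, cached plans, single threaded);
// round-2 correlations are evaluated in Fourier space so no inverse
// transforms are needed in the refinement inner loop.

#include <RcppArmadillo.h>
#include <fftw3.h>
#include <complex>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double ELECTRON_WAVELENGTH_A = 0.0197;  // 300 keV

// ---------------------------------------------------------------- FFT cache

struct FftPlans {
  fftw_complex *buf_in, *buf_out;
  fftw_plan fwd, bwd;
};

// one persistent in/out buffer + plan pair per box size (single threaded)
static FftPlans &fft_plans(int n) {
  static std::unordered_map<int, FftPlans> cache;
  auto it = cache.find(n);
  if (it != cache.end()) return it->second;
  FftPlans p;
  p.buf_in = fftw_alloc_complex(n * n);
  p.buf_out = fftw_alloc_complex(n * n);
  p.fwd = fftw_plan_dft_2d(n, n, p.buf_in, p.buf_out, FFTW_FORWARD, FFTW_ESTIMATE);
  p.bwd = fftw_plan_dft_2d(n, n, p.buf_in, p.buf_out, FFTW_BACKWARD, FFTW_ESTIMATE);
  return cache.emplace(n, p).first->second;
}

// forward DFT of a real matrix (arma column-major memory treated as the
// FFTW array; the resulting axis swap is immaterial because every grid it
// meets is symmetric in the two frequency axes)
static void fft2_fwd(const mat &x, cx_vec &out) {
  const int n = x.n_rows, nn = n * n;
  FftPlans &p = fft_plans(n);
  const double *src = x.memptr();
  for (int k = 0; k < nn; ++k) { p.buf_in[k][0] = src[k]; p.buf_in[k][1] = 0.0; }
  fftw_execute(p.fwd);
  out.set_size(nn);
  std::memcpy(out.memptr(), p.buf_out, sizeof(fftw_complex) * nn);
}

// inverse DFT (real part), normalized by 1/(n*n)
static void fft2_bwd_real(const cx_vec &f, mat &out, int n) {
  const int nn = n * n;
  FftPlans &p = fft_plans(n);
  std::memcpy(p.buf_in, f.memptr(), sizeof(fftw_complex) * nn);
  fftw_execute(p.bwd);
  out.set_size(n, n);
  double *dst = out.memptr();
  const double s = 1.0 / nn;
  for (int k = 0; k < nn; ++k) dst[k] = p.buf_out[k][0] * s;
}

// ------------------------------------------------------------- quaternions

static mat33 quat_rotmat(const vec &q) {
  double w = q(0), x = q(1), y = q(2), z = q(3);
  mat33 R;
  R(0, 0) = 1 - 2 * (y * y + z * z); R(0, 1) = 2 * (x * y - w * z); R(0, 2) = 2 * (x * z + w * y);
  R(1, 0) = 2 * (x * y + w * z); R(1, 1) = 1 - 2 * (x * x + z * z); R(1, 2) = 2 * (y * z - w * x);
  R(2, 0) = 2 * (x * z - w * y); R(2, 1) = 2 * (y * z + w * x); R(2, 2) = 1 - 2 * (x * x + y * y);
  return R;
}

static vec4 quat_mul(const vec4 &a, const vec4 &b) {
  vec4 r;
  r(0) = a(0) * b(0) - a(1) * b(1) - a(2) * b(2) - a(3) * b(3);
  r(1) = a(0) * b(1) + a(1) * b(0) + a(2) * b(3) - a(3) * b(2);
  r(2) = a(0) * b(2) - a(1) * b(3) + a(2) * b(0) + a(3) * b(1);
  r(3) = a(0) * b(3) + a(1) * b(2) - a(2) * b(1) + a(3) * b(0);
  return r;
}

// ---------------------------------------------------------------- rendering

// Render a bead model as a sum of integrable 2D Gaussians. sigma = r/sqrt(5)
// matches the per-axis second moment of a uniform ball of radius r; each
// bead integrates to its electron count.
// [[Rcpp::export]]
arma::mat cg_project_cpp(const arma::mat &pos, const arma::vec &radii,
                         const arma::vec &electrons, const arma::vec &quat,
                         double shift_x, double shift_y,
                         double pixel_size, int box) {
  const int n = box;
  mat img(n, n, fill::zeros);
  mat33 R = quat_rotmat(quat);
  rowvec ctr = mean(pos, 0);
  const double half = n / 2.0;
  for (uword b = 0; b < pos.n_rows; ++b) {
    vec3 p = {pos(b, 0) - ctr(0), pos(b, 1) - ctr(1), pos(b, 2) - ctr(2)};
    vec3 pr = R * p;
    double bx = pr(0) / pixel_size + half + shift_x;
    double by = pr(1) / pixel_size + half + shift_y;
    double sig = radii(b) / std::sqrt(5.0) / pixel_size;
    double amp = electrons(b) / (2.0 * M_PI * sig * sig);
    double cut = 5.0 * sig;
    int i0 = std::max(0, (int)std::ceil(bx - cut));
    int i1 = std::min(n - 1, (int)std::floor(bx + cut));
    int j0 = std::max(0, (int)std::ceil(by - cut));
    int j1 = std::min(n - 1, (int)std::floor(by + cut));
    if (i0 > i1 || j0 > j1) continue;
    vec ex(i1 - i0 + 1), ey(j1 - j0 + 1);
    double inv2s2 = 1.0 / (2.0 * sig * sig);
    for (int i = i0; i <= i1; ++i) ex(i - i0) = std::exp(-(i - bx) * (i - bx) * inv2s2);
    for (int j = j0; j <= j1; ++j) ey(j - j0) = std::exp(-(j - by) * (j - by) * inv2s2);
    for (int j = j0; j <= j1; ++j) {
      double a = amp * ey(j - j0);
      double *col = img.colptr(j);
      for (int i = i0; i <= i1; ++i) col[i] += a * ex(i - i0);
    }
  }
  return img;
}

// CTF(k) = -(sqrt(1-A^2) sin(chi) + A cos(chi)) * exp(-B k^2 / 4),
// chi = pi * lambda_e * defocus * k^2, frequencies in 1/Angstrom.
static mat ctf_grid(int n, double defocus_um, double amp, double bfactor,
                    double pixel_size) {
  mat ctf(n, n);
  const double df = defocus_um * 1e4;  // um -> Angstrom
  const double a2 = std::sqrt(std::max(0.0, 1.0 - amp * amp));
  vec f(n);
  for (int i = 0; i < n; ++i) {
    int fi = (i <= n / 2) ? i : i - n;
    f(i) = (double)fi / (n * pixel_size);
  }
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < n; ++i) {
      double k2 = f(i) * f(i) + f(j) * f(j);
      double chi = M_PI * ELECTRON_WAVELENGTH_A * df * k2;
      ctf(i, j) = -(a2 * std::sin(chi) + amp * std::cos(chi)) *
                  std::exp(-bfactor * k2 / 4.0);
    }
  }
  return ctf;
}

// [[Rcpp::export]]
arma::mat ctf_apply_cpp(const arma::mat &img, double defocus_um, double amp,
                        double bfactor, double pixel_size) {
  const int n = img.n_rows;
  mat ctf = ctf_grid(n, defocus_um, amp, bfactor, pixel_size);
  cx_vec F;
  fft2_fwd(img, F);
  const double *c = ctf.memptr();
  std::complex<double> *f = F.memptr();
  for (int k = 0; k < n * n; ++k) f[k] *= c[k];
  mat out;
  fft2_bwd_real(F, out, n);
  return out;
}

// Render the full (orientation x defocus) template bank for one node:
// one projection + forward FFT per orientation, one CTF multiply + inverse
// FFT per (orientation, defocus). Template order: defocus fastest.
// [[Rcpp::export]]
arma::cube build_templates_cpp(const arma::mat &pos, const arma::vec &radii,
                               const arma::vec &electrons,
                               const arma::mat &quats, const arma::vec &defoci,
                               double amp, double bfactor, double pixel_size,
                               int box) {
  const int n = box, nq = quats.n_rows, nd = defoci.n_elem;
  std::vector<mat> ctfs(nd);
  for (int d = 0; d < nd; ++d)
    ctfs[d] = ctf_grid(n, defoci(d), amp, bfactor, pixel_size);
  cube out(n, n, nq * nd);
  cx_vec F, Fd(n * n);
  for (int q = 0; q < nq; ++q) {
    vec quat = quats.row(q).t();
    mat proj = cg_project_cpp(pos, radii, electrons, quat, 0, 0, pixel_size, n);
    fft2_fwd(proj, F);
    for (int d = 0; d < nd; ++d) {
      const double *c = ctfs[d].memptr();
      for (int k = 0; k < n * n; ++k) Fd(k) = F(k) * c[k];
      mat T;
      fft2_bwd_real(Fd, T, n);
      out.slice(q * nd + d) = T;
    }
  }
  return out;
}

// ------------------------------------------------- per-pose log likelihood

// Closed-form per-pose log likelihood after integrating out the noise
// variance (Jeffreys prior), additive offset and multiplicative
// normalization (flat priors): see image_node_log_likelihood() in R.
static inline double pose_ll(double P, double cww, double ctt, double cwt,
                             double const_term) {
  double R = cww - cwt * cwt / ctt;
  double Rfloor = 1e-12 * cww;
  if (R < Rfloor) R = Rfloor;
  return const_term - 0.5 * std::log(P * ctt) - (P - 2.0) / 2.0 * std::log(R);
}

static inline double ll_const(double P) {
  return (1.0 - P / 2.0) * std::log(2.0 * M_PI) +
         (P - 4.0) / 2.0 * std::log(2.0) + std::lgamma((P - 2.0) / 2.0);
}

static inline double lse_arr(const double *v, int n) {
  double m = -datum::inf;
  for (int k = 0; k < n; ++k) if (v[k] > m) m = v[k];
  if (!std::isfinite(m)) return m;
  double s = 0.0;
  for (int k = 0; k < n; ++k) s += std::exp(v[k] - m);
  return m + std::log(s);
}

// ------------------------------------------------------- round 1 (spatial)

// Wrap-pad a template by ms pixels on every side so that all circular
// shifts become contiguous reads.
static mat wrap_pad(const mat &T, int ms) {
  const int n = T.n_rows, np = n + 2 * ms;
  mat Tp(np, np);
  for (int j = 0; j < np; ++j) {
    int js = ((j - ms) % n + n) % n;
    double *dst = Tp.colptr(j);
    const double *src = T.colptr(js);
    for (int i = 0; i < np; ++i) {
      int is = ((i - ms) % n + n) % n;
      dst[i] = src[is];
    }
  }
  return Tp;
}

// All (2ms+1)^2 circular-shift dot products of image W with padded
// template Tp, in a single fused pass (the shift prior is uniform, so the
// shift identity of each dot is irrelevant downstream).
static void shift_dots(const mat &W, const mat &Tp, int ms, double *out) {
  const int n = W.n_rows, ns = 2 * ms + 1;
  const int nd = ns * ns;
  if (ms == 1) {
    double a0 = 0, a1 = 0, a2 = 0, a3 = 0, a4 = 0, a5 = 0, a6 = 0, a7 = 0, a8 = 0;
    for (int j = 0; j < n; ++j) {
      const double *w = W.colptr(j);
      const double *t0 = Tp.colptr(j);
      const double *t1 = Tp.colptr(j + 1);
      const double *t2 = Tp.colptr(j + 2);
      for (int i = 0; i < n; ++i) {
        double wi = w[i];
        a0 += wi * t0[i]; a1 += wi * t0[i + 1]; a2 += wi * t0[i + 2];
        a3 += wi * t1[i]; a4 += wi * t1[i + 1]; a5 += wi * t1[i + 2];
        a6 += wi * t2[i]; a7 += wi * t2[i + 1]; a8 += wi * t2[i + 2];
      }
    }
    out[0] = a0; out[1] = a1; out[2] = a2; out[3] = a3; out[4] = a4;
    out[5] = a5; out[6] = a6; out[7] = a7; out[8] = a8;
    return;
  }
  for (int k = 0; k < nd; ++k) out[k] = 0.0;
  for (int co = 0; co < ns; ++co) {
    for (int ro = 0; ro < ns; ++ro) {
      double s0 = 0, s1 = 0;
      for (int j = 0; j < n; ++j) {
        const double *w = W.colptr(j);
        const double *t = Tp.colptr(j + co) + ro;
        int i = 0;
        for (; i + 1 < n; i += 2) { s0 += w[i] * t[i]; s1 += w[i + 1] * t[i + 1]; }
        for (; i < n; ++i) s0 += w[i] * t[i];
      }
      out[ro + ns * co] = s0 + s1;
    }
  }
}

// Shift-marginalized per-pose log likelihood of image (stats sw/cww) vs
// padded template.
static double pose_shift_ll(const mat &W, double sw, double cww,
                            const mat &Tp, double st, double ctt,
                            int ms, double P, double cterm, double *scratch) {
  const int ns = 2 * ms + 1, nd = ns * ns;
  shift_dots(W, Tp, ms, scratch);
  for (int k = 0; k < nd; ++k) {
    double cwt = scratch[k] - sw * st / P;
    scratch[k] = pose_ll(P, cww, ctt, cwt, cterm);
  }
  return lse_arr(scratch, nd) - std::log((double)nd);
}

// Round-1 marginal likelihood of every image against a set of templates
// sharing one node. Templates are indexed by (orientation, defocus);
// tmpl_logprior carries log(orientation weight * defocus weight). Returns
// the total log likelihood per image and per-orientation marginals used to
// pick the refinement seeds.
// [[Rcpp::export]]
Rcpp::List ll_round1_cpp(const arma::cube &images, const arma::cube &templates,
                         const arma::ivec &orient_of_tmpl,
                         const arma::vec &tmpl_logprior,
                         int n_orient, int max_shift) {
  const int nimg = images.n_slices, ntmpl = templates.n_slices;
  const int n = images.n_rows;
  const double P = (double)n * n;
  const double cterm = ll_const(P);
  const int ms = max_shift, ns = 2 * ms + 1;
  std::vector<double> scratch(ns * ns);

  vec sw(nimg), cww(nimg);
  for (int i = 0; i < nimg; ++i) {
    const mat &W = images.slice(i);
    double s = accu(W), ss = accu(W % W);
    sw(i) = s; cww(i) = ss - s * s / P;
  }

  // shift-marginalized log likelihood for every (template, image) pair
  mat mts(ntmpl, nimg);
  for (int t = 0; t < ntmpl; ++t) {
    const mat &T = templates.slice(t);
    double st = accu(T), stt = accu(T % T);
    double ctt = stt - st * st / P;
    if (ctt <= 1e-12 * std::max(1.0, stt))
      Rcpp::stop("degenerate (all-constant) template; projection has no contrast");
    mat Tp = wrap_pad(T, ms);
    for (int i = 0; i < nimg; ++i)
      mts(t, i) = pose_shift_ll(images.slice(i), sw(i), cww(i), Tp, st, ctt,
                                ms, P, cterm, scratch.data());
  }

  vec ll(nimg);
  mat orient_ll(nimg, n_orient);
  std::vector<double> buf(ntmpl);
  std::vector<std::vector<double>> obuf(n_orient);
  for (int i = 0; i < nimg; ++i) {
    for (auto &v : obuf) v.clear();
    for (int t = 0; t < ntmpl; ++t) {
      buf[t] = tmpl_logprior(t) + mts(t, i);
      obuf[orient_of_tmpl(t)].push_back(buf[t]);
    }
    ll(i) = lse_arr(buf.data(), ntmpl);
    for (int o = 0; o < n_orient; ++o)
      orient_ll(i, o) = lse_arr(obuf[o].data(), obuf[o].size());
  }
  return Rcpp::List::create(Rcpp::Named("ll") = ll,
                            Rcpp::Named("orient_ll") = orient_ll);
}

// ------------------------------------------------ round 2 (Fourier domain)

// Shift-marginalized per-pose log likelihood computed entirely in Fourier
// space: the template's DFT is That(k) = Phat(k) * C(k); its sums follow
// from Parseval, and the circular cross-correlations at all shifts come
// from phase-factorized reductions of conj(What) * That. Identical (up to
// rounding) to the real-space route; no inverse FFT needed.
static double pose_shift_ll_fourier(
    const cx_vec &What, double sw, double cww,
    const cx_vec &Phat, const double *ctf,
    int n, int ms, double P, double cterm,
    const std::vector<cx_vec> &phase,  // per shift value: phase factors over freq index
    double *scratch, cx_vec &zrow) {
  const int ns = 2 * ms + 1, nshift = ns * ns, nn = n * n;
  // fused: template DFT stats and z = conj(What) .* That
  double stt = 0.0;
  std::complex<double> st0(0, 0);
  static thread_local cx_vec z;
  z.set_size(nn);
  const std::complex<double> *wp = What.memptr();
  const std::complex<double> *pp = Phat.memptr();
  std::complex<double> *zp = z.memptr();
  for (int k = 0; k < nn; ++k) {
    std::complex<double> t = pp[k] * ctf[k];
    stt += std::norm(t);
    zp[k] = std::conj(wp[k]) * t;
  }
  stt /= P;
  double st = (pp[0] * ctf[0]).real();   // zero-frequency term = template sum
  double ctt = stt - st * st / P;
  if (ctt <= 1e-12 * std::max(1.0, stt))
    Rcpp::stop("degenerate (all-constant) template; projection has no contrast");

  // reduce over the first frequency axis for each shift value, then finish
  // over the second axis; c(shift) = Re(sum) / P
  // zrow: ns x n complex accumulators
  zrow.set_size(ns * n);
  zrow.zeros();
  for (int j = 0; j < n; ++j) {
    const std::complex<double> *zc = zp + j * n;
    for (int s = 0; s < ns; ++s) {
      const std::complex<double> *ph = phase[s].memptr();
      std::complex<double> acc(0, 0);
      for (int i = 0; i < n; ++i) acc += zc[i] * ph[i];
      zrow(s * n + j) = acc;
    }
  }
  int idx = 0;
  for (int s2 = 0; s2 < ns; ++s2) {
    const std::complex<double> *ph = phase[s2].memptr();
    for (int s1 = 0; s1 < ns; ++s1) {
      std::complex<double> acc(0, 0);
      const std::complex<double> *zr = zrow.memptr() + s1 * n;
      for (int j = 0; j < n; ++j) acc += zr[j] * ph[j];
      double cwt = acc.real() / P - sw * st / P;
      scratch[idx++] = pose_ll(P, cww, ctt, cwt, cterm);
    }
  }
  return lse_arr(scratch, nshift) - std::log((double)nshift);
}

// Iterative local orientation refinement for one image-node pair. Level 1
// puts an l x l x l rotation-vector grid of half-width hw around each of
// the K seed orientations (offsets ordered first-axis-fastest, matching
// refine_orientation_grid()); each further level re-grids around the best
// marginal orientation of the previous level with the half-width divided by
// l. The returned value is the pose-marginalized log likelihood over the
// union of all levels' grid points, each point carrying the rotation-space
// volume of its grid cell, so the union acts as a multi-resolution
// quadrature of the orientation integral under the uniform orientation
// prior (defocus grid with the given prior weights, shifts uniform).
// [[Rcpp::export]]
double ll_refine_iter_cpp(const arma::mat &image, const arma::mat &pos,
                          const arma::vec &radii, const arma::vec &electrons,
                          const arma::mat &seed_quats, int local_l,
                          double half_width, int n_levels,
                          const arma::vec &defocus_offsets,
                          const arma::vec &defocus_logprior,
                          double defocus_center,
                          double amp, double bfactor, double pixel_size,
                          int max_shift) {
  const int n = image.n_rows;
  const double P = (double)n * n;
  const double cterm = ll_const(P);
  const int ms = max_shift, ns = 2 * ms + 1;
  const int l3 = local_l * local_l * local_l;
  std::vector<double> scratch(ns * ns);

  double sw = accu(image), sww = accu(image % image);
  double cww = sww - sw * sw / P;
  cx_vec What;
  fft2_fwd(image, What);

  // shift phase factors exp(2 pi i f_k * delta) for delta = -ms..ms
  std::vector<cx_vec> phase(ns);
  for (int s = 0; s < ns; ++s) {
    int d = s - ms;
    phase[s].set_size(n);
    for (int i = 0; i < n; ++i) {
      int fi = (i <= n / 2) ? i : i - n;
      double a = 2.0 * M_PI * fi * d / n;
      phase[s](i) = std::complex<double>(std::cos(a), std::sin(a));
    }
  }

  const int ndef = defocus_offsets.n_elem;
  std::vector<mat> ctfs(ndef);
  for (int d = 0; d < ndef; ++d) {
    double df = std::max(defocus_center + defocus_offsets(d), 0.05);
    ctfs[d] = ctf_grid(n, df, amp, bfactor, pixel_size);
  }

  std::vector<vec4> seeds;
  for (uword k = 0; k < seed_quats.n_rows; ++k)
    seeds.push_back(seed_quats.row(k).t());

  double hw = half_width;
  cx_vec Phat, zrow;
  std::vector<double> dbuf(ndef);
  std::vector<double> all_terms;        // log(p_pose) + log(cell volume)
  double total_vol = 0.0;
  for (int level = 0; level < n_levels; ++level) {
    vec ax(local_l);
    if (local_l == 1) ax(0) = 0.0;
    else for (int k = 0; k < local_l; ++k)
      ax(k) = -hw + 2.0 * hw * k / (local_l - 1);
    const int nq = (int)seeds.size() * l3;
    std::vector<vec4> quats; quats.reserve(nq);
    for (const vec4 &s : seeds) {
      for (int k3 = 0; k3 < local_l; ++k3)
        for (int k2 = 0; k2 < local_l; ++k2)
          for (int k1 = 0; k1 < local_l; ++k1) {
            vec3 w = {ax(k1), ax(k2), ax(k3)};
            double ang = norm(w);
            vec4 dq;
            if (ang < 1e-15) dq = {1, 0, 0, 0};
            else {
              double sa = std::sin(ang / 2) / ang;
              dq = {std::cos(ang / 2), sa * w(0), sa * w(1), sa * w(2)};
            }
            quats.push_back(quat_mul(s, dq));
          }
    }
    // per-point cell volume of this level's grid (uniform prior up to the
    // common normalization, which cancels across nodes)
    const double cell_vol = std::pow(2.0 * hw / std::max(1, local_l - 1), 3);
    std::vector<double> q_ll(nq);
    for (int q = 0; q < nq; ++q) {
      vec quat = {quats[q](0), quats[q](1), quats[q](2), quats[q](3)};
      mat proj = cg_project_cpp(pos, radii, electrons, quat, 0.0, 0.0,
                                pixel_size, n);
      fft2_fwd(proj, Phat);
      for (int d = 0; d < ndef; ++d)
        dbuf[d] = defocus_logprior(d) +
                  pose_shift_ll_fourier(What, sw, cww, Phat, ctfs[d].memptr(),
                                        n, ms, P, cterm, phase,
                                        scratch.data(), zrow);
      q_ll[q] = lse_arr(dbuf.data(), ndef);
      all_terms.push_back(q_ll[q] + std::log(cell_vol));
    }
    total_vol += nq * cell_vol;
    // next level: one seed (the best marginal orientation), tighter box
    int best = 0;
    for (int q = 1; q < nq; ++q) if (q_ll[q] > q_ll[best]) best = q;
    seeds.assign(1, quats[best]);
    hw /= (local_l > 1) ? local_l : 2;
  }
  return lse_arr(all_terms.data(), all_terms.size()) - std::log(total_vol);
}
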