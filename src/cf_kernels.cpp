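// Characteristic-function kernels for the trivariate causal mixture model.
//
// The model CF for one tag variant with neighborhood weights w_k and
// per-trait sample sizes N_i is
//   phi(t) = exp(-t' Sigma0 t / 2) *
//            prod_k [ pi0 + sum_S pi_S exp(-w_k u' Sigma_S u / 2) ],
// with u = diag(sqrt(N)) t.  Densities are recovered by a trapezoidal sum
// over a symmetric grid; phi is even under t -> -t, so one half-space is
// enumerated with weight 2.  Two paths are provided:
//
//  * cpp_cf_pdf: double precision, exact per-neighbor weights; reference
//    path used for single-variant densities and accuracy checks.
//  * cpp_cf_pdf_batch: high-throughput path over many tag variants whose
//    neighborhood weights have been binned onto a shared geometric grid;
//    inner loops in single precision with double accumulators.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// build systems often append a conservative optimization level last;
// the hot loops here want full vectorization regardless
#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3,unroll-loops")
// runtime-dispatched wide-vector clones where the toolchain supports it
#define HOT_CLONES __attribute__((target_clones("default", "avx2")))
#else
#define HOT_CLONES
#endif

static inline double quad_form(const double* C, const double* u, int d) {
  double s = 0.0;
  for (int a = 0; a < d; ++a) {
    s += C[a + a * d] * u[a] * u[a];
    for (int b = a + 1; b < d; ++b) s += 2.0 * C[a + b * d] * u[a] * u[b];
  }
  return s;
}

// exp(x) for x <= ~1, accurate to ~1e-6 relative; flushes below exp(-87).
static inline float fast_expf(float x) {
  if (x < -87.0f) return 0.0f;
  float z = x * 1.44269504088896341f;
  float zi = std::floor(z);
  float f = z - zi;
  float p = 1.0f + f * (0.693147180559945f + f * (0.240226506959101f +
            f * (0.0555041086648216f + f * (0.00961812910762848f +
            f * (0.00133335581464284f + f * (1.54035303933816e-4f +
            f * 1.52527338040598e-5f))))));
  union { uint32_t u; float f; } s;
  s.u = (uint32_t)((int)zi + 127) << 23;
  return p * s.f;
}

struct GridSpec {
  double dt;
  int m[3];      // per-axis index bound (t = -m..m times dt); 0 for unused
  int d;
  bool ball;     // restrict to the ellipsoid (i1/m1)^2 + ... <= 1
};

// Enumerate the half grid (first nonzero coordinate positive, plus the
// origin) and call f(i1, i2, i3, weight).
template <typename F>
static void for_half_grid(const GridSpec& g, F f) {
  int m1 = g.m[0], m2 = g.d > 1 ? g.m[1] : 0, m3 = g.d > 2 ? g.m[2] : 0;
  for (int i1 = 0; i1 <= m1; ++i1) {
    int lo2 = (i1 > 0) ? -m2 : 0;
    for (int i2 = lo2; i2 <= m2; ++i2) {
      int lo3 = (i1 > 0 || i2 > 0) ? -m3 : 0;
      for (int i3 = lo3; i3 <= m3; ++i3) {
        if (g.ball && g.d > 1) {
          double r = (double)i1 * i1 / ((double)m1 * m1);
          if (m2) r += (double)i2 * i2 / ((double)m2 * m2);
          if (m3) r += (double)i3 * i3 / ((double)m3 * m3);
          if (r > 1.0) continue;
        }
        double wt = (i1 == 0 && i2 == 0 && i3 == 0) ? 1.0 : 2.0;
        f(i1, i2, i3, wt);
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_cf_pdf(NumericMatrix Z, NumericVector w, NumericVector nvec,
                         double pi0, NumericVector pis, NumericVector covs,
                         NumericVector sigma0, double dt, IntegerVector m,
                         bool ball) {
  const int nz = Z.nrow(), d = Z.ncol(), M = w.size(), nc = pis.size();
  GridSpec g; g.dt = dt; g.d = d; g.ball = ball;
  for (int a = 0; a < 3; ++a) g.m[a] = (a < d) ? m[a] : 0;
  std::vector<double> sqn(d);
  for (int a = 0; a < d; ++a) sqn[a] = std::sqrt(nvec[a]);
  std::vector<double> acc(nz, 0.0);
  std::vector<double> zloc(nz * d);
  for (int a = 0; a < d; ++a)
    for (int i = 0; i < nz; ++i) zloc[a * nz + i] = Z(i, a);

  for_half_grid(g, [&](int i1, int i2, int i3, double wt) {
    double t[3] = { i1 * dt, i2 * dt, i3 * dt };
    double u[3];
    for (int a = 0; a < d; ++a) u[a] = sqn[a] * t[a];
    double qs[7];
    for (int s = 0; s < nc; ++s)
      qs[s] = quad_form(&covs[s * d * d], u, d);
    double conv = 0.0;
    for (int k = 0; k < M; ++k) {
      double inner = pi0;
      for (int s = 0; s < nc; ++s)
        inner += pis[s] * std::exp(-0.5 * w[k] * qs[s]);
      conv += std::log(inner);
    }
    double a0 = -0.5 * quad_form(&sigma0[0], t, d);
    double val = wt * std::exp(a0 + conv);
    for (int i = 0; i < nz; ++i) {
      double tz = t[0] * zloc[i];
      if (d > 1) tz += t[1] * zloc[nz + i];
      if (d > 2) tz += t[2] * zloc[2 * nz + i];
      acc[i] += val * std::cos(tz);
    }
  });

  const double two_pi = 6.283185307179586;
  double scale = 1.0;
  for (int a = 0; a < d; ++a) scale *= dt / two_pi;
  NumericVector out(nz);
  for (int i = 0; i < nz; ++i) out[i] = acc[i] * scale;
  return out;
}

// Characteristic function at arbitrary t points (reference path; used for
// CF property checks).  T is nt x d.
// [[Rcpp::export]]
NumericVector cpp_cf_phi(NumericMatrix T, NumericVector w, NumericVector nvec,
                         double pi0, NumericVector pis, NumericVector covs,
                         NumericVector sigma0) {
  const int nt = T.nrow(), d = T.ncol(), M = w.size(), nc = pis.size();
  std::vector<double> sqn(d);
  for (int a = 0; a < d; ++a) sqn[a] = std::sqrt(nvec[a]);
  NumericVector out(nt);
  for (int i = 0; i < nt; ++i) {
    double t[3] = {0, 0, 0}, u[3] = {0, 0, 0};
    for (int a = 0; a < d; ++a) { t[a] = T(i, a); u[a] = sqn[a] * t[a]; }
    double qs[7];
    for (int s = 0; s < nc; ++s)
      qs[s] = quad_form(&covs[s * d * d], u, d);
    double conv = 0.0;
    for (int k = 0; k < M; ++k) {
      double inner = pi0;
      for (int s = 0; s < nc; ++s)
        inner += pis[s] * std::exp(-0.5 * w[k] * qs[s]);
      conv += std::log(inner);
    }
    out[i] = std::exp(-0.5 * quad_form(&sigma0[0], t, d) + conv);
  }
  return out;
}

// Per-axis trig tables for a (z, grid) combination, reusable across many
// likelihood evaluations at the same grid.
struct TrigTables {
  std::vector<std::vector<float> > cs, sn;
  int m[3];
  int n;
};

static void fill_trig(TrigTables& tt, const NumericMatrix& Z, double dt,
                      const int* m) {
  const int n = Z.nrow(), d = Z.ncol();
  tt.n = n;
  tt.cs.resize(d); tt.sn.resize(d);
  for (int a = 0; a < d; ++a) {
    tt.m[a] = m[a];
    tt.cs[a].resize((size_t)(m[a] + 1) * n);
    tt.sn[a].resize((size_t)(m[a] + 1) * n);
    for (int j = 0; j < n; ++j) {
      double zz = Z(j, a) * dt;
      // incremental rotation: cos/sin of i*zz
      double c = 1.0, s = 0.0, cd = std::cos(zz), sd = std::sin(zz);
      for (int i = 0; i <= m[a]; ++i) {
        tt.cs[a][(size_t)i * n + j] = (float)c;
        tt.sn[a][(size_t)i * n + j] = (float)s;
        double cn = c * cd - s * sd;
        s = c * sd + s * cd;
        c = cn;
      }
    }
  }
}

// [[Rcpp::export]]
SEXP cpp_make_trig(NumericMatrix Z, double dt, IntegerVector m) {
  TrigTables* tt = new TrigTables();
  int mm[3] = {0, 0, 0};
  for (int a = 0; a < Z.ncol(); ++a) mm[a] = m[a];
  fill_trig(*tt, Z, dt, mm);
  return XPtr<TrigTables>(tt, true);
}

// Batched densities for n tag variants with binned neighborhood weights.
// wptr/wbin/wcnt: CSR over variants; wbin indexes wmid (bin midpoints),
// wcnt the neighbor multiplicity in that bin.  Sample sizes are per trait
// (shared across variants).  Returns the density of each variant's
// observed z row.  `trig` may be a cache from cpp_make_trig for the same
// (Z, dt, m), or R_NilValue.
// [[Rcpp::export]]
HOT_CLONES
NumericVector cpp_cf_pdf_batch(NumericMatrix Z, IntegerVector wptr,
                               IntegerVector wbin, NumericVector wcnt,
                               NumericVector wmid, NumericVector nvec,
                               double pi0, NumericVector pis,
                               NumericVector covs, NumericVector sigma0,
                               double dt, IntegerVector m, bool ball,
                               SEXP trig = R_NilValue) {
  const int n = Z.nrow(), d = Z.ncol(), B = wmid.size(), nc = pis.size();
  GridSpec g; g.dt = dt; g.d = d; g.ball = ball;
  for (int a = 0; a < 3; ++a) g.m[a] = (a < d) ? m[a] : 0;

  TrigTables local;
  TrigTables* tt;
  if (trig == R_NilValue) {
    fill_trig(local, Z, dt, g.m);
    tt = &local;
  } else {
    tt = XPtr<TrigTables>(trig).get();
    if (tt->n != n) stop("trig cache does not match data");
  }
  const std::vector<std::vector<float> >& cs = tt->cs;
  const std::vector<std::vector<float> >& sn = tt->sn;

  std::vector<double> sqn(d);
  for (int a = 0; a < d; ++a) sqn[a] = std::sqrt(nvec[a]);
  std::vector<double> acc(n, 0.0);
  const int* pptr = INTEGER(wptr);
  const int* pbin = INTEGER(wbin);
  std::vector<float> cntf(wcnt.size());
  for (int p = 0; p < (int)wcnt.size(); ++p) cntf[p] = (float)wcnt[p];

  // enumerate the half grid once, then process points in blocks of Q so
  // the weight-bin gather and the exponentials run Q-wide
  struct Pt { int i1, i2, i3; float wt; };
  std::vector<Pt> pts;
  for_half_grid(g, [&](int i1, int i2, int i3, double wt) {
    pts.push_back(Pt{i1, i2, i3, (float)wt});
  });

  const int Q = 8;
  std::vector<float> Lq((size_t)B * Q), convq((size_t)n * Q), a0q(Q);
  std::vector<const float*> pc1(Q), ps1(Q), pc2(Q), ps2(Q), pc3(Q), ps3(Q);
  std::vector<float> g2(Q), g3(Q);

  for (size_t p0 = 0; p0 < pts.size(); p0 += Q) {
    const int qn = (int)std::min((size_t)Q, pts.size() - p0);
    for (int q = 0; q < qn; ++q) {
      const Pt& P = pts[p0 + q];
      double t[3] = { P.i1 * dt, P.i2 * dt, P.i3 * dt };
      double u[3];
      for (int a = 0; a < d; ++a) u[a] = sqn[a] * t[a];
      double qs[7];
      for (int s = 0; s < nc; ++s)
        qs[s] = quad_form(&covs[s * d * d], u, d);
      for (int b = 0; b < B; ++b) {
        float inner = (float)pi0;
        for (int s = 0; s < nc; ++s)
          inner += (float)pis[s] *
            fast_expf((float)(-0.5 * wmid[b] * qs[s]));
        Lq[(size_t)b * Q + q] = std::log(inner);
      }
      a0q[q] = (float)(-0.5 * quad_form(&sigma0[0], t, d));
      pc1[q] = &cs[0][(size_t)P.i1 * n];
      ps1[q] = &sn[0][(size_t)P.i1 * n];
      if (d > 1) {
        pc2[q] = &cs[1][(size_t)std::abs(P.i2) * n];
        ps2[q] = &sn[1][(size_t)std::abs(P.i2) * n];
        g2[q] = (P.i2 < 0) ? -1.0f : 1.0f;
      }
      if (d > 2) {
        pc3[q] = &cs[2][(size_t)std::abs(P.i3) * n];
        ps3[q] = &sn[2][(size_t)std::abs(P.i3) * n];
        g3[q] = (P.i3 < 0) ? -1.0f : 1.0f;
      }
    }
    // pad unused lanes so full-width inner loops are safe
    for (int q = qn; q < Q; ++q) {
      for (int b = 0; b < B; ++b) Lq[(size_t)b * Q + q] = 0.0f;
      a0q[q] = -87.0f;
    }

    // conv: Q-wide gather-accumulate over each variant's weight bins
    for (int j = 0; j < n; ++j) {
      float s[Q];
      for (int q = 0; q < Q; ++q) s[q] = a0q[q];
      for (int p = pptr[j]; p < pptr[j + 1]; ++p) {
        const float c = cntf[p];
        const float* Lrow = &Lq[(size_t)pbin[p] * Q];
        for (int q = 0; q < Q; ++q) s[q] += c * Lrow[q];
      }
      float* out = &convq[(size_t)j * Q];
      for (int q = 0; q < Q; ++q) out[q] = fast_expf(s[q]);
    }

    // accumulate wt * phi * cos(t'z) per lane
    for (int q = 0; q < qn; ++q) {
      const float wtf = pts[p0 + q].wt;
      const float* ex = &convq[0];
      if (d == 1) {
        const float* c1 = pc1[q];
        for (int j = 0; j < n; ++j)
          acc[j] += (double)(wtf * ex[(size_t)j * Q + q] * c1[j]);
      } else if (d == 2) {
        const float* c1 = pc1[q]; const float* s1 = ps1[q];
        const float* c2 = pc2[q]; const float* s2 = ps2[q];
        const float gg2 = g2[q];
        for (int j = 0; j < n; ++j) {
          float cosv = c1[j] * c2[j] - gg2 * s1[j] * s2[j];
          acc[j] += (double)(wtf * ex[(size_t)j * Q + q] * cosv);
        }
      } else {
        const float* c1 = pc1[q]; const float* s1 = ps1[q];
        const float* c2 = pc2[q]; const float* s2 = ps2[q];
        const float* c3 = pc3[q]; const float* s3 = ps3[q];
        const float gg2 = g2[q], gg3 = g3[q];
        for (int j = 0; j < n; ++j) {
          float sb = gg2 * s2[j], sc = gg3 * s3[j];
          float cosv = c1[j] * (c2[j] * c3[j] - sb * sc)
                     - s1[j] * (sb * c3[j] + c2[j] * sc);
          acc[j] += (double)(wtf * ex[(size_t)j * Q + q] * cosv);
        }
      }
    }
  }

  const double two_pi = 6.283185307179586;
  double scale = 1.0;
  for (int a = 0; a < d; ++a) scale *= dt / two_pi;
  NumericVector out(n);
  for (int j = 0; j < n; ++j) out[j] = acc[j] * scale;
  return out;
}
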