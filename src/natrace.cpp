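#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Periodic grid helpers. values is a column-major (n1,n2,n3) array; node
// (i,j,k) sits at origin + (i,j,k)*spacing and the grid tiles the cell.

static inline int wrap(int i, int n) {
  int r = i % n;
  return r < 0 ? r + n : r;
}

static inline double node_val(const double* v, const int* d, int i, int j, int k) {
  return v[wrap(i, d[0]) + (size_t)d[0] * (wrap(j, d[1]) + (size_t)d[1] * wrap(k, d[2]))];
}

static double trilin(const double* v, const int* d, const double* sp,
                     const double* org, double x, double y, double z) {
  double fx = (x - org[0]) / sp[0];
  double fy = (y - org[1]) / sp[1];
  double fz = (z - org[2]) / sp[2];
  int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy), k0 = (int)std::floor(fz);
  double tx = fx - i0, ty = fy - j0, tz = fz - k0;
  double acc = 0.0;
  for (int di = 0; di < 2; ++di)
    for (int dj = 0; dj < 2; ++dj)
      for (int dk = 0; dk < 2; ++dk) {
        double w = (di ? tx : 1.0 - tx) * (dj ? ty : 1.0 - ty) * (dk ? tz : 1.0 - tz);
        if (w != 0.0) acc += w * node_val(v, d, i0 + di, j0 + dj, k0 + dk);
      }
  return acc;
}

static double nearest(const double* v, const int* d, const double* sp,
                      const double* org, double x, double y, double z) {
  int i = (int)std::lround((x - org[0]) / sp[0]);
  int j = (int)std::lround((y - org[1]) / sp[1]);
  int k = (int)std::lround((z - org[2]) / sp[2]);
  return node_val(v, d, i, j, k);
}

// [[Rcpp::export]]
NumericVector cpp_interp(NumericVector values, IntegerVector dim,
                         NumericVector spacing, NumericVector origin,
                         NumericMatrix pos) {
  int n = pos.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = trilin(REAL(values), INTEGER(dim), REAL(spacing), REAL(origin),
                    pos(i, 0), pos(i, 1), pos(i, 2));
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_nearest(NumericVector values, IntegerVector dim,
                          NumericVector spacing, NumericVector origin,
                          NumericMatrix pos) {
  int n = pos.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = nearest(REAL(values), INTEGER(dim), REAL(spacing), REAL(origin),
                     pos(i, 0), pos(i, 1), pos(i, 2));
  return out;
}

// Batch s_mean over placements: rot is N x 9 (column-major 3x3 per row),
// trans is N x 3, high/low are n x 3 probe offsets in the fragment frame.
// [[Rcpp::export]]
NumericVector cpp_score_mean_batch(NumericVector values, IntegerVector dim,
                                   NumericVector spacing, NumericVector origin,
                                   NumericMatrix rot, NumericMatrix trans,
                                   NumericMatrix high, NumericMatrix low,
                                   bool interpolated) {
  int N = rot.nrow(), n = high.nrow();
  const double* v = REAL(values);
  const int* d = INTEGER(dim);
  const double* sp = REAL(spacing);
  const double* org = REAL(origin);
  NumericVector out(N);
  for (int r = 0; r < N; ++r) {
    double m[9];
    for (int q = 0; q < 9; ++q) m[q] = rot(r, q);
    double tx = trans(r, 0), ty = trans(r, 1), tz = trans(r, 2);
    double sh = 0.0, sl = 0.0;
    for (int p = 0; p < n; ++p) {
      double hx = m[0] * high(p, 0) + m[3] * high(p, 1) + m[6] * high(p, 2) + tx;
      double hy = m[1] * high(p, 0) + m[4] * high(p, 1) + m[7] * high(p, 2) + ty;
      double hz = m[2] * high(p, 0) + m[5] * high(p, 1) + m[8] * high(p, 2) + tz;
      double lx = m[0] * low(p, 0) + m[3] * low(p, 1) + m[6] * low(p, 2) + tx;
      double ly = m[1] * low(p, 0) + m[4] * low(p, 1) + m[7] * low(p, 2) + ty;
      double lz = m[2] * low(p, 0) + m[5] * low(p, 1) + m[8] * low(p, 2) + tz;
      if (interpolated) {
        sh += trilin(v, d, sp, org, hx, hy, hz);
        sl += trilin(v, d, sp, org, lx, ly, lz);
      } else {
        sh += nearest(v, d, sp, org, hx, hy, hz);
        sl += nearest(v, d, sp, org, lx, ly, lz);
      }
    }
    out[r] = (sh - sl) / n;
  }
  return out;
}

// Pruned local fingerprint search over rotations x grid-node translations.
//
// For each rotation the probe offsets are rotated once and rounded to the
// nearest grid vector; candidate translations are grid nodes within `radius`
// of `center` (or every node when whole_cell). Translations whose first
// high-probe density is below mean + sigma are eliminated immediately.
// Probe pairs are evaluated in order and scoring stops as soon as the
// running min(high) - max(low) drops below the live threshold. A best-list
// of size n_best keeps the threshold at the worst retained score (never
// below thresh0); on ties the earliest candidate in scan order is retained.
// [[Rcpp::export]]
List cpp_search_local(NumericVector values, IntegerVector dim,
                      NumericVector spacing, NumericVector origin,
                      double gmean, double gsigma,
                      NumericMatrix rots, NumericMatrix high, NumericMatrix low,
                      NumericVector center, double radius,
                      int n_best, double thresh0, bool whole_cell) {
  const double* v = REAL(values);
  const int* d = INTEGER(dim);
  const double* sp = REAL(spacing);
  const double* org = REAL(origin);
  int nrot = rots.nrow(), n = high.nrow();

  // enumerate candidate translation nodes (deterministic order, i fastest)
  std::vector<int> ti, tj, tk;
  if (whole_cell) {
    for (int k = 0; k < d[2]; ++k)
      for (int j = 0; j < d[1]; ++j)
        for (int i = 0; i < d[0]; ++i) { ti.push_back(i); tj.push_back(j); tk.push_back(k); }
  } else {
    double r2 = radius * radius;
    int ilo = (int)std::ceil((center[0] - radius - org[0]) / sp[0]);
    int ihi = (int)std::floor((center[0] + radius - org[0]) / sp[0]);
    int jlo = (int)std::ceil((center[1] - radius - org[1]) / sp[1]);
    int jhi = (int)std::floor((center[1] + radius - org[1]) / sp[1]);
    int klo = (int)std::ceil((center[2] - radius - org[2]) / sp[2]);
    int khi = (int)std::floor((center[2] + radius - org[2]) / sp[2]);
    for (int k = klo; k <= khi; ++k)
      for (int j = jlo; j <= jhi; ++j)
        for (int i = ilo; i <= ihi; ++i) {
          double dx = org[0] + i * sp[0] - center[0];
          double dy = org[1] + j * sp[1] - center[1];
          double dz = org[2] + k * sp[2] - center[2];
          if (dx * dx + dy * dy + dz * dz <= r2) {
            ti.push_back(i); tj.push_back(j); tk.push_back(k);
          }
        }
  }
  int nt = (int)ti.size();
  if (nt == 0) stop("no candidate translations within radius");

  // best list
  std::vector<double> bscore(n_best);
  std::vector<int> brot(n_best), bti(n_best), border(n_best);
  int bsize = 0;
  long arrival = 0;
  double thresh = thresh0;
  double first_cut = gmean + gsigma;

  std::vector<int> hi_off(3 * n), lo_off(3 * n);

  for (int r = 0; r < nrot; ++r) {
    double m[9];
    for (int q = 0; q < 9; ++q) m[q] = rots(r, q);
    // rotate offsets once per rotation, round to nearest grid vector
    for (int p = 0; p < n; ++p) {
      double hx = m[0] * high(p, 0) + m[3] * high(p, 1) + m[6] * high(p, 2);
      double hy = m[1] * high(p, 0) + m[4] * high(p, 1) + m[7] * high(p, 2);
      double hz = m[2] * high(p, 0) + m[5] * high(p, 1) + m[8] * high(p, 2);
      double lx = m[0] * low(p, 0) + m[3] * low(p, 1) + m[6] * low(p, 2);
      double ly = m[1] * low(p, 0) + m[4] * low(p, 1) + m[7] * low(p, 2);
      double lz = m[2] * low(p, 0) + m[5] * low(p, 1) + m[8] * low(p, 2);
      hi_off[3 * p + 0] = (int)std::lround(hx / sp[0]);
      hi_off[3 * p + 1] = (int)std::lround(hy / sp[1]);
      hi_off[3 * p + 2] = (int)std::lround(hz / sp[2]);
      lo_off[3 * p + 0] = (int)std::lround(lx / sp[0]);
      lo_off[3 * p + 1] = (int)std::lround(ly / sp[1]);
      lo_off[3 * p + 2] = (int)std::lround(lz / sp[2]);
    }
    for (int t = 0; t < nt; ++t) {
      int i = ti[t], j = tj[t], k = tk[t];
      // optimization (iii): first high probe must stand out of the noise
      double v1 = node_val(v, d, i + hi_off[0], j + hi_off[1], k + hi_off[2]);
      if (v1 < first_cut) continue;
      // early-terminated min/max evaluation
      double minh = v1;
      double maxl = node_val(v, d, i + lo_off[0], j + lo_off[1], k + lo_off[2]);
      double partial = minh - maxl;
      bool rejected = partial < thresh;
      for (int p = 1; p < n && !rejected; ++p) {
        double hv = node_val(v, d, i + hi_off[3 * p], j + hi_off[3 * p + 1], k + hi_off[3 * p + 2]);
        double lv = node_val(v, d, i + lo_off[3 * p], j + lo_off[3 * p + 1], k + lo_off[3 * p + 2]);
        if (hv < minh) minh = hv;
        if (lv > maxl) maxl = lv;
        partial = minh - maxl;
        if (partial < thresh) rejected = true;
      }
      if (rejected) continue;
      double score = partial;
      ++arrival;
      if (bsize < n_best) {
        bscore[bsize] = score; brot[bsize] = r; bti[bsize] = t; border[bsize] = arrival;
        ++bsize;
        if (bsize == n_best) {
          double w = bscore[0];
          for (int q = 1; q < n_best; ++q) if (bscore[q] < w) w = bscore[q];
          thresh = w > thresh0 ? w : thresh0;
        }
      } else {
        // locate worst (min score; among ties the latest arrival is evicted)
        int wi = 0;
        for (int q = 1; q < n_best; ++q) {
          if (bscore[q] < bscore[wi] ||
              (bscore[q] == bscore[wi] && border[q] > border[wi])) wi = q;
        }
        if (score > bscore[wi]) {
          bscore[wi] = score; brot[wi] = r; bti[wi] = t; border[wi] = arrival;
          double w = bscore[0];
          for (int q = 1; q < n_best; ++q) if (bscore[q] < w) w = bscore[q];
          thresh = w > thresh0 ? w : thresh0;
        }
      }
    }
  }

  NumericVector oscore(bsize);
  IntegerVector orot(bsize), onode_i(bsize), onode_j(bsize), onode_k(bsize);
  NumericMatrix otrans(bsize, 3);
  for (int q = 0; q < bsize; ++q) {
    oscore[q] = bscore[q];
    orot[q] = brot[q] + 1;  // 1-based rotation index for R
    int t = bti[q];
    onode_i[q] = ti[t]; onode_j[q] = tj[t]; onode_k[q] = tk[t];
    otrans(q, 0) = org[0] + ti[t] * sp[0];
    otrans(q, 1) = org[1] + tj[t] * sp[1];
    otrans(q, 2) = org[2] + tk[t] * sp[2];
  }
  return List::create(_["score_minmax"] = oscore, _["rot_index"] = orot,
                      _["node_i"] = onode_i, _["node_j"] = onode_j,
                      _["node_k"] = onode_k, _["translation"] = otrans,
                      _["n_translations"] = nt);
}
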