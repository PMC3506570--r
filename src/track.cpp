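#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Termination codes shared with the R side:
// 1 = angle, 2 = mask_exit, 3 = length_cap, 4 = invalid_voxel, 5 = step_cap
// Eigenvector fields carry antipodal ambiguity; every lookup aligns the
// voxel vectors with a reference direction (dot >= 0) before interpolating.

struct Grid {
  const double *e1;   // nx*ny*nz*3, column-major
  const int *mask;    // nx*ny*nz
  const int *roi;     // nx*ny*nz or NULL
  int nx, ny, nz;
  double sx, sy, sz;

  inline long vidx(int i, int j, int k) const {
    return (long)i + (long)nx * ((long)j + (long)ny * (long)k);
  }
  inline bool in_grid(int i, int j, int k) const {
    return i >= 0 && j >= 0 && k >= 0 && i < nx && j < ny && k < nz;
  }
  // voxel containing world point p (voxel centers at (i + 0.5) * spacing)
  inline bool nearest(const double p[3], int out[3]) const {
    out[0] = (int)std::floor(p[0] / sx);
    out[1] = (int)std::floor(p[1] / sy);
    out[2] = (int)std::floor(p[2] / sz);
    return in_grid(out[0], out[1], out[2]);
  }
  inline bool in_mask(const double p[3]) const {
    int v[3];
    if (!nearest(p, v)) return false;
    return mask[vidx(v[0], v[1], v[2])] != 0;
  }
  inline bool in_roi(const double p[3]) const {
    if (roi == NULL) return true;
    int v[3];
    if (!nearest(p, v)) return false;
    return roi[vidx(v[0], v[1], v[2])] != 0;
  }
};

// Sign-aligned, mask-weighted trilinear interpolation of e1 at world p.
// Returns 0 on success, 2 when effectively outside the field (grid edge or
// total in-mask weight < 0.5), 4 when a contributing in-mask voxel holds a
// non-finite vector (flagged tensor fit).
static int interp_dir(const Grid &g, const double p[3], const double ref[3],
                      double out[3]) {
  double u[3] = {p[0] / g.sx - 0.5, p[1] / g.sy - 0.5, p[2] / g.sz - 0.5};
  int i0[3];
  double t[3];
  for (int a = 0; a < 3; ++a) {
    i0[a] = (int)std::floor(u[a]);
    t[a] = u[a] - i0[a];
  }
  double acc[3] = {0.0, 0.0, 0.0};
  double wtot = 0.0;
  long n3 = (long)g.nx * g.ny * g.nz;
  for (int dk = 0; dk < 2; ++dk) {
    for (int dj = 0; dj < 2; ++dj) {
      for (int di = 0; di < 2; ++di) {
        int i = i0[0] + di, j = i0[1] + dj, k = i0[2] + dk;
        if (!g.in_grid(i, j, k)) continue;
        long v = g.vidx(i, j, k);
        if (g.mask[v] == 0) continue;
        double w = (di ? t[0] : 1.0 - t[0]) * (dj ? t[1] : 1.0 - t[1]) *
                   (dk ? t[2] : 1.0 - t[2]);
        if (w <= 0.0) continue;
        double ex = g.e1[v], ey = g.e1[v + n3], ez = g.e1[v + 2 * n3];
        if (!std::isfinite(ex) || !std::isfinite(ey) || !std::isfinite(ez))
          return 4;
        double d = ex * ref[0] + ey * ref[1] + ez * ref[2];
        double s = (d >= 0.0) ? 1.0 : -1.0;
        acc[0] += w * s * ex;
        acc[1] += w * s * ey;
        acc[2] += w * s * ez;
        wtot += w;
      }
    }
  }
  if (wtot < 0.5) return 2;
  double nrm = std::sqrt(acc[0] * acc[0] + acc[1] * acc[1] + acc[2] * acc[2]);
  if (nrm < 1e-12) return 2;
  out[0] = acc[0] / nrm;
  out[1] = acc[1] / nrm;
  out[2] = acc[2] / nrm;
  return 0;
}

// One RK4 step direction at p with incoming direction d_prev.
static int rk4_dir(const Grid &g, const double p[3], const double d_prev[3],
                   double h, double out[3]) {
  double k1[3], k2[3], k3[3], k4[3], q[3];
  int rc;
  if ((rc = interp_dir(g, p, d_prev, k1))) return rc;
  for (int a = 0; a < 3; ++a) q[a] = p[a] + 0.5 * h * k1[a];
  if ((rc = interp_dir(g, q, k1, k2))) return rc;
  for (int a = 0; a < 3; ++a) q[a] = p[a] + 0.5 * h * k2[a];
  if ((rc = interp_dir(g, q, k2, k3))) return rc;
  for (int a = 0; a < 3; ++a) q[a] = p[a] + h * k3[a];
  if ((rc = interp_dir(g, q, k3, k4))) return rc;
  for (int a = 0; a < 3; ++a)
    out[a] = (k1[a] + 2.0 * k2[a] + 2.0 * k3[a] + k4[a]) / 6.0;
  double nrm = std::sqrt(out[0] * out[0] + out[1] * out[1] + out[2] * out[2]);
  if (nrm < 1e-12) return 2;
  for (int a = 0; a < 3; ++a) out[a] /= nrm;
  return 0;
}

// Grow one branch from seed along d0. Appends points (excluding the seed)
// to pts; returns the termination code.
static int grow_branch(const Grid &g, const double seed[3], const double d0[3],
                       double h, double cos_max, double branch_cap,
                       int max_steps, bool use_roi,
                       std::vector<double> &pts) {
  double p[3] = {seed[0], seed[1], seed[2]};
  double d_prev[3] = {d0[0], d0[1], d0[2]};
  double len = 0.0;
  bool first = true;
  for (int step = 0; step < max_steps; ++step) {
    if (len + h > branch_cap + 1e-9) return 3;
    double v[3];
    int rc = rk4_dir(g, p, d_prev, h, v);
    if (rc) return rc;
    if (!first) {
      double c = v[0] * d_prev[0] + v[1] * d_prev[1] + v[2] * d_prev[2];
      if (c < cos_max) return 1;
    }
    double pn[3] = {p[0] + h * v[0], p[1] + h * v[1], p[2] + h * v[2]};
    if (!g.in_mask(pn)) return 2;
    if (use_roi && !g.in_roi(pn)) return 3;
    pts.push_back(pn[0]);
    pts.push_back(pn[1]);
    pts.push_back(pn[2]);
    for (int a = 0; a < 3; ++a) {
      p[a] = pn[a];
      d_prev[a] = v[a];
    }
    len += h;
    first = false;
  }
  return 5;
}

// [[Rcpp::export(name = ".track_cpp")]]
List track_cpp(NumericVector e1, IntegerVector mask, IntegerVector dims,
               NumericVector spacing, NumericMatrix seeds, double step,
               double max_angle_deg, double branch_cap, int max_steps,
               Nullable<IntegerVector> roi = R_NilValue) {
  Grid g;
  g.e1 = REAL(e1);
  g.mask = INTEGER(mask);
  g.nx = dims[0];
  g.ny = dims[1];
  g.nz = dims[2];
  g.sx = spacing[0];
  g.sy = spacing[1];
  g.sz = spacing[2];
  IntegerVector roi_vec;
  bool use_roi = false;
  if (roi.isNotNull()) {
    roi_vec = roi.get();
    g.roi = INTEGER(roi_vec);
    use_roi = true;
  } else {
    g.roi = NULL;
  }

  int ns = seeds.nrow();
  double cos_max = std::cos(max_angle_deg * M_PI / 180.0);
  long n3 = (long)g.nx * g.ny * g.nz;

  List out_pts(ns);
  IntegerMatrix term(ns, 2);
  LogicalVector kept(ns);
  int skipped = 0;

  for (int s = 0; s < ns; ++s) {
    double seed[3] = {seeds(s, 0), seeds(s, 1), seeds(s, 2)};
    int v[3];
    if (!g.nearest(seed, v) || g.mask[g.vidx(v[0], v[1], v[2])] == 0) {
      kept[s] = false;
      ++skipped;
      continue;
    }
    long vi = g.vidx(v[0], v[1], v[2]);
    double d0[3] = {g.e1[vi], g.e1[vi + n3], g.e1[vi + 2 * n3]};
    if (!std::isfinite(d0[0]) || !std::isfinite(d0[1]) ||
        !std::isfinite(d0[2])) {
      kept[s] = false;
      ++skipped;
      continue;
    }
    // deterministic hemisphere: first non-zero component positive
    double lead = (std::fabs(d0[0]) > 1e-12)
                      ? d0[0]
                      : ((std::fabs(d0[1]) > 1e-12) ? d0[1] : d0[2]);
    if (lead < 0.0)
      for (int a = 0; a < 3; ++a) d0[a] = -d0[a];
    double nrm = std::sqrt(d0[0] * d0[0] + d0[1] * d0[1] + d0[2] * d0[2]);
    if (nrm < 1e-12) {
      kept[s] = false;
      ++skipped;
      continue;
    }
    for (int a = 0; a < 3; ++a) d0[a] /= nrm;

    std::vector<double> fwd, bwd;
    int tf = grow_branch(g, seed, d0, step, cos_max, branch_cap, max_steps,
                         use_roi, fwd);
    double d0n[3] = {-d0[0], -d0[1], -d0[2]};
    int tb = grow_branch(g, seed, d0n, step, cos_max, branch_cap, max_steps,
                         use_roi, bwd);

    int nb = (int)bwd.size() / 3, nf = (int)fwd.size() / 3;
    NumericMatrix pts(nb + 1 + nf, 3);
    for (int i = 0; i < nb; ++i) {  // backward branch reversed
      int r = nb - 1 - i;
      pts(i, 0) = bwd[3 * r];
      pts(i, 1) = bwd[3 * r + 1];
      pts(i, 2) = bwd[3 * r + 2];
    }
    pts(nb, 0) = seed[0];
    pts(nb, 1) = seed[1];
    pts(nb, 2) = seed[2];
    for (int i = 0; i < nf; ++i) {
      pts(nb + 1 + i, 0) = fwd[3 * i];
      pts(nb + 1 + i, 1) = fwd[3 * i + 1];
      pts(nb + 1 + i, 2) = fwd[3 * i + 2];
    }
    out_pts[s] = pts;
    term(s, 0) = tf;
    term(s, 1) = tb;
    kept[s] = true;
  }

  return List::create(_["points"] = out_pts, _["termination"] = term,
                      _["kept"] = kept, _["n_skipped"] = skipped);
}
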