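// Deterministic tensor-field streamline tracker.
//
// Propagation follows the principal eigenvector of the tri-linearly
// interpolated diffusion tensor, bidirectionally from each seed, with a
// per-step bend limit derived from a curvature radius. All randomness
// (seed points) is generated in R and passed in, so the C++ side is a
// pure function.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// 3x3 symmetric eigen-decomposition by cyclic Jacobi. a is row-major
// 3x3, overwritten; returns eigenvalues in w and eigenvectors in the
// columns of v.
static void jacobi3(double a[3][3], double w[3], double v[3][3]) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) v[i][j] = (i == j) ? 1.0 : 0.0;
  for (int sweep = 0; sweep < 32; ++sweep) {
    double off = a[0][1] * a[0][1] + a[0][2] * a[0][2] + a[1][2] * a[1][2];
    if (off < 1e-30) break;
    for (int p = 0; p < 2; ++p) {
      for (int q = p + 1; q < 3; ++q) {
        if (std::fabs(a[p][q]) < 1e-30) continue;
        double theta = (a[q][q] - a[p][p]) / (2.0 * a[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0);
        double s = t * c;
        for (int k = 0; k < 3; ++k) {
          double akp = a[k][p], akq = a[k][q];
          a[k][p] = c * akp - s * akq;
          a[k][q] = s * akp + c * akq;
        }
        for (int k = 0; k < 3; ++k) {
          double apk = a[p][k], aqk = a[q][k];
          a[p][k] = c * apk - s * aqk;
          a[q][k] = s * apk + c * aqk;
        }
        for (int k = 0; k < 3; ++k) {
          double vkp = v[k][p], vkq = v[k][q];
          v[k][p] = c * vkp - s * vkq;
          v[k][q] = s * vkp + c * vkq;
        }
      }
    }
  }
  for (int i = 0; i < 3; ++i) w[i] = a[i][i];
}

struct Grid {
  const double* coef;  // X*Y*Z*6, column-major R array
  const int* wm;       // X*Y*Z
  int nx, ny, nz;
  long nxyz;
};

// Tri-linear interpolation of the 6 tensor coefficients at continuous
// 0-based voxel coordinate (x, y, z). Returns false outside the grid.
static bool interp_coef(const Grid& g, double x, double y, double z,
                        double out[6]) {
  if (x < 0 || y < 0 || z < 0 || x > g.nx - 1 || y > g.ny - 1 ||
      z > g.nz - 1)
    return false;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
      z0 = (int)std::floor(z);
  if (x0 > g.nx - 2) x0 = g.nx - 2;
  if (y0 > g.ny - 2) y0 = g.ny - 2;
  if (z0 > g.nz - 2) z0 = g.nz - 2;
  if (x0 < 0) x0 = 0;
  if (y0 < 0) y0 = 0;
  if (z0 < 0) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  for (int p = 0; p < 6; ++p) out[p] = 0.0;
  for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
      for (int dx = 0; dx < 2; ++dx) {
        double wgt = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                     (dz ? fz : 1 - fz);
        if (wgt == 0.0) continue;
        long base = (x0 + dx) +
                    (long)g.nx * ((y0 + dy) + (long)g.ny * (z0 + dz));
        for (int p = 0; p < 6; ++p)
          out[p] += wgt * g.coef[base + g.nxyz * p];
      }
  return true;
}

static bool in_wm(const Grid& g, double x, double y, double z) {
  long i = (long)std::lround(x), j = (long)std::lround(y),
       k = (long)std::lround(z);
  if (i < 0 || j < 0 || k < 0 || i >= g.nx || j >= g.ny || k >= g.nz)
    return false;
  return g.wm[i + (long)g.nx * (j + (long)g.ny * k)] != 0;
}

// Principal direction and FA of the interpolated tensor; returns false
// when the tensor vanishes.
static bool principal_dir(const double lt[6], double dir[3], double* fa) {
  double a[3][3] = {{lt[0], lt[1], lt[3]},
                    {lt[1], lt[2], lt[4]},
                    {lt[3], lt[4], lt[5]}};
  double w[3], v[3][3];
  jacobi3(a, w, v);
  int imax = 0;
  if (w[1] > w[imax]) imax = 1;
  if (w[2] > w[imax]) imax = 2;
  double l1 = w[imax] > 0 ? w[imax] : 0;
  double md = 0, ss = 0, num = 0;
  double lam[3];
  for (int i = 0; i < 3; ++i) lam[i] = w[i] > 0 ? w[i] : 0;
  md = (lam[0] + lam[1] + lam[2]) / 3.0;
  for (int i = 0; i < 3; ++i) {
    num += (lam[i] - md) * (lam[i] - md);
    ss += lam[i] * lam[i];
  }
  *fa = ss > 0 ? std::sqrt(1.5 * num / ss) : 0.0;
  if (l1 <= 0) return false;
  for (int i = 0; i < 3; ++i) dir[i] = v[i][imax];
  double n = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] + dir[2] * dir[2]);
  if (n == 0) return false;
  for (int i = 0; i < 3; ++i) dir[i] /= n;
  return true;
}

// Propagate from `seed` (voxel coords) in the direction sign of d0,
// appending world points to pts (excluding the seed itself).
static void propagate(const Grid& g, const NumericMatrix& affine,
                      double seed[3], double d0[3], double step_vox,
                      double cos_min, double fa_min, int max_steps,
                      std::vector<double>& pts) {
  double p[3] = {seed[0], seed[1], seed[2]};
  double d[3] = {d0[0], d0[1], d0[2]};
  for (int s = 0; s < max_steps; ++s) {
    double q[3] = {p[0] + step_vox * d[0], p[1] + step_vox * d[1],
                   p[2] + step_vox * d[2]};
    if (!in_wm(g, q[0], q[1], q[2])) break;
    double lt[6], nd[3], fa;
    if (!interp_coef(g, q[0], q[1], q[2], lt)) break;
    if (!principal_dir(lt, nd, &fa)) break;
    if (fa < fa_min) break;
    double dot = nd[0] * d[0] + nd[1] * d[1] + nd[2] * d[2];
    if (dot < 0) {
      nd[0] = -nd[0]; nd[1] = -nd[1]; nd[2] = -nd[2];
      dot = -dot;
    }
    if (dot < cos_min) break;
    for (int i = 0; i < 3; ++i) { p[i] = q[i]; d[i] = nd[i]; }
    double wx = affine(0, 0) * p[0] + affine(0, 1) * p[1] +
                affine(0, 2) * p[2] + affine(0, 3);
    double wy = affine(1, 0) * p[0] + affine(1, 1) * p[1] +
                affine(1, 2) * p[2] + affine(1, 3);
    double wz = affine(2, 0) * p[0] + affine(2, 1) * p[1] +
                affine(2, 2) * p[2] + affine(2, 3);
    pts.push_back(wx); pts.push_back(wy); pts.push_back(wz);
  }
}

static double min_dist2_to_set(const double* pt, const NumericMatrix& set) {
  double best = R_PosInf;
  for (int r = 0; r < set.nrow(); ++r) {
    double dx = pt[0] - set(r, 0), dy = pt[1] - set(r, 1),
           dz = pt[2] - set(r, 2);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < best) best = d2;
  }
  return best;
}

static bool any_within(const std::vector<double>& pts,
                       const NumericMatrix& set, double max_d2) {
  for (size_t i = 0; i + 2 < pts.size(); i += 3) {
    double pt[3] = {pts[i], pts[i + 1], pts[i + 2]};
    if (min_dist2_to_set(pt, set) <= max_d2) return true;
  }
  return false;
}

// [[Rcpp::export]]
List track_streamlines_cpp(NumericVector coef, IntegerVector wm,
                           IntegerVector dims, NumericMatrix affine,
                           NumericMatrix inv_affine, NumericMatrix seeds,
                           double step_mm, double theta_max_deg,
                           double min_len_mm, double max_len_mm,
                           int max_fibers, NumericMatrix roiA,
                           NumericMatrix roiB, double max_dist_mm,
                           double fa_min, double voxel_size) {
  Grid g;
  g.coef = coef.begin();
  g.wm = wm.begin();
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.nxyz = (long)g.nx * g.ny * g.nz;

  double step_vox = step_mm / voxel_size;
  double cos_min = std::cos(theta_max_deg * M_PI / 180.0);
  if (theta_max_deg >= 180.0) cos_min = -2.0;  // no bend constraint
  int max_steps = (int)(max_len_mm / step_mm) + 2;
  double max_d2 = max_dist_mm * max_dist_mm;

  std::vector<NumericMatrix> out;
  int trials_used = 0;
  for (int t = 0; t < seeds.nrow(); ++t) {
    trials_used = t + 1;
    double seed_w[3] = {seeds(t, 0), seeds(t, 1), seeds(t, 2)};
    double sv[3];
    for (int i = 0; i < 3; ++i)
      sv[i] = inv_affine(i, 0) * seed_w[0] + inv_affine(i, 1) * seed_w[1] +
              inv_affine(i, 2) * seed_w[2] + inv_affine(i, 3);
    if (!in_wm(g, sv[0], sv[1], sv[2])) continue;
    double lt[6], d0[3], fa;
    if (!interp_coef(g, sv[0], sv[1], sv[2], lt)) continue;
    if (!principal_dir(lt, d0, &fa) || fa < fa_min) continue;

    std::vector<double> fwd, bwd;
    propagate(g, affine, sv, d0, step_vox, cos_min, fa_min, max_steps, fwd);
    double d0n[3] = {-d0[0], -d0[1], -d0[2]};
    propagate(g, affine, sv, d0n, step_vox, cos_min, fa_min, max_steps, bwd);

    size_t npt = fwd.size() / 3 + bwd.size() / 3 + 1;
    if (npt < 2) continue;
    double len = (npt - 1) * step_mm;
    if (len < min_len_mm || len > max_len_mm) continue;

    NumericMatrix sl(npt, 3);
    int row = 0;
    for (long i = (long)bwd.size() / 3 - 1; i >= 0; --i, ++row)
      for (int c = 0; c < 3; ++c) sl(row, c) = bwd[3 * i + c];
    for (int c = 0; c < 3; ++c)
      sl(row, c) = affine(c, 0) * sv[0] + affine(c, 1) * sv[1] +
                   affine(c, 2) * sv[2] + affine(c, 3);
    ++row;
    for (size_t i = 0; i < fwd.size() / 3; ++i, ++row)
      for (int c = 0; c < 3; ++c) sl(row, c) = fwd[3 * i + c];

    // acceptance: traverse both ROIs within the distance criterion, and
    // both endpoints near the seed-region union
    std::vector<double> ptsv(npt * 3);
    for (size_t r2 = 0; r2 < npt; ++r2)
      for (int c = 0; c < 3; ++c) ptsv[3 * r2 + c] = sl(r2, c);
    if (!any_within(ptsv, roiA, max_d2)) continue;
    if (!any_within(ptsv, roiB, max_d2)) continue;
    double e1[3] = {sl(0, 0), sl(0, 1), sl(0, 2)};
    double e2[3] = {sl(npt - 1, 0), sl(npt - 1, 1), sl(npt - 1, 2)};
    double dA1 = min_dist2_to_set(e1, roiA), dB1 = min_dist2_to_set(e1, roiB);
    double dA2 = min_dist2_to_set(e2, roiA), dB2 = min_dist2_to_set(e2, roiB);
    if (std::min(dA1, dB1) > max_d2 || std::min(dA2, dB2) > max_d2) continue;

    out.push_back(sl);
    if (out.size() >= (size_t)max_fibers) break;
  }
  List sls(out.size());
  for (size_t i = 0; i < out.size(); ++i) sls[i] = out[i];
  return List::create(_["streamlines"] = sls,
                      _["trials_used"] = trials_used);
}
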