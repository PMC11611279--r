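// Ray-tracing core: exit-face search, voxel traversal, attenuation exponents,
// angular grids. All coordinates are 0-based (z, y, x) with voxel centers at
// integer positions; the cuboid occupies [0, dim-1] along each axis.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <cstdio>
#include <vector>
using namespace Rcpp;

namespace {

struct Grid3 {
  const int* lab;
  int dims[3];  // (z, y, x)
  explicit Grid3(const IntegerVector& labels) {
    IntegerVector d = labels.attr("dim");
    if (d.size() != 3) stop("labels must be a 3D array");
    dims[0] = d[0]; dims[1] = d[1]; dims[2] = d[2];
    lab = INTEGER(labels);
  }
  inline int at(const int c[3]) const {
    return lab[(R_xlen_t)c[0] + (R_xlen_t)dims[0] * c[1] +
               (R_xlen_t)dims[0] * dims[1] * c[2]];
  }
};

// Faces are ordered x-, x+, y-, y+, z-, z+ (ids 0..5); ties in exit distance
// resolve to the lowest face id, which keeps the driving axis on X for rays
// leaving exactly through an X/Y edge (required by the 2D worked traversal).
const int AXIS_OF_FACE[6] = {2, 2, 1, 1, 0, 0};  // component index in (z,y,x)

int exit_face_core(const double P0[3], const double d[3], const int dims[3],
                   double& tmin) {
  tmin = R_PosInf;
  int face = -1;
  for (int f = 0; f < 6; ++f) {
    int a = AXIS_OF_FACE[f];
    bool maxside = (f % 2) == 1;
    if (d[a] == 0.0) continue;                       // parallel: no candidate
    if (maxside ? (d[a] < 0) : (d[a] > 0)) continue; // not outgoing
    double bound = maxside ? (double)(dims[a] - 1) : 0.0;
    double t = (bound - P0[a]) / d[a];
    if (t < 0) t = 0;  // P0 numerically on the face
    if (t < tmin - 1e-12) { tmin = t; face = f; }
  }
  return face;
}

void unit3(const double* in, double* out) {
  double nrm = std::sqrt(in[0]*in[0] + in[1]*in[1] + in[2]*in[2]);
  if (nrm == 0.0) stop("zero direction vector");
  out[0] = in[0]/nrm; out[1] = in[1]/nrm; out[2] = in[2]/nrm;
}

struct TravResult {
  std::vector<long> counts;  // indexed by label code
  int n;                     // maximum interval index (steps from start)
  int end[3];
  double euclid;
  int axis;                  // driving axis component (0=z, 1=y, 2=x)
};

void traverse_core(const Grid3& g, const int start[3], const double dir[3],
                   int max_code, TravResult& out, IntegerMatrix* path = NULL) {
  double d[3];
  unit3(dir, d);
  double P0[3] = {(double)start[0], (double)start[1], (double)start[2]};
  for (int a = 0; a < 3; ++a)
    if (start[a] < 0 || start[a] > g.dims[a] - 1) stop("start outside volume");
  double tmin;
  int face = exit_face_core(P0, d, g.dims, tmin);
  if (face < 0) stop("zero direction vector");
  int axis = AXIS_OF_FACE[face];
  double da = d[axis];
  double w[3] = {d[0]/std::fabs(da), d[1]/std::fabs(da), d[2]/std::fabs(da)};
  int n = (da > 0) ? (g.dims[axis] - 1 - start[axis]) : start[axis];
  out.counts.assign((size_t)max_code + 1, 0L);
  int c[3] = {start[0], start[1], start[2]};
  for (int s = 0; s <= n; ++s) {
    for (int a = 0; a < 3; ++a) {
      // round half away from zero ("nearest pixel"), clamp against fp drift
      long r = (long)std::llround(P0[a] + s * w[a]);
      if (r < 0) r = 0;
      if (r > g.dims[a] - 1) r = g.dims[a] - 1;
      c[a] = (int)r;
    }
    int code = g.at(c);
    if (code < 0 || code > max_code) stop("label code outside label map");
    out.counts[code]++;
    if (path) { (*path)(s, 0) = c[0]; (*path)(s, 1) = c[1]; (*path)(s, 2) = c[2]; }
  }
  double dz = c[0] - P0[0], dy = c[1] - P0[1], dx = c[2] - P0[2];
  out.n = n;
  out.end[0] = c[0]; out.end[1] = c[1]; out.end[2] = c[2];
  out.euclid = std::sqrt(dz*dz + dy*dy + dx*dx);
  out.axis = axis;
}

// One-way attenuation exponent sum_m mu_m * L_m for a ray leaving `start`
// along `dir`; mu is indexed by label code.
double oneway_exponent(const Grid3& g, const double* mu, int n_mu,
                       const int start[3], const double dir[3],
                       double voxel_size, bool fp32) {
  TravResult tr;
  traverse_core(g, start, dir, n_mu - 1, tr);
  double acc = 0.0;
  for (int m = 0; m < n_mu; ++m)
    if (tr.counts[m] > 0) acc += mu[m] * (double)tr.counts[m];
  double e = acc * (tr.euclid / (double)(tr.n + 1)) * voxel_size;
  return fp32 ? (double)(float)e : e;
}

double reflection_exponent(const Grid3& g, const double* mu, int n_mu,
                           const int start[3], const double inc[3],
                           const double dif[3], double voxel_size, bool fp32) {
  double rev[3] = {-inc[0], -inc[1], -inc[2]};
  double e = oneway_exponent(g, mu, n_mu, start, rev, voxel_size, fp32) +
             oneway_exponent(g, mu, n_mu, start, dif, voxel_size, fp32);
  return fp32 ? (double)(float)e : e;
}

}  // namespace

// [[Rcpp::export]]
List exit_point_cpp(NumericVector P0, NumericVector d, IntegerVector dims) {
  if (P0.size() != 3 || d.size() != 3 || dims.size() != 3)
    stop("P0, d and dims must have length 3");
  double p[3] = {P0[0], P0[1], P0[2]};
  for (int a = 0; a < 3; ++a)
    if (p[a] < -1e-9 || p[a] > dims[a] - 1 + 1e-9)
      stop("P0 outside the cuboid");
  double du[3];
  double draw[3] = {d[0], d[1], d[2]};
  unit3(draw, du);
  int dm[3] = {dims[0], dims[1], dims[2]};
  double t;
  int face = exit_face_core(p, du, dm, t);
  if (face < 0) stop("zero direction vector");
  NumericVector pt(3);
  for (int a = 0; a < 3; ++a) pt[a] = p[a] + t * du[a];
  return List::create(_["t"] = t, _["exit_point"] = pt, _["face"] = face + 1);
}

// [[Rcpp::export]]
List traverse_cpp(IntegerVector labels, IntegerVector start, NumericVector d,
                  int max_code, bool record_path) {
  Grid3 g(labels);
  int st[3] = {start[0], start[1], start[2]};
  double dir[3] = {d[0], d[1], d[2]};
  TravResult tr;
  IntegerMatrix* pp = NULL;
  IntegerMatrix path;
  if (record_path) {
    // need n first: cheap dry computation of n via exit face
    double du[3]; unit3(dir, du);
    double P0[3] = {(double)st[0], (double)st[1], (double)st[2]};
    double t; int face = exit_face_core(P0, du, g.dims, t);
    if (face < 0) stop("zero direction vector");
    int axis = AXIS_OF_FACE[face];
    int n = (du[axis] > 0) ? (g.dims[axis] - 1 - st[axis]) : st[axis];
    path = IntegerMatrix(n + 1, 3);
    pp = &path;
  }
  traverse_core(g, st, dir, max_code, tr, pp);
  IntegerVector counts(max_code + 1);
  for (int m = 0; m <= max_code; ++m) counts[m] = (int)tr.counts[m];
  List out = List::create(
      _["counts"] = counts, _["n"] = tr.n,
      _["end"] = IntegerVector::create(tr.end[0], tr.end[1], tr.end[2]),
      _["euclid"] = tr.euclid, _["axis"] = tr.axis,
      _["path"] = record_path ? (SEXP)path : R_NilValue);
  return out;
}

// [[Rcpp::export]]
double exponent_cpp(IntegerVector labels, NumericVector mu, IntegerVector start,
                    NumericVector incident, NumericVector diffracted,
                    double voxel_size, bool fp32) {
  Grid3 g(labels);
  int st[3] = {start[0], start[1], start[2]};
  double inc[3] = {incident[0], incident[1], incident[2]};
  double dif[3] = {diffracted[0], diffracted[1], diffracted[2]};
  return reflection_exponent(g, REAL(mu), mu.size(), st, inc, dif, voxel_size, fp32);
}

// Per-voxel linear factors exp(-exponent) for one reflection over `sel`
// (rows of 0-based (z,y,x) voxel coordinates).
// [[Rcpp::export]]
NumericVector voxel_factors_cpp(IntegerVector labels, NumericVector mu,
                                IntegerMatrix sel, NumericVector refl,
                                double voxel_size, bool fp32) {
  Grid3 g(labels);
  int nv = sel.nrow();
  NumericVector out(nv);
  double inc[3] = {refl[0], refl[1], refl[2]};
  double dif[3] = {refl[3], refl[4], refl[5]};
  for (int i = 0; i < nv; ++i) {
    int st[3] = {sel(i, 0), sel(i, 1), sel(i, 2)};
    double e = reflection_exponent(g, REAL(mu), mu.size(), st, inc, dif,
                                   voxel_size, fp32);
    out[i] = fp32 ? (double)std::exp((float)-e) : std::exp(-e);
  }
  return out;
}

// Absorption factors for many reflections: rows of `refl` are
// (iz, iy, ix, dz, dy, dx); mean of exp(-exponent) over selected voxels.
// [[Rcpp::export]]
NumericVector factors_cpp(IntegerVector labels, NumericVector mu,
                          IntegerMatrix sel, NumericMatrix refl,
                          double voxel_size, bool fp32) {
  Grid3 g(labels);
  int nr = refl.nrow(), nv = sel.nrow();
  if (nv < 1) stop("empty voxel selection");
  NumericVector out(nr);
  for (int r = 0; r < nr; ++r) {
    double inc[3] = {refl(r, 0), refl(r, 1), refl(r, 2)};
    double dif[3] = {refl(r, 3), refl(r, 4), refl(r, 5)};
    double acc = 0.0;
    for (int i = 0; i < nv; ++i) {
      int st[3] = {sel(i, 0), sel(i, 1), sel(i, 2)};
      double e = reflection_exponent(g, REAL(mu), mu.size(), st, inc, dif,
                                     voxel_size, fp32);
      acc += fp32 ? (double)std::exp((float)-e) : std::exp(-e);
    }
    out[r] = acc / (double)nv;
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// (360, 180) grid of one-way exponents for rays leaving `voxel` in direction
// theta = row degree (azimuth about z), phi = column degree (polar from +z).
// [[Rcpp::export]]
NumericMatrix grid_cpp(IntegerVector labels, NumericVector mu,
                       IntegerVector voxel, double voxel_size) {
  Grid3 g(labels);
  int st[3] = {voxel[0], voxel[1], voxel[2]};
  NumericMatrix gm(360, 180);
  for (int i = 0; i < 360; ++i) {
    double th = i * M_PI / 180.0;
    for (int j = 0; j < 180; ++j) {
      double ph = j * M_PI / 180.0;
      double d[3] = {std::cos(ph), std::sin(ph) * std::sin(th),
                     std::sin(ph) * std::cos(th)};
      gm(i, j) = oneway_exponent(g, REAL(mu), mu.size(), st, d, voxel_size,
                                 false);
    }
    Rcpp::checkUserInterrupt();
  }
  return gm;
}

// Mean of exp(-e) with plain double accumulation, mirroring factors_cpp so
// back-ends that assemble exponents in R produce identical factors.
// [[Rcpp::export]]
double mean_exp_neg_cpp(NumericVector e) {
  if (e.size() == 0) stop("empty exponent vector");
  double acc = 0.0;
  for (R_xlen_t i = 0; i < e.size(); ++i) acc += std::exp(-e[i]);
  return acc / (double)e.size();
}

// FNV-1a 64-bit over the raw label buffer: cheap content checksum used to key
// grid caches and stamp output metadata.
// [[Rcpp::export]]
std::string checksum_cpp(IntegerVector labels) {
  const uint8_t* p = (const uint8_t*)INTEGER(labels);
  R_xlen_t nb = XLENGTH(labels) * (R_xlen_t)sizeof(int);
  uint64_t h = 1469598103934665603ULL;
  for (R_xlen_t i = 0; i < nb; ++i) {
    h ^= (uint64_t)p[i];
    h *= 1099511628211ULL;
  }
  char buf[17];
  std::snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}
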