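#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Minimum-image fold for coordinates already wrapped into [0, L):
// differences lie in (-L, L), so one conditional fold suffices.
static inline double fold(double d, double L, double half) {
  if (d > half) return d - L;
  if (d < -half) return d + L;
  return d;
}

// Pair-distance histogram under orthorhombic minimum-image convention.
// Coordinates must be pre-wrapped into the primary box.
// Self mode: unordered pairs i<j within one index set.
// [[Rcpp::export]]
IntegerVector pair_hist_self(NumericMatrix xyz, IntegerVector rows,
                             NumericVector box, double rmax, double dr) {
  const int n = rows.size();
  const int nb = (int)std::ceil(rmax / dr);
  IntegerVector hist(nb);
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    int r = rows[i] - 1;
    x[i] = xyz(r, 0); y[i] = xyz(r, 1); z[i] = xyz(r, 2);
  }
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const double hx = Lx / 2, hy = Ly / 2, hz = Lz / 2;
  const double r2max = rmax * rmax;
  for (int i = 0; i < n - 1; ++i) {
    const double xi = x[i], yi = y[i], zi = z[i];
    for (int j = i + 1; j < n; ++j) {
      double dx = fold(x[j] - xi, Lx, hx);
      if (dx > rmax || dx < -rmax) continue;
      double dy = fold(y[j] - yi, Ly, hy);
      if (dy > rmax || dy < -rmax) continue;
      double dz = fold(z[j] - zi, Lz, hz);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < r2max) {
        int k = (int)(std::sqrt(r2) / dr);
        if (k < nb) ++hist[k];
      }
    }
  }
  return hist;
}

// Cross mode: ordered pairs (a in A, b in B), skipping identical sites.
// [[Rcpp::export]]
IntegerVector pair_hist_cross(NumericMatrix xyz, IntegerVector rowsA,
                              IntegerVector rowsB, NumericVector box,
                              double rmax, double dr) {
  const int na = rowsA.size(), nbt = rowsB.size();
  const int nb = (int)std::ceil(rmax / dr);
  IntegerVector hist(nb);
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const double hx = Lx / 2, hy = Ly / 2, hz = Lz / 2;
  const double r2max = rmax * rmax;
  for (int i = 0; i < na; ++i) {
    const int a = rowsA[i] - 1;
    const double ax = xyz(a, 0), ay = xyz(a, 1), az = xyz(a, 2);
    for (int j = 0; j < nbt; ++j) {
      const int b = rowsB[j] - 1;
      if (a == b) continue;
      double dx = fold(xyz(b, 0) - ax, Lx, hx);
      if (dx > rmax || dx < -rmax) continue;
      double dy = fold(xyz(b, 1) - ay, Ly, hy);
      if (dy > rmax || dy < -rmax) continue;
      double dz = fold(xyz(b, 2) - az, Lz, hz);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < r2max) {
        int k = (int)(std::sqrt(r2) / dr);
        if (k < nb) ++hist[k];
      }
    }
  }
  return hist;
}

// Minimum distance between two pre-wrapped site groups.
// [[Rcpp::export]]
double min_pair_dist(NumericMatrix xyz, IntegerVector rowsA,
                     IntegerVector rowsB, NumericVector box) {
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const double hx = Lx / 2, hy = Ly / 2, hz = Lz / 2;
  double best = R_PosInf;
  for (int i = 0; i < rowsA.size(); ++i) {
    const int a = rowsA[i] - 1;
    const double ax = xyz(a, 0), ay = xyz(a, 1), az = xyz(a, 2);
    for (int j = 0; j < rowsB.size(); ++j) {
      const int b = rowsB[j] - 1;
      double dx = fold(xyz(b, 0) - ax, Lx, hx);
      double dy = fold(xyz(b, 1) - ay, Ly, hy);
      double dz = fold(xyz(b, 2) - az, Lz, hz);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < best) best = r2;
    }
  }
  return std::sqrt(best);
}
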