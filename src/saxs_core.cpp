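#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double sinc(double x) {
  // sin(x)/x with the limit value 1 at x = 0
  if (std::fabs(x) < 1e-12) return 1.0;
  return std::sin(x) / x;
}

// Direct O(n^2) Debye sum: S(q) = sum_ij b_i b_j sin(q d_ij)/(q d_ij).
// Returns the unnormalized, unsmeared sum for each q.
// [[Rcpp::export]]
NumericVector cpp_debye_direct(const NumericMatrix& xyz,
                               const NumericVector& b,
                               const NumericVector& q) {
  const int n = xyz.nrow(), nq = q.size();
  NumericVector out(nq);
  // self terms
  double self = 0.0;
  for (int i = 0; i < n; ++i) self += b[i] * b[i];
  std::vector<double> acc(nq, 0.0);
  for (int i = 0; i < n; ++i) {
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - xyz(j, 0), dy = yi - xyz(j, 1), dz = zi - xyz(j, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double bb = 2.0 * b[i] * b[j];
      for (int k = 0; k < nq; ++k) acc[k] += bb * sinc(q[k] * d);
    }
  }
  for (int k = 0; k < nq; ++k) out[k] = self + acc[k];
  return out;
}

// Weighted pair-distance histogram for the accelerated Debye sum.
// Per bin: total weight w = sum b_i b_j, weighted mean distance, and the
// weighted second central moment (for a curvature correction of sinc).
// [[Rcpp::export]]
List cpp_pair_hist(const NumericMatrix& xyz,
                   const NumericVector& b,
                   const double bin_width) {
  const int n = xyz.nrow();
  double dmax = 0.0, self = 0.0;
  for (int i = 0; i < n; ++i) self += b[i] * b[i];
  // first pass: max distance
  for (int i = 0; i < n; ++i) {
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - xyz(j, 0), dy = yi - xyz(j, 1), dz = zi - xyz(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > dmax) dmax = d2;
    }
  }
  dmax = std::sqrt(dmax);
  const int nb = std::max(1, (int)std::ceil(dmax / bin_width + 1e-9));
  std::vector<double> w(nb, 0.0), s1(nb, 0.0), s2(nb, 0.0);
  for (int i = 0; i < n; ++i) {
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - xyz(j, 0), dy = yi - xyz(j, 1), dz = zi - xyz(j, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      int k = (int)(d / bin_width);
      if (k >= nb) k = nb - 1;
      const double bb = 2.0 * b[i] * b[j];
      w[k] += bb;
      s1[k] += bb * d;
      s2[k] += bb * d * d;
    }
  }
  std::vector<double> dm, m2, wt;
  for (int k = 0; k < nb; ++k) {
    if (w[k] <= 0.0) continue;
    const double mean = s1[k] / w[k];
    wt.push_back(w[k]);
    dm.push_back(mean);
    m2.push_back(std::max(0.0, s2[k] / w[k] - mean * mean));
  }
  return List::create(_["w"] = wt, _["d"] = dm, _["m2"] = m2,
                      _["self"] = self, _["dmax"] = dmax);
}

// Evaluate the Debye sum from a pair histogram with a second-order
// (curvature) correction: f(d) ~ f(dbar) + f''(dbar) * m2 / 2.
// [[Rcpp::export]]
NumericVector cpp_debye_from_hist(const NumericVector& w,
                                  const NumericVector& d,
                                  const NumericVector& m2,
                                  const double self,
                                  const NumericVector& q) {
  const int nb = w.size(), nq = q.size();
  NumericVector out(nq);
  for (int k = 0; k < nq; ++k) {
    const double qk = q[k];
    double acc = self;
    if (qk < 1e-12) {
      for (int i = 0; i < nb; ++i) acc += w[i];
    } else {
      for (int i = 0; i < nb; ++i) {
        const double x = qk * d[i];
        double f, fpp;
        if (x < 1e-8) {
          f = 1.0;
          fpp = -qk * qk / 3.0;
        } else {
          const double s = std::sin(x), c = std::cos(x);
          f = s / x;
          // d^2/dd^2 [sin(qd)/(qd)] = q^2 * (2 s/x^3 - 2 c/x^2 - s/x)
          fpp = qk * qk * (2.0 * s / (x * x * x) - 2.0 * c / (x * x) - s / x);
        }
        acc += w[i] * (f + 0.5 * fpp * m2[i]);
      }
    }
    out[k] = acc;
  }
  return out;
}

// Orientation-averaged amplitude about the b-weighted centroid:
// sum_i b_i sin(q d_iCM)/(q d_iCM), unnormalized and unsmeared.
// [[Rcpp::export]]
NumericVector cpp_amplitude_cm(const NumericMatrix& xyz,
                               const NumericVector& b,
                               const NumericVector& q) {
  const int n = xyz.nrow(), nq = q.size();
  double bsum = 0.0, cx = 0.0, cy = 0.0, cz = 0.0;
  for (int i = 0; i < n; ++i) {
    bsum += b[i];
    cx += b[i] * xyz(i, 0);
    cy += b[i] * xyz(i, 1);
    cz += b[i] * xyz(i, 2);
  }
  cx /= bsum; cy /= bsum; cz /= bsum;
  std::vector<double> d(n);
  for (int i = 0; i < n; ++i) {
    const double dx = xyz(i, 0) - cx, dy = xyz(i, 1) - cy,
                 dz = xyz(i, 2) - cz;
    d[i] = std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  NumericVector out(nq);
  for (int k = 0; k < nq; ++k) {
    double acc = 0.0;
    for (int i = 0; i < n; ++i) acc += b[i] * sinc(q[k] * d[i]);
    out[k] = acc;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_max_pair_dist(const NumericMatrix& xyz) {
  const int n = xyz.nrow();
  double best = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - xyz(j, 0), dy = yi - xyz(j, 1), dz = zi - xyz(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  }
  return std::sqrt(best);
}

// Soft-sphere excluded-volume penalty between bodies:
// sum over pairs in different bodies with d < cutoff of (cutoff - d)^2.
// Cell-list pruning keeps this near-linear for clash-free states.
// [[Rcpp::export]]
double cpp_clash_penalty(const NumericMatrix& xyz,
                         const IntegerVector& body,
                         const double cutoff) {
  const int n = xyz.nrow();
  if (n == 0) return 0.0;
  double xmin = xyz(0, 0), ymin = xyz(0, 1), zmin = xyz(0, 2);
  for (int i = 1; i < n; ++i) {
    if (xyz(i, 0) < xmin) xmin = xyz(i, 0);
    if (xyz(i, 1) < ymin) ymin = xyz(i, 1);
    if (xyz(i, 2) < zmin) zmin = xyz(i, 2);
  }
  const double cell = cutoff;
  std::vector<int> cx(n), cy(n), cz(n);
  int nx = 1, ny = 1, nz = 1;
  for (int i = 0; i < n; ++i) {
    cx[i] = (int)((xyz(i, 0) - xmin) / cell);
    cy[i] = (int)((xyz(i, 1) - ymin) / cell);
    cz[i] = (int)((xyz(i, 2) - zmin) / cell);
    if (cx[i] + 1 > nx) nx = cx[i] + 1;
    if (cy[i] + 1 > ny) ny = cy[i] + 1;
    if (cz[i] + 1 > nz) nz = cz[i] + 1;
  }
  std::vector<std::vector<int> > cells((size_t)nx * ny * nz);
  for (int i = 0; i < n; ++i)
    cells[(size_t)(cx[i] + nx * (cy[i] + (size_t)ny * cz[i]))].push_back(i);
  const double c2 = cutoff * cutoff;
  double pen = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int ax = cx[i] - 1; ax <= cx[i] + 1; ++ax) {
      if (ax < 0 || ax >= nx) continue;
      for (int ay = cy[i] - 1; ay <= cy[i] + 1; ++ay) {
        if (ay < 0 || ay >= ny) continue;
        for (int az = cz[i] - 1; az <= cz[i] + 1; ++az) {
          if (az < 0 || az >= nz) continue;
          const std::vector<int>& cl = cells[(size_t)(ax + nx * (ay + (size_t)ny * az))];
          for (size_t t = 0; t < cl.size(); ++t) {
            const int j = cl[t];
            if (j <= i || body[j] == body[i]) continue;
            const double dx = xyz(i, 0) - xyz(j, 0);
            const double dy = xyz(i, 1) - xyz(j, 1);
            const double dz = xyz(i, 2) - xyz(j, 2);
            const double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 < c2) {
              const double d = std::sqrt(d2);
              pen += (cutoff - d) * (cutoff - d);
            }
          }
        }
      }
    }
  }
  return pen;
}

// Minimum distance from each query point to a reference point set.
// [[Rcpp::export]]
NumericVector cpp_min_dist(const NumericMatrix& query,
                           const NumericMatrix& ref) {
  const int m = query.nrow(), n = ref.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double best = R_PosInf;
    const double xi = query(i, 0), yi = query(i, 1), zi = query(i, 2);
    for (int j = 0; j < n; ++j) {
      const double dx = xi - ref(j, 0), dy = yi - ref(j, 1), dz = zi - ref(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
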