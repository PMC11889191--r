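#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Pt {
  double x, y;
};

std::vector<Pt> sorted_by_x(const NumericVector& x, const NumericVector& y) {
  std::vector<Pt> p(x.size());
  for (int i = 0; i < x.size(); ++i) p[i] = {x[i], y[i]};
  std::sort(p.begin(), p.end(), [](const Pt& a, const Pt& b) { return a.x < b.x; });
  return p;
}

}  // namespace

// Count unordered reference-target pairs with Euclidean distance <= r.
// Plane sweep over x-sorted copies; exact (no tolerance), inclusive boundary.
// [[Rcpp::export(name = ".countPairsCross")]]
double count_pairs_cross(NumericVector xr, NumericVector yr,
                         NumericVector xt, NumericVector yt, double r) {
  if (r < 0) stop("radius must be non-negative");
  const std::vector<Pt> a = sorted_by_x(xr, yr);
  const std::vector<Pt> b = sorted_by_x(xt, yt);
  const double r2 = r * r;
  double count = 0.0;
  std::size_t lo = 0;
  for (std::size_t i = 0; i < a.size(); ++i) {
    while (lo < b.size() && b[lo].x < a[i].x - r) ++lo;
    for (std::size_t j = lo; j < b.size() && b[j].x <= a[i].x + r; ++j) {
      const double dx = a[i].x - b[j].x, dy = a[i].y - b[j].y;
      if (dx * dx + dy * dy <= r2) count += 1.0;
    }
  }
  return count;
}

// Count unordered distinct pairs within one point set (self-pairs excluded).
// [[Rcpp::export(name = ".countPairsSelf")]]
double count_pairs_self(NumericVector x, NumericVector y, double r) {
  if (r < 0) stop("radius must be non-negative");
  const std::vector<Pt> p = sorted_by_x(x, y);
  const double r2 = r * r;
  double count = 0.0;
  for (std::size_t i = 0; i < p.size(); ++i) {
    for (std::size_t j = i + 1; j < p.size() && p[j].x <= p[i].x + r; ++j) {
      const double dx = p[i].x - p[j].x, dy = p[i].y - p[j].y;
      if (dx * dx + dy * dy <= r2) count += 1.0;
    }
  }
  return count;
}

// For each query point, the distance to the nearest point of (px, py).
// Binary search on x then outward expansion with pruning.
// [[Rcpp::export(name = ".nearestDist")]]
NumericVector nearest_dist(NumericVector qx, NumericVector qy,
                           NumericVector px, NumericVector py) {
  const int nq = qx.size(), np = px.size();
  NumericVector out(nq);
  if (np == 0) {
    std::fill(out.begin(), out.end(), R_PosInf);
    return out;
  }
  const std::vector<Pt> p = sorted_by_x(px, py);
  for (int i = 0; i < nq; ++i) {
    const double x = qx[i], y = qy[i];
    // first index with p.x >= x
    int hi = std::lower_bound(p.begin(), p.end(), x,
                              [](const Pt& a, double v) { return a.x < v; }) -
             p.begin();
    int lo = hi - 1;
    double best2 = R_PosInf;
    while (lo >= 0 || hi < np) {
      const double dlo = lo >= 0 ? x - p[lo].x : R_PosInf;
      const double dhi = hi < np ? p[hi].x - x : R_PosInf;
      if (dlo * dlo > best2 && dhi * dhi > best2) break;
      if (dlo <= dhi) {
        const double dx = x - p[lo].x, dy = y - p[lo].y;
        const double d2 = dx * dx + dy * dy;
        if (d2 < best2) best2 = d2;
        --lo;
      } else {
        const double dx = x - p[hi].x, dy = y - p[hi].y;
        const double d2 = dx * dx + dy * dy;
        if (d2 < best2) best2 = d2;
        ++hi;
      }
    }
    out[i] = std::sqrt(best2);
  }
  return out;
}
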