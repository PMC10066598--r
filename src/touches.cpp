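#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <unordered_map>
using namespace Rcpp;

// Minimum distance between two 3D segments (standard clamped closed form).
static double seg_seg_dist(const double* p1, const double* q1,
                           const double* p2, const double* q2) {
  double d1[3], d2[3], r[3];
  for (int k = 0; k < 3; k++) {
    d1[k] = q1[k] - p1[k];
    d2[k] = q2[k] - p2[k];
    r[k] = p1[k] - p2[k];
  }
  double a = d1[0]*d1[0] + d1[1]*d1[1] + d1[2]*d1[2];
  double e = d2[0]*d2[0] + d2[1]*d2[1] + d2[2]*d2[2];
  double f = d2[0]*r[0] + d2[1]*r[1] + d2[2]*r[2];
  double s, t;
  const double EPS = 1e-12;
  if (a <= EPS && e <= EPS) { s = t = 0.0; }
  else if (a <= EPS) { s = 0.0; t = std::min(1.0, std::max(0.0, f / e)); }
  else {
    double c = d1[0]*r[0] + d1[1]*r[1] + d1[2]*r[2];
    if (e <= EPS) { t = 0.0; s = std::min(1.0, std::max(0.0, -c / a)); }
    else {
      double b = d1[0]*d2[0] + d1[1]*d2[1] + d1[2]*d2[2];
      double denom = a * e - b * b;
      s = denom > EPS ? std::min(1.0, std::max(0.0, (b * f - c * e) / denom)) : 0.0;
      t = (b * s + f) / e;
      if (t < 0.0) { t = 0.0; s = std::min(1.0, std::max(0.0, -c / a)); }
      else if (t > 1.0) { t = 1.0; s = std::min(1.0, std::max(0.0, (b - c) / a)); }
    }
  }
  double dx = p1[0] + d1[0]*s - (p2[0] + d2[0]*t);
  double dy = p1[1] + d1[1]*s - (p2[1] + d2[1]*t);
  double dz = p1[2] + d1[2]*s - (p2[2] + d2[2]*t);
  return std::sqrt(dx*dx + dy*dy + dz*dz);
}

// Apposition ("touch") detection between pre-element segments and
// post-element segments. A touch is a pair whose surface gap
// (centerline distance minus both mean radii, clamped at 0) is
// <= touch_distance, with pre cell != post cell.
//
// seg matrix columns: x0 y0 z0 x1 y1 z1 radius. cell/elem/node are
// per-segment integer vectors: elem 1 = soma, 2 = axon, 3 = dendrite.
// pre_ok / post_ok flag which segments may act as pre / post elements.
// [[Rcpp::export]]
DataFrame cpp_detect_touches(NumericMatrix seg, IntegerVector cell,
                             IntegerVector node, LogicalVector pre_ok,
                             LogicalVector post_ok, double touch_distance) {
  int n = seg.nrow();
  // grid on segment midpoints; bin size from max segment extent
  double maxlen = 1.0;
  for (int i = 0; i < n; i++) {
    double dx = seg(i,3)-seg(i,0), dy = seg(i,4)-seg(i,1), dz = seg(i,5)-seg(i,2);
    double L = std::sqrt(dx*dx+dy*dy+dz*dz);
    if (L > maxlen) maxlen = L;
  }
  double rmax = 0.0;
  for (int i = 0; i < n; i++) if (seg(i,6) > rmax) rmax = seg(i,6);
  double cellsz = maxlen + touch_distance + 2 * rmax + 1e-9;

  double mn[3] = {1e30, 1e30, 1e30};
  for (int i = 0; i < n; i++)
    for (int k = 0; k < 3; k++) {
      double lo = std::min(seg(i,k), seg(i,k+3));
      if (lo < mn[k]) mn[k] = lo;
    }

  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve((size_t)n * 2);
  std::vector<int> gx(n), gy(n), gz(n);
  for (int i = 0; i < n; i++) {
    double cx = 0.5*(seg(i,0)+seg(i,3)), cy = 0.5*(seg(i,1)+seg(i,4)), cz = 0.5*(seg(i,2)+seg(i,5));
    gx[i] = (int)((cx - mn[0]) / cellsz);
    gy[i] = (int)((cy - mn[1]) / cellsz);
    gz[i] = (int)((cz - mn[2]) / cellsz);
    long long key = ((long long)gx[i] << 40) ^ ((long long)gy[i] << 20) ^ (long long)gz[i];
    grid[key].push_back(i);
  }

  std::vector<int> out_pre_cell, out_post_cell, out_pre_node, out_post_node;
  std::vector<double> out_gap, out_x, out_y, out_z;

  double p1[3], q1[3], p2[3], q2[3];
  for (int i = 0; i < n; i++) {
    if (!pre_ok[i]) continue;
    p1[0]=seg(i,0); p1[1]=seg(i,1); p1[2]=seg(i,2);
    q1[0]=seg(i,3); q1[1]=seg(i,4); q1[2]=seg(i,5);
    for (int dx = -1; dx <= 1; dx++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dz = -1; dz <= 1; dz++) {
          long long key = ((long long)(gx[i]+dx) << 40) ^ ((long long)(gy[i]+dy) << 20) ^ (long long)(gz[i]+dz);
          auto it = grid.find(key);
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (!post_ok[j] || cell[j] == cell[i]) continue;
            // when both directions are eligible, emit each ordered pair once
            p2[0]=seg(j,0); p2[1]=seg(j,1); p2[2]=seg(j,2);
            q2[0]=seg(j,3); q2[1]=seg(j,4); q2[2]=seg(j,5);
            double d = seg_seg_dist(p1, q1, p2, q2);
            double gap = d - seg(i,6) - seg(j,6);
            if (gap < 0) gap = 0;
            if (gap <= touch_distance) {
              out_pre_cell.push_back(cell[i]);
              out_post_cell.push_back(cell[j]);
              out_pre_node.push_back(node[i]);
              out_post_node.push_back(node[j]);
              out_gap.push_back(gap);
              out_x.push_back(0.5*(p1[0]+q1[0]));
              out_y.push_back(0.5*(p1[1]+q1[1]));
              out_z.push_back(0.5*(p1[2]+q1[2]));
            }
          }
        }
  }

  return DataFrame::create(
    _["pre"] = out_pre_cell, _["post"] = out_post_cell,
    _["pre_node"] = out_pre_node, _["post_node"] = out_post_node,
    _["gap"] = out_gap,
    _["x"] = out_x, _["y"] = out_y, _["z"] = out_z);
}
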