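#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 3-D voxel grids are stored column-major with the first (x) index fastest,
// matching R's array layout: lin = ix + nx*(iy + ny*iz), all 0-based.

namespace {

struct Offsets {
  std::vector<int> dx, dy, dz;
  std::vector<double> step; // Euclidean step length in voxel units
};

Offsets make_offsets(int connectivity) {
  Offsets o;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nn = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nn == 0) continue;
        if (connectivity == 6 && nn > 1) continue;
        o.dx.push_back(dx); o.dy.push_back(dy); o.dz.push_back(dz);
        o.step.push_back(std::sqrt((double)(dx*dx + dy*dy + dz*dz)));
      }
  return o;
}

} // namespace

// Label connected components of {values > threshold}. Labels are 1-based in
// discovery order (scan order of the lowest linear index in each component);
// voxels at or below threshold get 0.
// [[Rcpp::export]]
IntegerVector cpp_label_components(NumericVector values, IntegerVector dims,
                                   double threshold, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = values.size();
  IntegerVector labels(n, 0);
  Offsets off = make_offsets(connectivity);
  int next_label = 0;
  std::vector<int> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (labels[s] != 0 || !(values[s] > threshold)) continue;
    ++next_label;
    labels[s] = next_label;
    stack.clear();
    stack.push_back((int)s);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int ix = cur % nx, iy = (cur / nx) % ny, iz = cur / (nx * ny);
      for (size_t k = 0; k < off.dx.size(); ++k) {
        int jx = ix + off.dx[k], jy = iy + off.dy[k], jz = iz + off.dz[k];
        if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
          continue;
        int j = jx + nx * (jy + ny * jz);
        if (labels[j] == 0 && values[j] > threshold) {
          labels[j] = next_label;
          stack.push_back(j);
        }
      }
    }
  }
  return labels;
}

// Density-weighted Dijkstra over the voxels of one region.
//
// Edge cost for a step u -> v of Euclidean length L voxels:
//   node-entered form (the default): cost = w(rho_v) * L
//   symmetrized form:                cost = 0.5 * (w(rho_u) + w(rho_v)) * L
// with w(rho) = ((rho_max - rho) / (rho_max - rho_min))^a, clamped to [0,1];
// a flat region (rho_max == rho_min) gives all weights 0.
//
// sources: 0-based linear indices, all seeded at distance 0 (multi-source
// search is used for branch-length measurement from a whole path).
// Returns weighted distance, 0-based parent (-1 = source/unreached), and the
// unweighted Angstrom length accumulated along each chosen path.
// [[Rcpp::export]]
List cpp_dijkstra(NumericVector dens, LogicalVector in_region,
                  IntegerVector dims, NumericVector voxel_size,
                  IntegerVector sources, double rho_min, double rho_max,
                  double exponent_a, bool symmetric, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = dens.size();
  const double vx = voxel_size[0], vy = voxel_size[1], vz = voxel_size[2];
  const double span = rho_max - rho_min;
  Offsets off = make_offsets(connectivity);

  std::vector<double> wnode(n, 0.0);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!in_region[i]) continue;
    if (span <= 0) { wnode[i] = 0.0; continue; }
    double t = (rho_max - dens[i]) / span;
    if (t < 0) t = 0; else if (t > 1) t = 1;
    wnode[i] = std::pow(t, exponent_a);
  }

  NumericVector dist(n, R_PosInf), udist(n, R_PosInf);
  IntegerVector parent(n, -1);
  std::vector<bool> done(n, false);

  typedef std::pair<double, int> QE; // (dist, node); ties -> smaller index
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (R_xlen_t k = 0; k < sources.size(); ++k) {
    int s = sources[k];
    if (s < 0 || s >= n || !in_region[s]) continue;
    dist[s] = 0.0; udist[s] = 0.0;
    pq.push(QE(0.0, s));
  }

  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    int u = top.second;
    if (done[u] || top.first > dist[u]) continue;
    done[u] = true;
    int ix = u % nx, iy = (u / nx) % ny, iz = u / (nx * ny);
    for (size_t k = 0; k < off.dx.size(); ++k) {
      int jx = ix + off.dx[k], jy = iy + off.dy[k], jz = iz + off.dz[k];
      if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
        continue;
      int v = jx + nx * (jy + ny * jz);
      if (!in_region[v] || done[v]) continue;
      double w = symmetric ? 0.5 * (wnode[u] + wnode[v]) : wnode[v];
      double nd = dist[u] + w * off.step[k];
      double ddx = off.dx[k] * vx, ddy = off.dy[k] * vy, ddz = off.dz[k] * vz;
      double stepA = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
      if (nd < dist[v] - 1e-15) {
        dist[v] = nd;
        udist[v] = udist[u] + stepA;
        parent[v] = u;
        pq.push(QE(nd, v));
      } else if (nd < dist[v] + 1e-15 && parent[v] >= 0 && u < parent[v]) {
        // deterministic tie-break: prefer the lexicographically smaller parent
        udist[v] = udist[u] + stepA;
        parent[v] = u;
        pq.push(QE(dist[v], v));
      }
    }
  }
  return List::create(_["dist"] = dist, _["parent"] = parent,
                      _["udist"] = udist);
}
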