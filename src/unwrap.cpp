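#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Voxels are addressed by 0-based linear index in column-major (x fastest)
// order. An undirected 6-neighbour edge is identified by its axis (0 = x,
// 1 = y, 2 = z) and the lower-corner voxel, so each edge exists exactly once.
// Edge id = axis * nvox + lower voxel index.
//
// Costs are 8-bit: 1 (best connection) .. 255 (worst); 0 = no connection.
// Rewrap rounding uses nearbyint(), i.e. round-half-to-even under the default
// rounding mode, matching R's round().

static const double TWO_PI = 6.283185307179586476925286766559;

struct Grid {
  int nx, ny, nz;
  R_xlen_t nvox;
  const int *cx, *cy, *cz; // per-axis cost arrays

  // cost of edge along `axis` with lower corner (ix,iy,iz); caller must
  // ensure the edge exists (ix < nx-1 for axis 0, etc.)
  inline int cost(int axis, int ix, int iy, int iz) const {
    switch (axis) {
    case 0: return cx[ix + (R_xlen_t)(nx - 1) * (iy + (R_xlen_t)ny * iz)];
    case 1: return cy[ix + (R_xlen_t)nx * (iy + (R_xlen_t)(ny - 1) * iz)];
    default: return cz[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
    }
  }
  inline R_xlen_t stride(int axis) const {
    switch (axis) {
    case 0: return 1;
    case 1: return nx;
    default: return (R_xlen_t)nx * ny;
    }
  }
  inline void coords(R_xlen_t v, int &ix, int &iy, int &iz) const {
    ix = (int)(v % nx);
    iy = (int)((v / nx) % ny);
    iz = (int)(v / ((R_xlen_t)nx * ny));
  }
};

// FIFO bucket priority queue over integer costs 1..255 with lazy deletion.
struct BucketQueue {
  std::vector<std::vector<int64_t> > bucket;
  std::vector<size_t> head; // index of next element to pop per bucket
  int curmin;
  size_t nlive;

  BucketQueue() : bucket(256), head(256, 0), curmin(256), nlive(0) {}

  inline void push(int cost, int64_t id) {
    bucket[cost].push_back(id);
    ++nlive;
    if (cost < curmin) curmin = cost;
  }
  inline bool empty() const { return nlive == 0; }
  inline int64_t pop() {
    while (curmin <= 255 && head[curmin] >= bucket[curmin].size()) {
      bucket[curmin].clear();
      head[curmin] = 0;
      ++curmin;
    }
    int64_t id = bucket[curmin][head[curmin]++];
    --nlive;
    return id;
  }
};

// push every cost>0 edge between voxel v and a not-yet-visited neighbour
static void push_incident(const Grid &g, BucketQueue &q, R_xlen_t v,
                          const std::vector<uint8_t> &visited) {
  int ix, iy, iz;
  g.coords(v, ix, iy, iz);
  const int lo[3] = {ix, iy, iz};
  const int hi[3] = {g.nx - 1, g.ny - 1, g.nz - 1};
  for (int axis = 0; axis < 3; ++axis) {
    R_xlen_t s = g.stride(axis);
    if (lo[axis] < hi[axis] && !visited[v + s]) { // +axis edge, lower = v
      int c = g.cost(axis, ix, iy, iz);
      if (c > 0) q.push(c, (int64_t)axis * g.nvox + v);
    }
    if (lo[axis] > 0 && !visited[v - s]) {        // -axis edge, lower = v - s
      int jx = ix, jy = iy, jz = iz;
      if (axis == 0) --jx; else if (axis == 1) --jy; else --jz;
      int c = g.cost(axis, jx, jy, jz);
      if (c > 0) q.push(c, (int64_t)axis * g.nvox + (v - s));
    }
  }
}

// Scan all edges in voxel-major order (per voxel: +x, +y, +z) and return the
// lower endpoint of the first minimum-cost edge among edges whose endpoints
// are both unseeded (`eligible`). Returns -1 if no cost>0 edge exists.
static R_xlen_t scan_seed(const Grid &g, const std::vector<uint8_t> *eligible) {
  int best = 256;
  R_xlen_t best_v = -1;
  for (R_xlen_t v = 0; v < g.nvox; ++v) {
    if (eligible && !(*eligible)[v]) continue;
    int ix, iy, iz;
    g.coords(v, ix, iy, iz);
    const int room[3] = {g.nx - 1 - ix, g.ny - 1 - iy, g.nz - 1 - iz};
    for (int axis = 0; axis < 3; ++axis) {
      if (room[axis] <= 0) continue;
      if (eligible && !(*eligible)[v + g.stride(axis)]) continue;
      int c = g.cost(axis, ix, iy, iz);
      if (c > 0 && c < best) {
        best = c;
        best_v = v;
        if (best == 1) return best_v; // cannot improve
      }
    }
  }
  return best_v;
}

// [[Rcpp::export(name = ".select_seed_cpp")]]
R_xlen_t select_seed_cpp(IntegerVector dim, IntegerVector cx, IntegerVector cy,
                         IntegerVector cz) {
  Grid g;
  g.nx = dim[0]; g.ny = dim[1]; g.nz = dim[2];
  g.nvox = (R_xlen_t)g.nx * g.ny * g.nz;
  g.cx = INTEGER(cx); g.cy = INTEGER(cy); g.cz = INTEGER(cz);
  return scan_seed(g, NULL); // 0-based; -1 if none
}

// [[Rcpp::export(name = ".unwrap_spatial_cpp")]]
List unwrap_spatial_cpp(NumericVector phase, IntegerVector dim,
                        IntegerVector cx, IntegerVector cy, IntegerVector cz,
                        R_xlen_t seed0, bool track_order) {
  Grid g;
  g.nx = dim[0]; g.ny = dim[1]; g.nz = dim[2];
  g.nvox = (R_xlen_t)g.nx * g.ny * g.nz;
  g.cx = INTEGER(cx); g.cy = INTEGER(cy); g.cz = INTEGER(cz);

  NumericVector theta = clone(phase);
  std::vector<uint8_t> visited(g.nvox, 0);
  std::vector<uint8_t> unseeded(g.nvox, 1); // eligible for re-seeding
  IntegerVector order;
  if (track_order) order = IntegerVector(g.nvox, NA_INTEGER);
  int rank = 0;

  std::vector<R_xlen_t> comp_seed;
  std::vector<double> comp_size;

  R_xlen_t seed = seed0; // 0-based, or -1 for automatic
  if (seed < 0) seed = scan_seed(g, NULL);
  if (seed < 0) stop("no edge with cost > 0: nothing to unwrap");

  BucketQueue q;
  const double *phi = REAL(phase);
  double *th = REAL(theta);

  for (;;) {
    // anchor this component's seed at its measured (wrapped) value
    visited[seed] = 1;
    unseeded[seed] = 0;
    if (track_order) order[seed] = ++rank;
    comp_seed.push_back(seed);
    double n_in_comp = 1;
    push_incident(g, q, seed, visited);

    while (!q.empty()) {
      int64_t id = q.pop();
      int axis = (int)(id / g.nvox);
      R_xlen_t lo = (R_xlen_t)(id % g.nvox);
      R_xlen_t hi = lo + g.stride(axis);
      if (visited[lo] && visited[hi]) continue; // lazy deletion
      R_xlen_t nv = visited[lo] ? hi : lo;      // new voxel
      R_xlen_t rv = visited[lo] ? lo : hi;      // its visited reference
      th[nv] = phi[nv] - TWO_PI * nearbyint((phi[nv] - th[rv]) / TWO_PI);
      visited[nv] = 1;
      unseeded[nv] = 0;
      if (track_order) order[nv] = ++rank;
      n_in_comp += 1;
      push_incident(g, q, nv, visited);
    }
    comp_size.push_back(n_in_comp);

    // further cost-connected components, each re-seeded independently
    seed = scan_seed(g, &unseeded);
    if (seed < 0) break;
  }

  LogicalVector vis(g.nvox);
  for (R_xlen_t v = 0; v < g.nvox; ++v) vis[v] = (visited[v] != 0);

  NumericVector seeds(comp_seed.size());
  NumericVector sizes(comp_size.size());
  for (size_t k = 0; k < comp_seed.size(); ++k) {
    seeds[k] = (double)comp_seed[k]; // 0-based; R side converts
    sizes[k] = comp_size[k];
  }

  List out = List::create(_["theta"] = theta, _["visited"] = vis,
                          _["seed"] = (double)comp_seed[0],
                          _["component_seeds"] = seeds,
                          _["component_sizes"] = sizes);
  if (track_order) out["order"] = order;
  return out;
}
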