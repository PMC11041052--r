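// 3D morphological primitives used by the abdomen-mask and cyst-filter
// stages: connected-component labelling (6/18/26-connectivity), ball
// erosion, border-seeded hole filling and component-contact queries.

#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

static std::vector<std::array<int,3>> neighbourhood(int connectivity) {
  std::vector<std::array<int,3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off.push_back({dx, dy, dz});
      }
  return off;
}

// Label the nonzero voxels of `mask`; background stays 0, components 1..K.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims,
                                   int connectivity) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const size_t n = (size_t)X * Y * Z;
  IntegerVector lab(n);
  const auto off = neighbourhood(connectivity);
  std::vector<size_t> stack;
  int next = 0;
  for (size_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      const size_t v = stack.back();
      stack.pop_back();
      const int x = (int)(v % X), y = (int)((v / X) % Y), z = (int)(v / ((size_t)X * Y));
      for (const auto& d : off) {
        const int nx = x + d[0], ny = y + d[1], nz = z + d[2];
        if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z) continue;
        const size_t u = (size_t)nx + (size_t)X * (ny + (size_t)Y * nz);
        if (mask[u] != 0 && lab[u] == 0) { lab[u] = next; stack.push_back(u); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Erosion by a discrete ball: a voxel survives iff every offset within
// `radius` (Euclidean, voxel units) is in-bounds and foreground.
// [[Rcpp::export]]
IntegerVector cpp_erode_ball(IntegerVector mask, IntegerVector dims,
                             double radius) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  IntegerVector out((size_t)X * Y * Z);
  const int r = (int)std::floor(radius);
  std::vector<std::array<int,3>> off;
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx)
        if (dx * dx + dy * dy + dz * dz <= radius * radius)
          off.push_back({dx, dy, dz});
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x) {
        const size_t v = (size_t)x + (size_t)X * (y + (size_t)Y * z);
        if (mask[v] == 0) continue;
        bool keep = true;
        for (const auto& d : off) {
          const int nx = x + d[0], ny = y + d[1], nz = z + d[2];
          if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z ||
              mask[(size_t)nx + (size_t)X * (ny + (size_t)Y * nz)] == 0) {
            keep = false;
            break;
          }
        }
        if (keep) out[v] = 1;
      }
  out.attr("dim") = dims;
  return out;
}

// Fill internal cavities: background voxels unreachable (6-connectivity)
// from the volume border become foreground.
// [[Rcpp::export]]
IntegerVector cpp_fill_holes(IntegerVector mask, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const size_t n = (size_t)X * Y * Z;
  std::vector<char> outside(n, 0);
  std::vector<size_t> stack;
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x) {
        if (x != 0 && x != X - 1 && y != 0 && y != Y - 1 && z != 0 && z != Z - 1)
          continue;
        const size_t v = (size_t)x + (size_t)X * (y + (size_t)Y * z);
        if (mask[v] == 0 && !outside[v]) { outside[v] = 1; stack.push_back(v); }
      }
  const auto off = neighbourhood(6);
  while (!stack.empty()) {
    const size_t v = stack.back();
    stack.pop_back();
    const int x = (int)(v % X), y = (int)((v / X) % Y), z = (int)(v / ((size_t)X * Y));
    for (const auto& d : off) {
      const int nx = x + d[0], ny = y + d[1], nz = z + d[2];
      if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z) continue;
      const size_t u = (size_t)nx + (size_t)X * (ny + (size_t)Y * nz);
      if (mask[u] == 0 && !outside[u]) { outside[u] = 1; stack.push_back(u); }
    }
  }
  IntegerVector out(n);
  for (size_t v = 0; v < n; ++v) out[v] = (mask[v] != 0 || !outside[v]) ? 1 : 0;
  out.attr("dim") = dims;
  return out;
}

// For each component label 1..K, report whether any of its voxels has a
// neighbour (given connectivity) inside `other`.
// [[Rcpp::export]]
LogicalVector cpp_touching_labels(IntegerVector lab, IntegerVector other,
                                  IntegerVector dims, int connectivity,
                                  int nlab) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  LogicalVector touch(nlab);
  const auto off = neighbourhood(connectivity);
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x) {
        const size_t v = (size_t)x + (size_t)X * (y + (size_t)Y * z);
        const int l = lab[v];
        if (l == 0 || touch[l - 1]) continue;
        for (const auto& d : off) {
          const int nx = x + d[0], ny = y + d[1], nz = z + d[2];
          if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z) continue;
          if (other[(size_t)nx + (size_t)X * (ny + (size_t)Y * nz)] != 0) {
            touch[l - 1] = true;
            break;
          }
        }
      }
  return touch;
}
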