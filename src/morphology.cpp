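// 3D binary morphology kernels: topology-preserving thinning and
// hysteresis thresholding. Arrays are R column-major logical/numeric
// vectors with an explicit dim attribute; voxels outside the array are
// treated as background.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstring>

using namespace Rcpp;

namespace {

inline int idx3(int i, int j, int k, int d1, int d2) {
  return i + d1 * (j + d2 * k);
}

// Extract the 3x3x3 neighbourhood of (i,j,k) into nb[27],
// nb index = (di+1) + 3*(dj+1) + 9*(dk+1); out-of-bounds = 0.
inline void neighborhood27(const std::vector<unsigned char>& m,
                           int i, int j, int k,
                           int d1, int d2, int d3,
                           unsigned char nb[27]) {
  int p = 0;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di, ++p) {
        int ii = i + di, jj = j + dj, kk = k + dk;
        nb[p] = (ii >= 0 && ii < d1 && jj >= 0 && jj < d2 && kk >= 0 && kk < d3)
          ? m[idx3(ii, jj, kk, d1, d2)] : 0;
      }
}

inline void unpack(int p, int& di, int& dj, int& dk) {
  di = p % 3 - 1; dj = (p / 3) % 3 - 1; dk = p / 9 - 1;
}

// Number of 26-connected components of foreground in N26 (center excluded).
int t26_foreground(const unsigned char nb[27]) {
  int label[27]; for (int p = 0; p < 27; ++p) label[p] = -1;
  int ncomp = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || label[s] >= 0) continue;
    // BFS over 26-adjacency within the cube
    std::queue<int> q; q.push(s); label[s] = ncomp;
    while (!q.empty()) {
      int p = q.front(); q.pop();
      int pi, pj, pk; unpack(p, pi, pj, pk);
      for (int t = 0; t < 27; ++t) {
        if (t == 13 || !nb[t] || label[t] >= 0) continue;
        int ti, tj, tk; unpack(t, ti, tj, tk);
        if (std::abs(ti - pi) <= 1 && std::abs(tj - pj) <= 1 &&
            std::abs(tk - pk) <= 1) {
          label[t] = ncomp; q.push(t);
        }
      }
    }
    ++ncomp;
  }
  return ncomp;
}

// Number of 6-connected components of background in N18 that are
// 6-adjacent to the center.
int t6_background(const unsigned char nb[27]) {
  bool in18[27]; // face + edge neighbours of the center
  for (int p = 0; p < 27; ++p) {
    int di, dj, dk; unpack(p, di, dj, dk);
    int nz = (di != 0) + (dj != 0) + (dk != 0);
    in18[p] = (p != 13) && nz <= 2;
  }
  int label[27]; for (int p = 0; p < 27; ++p) label[p] = -1;
  int ncomp = 0;
  for (int s = 0; s < 27; ++s) {
    if (!in18[s] || nb[s] || label[s] >= 0) continue;
    std::queue<int> q; q.push(s); label[s] = ncomp;
    bool touches_center = false;
    while (!q.empty()) {
      int p = q.front(); q.pop();
      int pi, pj, pk; unpack(p, pi, pj, pk);
      if (std::abs(pi) + std::abs(pj) + std::abs(pk) == 1) touches_center = true;
      for (int t = 0; t < 27; ++t) {
        if (!in18[t] || nb[t] || label[t] >= 0) continue;
        int ti, tj, tk; unpack(t, ti, tj, tk);
        if (std::abs(ti - pi) + std::abs(tj - pj) + std::abs(tk - pk) == 1) {
          label[t] = ncomp; q.push(t);
        }
      }
    }
    if (touches_center) ++ncomp; else {
      // component not 6-adjacent to center: does not count, but keep label
    }
  }
  return ncomp;
}

// A voxel is simple iff deleting it preserves local topology:
// exactly one 26-component of foreground in N26 and exactly one
// 6-component of background in N18 touching the center face-wise.
inline bool is_simple(const unsigned char nb[27]) {
  return t26_foreground(nb) == 1 && t6_background(nb) == 1;
}

inline int n26_count(const unsigned char nb[27]) {
  int n = 0;
  for (int p = 0; p < 27; ++p) if (p != 13 && nb[p]) ++n;
  return n;
}

} // namespace

// Chamfer 3-4-5 distance-to-background (two raster passes).
static std::vector<int> chamfer345(const std::vector<unsigned char>& m,
                                   int d1, int d2, int d3) {
  const int BIG = 1 << 28;
  R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  std::vector<int> dist(n);
  for (R_xlen_t p = 0; p < n; ++p) dist[p] = m[p] ? BIG : 0;
  // forward pass
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        int p = idx3(i, j, k, d1, d2);
        if (!m[p]) continue;
        int best = dist[p];
        for (int dk = -1; dk <= 0; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (dk == 0 && (dj > 0 || (dj == 0 && di >= 0))) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              int w = 2 + (di != 0) + (dj != 0) + (dk != 0); // 3/4/5
              int dv = (ii >= 0 && ii < d1 && jj >= 0 && jj < d2 &&
                        kk >= 0 && kk < d3)
                ? dist[idx3(ii, jj, kk, d1, d2)] : 0; // outside = background
              if (dv + w < best) best = dv + w;
            }
        dist[p] = best;
      }
  // backward pass
  for (int k = d3 - 1; k >= 0; --k)
    for (int j = d2 - 1; j >= 0; --j)
      for (int i = d1 - 1; i >= 0; --i) {
        int p = idx3(i, j, k, d1, d2);
        if (!m[p]) continue;
        int best = dist[p];
        for (int dk = 0; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (dk == 0 && (dj < 0 || (dj == 0 && di <= 0))) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              int w = 2 + (di != 0) + (dj != 0) + (dk != 0);
              int dv = (ii >= 0 && ii < d1 && jj >= 0 && jj < d2 &&
                        kk >= 0 && kk < d3)
                ? dist[idx3(ii, jj, kk, d1, d2)] : 0;
              if (dv + w < best) best = dv + w;
            }
        dist[p] = best;
      }
  return dist;
}

// Distance-ordered homotopic thinning: peel simple, non-endpoint border
// voxels in increasing distance-to-background order so the surviving
// curve tracks the medial line of the object.
// [[Rcpp::export(name = ".thin3d_cpp")]]
LogicalVector thin3d_cpp(LogicalVector mask, IntegerVector dim) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dim");
  std::vector<unsigned char> m(n);
  for (R_xlen_t p = 0; p < n; ++p) m[p] = mask[p] == TRUE ? 1 : 0;

  std::vector<int> dist = chamfer345(m, d1, d2, d3);
  int maxd = 0;
  for (R_xlen_t p = 0; p < n; ++p) if (m[p] && dist[p] > maxd) maxd = dist[p];

  const int dirs[6][3] = {
    {-1, 0, 0}, {1, 0, 0}, {0, -1, 0}, {0, 1, 0}, {0, 0, -1}, {0, 0, 1}
  };
  unsigned char nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    // peel strictly inside-out: lower chamfer levels first, and within a
    // level alternate the six face directions for symmetric tie-breaking
    for (int L = 1; L <= maxd; ++L) {
      bool inner = true;
      while (inner) {
        inner = false;
        for (int d = 0; d < 6; ++d) {
          std::vector<int> cand;
          for (int k = 0; k < d3; ++k)
            for (int j = 0; j < d2; ++j)
              for (int i = 0; i < d1; ++i) {
                int p = idx3(i, j, k, d1, d2);
                if (!m[p] || dist[p] != L) continue;
                int ii = i + dirs[d][0], jj = j + dirs[d][1],
                    kk = k + dirs[d][2];
                bool border = !(ii >= 0 && ii < d1 && jj >= 0 && jj < d2 &&
                                kk >= 0 && kk < d3) ||
                              !m[idx3(ii, jj, kk, d1, d2)];
                if (!border) continue;
                neighborhood27(m, i, j, k, d1, d2, d3, nb);
                if (n26_count(nb) <= 1) continue; // curve endpoint: keep
                if (is_simple(nb)) cand.push_back(p);
              }
          // sequential deletion with re-check preserves topology even
          // when candidates are neighbours
          for (size_t c = 0; c < cand.size(); ++c) {
            int p = cand[c];
            int i = p % d1, j = (p / d1) % d2, k = p / (d1 * d2);
            neighborhood27(m, i, j, k, d1, d2, d3, nb);
            if (n26_count(nb) <= 1) continue;
            if (is_simple(nb)) { m[p] = 0; inner = true; }
          }
        }
        if (inner) changed = true;
      }
    }
  }

  LogicalVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) out[p] = m[p] ? TRUE : FALSE;
  out.attr("dim") = dim;
  return out;
}

// Hysteresis thresholding: voxels with value >= high (and > 0) seed a
// 26-connected flood fill over voxels with value >= low.
// [[Rcpp::export(name = ".hysteresis_cpp")]]
LogicalVector hysteresis_cpp(NumericVector x, IntegerVector dim,
                             double low, double high) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (x.size() != n) stop("map length does not match dim");
  std::vector<unsigned char> keep(n, 0);
  std::queue<int> q;
  for (R_xlen_t p = 0; p < n; ++p) {
    if (x[p] >= high && x[p] > 0) { keep[p] = 1; q.push((int)p); }
  }
  while (!q.empty()) {
    int p = q.front(); q.pop();
    int i = p % d1, j = (p / d1) % d2, k = p / (d1 * d2);
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj && !dk) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
            continue;
          int t = idx3(ii, jj, kk, d1, d2);
          if (!keep[t] && x[t] >= low && x[t] > 0) { keep[t] = 1; q.push(t); }
        }
  }
  LogicalVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) out[p] = keep[p] ? TRUE : FALSE;
  out.attr("dim") = dim;
  return out;
}

// Connected-component labelling (26-connectivity); 0 = background.
// [[Rcpp::export(name = ".label26_cpp")]]
IntegerVector label26_cpp(LogicalVector mask, IntegerVector dim) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dim");
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<int> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] != TRUE || lab[s] != 0) continue;
    ++next; lab[s] = next; q.push((int)s);
    while (!q.empty()) {
      int p = q.front(); q.pop();
      int i = p % d1, j = (p / d1) % d2, k = p / (d1 * d2);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
              continue;
            int t = idx3(ii, jj, kk, d1, d2);
            if (mask[t] == TRUE && lab[t] == 0) { lab[t] = next; q.push(t); }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
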