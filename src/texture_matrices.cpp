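// Texture-matrix accumulation for 3-D ROIs on a discretized gray-level
// array. The input is an integer array of gray levels (1..ng) with
// NA_INTEGER outside the ROI; all neighbourhood definitions use
// 26-connectivity / the 13 unique direction vectors at Chebyshev distance 1.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static const int DIR13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}};

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Symmetric co-occurrence counts, one ng x ng slab per direction.
// [[Rcpp::export]]
NumericVector glcm_counts_cpp(IntegerVector levels, int ng) {
  IntegerVector dims = levels.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(ng * ng * 13);
  out.attr("dim") = IntegerVector::create(ng, ng, 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int li = levels[idx3(x, y, z, nx, ny)];
          if (li == NA_INTEGER) continue;
          int X = x + dx, Y = y + dy, Z = z + dz;
          if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
            continue;
          int lj = levels[idx3(X, Y, Z, nx, ny)];
          if (lj == NA_INTEGER) continue;
          out[(li - 1) + ng * (lj - 1) + ng * ng * d] += 1.0;
          out[(lj - 1) + ng * (li - 1) + ng * ng * d] += 1.0;
        }
  }
  return out;
}

// Run-length counts, one ng x maxlen slab per direction. Runs are maximal
// stretches of equal gray level along the direction; voxels outside the ROI
// break runs.
// [[Rcpp::export]]
NumericVector glrlm_counts_cpp(IntegerVector levels, int ng) {
  IntegerVector dims = levels.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int maxlen = std::max(nx, std::max(ny, nz));
  NumericVector out(ng * maxlen * 13);
  out.attr("dim") = IntegerVector::create(ng, maxlen, 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int li = levels[idx3(x, y, z, nx, ny)];
          if (li == NA_INTEGER) continue;
          // run start: predecessor out of bounds, out of ROI, or different
          int px = x - dx, py = y - dy, pz = z - dz;
          if (px >= 0 && px < nx && py >= 0 && py < ny && pz >= 0 && pz < nz) {
            int lp = levels[idx3(px, py, pz, nx, ny)];
            if (lp != NA_INTEGER && lp == li) continue;
          }
          int len = 1;
          int X = x + dx, Y = y + dy, Z = z + dz;
          while (X >= 0 && X < nx && Y >= 0 && Y < ny && Z >= 0 && Z < nz) {
            int ln = levels[idx3(X, Y, Z, nx, ny)];
            if (ln == NA_INTEGER || ln != li) break;
            ++len;
            X += dx; Y += dy; Z += dz;
          }
          out[(li - 1) + ng * (len - 1) + ng * maxlen * d] += 1.0;
        }
  }
  return out;
}

// Size zones: 26-connected components of equal gray level. Returns a
// two-column matrix (level, size), one row per zone.
// [[Rcpp::export]]
IntegerMatrix glszm_zones_cpp(IntegerVector levels) {
  IntegerVector dims = levels.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs, stack;
  for (int start = 0; start < n; ++start) {
    if (seen[start] || levels[start] == NA_INTEGER) continue;
    int lv = levels[start];
    int size = 0;
    stack.clear();
    stack.push_back(start);
    seen[start] = 1;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      ++size;
      int cz = cur / (nx * ny), cy = (cur / nx) % ny, cx = cur % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int X = cx + dx, Y = cy + dy, Z = cz + dz;
            if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
              continue;
            int q = idx3(X, Y, Z, nx, ny);
            if (seen[q] || levels[q] == NA_INTEGER || levels[q] != lv)
              continue;
            seen[q] = 1;
            stack.push_back(q);
          }
    }
    zl.push_back(lv);
    zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t i = 0; i < zl.size(); ++i) {
    out(i, 0) = zl[i];
    out(i, 1) = zs[i];
  }
  return out;
}

// Dependence counts: D(i, d+1) where d = number of 26-neighbours inside the
// ROI whose |level difference| <= alpha.
// [[Rcpp::export]]
NumericMatrix gldm_counts_cpp(IntegerVector levels, int ng, int alpha) {
  IntegerVector dims = levels.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(ng, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int li = levels[idx3(x, y, z, nx, ny)];
        if (li == NA_INTEGER) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int X = x + dx, Y = y + dy, Z = z + dz;
              if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
                continue;
              int lj = levels[idx3(X, Y, Z, nx, ny)];
              if (lj == NA_INTEGER) continue;
              if (std::abs(lj - li) <= alpha) ++dep;
            }
        out(li - 1, dep) += 1.0;
      }
  return out;
}

// NGTDM per-level counts n_i and absolute-difference sums s_i. Voxels with
// no in-ROI neighbour are excluded from both.
// [[Rcpp::export]]
List ngtdm_stats_cpp(IntegerVector levels, int ng) {
  IntegerVector dims = levels.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector ncount(ng), s(ng);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int li = levels[idx3(x, y, z, nx, ny)];
        if (li == NA_INTEGER) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int X = x + dx, Y = y + dy, Z = z + dz;
              if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
                continue;
              int lj = levels[idx3(X, Y, Z, nx, ny)];
              if (lj == NA_INTEGER) continue;
              sum += lj;
              ++cnt;
            }
        if (cnt > 0) {
          ncount[li - 1] += 1.0;
          s[li - 1] += std::fabs(li - sum / cnt);
        }
      }
  return List::create(_["n"] = ncount, _["s"] = s);
}
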