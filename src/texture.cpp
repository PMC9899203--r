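#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// The 13 unique 3D directions (half of the 26-neighbourhood; the other half
// is covered by symmetric/double counting).
static const int DIRS[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Gray-level co-occurrence counts for one window, accumulated over all 13
// unique 3D directions at the given voxel distance. `levels` is a 3D integer
// array (1..ngray) with NA marking out-of-mask voxels. Counts are symmetric:
// each valid ordered pair contributes to (i,j) and (j,i).
// [[Rcpp::export]]
NumericMatrix cpp_glcm_counts(IntegerVector levels, int ngray, int distance) {
  IntegerVector dim = levels.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix counts(ngray, ngray);
  for (int d = 0; d < 13; ++d) {
    int dx = DIRS[d][0] * distance, dy = DIRS[d][1] * distance,
        dz = DIRS[d][2] * distance;
    for (int z = 0; z < nz; ++z) {
      int z2 = z + dz;
      if (z2 < 0 || z2 >= nz) continue;
      for (int y = 0; y < ny; ++y) {
        int y2 = y + dy;
        if (y2 < 0 || y2 >= ny) continue;
        for (int x = 0; x < nx; ++x) {
          int x2 = x + dx;
          if (x2 < 0 || x2 >= nx) continue;
          int a = levels[idx3(x, y, z, nx, ny)];
          int b = levels[idx3(x2, y2, z2, nx, ny)];
          if (a == NA_INTEGER || b == NA_INTEGER) continue;
          counts(a - 1, b - 1) += 1.0;
          counts(b - 1, a - 1) += 1.0;
        }
      }
    }
  }
  return counts;
}

// Gray-level run-length counts for one window over the same 13 directions.
// Runs are maximal strings of equal levels along a ray; NA (out-of-mask) and
// window boundaries break runs. Returns the ngray x maxlen count matrix plus
// the voxel-count denominator (in-mask voxels summed over directions) used by
// run percentage.
// [[Rcpp::export]]
List cpp_glrlm_counts(IntegerVector levels, int ngray) {
  IntegerVector dim = levels.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int maxlen = std::max(nx, std::max(ny, nz));
  NumericMatrix counts(ngray, maxlen);
  long nmask = 0;
  for (int i = 0; i < levels.size(); ++i)
    if (levels[i] != NA_INTEGER) ++nmask;

  for (int d = 0; d < 13; ++d) {
    int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    // Ray start voxels: those with no predecessor along (dx,dy,dz).
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          int px = x - dx, py = y - dy, pz = z - dz;
          if (px >= 0 && px < nx && py >= 0 && py < ny && pz >= 0 && pz < nz)
            continue;  // not a ray start
          int cur = NA_INTEGER, len = 0;
          int cx = x, cy = y, cz = z;
          while (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 && cz < nz) {
            int v = levels[idx3(cx, cy, cz, nx, ny)];
            if (v == NA_INTEGER) {
              if (len > 0) counts(cur - 1, len - 1) += 1.0;
              cur = NA_INTEGER; len = 0;
            } else if (v == cur) {
              ++len;
            } else {
              if (len > 0) counts(cur - 1, len - 1) += 1.0;
              cur = v; len = 1;
            }
            cx += dx; cy += dy; cz += dz;
          }
          if (len > 0) counts(cur - 1, len - 1) += 1.0;
        }
      }
    }
  }
  return List::create(_["counts"] = counts,
                      _["n_voxels"] = (double)nmask * 13.0);
}

// 3D connected-component labelling with 26-connectivity (BFS).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask) {
  IntegerVector dim = mask.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector labels(mask.size(), 0);
  int next = 0;
  std::queue<int> q;
  for (int start = 0; start < mask.size(); ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    labels[start] = ++next;
    q.push(start);
    while (!q.empty()) {
      int i = q.front(); q.pop();
      int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz) {
        int z2 = z + dz;
        if (z2 < 0 || z2 >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int y2 = y + dy;
          if (y2 < 0 || y2 >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            int x2 = x + dx;
            if (x2 < 0 || x2 >= nx) continue;
            int j = idx3(x2, y2, z2, nx, ny);
            if (mask[j] && labels[j] == 0) {
              labels[j] = next;
              q.push(j);
            }
          }
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}

// Binary dilation (or erosion) with an arbitrary structuring element given as
// a matrix of integer voxel offsets (n x 3). Used for morphological closing
// with a physically spherical element under anisotropic spacing.
// [[Rcpp::export]]
LogicalVector cpp_binary_morph(LogicalVector mask, IntegerMatrix offsets,
                               bool dilate) {
  IntegerVector dim = mask.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(mask.size());
  int noff = offsets.nrow();
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        bool hit = dilate ? false : true;
        for (int k = 0; k < noff; ++k) {
          int x2 = x + offsets(k, 0), y2 = y + offsets(k, 1),
              z2 = z + offsets(k, 2);
          bool v;
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
            v = false;  // outside the grid counts as background
          else
            v = mask[idx3(x2, y2, z2, nx, ny)];
          if (dilate) {
            if (v) { hit = true; break; }
          } else {
            if (!v) { hit = false; break; }
          }
        }
        out[idx3(x, y, z, nx, ny)] = hit;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
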