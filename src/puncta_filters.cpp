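#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Circular median filter applied slice-by-slice (2D, within each z-plane),
// Fiji "Median... radius" mask semantics: a pixel (dx,dy) belongs to the
// kernel iff dx*dx + dy*dy <= r*r + 1. NA voxels are ignored in the median;
// a pixel that is itself NA stays NA.
// [[Rcpp::export(name = ".median_filter_stack_cpp")]]
NumericVector median_filter_stack_cpp(NumericVector vol, IntegerVector dim,
                                      int radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if (radius < 1) stop("radius must be >= 1");

  // kernel offsets
  std::vector<int> kdx, kdy;
  const int r2 = radius * radius + 1;
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx)
      if (dx * dx + dy * dy <= r2) { kdx.push_back(dx); kdy.push_back(dy); }
  const int K = (int)kdx.size();

  NumericVector out(vol.size());
  std::vector<double> buf(K);
  for (int z = 0; z < nz; ++z) {
    const R_xlen_t zoff = (R_xlen_t)z * nx * ny;
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t idx = zoff + (R_xlen_t)y * nx + x;
        const double v = vol[idx];
        if (NumericVector::is_na(v)) { out[idx] = NA_REAL; continue; }
        int n = 0;
        for (int k = 0; k < K; ++k) {
          const int xx = x + kdx[k], yy = y + kdy[k];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny) continue;
          const double w = vol[zoff + (R_xlen_t)yy * nx + xx];
          if (!NumericVector::is_na(w)) buf[n++] = w;
        }
        if (n == 0) { out[idx] = NA_REAL; continue; }
        std::vector<double>::iterator first = buf.begin();
        std::vector<double>::iterator last = buf.begin() + n;
        std::vector<double>::iterator mid = first + n / 2;
        std::nth_element(first, mid, last);
        double m = *mid;
        if (n % 2 == 0) {
          std::nth_element(first, mid - 1, mid);
          m = 0.5 * (m + *(mid - 1));
        }
        out[idx] = m;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// 3D connected-component labeling of a binary mask by breadth-first search.
// connectivity: 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
// Labels are assigned in increasing order of each component's smallest
// linear (column-major) voxel index, so the labeling is deterministic.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::vector<int> ndx, ndy, ndz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        ndx.push_back(dx); ndy.push_back(dy); ndz.push_back(dz);
      }
  const int K = (int)ndx.size();

  IntegerVector labels(mask.size(), 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  for (R_xlen_t start = 0; start < ntot; ++start) {
    if (mask[start] != TRUE || labels[start] != 0) continue;
    ++next;
    labels[start] = next;
    q.push(start);
    while (!q.empty()) {
      const R_xlen_t cur = q.front(); q.pop();
      const int x = (int)(cur % nx);
      const int y = (int)((cur / nx) % ny);
      const int z = (int)(cur / ((R_xlen_t)nx * ny));
      for (int k = 0; k < K; ++k) {
        const int xx = x + ndx[k], yy = y + ndy[k], zz = z + ndz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const R_xlen_t nb = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[nb] == TRUE && labels[nb] == 0) {
          labels[nb] = next;
          q.push(nb);
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}
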