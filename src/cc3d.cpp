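#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 6-connected components of equal-label regions in a 3D label array.
//
// `labels` is the array flattened in R (column-major) order with
// dim = c(nz, ny, nx); value 0 is background and stays 0.  Two voxels
// belong to the same component iff they carry the same nonzero label and
// are joined by a face-connected path through that label.  Component ids
// are assigned 1..k in ascending order of each component's smallest
// linear index, which makes the labeling canonical: it does not depend
// on how the volume was partitioned before being reassembled.

// [[Rcpp::export]]
IntegerVector cc_label6_cpp(IntegerVector labels, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = labels.size();
  if (n != (R_xlen_t)nz * ny * nx) stop("dim does not match array length");
  IntegerVector comp(n, 0);
  std::vector<int> stack;
  stack.reserve(1024);
  int next = 0;
  const int dz = 1, dy = nz, dx = nz * ny;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (labels[i] == 0 || comp[i] != 0) continue;
    const int lab = labels[i];
    ++next;
    comp[i] = next;
    stack.push_back((int)i);
    while (!stack.empty()) {
      const int v = stack.back();
      stack.pop_back();
      const int z = v % nz;
      const int rest = v / nz;
      const int y = rest % ny;
      const int x = rest / ny;
      if (z > 0      && labels[v - dz] == lab && comp[v - dz] == 0) { comp[v - dz] = next; stack.push_back(v - dz); }
      if (z < nz - 1 && labels[v + dz] == lab && comp[v + dz] == 0) { comp[v + dz] = next; stack.push_back(v + dz); }
      if (y > 0      && labels[v - dy] == lab && comp[v - dy] == 0) { comp[v - dy] = next; stack.push_back(v - dy); }
      if (y < ny - 1 && labels[v + dy] == lab && comp[v + dy] == 0) { comp[v + dy] = next; stack.push_back(v + dy); }
      if (x > 0      && labels[v - dx] == lab && comp[v - dx] == 0) { comp[v - dx] = next; stack.push_back(v - dx); }
      if (x < nx - 1 && labels[v + dx] == lab && comp[v + dx] == 0) { comp[v + dx] = next; stack.push_back(v + dx); }
    }
  }
  return comp;
}
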