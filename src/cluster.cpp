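#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static void make_offsets(int conn, std::vector<int> &dx, std::vector<int> &dy,
                         std::vector<int> &dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0) continue;
        if ((conn == 6 && m > 1) || (conn == 18 && m > 2)) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

// Label connected components of a foreground mask (nonzero voxels).
// conn in {6, 18, 26}. Returns integer array of labels (0 = background),
// components numbered 1..n in decreasing size order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, int conn) {
  IntegerVector d = mask.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> dxs, dys, dzs;
  make_offsets(conn, dxs, dys, dzs);
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  std::vector<R_xlen_t> sizes_order;
  std::vector<int> sizes;
  int next = 0;
  for (R_xlen_t p = 0; p < n; ++p) {
    if (!mask[p] || lab[p]) continue;
    ++next;
    int sz = 0;
    stack.push_back(p);
    lab[p] = next;
    while (!stack.empty()) {
      R_xlen_t q = stack.back(); stack.pop_back();
      ++sz;
      int x = (int)(q % nx), y = (int)((q / nx) % ny), z = (int)(q / ((R_xlen_t)nx * ny));
      for (size_t o = 0; o < dxs.size(); ++o) {
        int xx = x + dxs[o], yy = y + dys[o], zz = z + dzs[o];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t r = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[r] && !lab[r]) { lab[r] = next; stack.push_back(r); }
      }
    }
    sizes.push_back(sz);
  }
  // renumber by decreasing size
  std::vector<int> order(next);
  for (int i = 0; i < next; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return sizes[a] > sizes[b]; });
  std::vector<int> remap(next + 1, 0);
  for (int rank = 0; rank < next; ++rank) remap[order[rank] + 1] = rank + 1;
  for (R_xlen_t p = 0; p < n; ++p) lab[p] = remap[lab[p]];
  lab.attr("dim") = d;
  return lab;
}

// Max suprathreshold cluster size for a sign-split t map: clusters are formed
// separately among t >= t_crit and t <= -t_crit voxels, and the maximum size
// over both signs is returned. Internal helper shared by the permutation
// null below.
static int max_cluster_size(const std::vector<double> &t,
                            const std::vector<R_xlen_t> &voxidx,
                            const int *dims, double t_crit,
                            const std::vector<int> &dxs,
                            const std::vector<int> &dys,
                            const std::vector<int> &dzs,
                            std::vector<signed char> &sign,
                            std::vector<R_xlen_t> &stack) {
  const int nx = dims[0], ny = dims[1];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  // sign is a full-volume workspace, zeroed only at masked voxels
  for (size_t i = 0; i < voxidx.size(); ++i) {
    double v = t[i];
    sign[voxidx[i]] = (v >= t_crit) ? 1 : (v <= -t_crit ? -1 : 0);
  }
  int best = 0;
  for (size_t i = 0; i < voxidx.size(); ++i) {
    R_xlen_t p = voxidx[i];
    signed char sg = sign[p];
    if (sg == 0) continue;
    int sz = 0;
    stack.clear();
    stack.push_back(p);
    sign[p] = 0;
    while (!stack.empty()) {
      R_xlen_t q = stack.back(); stack.pop_back();
      ++sz;
      int x = (int)(q % nx), y = (int)((q / nx) % ny), z = (int)(q / nxy);
      for (size_t o = 0; o < dxs.size(); ++o) {
        int xx = x + dxs[o], yy = y + dys[o], zz = z + dzs[o];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= dims[2])
          continue;
        R_xlen_t r = (R_xlen_t)zz * nxy + (R_xlen_t)yy * nx + xx;
        if (sign[r] == sg) { sign[r] = 0; stack.push_back(r); }
      }
    }
    if (sz > best) best = sz;
  }
  return best;
}

// Permutation null distribution of the maximum cluster size.
//
// data: nv x n matrix of masked voxel values (columns = samples; the first
// nA columns are group A in the observed labelling, which is irrelevant here
// since labels are permuted). voxidx0: 0-based linear indices of the masked
// voxels in the full volume of dimension dims. For each permutation the
// group-A column set is redrawn uniformly (Fisher-Yates driven by R's RNG),
// the pooled two-sample t statistic is computed per voxel, clusters are
// formed at |t| >= t_crit with the given connectivity, and the maximum
// cluster size (over positive and negative clusters jointly) is recorded.
// [[Rcpp::export]]
IntegerVector cpp_perm_max_cluster(NumericMatrix data, int nA,
                                   IntegerVector voxidx0, IntegerVector dims,
                                   double t_crit, int conn, int n_perm) {
  const int nv = data.nrow(), n = data.ncol();
  const int nB = n - nA;
  const int d[3] = {dims[0], dims[1], dims[2]};
  const R_xlen_t nfull = (R_xlen_t)d[0] * d[1] * d[2];
  std::vector<int> dxs, dys, dzs;
  make_offsets(conn, dxs, dys, dzs);
  std::vector<R_xlen_t> voxidx(nv);
  for (int i = 0; i < nv; ++i) voxidx[i] = (R_xlen_t)voxidx0[i];
  // per-voxel totals over all samples
  std::vector<double> totsum(nv, 0.0), totsq(nv, 0.0);
  std::vector<double> sq((size_t)nv * n);
  for (int j = 0; j < n; ++j) {
    const double *col = &data(0, j);
    double *sqc = &sq[(size_t)nv * j];
    for (int i = 0; i < nv; ++i) {
      double v = col[i];
      totsum[i] += v;
      totsq[i] += v * v;
      sqc[i] = v * v;
    }
  }
  const double df = n - 2;
  const double inv_nA = 1.0 / nA, inv_nB = 1.0 / nB;
  const double nfac = inv_nA + inv_nB;
  std::vector<double> sumA(nv), sqA(nv), t(nv);
  std::vector<int> idx(n);
  std::vector<signed char> sign(nfull, 0);
  std::vector<R_xlen_t> stack;
  IntegerVector out(n_perm);
  GetRNGstate();
  for (int perm = 0; perm < n_perm; ++perm) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int i = 0; i < nA; ++i) {
      int j = i + (int)std::floor(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(idx[i], idx[j]);
    }
    std::fill(sumA.begin(), sumA.end(), 0.0);
    std::fill(sqA.begin(), sqA.end(), 0.0);
    for (int a = 0; a < nA; ++a) {
      const double *col = &data(0, idx[a]);
      const double *sqc = &sq[(size_t)nv * idx[a]];
      for (int i = 0; i < nv; ++i) {
        sumA[i] += col[i];
        sqA[i] += sqc[i];
      }
    }
    for (int i = 0; i < nv; ++i) {
      double sA = sumA[i], sB = totsum[i] - sA;
      double mA = sA * inv_nA, mB = sB * inv_nB;
      double ssA = sqA[i] - nA * mA * mA;
      double ssB = (totsq[i] - sqA[i]) - nB * mB * mB;
      double sp2 = (ssA + ssB) / df;
      if (sp2 <= 0) {
        t[i] = 0.0;
      } else {
        t[i] = (mB - mA) / std::sqrt(sp2 * nfac);
      }
    }
    out[perm] = max_cluster_size(t, voxidx, d, t_crit, dxs, dys, dzs, sign,
                                 stack);
  }
  PutRNGstate();
  return out;
}
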