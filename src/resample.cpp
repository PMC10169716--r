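#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Affine grid resampling. The caller supplies the map from 0-based output
// voxel index to continuous 0-based source voxel index: s = A * o + b.
// method: 0 = trilinear, 1 = nearest neighbour.
// Returns list(data, inside) where inside marks output voxels whose mapped
// position lies within the source grid (half-open voxel-centre extent).
// [[Rcpp::export]]
List cpp_resample_affine(NumericVector src, IntegerVector dim_out,
                         NumericMatrix A, NumericVector b,
                         int method, double outside) {
  IntegerVector dsrc = src.attr("dim");
  const int sx = dsrc[0], sy = dsrc[1], sz = dsrc[2];
  const int ox = dim_out[0], oy = dim_out[1], oz = dim_out[2];
  const R_xlen_t nout = (R_xlen_t)ox * oy * oz;
  NumericVector out(nout);
  LogicalVector inside(nout);
  const double *s = src.begin();
  const double a00 = A(0,0), a01 = A(0,1), a02 = A(0,2);
  const double a10 = A(1,0), a11 = A(1,1), a12 = A(1,2);
  const double a20 = A(2,0), a21 = A(2,1), a22 = A(2,2);
  R_xlen_t p = 0;
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      for (int i = 0; i < ox; ++i, ++p) {
        double xs = a00*i + a01*j + a02*k + b[0];
        double ys = a10*i + a11*j + a12*k + b[1];
        double zs = a20*i + a21*j + a22*k + b[2];
        if (method == 1) {
          int xi = (int)std::lround(xs), yi = (int)std::lround(ys),
              zi = (int)std::lround(zs);
          if (xi >= 0 && xi < sx && yi >= 0 && yi < sy && zi >= 0 && zi < sz) {
            out[p] = s[(R_xlen_t)zi*sx*sy + (R_xlen_t)yi*sx + xi];
            inside[p] = true;
          } else {
            out[p] = outside;
            inside[p] = false;
          }
        } else {
          if (xs < -0.5 || xs > sx - 0.5 || ys < -0.5 || ys > sy - 0.5 ||
              zs < -0.5 || zs > sz - 0.5) {
            out[p] = outside;
            inside[p] = false;
            continue;
          }
          inside[p] = true;
          // clamp to the valid interpolation cell
          double xc = std::min(std::max(xs, 0.0), (double)(sx - 1));
          double yc = std::min(std::max(ys, 0.0), (double)(sy - 1));
          double zc = std::min(std::max(zs, 0.0), (double)(sz - 1));
          int x0 = (int)std::floor(xc); if (x0 == sx - 1 && sx > 1) --x0;
          int y0 = (int)std::floor(yc); if (y0 == sy - 1 && sy > 1) --y0;
          int z0 = (int)std::floor(zc); if (z0 == sz - 1 && sz > 1) --z0;
          int x1 = std::min(x0 + 1, sx - 1);
          int y1 = std::min(y0 + 1, sy - 1);
          int z1 = std::min(z0 + 1, sz - 1);
          double fx = xc - x0, fy = yc - y0, fz = zc - z0;
          const R_xlen_t sxy = (R_xlen_t)sx * sy;
          double c000 = s[(R_xlen_t)z0*sxy + (R_xlen_t)y0*sx + x0];
          double c100 = s[(R_xlen_t)z0*sxy + (R_xlen_t)y0*sx + x1];
          double c010 = s[(R_xlen_t)z0*sxy + (R_xlen_t)y1*sx + x0];
          double c110 = s[(R_xlen_t)z0*sxy + (R_xlen_t)y1*sx + x1];
          double c001 = s[(R_xlen_t)z1*sxy + (R_xlen_t)y0*sx + x0];
          double c101 = s[(R_xlen_t)z1*sxy + (R_xlen_t)y0*sx + x1];
          double c011 = s[(R_xlen_t)z1*sxy + (R_xlen_t)y1*sx + x0];
          double c111 = s[(R_xlen_t)z1*sxy + (R_xlen_t)y1*sx + x1];
          double c00 = c000*(1-fx) + c100*fx;
          double c10 = c010*(1-fx) + c110*fx;
          double c01 = c001*(1-fx) + c101*fx;
          double c11 = c011*(1-fx) + c111*fx;
          double c0 = c00*(1-fy) + c10*fy;
          double c1 = c01*(1-fy) + c11*fy;
          out[p] = c0*(1-fz) + c1*fz;
        }
      }
    }
  }
  out.attr("dim") = dim_out;
  inside.attr("dim") = dim_out;
  return List::create(_["data"] = out, _["inside"] = inside);
}

// Trilinear sampling at arbitrary continuous 0-based voxel coordinates.
// pts is n x 3. Values outside the grid are NA.
// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector src, NumericMatrix pts) {
  IntegerVector dsrc = src.attr("dim");
  const int sx = dsrc[0], sy = dsrc[1], sz = dsrc[2];
  const R_xlen_t sxy = (R_xlen_t)sx * sy;
  const double *s = src.begin();
  const int n = pts.nrow();
  NumericVector out(n);
  for (int q = 0; q < n; ++q) {
    double xs = pts(q,0), ys = pts(q,1), zs = pts(q,2);
    if (xs < 0 || xs > sx - 1 || ys < 0 || ys > sy - 1 ||
        zs < 0 || zs > sz - 1 || !R_finite(xs) || !R_finite(ys) || !R_finite(zs)) {
      out[q] = NA_REAL;
      continue;
    }
    int x0 = (int)std::floor(xs); if (x0 == sx - 1 && sx > 1) --x0;
    int y0 = (int)std::floor(ys); if (y0 == sy - 1 && sy > 1) --y0;
    int z0 = (int)std::floor(zs); if (z0 == sz - 1 && sz > 1) --z0;
    int x1 = std::min(x0 + 1, sx - 1);
    int y1 = std::min(y0 + 1, sy - 1);
    int z1 = std::min(z0 + 1, sz - 1);
    double fx = xs - x0, fy = ys - y0, fz = zs - z0;
    double c000 = s[(R_xlen_t)z0*sxy + (R_xlen_t)y0*sx + x0];
    double c100 = s[(R_xlen_t)z0*sxy + (R_xlen_t)y0*sx + x1];
    double c010 = s[(R_xlen_t)z0*sxy + (R_xlen_t)y1*sx + x0];
    double c110 = s[(R_xlen_t)z0*sxy + (R_xlen_t)y1*sx + x1];
    double c001 = s[(R_xlen_t)z1*sxy + (R_xlen_t)y0*sx + x0];
    double c101 = s[(R_xlen_t)z1*sxy + (R_xlen_t)y0*sx + x1];
    double c011 = s[(R_xlen_t)z1*sxy + (R_xlen_t)y1*sx + x0];
    double c111 = s[(R_xlen_t)z1*sxy + (R_xlen_t)y1*sx + x1];
    double c00 = c000*(1-fx) + c100*fx;
    double c10 = c010*(1-fx) + c110*fx;
    double c01 = c001*(1-fx) + c101*fx;
    double c11 = c011*(1-fx) + c111*fx;
    double c0 = c00*(1-fy) + c10*fy;
    double c1 = c01*(1-fy) + c11*fy;
    out[q] = c0*(1-fz) + c1*fz;
  }
  return out;
}
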