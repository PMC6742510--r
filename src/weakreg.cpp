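#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Layout conventions (match R's column-major arrays):
//  - activations: 5D (nx, ny, nz, C, K)
//  - kernels:     5D (k, k, k, inC, outC), k odd, stride 1, zero "same" padding
//  - im2col column ordering = ti + k*(tj + k*(tk + k*ci)), identical to the
//    column-major reshape of the kernel array, so conv is a single GEMM.

static void im2col(const double* x, int nx, int ny, int nz, int inC, int k,
                   arma::mat& M) {
  const int pad = (k - 1) / 2;
  const int nvox = nx * ny * nz;
  M.zeros(nvox, (std::size_t)k * k * k * inC);
  for (int ci = 0; ci < inC; ++ci) {
    const double* xc = x + (std::size_t)ci * nvox;
    for (int tk = 0; tk < k; ++tk) {
      const int dz = tk - pad;
      for (int tj = 0; tj < k; ++tj) {
        const int dy = tj - pad;
        for (int ti = 0; ti < k; ++ti) {
          const int dx = ti - pad;
          const std::size_t col = (std::size_t)ti + k * (tj + k * (tk + (std::size_t)k * ci));
          double* Mcol = M.colptr(col);
          const int z0 = std::max(0, -dz), z1 = std::min(nz, nz - dz);
          const int y0 = std::max(0, -dy), y1 = std::min(ny, ny - dy);
          const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
          for (int zz = z0; zz < z1; ++zz) {
            for (int yy = y0; yy < y1; ++yy) {
              const double* src = xc + (x0 + dx) + (std::size_t)nx * ((yy + dy) + (std::size_t)ny * (zz + dz));
              double* dst = Mcol + x0 + (std::size_t)nx * (yy + (std::size_t)ny * zz);
              std::copy(src, src + (x1 - x0), dst);
            }
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& M, int nx, int ny, int nz, int inC, int k,
                   double* gx) {
  const int pad = (k - 1) / 2;
  const int nvox = nx * ny * nz;
  for (int ci = 0; ci < inC; ++ci) {
    double* gc = gx + (std::size_t)ci * nvox;
    for (int tk = 0; tk < k; ++tk) {
      const int dz = tk - pad;
      for (int tj = 0; tj < k; ++tj) {
        const int dy = tj - pad;
        for (int ti = 0; ti < k; ++ti) {
          const int dx = ti - pad;
          const std::size_t col = (std::size_t)ti + k * (tj + k * (tk + (std::size_t)k * ci));
          const double* Mcol = M.colptr(col);
          const int z0 = std::max(0, -dz), z1 = std::min(nz, nz - dz);
          const int y0 = std::max(0, -dy), y1 = std::min(ny, ny - dy);
          const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
          for (int zz = z0; zz < z1; ++zz) {
            for (int yy = y0; yy < y1; ++yy) {
              double* dst = gc + (x0 + dx) + (std::size_t)nx * ((yy + dy) + (std::size_t)ny * (zz + dz));
              const double* src = Mcol + x0 + (std::size_t)nx * (yy + (std::size_t)ny * zz);
              for (int xx = 0; xx < (x1 - x0); ++xx) dst[xx] += src[xx];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], inC = xd[3], K = xd[4];
  const int k = wd[0], outC = wd[4];
  const int nvox = nx * ny * nz;
  NumericVector y((std::size_t)nvox * outC * K);
  y.attr("dim") = IntegerVector::create(nx, ny, nz, outC, K);
  arma::mat W(const_cast<double*>(w.begin()), (std::size_t)k * k * k * inC, outC, false, true);
  arma::mat M;
  for (int n = 0; n < K; ++n) {
    im2col(x.begin() + (std::size_t)n * nvox * inC, nx, ny, nz, inC, k, M);
    arma::mat Y(y.begin() + (std::size_t)n * nvox * outC, nvox, outC, false, true);
    Y = M * W;
    for (int co = 0; co < outC; ++co) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    bool need_gx = true) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], inC = xd[3], K = xd[4];
  const int k = wd[0], outC = wd[4];
  const int nvox = nx * ny * nz;
  NumericVector gx((std::size_t)nvox * inC * K);
  gx.attr("dim") = IntegerVector::create(nx, ny, nz, inC, K);
  NumericVector gw((std::size_t)k * k * k * inC * outC);
  gw.attr("dim") = IntegerVector::create(k, k, k, inC, outC);
  NumericVector gb(outC);
  arma::mat W(const_cast<double*>(w.begin()), (std::size_t)k * k * k * inC, outC, false, true);
  arma::mat GW(gw.begin(), (std::size_t)k * k * k * inC, outC, false, true);
  arma::vec GB(gb.begin(), outC, false, true);
  arma::mat M, GM;
  for (int n = 0; n < K; ++n) {
    im2col(x.begin() + (std::size_t)n * nvox * inC, nx, ny, nz, inC, k, M);
    arma::mat GY(const_cast<double*>(gy.begin()) + (std::size_t)n * nvox * outC, nvox, outC, false, true);
    GW += M.t() * GY;
    GB += arma::sum(GY, 0).t();
    if (need_gx) {
      GM = GY * W.t();
      col2im(GM, nx, ny, nz, inC, k, gx.begin() + (std::size_t)n * nvox * inC);
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Trilinear sampling of a multi-channel field at continuous 0-based voxel
// positions; samples outside the extent contribute 0 (background).
// field: (nx, ny, nz, C); pos: (m, 3); returns (m, C).
// [[Rcpp::export]]
NumericMatrix cpp_resample3_fwd(NumericVector field, NumericMatrix pos) {
  IntegerVector fd = field.attr("dim");
  const int nx = fd[0], ny = fd[1], nz = fd[2], C = fd[3];
  const int m = pos.nrow();
  const int nvox = nx * ny * nz;
  NumericMatrix out(m, C);
  const double* f = field.begin();
  for (int p = 0; p < m; ++p) {
    const double px = pos(p, 0), py = pos(p, 1), pz = pos(p, 2);
    const int ix = (int)std::floor(px), iy = (int)std::floor(py), iz = (int)std::floor(pz);
    const double wx = px - ix, wy = py - iy, wz = pz - iz;
    for (int dz = 0; dz < 2; ++dz) {
      const int z = iz + dz;
      if (z < 0 || z >= nz) continue;
      const double wzz = dz ? wz : 1.0 - wz;
      for (int dy = 0; dy < 2; ++dy) {
        const int yv = iy + dy;
        if (yv < 0 || yv >= ny) continue;
        const double wyy = dy ? wy : 1.0 - wy;
        for (int dx = 0; dx < 2; ++dx) {
          const int xv = ix + dx;
          if (xv < 0 || xv >= nx) continue;
          const double wt = (dx ? wx : 1.0 - wx) * wyy * wzz;
          if (wt == 0.0) continue;
          const std::size_t base = xv + (std::size_t)nx * (yv + (std::size_t)ny * z);
          for (int c = 0; c < C; ++c) out(p, c) += wt * f[base + (std::size_t)c * nvox];
        }
      }
    }
  }
  return out;
}

// Backward of cpp_resample3_fwd: gradients w.r.t. the field (scatter of the
// interpolation weights) and w.r.t. the positions (spatial derivative of the
// trilinear interpolant).
// [[Rcpp::export]]
List cpp_resample3_bwd(NumericVector field, NumericMatrix pos, NumericMatrix gout) {
  IntegerVector fd = field.attr("dim");
  const int nx = fd[0], ny = fd[1], nz = fd[2], C = fd[3];
  const int m = pos.nrow();
  const int nvox = nx * ny * nz;
  NumericVector gfield((std::size_t)nvox * C);
  gfield.attr("dim") = IntegerVector::create(nx, ny, nz, C);
  NumericMatrix gpos(m, 3);
  const double* f = field.begin();
  double* gf = gfield.begin();
  for (int p = 0; p < m; ++p) {
    const double px = pos(p, 0), py = pos(p, 1), pz = pos(p, 2);
    const int ix = (int)std::floor(px), iy = (int)std::floor(py), iz = (int)std::floor(pz);
    const double wx = px - ix, wy = py - iy, wz = pz - iz;
    double gpx = 0.0, gpy = 0.0, gpz = 0.0;
    for (int dz = 0; dz < 2; ++dz) {
      const int z = iz + dz;
      if (z < 0 || z >= nz) continue;
      const double wzz = dz ? wz : 1.0 - wz;
      const double dwz = dz ? 1.0 : -1.0;
      for (int dy = 0; dy < 2; ++dy) {
        const int yv = iy + dy;
        if (yv < 0 || yv >= ny) continue;
        const double wyy = dy ? wy : 1.0 - wy;
        const double dwy = dy ? 1.0 : -1.0;
        for (int dx = 0; dx < 2; ++dx) {
          const int xv = ix + dx;
          if (xv < 0 || xv >= nx) continue;
          const double wxx = dx ? wx : 1.0 - wx;
          const double dwx = dx ? 1.0 : -1.0;
          const std::size_t base = xv + (std::size_t)nx * (yv + (std::size_t)ny * z);
          for (int c = 0; c < C; ++c) {
            const double g = gout(p, c);
            if (g == 0.0) continue;
            const double fv = f[base + (std::size_t)c * nvox];
            gf[base + (std::size_t)c * nvox] += g * wxx * wyy * wzz;
            gpx += g * fv * dwx * wyy * wzz;
            gpy += g * fv * wxx * dwy * wzz;
            gpz += g * fv * wxx * wyy * dwz;
          }
        }
      }
    }
    gpos(p, 0) = gpx; gpos(p, 1) = gpy; gpos(p, 2) = gpz;
  }
  return List::create(_["gfield"] = gfield, _["gpos"] = gpos);
}

// Contract matrix M (m x n) over the middle extent of a, viewed as
// (pre, n, post): out(pre, m, post) = sum_j M(i, j) * a(pre, j, post).
// [[Rcpp::export]]
NumericVector cpp_apply_axis(NumericVector a, NumericMatrix M, int pre,
                             int n, int post) {
  const int m = M.nrow();
  NumericVector out((std::size_t)pre * m * post);
  arma::mat Mm(const_cast<double*>(M.begin()), m, n, false, true);
  if (pre == 1) {
    arma::mat A(const_cast<double*>(a.begin()), n, post, false, true);
    arma::mat O(out.begin(), m, post, false, true);
    O = Mm * A;
  } else {
    arma::mat Mt = Mm.t();
    for (int p = 0; p < post; ++p) {
      arma::mat A(const_cast<double*>(a.begin()) + (std::size_t)p * pre * n,
                  pre, n, false, true);
      arma::mat O(out.begin() + (std::size_t)p * pre * m, pre, m, false, true);
      O = A * Mt;
    }
  }
  return out;
}
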