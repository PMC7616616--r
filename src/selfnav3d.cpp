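// Hot paths of the structured low-rank / SPIRiT machinery:
//  - block-Hankel (sliding-window) matrix construction and its exact adjoint
//  - fused ADMM state updates on the large Hankel-shaped arrays
//  - SPIRiT kernel application (zero-padded k-space convolution) over a
//    stack of coil planes, with exact adjoint
// All functions take R complex arrays by proxy (no copies); the large
// Hankel-shaped matrices are touched in single passes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline cx_double* cptr(Rcpp::ComplexVector& v) {
  return reinterpret_cast<cx_double*>(v.begin());
}
static inline const cx_double* cptr(const Rcpp::ComplexVector& v) {
  return reinterpret_cast<const cx_double*>(v.begin());
}

// x: [Nx, Ny, P] planes (flattened complex vector); w: window size.
// Returns [(Nx-w+1)(Ny-w+1)] x [w^2 P]; row r = (i, j) window origin with
// i fastest; plane-major columns, offset (a, b) with a fastest inside.
// [[Rcpp::export]]
Rcpp::ComplexMatrix cpp_hankel_build(const Rcpp::ComplexVector& x,
                                     const int Nx, const int Ny,
                                     const int P, const int w) {
  const int mr = Nx - w + 1, mc = Ny - w + 1;
  Rcpp::ComplexMatrix Hr(mr * mc, w * w * P);
  cx_double* H = reinterpret_cast<cx_double*>(Hr.begin());
  const cx_double* xp = cptr(x);
  const R_xlen_t crows = (R_xlen_t)mr * mc;
  for (int p = 0; p < P; ++p) {
    const cx_double* xs = xp + (R_xlen_t)p * Nx * Ny;
    for (int b = 0; b < w; ++b) {
      for (int a = 0; a < w; ++a) {
        cx_double* col = H + crows * (p * w * w + b * w + a);
        for (int j = 0; j < mc; ++j)
          std::memcpy(col + (R_xlen_t)j * mr, xs + (R_xlen_t)(j + b) * Nx + a,
                      mr * sizeof(cx_double));
      }
    }
  }
  return Hr;
}

// Rebuild an existing Hankel matrix in place (avoids reallocating the
// large matrix every ADMM iteration). H must be the caller's only
// reference and have the correct shape.
// [[Rcpp::export]]
void cpp_hankel_build_into(Rcpp::ComplexMatrix& Hr,
                           const Rcpp::ComplexVector& x, const int Nx,
                           const int Ny, const int P, const int w) {
  const int mr = Nx - w + 1, mc = Ny - w + 1;
  if (Hr.nrow() != mr * mc || Hr.ncol() != w * w * P)
    Rcpp::stop("Hankel buffer shape mismatch");
  cx_double* H = reinterpret_cast<cx_double*>(Hr.begin());
  const cx_double* xp = cptr(x);
  const R_xlen_t crows = (R_xlen_t)mr * mc;
  for (int p = 0; p < P; ++p) {
    const cx_double* xs = xp + (R_xlen_t)p * Nx * Ny;
    for (int b = 0; b < w; ++b) {
      for (int a = 0; a < w; ++a) {
        cx_double* col = H + crows * (p * w * w + b * w + a);
        for (int j = 0; j < mc; ++j)
          std::memcpy(col + (R_xlen_t)j * mr, xs + (R_xlen_t)(j + b) * Nx + a,
                      mr * sizeof(cx_double));
      }
    }
  }
}

// Exact adjoint of cpp_hankel_build (overlap-add scatter); returns a
// flattened [Nx, Ny, P] vector.
// [[Rcpp::export]]
Rcpp::ComplexVector cpp_hankel_adjoint(const Rcpp::ComplexMatrix& Hr,
                                       const int Nx, const int Ny,
                                       const int P, const int w) {
  const int mr = Nx - w + 1, mc = Ny - w + 1;
  Rcpp::ComplexVector xr((R_xlen_t)Nx * Ny * P);
  std::memset(xr.begin(), 0, sizeof(Rcomplex) * xr.size());
  cx_double* xp = cptr(xr);
  const cx_double* H = reinterpret_cast<const cx_double*>(Hr.begin());
  const R_xlen_t crows = (R_xlen_t)mr * mc;
  for (int p = 0; p < P; ++p) {
    cx_double* xs = xp + (R_xlen_t)p * Nx * Ny;
    for (int b = 0; b < w; ++b) {
      for (int a = 0; a < w; ++a) {
        const cx_double* col = H + crows * (p * w * w + b * w + a);
        for (int j = 0; j < mc; ++j) {
          cx_double* dst = xs + (R_xlen_t)(j + b) * Nx + a;
          const cx_double* src = col + (R_xlen_t)j * mr;
          for (int i = 0; i < mr; ++i) dst[i] += src[i];
        }
      }
    }
  }
  return xr;
}

// Adjoint of the Hankel map applied to (za * Z + da * D) without
// materializing the combination (fused pass over both arrays).
// [[Rcpp::export]]
Rcpp::ComplexVector cpp_hankel_adjoint_comb(const Rcpp::ComplexMatrix& Zr,
                                            const Rcpp::ComplexMatrix& Dr,
                                            const double za, const double da,
                                            const int Nx, const int Ny,
                                            const int P, const int w) {
  const int mr = Nx - w + 1, mc = Ny - w + 1;
  Rcpp::ComplexVector xr((R_xlen_t)Nx * Ny * P);
  std::memset(xr.begin(), 0, sizeof(Rcomplex) * xr.size());
  cx_double* xp = cptr(xr);
  const cx_double* Z = reinterpret_cast<const cx_double*>(Zr.begin());
  const cx_double* D = reinterpret_cast<const cx_double*>(Dr.begin());
  const R_xlen_t crows = (R_xlen_t)mr * mc;
  for (int p = 0; p < P; ++p) {
    cx_double* xs = xp + (R_xlen_t)p * Nx * Ny;
    for (int b = 0; b < w; ++b) {
      for (int a = 0; a < w; ++a) {
        const R_xlen_t off = crows * (p * w * w + b * w + a);
        const cx_double* sz = Z + off;
        const cx_double* sd = D + off;
        for (int j = 0; j < mc; ++j) {
          cx_double* dst = xs + (R_xlen_t)(j + b) * Nx + a;
          for (int i = 0; i < mr; ++i) {
            const R_xlen_t q = (R_xlen_t)j * mr + i;
            dst[i] += za * sz[q] + da * sd[q];
          }
        }
      }
    }
  }
  return xr;
}

// In-place D += H - Z (single pass). D must be the caller's private copy.
// [[Rcpp::export]]
void cpp_inplace_add_sub(Rcpp::ComplexMatrix& Dr,
                         const Rcpp::ComplexMatrix& Hr,
                         const Rcpp::ComplexMatrix& Zr) {
  const R_xlen_t n = (R_xlen_t)Dr.nrow() * Dr.ncol();
  cx_double* d = reinterpret_cast<cx_double*>(Dr.begin());
  const cx_double* h = reinterpret_cast<const cx_double*>(Hr.begin());
  const cx_double* z = reinterpret_cast<const cx_double*>(Zr.begin());
  for (R_xlen_t i = 0; i < n; ++i) d[i] += h[i] - z[i];
}

// ||A - B||_F^2 in one fused pass.
// [[Rcpp::export]]
double cpp_diff_norm2(const Rcpp::ComplexMatrix& Ar,
                      const Rcpp::ComplexMatrix& Br) {
  const R_xlen_t n = (R_xlen_t)Ar.nrow() * Ar.ncol();
  const cx_double* a = reinterpret_cast<const cx_double*>(Ar.begin());
  const cx_double* b = reinterpret_cast<const cx_double*>(Br.begin());
  double s = 0;
  for (R_xlen_t i = 0; i < n; ++i) s += std::norm(a[i] - b[i]);
  return s;
}

// SPIRiT kernel application with zero-padded borders.
// x: [Nx, Ny, Cfrom * nblock] planes; kern: [Cin, Cout, w^2] mixing
// matrices, slice o = a + w*b for offset (a - h, b - h).
static void spirit_apply_core(const cx_double* xp, cx_double* op,
                              const cx_double* kp, const int Nx,
                              const int Ny, const int Cin, const int Cout,
                              const int w, const int nblock,
                              const bool adjoint) {
  const int h = (w - 1) / 2;
  const int Cfrom = adjoint ? Cout : Cin;
  const int Cto = adjoint ? Cin : Cout;
  const R_xlen_t plane = (R_xlen_t)Nx * Ny;
  cx_mat src, res, K;
  for (int o = 0; o < w * w; ++o) {
    const int da = (o % w) - h, db = (o / w) - h;
    const int sa = adjoint ? -da : da, sb = adjoint ? -db : db;
    const int i0 = std::max(0, -sa), i1 = std::min(Nx, Nx - sa) - 1;
    const int j0 = std::max(0, -sb), j1 = std::min(Ny, Ny - sb) - 1;
    if (i0 > i1 || j0 > j1) continue;
    const int nr = i1 - i0 + 1, nc = j1 - j0 + 1;
    const cx_mat Ko(const_cast<cx_double*>(kp) + (R_xlen_t)o * Cin * Cout,
                    Cin, Cout, false, true);
    K = adjoint ? cx_mat(Ko.t()) : Ko;
    // stack all blocks into one matrix so each offset costs one GEMM
    const R_xlen_t seg = (R_xlen_t)nr * nc;
    src.set_size(seg * nblock, Cfrom);
    for (int blk = 0; blk < nblock; ++blk) {
      for (int c = 0; c < Cfrom; ++c) {
        const cx_double* xs = xp + plane * (blk * Cfrom + c);
        cx_double* sp = src.colptr(c) + seg * blk;
        for (int j = 0; j < nc; ++j)
          std::memcpy(sp + (R_xlen_t)j * nr,
                      xs + (R_xlen_t)(j0 + sb + j) * Nx + i0 + sa,
                      nr * sizeof(cx_double));
      }
    }
    res = src * K;
    for (int blk = 0; blk < nblock; ++blk) {
      for (int c = 0; c < Cto; ++c) {
        cx_double* os = op + plane * (blk * Cto + c);
        const cx_double* rp = res.colptr(c) + seg * blk;
        for (int j = 0; j < nc; ++j) {
          cx_double* dst = os + (R_xlen_t)(j0 + j) * Nx + i0;
          const cx_double* sr = rp + (R_xlen_t)j * nr;
          for (int i = 0; i < nr; ++i) dst[i] += sr[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::ComplexVector cpp_spirit_apply(const Rcpp::ComplexVector& x,
                                     const Rcpp::ComplexVector& kern,
                                     const int Nx, const int Ny,
                                     const int Cin, const int Cout,
                                     const int w, const int nblock,
                                     const bool adjoint) {
  const int Cto = adjoint ? Cin : Cout;
  Rcpp::ComplexVector out((R_xlen_t)Nx * Ny * Cto * nblock);
  std::memset(out.begin(), 0, sizeof(Rcomplex) * out.size());
  spirit_apply_core(cptr(x), cptr(out), cptr(kern), Nx, Ny, Cin, Cout, w,
                    nblock, adjoint);
  return out;
}

// Fused SPIRiT normal operator: (G - I)^H (G - I) x.
// [[Rcpp::export]]
Rcpp::ComplexVector cpp_spirit_normal(const Rcpp::ComplexVector& x,
                                      const Rcpp::ComplexVector& kern,
                                      const int Nx, const int Ny,
                                      const int C, const int w,
                                      const int nblock) {
  const R_xlen_t n = (R_xlen_t)Nx * Ny * C * nblock;
  std::vector<cx_double> t(n, cx_double(0, 0));
  const cx_double* xp = cptr(x);
  spirit_apply_core(xp, t.data(), cptr(kern), Nx, Ny, C, C, w, nblock,
                    false);
  for (R_xlen_t i = 0; i < n; ++i) t[i] -= xp[i];
  Rcpp::ComplexVector out(n);
  std::memset(out.begin(), 0, sizeof(Rcomplex) * n);
  cx_double* op = cptr(out);
  spirit_apply_core(t.data(), op, cptr(kern), Nx, Ny, C, C, w, nblock,
                    true);
  for (R_xlen_t i = 0; i < n; ++i) op[i] -= t[i];
  return out;
}
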