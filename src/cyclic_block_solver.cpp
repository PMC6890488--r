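#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Direct O(N) solve of a cyclic block-tridiagonal system with 2x2 blocks:
//
//   L_i x_{i-1} + D_i x_i + U_i x_{i+1} = b_i,   i = 1..N (periodic: x_0 = x_N,
//   x_{N+1} = x_1),
//
// by condensation: eliminate x_1..x_{N-1} in terms of x_N with a block Thomas
// sweep carrying the corner-coupling columns, then close with the last block
// row.  Blocks are passed as N x 4 matrices in (a11, a12, a21, a22) order and
// the right-hand side / solution are interleaved (x_1, y_1, ..., x_N, y_N).
//
// The systems assembled by the time integrators have block rows built from a
// (near-)orthonormal tangent/normal pair, so the unpivoted 2x2 eliminations
// are well conditioned; a singular pivot is reported as an error.

struct B2 { double a, b, c, d; };  // [a b; c d]

static inline B2 inv2(const B2 &m) {
  double det = m.a * m.d - m.b * m.c;
  if (det == 0.0 || !R_finite(det)) stop("singular 2x2 pivot in cyclic solve");
  double id = 1.0 / det;
  B2 r = { m.d * id, -m.b * id, -m.c * id, m.a * id };
  return r;
}
static inline B2 mul2(const B2 &x, const B2 &y) {
  B2 r = { x.a * y.a + x.b * y.c, x.a * y.b + x.b * y.d,
           x.c * y.a + x.d * y.c, x.c * y.b + x.d * y.d };
  return r;
}
static inline B2 sub2(const B2 &x, const B2 &y) {
  B2 r = { x.a - y.a, x.b - y.b, x.c - y.c, x.d - y.d };
  return r;
}
static inline void mv2(const B2 &m, double vx, double vy, double &ox, double &oy) {
  ox = m.a * vx + m.b * vy;
  oy = m.c * vx + m.d * vy;
}
static inline B2 getblk(const NumericMatrix &M, int i) {
  B2 r = { M(i, 0), M(i, 1), M(i, 2), M(i, 3) };
  return r;
}

// [[Rcpp::export]]
NumericVector cyclic_block_solve(NumericMatrix L, NumericMatrix D,
                                 NumericMatrix U, NumericVector rhs) {
  const int N = D.nrow();
  if (L.nrow() != N || U.nrow() != N || rhs.size() != 2 * N)
    stop("inconsistent system dimensions");
  if (N < 3) stop("need at least 3 block rows");

  const int M = N - 1;  // interior unknowns x_1..x_{N-1}
  std::vector<B2> DhatInv(M), What(M), Z(M);
  std::vector<double> bx(M), by(M), yx(M), yy(M);

  // forward elimination over rows 1..N-1 (0-based 0..M-1), carrying the
  // x_N-coupling matrix What alongside the right-hand side
  for (int i = 0; i < M; ++i) {
    B2 Di = getblk(D, i);
    double bxi = rhs[2 * i], byi = rhs[2 * i + 1];
    B2 Wi = { 0, 0, 0, 0 };
    if (i == 0) Wi = getblk(L, 0);                      // row 1 couples to x_N
    if (i == M - 1) {
      B2 Ui = getblk(U, M - 1);                         // row N-1 couples to x_N
      Wi.a += Ui.a; Wi.b += Ui.b; Wi.c += Ui.c; Wi.d += Ui.d;
    }
    if (i > 0) {
      B2 m = mul2(getblk(L, i), DhatInv[i - 1]);
      Di = sub2(Di, mul2(m, getblk(U, i - 1)));
      double tx, ty;
      mv2(m, bx[i - 1], by[i - 1], tx, ty);
      bxi -= tx; byi -= ty;
      Wi = sub2(Wi, mul2(m, What[i - 1]));
    }
    DhatInv[i] = inv2(Di);
    bx[i] = bxi; by[i] = byi; What[i] = Wi;
  }

  // back substitution: x_i = y_i - Z_i x_N
  for (int i = M - 1; i >= 0; --i) {
    double bxi = bx[i], byi = by[i];
    B2 Wi = What[i];
    if (i < M - 1 && i != M - 1) {
      B2 Ui = getblk(U, i);
      double tx, ty;
      mv2(Ui, yx[i + 1], yy[i + 1], tx, ty);
      bxi -= tx; byi -= ty;
      Wi = sub2(Wi, mul2(Ui, Z[i + 1]));
    }
    mv2(DhatInv[i], bxi, byi, yx[i], yy[i]);
    Z[i] = mul2(DhatInv[i], Wi);
  }

  // close with block row N: L_N x_{N-1} + D_N x_N + U_N x_1 = b_N
  B2 LN = getblk(L, N - 1), DN = getblk(D, N - 1), UN = getblk(U, N - 1);
  B2 S = sub2(sub2(DN, mul2(LN, Z[M - 1])), mul2(UN, Z[0]));
  double rx = rhs[2 * (N - 1)], ry = rhs[2 * (N - 1) + 1], tx, ty;
  mv2(LN, yx[M - 1], yy[M - 1], tx, ty); rx -= tx; ry -= ty;
  mv2(UN, yx[0], yy[0], tx, ty);         rx -= tx; ry -= ty;
  double xN, yN;
  mv2(inv2(S), rx, ry, xN, yN);

  NumericVector out(2 * N);
  out[2 * (N - 1)] = xN;
  out[2 * (N - 1) + 1] = yN;
  for (int i = 0; i < M; ++i) {
    double zx, zy;
    mv2(Z[i], xN, yN, zx, zy);
    out[2 * i] = yx[i] - zx;
    out[2 * i + 1] = yy[i] - zy;
  }
  return out;
}
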