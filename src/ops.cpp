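#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
using namespace Rcpp;

// Voxel linear order everywhere: v = ix + X*(iy + Y*iz), 0-based, matching an
// R array of dim c(X, Y, Z) flattened column-major.

// ---- 3x3x3 im2col / col2im (zero padding 1) ------------------------------

// x: [N, C] feature matrix over an (X,Y,Z) grid -> [N, 27*C], where column
// c*27 + o holds x(v + off_o, c); off order o = (dx+1) + 3*(dy+1) + 9*(dz+1).
// [[Rcpp::export]]
NumericMatrix im2col3(NumericMatrix x, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int N = X * Y * Z, C = x.ncol();
  if (x.nrow() != N) stop("im2col3: nrow(x) != prod(dims)");
  NumericMatrix out(no_init(N, 27 * C));
  const double* xp = REAL(x);
  double* op = REAL(out);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)N * c;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          const int o = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
          double* oc = op + (size_t)N * (c * 27 + o);
          for (int iz = 0; iz < Z; ++iz) {
            const int jz = iz + dz;
            if (jz < 0 || jz >= Z) { // padded plane: zeros
              std::fill(oc + (size_t)X * Y * iz, oc + (size_t)X * Y * (iz + 1), 0.0);
              continue;
            }
            for (int iy = 0; iy < Y; ++iy) {
              const int jy = iy + dy;
              const int base = X * (iy + Y * iz);
              if (jy < 0 || jy >= Y) {
                std::fill(oc + base, oc + base + X, 0.0);
                continue;
              }
              const int jbase = X * (jy + Y * jz);
              if (dx < 0) oc[base] = 0.0;
              if (dx > 0) oc[base + X - 1] = 0.0;
              const int x0 = dx < 0 ? -dx : 0;
              const int x1 = dx > 0 ? X - dx : X;
              std::copy(xc + jbase + x0 + dx, xc + jbase + x1 + dx, oc + base + x0);
            }
          }
        }
  }
  return out;
}

// Adjoint of im2col3: dcol [N, 27*C] -> dx [N, C];
// dx(v + off_o, c) += dcol(v, c*27 + o).
// [[Rcpp::export]]
NumericMatrix col2im3(NumericMatrix dcol, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int N = X * Y * Z;
  if (dcol.ncol() % 27 != 0) stop("col2im3: ncol not a multiple of 27");
  const int C = dcol.ncol() / 27;
  if (dcol.nrow() != N) stop("col2im3: nrow != prod(dims)");
  NumericMatrix dx(N, C);
  const double* dp = REAL(dcol);
  double* op = REAL(dx);
  for (int c = 0; c < C; ++c) {
    double* oc = op + (size_t)N * c;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx_ = -1; dx_ <= 1; ++dx_) {
          const int o = (dx_ + 1) + 3 * (dy + 1) + 9 * (dz + 1);
          const double* dc = dp + (size_t)N * (c * 27 + o);
          for (int iz = 0; iz < Z; ++iz) {
            const int jz = iz + dz;
            if (jz < 0 || jz >= Z) continue;
            for (int iy = 0; iy < Y; ++iy) {
              const int jy = iy + dy;
              if (jy < 0 || jy >= Y) continue;
              const int base = X * (iy + Y * iz);
              const int jbase = X * (jy + Y * jz);
              const int x0 = dx_ < 0 ? -dx_ : 0;
              const int x1 = dx_ > 0 ? X - dx_ : X;
              for (int ix = x0; ix < x1; ++ix)
                oc[jbase + ix + dx_] += dc[base + ix];
            }
          }
        }
  }
  return dx;
}

// ---- fused shifted-GEMM 3x3x3 convolution --------------------------------
//
// y[v, ] += x[v + s_o, ] %*% W_o for each of the 27 offsets, realized as one
// BLAS GEMM over the valid contiguous row range per offset plus explicit
// subtraction at the x/y wrap-around rows. Equivalent to im2col + GEMM (the
// im2col kernels above serve as the reference in the tests) but without the
// 27x feature-map scratch matrix, which matters on a single CPU.

namespace {

// dst[v, 1:dstC] += src[v + s, 1:srcC] %*% M (srcC x dstC) over voxels where
// the (dx,dy,dz)-neighbour exists; N rows, grid (X,Y,Z), column-major.
void shiftAccum(double* dst, int dstC, const double* src, int srcC,
                const double* M, int N, int X, int Y, int Z,
                int dx, int dy, int dz) {
  const int s = dx + X * dy + X * Y * dz;
  const int z0 = dz < 0 ? -dz : 0;
  const int z1 = dz > 0 ? Z - 1 - dz : Z - 1;
  if (z1 < z0) return;
  const int a = std::max(z0 * X * Y, -s);
  const int b = std::min((z1 + 1) * X * Y - 1, N - 1 - s);
  if (b < a) return;
  const int mRows = b - a + 1;
  const double one = 1.0;
  F77_CALL(dgemm)("N", "N", &mRows, &dstC, &srcC, &one,
                  src + (a + s), &N, M, &srcC, &one,
                  dst + a, &N FCONE FCONE);
  // undo contributions GEMM added at rows whose neighbour wraps in x or y
  auto correct = [&](int v) {
    for (int co = 0; co < dstC; ++co) {
      double acc = 0.0;
      for (int ci = 0; ci < srcC; ++ci)
        acc += src[v + s + (size_t)N * ci] * M[ci + (size_t)srcC * co];
      dst[v + (size_t)N * co] -= acc;
    }
  };
  for (int iz = z0; iz <= z1; ++iz) {
    for (int iy = 0; iy < Y; ++iy) {
      const int jy = iy + dy;
      const int rowbase = X * (iy + Y * iz);
      if (jy < 0 || jy >= Y) {
        const int v0 = std::max(rowbase, a), v1 = std::min(rowbase + X - 1, b);
        for (int v = v0; v <= v1; ++v) correct(v);
      } else if (dx != 0) {
        const int v = dx < 0 ? rowbase : rowbase + X - 1;
        if (v >= a && v <= b) correct(v);
      }
    }
  }
}

} // namespace

// Forward: x [N, Cin], W [(27*Cin), Cout] with row (ci*27 + o) -> y [N, Cout].
// [[Rcpp::export]]
NumericMatrix conv3fwd(NumericMatrix x, IntegerVector dims, NumericMatrix W) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int N = X * Y * Z, Ci = x.ncol();
  if (x.nrow() != N) stop("conv3fwd: nrow(x) != prod(dims)");
  if (W.nrow() != 27 * Ci) stop("conv3fwd: nrow(W) != 27 * ncol(x)");
  const int Co = W.ncol();
  NumericMatrix y(N, Co);
  std::vector<double> Wo((size_t)Ci * Co);
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int o = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
        for (int co = 0; co < Co; ++co)
          for (int ci = 0; ci < Ci; ++ci)
            Wo[ci + (size_t)Ci * co] = W(ci * 27 + o, co);
        shiftAccum(REAL(y), Co, REAL(x), Ci, Wo.data(), N, X, Y, Z, dx, dy, dz);
      }
  return y;
}

// Gradient w.r.t. the input: dy [N, Cout] -> dx [N, Cin].
// [[Rcpp::export]]
NumericMatrix conv3bwdData(NumericMatrix dy, IntegerVector dims, NumericMatrix W) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int N = X * Y * Z, Co = dy.ncol();
  if (dy.nrow() != N) stop("conv3bwdData: nrow(dy) != prod(dims)");
  if (W.ncol() != Co) stop("conv3bwdData: ncol(W) != ncol(dy)");
  const int Ci = W.nrow() / 27;
  NumericMatrix dx(N, Ci);
  std::vector<double> WoT((size_t)Co * Ci);
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy_ = -1; dy_ <= 1; ++dy_)
      for (int dx_ = -1; dx_ <= 1; ++dx_) {
        const int o = (dx_ + 1) + 3 * (dy_ + 1) + 9 * (dz + 1);
        for (int ci = 0; ci < Ci; ++ci)
          for (int co = 0; co < Co; ++co)
            WoT[co + (size_t)Co * ci] = W(ci * 27 + o, co);
        shiftAccum(REAL(dx), Ci, REAL(dy), Co, WoT.data(), N, X, Y, Z,
                   -dx_, -dy_, -dz);
      }
  return dx;
}

// Gradient w.r.t. the weights: dW [(27*Cin), Cout].
// [[Rcpp::export]]
NumericMatrix conv3dW(NumericMatrix x, NumericMatrix dy, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int N = X * Y * Z, Ci = x.ncol(), Co = dy.ncol();
  if (x.nrow() != N || dy.nrow() != N) stop("conv3dW: shape mismatch");
  NumericMatrix dW(27 * Ci, Co);
  std::vector<double> G((size_t)Ci * Co);
  const double one = 1.0, zero = 0.0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy_ = -1; dy_ <= 1; ++dy_)
      for (int dx_ = -1; dx_ <= 1; ++dx_) {
        const int o = (dx_ + 1) + 3 * (dy_ + 1) + 9 * (dz + 1);
        const int s = dx_ + X * dy_ + X * Y * dz;
        const int z0 = dz < 0 ? -dz : 0;
        const int z1 = dz > 0 ? Z - 1 - dz : Z - 1;
        std::fill(G.begin(), G.end(), 0.0);
        if (z1 >= z0) {
          const int a = std::max(z0 * X * Y, -s);
          const int b = std::min((z1 + 1) * X * Y - 1, N - 1 - s);
          if (b >= a) {
            const int mRows = b - a + 1;
            F77_CALL(dgemm)("T", "N", &Ci, &Co, &mRows, &one,
                            REAL(x) + (a + s), &N, REAL(dy) + a, &N, &zero,
                            G.data(), &Ci FCONE FCONE);
            (void)zero;
            for (int iz = z0; iz <= z1; ++iz) {
              for (int iy = 0; iy < Y; ++iy) {
                const int jy = iy + dy_;
                const int rowbase = X * (iy + Y * iz);
                auto correct = [&](int v) {
                  for (int co = 0; co < Co; ++co)
                    for (int ci = 0; ci < Ci; ++ci)
                      G[ci + (size_t)Ci * co] -=
                        x(v + s, ci) * dy(v, co);
                };
                if (jy < 0 || jy >= Y) {
                  const int v0 = std::max(rowbase, a), v1 = std::min(rowbase + X - 1, b);
                  for (int v = v0; v <= v1; ++v) correct(v);
                } else if (dx_ != 0) {
                  const int v = dx_ < 0 ? rowbase : rowbase + X - 1;
                  if (v >= a && v <= b) correct(v);
                }
              }
            }
          }
        }
        for (int co = 0; co < Co; ++co)
          for (int ci = 0; ci < Ci; ++ci)
            dW(ci * 27 + o, co) = G[ci + (size_t)Ci * co];
      }
  return dW;
}

// ---- 2x2x2 max pooling ----------------------------------------------------

// [[Rcpp::export]]
List maxpool3(NumericMatrix x, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  if (X % 2 || Y % 2 || Z % 2) stop("maxpool3: dims must be even");
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  const int No = Xo * Yo * Zo, C = x.ncol();
  NumericMatrix y(No, C);
  IntegerMatrix arg(No, C); // 1-based row index into x
  const double* xp = REAL(x);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)(X * Y * Z) * c;
    for (int oz = 0; oz < Zo; ++oz)
      for (int oy = 0; oy < Yo; ++oy)
        for (int ox = 0; ox < Xo; ++ox) {
          double best = -1e300; int bi = -1;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const int v = (2 * ox + dx) + X * ((2 * oy + dy) + Y * (2 * oz + dz));
                if (xc[v] > best) { best = xc[v]; bi = v; }
              }
          const int vo = ox + Xo * (oy + Yo * oz);
          y(vo, c) = best;
          arg(vo, c) = bi + 1;
        }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericMatrix maxpool3_back(NumericMatrix dy, IntegerMatrix arg, int nIn) {
  const int No = dy.nrow(), C = dy.ncol();
  NumericMatrix dx(nIn, C);
  for (int c = 0; c < C; ++c)
    for (int v = 0; v < No; ++v)
      dx(arg(v, c) - 1, c) += dy(v, c);
  return dx;
}

// ---- nearest-neighbour distances -----------------------------------------

// For each row a of A (n x 3), the minimum Euclidean distance to any row of B.
// [[Rcpp::export]]
NumericVector nearestDistCpp(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  if (m == 0) stop("nearestDistCpp: empty reference point set");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// ---- connected components (26-connectivity) ------------------------------

// mask: logical over (X,Y,Z) grid; returns integer labels (0 = background).
// [[Rcpp::export]]
IntegerVector ccLabel3d(LogicalVector mask, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int N = X * Y * Z;
  if (mask.size() != N) stop("ccLabel3d: length(mask) != prod(dims)");
  IntegerVector lab(N, 0);
  int next = 0;
  std::vector<int> stack;
  for (int s = 0; s < N; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      const int v = stack.back(); stack.pop_back();
      const int ix = v % X, iy = (v / X) % Y, iz = v / (X * Y);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            const int jx = ix + dx, jy = iy + dy, jz = iz + dz;
            if (jx < 0 || jx >= X || jy < 0 || jy >= Y || jz < 0 || jz >= Z) continue;
            const int w = jx + X * (jy + Y * jz);
            if (mask[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
          }
    }
  }
  return lab;
}

// ---- 3D thinning by sequential simple-point removal -----------------------

namespace {

// 26-neighbour offsets within a 3x3x3 block, center excluded.
// A point is *simple* iff (a) its object 26-neighbours form exactly one
// 26-connected component, and (b) the background voxels of its 18-neighbourhood
// form exactly one 6-connected component touching a face neighbour
// (Bertrand-Malandain characterization). Deleting simple points sequentially
// preserves topology.
inline int blockIndex(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

bool isSimple(const bool nb[27]) {
  // (a) one 26-component among object neighbours
  bool obj[27];
  int nObj = 0;
  for (int i = 0; i < 27; ++i) { obj[i] = (i != 13) && nb[i]; if (obj[i]) ++nObj; }
  if (nObj == 0) return false;
  {
    bool seen[27] = {false};
    int seed = -1;
    for (int i = 0; i < 27; ++i) if (obj[i]) { seed = i; break; }
    std::vector<int> st; st.push_back(seed); seen[seed] = true;
    while (!st.empty()) {
      const int v = st.back(); st.pop_back();
      const int vx = v % 3, vy = (v / 3) % 3, vz = v / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            const int jx = vx + dx, jy = vy + dy, jz = vz + dz;
            if (jx < 0 || jx > 2 || jy < 0 || jy > 2 || jz < 0 || jz > 2) continue;
            const int w = jx + 3 * jy + 9 * jz;
            if (obj[w] && !seen[w]) { seen[w] = true; st.push_back(w); }
          }
    }
    for (int i = 0; i < 27; ++i) if (obj[i] && !seen[i]) return false;
  }
  // (b) one 6-component of background within the 18-neighbourhood containing
  // a face neighbour; 6-adjacency restricted to the 18-neighbourhood.
  {
    bool bg18[27] = {false};
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          const int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
          if (m == 0 || m == 3) continue; // 18-neighbourhood only
          const int i = blockIndex(dx, dy, dz);
          bg18[i] = !nb[i];
        }
    const int faces[6] = {blockIndex(-1,0,0), blockIndex(1,0,0), blockIndex(0,-1,0),
                          blockIndex(0,1,0), blockIndex(0,0,-1), blockIndex(0,0,1)};
    int seed = -1;
    for (int f = 0; f < 6; ++f) if (bg18[faces[f]]) { seed = faces[f]; break; }
    if (seed < 0) return false; // no background face neighbour: interior point
    bool seen[27] = {false};
    std::vector<int> st; st.push_back(seed); seen[seed] = true;
    while (!st.empty()) {
      const int v = st.back(); st.pop_back();
      const int vx = v % 3, vy = (v / 3) % 3, vz = v / 9;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        const int jx = vx + d6[k][0], jy = vy + d6[k][1], jz = vz + d6[k][2];
        if (jx < 0 || jx > 2 || jy < 0 || jy > 2 || jz < 0 || jz > 2) continue;
        const int w = jx + 3 * jy + 9 * jz;
        if (bg18[w] && !seen[w]) { seen[w] = true; st.push_back(w); }
      }
    }
    // every background face neighbour must be reachable from the seed
    for (int f = 0; f < 6; ++f) if (bg18[faces[f]] && !seen[faces[f]]) return false;
  }
  return true;
}

} // namespace

// Thin a 3D mask to a ~1-voxel skeleton. `protect` holds 1-based linear voxel
// indices never deleted (e.g. the soma anchor). Endpoints (<= 1 object
// neighbour) are kept to preserve fiber tips.
// [[Rcpp::export]]
LogicalVector thin3d(LogicalVector mask, IntegerVector dims, IntegerVector protect) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int N = X * Y * Z;
  if (mask.size() != N) stop("thin3d: length(mask) != prod(dims)");
  std::vector<char> m(N);
  for (int i = 0; i < N; ++i) m[i] = mask[i] ? 1 : 0;
  std::vector<char> keep(N, 0);
  for (int i = 0; i < protect.size(); ++i) {
    const int v = protect[i] - 1;
    if (v >= 0 && v < N) keep[v] = 1;
  }
  const int dirs[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  bool nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      for (int v = 0; v < N; ++v) {
        if (!m[v] || keep[v]) continue;
        const int ix = v % X, iy = (v / X) % Y, iz = v / (X * Y);
        // border in direction d?
        const int bx = ix + dirs[d][0], by = iy + dirs[d][1], bz = iz + dirs[d][2];
        const bool borderOut = bx < 0 || bx >= X || by < 0 || by >= Y || bz < 0 || bz >= Z;
        if (!borderOut && m[bx + X * (by + Y * bz)]) continue;
        if (borderOut) continue; // keep voxels at the volume face conservative
        int nObj = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              const int jx = ix + dx, jy = iy + dy, jz = iz + dz;
              bool val = false;
              if (jx >= 0 && jx < X && jy >= 0 && jy < Y && jz >= 0 && jz < Z)
                val = m[jx + X * (jy + Y * jz)] != 0;
              nb[blockIndex(dx, dy, dz)] = val;
              if (val && !(dx == 0 && dy == 0 && dz == 0)) ++nObj;
            }
        if (nObj <= 1) continue; // endpoint
        if (isSimple(nb)) { m[v] = 0; changed = true; }
      }
    }
  }
  LogicalVector out(N);
  for (int i = 0; i < N; ++i) out[i] = m[i] != 0;
  return out;
}
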