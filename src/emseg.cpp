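#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Image arrays are column-major [H, W] matrices or [H, W, C] arrays,
// matching R's layout. All neighbourhood code treats pixels outside the
// image as background unless stated otherwise.

// ---------------------------------------------------------------------------
// 2D convolution, odd kernel, stride 1, zero same-padding.
// x: [H, W, Cin], w: [k, k, Cin, Cout] (w[ki, kj, ci, co]), b: [Cout].
// y[i, j, co] = b[co] + sum_{ki, kj, ci} x[i + ki - p, j + kj - p, ci] * w[ki, kj, ci, co]
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int k = wd[0], Cout = wd[3];
  const int p = k / 2;
  NumericVector y(static_cast<R_xlen_t>(H) * W * Cout);
  double* yp = REAL(y);
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  for (int co = 0; co < Cout; ++co) {
    double* yc = yp + static_cast<R_xlen_t>(co) * H * W;
    const double bias = b[co];
    for (R_xlen_t t = 0; t < static_cast<R_xlen_t>(H) * W; ++t) yc[t] = bias;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = xp + static_cast<R_xlen_t>(ci) * H * W;
      for (int kj = 0; kj < k; ++kj) {
        const int dj = kj - p;
        for (int ki = 0; ki < k; ++ki) {
          const int di = ki - p;
          const double wv = wp[ki + k * (kj + k * (ci + Cin * co))];
          if (wv == 0.0) continue;
          const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int j = j0; j < j1; ++j) {
            double* yrow = yc + static_cast<R_xlen_t>(j) * H;
            const double* xrow = xc + static_cast<R_xlen_t>(j + dj) * H + di;
            for (int i = i0; i < i1; ++i) yrow[i] += wv * xrow[i];
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, Cout);
  return y;
}

// Gradients of the same convolution. dy: [H, W, Cout].
// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int k = wd[0], Cout = wd[3];
  const int p = k / 2;
  NumericVector dx(static_cast<R_xlen_t>(H) * W * Cin);
  NumericVector dw(static_cast<R_xlen_t>(k) * k * Cin * Cout);
  NumericVector db(Cout);
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  const double* dyp = REAL(dy);
  double* dxp = REAL(dx);
  double* dwp = REAL(dw);
  for (int co = 0; co < Cout; ++co) {
    const double* dyc = dyp + static_cast<R_xlen_t>(co) * H * W;
    double acc = 0.0;
    for (R_xlen_t t = 0; t < static_cast<R_xlen_t>(H) * W; ++t) acc += dyc[t];
    db[co] = acc;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = xp + static_cast<R_xlen_t>(ci) * H * W;
      double* dxc = dxp + static_cast<R_xlen_t>(ci) * H * W;
      for (int kj = 0; kj < k; ++kj) {
        const int dj = kj - p;
        for (int ki = 0; ki < k; ++ki) {
          const int di = ki - p;
          const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          const double wv = wp[ki + k * (kj + k * (ci + Cin * co))];
          double gw = 0.0;
          for (int j = j0; j < j1; ++j) {
            const double* dyrow = dyc + static_cast<R_xlen_t>(j) * H;
            const double* xrow = xc + static_cast<R_xlen_t>(j + dj) * H + di;
            double* dxrow = dxc + static_cast<R_xlen_t>(j + dj) * H + di;
            for (int i = i0; i < i1; ++i) {
              gw += dyrow[i] * xrow[i];
              dxrow[i] += dyrow[i] * wv;
            }
          }
          dwp[ki + k * (kj + k * (ci + Cin * co))] += gw;
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, Cin);
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2. Returns pooled values and 1-based argmax
// indices into the input plane (per channel).
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C);
  IntegerVector idx(static_cast<R_xlen_t>(Ho) * Wo * C);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ip = INTEGER(idx);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + static_cast<R_xlen_t>(c) * H * W;
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        int best = 2 * io + H * (2 * jo);
        double bv = xc[best];
        const int cand[3] = {2 * io + 1 + H * (2 * jo),
                             2 * io + H * (2 * jo + 1),
                             2 * io + 1 + H * (2 * jo + 1)};
        for (int t = 0; t < 3; ++t) {
          if (xc[cand[t]] > bv) { bv = xc[cand[t]]; best = cand[t]; }
        }
        const R_xlen_t o = io + static_cast<R_xlen_t>(Ho) * jo +
          static_cast<R_xlen_t>(c) * Ho * Wo;
        yp[o] = bv;
        ip[o] = best + 1;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector idx, NumericVector dy, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2];
  NumericVector dx(static_cast<R_xlen_t>(H) * W * C);
  double* dxp = REAL(dx);
  const double* dyp = REAL(dy);
  const int* ip = INTEGER(idx);
  for (int c = 0; c < C; ++c) {
    const R_xlen_t oy = static_cast<R_xlen_t>(c) * Ho * Wo;
    const R_xlen_t ox = static_cast<R_xlen_t>(c) * H * W;
    for (R_xlen_t t = 0; t < static_cast<R_xlen_t>(Ho) * Wo; ++t) {
      dxp[ox + ip[oy + t] - 1] += dyp[oy + t];
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}

// ---------------------------------------------------------------------------
// Chessboard (Chebyshev, L-infinity) distance from labelled (true) pixels to
// the nearest unlabelled (false) pixel; pixels outside the image count as
// unlabelled. Two-pass chamfer with unit weights, which is exact for L-inf.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_chessboard_distance(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  const int INF = H + W + 2;
  IntegerMatrix d(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      d(i, j) = mask(i, j) ? INF : 0;
  // value just outside the image is 0 (unlabelled)
  auto at = [&](int i, int j) -> int {
    if (i < 0 || j < 0 || i >= H || j >= W) return 0;
    return d(i, j);
  };
  // forward pass (column-major scan: mask = N, W, NW, SW)
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (d(i, j) == 0) continue;
      int m = std::min(std::min(at(i - 1, j), at(i, j - 1)),
                       std::min(at(i - 1, j - 1), at(i + 1, j - 1)));
      d(i, j) = std::min(d(i, j), m + 1);
    }
  }
  // backward pass (mask = S, E, SE, NE)
  for (int j = W - 1; j >= 0; --j) {
    for (int i = H - 1; i >= 0; --i) {
      if (d(i, j) == 0) continue;
      int m = std::min(std::min(at(i + 1, j), at(i, j + 1)),
                       std::min(at(i + 1, j + 1), at(i - 1, j + 1)));
      d(i, j) = std::min(d(i, j), m + 1);
    }
  }
  return d;
}

// ---------------------------------------------------------------------------
// Connected-component labelling (4 or 8 connectivity), labels 1..n in
// raster-scan discovery order; 0 outside the mask.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_cc_label(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int>> nb;
  nb.push_back({-1, 0}); nb.push_back({1, 0}); nb.push_back({0, -1}); nb.push_back({0, 1});
  if (connectivity == 8) {
    nb.push_back({-1, -1}); nb.push_back({-1, 1}); nb.push_back({1, -1}); nb.push_back({1, 1});
  }
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + H * j);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int q = stack.back(); stack.pop_back();
        const int qi = q % H, qj = q / H;
        for (size_t t = 0; t < nb.size(); ++t) {
          const int ni = qi + nb[t].first, nj = qj + nb[t].second;
          if (ni < 0 || nj < 0 || ni >= H || nj >= W) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + H * nj);
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Binary erosion / dilation by a Euclidean disk {(di,dj): di^2+dj^2 <= r^2}.
// Outside the image counts as background (so erosion eats borders).
// ---------------------------------------------------------------------------

static std::vector<std::pair<int, int>> disk_offsets(int r) {
  std::vector<std::pair<int, int>> off;
  for (int di = -r; di <= r; ++di)
    for (int dj = -r; dj <= r; ++dj)
      if (di * di + dj * dj <= r * r) off.push_back({di, dj});
  return off;
}

// [[Rcpp::export]]
LogicalMatrix cpp_erode_disk(LogicalMatrix mask, int r) {
  const int H = mask.nrow(), W = mask.ncol();
  LogicalMatrix out(H, W);
  std::vector<std::pair<int, int>> off = disk_offsets(r);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) { out(i, j) = false; continue; }
      bool keep = true;
      for (size_t t = 0; t < off.size() && keep; ++t) {
        const int ni = i + off[t].first, nj = j + off[t].second;
        if (ni < 0 || nj < 0 || ni >= H || nj >= W || !mask(ni, nj)) keep = false;
      }
      out(i, j) = keep;
    }
  }
  return out;
}

// [[Rcpp::export]]
LogicalMatrix cpp_dilate_disk(LogicalMatrix mask, int r) {
  const int H = mask.nrow(), W = mask.ncol();
  LogicalMatrix out(H, W);
  std::vector<std::pair<int, int>> off = disk_offsets(r);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      bool hit = false;
      for (size_t t = 0; t < off.size() && !hit; ++t) {
        const int ni = i + off[t].first, nj = j + off[t].second;
        if (ni >= 0 && nj >= 0 && ni < H && nj < W && mask(ni, nj)) hit = true;
      }
      out(i, j) = hit;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Guo-Hall thinning to a 1-pixel-wide skeleton; preserves 8-connectivity.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalMatrix cpp_thin_guo_hall(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<unsigned char> img(static_cast<size_t>(H) * W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      img[i + static_cast<size_t>(H) * j] = mask(i, j) ? 1 : 0;
  auto px = [&](int i, int j) -> int {
    if (i < 0 || j < 0 || i >= H || j >= W) return 0;
    return img[i + static_cast<size_t>(H) * j];
  };
  bool changed = true;
  while (changed) {
    changed = false;
    for (int iter = 0; iter < 2; ++iter) {
      std::vector<int> kill;
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          if (!px(i, j)) continue;
          const int p2 = px(i - 1, j), p3 = px(i - 1, j + 1), p4 = px(i, j + 1);
          const int p5 = px(i + 1, j + 1), p6 = px(i + 1, j), p7 = px(i + 1, j - 1);
          const int p8 = px(i, j - 1), p9 = px(i - 1, j - 1);
          const int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                        ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
          const int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
          const int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
          const int N = std::min(N1, N2);
          const int m = (iter == 0) ? ((p6 | p7 | (!p9)) & p8)
                                    : ((p2 | p3 | (!p5)) & p4);
          if (C == 1 && N >= 2 && N <= 3 && m == 0) kill.push_back(i + H * j);
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t t = 0; t < kill.size(); ++t) img[kill[t]] = 0;
    }
  }
  LogicalMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out(i, j) = img[i + static_cast<size_t>(H) * j] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// h-minima suppression: geodesic reconstruction by erosion of (f + h) above
// f, 8-connected, by alternating raster/anti-raster sweeps until stable.
// Fills in all regional minima whose depth is below h.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_hmin_suppress(NumericMatrix f, double h) {
  const int H = f.nrow(), W = f.ncol();
  NumericMatrix rec(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      rec(i, j) = f(i, j) + h;
  auto at = [&](int i, int j) -> double {
    if (i < 0 || j < 0 || i >= H || j >= W) return std::numeric_limits<double>::infinity();
    return rec(i, j);
  };
  bool changed = true;
  int guard = 0;
  while (changed && guard++ < 4 * (H + W)) {
    changed = false;
    for (int j = 0; j < W; ++j) {      // raster sweep
      for (int i = 0; i < H; ++i) {
        double m = std::min(std::min(at(i - 1, j - 1), at(i - 1, j)),
                            std::min(std::min(at(i - 1, j + 1), at(i, j - 1)), rec(i, j)));
        const double v = std::max(m, f(i, j));
        if (v < rec(i, j)) { rec(i, j) = v; changed = true; }
      }
    }
    for (int j = W - 1; j >= 0; --j) { // anti-raster sweep
      for (int i = H - 1; i >= 0; --i) {
        double m = std::min(std::min(at(i + 1, j + 1), at(i + 1, j)),
                            std::min(std::min(at(i + 1, j - 1), at(i, j + 1)), rec(i, j)));
        const double v = std::max(m, f(i, j));
        if (v < rec(i, j)) { rec(i, j) = v; changed = true; }
      }
    }
  }
  return rec;
}

// ---------------------------------------------------------------------------
// Seeded watershed (Meyer flooding) on a scalar landscape. seeds: labelled
// seed regions (>0), 0 elsewhere. Pixels reached from two or more distinct
// regions become ridge pixels and keep label 0.
// ---------------------------------------------------------------------------

struct WsEntry {
  double v;
  long long order;
  int pix;
};
struct WsCmp {
  bool operator()(const WsEntry& a, const WsEntry& b) const {
    if (a.v != b.v) return a.v > b.v;      // lowest value first
    return a.order > b.order;              // FIFO among equals
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_watershed_seeded(NumericMatrix f, IntegerMatrix seeds, int connectivity) {
  const int H = f.nrow(), W = f.ncol();
  const int RIDGE = -1;
  IntegerMatrix lab(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      lab(i, j) = seeds(i, j) > 0 ? seeds(i, j) : 0;
  std::vector<std::pair<int, int>> nb;
  nb.push_back({-1, 0}); nb.push_back({1, 0}); nb.push_back({0, -1}); nb.push_back({0, 1});
  if (connectivity == 8) {
    nb.push_back({-1, -1}); nb.push_back({-1, 1}); nb.push_back({1, -1}); nb.push_back({1, 1});
  }
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;
  std::vector<unsigned char> queued(static_cast<size_t>(H) * W, 0);
  long long order = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (lab(i, j) <= 0) continue;
      for (size_t t = 0; t < nb.size(); ++t) {
        const int ni = i + nb[t].first, nj = j + nb[t].second;
        if (ni < 0 || nj < 0 || ni >= H || nj >= W) continue;
        const int q = ni + H * nj;
        if (lab(ni, nj) == 0 && !queued[q]) {
          queued[q] = 1;
          pq.push({f(ni, nj), order++, q});
        }
      }
    }
  }
  while (!pq.empty()) {
    const WsEntry e = pq.top(); pq.pop();
    const int i = e.pix % H, j = e.pix / H;
    if (lab(i, j) != 0) continue;
    int found = 0;
    bool conflict = false;
    for (size_t t = 0; t < nb.size(); ++t) {
      const int ni = i + nb[t].first, nj = j + nb[t].second;
      if (ni < 0 || nj < 0 || ni >= H || nj >= W) continue;
      const int l = lab(ni, nj);
      if (l > 0) {
        if (found == 0) found = l;
        else if (found != l) conflict = true;
      }
    }
    if (found == 0 || conflict) {
      lab(i, j) = RIDGE;
    } else {
      lab(i, j) = found;
    }
    for (size_t t = 0; t < nb.size(); ++t) {
      const int ni = i + nb[t].first, nj = j + nb[t].second;
      if (ni < 0 || nj < 0 || ni >= H || nj >= W) continue;
      const int q = ni + H * nj;
      if (lab(ni, nj) == 0 && !queued[q]) {
        queued[q] = 1;
        pq.push({f(ni, nj), order++, q});
      }
    }
  }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (lab(i, j) == RIDGE) lab(i, j) = 0;
  return lab;
}
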