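// Compact convolutional network used by the image-based detector and size
// regressor: blocks of [3x3 same-padding conv -> ReLU -> 2x2 max-pool],
// global average pooling, one hidden dense layer with ReLU, and a scalar
// head (sigmoid for detection, linear for size). Trained with Adam on
// binary cross-entropy or squared error. All randomness (weight init,
// epoch shuffling) is drawn from R's RNG so set.seed() controls it; the
// implementation is single-threaded and deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::cube;
using arma::mat;
using arma::uvec;
using arma::uword;
using arma::vec;

struct Net {
  std::vector<mat> W;  // conv kernels as (Cout x 9*Cin)
  std::vector<vec> b;
  mat Wd1;
  vec bd1;
  mat Wd2;
  vec bd2;
};

static Net net_from_list(const Rcpp::List& w) {
  Net n;
  Rcpp::List cw = w["conv_w"], cb = w["conv_b"];
  for (int i = 0; i < cw.size(); ++i) {
    n.W.push_back(Rcpp::as<mat>(cw[i]));
    n.b.push_back(Rcpp::as<vec>(cb[i]));
  }
  n.Wd1 = Rcpp::as<mat>(w["dense_w1"]);
  n.bd1 = Rcpp::as<vec>(w["dense_b1"]);
  n.Wd2 = Rcpp::as<mat>(w["dense_w2"]);
  n.bd2 = Rcpp::as<vec>(w["dense_b2"]);
  return n;
}

static Rcpp::List net_to_list(const Net& n) {
  Rcpp::List cw(n.W.size()), cb(n.b.size());
  for (size_t i = 0; i < n.W.size(); ++i) {
    cw[i] = Rcpp::wrap(n.W[i]);
    cb[i] = Rcpp::wrap(n.b[i]);
  }
  return Rcpp::List::create(
      Rcpp::Named("conv_w") = cw, Rcpp::Named("conv_b") = cb,
      Rcpp::Named("dense_w1") = Rcpp::wrap(n.Wd1),
      Rcpp::Named("dense_b1") = Rcpp::wrap(n.bd1),
      Rcpp::Named("dense_w2") = Rcpp::wrap(n.Wd2),
      Rcpp::Named("dense_b2") = Rcpp::wrap(n.bd2));
}

// 3x3 same-padding patch matrix: (9*C x H*W), spatial index q = w*H + h.
static mat im2col3(const cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  mat P(9 * C, H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int r = c * 9 + (dy + 1) * 3 + (dx + 1);
        for (int w = 0; w < W; ++w) {
          const int sw = w + dx;
          if (sw < 0 || sw >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int sh = h + dy;
            if (sh < 0 || sh >= H) continue;
            P(r, w * H + h) = X(sh, sw, c);
          }
        }
      }
  return P;
}

static void col2im3_add(const mat& dP, cube& dX) {
  const int H = dX.n_rows, W = dX.n_cols, C = dX.n_slices;
  for (int c = 0; c < C; ++c)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int r = c * 9 + (dy + 1) * 3 + (dx + 1);
        for (int w = 0; w < W; ++w) {
          const int sw = w + dx;
          if (sw < 0 || sw >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int sh = h + dy;
            if (sh < 0 || sh >= H) continue;
            dX(sh, sw, c) += dP(r, w * H + h);
          }
        }
      }
}

struct BlockCache {
  mat P;        // im2col of the block input
  mat Z;        // post-ReLU activations (Cout x H*W)
  arma::umat relu;  // ReLU mask
  uvec argmax;  // flat input index feeding each pooled output
  int H, W, H2, W2, Cout;
  cube out;     // pooled output (H2 x W2 x Cout)
};

static void block_forward(const Net& net, size_t blk, const cube& X,
                          BlockCache& cc) {
  const int H = X.n_rows, W = X.n_cols;
  const int Cout = net.W[blk].n_rows;
  cc.H = H; cc.W = W; cc.Cout = Cout;
  cc.P = im2col3(X);
  mat Z = net.W[blk] * cc.P;
  Z.each_col() += net.b[blk];
  cc.relu = Z > 0.0;
  Z.elem(arma::find(Z < 0.0)).zeros();
  cc.Z = Z;
  const int H2 = H / 2, W2 = W / 2;
  cc.H2 = H2; cc.W2 = W2;
  cc.out.set_size(H2, W2, Cout);
  cc.argmax.set_size((uword)H2 * W2 * Cout);
  for (int c = 0; c < Cout; ++c)
    for (int w2 = 0; w2 < W2; ++w2)
      for (int h2 = 0; h2 < H2; ++h2) {
        double best = -arma::datum::inf;
        int besti = 0;
        for (int dw = 0; dw < 2; ++dw)
          for (int dh = 0; dh < 2; ++dh) {
            const int q = (2 * w2 + dw) * H + (2 * h2 + dh);
            const double v = Z(c, q);
            if (v > best) { best = v; besti = q; }
          }
        cc.out(h2, w2, c) = best;
        cc.argmax((uword)c * H2 * W2 + (uword)w2 * H2 + h2) = besti;
      }
}

// Returns the input gradient cube; accumulates parameter grads into gW/gb.
static cube block_backward(const Net& net, size_t blk, const BlockCache& cc,
                           const cube& dOut, mat& gW, vec& gb, int Cin) {
  mat dZ(cc.Cout, cc.H * cc.W, arma::fill::zeros);
  for (int c = 0; c < cc.Cout; ++c)
    for (int w2 = 0; w2 < cc.W2; ++w2)
      for (int h2 = 0; h2 < cc.H2; ++h2) {
        const uword q = cc.argmax((uword)c * cc.H2 * cc.W2 +
                                  (uword)w2 * cc.H2 + h2);
        dZ(c, q) += dOut(h2, w2, c);
      }
  dZ %= arma::conv_to<mat>::from(cc.relu);
  gW += dZ * cc.P.t();
  gb += arma::sum(dZ, 1);
  mat dP = net.W[blk].t() * dZ;
  cube dX(cc.H, cc.W, Cin, arma::fill::zeros);
  col2im3_add(dP, dX);
  return dX;
}

// Forward pass for one image; caches are only filled when train = true.
static double net_forward(const Net& net, const cube& X, int head,
                          std::vector<BlockCache>& caches, vec& gvec,
                          vec& z1, vec& a1, bool train) {
  const size_t nb = net.W.size();
  caches.resize(nb);
  cube cur = X;
  for (size_t b = 0; b < nb; ++b) {
    block_forward(net, b, cur, caches[b]);
    cur = caches[b].out;
  }
  const int C = cur.n_slices;
  gvec.set_size(C);
  for (int c = 0; c < C; ++c) gvec(c) = arma::accu(cur.slice(c)) /
                                        (cur.n_rows * cur.n_cols);
  z1 = net.Wd1 * gvec + net.bd1;
  a1 = z1;
  a1.elem(arma::find(a1 < 0.0)).zeros();
  double z = arma::as_scalar(net.Wd2 * a1) + net.bd2(0);
  if (head == 0) z = 1.0 / (1.0 + std::exp(-z));
  if (!train) { caches.clear(); }
  return z;
}

struct Grads {
  std::vector<mat> W;
  std::vector<vec> b;
  mat Wd1; vec bd1; mat Wd2; vec bd2;
  void zero_like(const Net& n) {
    W.clear(); b.clear();
    for (size_t i = 0; i < n.W.size(); ++i) {
      W.push_back(mat(arma::size(n.W[i]), arma::fill::zeros));
      b.push_back(vec(n.b[i].n_elem, arma::fill::zeros));
    }
    Wd1 = mat(arma::size(n.Wd1), arma::fill::zeros);
    bd1 = vec(n.bd1.n_elem, arma::fill::zeros);
    Wd2 = mat(arma::size(n.Wd2), arma::fill::zeros);
    bd2 = vec(1, arma::fill::zeros);
  }
};

static void adam_step(mat& w, mat& m, mat& v, const mat& g, double lr,
                      double t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  mat mh = m / (1 - std::pow(b1, t));
  mat vh = v / (1 - std::pow(b2, t));
  w -= lr * mh / (arma::sqrt(vh) + eps);
}

// [[Rcpp::export]]
Rcpp::List cnn_init_cpp(Rcpp::IntegerVector filters, int cin,
                        int dense_units) {
  Net n;
  int prev = cin;
  for (int i = 0; i < filters.size(); ++i) {
    const int cout = filters[i];
    const int fan_in = 9 * prev;
    mat W(cout, fan_in);
    for (uword k = 0; k < W.n_elem; ++k)
      W(k) = ::norm_rand() * std::sqrt(2.0 / fan_in);
    n.W.push_back(W);
    n.b.push_back(vec(cout, arma::fill::zeros));
    prev = cout;
  }
  n.Wd1.set_size(dense_units, prev);
  for (uword k = 0; k < n.Wd1.n_elem; ++k)
    n.Wd1(k) = ::norm_rand() * std::sqrt(2.0 / prev);
  n.bd1 = vec(dense_units, arma::fill::zeros);
  n.Wd2.set_size(1, dense_units);
  for (uword k = 0; k < n.Wd2.n_elem; ++k)
    n.Wd2(k) = ::norm_rand() * std::sqrt(2.0 / dense_units);
  n.bd2 = vec(1, arma::fill::zeros);
  return net_to_list(n);
}

static cube image_view(const Rcpp::NumericVector& x, int H, int W, int C,
                       int n) {
  // no-copy view into the (H, W, C, N) array
  return cube(const_cast<double*>(x.begin()) + (size_t)n * H * W * C, H, W, C,
              false, true);
}

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(Rcpp::List weights, Rcpp::NumericVector x,
                         const arma::vec& y, int epochs, double lr, int batch,
                         int head) {
  Rcpp::IntegerVector dims = x.attr("dim");
  if (dims.size() != 4) Rcpp::stop("x must be a (H, W, C, N) array");
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  if ((int)y.n_elem != N) Rcpp::stop("length(y) != number of images");
  Net net = net_from_list(weights);
  Grads g, m, v;
  m.zero_like(net);
  v.zero_like(net);
  double t = 0;
  vec loss_hist(epochs, arma::fill::zeros);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  std::vector<BlockCache> caches;
  vec gvec, z1, a1;
  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates from R's RNG: deterministic under set.seed()
    for (int i = N - 1; i > 0; --i) {
      int j = (int)std::floor(::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double epoch_loss = 0;
    for (int start = 0; start < N; start += batch) {
      const int bs = std::min(batch, N - start);
      g.zero_like(net);
      for (int kk = 0; kk < bs; ++kk) {
        const int n = order[start + kk];
        cube X = image_view(x, H, W, C, n);
        double out = net_forward(net, X, head, caches, gvec, z1, a1, true);
        double dz;
        if (head == 0) {
          double p = std::min(std::max(out, 1e-12), 1 - 1e-12);
          epoch_loss += -(y(n) * std::log(p) + (1 - y(n)) * std::log(1 - p));
          dz = out - y(n);
        } else {
          epoch_loss += (out - y(n)) * (out - y(n));
          dz = 2 * (out - y(n));
        }
        g.Wd2 += dz * a1.t();
        g.bd2(0) += dz;
        vec da1 = net.Wd2.t() * dz;
        vec dz1 = da1;
        dz1.elem(arma::find(z1 <= 0.0)).zeros();
        g.Wd1 += dz1 * gvec.t();
        g.bd1 += dz1;
        vec dg = net.Wd1.t() * dz1;
        const BlockCache& last = caches.back();
        cube dOut(last.H2, last.W2, last.Cout);
        for (int c = 0; c < last.Cout; ++c)
          dOut.slice(c).fill(dg(c) / (last.H2 * last.W2));
        for (int b = (int)net.W.size() - 1; b >= 0; --b) {
          const int cin = b == 0 ? C : (int)net.W[b - 1].n_rows;
          cube dX = block_backward(net, b, caches[b], dOut, g.W[b], g.b[b],
                                   cin);
          dOut = dX;
        }
      }
      t += 1;
      const double sc = 1.0 / bs;
      for (size_t i = 0; i < net.W.size(); ++i)
        adam_step(net.W[i], m.W[i], v.W[i], g.W[i] * sc, lr, t);
      // biases via the same rule (vectors wrapped as 1-col matrices)
      for (size_t i = 0; i < net.W.size(); ++i) {
        mat bw(net.b[i]), bm(m.b[i]), bv(v.b[i]), bg(g.b[i] * sc);
        adam_step(bw, bm, bv, bg, lr, t);
        net.b[i] = bw.col(0); m.b[i] = bm.col(0); v.b[i] = bv.col(0);
      }
      adam_step(net.Wd1, m.Wd1, v.Wd1, g.Wd1 * sc, lr, t);
      {
        mat bw(net.bd1), bm(m.bd1), bv(v.bd1), bg(g.bd1 * sc);
        adam_step(bw, bm, bv, bg, lr, t);
        net.bd1 = bw.col(0); m.bd1 = bm.col(0); v.bd1 = bv.col(0);
      }
      adam_step(net.Wd2, m.Wd2, v.Wd2, g.Wd2 * sc, lr, t);
      {
        mat bw(net.bd2), bm(m.bd2), bv(v.bd2), bg(g.bd2 * sc);
        adam_step(bw, bm, bv, bg, lr, t);
        net.bd2 = bw.col(0); m.bd2 = bm.col(0); v.bd2 = bv.col(0);
      }
      Rcpp::checkUserInterrupt();
    }
    loss_hist(ep) = epoch_loss / N;
  }
  return Rcpp::List::create(Rcpp::Named("weights") = net_to_list(net),
                            Rcpp::Named("loss") = Rcpp::wrap(loss_hist));
}

// [[Rcpp::export]]
arma::vec cnn_predict_cpp(Rcpp::List weights, Rcpp::NumericVector x,
                          int head) {
  Rcpp::IntegerVector dims = x.attr("dim");
  if (dims.size() != 4) Rcpp::stop("x must be a (H, W, C, N) array");
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  Net net = net_from_list(weights);
  vec out(N);
  std::vector<BlockCache> caches;
  vec gvec, z1, a1;
  for (int n = 0; n < N; ++n) {
    cube X = image_view(x, H, W, C, n);
    out(n) = net_forward(net, X, head, caches, gvec, z1, a1, false);
  }
  return out;
}

// [[Rcpp::export]]
double cnn_n_parameters_cpp(Rcpp::List weights) {
  Net net = net_from_list(weights);
  double n = 0;
  for (size_t i = 0; i < net.W.size(); ++i)
    n += net.W[i].n_elem + net.b[i].n_elem;
  n += net.Wd1.n_elem + net.bd1.n_elem + net.Wd2.n_elem + net.bd2.n_elem;
  return n;
}
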