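// Compiled core of the eight-layer picking network.
//
// Everything here is plain, explicitly-indexed arithmetic: valid
// cross-correlation, non-overlapping block averaging, the fully connected
// scoring head, and the exact reverse-mode gradients of the half-mean-squared
// error.  No autodiff, no BLAS convolution tricks; the test suite holds these
// routines against brute-force R oracles and central finite differences.
//
// Conventions shared with the R side:
//  * matrices are column-major, indexed (row, col) 0-based in C++;
//  * a 4-d kernel array has dim (k, k, n_in, n_out);
//  * the flattened feature vector entering the output layer is the
//    column-major flatten of the (side, side, n_maps) activation array;
//  * "convolution" means cross-correlation (no kernel flip).

#include <RcppArmadillo.h>
#include <map>
#include <utility>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;

static const int ACT_SIGMOID = 0;
static const int ACT_RELU = 1;

static inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static inline void apply_act(mat& m, int act) {
  if (act == ACT_SIGMOID) {
    m.transform([](double x) { return sigm(x); });
  } else {
    m.transform([](double x) { return x > 0.0 ? x : 0.0; });
  }
}

// valid cross-correlation: out(i,j) = sum_{a,b} X(i+a, j+b) K(a,b)
static mat conv_valid(const mat& X, const mat& K) {
  const int k = K.n_rows;
  const int R = X.n_rows - k + 1, C = X.n_cols - k + 1;
  mat out(R, C);
  for (int j = 0; j < C; ++j) {
    for (int i = 0; i < R; ++i) {
      double acc = 0.0;
      for (int b = 0; b < k; ++b) {
        const double* xcol = X.colptr(j + b) + i;
        const double* kcol = K.colptr(b);
        for (int a = 0; a < k; ++a) acc += xcol[a] * kcol[a];
      }
      out.at(i, j) = acc;
    }
  }
  return out;
}

// gradient of a shared kernel: gW(a,b) = sum_{i,j} X(i+a, j+b) dY(i,j)
static mat conv_grad_kernel(const mat& X, const mat& dY, int k) {
  const int R = dY.n_rows, C = dY.n_cols;
  mat g(k, k);
  for (int b = 0; b < k; ++b)
    for (int a = 0; a < k; ++a)
      g.at(a, b) = arma::accu(X.submat(a, b, a + R - 1, b + C - 1) % dY);
  return g;
}

// accumulate gradient w.r.t. the convolution input
static void conv_backward_input(mat& dX, const mat& dY, const mat& K) {
  const int k = K.n_rows;
  const int R = dY.n_rows, C = dY.n_cols;
  for (int b = 0; b < k; ++b)
    for (int a = 0; a < k; ++a)
      dX.submat(a, b, a + R - 1, b + C - 1) += K.at(a, b) * dY;
}

// non-overlapping block average with a (pr, pc) phase offset
static mat pool_avg_phase(const mat& X, int qr, int qc, int pr, int pc) {
  const int R = (X.n_rows - pr) / qr, C = (X.n_cols - pc) / qc;
  mat out(R, C);
  const double f = 1.0 / (double(qr) * double(qc));
  for (int j = 0; j < C; ++j)
    for (int i = 0; i < R; ++i) {
      double acc = 0.0;
      for (int b = 0; b < qc; ++b)
        for (int a = 0; a < qr; ++a)
          acc += X.at(pr + i * qr + a, pc + j * qc + b);
      out.at(i, j) = acc * f;
    }
  return out;
}

// gradient through an average pool: spread uniformly with factor 1/(q*q)
static mat pool_backward(const mat& dP, int q) {
  mat dX(dP.n_rows * q, dP.n_cols * q);
  const double f = 1.0 / (double(q) * double(q));
  for (arma::uword j = 0; j < dP.n_cols; ++j)
    for (arma::uword i = 0; i < dP.n_rows; ++i)
      dX.submat(i * q, j * q, i * q + q - 1, j * q + q - 1).fill(dP.at(i, j) * f);
  return dX;
}

// ---------------------------------------------------------------------------
// parameter container

struct Net {
  int box, k1, k3, k5, q2, q4, q6;
  int n1, n3, n5;
  int s1, s2, s3, s4, s5, s6;
  int act;                       // hidden-layer activation
  std::vector<mat> W1, W3, W5;   // W3[i + n_in * j] etc.
  vec b1, b3, b5;
  vec wout;
  double bout;
};

static std::vector<mat> unpack_kernels(const NumericVector& W, int& k, int& nin,
                                       int& nout) {
  IntegerVector d = W.attr("dim");
  k = d[0];
  nin = d[2];
  nout = d[3];
  std::vector<mat> out;
  out.reserve(nin * nout);
  const double* p = W.begin();
  for (int j = 0; j < nout; ++j)
    for (int i = 0; i < nin; ++i) {
      // column-major slab (k x k) at offset (i + nin*j) * k * k
      out.push_back(mat(const_cast<double*>(p) + (std::size_t)(j * nin + i) * k * k,
                        k, k, /*copy*/ true));
    }
  // reorder to [i + nin * j]
  std::vector<mat> ordered(nin * nout);
  std::size_t idx = 0;
  for (int j = 0; j < nout; ++j)
    for (int i = 0; i < nin; ++i) ordered[i + nin * j] = out[idx++];
  return ordered;
}

static Net parse_net(const List& params, int box_side, const IntegerVector& pools,
                     int act) {
  Net n;
  n.box = box_side;
  n.q2 = pools[0];
  n.q4 = pools[1];
  n.q6 = pools[2];
  n.act = act;
  List conv = params["conv"];
  List c1 = conv[0], c3 = conv[1], c5 = conv[2];
  int nin;
  n.W1 = unpack_kernels(c1["W"], n.k1, nin, n.n1);
  n.b1 = as<vec>(c1["b"]);
  n.W3 = unpack_kernels(c3["W"], n.k3, nin, n.n3);
  n.b3 = as<vec>(c3["b"]);
  n.W5 = unpack_kernels(c5["W"], n.k5, nin, n.n5);
  n.b5 = as<vec>(c5["b"]);
  List out = params["out"];
  n.wout = as<vec>(out["w"]);
  n.bout = as<double>(out["b"]);
  n.s1 = n.box - n.k1 + 1;
  n.s2 = n.s1 / n.q2;
  n.s3 = n.s2 - n.k3 + 1;
  n.s4 = n.s3 / n.q4;
  n.s5 = n.s4 - n.k5 + 1;
  n.s6 = n.s5 / n.q6;
  if ((int)n.wout.n_elem != n.n5 * n.s6 * n.s6)
    stop("output weight length does not match the layer schedule");
  return n;
}

// ---------------------------------------------------------------------------
// single-box forward pass with cached activations (for backprop)

struct Cache {
  std::vector<mat> A1, P2, A3, P4, A5, P6;
  vec flat;
  double pre_out, y;
};

static double forward_box(const mat& X0, const Net& net, Cache* cache) {
  std::vector<mat> A1(net.n1), P2(net.n1);
  for (int j = 0; j < net.n1; ++j) {
    mat a = conv_valid(X0, net.W1[j]);
    a += net.b1[j];
    apply_act(a, net.act);
    P2[j] = pool_avg_phase(a, net.q2, net.q2, 0, 0);
    A1[j] = std::move(a);
  }
  std::vector<mat> A3(net.n3), P4(net.n3);
  for (int j = 0; j < net.n3; ++j) {
    mat a(net.s3, net.s3, arma::fill::value(net.b3[j]));
    for (int i = 0; i < net.n1; ++i) a += conv_valid(P2[i], net.W3[i + net.n1 * j]);
    apply_act(a, net.act);
    P4[j] = pool_avg_phase(a, net.q4, net.q4, 0, 0);
    A3[j] = std::move(a);
  }
  std::vector<mat> A5(net.n5), P6(net.n5);
  for (int j = 0; j < net.n5; ++j) {
    mat a(net.s5, net.s5, arma::fill::value(net.b5[j]));
    for (int i = 0; i < net.n3; ++i) a += conv_valid(P4[i], net.W5[i + net.n3 * j]);
    apply_act(a, net.act);
    P6[j] = pool_avg_phase(a, net.q6, net.q6, 0, 0);
    A5[j] = std::move(a);
  }
  vec flat(net.n5 * net.s6 * net.s6);
  std::size_t idx = 0;
  for (int m = 0; m < net.n5; ++m)
    for (int c = 0; c < net.s6; ++c)
      for (int r = 0; r < net.s6; ++r) flat[idx++] = P6[m].at(r, c);
  double pre = arma::dot(flat, net.wout) + net.bout;
  double y = sigm(pre);  // the scoring head is always sigmoid
  if (cache) {
    cache->A1 = std::move(A1);
    cache->P2 = std::move(P2);
    cache->A3 = std::move(A3);
    cache->P4 = std::move(P4);
    cache->A5 = std::move(A5);
    cache->P6 = std::move(P6);
    cache->flat = std::move(flat);
    cache->pre_out = pre;
    cache->y = y;
  }
  return y;
}

// derivative of the hidden activation expressed through the activation value
static mat act_deriv(const mat& A, int act) {
  if (act == ACT_SIGMOID) return A % (1.0 - A);
  mat d(A.n_rows, A.n_cols);
  for (arma::uword i = 0; i < A.n_elem; ++i) d(i) = A(i) > 0.0 ? 1.0 : 0.0;
  return d;
}

// [[Rcpp::export]]
NumericMatrix cpp_conv_valid(NumericMatrix X, NumericMatrix K) {
  mat x = as<mat>(X), k = as<mat>(K);
  return wrap(conv_valid(x, k));
}

// [[Rcpp::export]]
NumericMatrix cpp_pool_avg(NumericMatrix X, int qr, int qc) {
  mat x = as<mat>(X);
  return wrap(pool_avg_phase(x, qr, qc, 0, 0));
}

// [[Rcpp::export]]
NumericVector cpp_forward_batch(NumericVector boxes, List params, int box_side,
                                IntegerVector pools, int act) {
  IntegerVector d = boxes.attr("dim");
  const int b = d[0], nbox = d[2];
  Net net = parse_net(params, box_side, pools, act);
  NumericVector scores(nbox);
  const double* p = boxes.begin();
  for (int n = 0; n < nbox; ++n) {
    mat X0(const_cast<double*>(p) + (std::size_t)n * b * b, b, b, true);
    scores[n] = forward_box(X0, net, nullptr);
  }
  return scores;
}

// gradients of E = 1/(2N) sum (t_n - y_n)^2 over the whole batch
// [[Rcpp::export]]
List cpp_backprop_batch(NumericVector boxes, NumericVector targets, List params,
                        int box_side, IntegerVector pools, int act) {
  IntegerVector d = boxes.attr("dim");
  const int b = d[0], nbox = d[2];
  Net net = parse_net(params, box_side, pools, act);

  std::vector<mat> gW1(net.n1, mat(net.k1, net.k1, arma::fill::zeros));
  std::vector<mat> gW3(net.n1 * net.n3, mat(net.k3, net.k3, arma::fill::zeros));
  std::vector<mat> gW5(net.n3 * net.n5, mat(net.k5, net.k5, arma::fill::zeros));
  vec gb1(net.n1, arma::fill::zeros), gb3(net.n3, arma::fill::zeros),
      gb5(net.n5, arma::fill::zeros);
  vec gwout(net.wout.n_elem, arma::fill::zeros);
  double gbout = 0.0;
  NumericVector scores(nbox);

  const double* p = boxes.begin();
  for (int n = 0; n < nbox; ++n) {
    mat X0(const_cast<double*>(p) + (std::size_t)n * b * b, b, b, true);
    Cache c;
    forward_box(X0, net, &c);
    scores[n] = c.y;
    // dE/dy for this sample, batch-mean convention
    const double dy = (c.y - targets[n]) / double(nbox);
    const double dpre = dy * c.y * (1.0 - c.y);
    gwout += dpre * c.flat;
    gbout += dpre;
    // back into the S6 maps
    std::vector<mat> dP6(net.n5);
    std::size_t idx = 0;
    for (int m = 0; m < net.n5; ++m) {
      mat dm(net.s6, net.s6);
      for (int cc = 0; cc < net.s6; ++cc)
        for (int r = 0; r < net.s6; ++r) dm.at(r, cc) = net.wout[idx++] * dpre;
      dP6[m] = std::move(dm);
    }
    // S6 -> C5
    std::vector<mat> dpre5(net.n5);
    for (int j = 0; j < net.n5; ++j)
      dpre5[j] = pool_backward(dP6[j], net.q6) % act_deriv(c.A5[j], net.act);
    std::vector<mat> dP4(net.n3, mat(net.s4, net.s4, arma::fill::zeros));
    for (int j = 0; j < net.n5; ++j) {
      gb5[j] += arma::accu(dpre5[j]);
      for (int i = 0; i < net.n3; ++i) {
        gW5[i + net.n3 * j] += conv_grad_kernel(c.P4[i], dpre5[j], net.k5);
        conv_backward_input(dP4[i], dpre5[j], net.W5[i + net.n3 * j]);
      }
    }
    // S4 -> C3
    std::vector<mat> dpre3(net.n3);
    for (int j = 0; j < net.n3; ++j)
      dpre3[j] = pool_backward(dP4[j], net.q4) % act_deriv(c.A3[j], net.act);
    std::vector<mat> dP2(net.n1, mat(net.s2, net.s2, arma::fill::zeros));
    for (int j = 0; j < net.n3; ++j) {
      gb3[j] += arma::accu(dpre3[j]);
      for (int i = 0; i < net.n1; ++i) {
        gW3[i + net.n1 * j] += conv_grad_kernel(c.P2[i], dpre3[j], net.k3);
        conv_backward_input(dP2[i], dpre3[j], net.W3[i + net.n1 * j]);
      }
    }
    // S2 -> C1
    for (int j = 0; j < net.n1; ++j) {
      mat dpre1 = pool_backward(dP2[j], net.q2) % act_deriv(c.A1[j], net.act);
      gb1[j] += arma::accu(dpre1);
      gW1[j] += conv_grad_kernel(X0, dpre1, net.k1);
    }
  }

  auto pack = [](const std::vector<mat>& g, int k, int nin, int nout) {
    NumericVector out((std::size_t)k * k * nin * nout);
    out.attr("dim") = IntegerVector::create(k, k, nin, nout);
    double* q = out.begin();
    for (int j = 0; j < nout; ++j)
      for (int i = 0; i < nin; ++i) {
        const mat& m = g[i + nin * j];
        std::copy(m.begin(), m.end(), q + (std::size_t)(j * nin + i) * k * k);
      }
    return out;
  };

  auto as_plain = [](const vec& v) {
    return NumericVector(v.begin(), v.end());  // no dim attribute
  };
  List conv = List::create(
      List::create(_["W"] = pack(gW1, net.k1, 1, net.n1), _["b"] = as_plain(gb1)),
      List::create(_["W"] = pack(gW3, net.k3, net.n1, net.n3), _["b"] = as_plain(gb3)),
      List::create(_["W"] = pack(gW5, net.k5, net.n3, net.n5), _["b"] = as_plain(gb5)));
  return List::create(_["conv"] = conv,
                      _["out"] = List::create(_["w"] = as_plain(gwout), _["b"] = gbout),
                      _["scores"] = scores);
}

// ---------------------------------------------------------------------------
// raster scan
//
// Shared (fully convolutional) path: because every layer is translation
// covariant, the first convolution is computed once over the whole micrograph;
// pooling alignment splits scan positions into residue classes modulo the
// cumulative pooling factor, and deeper layers are computed once per class.
// Arithmetic is identical to boxing out each window and running the network.

typedef std::map<std::pair<int, int>, std::vector<mat> > PhaseCache;

// [[Rcpp::export]]
NumericMatrix cpp_scan_shared(NumericMatrix micro, List params, int box_side,
                              IntegerVector pools, int act, int stride) {
  mat M = as<mat>(micro);
  Net net = parse_net(params, box_side, pools, act);
  const int H = M.n_rows, W = M.n_cols;
  const int ny = (H - net.box) / stride + 1, nx = (W - net.box) / stride + 1;
  const int F2 = net.q2, F4 = net.q2 * net.q4, F6 = net.q2 * net.q4 * net.q6;

  // full first convolutional layer
  std::vector<mat> A1(net.n1);
  for (int j = 0; j < net.n1; ++j) {
    mat a = conv_valid(M, net.W1[j]);
    a += net.b1[j];
    apply_act(a, net.act);
    A1[j] = std::move(a);
  }

  PhaseCache lvl2, lvl4, lvl6;  // keyed by (row, col) residues mod F2 / F4 / F6

  // residues are enumerated from the actual scan positions
  auto get_lvl2 = [&](int ry, int rx) -> const std::vector<mat>& {
    auto key = std::make_pair(ry, rx);
    auto it = lvl2.find(key);
    if (it != lvl2.end()) return it->second;
    std::vector<mat> P2(net.n1);
    for (int i = 0; i < net.n1; ++i)
      P2[i] = pool_avg_phase(A1[i], net.q2, net.q2, ry, rx);
    std::vector<mat> A3(net.n3);
    for (int j = 0; j < net.n3; ++j) {
      mat a(P2[0].n_rows - net.k3 + 1, P2[0].n_cols - net.k3 + 1,
            arma::fill::value(net.b3[j]));
      for (int i = 0; i < net.n1; ++i) a += conv_valid(P2[i], net.W3[i + net.n1 * j]);
      apply_act(a, net.act);
      A3[j] = std::move(a);
    }
    return lvl2.emplace(key, std::move(A3)).first->second;
  };

  auto get_lvl4 = [&](int ry, int rx) -> const std::vector<mat>& {
    auto key = std::make_pair(ry, rx);
    auto it = lvl4.find(key);
    if (it != lvl4.end()) return it->second;
    const int p2y = ry % net.q2, p2x = rx % net.q2;
    const std::vector<mat>& A3 = get_lvl2(p2y, p2x);
    const int p4y = ((ry - p2y) / net.q2) % net.q4;
    const int p4x = ((rx - p2x) / net.q2) % net.q4;
    std::vector<mat> P4(net.n3);
    for (int i = 0; i < net.n3; ++i)
      P4[i] = pool_avg_phase(A3[i], net.q4, net.q4, p4y, p4x);
    std::vector<mat> A5(net.n5);
    for (int j = 0; j < net.n5; ++j) {
      mat a(P4[0].n_rows - net.k5 + 1, P4[0].n_cols - net.k5 + 1,
            arma::fill::value(net.b5[j]));
      for (int i = 0; i < net.n3; ++i) a += conv_valid(P4[i], net.W5[i + net.n3 * j]);
      apply_act(a, net.act);
      A5[j] = std::move(a);
    }
    return lvl4.emplace(key, std::move(A5)).first->second;
  };

  auto get_lvl6 = [&](int ry, int rx) -> const std::vector<mat>& {
    auto key = std::make_pair(ry, rx);
    auto it = lvl6.find(key);
    if (it != lvl6.end()) return it->second;
    const int r4y = ry % F4, r4x = rx % F4;
    const std::vector<mat>& A5 = get_lvl4(r4y, r4x);
    const int p2y = ry % net.q2, p2x = rx % net.q2;
    const int p4y = ((ry - p2y) / net.q2) % net.q4;
    const int p4x = ((rx - p2x) / net.q2) % net.q4;
    const int p6y = (((ry - p2y) / net.q2 - p4y) / net.q4) % net.q6;
    const int p6x = (((rx - p2x) / net.q2 - p4x) / net.q4) % net.q6;
    std::vector<mat> P6(net.n5);
    for (int i = 0; i < net.n5; ++i)
      P6[i] = pool_avg_phase(A5[i], net.q6, net.q6, p6y, p6x);
    return lvl6.emplace(key, std::move(P6)).first->second;
  };

  NumericMatrix out(ny, nx);
  const int nfeat = net.s6 * net.s6;
  for (int iy = 0; iy < ny; ++iy) {
    const int y = iy * stride;
    const int ry = y % F6;
    const int p2y = ry % net.q2;
    const int p4y = ((ry - p2y) / net.q2) % net.q4;
    const int p6y = (((ry - p2y) / net.q2 - p4y) / net.q4) % net.q6;
    const int u6y = (((y - p2y) / net.q2 - p4y) / net.q4 - p6y) / net.q6;
    for (int ix = 0; ix < nx; ++ix) {
      const int x = ix * stride;
      const int rx = x % F6;
      const int p2x = rx % net.q2;
      const int p4x = ((rx - p2x) / net.q2) % net.q4;
      const int p6x = (((rx - p2x) / net.q2 - p4x) / net.q4) % net.q6;
      const int u6x = (((x - p2x) / net.q2 - p4x) / net.q4 - p6x) / net.q6;
      const std::vector<mat>& P6 = get_lvl6(ry, rx);
      double pre = net.bout;
      std::size_t idx = 0;
      for (int m = 0; m < net.n5; ++m)
        for (int c = 0; c < net.s6; ++c)
          for (int r = 0; r < net.s6; ++r)
            pre += P6[m].at(u6y + r, u6x + c) * net.wout[idx++];
      out(iy, ix) = sigm(pre);
    }
  }
  return out;
}

// clockwise quarter turn: out(i, j) = in(H - 1 - j, i)
static mat rot90cw(const mat& X) {
  mat out(X.n_cols, X.n_rows);
  for (arma::uword j = 0; j < out.n_cols; ++j)
    for (arma::uword i = 0; i < out.n_rows; ++i)
      out.at(i, j) = X.at(X.n_rows - 1 - j, i);
  return out;
}

// per-box scan; optional four-fold rotation averaging inside
// [[Rcpp::export]]
NumericMatrix cpp_scan_naive(NumericMatrix micro, List params, int box_side,
                             IntegerVector pools, int act, int stride,
                             bool rotate_average) {
  mat M = as<mat>(micro);
  Net net = parse_net(params, box_side, pools, act);
  const int H = M.n_rows, W = M.n_cols;
  const int ny = (H - net.box) / stride + 1, nx = (W - net.box) / stride + 1;
  NumericMatrix out(ny, nx);
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      mat box = M.submat(iy * stride, ix * stride, iy * stride + net.box - 1,
                         ix * stride + net.box - 1);
      double s = forward_box(box, net, nullptr);
      if (rotate_average) {
        mat b = box;
        for (int r = 0; r < 3; ++r) {
          b = rot90cw(b);
          s += forward_box(b, net, nullptr);
        }
        s /= 4.0;
      }
      out(iy, ix) = s;
    }
  return out;
}

// strict local maxima within a Chebyshev radius (in grid cells); score ties are
// broken by raster order (row-major, top-left first): the earlier position wins
// [[Rcpp::export]]
LogicalMatrix cpp_local_maxima(NumericMatrix S, int rad) {
  const int ny = S.nrow(), nx = S.ncol();
  LogicalMatrix keep(ny, nx);
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      const double s = S(iy, ix);
      bool ok = true;
      for (int dy = -rad; dy <= rad && ok; ++dy) {
        const int jy = iy + dy;
        if (jy < 0 || jy >= ny) continue;
        for (int dx = -rad; dx <= rad; ++dx) {
          const int jx = ix + dx;
          if (jx < 0 || jx >= nx || (dy == 0 && dx == 0)) continue;
          const double t = S(jy, jx);
          const bool earlier = (jy < iy) || (jy == iy && jx < ix);
          if (t > s || (t == s && earlier)) { ok = false; break; }
        }
      }
      keep(iy, ix) = ok;
    }
  return keep;
}
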