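// Compact add-skip encoder-decoder for single-frame hologram inversion.
//
// Activations are stored channels-first as C x n matrices with
// n = batch * H * W and column index b*H*W + i*W + j, so im2col and the
// scatter/gather steps are contiguous column copies. All layers carry
// their own Adam state; the whole engine is single-threaded and
// deterministic given the creation seed.

#include <RcppArmadillo.h>
#include <map>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Adam {
  mat mW, vW;
  void init(const mat& W) {
    mW.zeros(W.n_rows, W.n_cols);
    vW.zeros(W.n_rows, W.n_cols);
  }
  void step(mat& W, const mat& g, double lr, long t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    mW = b1 * mW + (1 - b1) * g;
    vW = b2 * vW + (1 - b2) * square(g);
    double c1 = 1 - std::pow(b1, (double)t);
    double c2 = 1 - std::pow(b2, (double)t);
    W -= lr * (mW / c1) / (sqrt(vW / c2) + eps);
  }
};

// spatial neighbor table for 3x3 im2col at one resolution: for tap t and
// pixel p, nb[t*HW + p] = source pixel or -1 (zero padding)
struct Res {
  int H = 0, W = 0;
  ivec nb;        // 9*HW
  ivec pool;      // 4*HWo : the 4 source pixels of each pooled pixel
  ivec up;        // 4*HW  : destination pixel of tap t from source p (2x upsampling)
};

Res make_res(int H, int W) {
  Res r; r.H = H; r.W = W;
  int HW = H * W;
  r.nb.set_size(9 * HW);
  for (int t = 0; t < 9; ++t) {
    int di = t / 3 - 1, dj = t % 3 - 1;
    for (int i = 0; i < H; ++i) for (int j = 0; j < W; ++j) {
      int ii = i + di, jj = j + dj;
      r.nb[t * HW + i * W + j] =
        (ii < 0 || ii >= H || jj < 0 || jj >= W) ? -1 : ii * W + jj;
    }
  }
  int Ho = H / 2, Wo = W / 2, HWo = Ho * Wo;
  r.pool.set_size(4 * HWo);
  for (int i = 0; i < Ho; ++i) for (int j = 0; j < Wo; ++j) {
    int p = i * Wo + j;
    for (int t = 0; t < 4; ++t) {
      int di = t / 2, dj = t % 2;
      r.pool[t * HWo + p] = (2 * i + di) * W + (2 * j + dj);
    }
  }
  r.up.set_size(4 * HW);  // source resolution H x W -> destination 2H x 2W
  for (int i = 0; i < H; ++i) for (int j = 0; j < W; ++j) {
    int p = i * W + j;
    for (int t = 0; t < 4; ++t) {
      int di = t / 2, dj = t % 2;
      r.up[t * HW + p] = (2 * i + di) * (2 * W) + (2 * j + dj);
    }
  }
  return r;
}

struct Conv {  // 3x3, pad 1 (kernel = 1 for the 1x1 head)
  int cin = 0, cout = 0, ksize = 9;
  mat W;       // (ksize*cin) x cout
  rowvec b;
  Adam aW, ab_;
  mat cols;    // cache: (ksize*cin) x n
  void init(int ci, int co, int ks, std::mt19937_64& rng) {
    cin = ci; cout = co; ksize = ks;
    std::normal_distribution<double> nd(0.0, std::sqrt(2.0 / (ksize * cin)));
    W.set_size(ksize * cin, cout);
    for (uword k = 0; k < W.n_elem; ++k) W[k] = nd(rng);
    b.zeros(cout);
    aW.init(W);
    mat bm(b.t()); ab_.init(bm);
  }
  long nparams() const { return (long)W.n_elem + (long)b.n_elem; }
};

struct BN {
  vec gamma, beta, rmean, rvar;
  Adam ag, ab_;
  mat xhat; vec istd;   // cache
  double momentum = 0.1, eps = 1e-5;
  void init(int c) {
    gamma.ones(c); beta.zeros(c); rmean.zeros(c); rvar.ones(c);
    mat g(gamma), b(beta);
    ag.init(g); ab_.init(b);
  }
  long nparams() const { return 2L * gamma.n_elem; }
  mat forward(const mat& x, bool train) {
    if (train) {
      vec mu = mean(x, 1);
      mat cen = x.each_col() - mu;
      vec var = mean(square(cen), 1);
      istd = 1.0 / sqrt(var + eps);
      xhat = cen.each_col() % istd;
      rmean = (1 - momentum) * rmean + momentum * mu;
      rvar = (1 - momentum) * rvar + momentum * var;
      return (xhat.each_col() % gamma).each_col() + beta;
    }
    mat xh = (x.each_col() - rmean).each_col() % (1.0 / sqrt(rvar + eps));
    return (xh.each_col() % gamma).each_col() + beta;
  }
  mat backward(const mat& dy, vec& dgamma, vec& dbeta) {
    double n = (double)dy.n_cols;
    dbeta = sum(dy, 1);
    dgamma = sum(dy % xhat, 1);
    mat dxh = dy.each_col() % gamma;
    vec s1 = sum(dxh, 1);
    vec s2 = sum(dxh % xhat, 1);
    mat dx = dxh * n;
    dx.each_col() -= s1;
    dx -= xhat.each_col() % s2;
    dx.each_col() %= istd / n;
    return dx;
  }
};

struct TConv {  // 2x2, stride 2
  int cin = 0, cout = 0;
  mat W;        // (4*cin) x cout, tap-major blocks of cin rows
  rowvec b;
  Adam aW, ab_;
  mat in_cache;
  void init(int ci, int co, std::mt19937_64& rng) {
    cin = ci; cout = co;
    std::normal_distribution<double> nd(0.0, std::sqrt(2.0 / (4.0 * cin)));
    W.set_size(4 * cin, cout);
    for (uword k = 0; k < W.n_elem; ++k) W[k] = nd(rng);
    b.zeros(cout);
    aW.init(W);
    mat bm(b.t()); ab_.init(bm);
  }
  long nparams() const { return (long)W.n_elem + (long)b.n_elem; }
};

struct ConvBNRelu {
  Conv conv;
  BN bn;
  mat relu_in;  // cache: pre-ReLU activations (post-BN)
};

struct UNet {
  int depth, ncv, in_ch;
  bool add_skip;
  ivec widths;          // depth entries; bottleneck = 2*widths[depth-1]
  int inH = 0, inW = 0, batch = 0;
  long adam_t = 0;
  std::mt19937_64 rng;

  std::vector<std::vector<ConvBNRelu>> enc;   // depth blocks
  std::vector<ConvBNRelu> bottom;
  std::vector<TConv> up;                      // depth (index by level)
  std::vector<std::vector<ConvBNRelu>> dec;   // depth blocks
  Conv head;
  mat head_in, sig_out, target;

  // caches
  std::map<long, Res> res_cache;
  std::vector<mat> enc_out;                   // skip features per level
  std::vector<umat> pool_idx;                 // argmax source column per pooled col
  std::vector<mat> pool_in_dims;              // unused placeholder

  Res& res(int H, int W) {
    long key = (long)H * 100000L + W;
    auto it = res_cache.find(key);
    if (it == res_cache.end()) it = res_cache.emplace(key, make_res(H, W)).first;
    return it->second;
  }
};

mat im2col(const mat& A, int HW, int B, const ivec& nb) {
  int C = A.n_rows, n = A.n_cols;
  mat cols(9 * C, n);
  for (int t = 0; t < 9; ++t) {
    const sword* src = nb.memptr() + (long)t * HW;
    for (int b = 0; b < B; ++b) {
      int off = b * HW;
      for (int p = 0; p < HW; ++p) {
        double* dst = cols.colptr(off + p) + t * C;
        long q = src[p];
        if (q < 0) std::memset(dst, 0, C * sizeof(double));
        else std::memcpy(dst, A.colptr(off + q), C * sizeof(double));
      }
    }
  }
  return cols;
}

void col2im_add(mat& dA, const mat& dcols, int HW, int B, const ivec& nb) {
  int C = dA.n_rows;
  for (int t = 0; t < 9; ++t) {
    const sword* src = nb.memptr() + (long)t * HW;
    for (int b = 0; b < B; ++b) {
      int off = b * HW;
      for (int p = 0; p < HW; ++p) {
        long q = src[p];
        if (q < 0) continue;
        double* dst = dA.colptr(off + q);
        const double* s = dcols.colptr(off + p) + t * C;
        for (int c = 0; c < C; ++c) dst[c] += s[c];
      }
    }
  }
}

mat conv_forward(Conv& cv, const mat& x, int HW, int B, Res& r) {
  if (cv.ksize == 1) {
    cv.cols = x;
  } else {
    cv.cols = im2col(x, HW, B, r.nb);
  }
  mat out = cv.W.t() * cv.cols;
  out.each_col() += vec(cv.b.t());
  return out;
}

mat conv_backward(Conv& cv, const mat& dout, int HW, int B, Res& r,
                  double lr, long t) {
  mat dW = cv.cols * dout.t();
  rowvec db = sum(dout, 1).t();
  mat dcols = cv.W * dout;
  mat dx;
  if (cv.ksize == 1) {
    dx = dcols;
  } else {
    dx.zeros(cv.cin, dout.n_cols);
    col2im_add(dx, dcols, HW, B, r.nb);
  }
  cv.aW.step(cv.W, dW, lr, t);
  mat bm(cv.b.t()), gbm(db.t());
  cv.ab_.step(bm, gbm, lr, t);
  cv.b = bm.t();
  return dx;
}

mat block_forward(std::vector<ConvBNRelu>& blk, mat x, int HW, int B, Res& r,
                  bool train) {
  for (auto& u : blk) {
    x = conv_forward(u.conv, x, HW, B, r);
    x = u.bn.forward(x, train);
    u.relu_in = x;
    x.transform([](double v) { return v > 0 ? v : 0.0; });
  }
  return x;
}

mat block_backward(std::vector<ConvBNRelu>& blk, mat d, int HW, int B, Res& r,
                   double lr, long t) {
  for (int i = (int)blk.size() - 1; i >= 0; --i) {
    auto& u = blk[i];
    d %= conv_to<mat>::from(u.relu_in > 0);
    vec dg, db;
    d = u.bn.backward(d, dg, db);
    mat gm(u.bn.gamma), bm(u.bn.beta);
    u.bn.ag.step(gm, mat(dg), lr, t);
    u.bn.ab_.step(bm, mat(db), lr, t);
    u.bn.gamma = gm; u.bn.beta = bm;
    d = conv_backward(u.conv, d, HW, B, r, lr, t);
  }
  return d;
}

// 2x2 max pooling: returns pooled matrix, records argmax source columns
mat pool_forward(const mat& x, int HW, int B, const Res& r, umat& idx) {
  int C = x.n_rows, HWo = HW / 4;
  mat out(C, (long)B * HWo);
  idx.set_size(C, (long)B * HWo);
  for (int b = 0; b < B; ++b) {
    for (int p = 0; p < HWo; ++p) {
      long oc = (long)b * HWo + p;
      double* o = out.colptr(oc);
      uword* ix = idx.colptr(oc);
      for (int c = 0; c < C; ++c) { o[c] = -datum::inf; }
      for (int t = 0; t < 4; ++t) {
        long q = (long)b * HW + r.pool[(long)t * HWo + p];
        const double* s = x.colptr(q);
        for (int c = 0; c < C; ++c) {
          if (s[c] > o[c]) { o[c] = s[c]; ix[c] = q; }
        }
      }
    }
  }
  return out;
}

mat pool_backward(const mat& dout, const umat& idx, long n_in) {
  int C = dout.n_rows;
  mat dx(C, n_in, fill::zeros);
  for (uword oc = 0; oc < dout.n_cols; ++oc) {
    const double* d = dout.colptr(oc);
    const uword* ix = idx.colptr(oc);
    for (int c = 0; c < C; ++c) dx.at(c, ix[c]) += d[c];
  }
  return dx;
}

// transposed conv 2x2 stride 2: input at H x W, output at 2H x 2W
mat tconv_forward(TConv& tc, const mat& x, int HW, int B, const Res& r) {
  tc.in_cache = x;
  int HWo = 4 * HW;
  mat out((uword)tc.cout, x.n_cols * 4);
  out.each_col() = vec(tc.b.t());
  for (int t = 0; t < 4; ++t) {
    mat P = tc.W.rows(t * tc.cin, (t + 1) * tc.cin - 1).t() * x;
    for (int b = 0; b < B; ++b) {
      for (int p = 0; p < HW; ++p) {
        long dst = (long)b * HWo + r.up[(long)t * HW + p];
        out.col(dst) += P.col((long)b * HW + p);
      }
    }
  }
  return out;
}

mat tconv_backward(TConv& tc, const mat& dout, int HW, int B, const Res& r,
                   double lr, long tstep) {
  int HWo = 4 * HW;
  mat dx((uword)tc.cin, tc.in_cache.n_cols, fill::zeros);
  mat dW(size(tc.W), fill::zeros);
  for (int t = 0; t < 4; ++t) {
    mat dP((uword)tc.cout, tc.in_cache.n_cols);
    for (int b = 0; b < B; ++b) {
      for (int p = 0; p < HW; ++p) {
        long dst = (long)b * HWo + r.up[(long)t * HW + p];
        dP.col((long)b * HW + p) = dout.col(dst);
      }
    }
    dW.rows(t * tc.cin, (t + 1) * tc.cin - 1) = tc.in_cache * dP.t();
    dx += tc.W.rows(t * tc.cin, (t + 1) * tc.cin - 1) * dP;
  }
  rowvec db = sum(dout, 1).t();
  tc.aW.step(tc.W, dW, lr, tstep);
  mat bm(tc.b.t()), gbm(db.t());
  tc.ab_.step(bm, gbm, lr, tstep);
  tc.b = bm.t();
  return dx;
}

void init_block(std::vector<ConvBNRelu>& blk, int cin, int cout, int ncv,
                std::mt19937_64& rng) {
  blk.resize(ncv);
  for (int i = 0; i < ncv; ++i) {
    blk[i].conv.init(i == 0 ? cin : cout, cout, 9, rng);
    blk[i].bn.init(cout);
  }
}

mat forward(UNet& net, const mat& x0, int B, bool train) {
  int H = net.inH, W = net.inW;
  net.batch = B;
  net.enc_out.assign(net.depth, mat());
  net.pool_idx.assign(net.depth, umat());
  mat x = x0;
  for (int l = 0; l < net.depth; ++l) {
    Res& r = net.res(H, W);
    x = block_forward(net.enc[l], x, H * W, B, r, train);
    net.enc_out[l] = x;
    x = pool_forward(x, H * W, B, r, net.pool_idx[l]);
    H /= 2; W /= 2;
  }
  x = block_forward(net.bottom, x, H * W, B, net.res(H, W), train);
  for (int l = net.depth - 1; l >= 0; --l) {
    Res& rlow = net.res(H, W);
    x = tconv_forward(net.up[l], x, H * W, B, rlow);
    H *= 2; W *= 2;
    if (net.add_skip) {
      x += net.enc_out[l];
    } else {
      x = join_cols(x, net.enc_out[l]);
    }
    x = block_forward(net.dec[l], x, H * W, B, net.res(H, W), train);
  }
  net.head_in = x;
  mat z = conv_forward(net.head, x, H * W, B, net.res(H, W));
  net.sig_out = 1.0 / (1.0 + exp(-z));
  return net.sig_out;
}

double backward(UNet& net, const mat& target, double lr) {
  net.adam_t += 1;
  long t = net.adam_t;
  int B = net.batch;
  double n = (double)net.sig_out.n_cols;
  mat diff = net.sig_out - target;
  double loss = accu(square(diff)) / n;
  // d(MSE)/dz through the sigmoid head
  mat d = (2.0 / n) * diff % net.sig_out % (1.0 - net.sig_out);
  int H = net.inH, W = net.inW;
  d = conv_backward(net.head, d, H * W, B, net.res(H, W), lr, t);
  for (int l = 0; l < net.depth; ++l) {
    d = block_backward(net.dec[l], d, H * W, B, net.res(H, W), lr, t);
    mat dskip;
    if (net.add_skip) {
      dskip = d;
    } else {
      int cu = net.up[l].cout;
      dskip = d.rows(cu, d.n_rows - 1);
      d = d.rows(0, cu - 1);
    }
    // gradient into the encoder skip is re-injected below after pooling path
    H /= 2; W /= 2;
    d = tconv_backward(net.up[l], d, H * W, B, net.res(H, W), lr, t);
    // stash skip gradient on the enc_out cache (reuse storage)
    net.enc_out[l] = dskip;
  }
  d = block_backward(net.bottom, d, H * W, B, net.res(H, W), lr, t);
  for (int l = net.depth; l-- > 0; ) {
    // actually iterate encoder from deepest to shallowest
    long n_in = (long)B * (H * 2) * (W * 2);
    d = pool_backward(d, net.pool_idx[l], n_in);
    H *= 2; W *= 2;
    d += net.enc_out[l];  // skip-connection gradient
    d = block_backward(net.enc[l], d, H * W, B, net.res(H, W), lr, t);
  }
  return loss;
}

mat cube_to_act(const cube& x) {
  int H = x.n_rows, W = x.n_cols, B = x.n_slices;
  mat A(1, (long)B * H * W);
  for (int b = 0; b < B; ++b)
    for (int i = 0; i < H; ++i)
      for (int j = 0; j < W; ++j)
        A.at(0, (long)b * H * W + (long)i * W + j) = x(i, j, b);
  return A;
}

cube act_to_cube(const mat& A, int H, int W, int B) {
  cube x(H, W, B);
  for (int b = 0; b < B; ++b)
    for (int i = 0; i < H; ++i)
      for (int j = 0; j < W; ++j)
        x(i, j, b) = A.at(0, (long)b * H * W + (long)i * W + j);
  return x;
}

}  // namespace

// [[Rcpp::export]]
SEXP unet_create(int input_rows, int input_cols, int depth,
                 Rcpp::IntegerVector widths, int convs_per_level,
                 bool add_skip, int seed) {
  if (depth < 1 || (int)widths.size() != depth)
    Rcpp::stop("widths must have one entry per level");
  if (input_rows % (1 << depth) || input_cols % (1 << depth))
    Rcpp::stop("input dimensions must be divisible by 2^depth");
  UNet* net = new UNet();
  net->depth = depth;
  net->ncv = convs_per_level;
  net->in_ch = 1;
  net->add_skip = add_skip;
  net->inH = input_rows; net->inW = input_cols;
  net->widths.set_size(depth);
  for (int l = 0; l < depth; ++l) net->widths[l] = widths[l];
  net->rng.seed((uint64_t)seed);
  int wb = 2 * widths[depth - 1];
  net->enc.resize(depth);
  net->dec.resize(depth);
  net->up.resize(depth);
  int cin = 1;
  for (int l = 0; l < depth; ++l) {
    init_block(net->enc[l], cin, widths[l], convs_per_level, net->rng);
    cin = widths[l];
  }
  init_block(net->bottom, widths[depth - 1], wb, convs_per_level, net->rng);
  for (int l = depth - 1; l >= 0; --l) {
    int from = (l == depth - 1) ? wb : widths[l + 1];
    net->up[l].init(from, widths[l], net->rng);
    int dec_in = net->add_skip ? widths[l] : 2 * widths[l];
    init_block(net->dec[l], dec_in, widths[l], convs_per_level, net->rng);
  }
  net->head.init(widths[0], 1, 1, net->rng);
  Rcpp::XPtr<UNet> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
double unet_nparams(SEXP ptr_) {
  Rcpp::XPtr<UNet> net(ptr_);
  long n = net->head.nparams();
  for (auto& blk : net->enc) for (auto& u : blk) n += u.conv.nparams() + u.bn.nparams();
  for (auto& u : net->bottom) n += u.conv.nparams() + u.bn.nparams();
  for (auto& blk : net->dec) for (auto& u : blk) n += u.conv.nparams() + u.bn.nparams();
  for (auto& tc : net->up) n += tc.nparams();
  return (double)n;
}

// [[Rcpp::export]]
double unet_train_batch(SEXP ptr_, arma::cube x, arma::cube y, double lr) {
  Rcpp::XPtr<UNet> net(ptr_);
  if ((int)x.n_rows != net->inH || (int)x.n_cols != net->inW)
    Rcpp::stop("batch spatial shape does not match the model input shape");
  mat A = cube_to_act(x);
  mat T = cube_to_act(y);
  forward(*net, A, x.n_slices, true);
  return backward(*net, T, lr);
}

// [[Rcpp::export]]
arma::cube unet_predict(SEXP ptr_, arma::cube x) {
  Rcpp::XPtr<UNet> net(ptr_);
  if ((int)x.n_rows != net->inH || (int)x.n_cols != net->inW)
    Rcpp::stop("input spatial shape does not match the model input shape");
  mat A = cube_to_act(x);
  mat out = forward(*net, A, x.n_slices, false);
  return act_to_cube(out, net->inH, net->inW, x.n_slices);
}

// [[Rcpp::export]]
double unet_eval_loss(SEXP ptr_, arma::cube x, arma::cube y) {
  Rcpp::XPtr<UNet> net(ptr_);
  mat A = cube_to_act(x);
  mat T = cube_to_act(y);
  mat out = forward(*net, A, x.n_slices, false);
  return accu(square(out - T)) / out.n_cols;
}

// [[Rcpp::export]]
Rcpp::List unet_get_params(SEXP ptr_) {
  Rcpp::XPtr<UNet> net(ptr_);
  Rcpp::List out;
  int k = 0;
  auto push = [&](const mat& m, const std::string& nm) {
    out[nm + std::to_string(k++)] = Rcpp::wrap(m);
  };
  auto push_block = [&](std::vector<ConvBNRelu>& blk, const std::string& nm) {
    for (auto& u : blk) {
      push(u.conv.W, nm + "_W"); push(mat(u.conv.b), nm + "_b");
      push(mat(u.bn.gamma), nm + "_g"); push(mat(u.bn.beta), nm + "_be");
      push(mat(u.bn.rmean), nm + "_rm"); push(mat(u.bn.rvar), nm + "_rv");
    }
  };
  for (auto& blk : net->enc) push_block(blk, "enc");
  push_block(net->bottom, "bottom");
  for (auto& tc : net->up) { push(tc.W, "up_W"); push(mat(tc.b), "up_b"); }
  for (auto& blk : net->dec) push_block(blk, "dec");
  push(net->head.W, "head_W"); push(mat(net->head.b), "head_b");
  return out;
}

// [[Rcpp::export]]
void unet_set_params(SEXP ptr_, Rcpp::List params) {
  Rcpp::XPtr<UNet> net(ptr_);
  int k = 0;
  auto pull = [&](mat& m) {
    mat v = Rcpp::as<mat>(params[k++]);
    if (v.n_rows != m.n_rows || v.n_cols != m.n_cols)
      Rcpp::stop("parameter shape mismatch at slot %d", k);
    m = v;
  };
  auto pull_vec = [&](vec& v0) { mat m(v0); pull(m); v0 = m.col(0); };
  auto pull_row = [&](rowvec& r) { mat m(r); pull(m); r = m.row(0); };
  auto pull_block = [&](std::vector<ConvBNRelu>& blk) {
    for (auto& u : blk) {
      pull(u.conv.W); pull_row(u.conv.b);
      pull_vec(u.bn.gamma); pull_vec(u.bn.beta);
      pull_vec(u.bn.rmean); pull_vec(u.bn.rvar);
    }
  };
  for (auto& blk : net->enc) pull_block(blk);
  pull_block(net->bottom);
  for (auto& tc : net->up) { pull(tc.W); pull_row(tc.b); }
  for (auto& blk : net->dec) pull_block(blk);
  pull(net->head.W); pull_row(net->head.b);
}
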