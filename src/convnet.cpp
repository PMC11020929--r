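// Small convolutional network for 84x84 digit-scene tasks.
//
// Layout conventions (fixed throughout):
//  - an image batch is an arma::fmat of size (B*H*W) x C, pixel index
//    p = r*W + c (row-major within an image), image b occupying rows
//    [b*H*W, (b+1)*H*W);
//  - convolutions are 3x3, "same" padding, realised as im2col + GEMM;
//    the im2col column index is k*C + ch with k = (dr+1)*3 + (dc+1);
//  - pooling is 2x2 average, stride 2, trailing odd row/column dropped;
//  - the flatten of a pooled map (P pixels x C channels) for image b is
//    X(b, ch*P + p) = map(b*P + p, ch).
//
// All stochastic choices (weight init, shuffling, Fisher label sampling)
// happen on the R side; this file is deterministic given its inputs.

#include <RcppArmadillo.h>
#include <cstring>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Tensor {
  fmat W, m, v;   // value and Adam moments
  long t = 0;     // per-tensor Adam step (bias correction)
};

struct ConvNet {
  int n_conv = 2;        // 2 or 3 conv layers
  int head_kind = 0;     // 0 = classification head (2-2 stack), 1 = magnitude (20 sigmoids)
  int H = 84;            // input side
  float lr = 1e-3f;
  long step = 0;         // optimizer steps taken (batches)
  std::vector<int> filters;   // f1, f2[, f3]
  int H1 = 0, H2 = 0, H3 = 0; // spatial side after each pool
  int D = 0;                  // flatten dimension
  std::vector<Tensor> T;      // conv1_W,b ; conv2_W,b ; [conv3_W,b] ; dense1_W,b ; head...
  int ihead = 0;              // index in T where head tensors begin
  std::vector<std::string> names;
};


void relu_(fmat& z) {
  float* p = z.memptr();
  const size_t n = z.n_elem;
  for (size_t i = 0; i < n; ++i) p[i] = p[i] < 0.0f ? 0.0f : p[i];
}

// grad <- grad where act > 0 else 0 (in place)
void relu_mask_(fmat& grad, const fmat& act) {
  float* g = grad.memptr();
  const float* a = act.memptr();
  const size_t n = grad.n_elem;
  for (size_t i = 0; i < n; ++i) if (a[i] <= 0.0f) g[i] = 0.0f;
}

const float ADAM_B1 = 0.9f, ADAM_B2 = 0.999f, ADAM_EPS = 1e-8f;

// ---- structural helpers -------------------------------------------------

// 3x3 same-padding im2col: in (B*H*W) x C -> col (B*H*W) x 9C.
fmat im2col3(const fmat& in, int B, int H, int W) {
  const int C = in.n_cols, HW = H * W;
  fmat col((uword)B * HW, (uword)9 * C, fill::none);
  for (int k = 0; k < 9; ++k) {
    const int dr = k / 3 - 1, dc = k % 3 - 1, s = dr * W + dc;
    for (int ch = 0; ch < C; ++ch) {
      const float* src0 = in.colptr(ch);
      float* dst0 = col.colptr((uword)k * C + ch);
      for (int b = 0; b < B; ++b) {
        const float* src = src0 + (size_t)b * HW;
        float* dst = dst0 + (size_t)b * HW;
        const int p0 = s < 0 ? -s : 0;
        const int p1 = s > 0 ? HW - s : HW;
        if (p1 > p0) std::memcpy(dst + p0, src + p0 + s, sizeof(float) * (p1 - p0));
        if (p0 > 0) std::memset(dst, 0, sizeof(float) * p0);
        if (p1 < HW) std::memset(dst + p1, 0, sizeof(float) * (HW - p1));
        if (dr == -1) std::memset(dst, 0, sizeof(float) * W);
        if (dr == 1) std::memset(dst + (size_t)(H - 1) * W, 0, sizeof(float) * W);
        if (dc == -1) for (int r = 0; r < H; ++r) dst[(size_t)r * W] = 0.0f;
        if (dc == 1) for (int r = 0; r < H; ++r) dst[(size_t)r * W + W - 1] = 0.0f;
      }
    }
  }
  return col;
}

// Adjoint of im2col3: dcol (B*H*W) x 9C -> din (B*H*W) x C (accumulated).
fmat col2im3(const fmat& dcol, int B, int H, int W, int C) {
  const int HW = H * W;
  fmat din((uword)B * HW, (uword)C, fill::zeros);
  for (int k = 0; k < 9; ++k) {
    const int dr = k / 3 - 1, dc = k % 3 - 1, s = dr * W + dc;
    const int r0 = dr == -1 ? 1 : 0, r1 = dr == 1 ? H - 1 : H;
    const int c0 = dc == -1 ? 1 : 0, c1 = dc == 1 ? W - 1 : W;
    for (int ch = 0; ch < C; ++ch) {
      const float* src0 = dcol.colptr((uword)k * C + ch);
      float* dst0 = din.colptr(ch);
      for (int b = 0; b < B; ++b) {
        const float* src = src0 + (size_t)b * HW;
        float* dst = dst0 + (size_t)b * HW;
        for (int r = r0; r < r1; ++r) {
          const float* sp = src + (size_t)r * W + c0;
          float* dp = dst + (size_t)r * W + c0 + s;
          for (int c = c0; c < c1; ++c) *dp++ += *sp++;
        }
      }
    }
  }
  return din;
}

// 2x2 average pooling, stride 2; odd trailing row/col dropped.
fmat avgpool2(const fmat& in, int B, int H, int W) {
  const int C = in.n_cols, Ho = H / 2, Wo = W / 2, HW = H * W, HWo = Ho * Wo;
  fmat out((uword)B * HWo, (uword)C, fill::none);
  for (int ch = 0; ch < C; ++ch) {
    const float* src0 = in.colptr(ch);
    float* dst0 = out.colptr(ch);
    for (int b = 0; b < B; ++b) {
      const float* src = src0 + (size_t)b * HW;
      float* dst = dst0 + (size_t)b * HWo;
      for (int r = 0; r < Ho; ++r)
        for (int c = 0; c < Wo; ++c) {
          const float* q = src + (size_t)(2 * r) * W + 2 * c;
          dst[(size_t)r * Wo + c] = 0.25f * (q[0] + q[1] + q[W] + q[W + 1]);
        }
    }
  }
  return out;
}

fmat avgpool2_back(const fmat& dout, int B, int H, int W) {
  const int C = dout.n_cols, Ho = H / 2, Wo = W / 2, HW = H * W, HWo = Ho * Wo;
  fmat din((uword)B * HW, (uword)C, fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    const float* src0 = dout.colptr(ch);
    float* dst0 = din.colptr(ch);
    for (int b = 0; b < B; ++b) {
      const float* src = src0 + (size_t)b * HWo;
      float* dst = dst0 + (size_t)b * HW;
      for (int r = 0; r < Ho; ++r)
        for (int c = 0; c < Wo; ++c) {
          const float g = 0.25f * src[(size_t)r * Wo + c];
          float* q = dst + (size_t)(2 * r) * W + 2 * c;
          q[0] += g; q[1] += g; q[W] += g; q[W + 1] += g;
        }
    }
  }
  return din;
}

fmat flatten_maps(const fmat& p, int B, int P) {
  const int C = p.n_cols;
  fmat X((uword)B, (uword)P * C, fill::none);
  for (int b = 0; b < B; ++b)
    for (int ch = 0; ch < C; ++ch)
      for (int q = 0; q < P; ++q)
        X(b, (uword)ch * P + q) = p((uword)b * P + q, ch);
  return X;
}

fmat unflatten_maps(const fmat& dX, int B, int P, int C) {
  fmat dp((uword)B * P, (uword)C, fill::none);
  for (int b = 0; b < B; ++b)
    for (int ch = 0; ch < C; ++ch)
      for (int q = 0; q < P; ++q)
        dp((uword)b * P + q, ch) = dX(b, (uword)ch * P + q);
  return dp;
}

fmat softmax_rows(const fmat& z) {
  fmat p = z;
  p.each_col() -= max(p, 1);
  p = exp(p);
  p.each_col() /= sum(p, 1);
  return p;
}

// ---- forward/backward ---------------------------------------------------

struct Cache {
  int B = 0;
  fmat col1, a1, p1, col2, a2, p2, col3, a3, p3;
  fmat X, z10, a10, z2a, a2a, zout, out;
};

// head_sel: 0 = task1 (loss at the 10-node dense layer), 1 = task2 head.
void forward(const ConvNet& net, const fmat& in, int B, int head_sel, Cache& C) {
  C.B = B;
  const int H = net.H;
  C.col1 = im2col3(in, B, H, H);
  C.a1 = C.col1 * net.T[0].W;
  C.a1.each_row() += net.T[1].W;
  relu_(C.a1);
  C.p1 = avgpool2(C.a1, B, H, H);

  C.col2 = im2col3(C.p1, B, net.H1, net.H1);
  C.a2 = C.col2 * net.T[2].W;
  C.a2.each_row() += net.T[3].W;
  relu_(C.a2);
  C.p2 = avgpool2(C.a2, B, net.H1, net.H1);

  fmat* last = &C.p2;
  int P = net.H2 * net.H2;
  if (net.n_conv == 3) {
    C.col3 = im2col3(C.p2, B, net.H2, net.H2);
    C.a3 = C.col3 * net.T[4].W;
    C.a3.each_row() += net.T[5].W;
    relu_(C.a3);
    C.p3 = avgpool2(C.a3, B, net.H2, net.H2);
    last = &C.p3;
    P = net.H3 * net.H3;
  }
  C.X = flatten_maps(*last, B, P);

  const int id = net.ihead - 2;  // dense1_W index
  C.z10 = C.X * net.T[id].W;
  C.z10.each_row() += net.T[id + 1].W;
  if (head_sel == 0) { C.out = softmax_rows(C.z10); return; }
  C.a10 = C.z10;   // the 10-node dense layer is linear; the head reads the logits
  if (net.head_kind == 0) {
    C.z2a = C.a10 * net.T[net.ihead].W;
    C.z2a.each_row() += net.T[net.ihead + 1].W;
    C.a2a = clamp(C.z2a, 0.0f, std::numeric_limits<float>::max());
    C.zout = C.a2a * net.T[net.ihead + 2].W;
    C.zout.each_row() += net.T[net.ihead + 3].W;
    C.out = softmax_rows(C.zout);
  } else {
    C.zout = C.a10 * net.T[net.ihead].W;
    C.zout.each_row() += net.T[net.ihead + 1].W;
    C.out = 1.0f / (1.0f + exp(-C.zout));
  }
}

// Backpropagate from dz_at_head to all tensors that receive gradient.
// For head_sel 0, dz is d/d z10; gradients for head tensors stay empty.
// For head_sel 1, dz is d/d zout.
std::vector<fmat> backward(const ConvNet& net, const fmat& in, const Cache& C,
                           int head_sel, const fmat& dz) {
  std::vector<fmat> G(net.T.size());
  const int B = C.B, id = net.ihead - 2;
  fmat dz10;
  if (head_sel == 0) {
    dz10 = dz;
  } else if (net.head_kind == 0) {
    G[net.ihead + 2] = C.a2a.t() * dz;
    G[net.ihead + 3] = sum(dz, 0);
    fmat dz2a = dz * net.T[net.ihead + 2].W.t();
    relu_mask_(dz2a, C.a2a);
    G[net.ihead] = C.a10.t() * dz2a;
    G[net.ihead + 1] = sum(dz2a, 0);
    dz10 = dz2a * net.T[net.ihead].W.t();
  } else {
    G[net.ihead] = C.a10.t() * dz;
    G[net.ihead + 1] = sum(dz, 0);
    dz10 = dz * net.T[net.ihead].W.t();
  }
  G[id] = C.X.t() * dz10;
  G[id + 1] = sum(dz10, 0);
  fmat dX = dz10 * net.T[id].W.t();

  int P = (net.n_conv == 3) ? net.H3 * net.H3 : net.H2 * net.H2;
  const int Clast = net.filters[net.n_conv - 1];
  fmat dmap = unflatten_maps(dX, B, P, Clast);

  if (net.n_conv == 3) {
    fmat dz3 = avgpool2_back(dmap, B, net.H2, net.H2);
    relu_mask_(dz3, C.a3);
    G[4] = C.col3.t() * dz3;
    G[5] = sum(dz3, 0);
    fmat dcol3 = dz3 * net.T[4].W.t();
    dmap = col2im3(dcol3, B, net.H2, net.H2, net.filters[1]);
  }
  fmat dz2 = avgpool2_back(dmap, B, net.H1, net.H1);
  relu_mask_(dz2, C.a2);
  G[2] = C.col2.t() * dz2;
  G[3] = sum(dz2, 0);
  fmat dcol2 = dz2 * net.T[2].W.t();
  fmat dp1 = col2im3(dcol2, B, net.H1, net.H1, net.filters[0]);

  fmat dz1 = avgpool2_back(dp1, B, net.H, net.H);
  relu_mask_(dz1, C.a1);
  G[0] = C.col1.t() * dz1;
  G[1] = sum(dz1, 0);
  return G;
}

void adam_step(ConvNet& net, std::vector<fmat>& G) {
  net.step += 1;
  for (size_t i = 0; i < net.T.size(); ++i) {
    if (G[i].n_elem == 0) continue;
    Tensor& t = net.T[i];
    t.t += 1;
    t.m = ADAM_B1 * t.m + (1.0f - ADAM_B1) * G[i];
    t.v = ADAM_B2 * t.v + (1.0f - ADAM_B2) * square(G[i]);
    const float bc1 = 1.0f - std::pow(ADAM_B1, (float)t.t);
    const float bc2 = 1.0f - std::pow(ADAM_B2, (float)t.t);
    t.W -= net.lr * (t.m / bc1) / (sqrt(t.v / bc2) + ADAM_EPS);
  }
}

// ---- R interop ----------------------------------------------------------

fmat images_to_mat(const Rcpp::NumericVector& images, int& n, int H) {
  Rcpp::IntegerVector dim = images.attr("dim");
  if (dim.size() != 3) Rcpp::stop("images must be an n x H x W array");
  n = dim[0];
  if (dim[1] != H || dim[2] != H)
    Rcpp::stop("images are %dx%d but the network expects %dx%d", (int)dim[1], (int)dim[2], H, H);
  const int HW = H * H;
  fmat in((uword)n * HW, 1, fill::none);
  const double* x = images.begin();
  float* dst = in.colptr(0);
  for (int b = 0; b < n; ++b)
    for (int r = 0; r < H; ++r)
      for (int c = 0; c < H; ++c)
        dst[(size_t)b * HW + (size_t)r * H + c] = (float)x[(size_t)b + (size_t)n * r + (size_t)n * H * c];
  return in;
}

fmat rows_of(const fmat& in, int HW, const std::vector<int>& idx) {
  fmat out((uword)idx.size() * HW, 1, fill::none);
  for (size_t j = 0; j < idx.size(); ++j)
    std::memcpy(out.colptr(0) + j * HW, in.colptr(0) + (size_t)idx[j] * HW, sizeof(float) * HW);
  return out;
}

fmat num_to_f(const Rcpp::NumericMatrix& x) {
  fmat out(x.nrow(), x.ncol());
  for (int j = 0; j < x.ncol(); ++j)
    for (int i = 0; i < x.nrow(); ++i) out(i, j) = (float)x(i, j);
  return out;
}

Rcpp::NumericMatrix f_to_num(const fmat& x) {
  Rcpp::NumericMatrix out(x.n_rows, x.n_cols);
  for (uword j = 0; j < x.n_cols; ++j)
    for (uword i = 0; i < x.n_rows; ++i) out(i, j) = x(i, j);
  return out;
}

int head_code(const ConvNet& net, const std::string& head) {
  if (head == "single_digit") return 0;
  if (head == "parity_sum") {
    if (net.head_kind != 0) Rcpp::stop("network was built with a magnitude head; no parity head attached");
    return 1;
  }
  if (head == "magnitude_sum") {
    if (net.head_kind != 1) Rcpp::stop("network was built with a classification head; no magnitude head attached");
    return 1;
  }
  Rcpp::stop("unknown head '%s'", head.c_str());
}

int out_dim(const ConvNet& net, int head_sel) {
  if (head_sel == 0) return 10;
  return net.head_kind == 0 ? 2 : 20;
}

void check_labels(const ConvNet& net, const Rcpp::NumericMatrix& labels, int n, int head_sel) {
  if (labels.nrow() != n)
    Rcpp::stop("labels have %d rows but there are %d images", (int)labels.nrow(), n);
  const int k = out_dim(net, head_sel);
  if (labels.ncol() != k)
    Rcpp::stop("labels have %d columns but this head expects %d", (int)labels.ncol(), k);
}

// loss and (optionally) gradient of the training loss at the head
double head_loss(const ConvNet& net, const Cache& C, const fmat& Y, int head_sel,
                 fmat* dz) {
  const int B = C.B;
  double loss = 0.0;
  if (head_sel == 0 || net.head_kind == 0) {
    // categorical cross-entropy against softmax probabilities
    for (int b = 0; b < B; ++b)
      for (uword j = 0; j < C.out.n_cols; ++j)
        if (Y(b, j) > 0.0f)
          loss -= Y(b, j) * std::log(std::max(C.out(b, j), 1e-12f));
    loss /= B;
    if (dz) *dz = (C.out - Y) / (float)B;
  } else {
    // mean absolute error over the 20 sigmoid outputs
    fmat diff = C.out - Y;
    loss = accu(abs(diff)) / (double)(B * diff.n_cols);
    if (dz) *dz = (sign(diff) % (C.out % (1.0f - C.out))) / (float)(B * diff.n_cols);
  }
  return loss;
}

}  // namespace

// ---- exported API -------------------------------------------------------

// Keep large scratch buffers on the heap between training batches instead of
// returning them to the OS; the conv workspaces are allocated and freed once
// per batch and page-fault churn otherwise dominates the runtime.
// [[Rcpp::export]]
void cn_tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
}

// [[Rcpp::export]]
SEXP cn_create(int n_conv, int head_kind, int input_size, double lr, Rcpp::List weights) {
  if (n_conv != 2 && n_conv != 3) Rcpp::stop("n_conv must be 2 or 3");
  ConvNet* net = new ConvNet();
  net->n_conv = n_conv;
  net->head_kind = head_kind;
  net->H = input_size;
  net->lr = (float)lr;
  Rcpp::CharacterVector nm = weights.names();
  for (int i = 0; i < weights.size(); ++i) {
    Tensor t;
    t.W = num_to_f(Rcpp::as<Rcpp::NumericMatrix>(weights[i]));
    t.m = fmat(t.W.n_rows, t.W.n_cols, fill::zeros);
    t.v = fmat(t.W.n_rows, t.W.n_cols, fill::zeros);
    net->T.push_back(t);
    net->names.push_back(Rcpp::as<std::string>(nm[i]));
  }
  net->filters = { (int)net->T[0].W.n_cols, (int)net->T[2].W.n_cols };
  net->H1 = net->H / 2;
  net->H2 = net->H1 / 2;
  if (n_conv == 3) {
    net->filters.push_back((int)net->T[4].W.n_cols);
    net->H3 = net->H2 / 2;
    net->D = net->H3 * net->H3 * net->filters[2];
    net->ihead = 8;
  } else {
    net->D = net->H2 * net->H2 * net->filters[1];
    net->ihead = 6;
  }
  const int id = net->ihead - 2;
  if ((int)net->T[id].W.n_rows != net->D)
    Rcpp::stop("dense1_W has %d rows but the flattened convolutional output has %d",
               (int)net->T[id].W.n_rows, net->D);
  return Rcpp::XPtr<ConvNet>(net, true);
}

// [[Rcpp::export]]
SEXP cn_clone(SEXP ptr) {
  Rcpp::XPtr<ConvNet> p(ptr);
  return Rcpp::XPtr<ConvNet>(new ConvNet(*p), true);
}

// [[Rcpp::export]]
Rcpp::List cn_get_weights(SEXP ptr) {
  Rcpp::XPtr<ConvNet> p(ptr);
  Rcpp::List out(p->T.size());
  out.names() = Rcpp::wrap(p->names);
  for (size_t i = 0; i < p->T.size(); ++i) out[i] = f_to_num(p->T[i].W);
  return out;
}

// [[Rcpp::export]]
void cn_set_weights(SEXP ptr, Rcpp::List weights) {
  Rcpp::XPtr<ConvNet> p(ptr);
  if ((size_t)weights.size() != p->T.size()) Rcpp::stop("wrong number of weight tensors");
  for (size_t i = 0; i < p->T.size(); ++i) {
    fmat W = num_to_f(Rcpp::as<Rcpp::NumericMatrix>(weights[i]));
    if (W.n_rows != p->T[i].W.n_rows || W.n_cols != p->T[i].W.n_cols)
      Rcpp::stop("tensor %d has the wrong shape", (int)i + 1);
    p->T[i].W = W;
  }
}

// [[Rcpp::export]]
double cn_step_count(SEXP ptr) {
  Rcpp::XPtr<ConvNet> p(ptr);
  return (double)p->step;
}

// [[Rcpp::export]]
int cn_n_weights(SEXP ptr, std::string head) {
  Rcpp::XPtr<ConvNet> p(ptr);
  const int head_sel = head_code(*p, head);
  size_t n = 0;
  for (int i = 0; i < (head_sel == 0 ? p->ihead : (int)p->T.size()); ++i)
    n += p->T[i].W.n_elem;
  return (int)n;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cn_forward(SEXP ptr, Rcpp::NumericVector images, std::string head) {
  Rcpp::XPtr<ConvNet> p(ptr);
  const int head_sel = head_code(*p, head);
  int n = 0;
  fmat in = images_to_mat(images, n, p->H);
  const int HW = p->H * p->H, chunk = 32;
  fmat out((uword)n, (uword)out_dim(*p, head_sel), fill::none);
  for (int b0 = 0; b0 < n; b0 += chunk) {
    const int B = std::min(chunk, n - b0);
    fmat sub((uword)B * HW, 1, fill::none);
    std::memcpy(sub.colptr(0), in.colptr(0) + (size_t)b0 * HW, sizeof(float) * (size_t)B * HW);
    Cache C;
    forward(*p, sub, B, head_sel, C);
    out.rows(b0, b0 + B - 1) = C.out;
  }
  return f_to_num(out);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cn_dense_activations(SEXP ptr, Rcpp::NumericVector images, bool rectified) {
  Rcpp::XPtr<ConvNet> p(ptr);
  int n = 0;
  fmat in = images_to_mat(images, n, p->H);
  const int HW = p->H * p->H, chunk = 32;
  fmat out((uword)n, 10, fill::none);
  for (int b0 = 0; b0 < n; b0 += chunk) {
    const int B = std::min(chunk, n - b0);
    fmat sub((uword)B * HW, 1, fill::none);
    std::memcpy(sub.colptr(0), in.colptr(0) + (size_t)b0 * HW, sizeof(float) * (size_t)B * HW);
    Cache C;
    forward(*p, sub, B, 0, C);
    out.rows(b0, b0 + B - 1) =
      rectified ? fmat(clamp(C.z10, 0.0f, std::numeric_limits<float>::max())) : C.z10;
  }
  return f_to_num(out);
}

// [[Rcpp::export]]
double cn_loss(SEXP ptr, Rcpp::NumericVector images, Rcpp::NumericMatrix labels, std::string head) {
  Rcpp::XPtr<ConvNet> p(ptr);
  const int head_sel = head_code(*p, head);
  int n = 0;
  fmat in = images_to_mat(images, n, p->H);
  check_labels(*p, labels, n, head_sel);
  fmat Y = num_to_f(labels);
  const int HW = p->H * p->H, chunk = 32;
  double total = 0.0;
  for (int b0 = 0; b0 < n; b0 += chunk) {
    const int B = std::min(chunk, n - b0);
    fmat sub((uword)B * HW, 1, fill::none);
    std::memcpy(sub.colptr(0), in.colptr(0) + (size_t)b0 * HW, sizeof(float) * (size_t)B * HW);
    Cache C;
    forward(*p, sub, B, head_sel, C);
    fmat Ysub = Y.rows(b0, b0 + B - 1);
    total += head_loss(*p, C, Ysub, head_sel, nullptr) * B;
  }
  return total / n;
}

// [[Rcpp::export]]
double cn_train_batch(SEXP ptr, Rcpp::NumericVector images, Rcpp::NumericMatrix labels, std::string head) {
  Rcpp::XPtr<ConvNet> p(ptr);
  const int head_sel = head_code(*p, head);
  int n = 0;
  fmat in = images_to_mat(images, n, p->H);
  check_labels(*p, labels, n, head_sel);
  Cache C;
  forward(*p, in, n, head_sel, C);
  fmat dz;
  const double loss = head_loss(*p, C, num_to_f(labels), head_sel, &dz);
  std::vector<fmat> G = backward(*p, in, C, head_sel, dz);
  adam_step(*p, G);
  return loss;
}

// Per-example gradient of the task loss at the 10-node dense layer
// (d loss_i / d z10, no 1/B averaging) — used to probe the orthogonality
// of the parity error signal to component digits.
// [[Rcpp::export]]
Rcpp::NumericMatrix cn_grad_z10(SEXP ptr, Rcpp::NumericVector images, Rcpp::NumericMatrix labels, std::string head) {
  Rcpp::XPtr<ConvNet> p(ptr);
  const int head_sel = head_code(*p, head);
  int n = 0;
  fmat in = images_to_mat(images, n, p->H);
  check_labels(*p, labels, n, head_sel);
  fmat Yall = num_to_f(labels);
  const int HW = p->H * p->H, chunk = 32;
  fmat dz10_all((uword)n, 10, fill::none);
  for (int b0 = 0; b0 < n; b0 += chunk) {
  const int B = std::min(chunk, n - b0);
  fmat sub((uword)B * HW, 1, fill::none);
  std::memcpy(sub.colptr(0), in.colptr(0) + (size_t)b0 * HW, sizeof(float) * (size_t)B * HW);
  Cache C;
  forward(*p, sub, B, head_sel, C);
  fmat Y = Yall.rows(b0, b0 + B - 1), dz10;
  if (head_sel == 0) {
    dz10 = C.out - Y;
  } else if (p->head_kind == 0) {
    fmat dz = C.out - Y;
    fmat dz2a = dz * p->T[p->ihead + 2].W.t();
    relu_mask_(dz2a, C.a2a);
    dz10 = dz2a * p->T[p->ihead].W.t();
  } else {
    fmat diff = C.out - Y;
    fmat dz = sign(diff) % (C.out % (1.0f - C.out)) / (float)diff.n_cols;
    dz10 = dz * p->T[p->ihead].W.t();
  }
  dz10_all.rows(b0, b0 + B - 1) = dz10;
  }
  return f_to_num(dz10_all);
}

// Diagonal empirical Fisher Information of the weights.
//
// For each example the label is sampled from the model's own predictive
// distribution (categorical for softmax heads, 20 independent Bernoullis
// for the magnitude head) using the uniform variates supplied from R; the
// per-weight squared gradient of the log-likelihood is accumulated in double
// precision, averaged over examples, and the reported value is the mean over
// all weights that receive gradient under the chosen head's loss.
// [[Rcpp::export]]
Rcpp::List cn_fisher(SEXP ptr, Rcpp::NumericVector images, std::string head, Rcpp::NumericVector unif) {
  Rcpp::XPtr<ConvNet> p(ptr);
  const int head_sel = head_code(*p, head);
  int n = 0;
  fmat in = images_to_mat(images, n, p->H);
  if (n < 1) Rcpp::stop("Fisher Information needs a non-empty sample");
  const int k = out_dim(*p, head_sel);
  const bool magnitude = (head_sel == 1 && p->head_kind == 1);
  const size_t need = magnitude ? (size_t)n * k : (size_t)n;
  if ((size_t)unif.size() < need)
    Rcpp::stop("need %d uniform variates, got %d", (int)need, (int)unif.size());

  const int ntens = (head_sel == 0 ? p->ihead : (int)p->T.size());
  std::vector<mat> acc(ntens);
  for (int i = 0; i < ntens; ++i)
    acc[i] = mat(p->T[i].W.n_rows, p->T[i].W.n_cols, fill::zeros);

  const int HW = p->H * p->H;
  for (int e = 0; e < n; ++e) {
    fmat one((uword)HW, 1, fill::none);
    std::memcpy(one.colptr(0), in.colptr(0) + (size_t)e * HW, sizeof(float) * HW);
    Cache C;
    forward(*p, one, 1, head_sel, C);
    fmat dz(1, k, fill::none);
    if (!magnitude) {
      // sample a class from the categorical output distribution
      double u = unif[e], cum = 0.0;
      int y = k - 1;
      for (int j = 0; j < k; ++j) { cum += C.out(0, j); if (u < cum) { y = j; break; } }
      for (int j = 0; j < k; ++j) dz(0, j) = C.out(0, j) - (j == y ? 1.0f : 0.0f);
    } else {
      // independent Bernoulli at each of the 20 outputs
      for (int j = 0; j < k; ++j) {
        const int y = (unif[(size_t)e * k + j] < C.out(0, j)) ? 1 : 0;
        dz(0, j) = C.out(0, j) - (float)y;
      }
    }
    std::vector<fmat> G = backward(*p, one, C, head_sel, dz);
    for (int i = 0; i < ntens; ++i)
      if (G[i].n_elem > 0) acc[i] += square(conv_to<mat>::from(G[i]));
  }

  double total = 0.0;
  size_t nw = 0;
  for (int i = 0; i < ntens; ++i) { total += accu(acc[i]); nw += acc[i].n_elem; }
  const double value = total / (double)n / (double)nw;
  return Rcpp::List::create(Rcpp::Named("value") = value,
                            Rcpp::Named("n_weights") = (double)nw,
                            Rcpp::Named("n_examples") = (double)n);
}
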