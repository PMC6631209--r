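// Minimal CNN engine: batched im2col/GEMM convolutions, transposed
// convolutions, ceil-mode max pooling, across-channel LRN, inverted dropout,
// inner products, centre crop / fit-to-target resampling and element-wise
// fusion, with softmax, per-pixel weighted softmax and Euclidean losses
// trained by momentum SGD with a step-down learning-rate schedule.
//
// Layout conventions (must match the R side):
//  * an activation "blob" is fmat(h*w*c, n); element (i,j,ch) of sample s is
//    data(i + h*j + h*w*ch, s) -- identical to an R array dim c(h,w,c).
//  * conv weights arrive as an R array dim c(k,k,c_in_per_group,c_out);
//    flattened row o, column ch*k*k + ki*k + kj.
//  * deconv weights arrive as dim c(k,k,c_out,c_in); flattened
//    (k*k*c_out, c_in), row o*k*k + ki*k + kj.
//  * inner-product weights arrive as dim c(in_features, out).
// All randomness (dropout, shuffling) is drawn from the R RNG so that
// set.seed() controls training exactly; execution is single-threaded.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>
#include <map>
#include <vector>
#include <string>

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::uword;

struct Blob {
  int h = 0, w = 0, c = 0, n = 0;
  fmat data;  // (h*w*c, n)
  void set(int h_, int w_, int c_, int n_, bool zero = true) {
    h = h_; w = w_; c = c_; n = n_;
    if (zero) data.zeros((uword)h * w * c, n);
    else data.set_size((uword)h * w * c, n);
  }
};

struct Layer {
  std::string name, type, bottom, bottom2;
  int kernel = 0, stride = 1, pad = 0, groups = 1, out_channels = 0;
  bool bias = true;
  int target_h = -1, target_w = -1;  // crop/fit target
  double rate = 0.5;                 // dropout
  int lrn_size = 5; double lrn_alpha = 1e-4, lrn_beta = 0.75;
  int out_features = 0;              // inner product
  bool has_weights = false;
  fmat W, dW, mW;
  fvec b, db, mb;
  // cached per-batch state
  arma::umat pool_idx;
  fmat drop_mask, lrn_scale, lrn_pow;
  std::vector<fmat> fwd_cols;  // per-group im2col kept for the backward pass
};

// s^(-beta); beta = 0.75 (the usual value) gets a sqrt fast path
static inline float pow_negbeta(float s, float beta) {
  if (beta == 0.75f) {
    float r = std::sqrt(s);
    return 1.0f / (r * std::sqrt(r));
  }
  return std::pow(s, -beta);
}

static int conv_out_dim(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}
// Caffe-style ceil pooling (pad 0), clipped so windows start inside the input
static int pool_out_dim(int in, int k, int s) {
  int out = (int)std::ceil((double)(in - k) / s) + 1;
  if ((out - 1) * s >= in) out--;
  return out;
}

// ---------------------------------------------------------------------------
// im2col / col2im

// Fill cols (k*k*cg rows, oh*ow cols) from one sample's channels
// [c0, c0+cg) of src blob (memory h*w per channel). Row layout is
// ch*k*k + kj*k + ki (ki fastest), so each kernel column is a contiguous
// run of the image and can be block-copied.
static void im2col_one(const float* src, int h, int w, int c0, int cg,
                       int k, int s, int p, int oh, int ow, fmat& cols,
                       uword col_off) {
  for (int oj = 0; oj < ow; ++oj) {
    for (int oi = 0; oi < oh; ++oi) {
      uword col = col_off + (uword)oj * oh + oi;
      float* dst = cols.colptr(col);
      int base_i = oi * s - p, base_j = oj * s - p;
      int i0 = std::max(0, -base_i), i1 = std::min(k, h - base_i);
      for (int ch = 0; ch < cg; ++ch) {
        const float* plane = src + (uword)(c0 + ch) * h * w;
        float* d = dst + (uword)ch * k * k;
        for (int kj = 0; kj < k; ++kj, d += k) {
          int jj = base_j + kj;
          if (jj < 0 || jj >= w || i1 <= i0) {
            std::memset(d, 0, k * sizeof(float));
            continue;
          }
          if (i0 > 0) std::memset(d, 0, i0 * sizeof(float));
          std::memcpy(d + i0, plane + (base_i + i0) + (uword)h * jj,
                      (i1 - i0) * sizeof(float));
          if (i1 < k) std::memset(d + i1, 0, (k - i1) * sizeof(float));
        }
      }
    }
  }
}

// Scatter-add cols back (transpose of im2col_one).
static void col2im_one(float* dst, int h, int w, int c0, int cg,
                       int k, int s, int p, int oh, int ow, const fmat& cols,
                       uword col_off) {
  for (int oj = 0; oj < ow; ++oj) {
    for (int oi = 0; oi < oh; ++oi) {
      uword col = col_off + (uword)oj * oh + oi;
      const float* src = cols.colptr(col);
      int base_i = oi * s - p, base_j = oj * s - p;
      int i0 = std::max(0, -base_i), i1 = std::min(k, h - base_i);
      for (int ch = 0; ch < cg; ++ch) {
        float* plane = dst + (uword)(c0 + ch) * h * w;
        const float* sc = src + (uword)ch * k * k;
        for (int kj = 0; kj < k; ++kj, sc += k) {
          int jj = base_j + kj;
          if (jj < 0 || jj >= w) continue;
          float* pp = plane + base_i + (uword)h * jj;
          for (int ki = i0; ki < i1; ++ki) pp[ki] += sc[ki];
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Direct convolution path for thin stride-1 layers (the FCN backbone):
// per kernel tap, a scaled shifted-plane accumulation with contiguous inner
// loops -- much cheaper than im2col when k*k*cin is small.

static inline bool use_direct(int k, int s, int g, int cin) {
  return s == 1 && g == 1 && k * k * cin <= 160;
}

static void direct_conv_fwd(const float* in, int h, int w, int cin,
                            const fmat& W, const fvec& b, bool bias,
                            int k, int p, float* out, int oh, int ow,
                            int cout) {
  for (int o = 0; o < cout; ++o) {
    float* op = out + (uword)o * oh * ow;
    float bv = bias ? b[o] : 0.0f;
    for (uword q = 0; q < (uword)oh * ow; ++q) op[q] = bv;
    for (int ci = 0; ci < cin; ++ci) {
      const float* ip = in + (uword)ci * h * w;
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          float wv = W(o, (uword)ci * k * k + kj * k + ki);
          if (wv == 0.0f) continue;
          int oj0 = std::max(0, p - kj), oj1 = std::min(ow, w + p - kj);
          int oi0 = std::max(0, p - ki), oi1 = std::min(oh, h + p - ki);
          int len = oi1 - oi0;
          if (len <= 0) continue;
          for (int oj = oj0; oj < oj1; ++oj) {
            float* dp = op + (uword)oj * oh + oi0;
            const float* sp = ip + (uword)(oj + kj - p) * h + (oi0 + ki - p);
            for (int t = 0; t < len; ++t) dp[t] += wv * sp[t];
          }
        }
      }
    }
  }
}

static void direct_conv_bwd_data(float* din, int h, int w, int cin,
                                 const fmat& W, int k, int p,
                                 const float* dout, int oh, int ow,
                                 int cout) {
  for (int o = 0; o < cout; ++o) {
    const float* gp = dout + (uword)o * oh * ow;
    for (int ci = 0; ci < cin; ++ci) {
      float* ip = din + (uword)ci * h * w;
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          float wv = W(o, (uword)ci * k * k + kj * k + ki);
          if (wv == 0.0f) continue;
          int oj0 = std::max(0, p - kj), oj1 = std::min(ow, w + p - kj);
          int oi0 = std::max(0, p - ki), oi1 = std::min(oh, h + p - ki);
          int len = oi1 - oi0;
          if (len <= 0) continue;
          for (int oj = oj0; oj < oj1; ++oj) {
            const float* dp = gp + (uword)oj * oh + oi0;
            float* sp = ip + (uword)(oj + kj - p) * h + (oi0 + ki - p);
            for (int t = 0; t < len; ++t) sp[t] += wv * dp[t];
          }
        }
      }
    }
  }
}

static void direct_conv_bwd_weight(const float* in, int h, int w, int cin,
                                   fmat& dW, fvec& db, bool bias,
                                   int k, int p, const float* dout,
                                   int oh, int ow, int cout) {
  for (int o = 0; o < cout; ++o) {
    const float* gp = dout + (uword)o * oh * ow;
    if (bias) {
      double acc = 0;
      for (uword q = 0; q < (uword)oh * ow; ++q) acc += gp[q];
      db[o] += (float)acc;
    }
    for (int ci = 0; ci < cin; ++ci) {
      const float* ip = in + (uword)ci * h * w;
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          int oj0 = std::max(0, p - kj), oj1 = std::min(ow, w + p - kj);
          int oi0 = std::max(0, p - ki), oi1 = std::min(oh, h + p - ki);
          int len = oi1 - oi0;
          if (len <= 0) continue;
          double acc = 0;
          for (int oj = oj0; oj < oj1; ++oj) {
            const float* dp = gp + (uword)oj * oh + oi0;
            const float* sp = ip + (uword)(oj + kj - p) * h + (oi0 + ki - p);
            for (int t = 0; t < len; ++t) acc += dp[t] * sp[t];
          }
          dW(o, (uword)ci * k * k + kj * k + ki) += (float)acc;
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Net

struct Net {
  std::vector<Layer> layers;
  std::map<std::string, int> index;
};

static Layer parse_layer(const List& spec) {
  Layer L;
  L.name = as<std::string>(spec["name"]);
  L.type = as<std::string>(spec["type"]);
  L.bottom = as<std::string>(spec["bottom"]);
  if (spec.containsElementNamed("bottom2") && !Rf_isNull(spec["bottom2"]))
    L.bottom2 = as<std::string>(spec["bottom2"]);
  auto geti = [&](const char* f, int d) {
    return spec.containsElementNamed(f) && !Rf_isNull(spec[f])
               ? as<int>(spec[f]) : d; };
  auto getd = [&](const char* f, double d) {
    return spec.containsElementNamed(f) && !Rf_isNull(spec[f])
               ? as<double>(spec[f]) : d; };
  L.kernel = geti("kernel", 0);
  L.stride = geti("stride", 1);
  L.pad = geti("pad", 0);
  L.groups = geti("groups", 1);
  L.out_channels = geti("out_channels", 0);
  L.out_features = geti("out_features", 0);
  L.target_h = geti("target_h", -1);
  L.target_w = geti("target_w", -1);
  L.rate = getd("rate", 0.5);
  L.lrn_size = geti("lrn_size", 5);
  L.lrn_alpha = getd("lrn_alpha", 1e-4);
  L.lrn_beta = getd("lrn_beta", 0.75);
  if (spec.containsElementNamed("bias") && !Rf_isNull(spec["bias"]))
    L.bias = as<bool>(spec["bias"]);
  return L;
}

static void load_weights(Layer& L, const List& w) {
  NumericVector Wr = w["W"];
  IntegerVector dim = Wr.attr("dim");
  if (L.type == "conv") {
    int k = dim[0], cpg = dim[2], out = dim[3];
    L.W.set_size(out, (uword)k * k * cpg);
    for (int o = 0; o < out; ++o)
      for (int ch = 0; ch < cpg; ++ch)
        for (int kj = 0; kj < k; ++kj)
          for (int ki = 0; ki < k; ++ki)
            L.W(o, (uword)ch * k * k + kj * k + ki) =
                (float)Wr[ki + (uword)k * kj + (uword)k * k * ch +
                          (uword)k * k * cpg * o];
  } else if (L.type == "deconv") {
    int k = dim[0], out = dim[2], cin = dim[3];
    L.W.set_size((uword)k * k * out, cin);
    for (int ci = 0; ci < cin; ++ci)
      for (int o = 0; o < out; ++o)
        for (int kj = 0; kj < k; ++kj)
          for (int ki = 0; ki < k; ++ki)
            L.W((uword)o * k * k + kj * k + ki, ci) =
                (float)Wr[ki + (uword)k * kj + (uword)k * k * o +
                          (uword)k * k * out * ci];
  } else {  // fc: (in, out) -> (out, in)
    int in = dim[0], out = dim[1];
    L.W.set_size(out, in);
    for (int o = 0; o < out; ++o)
      for (int i = 0; i < in; ++i) L.W(o, i) = (float)Wr[i + (uword)in * o];
  }
  if (L.bias) {
    NumericVector br = w["b"];
    L.b.set_size(br.size());
    for (int i = 0; i < br.size(); ++i) L.b[i] = (float)br[i];
  }
  L.has_weights = true;
  L.dW.zeros(arma::size(L.W)); L.mW.zeros(arma::size(L.W));
  if (L.bias) { L.db.zeros(L.b.n_elem); L.mb.zeros(L.b.n_elem); }
}

static Net build_net(const List& layers, const List& weights) {
  Net net;
  for (int i = 0; i < layers.size(); ++i) {
    Layer L = parse_layer(layers[i]);
    if (L.type == "conv" || L.type == "deconv" || L.type == "fc") {
      if (!weights.containsElementNamed(L.name.c_str()))
        stop("missing weights for layer '%s'", L.name.c_str());
      load_weights(L, weights[L.name.c_str()]);
    }
    net.index[L.name] = (int)net.layers.size();
    net.layers.push_back(L);
  }
  return net;
}

// ---------------------------------------------------------------------------
// Forward

static void forward_conv(Layer& L, const Blob& in, Blob& out) {
  int k = L.kernel, s = L.stride, p = L.pad, g = L.groups;
  int oh = conv_out_dim(in.h, k, s, p), ow = conv_out_dim(in.w, k, s, p);
  int cg = in.c / g, outg = L.out_channels / g;
  out.set(oh, ow, L.out_channels, in.n, false);
  if (use_direct(k, s, g, in.c)) {
    for (int sN = 0; sN < in.n; ++sN)
      direct_conv_fwd(in.data.colptr(sN), in.h, in.w, in.c, L.W, L.b,
                      L.bias, k, p, out.data.colptr(sN), oh, ow,
                      L.out_channels);
    return;
  }
  uword hw = (uword)oh * ow;
  bool keep = ((uword)k * k * cg) * hw * in.n <= 16000000u;
  L.fwd_cols.assign(keep ? g : 0, fmat());
  fmat scratch;
  for (int gi = 0; gi < g; ++gi) {
    fmat& cols = keep ? L.fwd_cols[gi] : scratch;
    cols.set_size((uword)k * k * cg, hw * in.n);
    for (int sN = 0; sN < in.n; ++sN)
      im2col_one(in.data.colptr(sN), in.h, in.w, gi * cg, cg, k, s, p, oh, ow,
                 cols, (uword)sN * hw);
    fmat R = L.W.rows((uword)gi * outg, (uword)(gi + 1) * outg - 1) * cols;
    // scatter rows (outg, hw*n) into out
    for (int sN = 0; sN < in.n; ++sN) {
      float* dst = out.data.colptr(sN);
      for (int o = 0; o < outg; ++o) {
        int oc = gi * outg + o;
        const float bia = L.bias ? L.b[oc] : 0.0f;
        float* d = dst + (uword)oc * hw;
        for (uword q = 0; q < hw; ++q) d[q] = R(o, (uword)sN * hw + q) + bia;
      }
    }
  }
}

static void forward_deconv(Layer& L, const Blob& in, Blob& out) {
  int k = L.kernel, s = L.stride;
  int oh = (in.h - 1) * s + k, ow = (in.w - 1) * s + k;
  out.set(oh, ow, L.out_channels, in.n);
  uword hw = (uword)in.h * in.w;
  for (int sN = 0; sN < in.n; ++sN) {
    fmat X((float*)in.data.colptr(sN), hw, in.c, false, true);
    fmat cols = L.W * X.t();  // (k*k*out, hw)
    col2im_one(out.data.colptr(sN), oh, ow, 0, L.out_channels, k, s, 0,
               in.h, in.w, cols, 0);
  }
}

static void forward_pool(Layer& L, const Blob& in, Blob& out) {
  int k = L.kernel, s = L.stride;
  int oh = pool_out_dim(in.h, k, s), ow = pool_out_dim(in.w, k, s);
  out.set(oh, ow, in.c, in.n, false);
  L.pool_idx.set_size((uword)oh * ow * in.c, in.n);
  for (int sN = 0; sN < in.n; ++sN) {
    const float* src = in.data.colptr(sN);
    float* dst = out.data.colptr(sN);
    for (int ch = 0; ch < in.c; ++ch) {
      const float* plane = src + (uword)ch * in.h * in.w;
      for (int oj = 0; oj < ow; ++oj)
        for (int oi = 0; oi < oh; ++oi) {
          float best = -1e30f; uword arg = 0;
          for (int ki = 0; ki < k; ++ki) {
            int ii = oi * s + ki; if (ii >= in.h) break;
            for (int kj = 0; kj < k; ++kj) {
              int jj = oj * s + kj; if (jj >= in.w) break;
              uword at = ii + (uword)in.h * jj;
              if (plane[at] > best) { best = plane[at]; arg = at; }
            }
          }
          uword oat = (uword)oi + (uword)oh * oj + (uword)oh * ow * ch;
          dst[oat] = best;
          L.pool_idx(oat, sN) = arg + (uword)ch * in.h * in.w;
        }
    }
  }
}

static void forward_lrn(Layer& L, const Blob& in, Blob& out) {
  out.set(in.h, in.w, in.c, in.n, false);
  L.lrn_scale.set_size(arma::size(in.data));
  L.lrn_pow.set_size(arma::size(in.data));
  uword hw = (uword)in.h * in.w;
  int half = (L.lrn_size - 1) / 2;
  float a = (float)(L.lrn_alpha / L.lrn_size);
  float beta = (float)L.lrn_beta;
  for (int sN = 0; sN < in.n; ++sN) {
    const float* x = in.data.colptr(sN);
    float* sc = L.lrn_scale.colptr(sN);
    float* pw = L.lrn_pow.colptr(sN);
    float* y = out.data.colptr(sN);
    for (uword px = 0; px < hw; ++px) {
      // running window sum over channels
      float acc = 0.0f;
      for (int c2 = 0; c2 <= std::min(in.c - 1, half); ++c2) {
        float v = x[px + hw * c2]; acc += v * v;
      }
      for (int ch = 0; ch < in.c; ++ch) {
        if (ch > 0) {
          int add = ch + half, drop = ch - half - 1;
          if (add < in.c) { float v = x[px + hw * add]; acc += v * v; }
          if (drop >= 0) { float v = x[px + hw * drop]; acc -= v * v; }
        }
        float s = 1.0f + a * std::max(acc, 0.0f);
        float p = pow_negbeta(s, beta);
        sc[px + hw * ch] = s;
        pw[px + hw * ch] = p;
        y[px + hw * ch] = x[px + hw * ch] * p;
      }
    }
  }
}

static void forward_fit(Layer& L, const Blob& in, Blob& out) {
  // centre crop when input >= target, centre zero-pad otherwise; padding
  // (rather than stretching) keeps the score grid aligned with the
  // backbone's receptive-field geometry
  int th = L.target_h, tw = L.target_w;
  out.set(th, tw, in.c, in.n);
  int offi = (in.h - th) / 2, offj = (in.w - tw) / 2;  // negative = pad
  for (int sN = 0; sN < in.n; ++sN) {
    const float* src = in.data.colptr(sN);
    float* dst = out.data.colptr(sN);
    for (int ch = 0; ch < in.c; ++ch)
      for (int j = 0; j < tw; ++j) {
        int sj = j + offj;
        if (sj < 0 || sj >= in.w) continue;
        for (int i = 0; i < th; ++i) {
          int si = i + offi;
          if (si < 0 || si >= in.h) continue;
          dst[i + (uword)th * j + (uword)th * tw * ch] =
              src[si + (uword)in.h * sj + (uword)in.h * in.w * ch];
        }
      }
  }
}

static void forward_layer(Layer& L, std::map<std::string, Blob>& acts,
                          bool train) {
  Blob& in = acts[L.bottom];
  Blob& out = acts[L.name];
  if (L.type == "conv") forward_conv(L, in, out);
  else if (L.type == "deconv") forward_deconv(L, in, out);
  else if (L.type == "pool") forward_pool(L, in, out);
  else if (L.type == "relu") {
    out = in; out.data.transform([](float v) { return v > 0 ? v : 0; });
  } else if (L.type == "lrn") forward_lrn(L, in, out);
  else if (L.type == "dropout") {
    out = in;
    if (train) {
      L.drop_mask.set_size(arma::size(in.data));
      float keep = 1.0f - (float)L.rate;
      for (uword i = 0; i < L.drop_mask.n_elem; ++i)
        L.drop_mask[i] = (unif_rand() >= L.rate) ? 1.0f / keep : 0.0f;
      out.data %= L.drop_mask;
    }
  } else if (L.type == "fc") {
    out.h = 1; out.w = 1; out.c = L.out_features; out.n = in.n;
    out.data = L.W * in.data;
    if (L.bias) out.data.each_col() += L.b;
  } else if (L.type == "crop") {
    Blob& ref = acts[L.bottom2];
    L.target_h = ref.h; L.target_w = ref.w;
    forward_fit(L, in, out);
  } else if (L.type == "fit") forward_fit(L, in, out);
  else if (L.type == "eltwise") {
    Blob& in2 = acts[L.bottom2];
    out = in; out.data += in2.data;
  } else stop("unknown layer type '%s'", L.type.c_str());
}

static void forward_net(Net& net, std::map<std::string, Blob>& acts,
                        bool train, const std::string& upto = "") {
  for (auto& L : net.layers) {
    forward_layer(L, acts, train);
    if (!upto.empty() && L.name == upto) return;
  }
}

// ---------------------------------------------------------------------------
// Backward

static void backward_conv(Layer& L, const Blob& in, const Blob& dout_blob,
                          Blob& din, bool need_din) {
  int k = L.kernel, s = L.stride, p = L.pad, g = L.groups;
  int oh = dout_blob.h, ow = dout_blob.w;
  int cg = in.c / g, outg = L.out_channels / g;
  if (use_direct(k, s, g, in.c)) {
    for (int sN = 0; sN < in.n; ++sN) {
      direct_conv_bwd_weight(in.data.colptr(sN), in.h, in.w, in.c, L.dW,
                             L.db, L.bias, k, p, dout_blob.data.colptr(sN),
                             oh, ow, L.out_channels);
      if (need_din)
        direct_conv_bwd_data(din.data.colptr(sN), in.h, in.w, in.c, L.W,
                             k, p, dout_blob.data.colptr(sN), oh, ow,
                             L.out_channels);
    }
    return;
  }
  uword hw = (uword)oh * ow;
  bool cached = L.fwd_cols.size() == (size_t)g &&
                L.fwd_cols[0].n_cols == hw * in.n;
  fmat scratch;
  fmat doutg(outg, hw * in.n);
  for (int gi = 0; gi < g; ++gi) {
    if (!cached) scratch.set_size((uword)k * k * cg, hw * in.n);
    fmat& cols = cached ? L.fwd_cols[gi] : scratch;
    for (int sN = 0; sN < in.n; ++sN) {
      if (!cached)
        im2col_one(in.data.colptr(sN), in.h, in.w, gi * cg, cg, k, s, p, oh,
                   ow, cols, (uword)sN * hw);
      const float* dsrc = dout_blob.data.colptr(sN);
      for (int o = 0; o < outg; ++o) {
        const float* dp = dsrc + (uword)(gi * outg + o) * hw;
        for (uword q = 0; q < hw; ++q) doutg(o, (uword)sN * hw + q) = dp[q];
      }
    }
    L.dW.rows((uword)gi * outg, (uword)(gi + 1) * outg - 1) +=
        doutg * cols.t();
    if (L.bias)
      for (int o = 0; o < outg; ++o)
        L.db[gi * outg + o] += arma::accu(doutg.row(o));
    if (need_din) {
      fmat dcols =
          L.W.rows((uword)gi * outg, (uword)(gi + 1) * outg - 1).t() * doutg;
      for (int sN = 0; sN < in.n; ++sN)
        col2im_one(din.data.colptr(sN), in.h, in.w, gi * cg, cg, k, s, p, oh,
                   ow, dcols, (uword)sN * hw);
    }
  }
}

static void backward_deconv(Layer& L, const Blob& in, const Blob& dout_blob,
                            Blob& din) {
  int k = L.kernel, s = L.stride;
  uword hw = (uword)in.h * in.w;
  fmat cols((uword)k * k * L.out_channels, hw);
  for (int sN = 0; sN < in.n; ++sN) {
    im2col_one(dout_blob.data.colptr(sN), dout_blob.h, dout_blob.w, 0,
               L.out_channels, k, s, 0, in.h, in.w, cols, 0);
    fmat X((float*)in.data.colptr(sN), hw, in.c, false, true);
    L.dW += cols * X;                       // (k*k*out, cin)
    fmat dX = L.W.t() * cols;               // (cin, hw)
    float* d = din.data.colptr(sN);
    for (int ci = 0; ci < in.c; ++ci)
      for (uword q = 0; q < hw; ++q) d[q + hw * ci] += dX(ci, q);
  }
}

static void backward_fit(Layer& L, const Blob& in, const Blob& dout_blob,
                         Blob& din) {
  int th = dout_blob.h, tw = dout_blob.w;
  int offi = (in.h - th) / 2, offj = (in.w - tw) / 2;
  for (int sN = 0; sN < in.n; ++sN) {
    const float* src = dout_blob.data.colptr(sN);
    float* dst = din.data.colptr(sN);
    for (int ch = 0; ch < in.c; ++ch)
      for (int j = 0; j < tw; ++j) {
        int sj = j + offj;
        if (sj < 0 || sj >= in.w) continue;
        for (int i = 0; i < th; ++i) {
          int si = i + offi;
          if (si < 0 || si >= in.h) continue;
          dst[si + (uword)in.h * sj + (uword)in.h * in.w * ch] +=
              src[i + (uword)th * j + (uword)th * tw * ch];
        }
      }
  }
}

static void backward_lrn(Layer& L, const Blob& in, const Blob& out,
                         const Blob& dout_blob, Blob& din) {
  uword hw = (uword)in.h * in.w;
  int half = (L.lrn_size - 1) / 2;
  double a2b = 2.0 * (L.lrn_alpha / L.lrn_size) * L.lrn_beta;
  for (int sN = 0; sN < in.n; ++sN) {
    const float* x = in.data.colptr(sN);
    const float* y = out.data.colptr(sN);
    const float* dy = dout_blob.data.colptr(sN);
    const float* sc = L.lrn_scale.colptr(sN);
    float* dx = din.data.colptr(sN);
    for (uword px = 0; px < hw; ++px) {
      for (int ch = 0; ch < in.c; ++ch) {
        double acc = 0.0;
        int lo = std::max(0, ch - half), hi = std::min(in.c - 1, ch + half);
        for (int c2 = lo; c2 <= hi; ++c2)
          acc += dy[px + hw * c2] * y[px + hw * c2] / sc[px + hw * c2];
        dx[px + hw * ch] +=
            dy[px + hw * ch] * L.lrn_pow.colptr(sN)[px + hw * ch] -
            (float)(a2b * x[px + hw * ch] * acc);
      }
    }
  }
}

static void backward_net(Net& net, std::map<std::string, Blob>& acts,
                         std::map<std::string, Blob>& grads) {
  for (int li = (int)net.layers.size() - 1; li >= 0; --li) {
    Layer& L = net.layers[li];
    if (grads.find(L.name) == grads.end()) continue;
    Blob& dout = grads[L.name];
    Blob& in = acts[L.bottom];
    Blob& din = grads[L.bottom];
    if (din.data.n_elem == 0) din.set(in.h, in.w, in.c, in.n);
    if (L.type == "conv") backward_conv(L, in, dout, din, L.bottom != "data");
    else if (L.type == "deconv") backward_deconv(L, in, dout, din);
    else if (L.type == "pool") {
      for (int sN = 0; sN < in.n; ++sN) {
        float* d = din.data.colptr(sN);
        const float* g = dout.data.colptr(sN);
        for (uword q = 0; q < L.pool_idx.n_rows; ++q)
          d[L.pool_idx(q, sN)] += g[q];
      }
    } else if (L.type == "relu") {
      const Blob& out = acts[L.name];
      din.data += dout.data % (out.data > 0);
    } else if (L.type == "lrn") {
      backward_lrn(L, in, acts[L.name], dout, din);
    } else if (L.type == "dropout") {
      if (L.drop_mask.n_elem == dout.data.n_elem)
        din.data += dout.data % L.drop_mask;
      else din.data += dout.data;
    } else if (L.type == "fc") {
      L.dW += dout.data * in.data.t();
      if (L.bias) L.db += arma::sum(dout.data, 1);
      din.data += L.W.t() * dout.data;
    } else if (L.type == "crop" || L.type == "fit") {
      backward_fit(L, in, dout, din);
    } else if (L.type == "eltwise") {
      din.data += dout.data;
      Blob& in2 = acts[L.bottom2];
      Blob& din2 = grads[L.bottom2];
      if (din2.data.n_elem == 0) din2.set(in2.h, in2.w, in2.c, in2.n);
      din2.data += dout.data;
    }
  }
}

// ---------------------------------------------------------------------------
// Losses (return mean loss over batch; fill gradient blob)

// classification: labels 0-based ints, one per sample
static double loss_softmax(const Blob& top, const IntegerVector& yb,
                           Blob& grad, IntegerVector* pred) {
  int nc = top.c, n = top.n;
  grad.set(1, 1, nc, n);
  double total = 0;
  for (int sN = 0; sN < n; ++sN) {
    const float* z = top.data.colptr(sN);
    float m = z[0];
    for (int c = 1; c < nc; ++c) m = std::max(m, z[c]);
    double den = 0;
    for (int c = 0; c < nc; ++c) den += std::exp((double)z[c] - m);
    int best = 0;
    for (int c = 1; c < nc; ++c) if (z[c] > z[best]) best = c;
    if (pred) (*pred)[sN] = best;
    int lab = yb[sN];
    double logp = (double)z[lab] - m - std::log(den);
    total += -logp;
    float* g = grad.data.colptr(sN);
    for (int c = 0; c < nc; ++c) {
      double p = std::exp((double)z[c] - m) / den;
      g[c] = (float)((p - (c == lab ? 1.0 : 0.0)) / n);
    }
  }
  return total / n;
}

// per-pixel weighted softmax; labels = list of IntegerMatrix (h x w)
static double loss_pixel_softmax(const Blob& top, const List& yb,
                                 const std::vector<double>& cw, Blob& grad,
                                 double* pix_acc) {
  int nc = top.c, n = top.n;
  uword hw = (uword)top.h * top.w;
  grad.set(top.h, top.w, nc, n);
  double total = 0; double correct = 0;
  std::vector<double> p(nc);
  for (int sN = 0; sN < n; ++sN) {
    IntegerMatrix lab = yb[sN];
    const float* z = top.data.colptr(sN);
    float* g = grad.data.colptr(sN);
    double wsum = 0;
    for (uword px = 0; px < hw; ++px)
      wsum += cw[lab[px]];
    double sloss = 0;
    for (uword px = 0; px < hw; ++px) {
      double m = z[px];
      for (int c = 1; c < nc; ++c) m = std::max(m, (double)z[px + hw * c]);
      double den = 0;
      for (int c = 0; c < nc; ++c) {
        p[c] = std::exp((double)z[px + hw * c] - m); den += p[c];
      }
      int best = 0;
      for (int c = 1; c < nc; ++c) if (p[c] > p[best]) best = c;
      int l = lab[px];
      if (best == l) correct += 1;
      double w = cw[l];
      sloss += -w * std::log(p[l] / den);
      for (int c = 0; c < nc; ++c)
        g[px + hw * c] =
            (float)(w * (p[c] / den - (c == l ? 1.0 : 0.0)) / wsum / n);
    }
    total += sloss / wsum;
  }
  if (pix_acc) *pix_acc = correct / ((double)hw * n);
  return total / n;
}

static double loss_euclidean(const Blob& top, const NumericVector& yb,
                             Blob& grad, NumericVector* pred) {
  int n = top.n;
  grad.set(1, 1, top.c, n);
  double total = 0;
  for (int sN = 0; sN < n; ++sN) {
    double d = (double)top.data(0, sN) - yb[sN];
    if (pred) (*pred)[sN] = top.data(0, sN);
    total += 0.5 * d * d;
    grad.data(0, sN) = (float)(d / n);
  }
  return total / n;
}

// ---------------------------------------------------------------------------
// Batching helpers

static Blob make_batch(const List& X, const std::vector<int>& idx) {
  NumericVector first = X[idx[0]];
  IntegerVector dim = first.attr("dim");
  int h = dim[0], w = dim[1], c = dim.size() > 2 ? dim[2] : 1;
  Blob b; b.set(h, w, c, (int)idx.size());
  // inputs are centred to [-1, 1] (images arrive on the [0, 1] scale)
  for (size_t s = 0; s < idx.size(); ++s) {
    NumericVector xi = X[idx[s]];
    float* d = b.data.colptr((uword)s);
    for (uword q = 0; q < (uword)h * w * c; ++q)
      d[q] = 2.0f * ((float)xi[q] - 0.5f);
  }
  return b;
}

static void zero_grads(Net& net) {
  for (auto& L : net.layers)
    if (L.has_weights) { L.dW.zeros(); if (L.bias) L.db.zeros(); }
}

static void sgd_step(Net& net, double lr, double momentum, double wd) {
  for (auto& L : net.layers) {
    if (!L.has_weights) continue;
    L.mW = (float)momentum * L.mW -
           (float)lr * (L.dW + (float)wd * L.W);
    L.W += L.mW;
    if (L.bias) {
      L.mb = (float)momentum * L.mb - (float)lr * L.db;  // no decay on biases
      L.b += L.mb;
    }
  }
}

static List export_weights(const Net& net, const List& weights_in) {
  List out = clone(weights_in);
  for (const auto& L : net.layers) {
    if (!L.has_weights) continue;
    List w = out[L.name.c_str()];
    NumericVector Wr = w["W"];
    IntegerVector dim = Wr.attr("dim");
    if (L.type == "conv") {
      int k = dim[0], cpg = dim[2], out_c = dim[3];
      for (int o = 0; o < out_c; ++o)
        for (int ch = 0; ch < cpg; ++ch)
          for (int kj = 0; kj < k; ++kj)
            for (int ki = 0; ki < k; ++ki)
              Wr[ki + (uword)k * kj + (uword)k * k * ch +
                 (uword)k * k * cpg * o] =
                  L.W(o, (uword)ch * k * k + kj * k + ki);
    } else if (L.type == "deconv") {
      int k = dim[0], out_c = dim[2], cin = dim[3];
      for (int ci = 0; ci < cin; ++ci)
        for (int o = 0; o < out_c; ++o)
          for (int kj = 0; kj < k; ++kj)
            for (int ki = 0; ki < k; ++ki)
              Wr[ki + (uword)k * kj + (uword)k * k * o +
                 (uword)k * k * out_c * ci] =
                  L.W((uword)o * k * k + kj * k + ki, ci);
    } else {
      int in = dim[0], out_c = dim[1];
      for (int o = 0; o < out_c; ++o)
        for (int i = 0; i < in; ++i) Wr[i + (uword)in * o] = L.W(o, i);
    }
    if (L.bias) {
      NumericVector br = w["b"];
      for (int i = 0; i < br.size(); ++i) br[i] = L.b[i];
    }
  }
  return out;
}

// evaluate loss/metric on a dataset without learning
static void eval_pass(Net& net, const List& X, SEXP y,
                      const std::string& loss_type,
                      const std::vector<double>& cw, int batch,
                      double* out_loss, double* out_metric) {
  int n = X.size();
  double total = 0, metric_acc = 0; int metric_n = 0;
  double se = 0;  // euclidean: squared error accumulator
  for (int start = 0; start < n; start += batch) {
    std::vector<int> idx;
    for (int i = start; i < std::min(n, start + batch); ++i) idx.push_back(i);
    Blob in = make_batch(X, idx);
    std::map<std::string, Blob> acts;
    acts["data"] = std::move(in);
    forward_net(net, acts, false);
    const Blob& top = acts[net.layers.back().name];
    Blob dummy;
    if (loss_type == "softmax") {
      IntegerVector yv(y);
      IntegerVector yb((int)idx.size()), pred((int)idx.size());
      for (size_t i = 0; i < idx.size(); ++i) yb[(int)i] = yv[idx[i]];
      total += loss_softmax(top, yb, dummy, &pred) * idx.size();
      for (size_t i = 0; i < idx.size(); ++i)
        if (pred[(int)i] == yb[(int)i]) metric_acc += 1;
      metric_n += (int)idx.size();
    } else if (loss_type == "pixel_softmax") {
      List yl(y);
      List yb((int)idx.size());
      for (size_t i = 0; i < idx.size(); ++i) yb[(int)i] = yl[idx[i]];
      double pa = 0;
      total += loss_pixel_softmax(top, yb, cw, dummy, &pa) * idx.size();
      metric_acc += pa * idx.size(); metric_n += (int)idx.size();
    } else {
      NumericVector yv(y);
      NumericVector yb((int)idx.size()), pred((int)idx.size());
      for (size_t i = 0; i < idx.size(); ++i) yb[(int)i] = yv[idx[i]];
      total += loss_euclidean(top, yb, dummy, &pred) * idx.size();
      for (size_t i = 0; i < idx.size(); ++i) {
        double d = pred[(int)i] - yb[(int)i]; se += d * d;
      }
      metric_n += (int)idx.size();
    }
  }
  *out_loss = total / n;
  *out_metric = (loss_type == "euclidean") ? std::sqrt(se / metric_n)
                                           : metric_acc / metric_n;
}

// ---------------------------------------------------------------------------
// Exported entry points

// [[Rcpp::export(name = ".cnn_train")]]
List cnn_train(List layers, List weights, List X, SEXP y, List Xval,
               SEXP yval, List cfg) {
  Net net = build_net(layers, weights);
  int epochs = as<int>(cfg["epochs"]);
  double lr0 = as<double>(cfg["lr"]);
  double momentum = as<double>(cfg["momentum"]);
  double gamma = as<double>(cfg["gamma"]);
  int step = as<int>(cfg["step_size"]);
  int batch = as<int>(cfg["batch_size"]);
  double wd = as<double>(cfg["weight_decay"]);
  std::string loss_type = as<std::string>(cfg["loss"]);
  std::vector<double> cw;
  if (cfg.containsElementNamed("class_weights") &&
      !Rf_isNull(cfg["class_weights"])) {
    NumericVector cwv = cfg["class_weights"];
    for (double v : cwv) cw.push_back(v);
  }
  int n = X.size();
  bool have_val = Xval.size() > 0;
  bool select_best = cfg.containsElementNamed("select_best") &&
                     as<bool>(cfg["select_best"]) && have_val;
  int eval_every = cfg.containsElementNamed("eval_every")
                       ? as<int>(cfg["eval_every"]) : 1;
  if (select_best) eval_every = 1;

  NumericVector tr_loss(epochs), te_loss(epochs), te_metric(epochs),
      lr_hist(epochs);
  double best_val = R_PosInf; int best_epoch = -1;
  std::vector<fmat> best_W; std::vector<fvec> best_b;
  GetRNGstate();
  for (int ep = 0; ep < epochs; ++ep) {
    double lr = lr0 * std::pow(gamma, (double)(ep / step));
    lr_hist[ep] = lr;
    // shuffle via R RNG (Fisher-Yates)
    std::vector<int> perm(n);
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    double ep_loss = 0; int nb = 0;
    for (int start = 0; start < n; start += batch) {
      std::vector<int> idx;
      for (int i = start; i < std::min(n, start + batch); ++i)
        idx.push_back(perm[i]);
      Blob in = make_batch(X, idx);
      std::map<std::string, Blob> acts;
      acts["data"] = std::move(in);
      forward_net(net, acts, true);
      const Blob& top = acts[net.layers.back().name];
      std::map<std::string, Blob> grads;
      Blob gtop;
      double l;
      if (loss_type == "softmax") {
        IntegerVector yv(y), yb((int)idx.size());
        for (size_t i = 0; i < idx.size(); ++i) yb[(int)i] = yv[idx[i]];
        l = loss_softmax(top, yb, gtop, nullptr);
      } else if (loss_type == "pixel_softmax") {
        List yl(y), yb((int)idx.size());
        for (size_t i = 0; i < idx.size(); ++i) yb[(int)i] = yl[idx[i]];
        l = loss_pixel_softmax(top, yb, cw, gtop, nullptr);
      } else {
        NumericVector yv(y), yb((int)idx.size());
        for (size_t i = 0; i < idx.size(); ++i) yb[(int)i] = yv[idx[i]];
        l = loss_euclidean(top, yb, gtop, nullptr);
      }
      ep_loss += l; nb++;
      zero_grads(net);
      grads[net.layers.back().name] = std::move(gtop);
      backward_net(net, acts, grads);
      sgd_step(net, lr, momentum, wd);
      Rcpp::checkUserInterrupt();
    }
    tr_loss[ep] = ep_loss / nb;
    if (have_val && ((ep + 1) % eval_every == 0 || ep == epochs - 1)) {
      double vl = 0, vm = 0;
      eval_pass(net, Xval, yval, loss_type, cw, batch, &vl, &vm);
      te_loss[ep] = vl; te_metric[ep] = vm;
      if (select_best && vl < best_val) {
        best_val = vl; best_epoch = ep;
        best_W.clear(); best_b.clear();
        for (auto& L : net.layers) {
          if (!L.has_weights) continue;
          best_W.push_back(L.W);
          best_b.push_back(L.bias ? L.b : fvec());
        }
      }
    } else {
      te_loss[ep] = NA_REAL; te_metric[ep] = NA_REAL;
    }
  }
  PutRNGstate();
  if (select_best && best_epoch >= 0) {
    size_t k = 0;
    for (auto& L : net.layers) {
      if (!L.has_weights) continue;
      L.W = best_W[k];
      if (L.bias) L.b = best_b[k];
      ++k;
    }
  }
  return List::create(
      _["best_epoch"] = best_epoch + 1,
      _["weights"] = export_weights(net, weights),
      _["curves"] = DataFrame::create(
          _["epoch"] = seq_len(epochs), _["lr"] = lr_hist,
          _["train_loss"] = tr_loss, _["test_loss"] = te_loss,
          _["test_metric"] = te_metric));
}

// forward a list of inputs, returning the activation of layer `upto`
// (or the top layer when upto == "") as a list of R arrays
// [[Rcpp::export(name = ".cnn_forward")]]
List cnn_forward(List layers, List weights, List X, std::string upto,
                 int batch_size) {
  Net net = build_net(layers, weights);
  std::string target = upto.empty() ? net.layers.back().name : upto;
  if (net.index.find(target) == net.index.end())
    stop("layer '%s' not found in network", target.c_str());
  int n = X.size();
  List out(n);
  for (int start = 0; start < n; start += batch_size) {
    std::vector<int> idx;
    for (int i = start; i < std::min(n, start + batch_size); ++i)
      idx.push_back(i);
    Blob in = make_batch(X, idx);
    std::map<std::string, Blob> acts;
    acts["data"] = std::move(in);
    forward_net(net, acts, false, target);
    const Blob& top = acts[target];
    for (size_t s = 0; s < idx.size(); ++s) {
      NumericVector a((uword)top.h * top.w * top.c);
      const float* d = top.data.colptr((uword)s);
      for (uword q = 0; q < a.size(); ++q) a[q] = d[q];
      a.attr("dim") = IntegerVector::create(top.h, top.w, top.c);
      out[idx[s]] = a;
    }
  }
  return out;
}

// numerical-vs-analytic gradient support: compute loss and weight gradients
// for a single batch (used by the finite-difference tests)
// [[Rcpp::export(name = ".cnn_loss_grad")]]
List cnn_loss_grad(List layers, List weights, List X, SEXP y,
                   std::string loss_type, Nullable<NumericVector> class_w) {
  Net net = build_net(layers, weights);
  std::vector<int> idx;
  for (int i = 0; i < X.size(); ++i) idx.push_back(i);
  Blob in = make_batch(X, idx);
  std::map<std::string, Blob> acts;
  acts["data"] = std::move(in);
  GetRNGstate();
  forward_net(net, acts, false);
  PutRNGstate();
  const Blob& top = acts[net.layers.back().name];
  std::vector<double> cw;
  if (class_w.isNotNull())
    for (double v : NumericVector(class_w)) cw.push_back(v);
  Blob gtop;
  double l;
  if (loss_type == "softmax") l = loss_softmax(top, IntegerVector(y), gtop,
                                               nullptr);
  else if (loss_type == "pixel_softmax")
    l = loss_pixel_softmax(top, List(y), cw, gtop, nullptr);
  else l = loss_euclidean(top, NumericVector(y), gtop, nullptr);
  zero_grads(net);
  std::map<std::string, Blob> grads;
  grads[net.layers.back().name] = std::move(gtop);
  backward_net(net, acts, grads);
  List gw;
  for (auto& L : net.layers) {
    if (!L.has_weights) continue;
    // export in the same flattened orientation used internally; the R test
    // reflattens its arrays the same way before comparing
    NumericMatrix dW(L.dW.n_rows, L.dW.n_cols);
    for (uword i = 0; i < L.dW.n_rows; ++i)
      for (uword j = 0; j < L.dW.n_cols; ++j) dW(i, j) = L.dW(i, j);
    List g = List::create(_["dW"] = dW);
    if (L.bias) {
      NumericVector db(L.db.n_elem);
      for (uword i = 0; i < L.db.n_elem; ++i) db[i] = L.db[i];
      g.push_back(db, "db");
    }
    gw.push_back(g, L.name);
  }
  return List::create(_["loss"] = l, _["grads"] = gw);
}
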