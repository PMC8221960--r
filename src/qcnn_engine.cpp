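// QCNN engine: forward and backward passes for the 5-block 1-D quantized
// CNN, fused in C++ to avoid interpreter allocation churn. Matrix products
// use BLAS through Armadillo. Semantics:
//   * activations are (B, P, C) cubes (batch fastest, Armadillo layout
//     matches R arrays);
//   * im2col matrices are (B*P) x (K*C), row b + B(p-1), column k + K(c-1);
//   * DoReFa quantizers: weights via tanh normalization (1-bit special case
//     sign(W)*mean|W|), activations clamp to [0,1] then project onto the
//     2^k-level grid; rounding is half away from zero;
//   * backward treats every quantizer as identity (straight-through
//     estimator); the activation clamp gates gradients outside [0,1];
//   * batch norm uses batch statistics in training and running statistics
//     in evaluation.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;

static const double BN_EPS = 1e-5;

static mat quant_weights_arma(const mat& W, int wb) {
  if (wb <= 0) return W; // full precision
  if (wb == 1) {
    double s = arma::mean(arma::mean(arma::abs(W)));
    return arma::sign(W) * s;
  }
  mat tw = arma::tanh(W);
  double m = arma::abs(tw).max();
  if (m == 0.0) return arma::zeros<mat>(W.n_rows, W.n_cols);
  double n = std::pow(2.0, wb) - 1.0;
  mat r = tw / (2.0 * m) + 0.5;
  r.transform([n](double v) { return std::floor(n * v + 0.5) / n; });
  return 2.0 * r - 1.0;
}

static cube quant_act_arma(const cube& A, int ab) {
  double n = std::pow(2.0, ab) - 1.0;
  cube out = A;
  out.transform([n](double v) {
    if (v < 0.0) v = 0.0;
    else if (v > 1.0) v = 1.0;
    return std::floor(n * v + 0.5) / n;
  });
  return out;
}

// gather (B, L, C) -> (B*P, K*C)
static mat im2col_arma(const cube& A, int K, int s, int P) {
  int B = A.n_rows, C = A.n_slices;
  mat M(B * P, K * C);
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < K; ++k) {
      double* mcol = M.colptr(k + K * c);
      for (int p = 0; p < P; ++p) {
        const double* src = A.slice_colptr(c, p * s + k);
        std::copy(src, src + B, mcol + (size_t)B * p);
      }
    }
  }
  return M;
}

// scatter-accumulate (B*P, K*C) -> (B, L, C)
static cube col2im_arma(const mat& dM, int B, int L, int C, int K, int s,
                        int P) {
  cube dA(B, L, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < K; ++k) {
      const double* mcol = dM.colptr(k + K * c);
      for (int p = 0; p < P; ++p) {
        double* dst = dA.slice_colptr(c, p * s + k);
        const double* src = mcol + (size_t)B * p;
        for (int b = 0; b < B; ++b) dst[b] += src[b];
      }
    }
  }
  return dA;
}

struct BlockPar {
  mat W;
  vec gamma, beta, run_mean, run_var;
  int kernel, stride, in_len, out_len, in_channels, filters;
  bool quantized;
};

struct BlockCache {
  cube A_pre;     // pre-quantization input (only when act-quantized)
  bool has_pre = false;
  mat M, W_eff, Xhat, R;
  vec inv_sd;
  int B;
};

static std::vector<BlockPar> read_blocks(const List& blocks) {
  std::vector<BlockPar> out;
  for (int i = 0; i < blocks.size(); ++i) {
    List b = blocks[i];
    BlockPar p;
    p.W = as<mat>(b["W"]);
    p.gamma = as<vec>(b["bn_gamma"]);
    p.beta = as<vec>(b["bn_beta"]);
    p.run_mean = as<vec>(b["bn_mean"]);
    p.run_var = as<vec>(b["bn_var"]);
    p.kernel = as<int>(b["kernel"]);
    p.stride = as<int>(b["stride"]);
    p.in_len = as<int>(b["in_len"]);
    p.out_len = as<int>(b["out_len"]);
    p.in_channels = as<int>(b["in_channels"]);
    p.filters = as<int>(b["filters"]);
    p.quantized = as<bool>(b["quantized"]);
    out.push_back(std::move(p));
  }
  return out;
}

// forward through the conv stack; fills caches when train-mode
static cube stack_forward(std::vector<BlockPar>& bp, const mat& X, int wb,
                          int ab, bool train, double momentum,
                          std::vector<BlockCache>* caches) {
  int B = X.n_rows;
  cube A(B, X.n_cols, 1);
  A.slice(0) = X;
  for (size_t i = 0; i < bp.size(); ++i) {
    BlockPar& bl = bp[i];
    BlockCache cc;
    cc.B = B;
    if (bl.quantized && ab > 0) {
      if (caches) { cc.A_pre = A; cc.has_pre = true; }
      A = quant_act_arma(A, ab);
    }
    mat M;
    if (bl.kernel == 1 && bl.stride == 1) {
      M = mat(A.memptr(), (size_t)B * bl.in_len, bl.in_channels);
    } else {
      M = im2col_arma(A, bl.kernel, bl.stride, bl.out_len);
    }
    mat W_eff = bl.quantized ? quant_weights_arma(bl.W, wb) : bl.W;
    mat Z = M * W_eff;
    int m = Z.n_rows, f = Z.n_cols;
    mat Xhat(m, f), R(m, f);
    vec inv_sd(f);
    for (int j = 0; j < f; ++j) {
      double mj, vj;
      const double* z = Z.colptr(j);
      if (train) {
        double s = 0.0;
        for (int t = 0; t < m; ++t) s += z[t];
        mj = s / m;
        double sv = 0.0;
        for (int t = 0; t < m; ++t) { double d = z[t] - mj; sv += d * d; }
        vj = sv / m;
        bl.run_mean[j] = (1.0 - momentum) * bl.run_mean[j] + momentum * mj;
        bl.run_var[j] = (1.0 - momentum) * bl.run_var[j] + momentum * vj;
      } else {
        mj = bl.run_mean[j];
        vj = bl.run_var[j];
      }
      double isd = 1.0 / std::sqrt(vj + BN_EPS);
      inv_sd[j] = isd;
      double g = bl.gamma[j], bt = bl.beta[j];
      double* xh = Xhat.colptr(j);
      double* r = R.colptr(j);
      for (int t = 0; t < m; ++t) {
        double x = (z[t] - mj) * isd;
        xh[t] = x;
        double y = g * x + bt;
        r[t] = y > 0.0 ? y : 0.0;
      }
    }
    if (caches) {
      cc.M = M; cc.W_eff = W_eff; cc.Xhat = Xhat; cc.R = R;
      cc.inv_sd = inv_sd;
      (*caches)[i] = std::move(cc);
    }
    A = cube(R.memptr(), B, bl.out_len, bl.filters);
  }
  return A;
}

// [[Rcpp::export]]
NumericVector qcnn_predict_cpp(List blocks, const arma::mat& X, int wb,
                               int ab, const arma::vec& head_w,
                               double head_b) {
  std::vector<BlockPar> bp = read_blocks(blocks);
  cube A = stack_forward(bp, X, wb, ab, false, 0.0, nullptr);
  int B = A.n_rows, P = A.n_cols, C = A.n_slices;
  mat G;
  if ((int)head_w.n_elem == C) {          // global-average-pool head
    G.set_size(B, C);
    for (int c = 0; c < C; ++c) G.col(c) = arma::mean(A.slice(c), 1);
  } else {                                // flatten head (per-position)
    G = mat(A.memptr(), B, (size_t)P * C);
  }
  vec pred = G * head_w + head_b;
  return wrap(pred);
}

// one training batch: forward with batch statistics, MSE loss, full
// backward with STE quantizer gradients. Returns loss, gradients and the
// updated batch-norm running statistics.
// [[Rcpp::export]]
List qcnn_train_batch(List blocks, const arma::mat& X, const arma::vec& y,
                      int wb, int ab, const arma::vec& head_w, double head_b,
                      double momentum) {
  std::vector<BlockPar> bp = read_blocks(blocks);
  int nb = bp.size();
  std::vector<BlockCache> caches(nb);
  cube A = stack_forward(bp, X, wb, ab, true, momentum, &caches);
  int B = A.n_rows, P = A.n_cols, C = A.n_slices;
  bool gap = (int)head_w.n_elem == C;
  mat G;
  if (gap) {
    G.set_size(B, C);
    for (int c = 0; c < C; ++c) G.col(c) = arma::mean(A.slice(c), 1);
  } else {
    G = mat(A.memptr(), B, (size_t)P * C);
  }
  vec pred = G * head_w + head_b;
  vec err = pred - y;
  double loss = arma::dot(err, err) / B;

  vec dpred = 2.0 * err / B;
  vec dWh = G.t() * dpred;
  double dbh = arma::accu(dpred);
  mat dG = dpred * head_w.t();          // (B, C) or (B, P*C)
  cube dA(B, P, C);
  if (gap) {
    for (int c = 0; c < C; ++c) {
      mat sl(B, P);
      sl.each_col() = dG.col(c) / P;
      dA.slice(c) = sl;
    }
  } else {
    dA = cube(dG.memptr(), B, P, C);
  }

  List grads(nb);
  for (int i = nb - 1; i >= 0; --i) {
    BlockPar& bl = bp[i];
    BlockCache& cc = caches[i];
    int m = (size_t)B * bl.out_len, f = bl.filters;
    mat dOut(dA.memptr(), m, f);        // (B*P, F)
    // fused ReLU + BN backward
    mat dZ(m, f);
    vec dgamma(f), dbeta(f);
    for (int j = 0; j < f; ++j) {
      const double* do_ = dOut.colptr(j);
      const double* r = cc.R.colptr(j);
      const double* xh = cc.Xhat.colptr(j);
      double s1 = 0.0, s2 = 0.0;
      double* dz = dZ.colptr(j);
      for (int t = 0; t < m; ++t) {
        double d = r[t] > 0.0 ? do_[t] : 0.0;
        dz[t] = d;                      // reuse as dY buffer
        s1 += d;
        s2 += d * xh[t];
      }
      dgamma[j] = s2;
      dbeta[j] = s1;
      double g = bl.gamma[j], isd = cc.inv_sd[j];
      double c1 = g * s1, c2 = g * s2;
      for (int t = 0; t < m; ++t) {
        dz[t] = isd / m * (m * g * dz[t] - c1 - xh[t] * c2);
      }
    }
    mat dW = cc.M.t() * dZ;             // STE: identity through W quantizer
    mat dM = dZ * cc.W_eff.t();
    if (bl.kernel == 1 && bl.stride == 1) {
      dA = cube(dM.memptr(), B, bl.in_len, bl.in_channels);
    } else {
      dA = col2im_arma(dM, B, bl.in_len, bl.in_channels, bl.kernel,
                       bl.stride, bl.out_len);
    }
    if (cc.has_pre) {
      // STE through the activation quantizer; clamp gate on [0, 1]
      const cube& ap = cc.A_pre;
      for (size_t t = 0; t < dA.n_elem; ++t) {
        double v = ap[t];
        if (v < 0.0 || v > 1.0) dA[t] = 0.0;
      }
    }
    grads[i] = List::create(_["dW"] = dW, _["dgamma"] = dgamma,
                            _["dbeta"] = dbeta);
  }

  List new_bn(nb);
  for (int i = 0; i < nb; ++i) {
    new_bn[i] = List::create(_["mean"] = bp[i].run_mean,
                             _["var"] = bp[i].run_var);
  }
  return List::create(_["loss"] = loss, _["pred"] = wrap(pred),
                      _["grads"] = grads, _["dWh"] = wrap(dWh),
                      _["dbh"] = dbh, _["bn"] = new_bn);
}
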