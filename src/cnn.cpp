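// 1D CNN for spectral classification: conv(kernel 3, same padding, tanh)
// stacks with valid max-pooling, a tanh fully connected layer and a softmax
// head, trained by mini-batch backpropagation with Adam.  Activations for a
// batch of B spectra of length L with C channels are stored as a C x (L*B)
// matrix (column j = b*L + p holds position p of sample b), so convolutions
// become one GEMM over an im2col expansion.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Net {
  std::vector<mat> convW;   // Cout x 3*Cin
  std::vector<vec> convB;
  mat fcW;  vec fcB;        // fc_width x flat
  mat outW; vec outB;       // n_class x fc_width
  ivec channels;            // Cout of each conv layer (length 2*blocks)
  int pool_size, pool_stride, input_len;
};

// lengths at the input of each block and the final flattened length
std::vector<int> block_lengths(const Net& net, int n_blocks) {
  std::vector<int> len(n_blocks + 1);
  len[0] = net.input_len;
  for (int k = 0; k < n_blocks; ++k)
    len[k + 1] = (len[k] - net.pool_size) / net.pool_stride + 1;
  return len;
}

// im2col for kernel length 3 with zero (same) padding
mat im2col3(const mat& A, int L, int B) {
  const int C = A.n_rows;
  mat K(3 * C, (uword)L * B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    int off = b * L;
    for (int p = 0; p < L; ++p) {
      if (p > 0)     K.submat(0,     off + p, C - 1,     off + p) = A.col(off + p - 1);
                     K.submat(C,     off + p, 2 * C - 1, off + p) = A.col(off + p);
      if (p < L - 1) K.submat(2 * C, off + p, 3 * C - 1, off + p) = A.col(off + p + 1);
    }
  }
  return K;
}

// scatter-add of the im2col gradient back onto the input activation grid
mat col2im3(const mat& dK, int L, int B) {
  const int C = dK.n_rows / 3;
  mat dA(C, (uword)L * B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    int off = b * L;
    for (int p = 0; p < L; ++p) {
      if (p > 0)     dA.col(off + p - 1) += dK.submat(0,     off + p, C - 1,     off + p);
                     dA.col(off + p)     += dK.submat(C,     off + p, 2 * C - 1, off + p);
      if (p < L - 1) dA.col(off + p + 1) += dK.submat(2 * C, off + p, 3 * C - 1, off + p);
    }
  }
  return dA;
}

void maxpool(const mat& A, int L, int B, int size, int stride,
             mat& P, umat& arg) {
  const int C = A.n_rows;
  const int Lo = (L - size) / stride + 1;
  P.set_size(C, (uword)Lo * B);
  arg.set_size(C, (uword)Lo * B);
  for (int b = 0; b < B; ++b) {
    for (int q = 0; q < Lo; ++q) {
      int in0 = b * L + q * stride, out = b * Lo + q;
      for (int c = 0; c < C; ++c) {
        double best = A(c, in0); int bi = 0;
        for (int k = 1; k < size; ++k)
          if (A(c, in0 + k) > best) { best = A(c, in0 + k); bi = k; }
        P(c, out) = best; arg(c, out) = bi;
      }
    }
  }
}

mat unpool(const mat& dP, const umat& arg, int L, int B, int size, int stride,
           int C) {
  const int Lo = (L - size) / stride + 1;
  mat dA(C, (uword)L * B, fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int q = 0; q < Lo; ++q) {
      int in0 = b * L + q * stride, out = b * Lo + q;
      for (int c = 0; c < C; ++c)
        dA(c, in0 + arg(c, out)) += dP(c, out);
    }
  return dA;
}

struct Cache {
  std::vector<mat> convK;   // im2col inputs per conv layer
  std::vector<mat> convA;   // tanh outputs per conv layer
  std::vector<mat> poolP;
  std::vector<umat> poolArg;
  mat F, H, Prob;           // flatten, fc hidden, softmax probabilities
};

// forward pass over a batch (columns of X); caches kept only if train
void forward(const Net& net, const mat& Xb, Cache& cc, bool keep) {
  const int B = Xb.n_cols, n_blocks = net.channels.n_elem / 2;
  std::vector<int> len = block_lengths(net, n_blocks);
  // input as 1 x (L*B)
  mat A(1, (uword)net.input_len * B);
  for (int b = 0; b < B; ++b)
    A.cols((uword)b * net.input_len, (uword)(b + 1) * net.input_len - 1) =
      Xb.col(b).t();
  cc.convK.clear(); cc.convA.clear(); cc.poolP.clear(); cc.poolArg.clear();
  int l = 0;
  for (int k = 0; k < n_blocks; ++k) {
    int L = len[k];
    for (int j = 0; j < 2; ++j, ++l) {
      mat K = im2col3(A, L, B);
      mat Z = net.convW[l] * K;
      Z.each_col() += net.convB[l];
      A = tanh(Z);
      if (keep) { cc.convK.push_back(std::move(K)); cc.convA.push_back(A); }
    }
    mat P; umat arg;
    maxpool(A, L, B, net.pool_size, net.pool_stride, P, arg);
    A = P;
    if (keep) { cc.poolP.push_back(std::move(P)); cc.poolArg.push_back(std::move(arg)); }
  }
  // flatten: per-sample block of Lo columns -> one column
  const int Lo = len[n_blocks], C = A.n_rows;
  mat F(C * Lo, B);
  for (int b = 0; b < B; ++b)
    F.col(b) = vectorise(A.cols((uword)b * Lo, (uword)(b + 1) * Lo - 1));
  mat H = tanh(net.fcW * F + repmat(net.fcB, 1, B));
  mat S = net.outW * H + repmat(net.outB, 1, B);
  S.each_row() -= max(S, 0);
  mat E = exp(S);
  cc.Prob = E.each_row() / sum(E, 0);
  cc.F = std::move(F);
  cc.H = std::move(H);
}

struct Adam {
  std::vector<mat> m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8, lr;
  long t = 0;
  void init(const std::vector<mat*>& params, double lr_) {
    lr = lr_;
    for (auto* p : params) {
      m.push_back(zeros<mat>(p->n_rows, p->n_cols));
      v.push_back(zeros<mat>(p->n_rows, p->n_cols));
    }
  }
  void step(const std::vector<mat*>& params, const std::vector<mat>& grads) {
    ++t;
    double c1 = 1.0 - std::pow(b1, (double)t);
    double c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t i = 0; i < params.size(); ++i) {
      m[i] = b1 * m[i] + (1 - b1) * grads[i];
      v[i] = b2 * v[i] + (1 - b2) * square(grads[i]);
      *params[i] -= lr * (m[i] / c1) / (sqrt(v[i] / c2) + eps);
    }
  }
};

Net unpack(const Rcpp::List& weights, const Rcpp::IntegerVector& channels,
           int pool_size, int pool_stride, int input_len) {
  Net net;
  Rcpp::List cw = weights["convW"], cb = weights["convB"];
  for (int i = 0; i < cw.size(); ++i) {
    net.convW.push_back(Rcpp::as<mat>(cw[i]));
    net.convB.push_back(Rcpp::as<vec>(cb[i]));
  }
  net.fcW = Rcpp::as<mat>(weights["fcW"]);
  net.fcB = Rcpp::as<vec>(weights["fcB"]);
  net.outW = Rcpp::as<mat>(weights["outW"]);
  net.outB = Rcpp::as<vec>(weights["outB"]);
  net.channels = Rcpp::as<ivec>(Rcpp::IntegerVector(channels));
  net.pool_size = pool_size; net.pool_stride = pool_stride;
  net.input_len = input_len;
  return net;
}

Rcpp::List pack(const Net& net) {
  Rcpp::List cw(net.convW.size()), cb(net.convB.size());
  for (size_t i = 0; i < net.convW.size(); ++i) {
    cw[i] = net.convW[i]; cb[i] = net.convB[i];
  }
  return Rcpp::List::create(
    Rcpp::Named("convW") = cw, Rcpp::Named("convB") = cb,
    Rcpp::Named("fcW") = net.fcW, Rcpp::Named("fcB") = net.fcB,
    Rcpp::Named("outW") = net.outW, Rcpp::Named("outB") = net.outB);
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(const arma::mat& X, const arma::ivec& y,
                         Rcpp::List weights, Rcpp::IntegerVector channels,
                         int pool_size, int pool_stride,
                         const arma::imat& order, int batch_size,
                         double lr) {
  Net net = unpack(weights, channels, pool_size, pool_stride, X.n_rows);
  const int n = X.n_cols, epochs = order.n_rows;
  const int n_class = net.outW.n_rows;
  const int n_blocks = net.channels.n_elem / 2;

  std::vector<mat*> params;
  std::vector<mat> convBm(net.convB.size());  // biases as 1-col mats
  for (size_t l = 0; l < net.convW.size(); ++l) params.push_back(&net.convW[l]);
  // hold bias vectors inside mats referenced by pointer
  std::vector<mat> biasStore;
  biasStore.reserve(net.convB.size() + 2);
  for (size_t l = 0; l < net.convB.size(); ++l)
    biasStore.push_back(mat(net.convB[l]));
  biasStore.push_back(mat(net.fcB));
  biasStore.push_back(mat(net.outB));
  for (auto& bmat : biasStore) params.push_back(&bmat);
  params.push_back(&net.fcW);
  params.push_back(&net.outW);

  Adam opt;
  opt.init(params, lr);

  vec epoch_loss(epochs, fill::zeros), epoch_acc(epochs, fill::zeros);
  Cache cc;
  for (int e = 0; e < epochs; ++e) {
    double loss_sum = 0; int correct = 0;
    for (int start = 0; start < n; start += batch_size) {
      int B = std::min(batch_size, n - start);
      mat Xb(X.n_rows, B);
      ivec yb(B);
      for (int b = 0; b < B; ++b) {
        int idx = order(e, start + b);
        Xb.col(b) = X.col(idx);
        yb(b) = y(idx);
      }
      // sync bias vectors from the Adam-updated storage
      for (size_t l = 0; l < net.convB.size(); ++l)
        net.convB[l] = biasStore[l].col(0);
      net.fcB = biasStore[net.convB.size()].col(0);
      net.outB = biasStore[net.convB.size() + 1].col(0);

      forward(net, Xb, cc, true);
      for (int b = 0; b < B; ++b) {
        loss_sum += -std::log(std::max(cc.Prob(yb(b), b), 1e-300));
        if ((int)index_max(cc.Prob.col(b)) == yb(b)) ++correct;
      }
      // backward
      mat dS = cc.Prob;
      for (int b = 0; b < B; ++b) dS(yb(b), b) -= 1.0;
      dS /= (double)B;
      mat doutW = dS * cc.H.t();
      mat doutB = sum(dS, 1);
      mat dH = net.outW.t() * dS;
      mat dZh = dH % (1 - square(cc.H));
      mat dfcW = dZh * cc.F.t();
      mat dfcB = sum(dZh, 1);
      mat dF = net.fcW.t() * dZh;

      std::vector<int> len = block_lengths(net, n_blocks);
      const int Lo = len[n_blocks];
      const int Ctop = net.channels(net.channels.n_elem - 1);
      mat dP(Ctop, (uword)Lo * B);
      for (int b = 0; b < B; ++b)
        dP.cols((uword)b * Lo, (uword)(b + 1) * Lo - 1) =
          reshape(dF.col(b), Ctop, Lo);

      std::vector<mat> dconvW(net.convW.size());
      std::vector<mat> dconvB(net.convB.size());
      mat dA;
      for (int k = n_blocks - 1; k >= 0; --k) {
        int L = len[k];
        dA = unpool(dP, cc.poolArg[k], L, B, net.pool_size, net.pool_stride,
                    net.channels(2 * k + 1));
        for (int j = 1; j >= 0; --j) {
          int l = 2 * k + j;
          mat dZ = dA % (1 - square(cc.convA[l]));
          dconvW[l] = dZ * cc.convK[l].t();
          dconvB[l] = sum(dZ, 1);
          if (l > 0) {
            mat dK = net.convW[l].t() * dZ;
            dA = col2im3(dK, L, B);
          }
        }
        if (k > 0) dP = dA;  // becomes the pooled-gradient of the block below
      }

      std::vector<mat> grads;
      for (size_t l = 0; l < net.convW.size(); ++l)
        grads.push_back(std::move(dconvW[l]));
      for (size_t l = 0; l < net.convB.size(); ++l)
        grads.push_back(std::move(dconvB[l]));
      grads.push_back(std::move(dfcB));
      grads.push_back(std::move(doutB));
      grads.push_back(std::move(dfcW));
      grads.push_back(std::move(doutW));
      opt.step(params, grads);
    }
    epoch_loss(e) = loss_sum / n;
    epoch_acc(e) = (double)correct / n;
    Rcpp::checkUserInterrupt();
  }
  // final bias sync
  for (size_t l = 0; l < net.convB.size(); ++l)
    net.convB[l] = biasStore[l].col(0);
  net.fcB = biasStore[net.convB.size()].col(0);
  net.outB = biasStore[net.convB.size() + 1].col(0);
  return Rcpp::List::create(
    Rcpp::Named("weights") = pack(net),
    Rcpp::Named("loss") = epoch_loss,
    Rcpp::Named("accuracy") = epoch_acc);
}

// [[Rcpp::export]]
arma::mat cnn_predict_cpp(const arma::mat& X, Rcpp::List weights,
                          Rcpp::IntegerVector channels, int pool_size,
                          int pool_stride, int batch_size) {
  Net net = unpack(weights, channels, pool_size, pool_stride, X.n_rows);
  const int n = X.n_cols, n_class = net.outW.n_rows;
  mat probs(n_class, n);
  Cache cc;
  for (int start = 0; start < n; start += batch_size) {
    int B = std::min(batch_size, n - start);
    forward(net, X.cols(start, start + B - 1), cc, false);
    probs.cols(start, start + B - 1) = cc.Prob;
  }
  return probs.t();
}
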