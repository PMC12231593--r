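// Fast path for the fixed four-conv CNN predictor.
//
// Layout: activations are (channels, positions, batch) cubes so every
// im2col column (one receptive field) is a contiguous memory block and all
// convolutions reduce to one gemm per layer. Training runs in single
// precision (the convention for deep-learning training); prediction and
// input gradients for sequence design run in double precision on the same
// weights.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

template <typename eT>
struct ConvLayer {
  Mat<eT> W;   // (k*Cin, Cout), row order channel-fastest within tap
  Col<eT> b;
  int k, pad, cin, cout;
};

template <typename eT>
struct CNNWeights {
  ConvLayer<eT> c1, c2, c3, c4;
  Col<eT> Wd;  // dense weights, flattened (channel-fastest) final maps
  eT bd;
};

template <typename eT>
static ConvLayer<eT> convFromList(const Rcpp::List& l, int k, int pad,
                                  int cin, int cout) {
  ConvLayer<eT> c;
  c.W = conv_to<Mat<eT>>::from(
      Rcpp::as<arma::mat>(l["W"]));
  c.b = conv_to<Col<eT>>::from(
      Rcpp::as<arma::vec>(l["b"]));
  c.k = k; c.pad = pad; c.cin = cin; c.cout = cout;
  return c;
}

template <typename eT>
static CNNWeights<eT> weightsFromR(const Rcpp::List& layers) {
  CNNWeights<eT> w;
  w.c1 = convFromList<eT>(layers["conv1"], 5, 2, 4, 100);
  w.c2 = convFromList<eT>(layers["conv2"], 5, 2, 100, 200);
  w.c3 = convFromList<eT>(layers["conv3"], 5, 2, 200, 200);
  w.c4 = convFromList<eT>(layers["conv4"], 5, 2, 200, 5);
  Rcpp::List dense = layers["dense"];
  w.Wd = conv_to<Col<eT>>::from(
      Rcpp::as<arma::vec>(Rcpp::as<Rcpp::NumericMatrix>(dense["W"])));
  Rcpp::NumericVector bd = dense["b"];
  w.bd = static_cast<eT>(bd[0]);
  return w;
}

// pad + im2col for a batch: X (Cin, L, B) -> M (k*Cin, L*B)
template <typename eT>
static void im2col(const Cube<eT>& X, int k, int pad, Mat<eT>& M) {
  const int C = X.n_rows, L = X.n_cols, B = X.n_slices, Lp = L + 2 * pad;
  M.set_size(k * C, L * B);
  Mat<eT> Xp(C, Lp);
  for (int b = 0; b < B; ++b) {
    Xp.zeros();
    Xp.cols(pad, pad + L - 1) = X.slice(b);
    for (int l = 0; l < L; ++l)
      std::memcpy(M.colptr((uword)b * L + l), Xp.colptr(l), sizeof(eT) * k * C);
  }
}

// scatter-add dM (k*Cin, L*B) back to dX (Cin, L, B)
template <typename eT>
static void col2im(const Mat<eT>& dM, int k, int pad, Cube<eT>& dX) {
  const int C = dX.n_rows, L = dX.n_cols, B = dX.n_slices, Lp = L + 2 * pad;
  Mat<eT> dXp(C, Lp);
  for (int b = 0; b < B; ++b) {
    dXp.zeros();
    for (int l = 0; l < L; ++l) {
      eT* dst = dXp.colptr(l);
      const eT* src = dM.colptr((uword)b * L + l);
      for (int j = 0; j < k * C; ++j) dst[j] += src[j];
    }
    dX.slice(b) = dXp.cols(pad, pad + L - 1);
  }
}

// forward conv + ReLU; Y (Cout, L, B); M kept for the backward pass
template <typename eT>
static void convFwd(const ConvLayer<eT>& c, const Cube<eT>& X,
                    Mat<eT>& M, Cube<eT>& Y) {
  const int L = X.n_cols, B = X.n_slices;
  im2col(X, c.k, c.pad, M);
  Mat<eT> Ym = c.W.t() * M;               // (Cout, L*B)
  Ym.each_col() += c.b;
  Ym.transform([](eT v) { return v > eT(0) ? v : eT(0); });
  Y = Cube<eT>(Ym.memptr(), c.cout, L, B);
}

// backward through ReLU + conv; dY modified in place by the ReLU mask
template <typename eT>
static void convBwd(const ConvLayer<eT>& c, const Mat<eT>& M,
                    const Cube<eT>& Y, Cube<eT>& dY,
                    Mat<eT>& dW, Col<eT>& db, Cube<eT>* dX) {
  const int L = dY.n_cols, B = dY.n_slices;
  for (uword i = 0; i < dY.n_elem; ++i)
    if (Y.mem[i] <= eT(0)) dY.memptr()[i] = eT(0);
  Mat<eT> dYm(dY.memptr(), c.cout, (uword)L * B, false, true);
  dW = M * dYm.t();
  db = sum(dYm, 1);
  if (dX) {
    Mat<eT> dM = c.W * dYm;
    dX->set_size(c.cin, L, B);
    col2im(dM, c.k, c.pad, *dX);
  }
}

// maxpool width 2, stride 2, drop trailing odd position
template <typename eT>
static void pool2Fwd(const Cube<eT>& X, Cube<eT>& Y) {
  const int C = X.n_rows, L2 = X.n_cols / 2, B = X.n_slices;
  Y.set_size(C, L2, B);
  for (int b = 0; b < B; ++b)
    for (int l = 0; l < L2; ++l) {
      const eT* a = X.slice(b).colptr(2 * l);
      const eT* c2 = X.slice(b).colptr(2 * l + 1);
      eT* y = Y.slice(b).colptr(l);
      for (int c = 0; c < C; ++c) y[c] = a[c] >= c2[c] ? a[c] : c2[c];
    }
}

template <typename eT>
static void pool2Bwd(const Cube<eT>& X, const Cube<eT>& dY, Cube<eT>& dX) {
  const int C = X.n_rows, L2 = dY.n_cols, B = X.n_slices;
  dX.set_size(C, X.n_cols, B);
  dX.zeros();
  for (int b = 0; b < B; ++b)
    for (int l = 0; l < L2; ++l) {
      const eT* a = X.slice(b).colptr(2 * l);
      const eT* c2 = X.slice(b).colptr(2 * l + 1);
      const eT* g = dY.slice(b).colptr(l);
      eT* d1 = dX.slice(b).colptr(2 * l);
      eT* d2 = dX.slice(b).colptr(2 * l + 1);
      for (int c = 0; c < C; ++c) {
        if (a[c] >= c2[c]) d1[c] = g[c]; else d2[c] = g[c];
      }
    }
}

template <typename eT>
struct FwdState {
  Mat<eT> M1, M2, M3, M4;
  Cube<eT> A1, A2, P1, A3, A4, P2;
  Col<eT> pred;
};

template <typename eT>
static void cnnForward(const CNNWeights<eT>& w, const Cube<eT>& X,
                       FwdState<eT>& s) {
  convFwd(w.c1, X, s.M1, s.A1);
  convFwd(w.c2, s.A1, s.M2, s.A2);
  pool2Fwd(s.A2, s.P1);
  convFwd(w.c3, s.P1, s.M3, s.A3);
  convFwd(w.c4, s.A3, s.M4, s.A4);
  pool2Fwd(s.A4, s.P2);
  const int B = X.n_slices;
  const uword F = s.P2.n_rows * s.P2.n_cols;
  s.pred.set_size(B);
  Mat<eT> flat(s.P2.memptr(), F, B, false, true);
  s.pred = flat.t() * w.Wd;
  s.pred += w.bd;
}

template <typename eT>
struct Grads {
  Mat<eT> dW1, dW2, dW3, dW4;
  Col<eT> db1, db2, db3, db4;
  Col<eT> dWd; eT dbd;
  Cube<eT> dX;
};

template <typename eT>
static void cnnBackward(const CNNWeights<eT>& w, const Cube<eT>& X,
                        const FwdState<eT>& s, const Col<eT>& dPred,
                        Grads<eT>& g, bool wantInputGrad) {
  const int B = X.n_slices;
  const uword F = s.P2.n_rows * s.P2.n_cols;
  Mat<eT> flat(const_cast<eT*>(s.P2.memptr()), F, B, false, true);
  g.dWd = flat * dPred;
  g.dbd = accu(dPred);
  Mat<eT> dFlat = w.Wd * dPred.t();       // (F, B)
  Cube<eT> dP2(dFlat.memptr(), s.P2.n_rows, s.P2.n_cols, B);
  Cube<eT> dA4;
  pool2Bwd(s.A4, dP2, dA4);
  Cube<eT> dA3;
  convBwd(w.c4, s.M4, s.A4, dA4, g.dW4, g.db4, &dA3);
  Cube<eT> dP1;
  convBwd(w.c3, s.M3, s.A3, dA3, g.dW3, g.db3, &dP1);
  Cube<eT> dA2;
  pool2Bwd(s.A2, dP1, dA2);
  Cube<eT> dA1;
  convBwd(w.c2, s.M2, s.A2, dA2, g.dW2, g.db2, &dA1);
  convBwd(w.c1, s.M1, s.A1, dA1, g.dW1, g.db1,
          wantInputGrad ? &g.dX : nullptr);
}

// R array [B, L, 4] -> cube (4, L, B)
template <typename eT>
static Cube<eT> encFromR(const Rcpp::NumericVector& Xr) {
  Rcpp::IntegerVector d = Xr.attr("dim");
  const int B = d[0], L = d[1], C = d[2];
  Cube<eT> X(C, L, B);
  const double* p = Xr.begin();
  for (int c = 0; c < C; ++c)
    for (int l = 0; l < L; ++l)
      for (int b = 0; b < B; ++b)
        X(c, l, b) = static_cast<eT>(p[(size_t)c * L * B + (size_t)l * B + b]);
  return X;
}

// cube (C, L, B) -> R array [B, L, C]
template <typename eT>
static Rcpp::NumericVector cubeToR(const Cube<eT>& X) {
  const int C = X.n_rows, L = X.n_cols, B = X.n_slices;
  Rcpp::NumericVector out((size_t)B * L * C);
  out.attr("dim") = Rcpp::IntegerVector::create(B, L, C);
  double* p = out.begin();
  for (int c = 0; c < C; ++c)
    for (int l = 0; l < L; ++l)
      for (int b = 0; b < B; ++b)
        p[(size_t)c * L * B + (size_t)l * B + b] = X(c, l, b);
  return out;
}

// [[Rcpp::export(name = ".cnnForwardCpp")]]
Rcpp::List cnnForwardCpp(Rcpp::NumericVector Xr, Rcpp::List layers,
                         bool keepFeatures = false) {
  CNNWeights<double> w = weightsFromR<double>(layers);
  Cube<double> X = encFromR<double>(Xr);
  FwdState<double> s;
  cnnForward(w, X, s);
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("pred") = Rcpp::NumericVector(s.pred.begin(), s.pred.end()));
  if (keepFeatures) {
    out["conv1"] = cubeToR(s.A1);
    out["conv2"] = cubeToR(s.A2);
    out["conv3"] = cubeToR(s.A3);
    out["conv4"] = cubeToR(s.A4);
  }
  return out;
}

// [[Rcpp::export(name = ".cnnGradCpp")]]
Rcpp::List cnnGradCpp(Rcpp::NumericVector Xr, Rcpp::List layers,
                      Rcpp::NumericVector dPred, bool inputGrad = true) {
  CNNWeights<double> w = weightsFromR<double>(layers);
  Cube<double> X = encFromR<double>(Xr);
  FwdState<double> s;
  cnnForward(w, X, s);
  Grads<double> g;
  Col<double> dp(dPred.begin(), dPred.size());
  cnnBackward(w, X, s, dp, g, inputGrad);
  auto mat2r = [](const Mat<double>& m) {
    return Rcpp::NumericMatrix(m.n_rows, m.n_cols, m.begin());
  };
  Rcpp::List grads = Rcpp::List::create(
      Rcpp::Named("conv1") = Rcpp::List::create(
          Rcpp::Named("W") = mat2r(g.dW1),
          Rcpp::Named("b") = Rcpp::NumericVector(g.db1.begin(), g.db1.end())),
      Rcpp::Named("conv2") = Rcpp::List::create(
          Rcpp::Named("W") = mat2r(g.dW2),
          Rcpp::Named("b") = Rcpp::NumericVector(g.db2.begin(), g.db2.end())),
      Rcpp::Named("conv3") = Rcpp::List::create(
          Rcpp::Named("W") = mat2r(g.dW3),
          Rcpp::Named("b") = Rcpp::NumericVector(g.db3.begin(), g.db3.end())),
      Rcpp::Named("conv4") = Rcpp::List::create(
          Rcpp::Named("W") = mat2r(g.dW4),
          Rcpp::Named("b") = Rcpp::NumericVector(g.db4.begin(), g.db4.end())),
      Rcpp::Named("dense") = Rcpp::List::create(
          Rcpp::Named("W") = Rcpp::NumericMatrix(g.dWd.n_elem, 1,
                                                 g.dWd.begin()),
          Rcpp::Named("b") = Rcpp::NumericVector::create(g.dbd)));
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("pred") = Rcpp::NumericVector(s.pred.begin(), s.pred.end()),
      Rcpp::Named("grads") = grads);
  if (inputGrad) out["dX"] = cubeToR(g.dX);
  return out;
}

// deterministic Fisher-Yates on [0, n)
static void shuffleIdx(std::vector<int>& idx, std::mt19937& rng) {
  for (int i = (int)idx.size() - 1; i > 0; --i) {
    int j = (int)(rng() % (uint32_t)(i + 1));
    std::swap(idx[i], idx[j]);
  }
}

// [[Rcpp::export(name = ".cnnTrainCpp")]]
Rcpp::List cnnTrainCpp(Rcpp::NumericVector Xr, Rcpp::NumericVector y,
                       Rcpp::NumericVector valXr, Rcpp::NumericVector valy,
                       Rcpp::List layers, int epochs, int batch,
                       double lr, double decay, double momentum,
                       int patience, int seed) {
  typedef float eT;
  CNNWeights<eT> w = weightsFromR<eT>(layers);
  Cube<eT> X = encFromR<eT>(Xr);
  Cube<eT> VX = encFromR<eT>(valXr);
  Col<eT> yv = conv_to<Col<eT>>::from(
      Rcpp::as<arma::vec>(y));
  Col<eT> vy = conv_to<Col<eT>>::from(
      Rcpp::as<arma::vec>(valy));
  const int n = X.n_slices;

  // momentum buffers
  Mat<eT> v1(size(w.c1.W), fill::zeros), v2(size(w.c2.W), fill::zeros),
      v3(size(w.c3.W), fill::zeros), v4(size(w.c4.W), fill::zeros);
  Col<eT> vb1(w.c1.b.n_elem, fill::zeros), vb2(w.c2.b.n_elem, fill::zeros),
      vb3(w.c3.b.n_elem, fill::zeros), vb4(w.c4.b.n_elem, fill::zeros),
      vd(w.Wd.n_elem, fill::zeros);
  eT vbd = 0;

  std::mt19937 rng((uint32_t)seed);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;

  double bestVal = datum::inf;
  CNNWeights<eT> best = w;
  int bestEpoch = 0, wait = 0, iter = 0, epochsRun = 0;
  std::vector<double> trainLog, valLog;
  FwdState<eT> s;
  Grads<eT> g;
  Cube<eT> Xb;

  for (int ep = 1; ep <= epochs; ++ep) {
    shuffleIdx(ord, rng);
    double trLoss = 0;
    for (int start = 0; start < n; start += batch) {
      int bs = std::min(batch, n - start);
      Xb.set_size(X.n_rows, X.n_cols, bs);
      Col<eT> yb(bs);
      for (int i = 0; i < bs; ++i) {
        Xb.slice(i) = X.slice(ord[start + i]);
        yb[i] = yv[ord[start + i]];
      }
      cnnForward(w, Xb, s);
      Col<eT> err = s.pred - yb;
      trLoss += accu(square(err));
      Col<eT> dPred = (eT(2) / bs) * err;
      cnnBackward(w, Xb, s, dPred, g, false);
      eT lrT = (eT)(lr / (1.0 + decay * iter));
      ++iter;
      eT mom = (eT)momentum;
      v1 = mom * v1 - lrT * g.dW1;  w.c1.W += v1;
      vb1 = mom * vb1 - lrT * g.db1; w.c1.b += vb1;
      v2 = mom * v2 - lrT * g.dW2;  w.c2.W += v2;
      vb2 = mom * vb2 - lrT * g.db2; w.c2.b += vb2;
      v3 = mom * v3 - lrT * g.dW3;  w.c3.W += v3;
      vb3 = mom * vb3 - lrT * g.db3; w.c3.b += vb3;
      v4 = mom * v4 - lrT * g.dW4;  w.c4.W += v4;
      vb4 = mom * vb4 - lrT * g.db4; w.c4.b += vb4;
      vd = mom * vd - lrT * g.dWd;  w.Wd += vd;
      vbd = mom * vbd - lrT * g.dbd; w.bd += vbd;
    }
    // validation pass (chunked to bound memory)
    double valLoss = 0;
    const int vb = 256;
    for (int start = 0; start < (int)VX.n_slices; start += vb) {
      int bs = std::min(vb, (int)VX.n_slices - start);
      Cube<eT> Vb = VX.slices(start, start + bs - 1);
      cnnForward(w, Vb, s);
      valLoss += accu(square(s.pred - vy.subvec(start, start + bs - 1)));
    }
    valLoss /= VX.n_slices;
    trainLog.push_back(trLoss / n);
    valLog.push_back(valLoss);
    epochsRun = ep;
    if (valLoss < bestVal - 1e-9) {
      bestVal = valLoss;
      best = w;
      bestEpoch = ep;
      wait = 0;
    } else if (++wait >= patience) break;
    Rcpp::checkUserInterrupt();
  }

  auto mat2r = [](const Mat<eT>& m) {
    Rcpp::NumericMatrix r(m.n_rows, m.n_cols);
    for (uword i = 0; i < m.n_elem; ++i) r[i] = m.mem[i];
    return r;
  };
  auto vec2r = [](const Col<eT>& v) {
    Rcpp::NumericVector r(v.n_elem);
    for (uword i = 0; i < v.n_elem; ++i) r[i] = v.mem[i];
    return r;
  };
  Rcpp::List outLayers = Rcpp::clone(layers);
  Rcpp::List l1 = outLayers["conv1"]; l1["W"] = mat2r(best.c1.W);
  l1["b"] = vec2r(best.c1.b);
  Rcpp::List l2 = outLayers["conv2"]; l2["W"] = mat2r(best.c2.W);
  l2["b"] = vec2r(best.c2.b);
  Rcpp::List l3 = outLayers["conv3"]; l3["W"] = mat2r(best.c3.W);
  l3["b"] = vec2r(best.c3.b);
  Rcpp::List l4 = outLayers["conv4"]; l4["W"] = mat2r(best.c4.W);
  l4["b"] = vec2r(best.c4.b);
  Rcpp::List ld = outLayers["dense"];
  Rcpp::NumericMatrix Wd(best.Wd.n_elem, 1);
  for (uword i = 0; i < best.Wd.n_elem; ++i) Wd[i] = best.Wd[i];
  ld["W"] = Wd;
  ld["b"] = Rcpp::NumericVector::create((double)best.bd);

  return Rcpp::List::create(
      Rcpp::Named("layers") = outLayers,
      Rcpp::Named("train_mse") = trainLog,
      Rcpp::Named("val_mse") = valLog,
      Rcpp::Named("bestEpoch") = bestEpoch,
      Rcpp::Named("bestValMSE") = bestVal,
      Rcpp::Named("epochsRun") = epochsRun);
}
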