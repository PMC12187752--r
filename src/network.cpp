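// Forward and backward pass of the dense convolutional network with
// residual channel attention, operating on batches of encoded peptide
// windows.  Activations are stored as C x (L*N) matrices (channels by
// positions, samples laid out in contiguous column blocks of width L),
// which keeps every layer a handful of BLAS calls.
//
// Parameter vector layout (must match param_layout() on the R side):
//   for block b = 1..B:
//     for layer l = 1..layers_per_block:
//       bn.gamma(C), bn.beta(C), conv.W(g x C*k), conv.b(g)     [C grows by g]
//     if b < B: trans.bn.gamma(C), trans.bn.beta(C),
//               trans.W(Cout x C), trans.b(Cout)                [C -> Cout, L -> L/2]
//   attention (cam/rcam): W1(h x C), b1(h), W2(C x h), b2(C)
//   head: for each fc width h: W(h x D), b(h); final W(2 x D), b(2)
// Conv weight columns are ordered tap-major: column t*C + c holds the
// weight for input channel c at kernel tap t (tap shift = t - pad).
// State vector: running mean(C), running var(C) for each BN in the same
// order as the parameters.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static const double BN_EPS = 1e-5;

struct NetCfg {
  int n_blocks, layers_per_block, growth, kernel, rr, C0, L0;
  int att;  // 0 none, 1 cam, 2 rcam
  double compression, dropout;
  std::vector<int> fc;
};

static NetCfg parse_cfg(const List& cfg) {
  NetCfg c;
  c.n_blocks = as<int>(cfg["n_blocks"]);
  c.layers_per_block = as<int>(cfg["layers_per_block"]);
  c.growth = as<int>(cfg["growth_rate"]);
  c.kernel = as<int>(cfg["kernel_size"]);
  c.compression = as<double>(cfg["compression"]);
  std::string a = as<std::string>(cfg["attention"]);
  c.att = (a == "rcam") ? 2 : (a == "cam" ? 1 : 0);
  c.rr = as<int>(cfg["reduction_ratio"]);
  IntegerVector fc = cfg["fc_sizes"];
  for (int i = 0; i < fc.size(); i++) c.fc.push_back(fc[i]);
  c.dropout = as<double>(cfg["dropout"]);
  c.C0 = as<int>(cfg["input_channels"]);
  c.L0 = as<int>(cfg["input_length"]);
  return c;
}

static int trans_channels(double compression, int C) {
  return (int)std::ceil(compression * (double)C - 1e-9);
}

// sequential reader over the flat parameter vector, recording offsets
struct Reader {
  const vec& v;
  uword pos;
  explicit Reader(const vec& v_) : v(v_), pos(0) {}
  mat M(uword r, uword c, uword& off) {
    off = pos;
    mat m(r, c);
    std::memcpy(m.memptr(), v.memptr() + pos, sizeof(double) * r * c);
    pos += r * c;
    return m;
  }
  vec V(uword n, uword& off) {
    off = pos;
    vec x(n);
    std::memcpy(x.memptr(), v.memptr() + pos, sizeof(double) * n);
    pos += n;
    return x;
  }
};

struct BNc {
  vec gamma, beta;
  uword og, ob, os;
  vec invstd;
  mat xhat;
};

struct ConvC {
  mat W;
  vec b;
  uword oW, ob;
  mat cols;  // im2col'ed input, saved for the weight gradient
  int Cin, Cout, k, L, N;
};

struct DenseL { BNc bn; mat act; ConvC cv; };
struct TransC { BNc bn; ConvC cv; int Lin; };
struct AttnC {
  mat F;
  int L, N, h;
  bool rcam;
  mat A, Mx, U, Um, mc, mr, w;
  umat idx;
  mat W1, W2;
  vec b1, b2;
  uword o1, ob1, o2, ob2;
};
struct FCc {
  mat W;
  vec b;
  uword oW, ob;
  mat X, mask, out;
  bool relu;
};

static mat bn_forward(const mat& X, BNc& bn, bool training, vec& state, double mom) {
  uword C = bn.gamma.n_elem;
  if (training) {
    vec mu = mean(X, 1);
    mat cent = X;
    cent.each_col() -= mu;
    vec var = mean(square(cent), 1);
    state.subvec(bn.os, bn.os + C - 1) =
        (1.0 - mom) * state.subvec(bn.os, bn.os + C - 1) + mom * mu;
    state.subvec(bn.os + C, bn.os + 2 * C - 1) =
        (1.0 - mom) * state.subvec(bn.os + C, bn.os + 2 * C - 1) + mom * var;
    bn.invstd = 1.0 / sqrt(var + BN_EPS);
    cent.each_col() %= bn.invstd;
    bn.xhat = cent;
  } else {
    vec rm = state.subvec(bn.os, bn.os + C - 1);
    vec rv = state.subvec(bn.os + C, bn.os + 2 * C - 1);
    bn.invstd = 1.0 / sqrt(rv + BN_EPS);
    mat cent = X;
    cent.each_col() -= rm;
    cent.each_col() %= bn.invstd;
    bn.xhat = cent;
  }
  mat Y = bn.xhat;
  Y.each_col() %= bn.gamma;
  Y.each_col() += bn.beta;
  return Y;
}

// training-mode BN backward (batch statistics)
static mat bn_backward(const mat& dY, const BNc& bn, vec& g) {
  uword C = bn.gamma.n_elem;
  double m = (double)dY.n_cols;
  g.subvec(bn.og, bn.og + C - 1) += sum(dY % bn.xhat, 1);
  g.subvec(bn.ob, bn.ob + C - 1) += sum(dY, 1);
  mat dxhat = dY;
  dxhat.each_col() %= bn.gamma;
  vec s1 = sum(dxhat, 1) / m;
  vec s2 = sum(dxhat % bn.xhat, 1) / m;
  mat dX = dxhat;
  dX.each_col() -= s1;
  dX -= bn.xhat.each_col() % s2;
  dX.each_col() %= bn.invstd;
  return dX;
}

static mat im2col(const mat& X, int L, int N, int k) {
  int C = X.n_rows;
  int pad = (k - 1) / 2;
  mat cols(C * k, (uword)L * N, fill::zeros);
  for (int t = 0; t < k; t++) {
    int sh = t - pad;
    int p0 = std::max(0, -sh), p1 = std::min(L, L - sh);
    if (p1 <= p0) continue;
    for (int n = 0; n < N; n++) {
      cols.submat(t * C, (uword)n * L + p0, (t + 1) * C - 1, (uword)n * L + p1 - 1) =
          X.cols((uword)n * L + p0 + sh, (uword)n * L + p1 - 1 + sh);
    }
  }
  return cols;
}

static mat col2im(const mat& dcols, int C, int L, int N, int k) {
  int pad = (k - 1) / 2;
  mat dX(C, (uword)L * N, fill::zeros);
  for (int t = 0; t < k; t++) {
    int sh = t - pad;
    int p0 = std::max(0, -sh), p1 = std::min(L, L - sh);
    if (p1 <= p0) continue;
    for (int n = 0; n < N; n++) {
      dX.cols((uword)n * L + p0 + sh, (uword)n * L + p1 - 1 + sh) +=
          dcols.submat(t * C, (uword)n * L + p0, (t + 1) * C - 1, (uword)n * L + p1 - 1);
    }
  }
  return dX;
}

static mat conv_forward(const mat& X, ConvC& cv) {
  cv.cols = im2col(X, cv.L, cv.N, cv.k);
  mat Y = cv.W * cv.cols;
  Y.each_col() += cv.b;
  return Y;
}

static mat conv_backward(const mat& dY, const ConvC& cv, vec& g) {
  mat dW = dY * cv.cols.t();
  vec db = sum(dY, 1);
  g.subvec(cv.oW, cv.oW + dW.n_elem - 1) += vectorise(dW);
  g.subvec(cv.ob, cv.ob + db.n_elem - 1) += db;
  mat dcols = cv.W.t() * dY;
  return col2im(dcols, cv.Cin, cv.L, cv.N, cv.k);
}

static mat avgpool2(const mat& X, int L, int N) {
  int C = X.n_rows, Lo = L / 2;
  mat Y(C, (uword)Lo * N);
  for (int n = 0; n < N; n++)
    for (int p = 0; p < Lo; p++)
      Y.col((uword)n * Lo + p) =
          0.5 * (X.col((uword)n * L + 2 * p) + X.col((uword)n * L + 2 * p + 1));
  return Y;
}

static mat avgpool2_backward(const mat& dY, int L, int N) {
  int C = dY.n_rows, Lo = L / 2;
  mat dX(C, (uword)L * N, fill::zeros);
  for (int n = 0; n < N; n++)
    for (int p = 0; p < Lo; p++) {
      dX.col((uword)n * L + 2 * p) = 0.5 * dY.col((uword)n * Lo + p);
      dX.col((uword)n * L + 2 * p + 1) = 0.5 * dY.col((uword)n * Lo + p);
    }
  return dX;
}

static mat sigmoid_m(const mat& X) { return 1.0 / (1.0 + exp(-X)); }

// [[Rcpp::export]]
List net_run_cpp(const arma::vec& params, const arma::vec& state0,
                 const arma::mat& X0, int N, const Rcpp::IntegerVector& y,
                 const Rcpp::List& cfgList, bool training, bool want_grad,
                 const Rcpp::List& dropmasks, double momentum) {
  NetCfg cfg = parse_cfg(cfgList);
  vec state = state0;
  Reader rd(params);

  int C = cfg.C0, L = cfg.L0;
  mat X = X0;

  std::vector<std::vector<DenseL> > blocks(cfg.n_blocks);
  std::vector<TransC> trans(std::max(cfg.n_blocks - 1, 0));
  AttnC at;
  std::vector<FCc> fcs;

  std::vector<std::string> stage_names;
  std::vector<int> stage_C, stage_L;
  stage_names.push_back("input"); stage_C.push_back(C); stage_L.push_back(L);

  // dense blocks with transitions
  for (int b = 0; b < cfg.n_blocks; b++) {
    blocks[b].resize(cfg.layers_per_block);
    for (int l = 0; l < cfg.layers_per_block; l++) {
      DenseL& dl = blocks[b][l];
      dl.bn.gamma = rd.V(C, dl.bn.og);
      dl.bn.beta = rd.V(C, dl.bn.ob);
      dl.cv.W = rd.M(cfg.growth, (uword)C * cfg.kernel, dl.cv.oW);
      dl.cv.b = rd.V(cfg.growth, dl.cv.ob);
      dl.cv.Cin = C; dl.cv.Cout = cfg.growth; dl.cv.k = cfg.kernel;
      dl.cv.L = L; dl.cv.N = N;
      C += cfg.growth;
    }
    std::ostringstream nm; nm << "block" << (b + 1);
    stage_names.push_back(nm.str()); stage_C.push_back(C); stage_L.push_back(L);
    if (b < cfg.n_blocks - 1) {
      TransC& tr = trans[b];
      tr.bn.gamma = rd.V(C, tr.bn.og);
      tr.bn.beta = rd.V(C, tr.bn.ob);
      int Cout = trans_channels(cfg.compression, C);
      tr.cv.W = rd.M(Cout, C, tr.cv.oW);
      tr.cv.b = rd.V(Cout, tr.cv.ob);
      tr.cv.Cin = C; tr.cv.Cout = Cout; tr.cv.k = 1;
      tr.cv.L = L; tr.cv.N = N;
      tr.Lin = L;
      C = Cout; L = L / 2;
      std::ostringstream nt; nt << "transition" << (b + 1);
      stage_names.push_back(nt.str()); stage_C.push_back(C); stage_L.push_back(L);
    }
  }
  if (cfg.att > 0) {
    at.h = std::max(1, C / cfg.rr);
    at.W1 = rd.M(at.h, C, at.o1);
    at.b1 = rd.V(at.h, at.ob1);
    at.W2 = rd.M(C, at.h, at.o2);
    at.b2 = rd.V(C, at.ob2);
    at.rcam = (cfg.att == 2);
    stage_names.push_back("attention"); stage_C.push_back(C); stage_L.push_back(L);
  }
  int D = C * L;
  for (size_t i = 0; i < cfg.fc.size(); i++) {
    FCc fc;
    fc.W = rd.M(cfg.fc[i], D, fc.oW);
    fc.b = rd.V(cfg.fc[i], fc.ob);
    fc.relu = true;
    fcs.push_back(fc);
    D = cfg.fc[i];
  }
  {
    FCc fo;
    fo.W = rd.M(2, D, fo.oW);
    fo.b = rd.V(2, fo.ob);
    fo.relu = false;
    fcs.push_back(fo);
  }
  if (rd.pos != params.n_elem)
    stop("parameter vector length mismatch: walked %d, got %d",
         (int)rd.pos, (int)params.n_elem);

  // assign BN state offsets in parameter order
  {
    uword spos = 0;
    for (int b = 0; b < cfg.n_blocks; b++) {
      for (int l = 0; l < cfg.layers_per_block; l++) {
        blocks[b][l].bn.os = spos;
        spos += 2 * blocks[b][l].bn.gamma.n_elem;
      }
      if (b < cfg.n_blocks - 1) {
        trans[b].bn.os = spos;
        spos += 2 * trans[b].bn.gamma.n_elem;
      }
    }
    if (spos != state.n_elem)
      stop("state vector length mismatch: walked %d, got %d",
           (int)spos, (int)state.n_elem);
  }

  // ---- forward ----
  C = cfg.C0; L = cfg.L0;
  for (int b = 0; b < cfg.n_blocks; b++) {
    for (int l = 0; l < cfg.layers_per_block; l++) {
      DenseL& dl = blocks[b][l];
      mat bno = bn_forward(X, dl.bn, training, state, momentum);
      dl.act = clamp(bno, 0.0, datum::inf);
      mat out = conv_forward(dl.act, dl.cv);
      X = join_cols(X, out);
      C += cfg.growth;
    }
    if (b < cfg.n_blocks - 1) {
      TransC& tr = trans[b];
      mat bno = bn_forward(X, tr.bn, training, state, momentum);
      mat cvo = conv_forward(bno, tr.cv);
      X = avgpool2(cvo, L, N);
      C = tr.cv.Cout; L = L / 2;
    }
  }
  if (cfg.att > 0) {
    at.F = X;
    at.L = L; at.N = N;
    at.A.set_size(C, N); at.Mx.set_size(C, N); at.idx.set_size(C, N);
    for (int n = 0; n < N; n++) {
      mat sub = X.cols((uword)n * L, (uword)n * L + L - 1);
      at.A.col(n) = mean(sub, 1);
      at.Mx.col(n) = max(sub, 1);
      at.idx.col(n) = index_max(sub, 1);
    }
    at.U = clamp(at.W1 * at.A + repmat(at.b1, 1, N), 0.0, datum::inf);
    at.Um = clamp(at.W1 * at.Mx + repmat(at.b1, 1, N), 0.0, datum::inf);
    mat Za = at.W2 * at.U; Za.each_col() += at.b2;
    mat Zm = at.W2 * at.Um; Zm.each_col() += at.b2;
    at.mc = sigmoid_m(Za + Zm);
    if (at.rcam) {
      at.mr = sigmoid_m(at.A + at.Mx);
      at.w = at.mc + at.mr;
    } else {
      at.w = at.mc;
    }
    for (int n = 0; n < N; n++)
      X.cols((uword)n * L, (uword)n * L + L - 1).each_col() %= at.w.col(n);
  }
  // flatten: columns of each sample are contiguous, so a reshape suffices
  mat H(X.memptr(), (uword)C * L, N);
  for (size_t i = 0; i < fcs.size(); i++) {
    FCc& fc = fcs[i];
    fc.X = H;
    H = fc.W * H;
    H.each_col() += fc.b;
    if (fc.relu) {
      H = clamp(H, 0.0, datum::inf);
      if (training && cfg.dropout > 0 && (int)i < dropmasks.size()) {
        fc.mask = as<mat>(dropmasks[i]);
        H %= fc.mask;
      }
      fc.out = H;
    }
  }
  // H is now logits (2 x N); stable softmax
  mat logits = H;
  rowvec mx = max(logits, 0);
  mat E = logits;
  E.each_row() -= mx;
  E = exp(E);
  rowvec Z = sum(E, 0);
  mat P = E;
  P.each_row() /= Z;

  double loss = NA_REAL;
  if (y.size() == N) {
    loss = 0.0;
    for (int n = 0; n < N; n++) {
      double lp = logits(y[n], n) - mx(n) - std::log(Z(n));
      loss -= lp;
    }
    loss /= N;
  }

  vec g;
  if (want_grad) {
    if (y.size() != N) stop("gradients require labels");
    g = vec(params.n_elem, fill::zeros);
    mat dH = P;
    for (int n = 0; n < N; n++) dH(y[n], n) -= 1.0;
    dH /= (double)N;
    // head backward
    for (int i = (int)fcs.size() - 1; i >= 0; i--) {
      FCc& fc = fcs[i];
      if (fc.relu) {
        dH %= conv_to<mat>::from(fc.out > 0);
        if (training && cfg.dropout > 0 && fc.mask.n_elem > 0) dH %= fc.mask;
      }
      mat dW = dH * fc.X.t();
      vec db = sum(dH, 1);
      g.subvec(fc.oW, fc.oW + dW.n_elem - 1) += vectorise(dW);
      g.subvec(fc.ob, fc.ob + db.n_elem - 1) += db;
      dH = fc.W.t() * dH;
    }
    // un-flatten
    mat dX(dH.memptr(), C, (uword)L * N);
    if (cfg.att > 0) {
      mat dF = dX;
      mat dw(C, N);
      for (int n = 0; n < N; n++) {
        mat dsub = dX.cols((uword)n * L, (uword)n * L + L - 1);
        mat fsub = at.F.cols((uword)n * L, (uword)n * L + L - 1);
        dw.col(n) = sum(dsub % fsub, 1);
        dF.cols((uword)n * L, (uword)n * L + L - 1).each_col() %= at.w.col(n);
      }
      mat dA(C, N, fill::zeros), dM(C, N, fill::zeros);
      if (at.rcam) {
        mat ds = dw % at.mr % (1.0 - at.mr);
        dA += ds;
        dM += ds;
      }
      mat dz = dw % at.mc % (1.0 - at.mc);  // shared by Za and Zm
      // FNN path on the average-pooled vector
      mat dUa = (at.W2.t() * dz) % conv_to<mat>::from(at.U > 0);
      mat dUm = (at.W2.t() * dz) % conv_to<mat>::from(at.Um > 0);
      mat dW2 = dz * at.U.t() + dz * at.Um.t();
      vec db2 = 2.0 * sum(dz, 1);
      mat dW1 = dUa * at.A.t() + dUm * at.Mx.t();
      vec db1 = sum(dUa, 1) + sum(dUm, 1);
      g.subvec(at.o2, at.o2 + dW2.n_elem - 1) += vectorise(dW2);
      g.subvec(at.ob2, at.ob2 + db2.n_elem - 1) += db2;
      g.subvec(at.o1, at.o1 + dW1.n_elem - 1) += vectorise(dW1);
      g.subvec(at.ob1, at.ob1 + db1.n_elem - 1) += db1;
      dA += at.W1.t() * dUa;
      dM += at.W1.t() * dUm;
      // pooling backward
      for (int n = 0; n < N; n++) {
        dF.cols((uword)n * L, (uword)n * L + L - 1).each_col() += dA.col(n) / (double)L;
        for (int c = 0; c < C; c++)
          dF(c, (uword)n * L + at.idx(c, n)) += dM(c, n);
      }
      dX = dF;
    }
    // blocks backward
    for (int b = cfg.n_blocks - 1; b >= 0; b--) {
      for (int l = cfg.layers_per_block - 1; l >= 0; l--) {
        DenseL& dl = blocks[b][l];
        int Cin = dl.cv.Cin;
        mat dout = dX.rows(Cin, Cin + cfg.growth - 1);
        mat dact = conv_backward(dout, dl.cv, g);
        dact %= conv_to<mat>::from(dl.act > 0);
        mat din = bn_backward(dact, dl.bn, g);
        dX = dX.rows(0, Cin - 1) + din;
      }
      if (b > 0) {
        TransC& tr = trans[b - 1];
        mat dcvo = avgpool2_backward(dX, tr.Lin, N);
        mat dbno = conv_backward(dcvo, tr.cv, g);
        dX = bn_backward(dbno, tr.bn, g);
      }
    }
  }

  List stages = List::create(
      _["stage"] = wrap(stage_names), _["channels"] = wrap(stage_C),
      _["length"] = wrap(stage_L));
  List out = List::create(
      _["probs"] = wrap(P.t()), _["loss"] = loss,
      _["state"] = wrap(state), _["stages"] = stages);
  if (want_grad) out["grad"] = wrap(g);
  return out;
}
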