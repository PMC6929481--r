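// Per-batch kernels of the CNN engine.
//
// A minibatch of n sequences is a C x (n*L) matrix whose column
// c = (p-1)*n + i is position p of sequence i. A shift by one position is
// a shift by n contiguous columns, so `same`-padded 1-D convolution is an
// im2col block copy plus one (F x K*C) * (K*C x m) product. The R side
// owns initialization, batching, Adam and epoch selection; these kernels
// are deterministic (no RNG).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.9;  // retained fraction of running stats

static mat im2col(const mat& X, const int n, const int K) {
  const uword m = X.n_cols, C = X.n_rows;
  const int h = (K - 1) / 2;
  mat Z(C * K, m, fill::zeros);
  for (int k = 0; k < K; ++k) {
    const int o = k - h;  // position offset of this kernel tap
    const uword r0 = k * C;
    if (o == 0) {
      Z.rows(r0, r0 + C - 1) = X;
    } else if (o > 0) {
      const uword s = (uword)(o * n);
      if (s < m)
        Z.submat(r0, 0, r0 + C - 1, m - s - 1) = X.cols(s, m - 1);
    } else {
      const uword s = (uword)(-o * n);
      if (s < m)
        Z.submat(r0, s, r0 + C - 1, m - 1) = X.cols(0, m - s - 1);
    }
  }
  return Z;
}

static mat col2im(const mat& dZ, const int n, const int C, const int K) {
  const uword m = dZ.n_cols;
  const int h = (K - 1) / 2;
  mat dX(C, m, fill::zeros);
  for (int k = 0; k < K; ++k) {
    const int o = k - h;
    const uword r0 = k * C;
    if (o == 0) {
      dX += dZ.rows(r0, r0 + C - 1);
    } else if (o > 0) {
      const uword s = (uword)(o * n);
      if (s < m)
        dX.cols(s, m - 1) += dZ.submat(r0, 0, r0 + C - 1, m - s - 1);
    } else {
      const uword s = (uword)(-o * n);
      if (s < m)
        dX.cols(0, m - s - 1) += dZ.submat(r0, s, r0 + C - 1, m - 1);
    }
  }
  return dX;
}

// columns of pooling-window member j (0-based) for output length Lout
static uvec poolCols(const int n, const int Lout, const int ps, const int j) {
  uvec idx(n * (uword)Lout);
  for (int g = 0; g < Lout; ++g) {
    const uword p = g * ps + j;
    for (int i = 0; i < n; ++i) idx[g * n + i] = p * n + i;
  }
  return idx;
}

struct BlockCache {
  mat Z, xhat, mask;
  vec invstd;
  imat poolArg;
  bool pooled = false;
  int L = 0, Lpre = 0;
};

struct ForwardOut {
  rowvec logits;
  std::vector<BlockCache> blocks;
  mat Xf, mask1, A1;
  int Lf = 0, Ff = 0;
};

static std::string nm(const int b, const char* part) {
  return "c" + std::to_string(b + 1) + "." + part;
}

static ForwardOut forwardPass(const List& theta, List& bnStats,
                              const mat& X0, const int n, const int L0,
                              const int K, const int nblocks, const int ps,
                              const LogicalVector& poolHere,
                              const bool train, const bool keepCache) {
  ForwardOut out;
  out.blocks.resize(nblocks);
  mat X = X0;
  int L = L0;
  for (int b = 0; b < nblocks; ++b) {
    BlockCache& blk = out.blocks[b];
    blk.L = L;
    mat Z = im2col(X, n, K);
    const mat W = as<mat>(theta[nm(b, "W")]);
    mat Yc = W * Z;
    Yc.each_col() += as<vec>(theta[nm(b, "b")]);

    vec mu, va;
    if (train) {
      mu = mean(Yc, 1);
      va = mean(square(Yc), 1) - square(mu);
      va.transform([](double v) { return v > 0 ? v : 0.0; });
      vec rm = as<vec>(bnStats[nm(b, "mean")]);
      vec rv = as<vec>(bnStats[nm(b, "var")]);
      bnStats[nm(b, "mean")] = BN_MOMENTUM * rm + (1 - BN_MOMENTUM) * mu;
      bnStats[nm(b, "var")] = BN_MOMENTUM * rv + (1 - BN_MOMENTUM) * va;
    } else {
      mu = as<vec>(bnStats[nm(b, "mean")]);
      va = as<vec>(bnStats[nm(b, "var")]);
    }
    vec invstd = 1.0 / sqrt(va + BN_EPS);
    mat xhat = Yc;
    xhat.each_col() -= mu;
    xhat.each_col() %= invstd;
    mat act = xhat;
    act.each_col() %= as<vec>(theta[nm(b, "g")]);
    act.each_col() += as<vec>(theta[nm(b, "be")]);
    mat mask = conv_to<mat>::from(act > 0.0);
    act %= mask;
    if (keepCache) {
      blk.Z = std::move(Z);
      blk.xhat = std::move(xhat);
      blk.invstd = invstd;
      blk.mask = std::move(mask);
    }

    if (poolHere[b]) {
      const int Lout = L / ps;
      if (Lout < 1) stop("pooling reduces the sequence length to zero");
      mat cur = act.cols(poolCols(n, Lout, ps, 0));
      imat arg(cur.n_rows, cur.n_cols, fill::zeros);
      for (int j = 1; j < ps; ++j) {
        mat Mj = act.cols(poolCols(n, Lout, ps, j));
        uvec upd = find(Mj > cur);
        ivec jv(upd.n_elem);
        jv.fill(j);
        arg.elem(upd) = jv;
        cur.elem(upd) = Mj.elem(upd);
      }
      if (keepCache) {
        blk.pooled = true;
        blk.poolArg = std::move(arg);
        blk.Lpre = L;
      }
      act = std::move(cur);
      L = Lout;
    }
    X = std::move(act);
  }

  const int Ff = X.n_rows;
  mat Xf(Ff * (uword)L, (uword)n);
  for (int p = 0; p < L; ++p)
    Xf.rows(p * Ff, (p + 1) * Ff - 1) = X.cols(p * n, (p + 1) * n - 1);
  const mat W1 = as<mat>(theta["fc1.W"]);
  mat Z1 = W1 * Xf;
  Z1.each_col() += as<vec>(theta["fc1.b"]);
  mat mask1 = conv_to<mat>::from(Z1 > 0.0);
  mat A1 = Z1 % mask1;
  const mat W2 = as<mat>(theta["fc2.W"]);
  rowvec logits = W2 * A1;
  logits += as<double>(theta["fc2.b"]);

  out.logits = std::move(logits);
  out.Lf = L;
  out.Ff = Ff;
  if (keepCache) {
    out.Xf = std::move(Xf);
    out.mask1 = std::move(mask1);
    out.A1 = std::move(A1);
  }
  return out;
}

static double bceLoss(const rowvec& z, const rowvec& y) {
  rowvec zp = z;
  zp.transform([](double v) { return v > 0 ? v : 0.0; });
  rowvec l = zp - z % y + log1p(exp(-abs(z)));
  return mean(l);
}

// One training step: forward in training mode, loss, full backward.
// Returns the loss, the per-parameter gradients (named like theta) and
// the updated batch-norm running statistics.
// [[Rcpp::export(name = ".cnnTrainStep")]]
List cnnTrainStep(const List& theta, const List& bnStats, const arma::mat& X,
                  const NumericVector& y, const int n, const int L,
                  const int K, const int nblocks, const int poolSize,
                  const LogicalVector& poolHere) {
  List stats = clone(bnStats);
  ForwardOut fw = forwardPass(theta, stats, X, n, L, K, nblocks, poolSize,
                              poolHere, true, true);
  rowvec yv = as<rowvec>(y);
  const double loss = bceLoss(fw.logits, yv);

  List grads;
  rowvec dz = (1.0 / (1.0 + exp(-fw.logits)) - yv) / (double)yv.n_elem;

  const mat W2 = as<mat>(theta["fc2.W"]);
  grads["fc2.W"] = mat(dz * fw.A1.t());
  grads["fc2.b"] = accu(dz);
  mat dZ1 = (W2.t() * dz) % fw.mask1;
  grads["fc1.W"] = mat(dZ1 * fw.Xf.t());
  grads["fc1.b"] = vec(sum(dZ1, 1));
  const mat W1 = as<mat>(theta["fc1.W"]);
  mat dXf = W1.t() * dZ1;

  mat d(fw.Ff, (uword)n * fw.Lf);
  for (int p = 0; p < fw.Lf; ++p)
    d.cols(p * n, (p + 1) * n - 1) = dXf.rows(p * fw.Ff, (p + 1) * fw.Ff - 1);

  for (int b = nblocks - 1; b >= 0; --b) {
    BlockCache& blk = fw.blocks[b];
    if (blk.pooled) {
      const int Lout = blk.Lpre / poolSize;
      mat dpre(d.n_rows, (uword)n * blk.Lpre, fill::zeros);
      for (int j = 0; j < poolSize; ++j) {
        mat sel = conv_to<mat>::from(blk.poolArg == j);
        dpre.cols(poolCols(n, Lout, poolSize, j)) = d % sel;
      }
      d = std::move(dpre);
    }
    d %= blk.mask;
    const vec g = as<vec>(theta[nm(b, "g")]);
    grads[nm(b, "g")] = vec(sum(d % blk.xhat, 1));
    grads[nm(b, "be")] = vec(sum(d, 1));
    mat dxhat = d;
    dxhat.each_col() %= g;
    const double m = (double)d.n_cols;
    vec s1 = sum(dxhat, 1);
    vec s2 = sum(dxhat % blk.xhat, 1);
    mat dYc = blk.xhat;
    dYc.each_col() %= (s2 / m);
    dYc = dxhat - dYc;
    dYc.each_col() -= s1 / m;
    dYc.each_col() %= blk.invstd;
    grads[nm(b, "b")] = vec(sum(dYc, 1));
    grads[nm(b, "W")] = mat(dYc * blk.Z.t());
    const mat W = as<mat>(theta[nm(b, "W")]);
    mat dZ = W.t() * dYc;
    d = col2im(dZ, n, blk.Z.n_rows / K, K);
  }

  return List::create(_["loss"] = loss, _["grads"] = grads,
                      _["bnStats"] = stats);
}

// Inference-mode logits (frozen batch-norm running statistics).
// [[Rcpp::export(name = ".cnnLogits")]]
NumericVector cnnLogits(const List& theta, const List& bnStats,
                        const arma::mat& X, const int n, const int L,
                        const int K, const int nblocks, const int poolSize,
                        const LogicalVector& poolHere) {
  List stats = clone(bnStats);  // not modified in inference mode
  ForwardOut fw = forwardPass(theta, stats, X, n, L, K, nblocks, poolSize,
                              poolHere, false, false);
  return wrap(conv_to<std::vector<double>>::from(fw.logits));
}
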