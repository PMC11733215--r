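// Compact 1-D temporal CNN for binary snippet classification.
//
// Architecture: n_conv blocks of [Conv1D (same padding, stride 1) ->
// BatchNorm -> ReLU -> Dropout], flatten, one FC block [Dense ->
// BatchNorm -> ReLU -> Dropout], and a single linear output unit.
// Loss is binary cross-entropy on the logit; optimization is Adam with
// mini-batches; early stopping monitors the validation loss (inference
// mode: running batch-norm statistics, dropout off) and the weights of
// the best validation epoch are returned.
//
// Samples of a mini-batch are stacked along the frame axis so each
// layer is a single GEMM; unfolding/folding is done per sample so
// convolutions never bleed across snippet boundaries.
//
// All randomness (initialization, shuffling, dropout) comes from an
// internal 64-bit generator seeded explicitly, so training is bit-wise
// reproducible from the seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double BN_EPS = 1e-3;
static const double BN_MOMENTUM = 0.99;

// deterministic RNG (splitmix64)
struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) : state(seed) {}
  uint64_t next_u64() {
    uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() {  // (0, 1)
    return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  void shuffle(std::vector<uword>& v) {
    for (uword i = v.size(); i > 1; --i) {
      uword j = static_cast<uword>(next_u64() % i);
      std::swap(v[i - 1], v[j]);
    }
  }
};

struct Arch {
  uvec kernels;   // n_kernels per conv layer
  uvec sizes;     // kernel size per conv layer
  uword fc_units;
  double dropout;
  bool batch_norm;
  uword frames;
  uword channels;
};

static Arch parse_arch(const Rcpp::List& config, uword frames,
                       uword channels) {
  Arch a;
  a.kernels = Rcpp::as<uvec>(config["conv_kernels"]);
  a.sizes = Rcpp::as<uvec>(config["conv_sizes"]);
  a.fc_units = Rcpp::as<uword>(config["fc_units"]);
  a.dropout = Rcpp::as<double>(config["dropout"]);
  a.batch_norm = Rcpp::as<bool>(config["batch_norm"]);
  a.frames = frames;
  a.channels = channels;
  if (a.kernels.n_elem != a.sizes.n_elem || a.kernels.n_elem == 0)
    Rcpp::stop("conv_kernels and conv_sizes must have equal length");
  for (uword l = 0; l < a.sizes.n_elem; ++l) {
    if (a.sizes[l] < 1 || a.sizes[l] > frames)
      Rcpp::stop("kernel size must be in [1, input frames]");
    if (a.kernels[l] < 1) Rcpp::stop("n_kernels must be >= 1");
  }
  if (a.dropout < 0 || a.dropout >= 1)
    Rcpp::stop("dropout must lie in [0, 1)");
  return a;
}

struct BnLayer {
  rowvec gamma, beta, rmean, rvar;
};

struct Params {
  std::vector<mat> convW;     // (k * in) x out
  std::vector<rowvec> convB;
  std::vector<BnLayer> convBn;
  mat fcW;                    // flat x fc
  rowvec fcB;
  BnLayer fcBn;
  mat outW;                   // fc x 1
  double outB;
};

static void glorot(mat& W, uword fan_in, uword fan_out, Rng& rng) {
  double lim = std::sqrt(6.0 / (double)(fan_in + fan_out));
  for (uword i = 0; i < W.n_elem; ++i)
    W(i) = (rng.unif() * 2.0 - 1.0) * lim;
}

static Params init_params(const Arch& a, Rng& rng) {
  Params p;
  uword in = a.channels;
  for (uword l = 0; l < a.kernels.n_elem; ++l) {
    uword k = a.sizes[l], out = a.kernels[l];
    mat W(k * in, out);
    glorot(W, k * in, k * out, rng);
    p.convW.push_back(W);
    p.convB.push_back(rowvec(out, fill::zeros));
    BnLayer bn;
    bn.gamma = rowvec(out, fill::ones);
    bn.beta = rowvec(out, fill::zeros);
    bn.rmean = rowvec(out, fill::zeros);
    bn.rvar = rowvec(out, fill::ones);
    p.convBn.push_back(bn);
    in = out;
  }
  uword flat = a.frames * in;
  p.fcW.set_size(flat, a.fc_units);
  glorot(p.fcW, flat, a.fc_units, rng);
  p.fcB = rowvec(a.fc_units, fill::zeros);
  p.fcBn.gamma = rowvec(a.fc_units, fill::ones);
  p.fcBn.beta = rowvec(a.fc_units, fill::zeros);
  p.fcBn.rmean = rowvec(a.fc_units, fill::zeros);
  p.fcBn.rvar = rowvec(a.fc_units, fill::ones);
  p.outW.set_size(a.fc_units, 1);
  glorot(p.outW, a.fc_units, 1, rng);
  p.outB = 0.0;
  return p;
}

// unfold a stacked (B*F) x C input into (B*F) x (k*C) with per-sample
// "same" zero padding
static mat unfold_stacked(const mat& x, uword k, uword B, uword F) {
  uword C = x.n_cols;
  uword pl = (k - 1) / 2;
  mat U(B * F, k * C, fill::zeros);
  for (uword b = 0; b < B; ++b) {
    uword r0 = b * F;
    for (uword d = 0; d < k; ++d) {
      // output frame t reads input frame t + d - pl
      long lo = (long)pl - (long)d;          // first valid output t
      long t_start = std::max<long>(0, lo);
      long t_end = std::min<long>((long)F - 1,
                                  (long)F - 1 + (long)pl - (long)d);
      if (t_start > t_end) continue;
      long s_start = t_start + (long)d - (long)pl;
      U.submat(r0 + t_start, d * C, r0 + t_end, d * C + C - 1) =
          x.rows(r0 + s_start, r0 + s_start + (t_end - t_start));
    }
  }
  return U;
}

// fold the gradient of an unfolded stack back to (B*F) x C
static mat fold_stacked(const mat& dU, uword k, uword B, uword F,
                        uword C) {
  uword pl = (k - 1) / 2;
  mat dx(B * F, C, fill::zeros);
  for (uword b = 0; b < B; ++b) {
    uword r0 = b * F;
    for (uword d = 0; d < k; ++d) {
      long t_start = std::max<long>(0, (long)pl - (long)d);
      long t_end = std::min<long>((long)F - 1,
                                  (long)F - 1 + (long)pl - (long)d);
      if (t_start > t_end) continue;
      long s_start = t_start + (long)d - (long)pl;
      dx.rows(r0 + s_start, r0 + s_start + (t_end - t_start)) +=
          dU.submat(r0 + t_start, d * C, r0 + t_end,
                    d * C + C - 1);
    }
  }
  return dx;
}

// stack selected samples of the cube along the frame axis
static mat stack_samples(const cube& X, const std::vector<uword>& idx) {
  uword F = X.n_rows, C = X.n_cols, B = idx.size();
  mat out(B * F, C);
  for (uword b = 0; b < B; ++b)
    out.rows(b * F, b * F + F - 1) = X.slice(idx[b]);
  return out;
}

// inference-mode logits for a set of samples
static vec forward_infer(const Params& p, const Arch& a, const cube& X,
                         const std::vector<uword>& idx) {
  uword F = a.frames, B = idx.size();
  mat x = stack_samples(X, idx);
  for (uword l = 0; l < a.kernels.n_elem; ++l) {
    mat z = unfold_stacked(x, a.sizes[l], B, F) * p.convW[l];
    z.each_row() += p.convB[l];
    if (a.batch_norm) {
      const BnLayer& bn = p.convBn[l];
      z.each_row() -= bn.rmean;
      z.each_row() %= bn.gamma / sqrt(bn.rvar + BN_EPS);
      z.each_row() += bn.beta;
    }
    x = clamp(z, 0.0, datum::inf);
  }
  uword flatdim = F * a.kernels[a.kernels.n_elem - 1];
  mat flat(B, flatdim);
  for (uword b = 0; b < B; ++b)
    flat.row(b) = vectorise(x.rows(b * F, b * F + F - 1)).t();
  mat z = flat * p.fcW;
  z.each_row() += p.fcB;
  if (a.batch_norm) {
    const BnLayer& bn = p.fcBn;
    z.each_row() -= bn.rmean;
    z.each_row() %= bn.gamma / sqrt(bn.rvar + BN_EPS);
    z.each_row() += bn.beta;
  }
  return clamp(z, 0.0, datum::inf) * p.outW + p.outB;
}

static double softplus(double z) {
  return z > 0 ? z + std::log1p(std::exp(-z)) : std::log1p(std::exp(z));
}

static double mean_bce(const Params& p, const Arch& a, const cube& X,
                       const std::vector<uword>& idx, const vec& y) {
  vec z = forward_infer(p, a, X, idx);
  double s = 0.0;
  for (uword i = 0; i < idx.size(); ++i)
    s += softplus(z[i]) - y[idx[i]] * z[i];
  return s / (double)idx.size();
}

struct Adam {
  std::vector<mat> mW, vW;
  double lr, b1, b2, eps;
  long t = 0;
  void add(const mat& shape_like) {
    mW.push_back(mat(size(shape_like), fill::zeros));
    vW.push_back(mat(size(shape_like), fill::zeros));
  }
  void step(uword i, mat& w, const mat& g) {
    mW[i] = b1 * mW[i] + (1 - b1) * g;
    vW[i] = b2 * vW[i] + (1 - b2) * square(g);
    double c1 = 1 - std::pow(b1, (double)t);
    double c2 = 1 - std::pow(b2, (double)t);
    w -= lr * (mW[i] / c1) / (sqrt(vW[i] / c2) + eps);
  }
};

// per-layer caches for one mini-batch
struct ConvCache {
  mat U;        // unfolded input stack
  mat xhat;     // BN-normalized pre-activations
  mat act;      // post-ReLU (pre-dropout)
  mat drop;     // dropout mask (scaled)
  rowvec invstd;
};

static mat dropout_mask(uword nr, uword nc, double rate, Rng& rng) {
  mat m(nr, nc);
  if (rate <= 0) {
    m.ones();
    return m;
  }
  double scale = 1.0 / (1.0 - rate);
  for (uword i = 0; i < m.n_elem; ++i)
    m(i) = rng.unif() >= rate ? scale : 0.0;
  return m;
}

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(Rcpp::NumericVector x_array,
                         Rcpp::NumericVector y_vec, Rcpp::List config,
                         Rcpp::List train_config) {
  Rcpp::IntegerVector dims = x_array.attr("dim");
  if (dims.size() != 3) Rcpp::stop("X must be frames x channels x n");
  uword F = dims[0], C = dims[1], N = dims[2];
  cube X(x_array.begin(), F, C, N, false);
  vec y = Rcpp::as<vec>(y_vec);
  Arch a = parse_arch(config, F, C);

  uword batch_size = Rcpp::as<uword>(train_config["batch_size"]);
  double lr = Rcpp::as<double>(train_config["learning_rate"]);
  double b1 = Rcpp::as<double>(train_config["beta1"]);
  double b2 = Rcpp::as<double>(train_config["beta2"]);
  double adam_eps = Rcpp::as<double>(train_config["epsilon"]);
  double val_split = Rcpp::as<double>(train_config["val_split"]);
  uword patience = Rcpp::as<uword>(train_config["patience"]);
  uword max_epochs = Rcpp::as<uword>(train_config["max_epochs"]);
  uint64_t seed = (uint64_t)Rcpp::as<double>(train_config["seed"]);

  Rng rng(seed * 2654435761ULL + 1ULL);
  Params p = init_params(a, rng);

  // validation set: last val_split fraction of a seeded shuffle
  std::vector<uword> order(N);
  for (uword i = 0; i < N; ++i) order[i] = i;
  rng.shuffle(order);
  uword n_val = (uword)std::floor((double)N * val_split);
  if (n_val < 1) n_val = 1;
  if (n_val >= N) Rcpp::stop("validation split leaves no training data");
  std::vector<uword> val_idx(order.end() - n_val, order.end());
  std::vector<uword> train_idx(order.begin(), order.end() - n_val);

  uword n_layers = a.kernels.n_elem;
  Adam opt;
  opt.lr = lr; opt.b1 = b1; opt.b2 = b2; opt.eps = adam_eps;
  for (uword l = 0; l < n_layers; ++l) {
    opt.add(p.convW[l]);
    opt.add(mat(p.convB[l]));
    opt.add(mat(p.convBn[l].gamma));
    opt.add(mat(p.convBn[l].beta));
  }
  opt.add(p.fcW);
  opt.add(mat(p.fcB));
  opt.add(mat(p.fcBn.gamma));
  opt.add(mat(p.fcBn.beta));
  opt.add(p.outW);
  opt.add(mat(1, 1));

  Params best = p;
  double best_val = datum::inf;
  uword best_epoch = 0, wait = 0;
  std::vector<double> train_losses, val_losses;

  for (uword epoch = 1; epoch <= max_epochs; ++epoch) {
    rng.shuffle(train_idx);
    double epoch_loss = 0.0;
    uword n_batches = 0;
    for (uword start = 0; start < train_idx.size();
         start += batch_size) {
      uword B = std::min<uword>(batch_size, train_idx.size() - start);
      std::vector<uword> bi(train_idx.begin() + start,
                            train_idx.begin() + start + B);

      // ---------------- forward ----------------
      std::vector<ConvCache> caches(n_layers);
      mat cur = stack_samples(X, bi);
      for (uword l = 0; l < n_layers; ++l) {
        ConvCache& cc = caches[l];
        cc.U = unfold_stacked(cur, a.sizes[l], B, F);
        mat z = cc.U * p.convW[l];
        z.each_row() += p.convB[l];
        if (a.batch_norm) {
          double nrows = (double)z.n_rows;
          rowvec mean_z = mean(z, 0);
          rowvec var_z = sum(square(z.each_row() - mean_z), 0) / nrows;
          cc.invstd = 1.0 / sqrt(var_z + BN_EPS);
          BnLayer& bn = p.convBn[l];
          bn.rmean = BN_MOMENTUM * bn.rmean +
                     (1 - BN_MOMENTUM) * mean_z;
          bn.rvar = BN_MOMENTUM * bn.rvar + (1 - BN_MOMENTUM) * var_z;
          cc.xhat = z;
          cc.xhat.each_row() -= mean_z;
          cc.xhat.each_row() %= cc.invstd;
          z = cc.xhat;
          z.each_row() %= bn.gamma;
          z.each_row() += bn.beta;
        }
        cc.act = clamp(z, 0.0, datum::inf);
        cc.drop = dropout_mask(z.n_rows, z.n_cols, a.dropout, rng);
        cur = cc.act % cc.drop;
      }
      uword flatdim = F * a.kernels[n_layers - 1];
      mat flat(B, flatdim);
      for (uword b = 0; b < B; ++b)
        flat.row(b) = vectorise(cur.rows(b * F, b * F + F - 1)).t();
      mat zfc = flat * p.fcW;
      zfc.each_row() += p.fcB;
      rowvec fc_invstd;
      mat fc_xhat;
      if (a.batch_norm) {
        double nb = (double)B;
        rowvec mean_z = mean(zfc, 0);
        rowvec var_z = sum(square(zfc.each_row() - mean_z), 0) / nb;
        fc_invstd = 1.0 / sqrt(var_z + BN_EPS);
        p.fcBn.rmean = BN_MOMENTUM * p.fcBn.rmean +
                       (1 - BN_MOMENTUM) * mean_z;
        p.fcBn.rvar = BN_MOMENTUM * p.fcBn.rvar +
                      (1 - BN_MOMENTUM) * var_z;
        fc_xhat = zfc;
        fc_xhat.each_row() -= mean_z;
        fc_xhat.each_row() %= fc_invstd;
        zfc = fc_xhat;
        zfc.each_row() %= p.fcBn.gamma;
        zfc.each_row() += p.fcBn.beta;
      }
      mat hfc = clamp(zfc, 0.0, datum::inf);
      mat fc_drop = dropout_mask(B, a.fc_units, a.dropout, rng);
      mat hdrop = hfc % fc_drop;
      vec logits = hdrop * p.outW + p.outB;

      double loss = 0.0;
      vec dlogit(B);
      for (uword b = 0; b < B; ++b) {
        double z = logits[b], yb = y[bi[b]];
        loss += softplus(z) - yb * z;
        dlogit[b] = (1.0 / (1.0 + std::exp(-z)) - yb) / (double)B;
      }
      loss /= (double)B;
      epoch_loss += loss;
      ++n_batches;

      // ---------------- backward ----------------
      mat d_outW = hdrop.t() * dlogit;
      double d_outB = accu(dlogit);
      mat dh = dlogit * p.outW.t();   // B x fc
      dh %= fc_drop;
      dh %= conv_to<mat>::from(zfc > 0);
      rowvec d_fc_gamma, d_fc_beta;
      mat dzfc;
      if (a.batch_norm) {
        mat dxhat = dh;
        dxhat.each_row() %= p.fcBn.gamma;
        d_fc_gamma = sum(dh % fc_xhat, 0);
        d_fc_beta = sum(dh, 0);
        double nb = (double)B;
        rowvec sum_dxhat = sum(dxhat, 0);
        rowvec sum_dxhat_xhat = sum(dxhat % fc_xhat, 0);
        dzfc = nb * dxhat;
        dzfc.each_row() -= sum_dxhat;
        dzfc -= fc_xhat.each_row() % sum_dxhat_xhat;
        dzfc.each_row() %= fc_invstd / nb;
      } else {
        dzfc = dh;
      }
      mat d_fcW = flat.t() * dzfc;
      rowvec d_fcB = sum(dzfc, 0);
      mat dflat = dzfc * p.fcW.t();   // B x flatdim

      mat dcur(B * F, a.kernels[n_layers - 1]);
      for (uword b = 0; b < B; ++b)
        dcur.rows(b * F, b * F + F - 1) =
            reshape(dflat.row(b).t(), F, a.kernels[n_layers - 1]);

      std::vector<mat> d_convW(n_layers);
      std::vector<rowvec> d_convB(n_layers);
      std::vector<rowvec> d_gamma(n_layers), d_beta(n_layers);
      for (uword li = n_layers; li-- > 0;) {
        ConvCache& cc = caches[li];
        mat dz = dcur % cc.drop;
        dz %= conv_to<mat>::from(cc.act > 0);
        if (a.batch_norm) {
          BnLayer& bn = p.convBn[li];
          double nrows = (double)dz.n_rows;
          d_gamma[li] = sum(dz % cc.xhat, 0);
          d_beta[li] = sum(dz, 0);
          mat dxhat = dz;
          dxhat.each_row() %= bn.gamma;
          rowvec sum_dxhat = sum(dxhat, 0);
          rowvec sum_dxhat_xhat = sum(dxhat % cc.xhat, 0);
          dz = nrows * dxhat;
          dz.each_row() -= sum_dxhat;
          dz -= cc.xhat.each_row() % sum_dxhat_xhat;
          dz.each_row() %= cc.invstd / nrows;
        }
        d_convW[li] = cc.U.t() * dz;
        d_convB[li] = sum(dz, 0);
        if (li > 0) {
          uword Cin = a.kernels[li - 1];
          mat dU = dz * p.convW[li].t();
          dcur = fold_stacked(dU, a.sizes[li], B, F, Cin);
        }
      }

      // ---------------- Adam updates ----------------
      ++opt.t;
      uword ti = 0;
      for (uword l = 0; l < n_layers; ++l) {
        opt.step(ti++, p.convW[l], d_convW[l]);
        mat bmat(p.convB[l]);
        opt.step(ti++, bmat, mat(d_convB[l]));
        p.convB[l] = bmat.row(0);
        if (a.batch_norm) {
          mat gm(p.convBn[l].gamma);
          opt.step(ti++, gm, mat(d_gamma[l]));
          p.convBn[l].gamma = gm.row(0);
          mat bt(p.convBn[l].beta);
          opt.step(ti++, bt, mat(d_beta[l]));
          p.convBn[l].beta = bt.row(0);
        } else {
          ti += 2;
        }
      }
      opt.step(ti++, p.fcW, d_fcW);
      {
        mat bmat(p.fcB);
        opt.step(ti++, bmat, mat(d_fcB));
        p.fcB = bmat.row(0);
      }
      if (a.batch_norm) {
        mat gm(p.fcBn.gamma);
        opt.step(ti++, gm, d_fc_gamma);
        p.fcBn.gamma = gm.row(0);
        mat bt(p.fcBn.beta);
        opt.step(ti++, bt, d_fc_beta);
        p.fcBn.beta = bt.row(0);
      } else {
        ti += 2;
      }
      opt.step(ti++, p.outW, d_outW);
      {
        mat bmat(1, 1);
        bmat(0, 0) = p.outB;
        mat gmat(1, 1);
        gmat(0, 0) = d_outB;
        opt.step(ti++, bmat, gmat);
        p.outB = bmat(0, 0);
      }
    }

    double train_loss = epoch_loss / (double)n_batches;
    double val_loss = mean_bce(p, a, X, val_idx, y);
    train_losses.push_back(train_loss);
    val_losses.push_back(val_loss);

    if (val_loss < best_val - 1e-12) {
      best_val = val_loss;
      best = p;
      best_epoch = epoch;
      wait = 0;
    } else if (++wait >= patience) {
      break;
    }
    Rcpp::checkUserInterrupt();
  }

  Rcpp::List conv_out(n_layers);
  for (uword l = 0; l < n_layers; ++l) {
    conv_out[l] = Rcpp::List::create(
        Rcpp::Named("W") = best.convW[l],
        Rcpp::Named("b") = best.convB[l],
        Rcpp::Named("gamma") = best.convBn[l].gamma,
        Rcpp::Named("beta") = best.convBn[l].beta,
        Rcpp::Named("rmean") = best.convBn[l].rmean,
        Rcpp::Named("rvar") = best.convBn[l].rvar);
  }
  Rcpp::List weights = Rcpp::List::create(
      Rcpp::Named("conv") = conv_out,
      Rcpp::Named("fc") = Rcpp::List::create(
          Rcpp::Named("W") = best.fcW, Rcpp::Named("b") = best.fcB,
          Rcpp::Named("gamma") = best.fcBn.gamma,
          Rcpp::Named("beta") = best.fcBn.beta,
          Rcpp::Named("rmean") = best.fcBn.rmean,
          Rcpp::Named("rvar") = best.fcBn.rvar),
      Rcpp::Named("out") = Rcpp::List::create(
          Rcpp::Named("W") = best.outW,
          Rcpp::Named("b") = best.outB));
  mat loss_log(train_losses.size(), 2);
  for (uword i = 0; i < train_losses.size(); ++i) {
    loss_log(i, 0) = train_losses[i];
    loss_log(i, 1) = val_losses[i];
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = weights,
      Rcpp::Named("log") = loss_log,
      Rcpp::Named("best_val_loss") = best_val,
      Rcpp::Named("best_epoch") = (double)best_epoch);
}

static Params import_params(const Rcpp::List& weights) {
  Params p;
  Rcpp::List conv = weights["conv"];
  for (uword l = 0; l < (uword)conv.size(); ++l) {
    Rcpp::List lay = conv[l];
    p.convW.push_back(Rcpp::as<mat>(lay["W"]));
    p.convB.push_back(Rcpp::as<rowvec>(lay["b"]));
    BnLayer bn;
    bn.gamma = Rcpp::as<rowvec>(lay["gamma"]);
    bn.beta = Rcpp::as<rowvec>(lay["beta"]);
    bn.rmean = Rcpp::as<rowvec>(lay["rmean"]);
    bn.rvar = Rcpp::as<rowvec>(lay["rvar"]);
    p.convBn.push_back(bn);
  }
  Rcpp::List fc = weights["fc"];
  p.fcW = Rcpp::as<mat>(fc["W"]);
  p.fcB = Rcpp::as<rowvec>(fc["b"]);
  p.fcBn.gamma = Rcpp::as<rowvec>(fc["gamma"]);
  p.fcBn.beta = Rcpp::as<rowvec>(fc["beta"]);
  p.fcBn.rmean = Rcpp::as<rowvec>(fc["rmean"]);
  p.fcBn.rvar = Rcpp::as<rowvec>(fc["rvar"]);
  Rcpp::List out = weights["out"];
  p.outW = Rcpp::as<mat>(out["W"]);
  p.outB = Rcpp::as<double>(out["b"]);
  return p;
}

// [[Rcpp::export]]
Rcpp::NumericVector cnn_forward_cpp(Rcpp::List weights,
                                    Rcpp::NumericVector x_array,
                                    Rcpp::List config) {
  Rcpp::IntegerVector dims = x_array.attr("dim");
  if (dims.size() != 3) Rcpp::stop("X must be frames x channels x n");
  uword F = dims[0], C = dims[1], N = dims[2];
  cube X(x_array.begin(), F, C, N, false);
  Arch a = parse_arch(config, F, C);
  Params p = import_params(weights);
  std::vector<uword> idx(N);
  for (uword i = 0; i < N; ++i) idx[i] = i;
  vec z = forward_infer(p, a, X, idx);
  return Rcpp::wrap(z);
}

// [[Rcpp::export]]
Rcpp::List cnn_init_cpp(Rcpp::List config, int frames, int channels,
                        double seed) {
  Arch a = parse_arch(config, (uword)frames, (uword)channels);
  Rng rng((uint64_t)seed * 2654435761ULL + 1ULL);
  Params p = init_params(a, rng);
  Rcpp::List conv_out(a.kernels.n_elem);
  for (uword l = 0; l < a.kernels.n_elem; ++l) {
    conv_out[l] = Rcpp::List::create(
        Rcpp::Named("W") = p.convW[l], Rcpp::Named("b") = p.convB[l],
        Rcpp::Named("gamma") = p.convBn[l].gamma,
        Rcpp::Named("beta") = p.convBn[l].beta,
        Rcpp::Named("rmean") = p.convBn[l].rmean,
        Rcpp::Named("rvar") = p.convBn[l].rvar);
  }
  return Rcpp::List::create(
      Rcpp::Named("conv") = conv_out,
      Rcpp::Named("fc") = Rcpp::List::create(
          Rcpp::Named("W") = p.fcW, Rcpp::Named("b") = p.fcB,
          Rcpp::Named("gamma") = p.fcBn.gamma,
          Rcpp::Named("beta") = p.fcBn.beta,
          Rcpp::Named("rmean") = p.fcBn.rmean,
          Rcpp::Named("rvar") = p.fcBn.rvar),
      Rcpp::Named("out") = Rcpp::List::create(
          Rcpp::Named("W") = p.outW, Rcpp::Named("b") = p.outB));
}
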