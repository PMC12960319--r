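// Minimal U-Net style encoder-decoder for 4-class semantic segmentation of
// single-channel images, trained with softmax cross-entropy (optionally plus
// soft-DICE) and Adam. Feature maps are stored as (channels x H*W) matrices
// in R's column-major pixel order; 3x3 convolutions go through im2col + GEMM.
// All randomness (weight init, epoch shuffling) is drawn from R's RNG so that
// set.seed() on the R side makes training bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::IntegerMatrix;
using Rcpp::NumericMatrix;
using Rcpp::NumericVector;

static const int N_CLASSES = 4;

// ---- im2col / col2im for 3x3 kernels, zero padding 1 -----------------------

// patch rows are laid out k-major: row = k * C + c, with k = (dx+1)*3 + (dy+1)
static mat im2col3(const mat& F, int H, int W) {
  const int C = F.n_rows;
  mat cols(9 * C, H * W, fill::zeros);
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy) {
      const int k = (dx + 1) * 3 + (dy + 1);
      const int r0 = k * C, r1 = r0 + C - 1;
      const int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
      const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
      if (x1 <= x0 || y1 <= y0) continue;
      if (dy == 0) {  // full columns: one contiguous block copy
        cols.submat(r0, x0 * H, r1, x1 * H - 1) =
          F.cols((x0 + dx) * H, (x1 + dx) * H - 1);
      } else {
        for (int x = x0; x < x1; ++x) {
          cols.submat(r0, x * H + y0, r1, x * H + y1 - 1) =
            F.cols((x + dx) * H + y0 + dy, (x + dx) * H + y1 - 1 + dy);
        }
      }
    }
  }
  return cols;
}

static mat col2im3(const mat& dcols, int H, int W, int C) {
  mat dF(C, H * W, fill::zeros);
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy) {
      const int k = (dx + 1) * 3 + (dy + 1);
      const int r0 = k * C, r1 = r0 + C - 1;
      const int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
      const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
      if (x1 <= x0 || y1 <= y0) continue;
      if (dy == 0) {
        dF.cols((x0 + dx) * H, (x1 + dx) * H - 1) +=
          dcols.submat(r0, x0 * H, r1, x1 * H - 1);
      } else {
        for (int x = x0; x < x1; ++x) {
          dF.cols((x + dx) * H + y0 + dy, (x + dx) * H + y1 - 1 + dy) +=
            dcols.submat(r0, x * H + y0, r1, x * H + y1 - 1);
        }
      }
    }
  }
  return dF;
}

// ---- layers ----------------------------------------------------------------

struct Conv {
  mat W;        // (cout, k * cin)
  vec b;        // cout
  mat dW, mW, vW;
  vec db, mb, vb;
  int cin = 0, cout = 0, k = 9;
  bool relu = true;
  // per-image caches
  mat cols, out;
  int fh = 0, fw = 0;

  void init(int cin_, int cout_, int k_, bool relu_, bool rnd) {
    cin = cin_; cout = cout_; k = k_; relu = relu_;
    W.set_size(cout, k * cin);
    if (rnd) {  // He-normal init drawn from R's RNG
      const double sd = std::sqrt(2.0 / (k * cin));
      for (uword i = 0; i < W.n_elem; ++i) W(i) = R::norm_rand() * sd;
    } else {
      W.zeros();
    }
    b.zeros(cout);
    zero_grad();
    mW.zeros(size(W)); vW.zeros(size(W));
    mb.zeros(cout);    vb.zeros(cout);
  }

  void zero_grad() { dW.zeros(cout, k * cin); db.zeros(cout); }

  mat forward(const mat& in, int H, int Wd) {
    fh = H; fw = Wd;
    cols = (k == 9) ? im2col3(in, H, Wd) : in;
    out = W * cols;
    out.each_col() += b;
    if (relu) out.transform([](double v) { return v > 0.0 ? v : 0.0; });
    return out;
  }

  mat backward(mat dout) {
    if (relu) dout %= conv_to<mat>::from(out > 0.0);
    dW += dout * cols.t();
    db += sum(dout, 1);
    mat dcols = W.t() * dout;
    if (k == 9) return col2im3(dcols, fh, fw, cin);
    return dcols;
  }

  void adam(double lr, double b1, double b2, double eps, int t, int nbatch) {
    const double corr = lr * std::sqrt(1.0 - std::pow(b2, t)) /
                        (1.0 - std::pow(b1, t));
    mat g = dW / nbatch;
    mW = b1 * mW + (1 - b1) * g;
    vW = b2 * vW + (1 - b2) * square(g);
    W -= corr * mW / (sqrt(vW) + eps);
    vec gb = db / nbatch;
    mb = b1 * mb + (1 - b1) * gb;
    vb = b2 * vb + (1 - b2) * square(gb);
    b -= corr * mb / (sqrt(vb) + eps);
    zero_grad();
  }
};

static mat maxpool2(const mat& F, int H, int W, umat& amax) {
  const int C = F.n_rows, Ho = H / 2, Wo = W / 2;
  mat out(C, Ho * Wo);
  amax.set_size(C, Ho * Wo);
  for (int x = 0; x < Wo; ++x) {
    for (int y = 0; y < Ho; ++y) {
      const int o = y + x * Ho;
      const int i00 = 2 * y + 2 * x * H;
      const int idx[4] = { i00, i00 + 1, i00 + H, i00 + H + 1 };
      for (int c = 0; c < C; ++c) {
        double best = F(c, idx[0]);
        int bi = idx[0];
        for (int j = 1; j < 4; ++j) {
          const double v = F(c, idx[j]);
          if (v > best) { best = v; bi = idx[j]; }
        }
        out(c, o) = best;
        amax(c, o) = bi;
      }
    }
  }
  return out;
}

static mat maxpool2_back(const mat& dout, const umat& amax, int H, int W) {
  const int C = dout.n_rows;
  mat dF(C, H * W, fill::zeros);
  for (uword o = 0; o < dout.n_cols; ++o)
    for (int c = 0; c < C; ++c) dF(c, amax(c, o)) += dout(c, o);
  return dF;
}

// nearest-neighbour 2x upsampling; H, W are the *input* (coarse) dims
static mat upsample2(const mat& F, int H, int W) {
  const int C = F.n_rows, Ho = 2 * H, Wo = 2 * W;
  mat out(C, Ho * Wo);
  for (int x = 0; x < Wo; ++x) {
    for (int y = 0; y < Ho; ++y) {
      const int o = y + x * Ho;
      const int i = (y / 2) + (x / 2) * H;
      std::memcpy(out.colptr(o), F.colptr(i), C * sizeof(double));
    }
  }
  return out;
}

static mat upsample2_back(const mat& dout, int H, int W) {
  const int C = dout.n_rows, Ho = 2 * H;
  mat dF(C, H * W, fill::zeros);
  for (int x = 0; x < 2 * W; ++x) {
    for (int y = 0; y < Ho; ++y) {
      const int o = y + x * Ho;
      const int i = (y / 2) + (x / 2) * H;
      for (int c = 0; c < C; ++c) dF(c, i) += dout(c, o);
    }
  }
  return dF;
}

// ---- network ---------------------------------------------------------------

struct UNet {
  int depth, base, H, W;
  std::vector<Conv> enc1, enc2, up, dec;
  Conv bott1, bott2, head;
  std::vector<umat> amax;

  void build(int depth_, int base_, int H_, int W_, bool rnd) {
    depth = depth_; base = base_; H = H_; W = W_;
    enc1.resize(depth); enc2.resize(depth);
    up.resize(depth); dec.resize(depth);
    amax.resize(depth);
    for (int i = 0; i < depth; ++i) {
      const int ci = base << i;
      enc1[i].init(i == 0 ? 1 : (base << (i - 1)), ci, 9, true, rnd);
      enc2[i].init(ci, ci, 9, true, rnd);
      up[i].init(base << (i + 1), ci, 9, true, rnd);
      dec[i].init(2 * ci, ci, 9, true, rnd);
    }
    const int cb = base << depth;
    bott1.init(base << (depth - 1), cb, 9, true, rnd);
    bott2.init(cb, cb, 9, true, rnd);
    head.init(base, N_CLASSES, 1, false, rnd);
  }

  mat forward(const rowvec& pixels) {
    mat f = pixels;  // (1, HW)
    int h = H, w = W;
    for (int i = 0; i < depth; ++i) {
      f = enc1[i].forward(f, h, w);
      f = enc2[i].forward(f, h, w);  // enc2[i].out is the skip tensor
      f = maxpool2(f, h, w, amax[i]);
      h /= 2; w /= 2;
    }
    f = bott1.forward(f, h, w);
    f = bott2.forward(f, h, w);
    for (int i = depth - 1; i >= 0; --i) {
      f = upsample2(f, h, w);
      h *= 2; w *= 2;
      f = up[i].forward(f, h, w);
      f = join_cols(enc2[i].out, f);
      f = dec[i].forward(f, h, w);
    }
    return head.forward(f, H, W);  // logits (4, HW)
  }

  void backward(const mat& dlogits) {
    std::vector<mat> dskip(depth);
    mat d = head.backward(dlogits);
    int h = H, w = W;
    for (int i = 0; i < depth; ++i) {
      const int ci = base << i;
      d = dec[i].backward(d);
      dskip[i] = d.rows(0, ci - 1);
      mat dup = up[i].backward(d.rows(ci, 2 * ci - 1));
      h /= 2; w /= 2;
      d = upsample2_back(dup, h, w);
    }
    d = bott2.backward(d);
    d = bott1.backward(d);
    for (int i = depth - 1; i >= 0; --i) {
      d = maxpool2_back(d, amax[i], h * 2, w * 2);
      h *= 2; w *= 2;
      d += dskip[i];
      d = enc2[i].backward(d);
      d = enc1[i].backward(d);
    }
  }

  std::vector<Conv*> layers() {
    std::vector<Conv*> L;
    for (int i = 0; i < depth; ++i) { L.push_back(&enc1[i]); L.push_back(&enc2[i]); }
    L.push_back(&bott1); L.push_back(&bott2);
    for (int i = 0; i < depth; ++i) { L.push_back(&up[i]); L.push_back(&dec[i]); }
    L.push_back(&head);
    return L;
  }

  List export_weights() {
    List out;
    for (Conv* c : layers()) {
      out.push_back(Rcpp::wrap(c->W));
      out.push_back(Rcpp::wrap(c->b));
    }
    return out;
  }

  void import_weights(const List& w) {
    std::vector<Conv*> L = layers();
    if ((int)w.size() != (int)(2 * L.size()))
      Rcpp::stop("weight list does not match the network architecture");
    for (size_t i = 0; i < L.size(); ++i) {
      mat Wm = Rcpp::as<mat>(w[2 * i]);
      vec bv = Rcpp::as<vec>(w[2 * i + 1]);
      if (Wm.n_rows != L[i]->W.n_rows || Wm.n_cols != L[i]->W.n_cols)
        Rcpp::stop("weight matrix %d has the wrong shape", (int)i);
      L[i]->W = Wm;
      L[i]->b = bv;
    }
  }
};

// ---- loss ------------------------------------------------------------------

static mat softmax_cols(const mat& logits) {
  mat P = logits;
  for (uword j = 0; j < P.n_cols; ++j) {
    vec col = P.col(j);
    col -= col.max();
    col = exp(col);
    P.col(j) = col / accu(col);
  }
  return P;
}

// returns loss; fills dlogits
static double ce_dice_loss(const mat& logits, const ivec& labels,
                           bool dice_term, mat& dlogits) {
  const int HW = logits.n_cols;
  mat P = softmax_cols(logits);
  double ce = 0.0;
  dlogits = P;
  for (int j = 0; j < HW; ++j) {
    ce -= std::log(std::max(P(labels(j), j), 1e-12));
    dlogits(labels(j), j) -= 1.0;
  }
  ce /= HW;
  dlogits /= HW;

  double loss = ce;
  if (dice_term) {
    const double eps = 1.0;
    mat G(N_CLASSES, HW, fill::zeros);  // dL_dice / dP
    double ld = 0.0;
    for (int c = 1; c < N_CLASSES; ++c) {
      double sp = accu(P.row(c)), st = 0.0, spt = 0.0;
      for (int j = 0; j < HW; ++j) {
        if (labels(j) == c) { st += 1.0; spt += P(c, j); }
      }
      const double denom = sp + st + eps;
      const double D = (2.0 * spt + eps) / denom;
      ld += (1.0 - D) / 3.0;
      for (int j = 0; j < HW; ++j) {
        const double t = (labels(j) == c) ? 1.0 : 0.0;
        G(c, j) = -(2.0 * t * denom - (2.0 * spt + eps)) / (denom * denom) / 3.0;
      }
    }
    // chain through the per-pixel softmax
    for (int j = 0; j < HW; ++j) {
      double dot = 0.0;
      for (int c = 0; c < N_CLASSES; ++c) dot += P(c, j) * G(c, j);
      for (int c = 0; c < N_CLASSES; ++c)
        dlogits(c, j) += P(c, j) * (G(c, j) - dot);
    }
    loss += ld;
  }
  return loss;
}

// ---- evaluation ------------------------------------------------------------

static ivec argmax_labels(const mat& logits) {
  ivec lab(logits.n_cols);
  for (uword j = 0; j < logits.n_cols; ++j) {
    int best = 0;
    double bv = logits(0, j);
    for (int c = 1; c < N_CLASSES; ++c) {
      if (logits(c, j) > bv) { bv = logits(c, j); best = c; }  // ties: lowest
    }
    lab(j) = best;
  }
  return lab;
}

// per-class DICE over foreground classes 1..3; both-empty = 1, one-empty = 0
static vec dice_classes(const ivec& pred, const ivec& truth) {
  vec d(3);
  for (int c = 1; c <= 3; ++c) {
    double nx = 0, ny = 0, ni = 0;
    for (uword j = 0; j < pred.n_elem; ++j) {
      const bool px = pred(j) == c, py = truth(j) == c;
      nx += px; ny += py; ni += (px && py);
    }
    d(c - 1) = (nx + ny == 0) ? 1.0 : 2.0 * ni / (nx + ny);
  }
  return d;
}

static rowvec as_rowvec(const NumericMatrix& m) {
  return rowvec(Rcpp::as<std::vector<double>>(NumericVector(m)));
}

static ivec as_ivec(const IntegerMatrix& m) {
  Rcpp::IntegerVector v(m);
  ivec out(v.size());
  for (int i = 0; i < v.size(); ++i) out(i) = v[i];
  return out;
}

// ---- exported entry points -------------------------------------------------

// [[Rcpp::export]]
List cpp_unet_train(List images, List masks, List test_images, List test_masks,
                    int depth, int base, int epochs, double lr, int batch,
                    bool dice_loss, double grad_clip,
                    Rcpp::Nullable<List> weights_in) {
  Rcpp::RNGScope rng;
  const int n = images.size();
  if (n < 1) Rcpp::stop("empty training set");
  NumericMatrix first = images[0];
  const int H = first.nrow(), W = first.ncol();

  std::vector<rowvec> X(n);
  std::vector<ivec> Y(n);
  for (int i = 0; i < n; ++i) {
    NumericMatrix im = images[i];
    IntegerMatrix mk = masks[i];
    if (im.nrow() != H || im.ncol() != W || mk.nrow() != H || mk.ncol() != W)
      Rcpp::stop("image/mask %d does not match the training size %dx%d",
                 i + 1, H, W);
    X[i] = as_rowvec(im);
    Y[i] = as_ivec(mk);
  }
  const int nt = test_images.size();
  std::vector<rowvec> Xt(nt);
  std::vector<ivec> Yt(nt);
  for (int i = 0; i < nt; ++i) {
    NumericMatrix im = test_images[i];
    IntegerMatrix mk = test_masks[i];
    Xt[i] = as_rowvec(im);
    Yt[i] = as_ivec(mk);
  }

  UNet net;
  net.build(depth, base, H, W, weights_in.isNull());
  if (weights_in.isNotNull()) net.import_weights(List(weights_in));

  mat history(epochs, 6);
  int t_adam = 0;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  for (int e = 0; e < epochs; ++e) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double epoch_loss = 0.0;
    int done = 0;
    while (done < n) {
      const int bsz = std::min(batch, n - done);
      for (int bi = 0; bi < bsz; ++bi) {
        const int idx = order[done + bi];
        mat logits = net.forward(X[idx]);
        mat dlogits;
        epoch_loss += ce_dice_loss(logits, Y[idx], dice_loss, dlogits);
        net.backward(dlogits);
      }
      // clip the global gradient norm (mean-over-batch scale) for stability
      if (grad_clip > 0) {
        double sq = 0.0;
        for (Conv* c : net.layers()) {
          sq += accu(square(c->dW)) + accu(square(c->db));
        }
        const double norm = std::sqrt(sq) / bsz;
        if (norm > grad_clip) {
          const double f = grad_clip / norm;
          for (Conv* c : net.layers()) { c->dW *= f; c->db *= f; }
        }
      }
      ++t_adam;
      for (Conv* c : net.layers()) c->adam(lr, 0.9, 0.999, 1e-8, t_adam, bsz);
      done += bsz;
      Rcpp::checkUserInterrupt();
    }
    epoch_loss /= n;

    vec dsum(3, fill::zeros);
    for (int i = 0; i < nt; ++i) {
      ivec pred = argmax_labels(net.forward(Xt[i]));
      dsum += dice_classes(pred, Yt[i]);
    }
    vec dmean = (nt > 0) ? vec(dsum / nt) : vec(3, fill::value(datum::nan));
    history(e, 0) = e + 1;
    history(e, 1) = epoch_loss;
    history(e, 2) = mean(dmean);
    history(e, 3) = dmean(0);
    history(e, 4) = dmean(1);
    history(e, 5) = dmean(2);
  }

  return List::create(
    Rcpp::Named("weights") = net.export_weights(),
    Rcpp::Named("history") = Rcpp::wrap(history));
}

// [[Rcpp::export]]
IntegerMatrix cpp_unet_predict(List weights, int depth, int base,
                               NumericMatrix image) {
  const int H = image.nrow(), W = image.ncol();
  UNet net;
  net.build(depth, base, H, W, false);
  net.import_weights(weights);
  ivec lab = argmax_labels(net.forward(as_rowvec(image)));
  IntegerMatrix out(H, W);
  for (int j = 0; j < H * W; ++j) out[j] = (int)lab(j);
  return out;
}
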