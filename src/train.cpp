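#include <Rcpp.h>
using namespace Rcpp;

// regulariser codes: 0 = L1, 1 = L2, 2 = none
// gated = false selects the simplified gateless model (weights only, no penalty)

static inline double sgn0(double x) { return (x > 0) - (x < 0); } // sign(0) = 0 (subgradient)

// soft-threshold: proximal step of the L1 penalty. For |g| > alpha*lambda it
// equals the explicit subgradient step; unlike it, the penalty can never carry
// a gate through zero, so a dead gate stays dead absent data signal or noise.
static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// One online pass over the trial sequence. All four parameters are updated
// synchronously from the pre-update state; the same eta realisation enters the
// forward pass and the residual of that trial's updates. Noise draws (eta, xi)
// are supplied by the caller so that a stored trace can be replayed exactly.
// [[Rcpp::export]]
List cpp_train_scalar(NumericVector xm, NumericVector xc, NumericVector y,
                      NumericVector eta, NumericMatrix xi,
                      double alpha, double lambda, int reg, bool gated,
                      NumericVector init,
                      int intervene_trial = -1,
                      double target_abs_wm = NA_REAL,
                      double target_abs_wc = NA_REAL,
                      bool l1_prox = true) {
  int n = xm.size();
  if (xi.nrow() != n || xi.ncol() != 4) stop("xi must be n x 4 (wm, wc, gm, gc)");
  double wm = init[0], wc = init[1], gm = init[2], gc = init[3];

  NumericMatrix states(n, 4), grads(n, 4);
  NumericVector z(n);
  IntegerVector yhat(n), correct(n);

  for (int t = 0; t < n; ++t) {
    if (t == intervene_trial) {
      // sign-preserving reset of |w| (gates untouched)
      wm = (wm >= 0 ? 1.0 : -1.0) * target_abs_wm;
      wc = (wc >= 0 ? 1.0 : -1.0) * target_abs_wc;
    }
    states(t, 0) = wm; states(t, 1) = wc; states(t, 2) = gm; states(t, 3) = gc;

    double em = gated ? gm * wm : wm;   // effective weights
    double ec = gated ? gc * wc : wc;
    double zt = em * xm[t] + ec * xc[t] + eta[t];
    z[t] = zt;
    yhat[t] = zt >= 0 ? 1 : -1;         // sign(0) = +1 (decision tie-break)
    correct[t] = (yhat[t] == (int)y[t]) ? 1 : 0;

    double r = zt - y[t];               // shared residual
    double dwm, dwc, dgm = 0.0, dgc = 0.0;
    double dgm_dat = 0.0, dgc_dat = 0.0;
    if (gated) {
      dwm = xm[t] * gm * r;
      dwc = xc[t] * gc * r;
      dgm_dat = xm[t] * wm * r;
      dgc_dat = xc[t] * wc * r;
      dgm = dgm_dat; dgc = dgc_dat;
      if (reg == 0) { dgm += lambda * sgn0(gm); dgc += lambda * sgn0(gc); }
      else if (reg == 1) { dgm += lambda * gm; dgc += lambda * gc; }
    } else {
      dwm = xm[t] * r;
      dwc = xc[t] * r;
    }
    grads(t, 0) = dwm; grads(t, 1) = dwc; grads(t, 2) = dgm; grads(t, 3) = dgc;

    wm += -alpha * dwm + xi(t, 0);
    wc += -alpha * dwc + xi(t, 1);
    if (gated) {
      if (reg == 0 && l1_prox) {
        gm = soft(gm - alpha * dgm_dat + xi(t, 2), alpha * lambda);
        gc = soft(gc - alpha * dgc_dat + xi(t, 3), alpha * lambda);
      } else {
        gm += -alpha * dgm + xi(t, 2);
        gc += -alpha * dgc + xi(t, 3);
      }
    }
    if (!R_finite(wm) || !R_finite(wc) || !R_finite(gm) || !R_finite(gc))
      stop("non-finite parameter update at trial %d (overflow)", t + 1);
  }

  return List::create(_["states"] = states, _["grads"] = grads, _["z"] = z,
                      _["yhat"] = yhat, _["correct"] = correct,
                      _["final"] = NumericVector::create(wm, wc, gm, gc));
}

// Lean objective kernel for accuracy matching: trains on a fixed curriculum
// (inputs reconstructed from standardised motion noise zm and candidate means M),
// then returns, per coherence level, the trajectory-averaged closed-form
// accuracy over motion-phase trials with the colour channel uncorrelated
// (its random-sign mean contributes only variance).
// [[Rcpp::export]]
NumericVector cpp_match_accuracy(NumericVector zm, NumericVector xc,
                                 NumericVector y, IntegerVector coh,
                                 LogicalVector in_motion,
                                 NumericVector eta, NumericMatrix xi,
                                 NumericVector M, double sigma_m,
                                 double M_c, double sigma_c, double sigma_eta,
                                 double alpha, double lambda, int reg,
                                 NumericVector init, bool l1_prox = true) {
  int n = zm.size();
  int K = M.size();
  double wm = init[0], wc = init[1], gm = init[2], gc = init[3];
  NumericVector psum(K);
  IntegerVector pcnt(K);

  for (int t = 0; t < n; ++t) {
    double xmt = y[t] * M[coh[t]] + sigma_m * zm[t];
    if (in_motion[t]) {
      // colour uncorrelated here: its random-sign mean makes the output a
      // two-component mixture, averaged over the signed colour means
      double em = gm * wm, ec = gc * wc;
      double mu = em * M[coh[t]];
      double var = em * em * sigma_m * sigma_m +
                   ec * ec * sigma_c * sigma_c + sigma_eta * sigma_eta;
      double p;
      if (var <= 0) {
        double a = mu + ec * M_c, b = mu - ec * M_c;
        p = 0.5 * (a == 0 ? 0.5 : (a > 0 ? 1.0 : 0.0)) +
            0.5 * (b == 0 ? 0.5 : (b > 0 ? 1.0 : 0.0));
      } else {
        double s = std::sqrt(var);
        p = 0.5 * R::pnorm((mu + ec * M_c) / s, 0.0, 1.0, 1, 0) +
            0.5 * R::pnorm((mu - ec * M_c) / s, 0.0, 1.0, 1, 0);
      }
      psum[coh[t]] += p;
      pcnt[coh[t]] += 1;
    }
    double zt = gm * wm * xmt + gc * wc * xc[t] + eta[t];
    double r = zt - y[t];
    double dwm = xmt * gm * r;
    double dwc = xc[t] * gc * r;
    double dgm = xmt * wm * r;
    double dgc = xc[t] * wc * r;
    wm += -alpha * dwm + xi(t, 0);
    wc += -alpha * dwc + xi(t, 1);
    if (reg == 0 && l1_prox) {
      gm = soft(gm - alpha * dgm + xi(t, 2), alpha * lambda);
      gc = soft(gc - alpha * dgc + xi(t, 3), alpha * lambda);
    } else {
      if (reg == 0) { dgm += lambda * sgn0(gm); dgc += lambda * sgn0(gc); }
      else if (reg == 1) { dgm += lambda * gm; dgc += lambda * gc; }
      gm += -alpha * dgm + xi(t, 2);
      gc += -alpha * dgc + xi(t, 3);
    }
  }
  NumericVector acc(K);
  for (int k = 0; k < K; ++k) acc[k] = pcnt[k] > 0 ? psum[k] / pcnt[k] : NA_REAL;
  return acc;
}

// ---- hidden-layer variant: 2 -> 48 ReLU -> 2, multiplicative gate on every
// input->hidden weight, L1 penalty on gates only, softmax/cross-entropy. ----

// One forward/backward step with explicit noise; returns gradients and the
// updated parameters. Used directly by the trainer and by finite-difference
// gradient checks (no noise).
static void hidden_step(const double* x, int ycls,
                        NumericMatrix& W1, NumericMatrix& G, NumericMatrix& W2,
                        const double* eta_out,
                        double alpha, double lambda,
                        double sigma_xi, bool add_noise,
                        NumericMatrix* gW1, NumericMatrix* gG, NumericMatrix* gW2,
                        double* loss_out, int* pred_out) {
  int H = W1.ncol();
  std::vector<double> a(H), h(H);
  double o0 = eta_out[0], o1 = eta_out[1];
  for (int j = 0; j < H; ++j) {
    double aj = G(0, j) * W1(0, j) * x[0] + G(1, j) * W1(1, j) * x[1];
    a[j] = aj;
    h[j] = aj > 0 ? aj : 0.0;
    o0 += W2(j, 0) * h[j];
    o1 += W2(j, 1) * h[j];
  }
  double mx = std::max(o0, o1);
  double e0 = std::exp(o0 - mx), e1 = std::exp(o1 - mx);
  double Z = e0 + e1;
  double p0 = e0 / Z, p1 = e1 / Z;
  if (loss_out) *loss_out = -std::log(ycls == 0 ? p0 : p1);
  if (pred_out) *pred_out = (o1 > o0) ? 1 : 0;

  double d0 = p0 - (ycls == 0 ? 1.0 : 0.0);
  double d1 = p1 - (ycls == 1 ? 1.0 : 0.0);

  // gradients, then synchronous update
  for (int j = 0; j < H; ++j) {
    double dh = W2(j, 0) * d0 + W2(j, 1) * d1;
    double da = (a[j] > 0) ? dh : 0.0;
    double gw20 = h[j] * d0, gw21 = h[j] * d1;
    double dV0 = x[0] * da, dV1 = x[1] * da;     // grad wrt effective weight
    double W1pre0 = W1(0, j), W1pre1 = W1(1, j);
    double gw10 = dV0 * G(0, j), gw11 = dV1 * G(1, j);
    double gg0 = dV0 * W1pre0 + lambda * sgn0(G(0, j));
    double gg1 = dV1 * W1pre1 + lambda * sgn0(G(1, j));
    if (gW1) { (*gW1)(0, j) = gw10; (*gW1)(1, j) = gw11; }
    if (gG)  { (*gG)(0, j) = gg0;  (*gG)(1, j) = gg1; }
    if (gW2) { (*gW2)(j, 0) = gw20; (*gW2)(j, 1) = gw21; }
    double n_w10 = 0, n_w11 = 0, n_g0 = 0, n_g1 = 0, n_w20 = 0, n_w21 = 0;
    if (add_noise) {
      n_w10 = R::norm_rand() * sigma_xi; n_w11 = R::norm_rand() * sigma_xi;
      n_g0 = R::norm_rand() * sigma_xi;  n_g1 = R::norm_rand() * sigma_xi;
      n_w20 = R::norm_rand() * sigma_xi; n_w21 = R::norm_rand() * sigma_xi;
    }
    W1(0, j) += -alpha * gw10 + n_w10;
    W1(1, j) += -alpha * gw11 + n_w11;
    G(0, j) = soft(G(0, j) - alpha * dV0 * W1pre0 + n_g0, alpha * lambda);
    G(1, j) = soft(G(1, j) - alpha * dV1 * W1pre1 + n_g1, alpha * lambda);
    W2(j, 0) += -alpha * gw20 + n_w20;
    W2(j, 1) += -alpha * gw21 + n_w21;
  }
}

// [[Rcpp::export]]
List cpp_train_hidden(NumericMatrix X, IntegerVector ycls,
                      NumericMatrix W1, NumericMatrix G, NumericMatrix W2,
                      double alpha, double lambda,
                      double sigma_eta, double sigma_xi) {
  int n = X.nrow(), H = W1.ncol();
  NumericMatrix W1c(clone(W1)), Gc(clone(G)), W2c(clone(W2));
  IntegerVector correct(n), pred(n);
  NumericVector loss(n);
  NumericMatrix wnorm(n, 2), gnorm(n, 2);
  RNGScope scope;
  for (int t = 0; t < n; ++t) {
    for (int i = 0; i < 2; ++i) {
      double sw = 0, sg = 0;
      for (int j = 0; j < H; ++j) { sw += std::fabs(W1c(i, j)); sg += std::fabs(Gc(i, j)); }
      wnorm(t, i) = sw / H; gnorm(t, i) = sg / H;
    }
    double x[2] = { X(t, 0), X(t, 1) };
    double eta[2] = { R::norm_rand() * sigma_eta, R::norm_rand() * sigma_eta };
    double l; int p;
    hidden_step(x, ycls[t], W1c, Gc, W2c, eta, alpha, lambda, sigma_xi, true,
                nullptr, nullptr, nullptr, &l, &p);
    loss[t] = l; pred[t] = p; correct[t] = (p == ycls[t]) ? 1 : 0;
  }
  return List::create(_["correct"] = correct, _["pred"] = pred, _["loss"] = loss,
                      _["wnorm"] = wnorm, _["gnorm"] = gnorm,
                      _["W1"] = W1c, _["G"] = Gc, _["W2"] = W2c);
}

// Single noiseless step exposed for gradient checking and unit tests.
// [[Rcpp::export]]
List cpp_hidden_step(NumericVector x, int ycls,
                     NumericMatrix W1, NumericMatrix G, NumericMatrix W2,
                     NumericVector eta_out, double alpha, double lambda) {
  NumericMatrix W1c(clone(W1)), Gc(clone(G)), W2c(clone(W2));
  int H = W1.ncol();
  NumericMatrix gW1(2, H), gG(2, H), gW2(H, 2);
  double xv[2] = { x[0], x[1] };
  double ev[2] = { eta_out[0], eta_out[1] };
  double l; int p;
  hidden_step(xv, ycls, W1c, Gc, W2c, ev, alpha, lambda, 0.0, false,
              &gW1, &gG, &gW2, &l, &p);
  return List::create(_["gW1"] = gW1, _["gG"] = gG, _["gW2"] = gW2,
                      _["W1"] = W1c, _["G"] = Gc, _["W2"] = W2c,
                      _["loss"] = l, _["pred"] = p);
}
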