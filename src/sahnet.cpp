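#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Logistic unit with offset and temperature: f(net) = 1/(1+exp(-(net-offset)/T)).
static inline double act(double net, double offset, double invT) {
  return 1.0 / (1.0 + std::exp(-(net - offset) * invT));
}

// One forward pass of the one-step-delay dynamics.
// W is (to x from); the first n_in units are clamped to `inputs` each step;
// dead (alive==FALSE) non-input units stay exactly 0. Initial state `init`.
static void forward_pass(const NumericMatrix& W, const NumericMatrix& inputs,
                         const LogicalVector& alive, double offset, double invT,
                         const std::vector<double>& init, NumericMatrix& A) {
  const int T = inputs.nrow(), n_in = inputs.ncol(), N = W.nrow();
  std::vector<double> prev(init), cur(N, 0.0);
  for (int t = 0; t < T; ++t) {
    for (int j = 0; j < n_in; ++j) cur[j] = inputs(t, j);
    for (int i = n_in; i < N; ++i) {
      if (!alive[i]) { cur[i] = 0.0; continue; }
      double s = 0.0;
      for (int j = 0; j < N; ++j) s += W(i, j) * prev[j];
      cur[i] = act(s, offset, invT);
    }
    for (int i = 0; i < N; ++i) { A(t, i) = cur[i]; prev[i] = cur[i]; }
  }
}

// Mean squared error of the output units over valid steps.
static double mse_of(const NumericMatrix& W, const NumericMatrix& inputs,
                     const NumericMatrix& targets, const LogicalVector& valid,
                     const LogicalVector& alive, double offset, double invT,
                     NumericMatrix& A) {
  const int T = inputs.nrow(), N = W.nrow(), n_out = targets.ncol();
  forward_pass(W, inputs, alive, offset, invT, std::vector<double>(N, 0.0), A);
  double sse = 0.0; int nv = 0;
  for (int t = 0; t < T; ++t) {
    if (!valid[t]) continue;
    ++nv;
    for (int k = 0; k < n_out; ++k) {
      double d = A(t, N - n_out + k) - targets(t, k);
      sse += d * d;
    }
  }
  if (nv == 0) return NA_REAL;
  return sse / ((double)nv * n_out);
}

// BPTT gradient of the MSE objective w.r.t. every weight; returns the MSE.
// G is accumulated into (caller zeroes it); entries for absent weights are
// masked out by the caller.
static double grad_of(const NumericMatrix& W, const NumericMatrix& inputs,
                      const NumericMatrix& targets, const LogicalVector& valid,
                      const LogicalVector& alive, double offset, double invT,
                      NumericMatrix& A, NumericMatrix& G,
                      double flat_spot = 0.0) {
  const int T = inputs.nrow(), n_in = inputs.ncol(), N = W.nrow();
  const int n_out = targets.ncol();
  forward_pass(W, inputs, alive, offset, invT, std::vector<double>(N, 0.0), A);
  int nv = 0;
  for (int t = 0; t < T; ++t) if (valid[t]) ++nv;
  if (nv == 0) return NA_REAL;
  const double denom = (double)nv * n_out;
  double sse = 0.0;
  std::vector<double> delta(N, 0.0), delta_next(N, 0.0);
  for (int t = T - 1; t >= 0; --t) {
    for (int i = n_in; i < N; ++i) {
      if (!alive[i]) { delta[i] = 0.0; continue; }
      double dA = 0.0;
      for (int ip = n_in; ip < N; ++ip)
        if (delta_next[ip] != 0.0) dA += delta_next[ip] * W(ip, i);
      const int k = i - (N - n_out);
      if (k >= 0 && valid[t]) {
        const double diff = A(t, i) - targets(t, k);
        dA += 2.0 * diff / denom;
        sse += diff * diff;
      }
      const double a = A(t, i);
      delta[i] = dA * (a * (1.0 - a) + flat_spot) * invT;
    }
    if (t > 0) {
      for (int i = n_in; i < N; ++i) {
        const double di = delta[i];
        if (di == 0.0) continue;
        for (int j = 0; j < N; ++j) G(i, j) += di * A(t - 1, j);
      }
    }
    std::swap(delta, delta_next);
  }
  return sse / denom;
}

// [[Rcpp::export]]
NumericMatrix cpp_forward(NumericMatrix W, NumericMatrix inputs,
                          LogicalVector alive, double offset, double temperature,
                          NumericVector init) {
  const int T = inputs.nrow(), N = W.nrow();
  NumericMatrix A(T, N);
  std::vector<double> init_v(N, 0.0);
  for (int i = 0; i < N && i < init.size(); ++i) init_v[i] = init[i];
  forward_pass(W, inputs, alive, offset, 1.0 / temperature, init_v, A);
  return A;
}

// [[Rcpp::export]]
double cpp_mse(NumericMatrix W, NumericMatrix inputs, NumericMatrix targets,
               LogicalVector valid, LogicalVector alive, double offset,
               double temperature) {
  NumericMatrix A(inputs.nrow(), W.nrow());
  return mse_of(W, inputs, targets, valid, alive, offset, 1.0 / temperature, A);
}

// [[Rcpp::export]]
List cpp_grad(NumericMatrix W, LogicalMatrix mask, NumericMatrix inputs,
              NumericMatrix targets, LogicalVector valid, LogicalVector alive,
              double offset, double temperature) {
  const int N = W.nrow();
  NumericMatrix A(inputs.nrow(), N), G(N, N);
  double mse = grad_of(W, inputs, targets, valid, alive, offset,
                       1.0 / temperature, A, G);
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i)
      if (!mask(i, j)) G(i, j) = 0.0;
  return List::create(_["gradient"] = G, _["mse"] = mse);
}

static inline double clamp1(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

struct EpisodeView {
  const double* inputs;   // T x n_in, column-major
  const double* targets;  // T x n_out, column-major
};

// Error of W moved distance s along unit direction d, projected into bounds.
static double step_err(const NumericMatrix& W, const NumericMatrix& D, double s,
                       const NumericMatrix& lb, const NumericMatrix& ub,
                       const std::vector<EpisodeView>& eps, int T, int n_in,
                       int n_out, const LogicalVector& valid,
                       const LogicalVector& alive, double offset, double invT,
                       NumericMatrix& Wtmp, NumericMatrix& A) {
  const int N = W.nrow();
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i)
      Wtmp(i, j) = clamp1(W(i, j) + s * D(i, j), lb(i, j), ub(i, j));
  double tot = 0.0;
  for (size_t e = 0; e < eps.size(); ++e) {
    NumericMatrix inp(T, n_in, eps[e].inputs);
    NumericMatrix tgt(T, n_out, eps[e].targets);
    tot += mse_of(Wtmp, inp, tgt, valid, alive, offset, invT, A);
  }
  return tot / eps.size();
}

// Backtracking line search: try step0 and halve until the error improves on
// err0, accepting the first improving step (at most max_evals evaluations).
// Returns the accepted step (0 if nothing improved) and its error.
static void line_search(const NumericMatrix& W, const NumericMatrix& D,
                        double step0, double err0, int max_evals,
                        const NumericMatrix& lb, const NumericMatrix& ub,
                        const std::vector<EpisodeView>& eps, int T, int n_in,
                        int n_out, const LogicalVector& valid,
                        const LogicalVector& alive, double offset, double invT,
                        NumericMatrix& Wtmp, NumericMatrix& A,
                        double& best_s, double& best_err) {
  best_s = 0.0; best_err = err0;
  const double s_max = 4.0;  // cap so one episode cannot rail the weights
  int evals = 0;
  double s = std::min(step0, s_max);
  double e = step_err(W, D, s, lb, ub, eps, T, n_in, n_out, valid, alive,
                      offset, invT, Wtmp, A);
  ++evals;
  if (e < best_err) {
    best_err = e; best_s = s;
    while (evals < max_evals && s * 2.0 <= s_max) {  // grow while improving
      s *= 2.0;
      e = step_err(W, D, s, lb, ub, eps, T, n_in, n_out, valid, alive, offset,
                   invT, Wtmp, A);
      ++evals;
      if (e < best_err) { best_err = e; best_s = s; } else break;
    }
  } else {
    while (evals < max_evals) {        // back off until something improves
      s *= 0.5;
      e = step_err(W, D, s, lb, ub, eps, T, n_in, n_out, valid, alive, offset,
                   invT, Wtmp, A);
      ++evals;
      if (e < best_err) { best_err = e; best_s = s; break; }
      if (s < 1e-10) break;
    }
  }
}

// Mean over test episodes of per-episode RMS output error, as percent.
static double test_percent_error(const NumericMatrix& W,
                                 const NumericVector& test_inputs,
                                 const NumericVector& test_targets,
                                 int n_test, int T, int n_in, int n_out,
                                 const LogicalVector& valid,
                                 const LogicalVector& alive, double offset,
                                 double invT, NumericMatrix& A) {
  double tot = 0.0;
  const double* ip = REAL(test_inputs);
  const double* tp = REAL(test_targets);
  for (int e = 0; e < n_test; ++e) {
    NumericMatrix inp(T, n_in, ip + (size_t)e * T * n_in);
    NumericMatrix tgt(T, n_out, tp + (size_t)e * T * n_out);
    tot += std::sqrt(mse_of(W, inp, tgt, valid, alive, offset, invT, A));
  }
  return 100.0 * tot / n_test;
}

// Run n_epochs of training: per epoch take `epe` fresh episodes, compute the
// first-order (normalized steepest-descent) direction and a second candidate
// preconditioned per weight by running moment estimates of the gradient
// history, line-search both, accept the better strictly-improving step,
// project into sign-class bounds, then optionally apply weight decay.
// Records the mean percent RMS error on the fixed test stream every
// `eval_every` epochs (global epoch counter starts at epoch_offset).
// [[Rcpp::export]]
List cpp_train_phase(NumericMatrix W_in, LogicalMatrix mask, NumericMatrix lb,
                     NumericMatrix ub, LogicalVector alive,
                     NumericVector inputs_all, NumericVector targets_all,
                     int n_episodes, int T, int n_in, int n_out,
                     LogicalVector valid, double offset, double temperature,
                     int n_epochs, int epe, double decay_amount, List state,
                     int max_evals, double flat_spot, NumericVector test_inputs,
                     NumericVector test_targets, int n_test, int eval_every,
                     int epoch_offset) {
  const int N = W_in.nrow();
  const double invT = 1.0 / temperature;
  NumericMatrix W = clone(W_in);
  NumericMatrix G(N, N), M1(N, N), M2(N, N), D1(N, N), D2(N, N);
  NumericMatrix Wtmp(N, N), A(T, N);
  bool have_prev = as<bool>(state["have_prev"]);
  double step1 = as<double>(state["step1"]);
  double step2 = as<double>(state["step2"]);
  double tmoments = as<double>(state["t_moments"]);
  if (have_prev) {
    NumericMatrix m1 = state["m1"], m2 = state["m2"];
    M1 = clone(m1); M2 = clone(m2);
  }
  const double b1 = 0.9, b2 = 0.999, meps = 1e-8;
  if (n_episodes < n_epochs * epe) stop("not enough episodes supplied");

  std::vector<double> hist_epoch, hist_err;
  const double* ip_all = REAL(inputs_all);
  const double* tp_all = REAL(targets_all);
  int ep_idx = 0;

  for (int epoch = 0; epoch < n_epochs; ++epoch) {
    // gradient averaged over this epoch's episodes
    std::fill(G.begin(), G.end(), 0.0);
    std::vector<EpisodeView> eps(epe);
    double err0 = 0.0;
    for (int e = 0; e < epe; ++e, ++ep_idx) {
      eps[e].inputs = ip_all + (size_t)ep_idx * T * n_in;
      eps[e].targets = tp_all + (size_t)ep_idx * T * n_out;
      NumericMatrix inp(T, n_in, eps[e].inputs);
      NumericMatrix tgt(T, n_out, eps[e].targets);
      err0 += grad_of(W, inp, tgt, valid, alive, offset, invT, A, G,
                      flat_spot);
    }
    err0 /= epe;
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < N; ++i)
        if (!mask(i, j)) G(i, j) = 0.0;

    // project out components that would push weights already sitting on a
    // bound further outside: descent quality near the rails depends on it
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < N; ++i) {
        if (!mask(i, j)) continue;
        const double w = W(i, j);
        if ((w >= ub(i, j) && G(i, j) < 0.0) ||
            (w <= lb(i, j) && G(i, j) > 0.0))
          G(i, j) = 0.0;
      }

    double gnorm2 = 0.0;
    for (int k = 0; k < N * N; ++k) gnorm2 += G[k] * G[k];
    if (gnorm2 > 0.0) {
      // first-order candidate: normalized steepest descent (the step length
      // carries the scale, adapted across epochs)
      const double gnorm = std::sqrt(gnorm2);
      for (int k = 0; k < N * N; ++k) D1[k] = -G[k] / gnorm;

      double s1, e1, s2 = 0.0, e2 = err0;
      line_search(W, D1, step1, err0, max_evals, lb, ub, eps, T, n_in, n_out,
                  valid, alive, offset, invT, Wtmp, A, s1, e1);

      // second-order candidate: gradient preconditioned per weight by
      // running first/second moment estimates of the gradient history,
      // which rescales the persistently small derivatives of silent or
      // saturated units into an effective search direction
      tmoments += 1.0;
      const double c1 = 1.0 - std::pow(b1, tmoments);
      const double c2 = 1.0 - std::pow(b2, tmoments);
      double d2norm2 = 0.0, descent = 0.0;
      for (int k = 0; k < N * N; ++k) {
        M1[k] = b1 * M1[k] + (1.0 - b1) * G[k];
        M2[k] = b2 * M2[k] + (1.0 - b2) * G[k] * G[k];
        D2[k] = -(M1[k] / c1) / (std::sqrt(M2[k] / c2) + meps);
        d2norm2 += D2[k] * D2[k];
        descent -= D2[k] * G[k];
      }
      bool used2 = false;
      if (d2norm2 > 0.0 && descent > 0.0) {
        const double d2norm = std::sqrt(d2norm2);
        for (int k = 0; k < N * N; ++k) D2[k] /= d2norm;
        line_search(W, D2, step2, err0, max_evals, lb, ub, eps, T, n_in,
                    n_out, valid, alive, offset, invT, Wtmp, A, s2, e2);
        used2 = true;
      }

      // accept the better strictly-improving candidate
      const bool pick2 = used2 && e2 < e1 && s2 > 0.0;
      const double s_best = pick2 ? s2 : s1;
      NumericMatrix& D = pick2 ? D2 : D1;
      if (s_best > 0.0) {
        for (int j = 0; j < N; ++j)
          for (int i = 0; i < N; ++i)
            W(i, j) = clamp1(W(i, j) + s_best * D(i, j), lb(i, j), ub(i, j));
      }
      // adapt each family's initial step toward its last accepted value
      if (s1 > 0.0) step1 = s1;
      else step1 = std::max(step1 * 0.5, 1e-12);
      if (used2) {
        if (s2 > 0.0) step2 = s2;
        else step2 = std::max(step2 * 0.5, 1e-12);
      }
      have_prev = true;
    }

    if (decay_amount > 0.0) {
      for (int j = 0; j < N; ++j)
        for (int i = 0; i < N; ++i) {
          if (!mask(i, j)) continue;
          double w = W(i, j);
          double m = std::fabs(w) - decay_amount;
          if (m < 0.0) m = 0.0;
          W(i, j) = w < 0.0 ? -m : m;
        }
    }

    const int global_epoch = epoch_offset + epoch + 1;
    if (eval_every > 0 && n_test > 0 &&
        (global_epoch % eval_every == 0 || epoch == n_epochs - 1)) {
      double pe = test_percent_error(W, test_inputs, test_targets, n_test, T,
                                     n_in, n_out, valid, alive, offset, invT, A);
      hist_epoch.push_back(global_epoch);
      hist_err.push_back(pe);
    }
  }

  return List::create(
      _["weights"] = W,
      _["state"] = List::create(_["have_prev"] = have_prev, _["m1"] = M1,
                                _["m2"] = M2, _["t_moments"] = tmoments,
                                _["step1"] = step1, _["step2"] = step2),
      _["history_epoch"] = wrap(hist_epoch), _["history_error"] = wrap(hist_err));
}

// [[Rcpp::export]]
double cpp_test_error(NumericMatrix W, NumericVector test_inputs,
                      NumericVector test_targets, int n_test, int T, int n_in,
                      int n_out, LogicalVector valid, LogicalVector alive,
                      double offset, double temperature) {
  NumericMatrix A(T, W.nrow());
  return test_percent_error(W, test_inputs, test_targets, n_test, T, n_in,
                            n_out, valid, alive, offset, 1.0 / temperature, A);
}
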