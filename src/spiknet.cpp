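#include <Rcpp.h>
using namespace Rcpp;

// Development loop for the spiking network: Poisson ON/OFF inputs, leaky
// integrate-and-fire outputs with an input-mean-cancellation current, and
// triplet STDP (linear or heterosynaptic LTD) on the excitatory weights,
// optionally with inhibitory STDP on recurrent connections.
//
// rates: n_patches x C matrix of Poisson rates (Hz), one row per patch.
// Uses R's RNG: determinism is controlled by set.seed() in the caller.
// [[Rcpp::export]]
List run_development_cpp(NumericMatrix rates, int n_neurons, int steps_per_patch,
                         double dt, double v_rest, double v_threshold,
                         double v_reset, double tau_mem,
                         double eta_plus, double eta_minus,
                         double lambda_decay, double trace_tau, double tau_h,
                         double ltd_scale, bool heterosyn, double w_max,
                         bool lateral_inhibition, double inhib_eta,
                         double inhib_theta, double inhib_lambda,
                         double w_init_max, double init_rate_hz, int record_rate_every) {
  RNGScope scope;
  const int n_patches = rates.nrow();
  const int C = rates.ncol();
  const int M = n_neurons;
  const double dts = dt / 1000.0;          // step in seconds
  const double trace_decay = std::exp(-dt / trace_tau);
  const double trace_jump = 1.0;           // unitless traces, jump 1 per spike
  const double rate_alpha = dts / tau_h;   // EMA coefficient for rate estimates
  const double leak = dt / tau_mem;

  NumericMatrix W(M, C);
  for (int m = 0; m < M; ++m)
    for (int c = 0; c < C; ++c) W(m, c) = unif_rand() * w_init_max;
  NumericMatrix Winh(M, M);                // stored non-positive

  std::vector<double> v(M, v_rest);
  std::vector<double> xbar_plus(C, 0.0);   // presynaptic LTP trace
  std::vector<double> rhat(C, 0.0);        // input rate estimate (spikes/step)
  std::vector<double> ybar_plus(M, 0.0), ybar_minus(M, 0.0), ybar_inh(M, 0.0);
  std::vector<double> out_rate(M, init_rate_hz);  // output rate estimate, Hz
  std::vector<int> sx(C), sy(M), sy_prev(M, 0);

  // initialise the input-rate estimates at their stationary values so the
  // mean-cancellation current is balanced from the start
  {
    std::vector<double> mean_p(C, 0.0);
    for (int k = 0; k < n_patches; ++k)
      for (int c = 0; c < C; ++c) mean_p[c] += rates(k, c);
    for (int c = 0; c < C; ++c) rhat[c] = mean_p[c] / n_patches * dts;
  }

  int n_rec = (record_rate_every > 0) ? n_patches / record_rate_every : 0;
  NumericVector rate_trace(n_rec), ltp_trace(n_rec), ltd_trace(n_rec);
  int rec_i = 0;
  double ltp_acc = 0.0, ltd_acc = 0.0;

  for (int k = 0; k < n_patches; ++k) {
    for (int t = 0; t < steps_per_patch; ++t) {
      // presynaptic spikes and traces
      for (int c = 0; c < C; ++c) {
        double p = rates(k, c) * dts;
        sx[c] = (unif_rand() < p) ? 1 : 0;
        xbar_plus[c] = xbar_plus[c] * trace_decay + sx[c] * trace_jump;
        rhat[c] += rate_alpha * (sx[c] - rhat[c]);
      }
      // membrane integration with mean-cancellation current
      for (int m = 0; m < M; ++m) {
        double I = 0.0;
        for (int c = 0; c < C; ++c)
          if (sx[c]) I += W(m, c);
        for (int c = 0; c < C; ++c) I -= W(m, c) * rhat[c];
        if (lateral_inhibition) {
          for (int j = 0; j < M; ++j)
            if (sy_prev[j]) I += Winh(m, j);
        }
        v[m] += leak * (v_rest - v[m]) + I;
        if (!std::isfinite(v[m])) stop("non-finite membrane potential");
        if (v[m] >= v_threshold) { sy[m] = 1; v[m] = v_reset; }
        else sy[m] = 0;
      }
      // triplet LTP at postsynaptic spikes (ybar_plus taken before this
      // spike is added to the trace); linear LTD at presynaptic spikes
      for (int m = 0; m < M; ++m) {
        if (sy[m]) {
          double a = eta_plus * ybar_plus[m];
          if (a != 0.0)
            for (int c = 0; c < C; ++c) {
              W(m, c) += a * xbar_plus[c];
              ltp_acc += a * xbar_plus[c];
            }
        }
        double hy = out_rate[m] * out_rate[m];
        if (heterosyn) {
          double d = eta_minus * ltd_scale * hy * dts;
          if (d != 0.0)
            for (int c = 0; c < C; ++c) {
              W(m, c) -= d * W(m, c);
              ltd_acc += d * W(m, c);
            }
        } else {
          double d = eta_minus * ltd_scale * hy * ybar_minus[m];
          if (d != 0.0)
            for (int c = 0; c < C; ++c)
              if (sx[c]) { W(m, c) -= d; ltd_acc += d; }
        }
      }
      // weight decay and clipping
      double wd = lambda_decay * dts;
      for (int m = 0; m < M; ++m)
        for (int c = 0; c < C; ++c) {
          double w = W(m, c) - wd * W(m, c);
          if (w < 0.0) w = 0.0;
          if (w > w_max) w = w_max;
          W(m, c) = w;
        }
      // inhibitory STDP between output neurons
      if (lateral_inhibition) {
        for (int i = 0; i < M; ++i) {
          for (int j = 0; j < M; ++j) {
            if (i == j) continue;
            // per-step integral of eta*(xbar*(y - theta) + x*(ybar - theta))
            double drive = ybar_inh[j] * (sy[i] - inhib_theta * dts) +
                           sy[j] * (ybar_inh[i] - inhib_theta);
            double w = Winh(i, j) - inhib_eta * drive -
                       inhib_lambda * Winh(i, j) * dts;
            Winh(i, j) = (w < 0.0) ? w : 0.0;
          }
        }
      }
      // postsynaptic traces and rate estimates (after the updates so the
      // LTP trace reflects spikes strictly before the current one)
      for (int m = 0; m < M; ++m) {
        ybar_plus[m] = ybar_plus[m] * trace_decay + sy[m] * trace_jump;
        ybar_minus[m] = ybar_minus[m] * trace_decay + sy[m] * trace_jump;
        ybar_inh[m] = ybar_inh[m] * trace_decay + sy[m] * trace_jump;
        out_rate[m] += rate_alpha * (sy[m] / dts - out_rate[m]);
        sy_prev[m] = sy[m];
      }
    }
    if (record_rate_every > 0 && (k + 1) % record_rate_every == 0 &&
        rec_i < n_rec) {
      double mr = 0.0;
      for (int m = 0; m < M; ++m) mr += out_rate[m];
      rate_trace[rec_i] = mr / M;
      ltp_trace[rec_i] = ltp_acc; ltd_trace[rec_i] = ltd_acc;
      ltp_acc = 0.0; ltd_acc = 0.0;
      ++rec_i;
    }
    if ((k & 255) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["W_exc"] = W, _["W_inh"] = Winh,
                      _["rates"] = NumericVector(out_rate.begin(), out_rate.end()),
                      _["rate_trace"] = rate_trace,
                      _["ltp_trace"] = ltp_trace, _["ltd_trace"] = ltd_trace);
}
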