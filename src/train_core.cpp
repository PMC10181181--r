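// Trial-binned Hebbian trainer with subtractive normalization.
//
// Implements, per trial, the correlation-driven weight update
//   dw_P(x,a) = eta [ sum_{b,P'} w_P'(x,b) C_{P,P'}(a,b)
//                     - w' C w / (2 sum_g R(x,g)) ]
// via the equivalent form using the postsynaptic trace
//   V_post(x,t) = sum_{b,P'} w_P'(x,b) V_P'(b,t):
//   dw_P(x,a) = eta/T [ sum_t V_post(x,t) V_P(a,t)
//                       - sum_t V_post(x,t)^2 / (2 K_x) ],
// followed by the nonnegativity constraint that zeroes negative weights and
// reduces positive ones proportionally, conserving each neuron's signed
// total.  Noise is drawn from a dedicated deterministic generator seeded
// from R so that results are reproducible given the R-level seed.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// constraint on one neuron's weight vector (both polarities concatenated)
static void constrain_neuron(double* w, int m) {
  double s_pos = 0.0, s_neg = 0.0;
  for (int k = 0; k < m; ++k) {
    if (w[k] > 0) s_pos += w[k];
    else s_neg -= w[k];
  }
  if (s_neg == 0.0) return;
  if (s_pos <= s_neg) {         // degenerate: conserving a non-positive total
    std::fill(w, w + m, 0.0);   // with nonnegative weights is impossible
    return;
  }
  const double f = 1.0 - s_neg / s_pos;
  for (int k = 0; k < m; ++k) w[k] = (w[k] > 0) ? w[k] * f : 0.0;
}

// [[Rcpp::export]]
List cpp_train(IntegerMatrix nbr,          // K x n, 1-based pixel index, 0 = absent
               NumericMatrix w_on_init,    // K x n
               NumericMatrix w_off_init,
               List epochs,                // each: list(pixel, frame, off_frames) int vectors
               IntegerVector neurons,      // 1-based neuron indices to train
               int n_px,
               double r, double gamma, int noise_background,
               int kern_len, int on_delay,
               double eta, int t_trial,    // 0 => one trial spanning the epoch
               double plast_sd, double dropout_p,
               bool conserve, int checkpoint_every,
               double noise_seed) {
  const int K = nbr.nrow(), n = nbr.ncol();
  NumericMatrix w_on(clone(w_on_init)), w_off(clone(w_off_init));
  std::vector<int> kcnt(n, 0);
  for (int x = 0; x < n; ++x)
    for (int k = 0; k < K; ++k) if (nbr(k, x) > 0) ++kcnt[x];

  std::vector<double> tot0(n, 0.0);
  if (conserve)
    for (int x = 0; x < n; ++x)
      for (int k = 0; k < K; ++k) tot0[x] += w_on(k, x) + w_off(k, x);

  std::mt19937_64 rng((uint64_t)noise_seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const bool plast_noise = plast_sd > 0.0 || dropout_p > 0.0;

  const int n_epochs = epochs.size();
  List checkpoints;
  std::vector<double> Von, Voff, vp;
  std::vector<int> touched;
  std::vector<char> is_touched(n_px, 0);

  for (int e = 0; e < n_epochs; ++e) {
    List ep = epochs[e];
    IntegerVector pix = ep[0], frame = ep[1], offd = ep[2];
    const int noise_d = std::abs(as<int>(ep[3]) - on_delay);
    const int m_act = pix.size();
    if (m_act == 0) continue;
    int off_min = 0, t_max = 0;
    for (int a = 0; a < m_act; ++a) off_min = std::min(off_min, offd[a]);
    const int shift = std::max(0, -std::min(on_delay, off_min));
    for (int a = 0; a < m_act; ++a)
      t_max = std::max(t_max, frame[a] + std::max(on_delay, offd[a]));
    const int T = t_max + shift + kern_len;   // frames indexed 1..T

    Von.assign((size_t)T * n_px, 0.0);
    Voff.assign((size_t)T * n_px, 0.0);
    touched.clear();
    for (int a = 0; a < m_act; ++a) {
      const int p = pix[a] - 1;
      if (!is_touched[p]) { is_touched[p] = 1; touched.push_back(p); }
      const int t_on = frame[a] + on_delay + shift;
      const int t_off = frame[a] + offd[a] + shift;
      double* con = &Von[(size_t)T * p];
      double* coff = &Voff[(size_t)T * p];
      for (int l = 0; l < kern_len; ++l) {
        con[t_on + l] += r;                  // frames t_on+1 .. t_on+L (0-based t_on+l)
        coff[t_off + l] += r;
      }
    }
    for (int p : touched) is_touched[p] = 0;

    if (gamma > 0.0) {
      if (noise_background >= 1) {
        // background trace per pixel; the OFF channel receives the SAME
        // trace delayed by the epoch's OFF delay (the OFF movie is a copy of
        // the ON movie, noise included)
        std::vector<double> z((size_t)T + noise_d);
        for (int p = 0; p < n_px; ++p) {
          for (auto& v : z) v = gauss(rng);
          double* con = &Von[(size_t)T * p];
          double* coff = &Voff[(size_t)T * p];
          for (int t = 0; t < T; ++t) {
            con[t] += gamma * z[t + noise_d];
            coff[t] += gamma * z[t];
          }
          if (noise_background == 2) {       // clipped variant
            for (int t = 0; t < T; ++t) {
              con[t] = std::max(con[t], 0.0);
              coff[t] = std::max(coff[t], 0.0);
            }
          }
        }
      } else {                               // kernel-literal: noise inside kernels,
        for (int a = 0; a < m_act; ++a) {    // shared between the polarities
          const int p = pix[a] - 1;
          const int t_on = frame[a] + on_delay + shift;
          const int t_off = frame[a] + offd[a] + shift;
          for (int l = 0; l < kern_len; ++l) {
            const double xi = gamma * gauss(rng);
            Von[(size_t)T * p + t_on + l] += xi;
            Voff[(size_t)T * p + t_off + l] += xi;
          }
        }
      }
    }

    const int Tt = (t_trial > 0) ? t_trial : T;
    for (int w0 = 0; w0 < T; w0 += Tt) {
      const int wlen = std::min(Tt, T - w0);
      for (int xi = 0; xi < neurons.size(); ++xi) {
        const int x = neurons[xi] - 1;
        if (kcnt[x] == 0) continue;
        vp.assign(wlen, 0.0);
        for (int k = 0; k < K; ++k) {
          const int j = nbr(k, x);
          if (j <= 0) continue;
          const double won = w_on(k, x), wof = w_off(k, x);
          const double* con = &Von[(size_t)T * (j - 1) + w0];
          const double* coff = &Voff[(size_t)T * (j - 1) + w0];
          for (int t = 0; t < wlen; ++t) vp[t] += won * con[t] + wof * coff[t];
        }
        double s2 = 0.0;
        for (int t = 0; t < wlen; ++t) s2 += vp[t] * vp[t];
        const double sub = eta * s2 / ((double)Tt * 2.0 * kcnt[x]);
        const double scale = eta / (double)Tt;
        for (int k = 0; k < K; ++k) {
          const int j = nbr(k, x);
          if (j <= 0) continue;
          const double* con = &Von[(size_t)T * (j - 1) + w0];
          const double* coff = &Voff[(size_t)T * (j - 1) + w0];
          double d_on = 0.0, d_off = 0.0;
          for (int t = 0; t < wlen; ++t) {
            d_on += vp[t] * con[t];
            d_off += vp[t] * coff[t];
          }
          d_on = scale * d_on - sub;
          d_off = scale * d_off - sub;
          if (plast_noise) {
            if (plast_sd > 0.0) {
              d_on *= 1.0 + plast_sd * gauss(rng);
              d_off *= 1.0 + plast_sd * gauss(rng);
            }
            if (dropout_p > 0.0) {
              if (unif(rng) < dropout_p) d_on = 0.0;
              if (unif(rng) < dropout_p) d_off = 0.0;
            }
          }
          w_on(k, x) += d_on;
          w_off(k, x) += d_off;
        }
        // apply Eq.-19-style constraint over both polarities jointly
        std::vector<double> wv(2 * K);
        for (int k = 0; k < K; ++k) { wv[k] = w_on(k, x); wv[K + k] = w_off(k, x); }
        constrain_neuron(wv.data(), 2 * K);
        if (conserve) {
          double tot = 0.0;
          for (int k = 0; k < 2 * K; ++k) tot += wv[k];
          if (tot > 0.0) {
            const double f = tot0[x] / tot;
            for (int k = 0; k < 2 * K; ++k) wv[k] *= f;
          }
        }
        for (int k = 0; k < K; ++k) {
          w_on(k, x) = nbr(k, x) > 0 ? wv[k] : 0.0;
          w_off(k, x) = nbr(k, x) > 0 ? wv[K + k] : 0.0;
        }
      }
    }

    if (checkpoint_every > 0 && (e + 1) % checkpoint_every == 0) {
      checkpoints.push_back(List::create(_["epoch"] = e + 1,
                                         _["w_on"] = clone(w_on),
                                         _["w_off"] = clone(w_off)));
    }
    if ((e & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["w_on"] = w_on, _["w_off"] = w_off,
                      _["checkpoints"] = checkpoints);
}
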