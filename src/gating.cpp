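// N independent two-state (closed/open) Markov channels advanced at the
// sampling interval; transition probabilities 1 - exp(-k*dt). Current is
// open_count * unitary current plus white Gaussian noise.

#include <Rcpp.h>
#include <random>

using namespace Rcpp;

// [[Rcpp::export]]
NumericVector gating_trace_cpp(int n_channels, double p_co, double p_oc,
                               double p_open_init, int n_samples,
                               double i_unit, double noise_sd, int seed) {
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> u01(0.0, 1.0);
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::vector<char> open(n_channels, 0);
  for (int c = 0; c < n_channels; ++c) open[c] = u01(rng) < p_open_init;
  NumericVector out(n_samples);
  for (int t = 0; t < n_samples; ++t) {
    if (t > 0)
      for (int c = 0; c < n_channels; ++c) {
        double u = u01(rng);
        if (open[c]) { if (u < p_oc) open[c] = 0; }
        else         { if (u < p_co) open[c] = 1; }
      }
    int k = 0;
    for (int c = 0; c < n_channels; ++c) k += open[c];
    out[t] = k * i_unit + (noise_sd > 0 ? noise_sd * gauss(rng) : 0.0);
  }
  return out;
}
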