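#include <Rcpp.h>
using namespace Rcpp;

// Probabilistic network update, run for nSteps.
//
// w is the full weight matrix with w(i, j) the outgoing weight from neuron i
// onto neuron j, so the input sum of neuron j at time t is
// sum_i w(i, j) * s_i(t).  Activation probability is that sum clipped to
// [0, 1].  Per step, in order: stochastic update of every neuron, background
// drive (one uniformly chosen neuron forced active), spike event with
// probability pIed (patch of neighbours forced active), off-step with
// probability pOff (whole network silenced, overriding drive and spikes).
//
// nbr is an npatch x N matrix (1-based indices) giving, per column c, the
// neurons forced active when a spike event is centred on neuron c.
//
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List simulateCore(NumericMatrix wt, int nSteps, double pOff, double pIed,
                  IntegerMatrix nbr) {
  // wt is the TRANSPOSED weight matrix: wt(j, i) = outgoing weight of i
  // onto j, so the contribution of an active neuron i is the contiguous
  // column i of wt (cache-friendly accumulation).
  const int N = wt.nrow();
  const int npatch = nbr.nrow();
  IntegerMatrix raster(N, nSteps);
  NumericVector pop(nSteps);
  LogicalVector offStep(nSteps), iedStep(nSteps);
  std::vector<double> s(N, 0.0), input(N, 0.0);
  std::vector<int> snew(N, 0);

  RNGScope scope;
  for (int t = 0; t < nSteps; ++t) {
    std::fill(input.begin(), input.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      if (s[i] != 0.0) {
        const double* col = &wt(0, i);
        for (int j = 0; j < N; ++j) input[j] += col[j];
      }
    }
    for (int j = 0; j < N; ++j) {
      double p = input[j];
      if (p < 0.0) p = 0.0; else if (p > 1.0) p = 1.0;
      snew[j] = (unif_rand() < p) ? 1 : 0;
    }
    // background drive: one uniformly chosen neuron per step
    int bg = (int)(unif_rand() * N);
    if (bg >= N) bg = N - 1;
    snew[bg] = 1;
    // spike event: centre neuron and nearest patch forced active
    if (pIed > 0.0 && unif_rand() < pIed) {
      int centre = (int)(unif_rand() * N);
      if (centre >= N) centre = N - 1;
      for (int k = 0; k < npatch; ++k) snew[nbr(k, centre) - 1] = 1;
      iedStep[t] = true;
    }
    // off-step silences everything, including drive and spike events
    if (pOff > 0.0 && unif_rand() < pOff) {
      std::fill(snew.begin(), snew.end(), 0);
      offStep[t] = true;
    }
    int nact = 0;
    for (int j = 0; j < N; ++j) {
      raster(j, t) = snew[j];
      s[j] = (double)snew[j];
      nact += snew[j];
    }
    pop[t] = (double)nact / N;
  }
  return List::create(_["raster"] = raster, _["pop"] = pop,
                      _["offStep"] = offStep, _["iedStep"] = iedStep);
}
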