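// 1D Metropolis Monte Carlo of the import coordinate n_in on the assembled
// free-energy landscape. Time is counted in attempted MC steps. The origin
// reflects (proposals to -1 are rejected and counted); position L absorbs.
// A bound chaperone imposes a hard retrotranslocation wall at
// nearest + threshold in both the assisted and ratchet-only modes.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

// modes: 0 = unassisted, 1 = assisted, 2 = ratchet_only
// Fu: length L+1 (index = n_in); dFc: length L+1 (index = n_in - n_B,
// entries below `threshold` are never read)
// [[Rcpp::export(name = ".run_import_cpp")]]
List run_import_cpp(NumericVector Fu, NumericVector dFc, IntegerVector sites,
                    int mode, int threshold, double step_cap, double seed,
                    bool record_events) {
  const int L = Fu.size() - 1;
  Rng rng((uint64_t)seed);
  int pos = 0;
  int nearest = -1; // no chaperone bound
  int next_site = 0;
  const int nsites = sites.size();

  // per-position acceptance probabilities for the current landscape piece
  std::vector<double> pUp(L + 1), pDown(L + 1);
  auto F_at = [&](int i) {
    double f = Fu[i];
    if (mode == 1 && nearest >= 0) f += dFc[i - nearest];
    return f;
  };
  auto rebuild = [&]() {
    int lo = (nearest >= 0 && mode != 0) ? nearest + threshold : 0;
    for (int i = lo; i <= L; ++i) {
      double fi = F_at(i);
      pUp[i] = (i == L) ? 0.0 : std::min(1.0, std::exp(-(F_at(i + 1) - fi)));
      pDown[i] = (i == lo) ? 0.0
        : std::min(1.0, std::exp(-(F_at(i - 1) - fi)));
    }
  };
  rebuild();

  std::vector<double> ev_step;
  std::vector<int> ev_site;
  double attempts = 0.0, accepted = 0.0;
  bool completed = false;

  while (attempts < step_cap) {
    attempts += 1.0;
    bool up = rng.next() & 1;
    double u = rng.unif();
    if (up) {
      if (u < pUp[pos]) {
        ++pos;
        accepted += 1.0;
        if (pos == L) { completed = true; break; }
        // instant irreversible binding of every newly exposed site
        bool bound_new = false;
        while (next_site < nsites && pos >= sites[next_site] + threshold) {
          nearest = sites[next_site];
          ++next_site;
          bound_new = true;
          if (record_events) {
            ev_step.push_back(attempts);
            ev_site.push_back(nearest);
          }
        }
        if (bound_new && mode != 0) rebuild();
      }
    } else {
      if (u < pDown[pos]) {
        --pos;
        accepted += 1.0;
      }
    }
    if (((long)attempts & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["tau"] = attempts, _["completed"] = completed,
                      _["acceptance_fraction"] = accepted / attempts,
                      _["final_pos"] = pos,
                      _["event_steps"] = wrap(ev_step),
                      _["event_sites"] = wrap(ev_site));
}

// Visited-state histogram of the same walk with absorption disabled
// (both ends reflect); used for Boltzmann-stationarity checks. `thin` counts
// only every thin-th step so chi-square tests see near-independent draws.
// [[Rcpp::export(name = ".mc_histogram_cpp")]]
NumericVector mc_histogram_cpp(NumericVector F, double n_steps, double seed,
                               int start, int thin) {
  const int m = F.size();
  Rng rng((uint64_t)seed);
  std::vector<double> pUp(m), pDown(m);
  for (int i = 0; i < m; ++i) {
    pUp[i] = (i == m - 1) ? 0.0 : std::min(1.0, std::exp(-(F[i + 1] - F[i])));
    pDown[i] = (i == 0) ? 0.0 : std::min(1.0, std::exp(-(F[i - 1] - F[i])));
  }
  NumericVector counts(m);
  int pos = start;
  long total = (long)n_steps;
  for (long s = 0; s < total; ++s) {
    bool up = rng.next() & 1;
    double u = rng.unif();
    if (up) { if (u < pUp[pos]) ++pos; }
    else { if (u < pDown[pos]) --pos; }
    if (s % thin == 0) counts[pos] += 1.0;
  }
  return counts;
}
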