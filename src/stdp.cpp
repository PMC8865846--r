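#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pair-based additive STDP over full spike trains, all-to-all pairing via
// exponential traces. Weights live on the edges of a fixed sparse directed
// graph given in CSC form (column = postsynaptic cell), with a parallel CSR
// view built here so both the incoming and outgoing edges of a spiking cell
// can be visited in O(degree).
//
// Per spike of cell s at time t (spikes processed in chronological order):
//   - every edge j->s gains A_plus * sum_{pre spikes of j} exp(-(t - t_j)/tau_plus)
//     (the potentiation branch, evaluated at the postsynaptic spike),
//   - every edge s->k gains A_minus * sum_{post spikes of k} exp(-(t - t_k)/tau_minus)
//     (the depression branch, evaluated at the presynaptic spike),
// each update clipped to [0, wmax] immediately (online clipping in event order).
// Exact ties (t_pre == t_post) are handled as a single update of A_plus on the
// connecting edge(s), not both branches.
//
// spike_t must be sorted ascending; spike_cell is 0-based. Amplitudes in nS.
// [[Rcpp::export]]
NumericVector cpp_learn_stdp(NumericVector spike_t, IntegerVector spike_cell,
                             int n_cells,
                             IntegerVector col_ptr, IntegerVector row_ind,
                             NumericVector w0,
                             double a_plus, double a_minus,
                             double tau_plus, double tau_minus,
                             double wmax) {
  const int n_spk = spike_t.size();
  const int nnz = row_ind.size();
  NumericVector w = clone(w0);

  // CSR view (out-edges): out_ptr[pre], out_post, out_widx -> index into w
  std::vector<int> out_deg(n_cells, 0);
  for (int j = 0; j < n_cells; ++j)
    for (int k = col_ptr[j]; k < col_ptr[j + 1]; ++k) out_deg[row_ind[k]]++;
  std::vector<int> out_ptr(n_cells + 1, 0);
  for (int i = 0; i < n_cells; ++i) out_ptr[i + 1] = out_ptr[i] + out_deg[i];
  std::vector<int> out_post(nnz), out_widx(nnz), fill(n_cells, 0);
  for (int j = 0; j < n_cells; ++j)
    for (int k = col_ptr[j]; k < col_ptr[j + 1]; ++k) {
      int i = row_ind[k];
      int pos = out_ptr[i] + fill[i]++;
      out_post[pos] = j;
      out_widx[pos] = k;
    }

  // per-cell exponential traces with lazy decay
  std::vector<double> tr_p(n_cells, 0.0), tr_m(n_cells, 0.0);
  std::vector<double> last_p(n_cells, -1e300), last_m(n_cells, -1e300);

  auto clip = [wmax](double x) { return x < 0.0 ? 0.0 : (x > wmax ? wmax : x); };

  int g0 = 0;
  while (g0 < n_spk) {
    int g1 = g0;
    const double t = spike_t[g0];
    while (g1 < n_spk && spike_t[g1] == t) ++g1;  // tie group [g0, g1)

    for (int s = g0; s < g1; ++s) {
      const int c = spike_cell[s];
      // potentiation on incoming edges (traces hold strictly earlier spikes)
      for (int k = col_ptr[c]; k < col_ptr[c + 1]; ++k) {
        const int pre = row_ind[k];
        if (tr_p[pre] != 0.0) {
          tr_p[pre] *= std::exp(-(t - last_p[pre]) / tau_plus);
          last_p[pre] = t;
          w[k] = clip(w[k] + a_plus * tr_p[pre]);
        }
      }
      // depression branch on outgoing edges
      for (int k = out_ptr[c]; k < out_ptr[c + 1]; ++k) {
        const int post = out_post[k];
        if (tr_m[post] != 0.0) {
          tr_m[post] *= std::exp(-(t - last_m[post]) / tau_minus);
          last_m[post] = t;
          w[out_widx[k]] = clip(w[out_widx[k]] + a_minus * tr_m[post]);
        }
      }
    }
    // exact ties: one update of A_plus per connected ordered pair in the group
    if (g1 - g0 > 1) {
      for (int s = g0; s < g1; ++s) {
        const int c = spike_cell[s];
        for (int k = col_ptr[c]; k < col_ptr[c + 1]; ++k) {
          const int pre = row_ind[k];
          for (int s2 = g0; s2 < g1; ++s2)
            if (spike_cell[s2] == pre) w[k] = clip(w[k] + a_plus);
        }
      }
    }
    // now add the group's spikes to the traces
    for (int s = g0; s < g1; ++s) {
      const int c = spike_cell[s];
      tr_p[c] = (last_p[c] > -1e299 ? tr_p[c] * std::exp(-(t - last_p[c]) / tau_plus) : 0.0) + 1.0;
      tr_m[c] = (last_m[c] > -1e299 ? tr_m[c] * std::exp(-(t - last_m[c]) / tau_minus) : 0.0) + 1.0;
      last_p[c] = t;
      last_m[c] = t;
    }
    g0 = g1;
    if ((g0 & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return w;
}

// Sequentially drop spikes closer than `refractory` to the previously kept
// spike (applied to the accepted sequence, as in thinning with a dead time).
// [[Rcpp::export]]
NumericVector cpp_refractory_filter(NumericVector t, double refractory) {
  const int n = t.size();
  std::vector<double> keep;
  keep.reserve(n);
  double last = -1e300;
  for (int i = 0; i < n; ++i) {
    if (t[i] - last > refractory) {
      keep.push_back(t[i]);
      last = t[i];
    }
  }
  return NumericVector(keep.begin(), keep.end());
}
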