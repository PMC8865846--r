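#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Forward-Euler simulation of a network of (Ad)ExpIF point neurons with
// conductance-based biexponential synapses, per-pathway axonal delays and
// external Poisson drive.
//
// State per neuron: V (mV), adaptation current w (pA), refractory counter.
// Synaptic kinetics are grouped into "slots" (one per distinct rise/decay/
// reversal triple); each slot keeps two exponential accumulators D (decay)
// and Rr (rise) per neuron, g(t) = D - Rr, so that a unit increment of both
// produces the normalized biexponential with peak 1 at t_p. Edge weights are
// pre-divided by the biexponential normalization constant, so incrementing
// D and Rr by the stored weight yields a conductance transient peaking at
// ghat nS. Currents are accumulated slot-major into contiguous excitatory/
// inhibitory arrays so the inner loops stay vectorizable.
//
// The exponential spike-initiation term is capped at its value at V = theta
// (the spike-detection threshold) to keep Euler steps finite, and skipped
// where its argument is below -9 (contribution < 2e-4 * gL * DeltaT pA,
// far below every other term); spikes are detected strictly at V > theta,
// V is reset and clamped for t_ref while w keeps integrating.
//
// External Poisson sources are drawn per step as a binomial count of
// spiking sources plus a uniform choice of which sources spike -
// distribution-identical to per-source Bernoulli draws. All randomness goes
// through R's RNG so set.seed() governs the whole simulation.
//
// Arguments (all times ms, conductances nS, voltages mV, currents pA):
//  neurons: list of numeric vectors of length N:
//    Cm, gL, Vrest, DeltaT, vth (exponential threshold), theta (detection),
//    Vreset, tref, tauw, a, b, has_w (0/1)
//  slots: list of list(tau_r, tau_d, E)
//  pathways: list of list(ptr (int, len N+1, CSR over presynaptic id),
//    targets (int, 0-based), w (per-edge, normalized), slot (0-based),
//    delay_steps (int >= 0))
//  ext_inputs: list of list(n_src, rate_hz, t_on, t_off, ptr, targets,
//    w (scalar, normalized), slot)
//  lfp_cells / probe_cells: 0-based indices for current / voltage records
// [[Rcpp::export]]
List cpp_simulate_network(List neurons, List slots, List pathways,
                          List ext_inputs, double duration, double dt,
                          IntegerVector lfp_cells, IntegerVector probe_cells,
                          double v_init_jitter) {
  NumericVector Cm = neurons["Cm"], gL = neurons["gL"], Vrest = neurons["Vrest"],
                DeltaT = neurons["DeltaT"], vth = neurons["vth"],
                theta = neurons["theta"], Vreset = neurons["Vreset"],
                tref = neurons["tref"], tauw = neurons["tauw"],
                a_ad = neurons["a"], b_ad = neurons["b"], has_w = neurons["has_w"];
  const int N = Cm.size();
  const int n_steps = (int)std::round(duration / dt);
  const int n_slot = slots.size();

  // slot state, flat slot-major arrays
  std::vector<double> D((size_t)n_slot * N, 0.0), Rr((size_t)n_slot * N, 0.0);
  std::vector<double> dec_d(n_slot), dec_r(n_slot), Erev(n_slot);
  std::vector<int> slot_exc(n_slot);
  for (int s = 0; s < n_slot; ++s) {
    List sl = slots[s];
    dec_d[s] = std::exp(-dt / as<double>(sl["tau_d"]));
    dec_r[s] = std::exp(-dt / as<double>(sl["tau_r"]));
    Erev[s] = as<double>(sl["E"]);
    slot_exc[s] = Erev[s] >= -30.0 ? 1 : 0;
  }

  // pathways
  const int n_pw = pathways.size();
  std::vector<IntegerVector> pw_ptr(n_pw), pw_tgt(n_pw);
  std::vector<NumericVector> pw_w(n_pw);
  std::vector<int> pw_slot(n_pw), pw_delay(n_pw), ring_len(n_pw);
  std::vector<std::vector<double>> ring(n_pw);
  for (int p = 0; p < n_pw; ++p) {
    List pw = pathways[p];
    pw_ptr[p] = pw["ptr"];
    pw_tgt[p] = pw["targets"];
    pw_w[p] = pw["w"];
    pw_slot[p] = as<int>(pw["slot"]);
    pw_delay[p] = as<int>(pw["delay_steps"]);
    ring_len[p] = pw_delay[p] + 1;
    ring[p].assign((size_t)ring_len[p] * N, 0.0);
  }

  // external inputs
  const int n_ext = ext_inputs.size();
  std::vector<int> ex_nsrc(n_ext), ex_slot(n_ext);
  std::vector<double> ex_p(n_ext), ex_w(n_ext), ex_on(n_ext), ex_off(n_ext);
  std::vector<IntegerVector> ex_ptr(n_ext), ex_tgt(n_ext);
  for (int e = 0; e < n_ext; ++e) {
    List ex = ext_inputs[e];
    ex_nsrc[e] = as<int>(ex["n_src"]);
    ex_p[e] = as<double>(ex["rate_hz"]) * dt / 1000.0;
    ex_on[e] = as<double>(ex["t_on"]);
    ex_off[e] = as<double>(ex["t_off"]);
    ex_ptr[e] = ex["ptr"];
    ex_tgt[e] = ex["targets"];
    ex_w[e] = as<double>(ex["w"]);
    ex_slot[e] = as<int>(ex["slot"]);
  }

  RNGScope rng;
  std::vector<double> V(N), w(N, 0.0), I_exc(N), I_inh(N);
  std::vector<int> refr(N, 0), tref_steps(N);
  std::vector<double> exp_cap(N);
  for (int i = 0; i < N; ++i) {
    V[i] = Vrest[i] + (v_init_jitter > 0 ? (unif_rand() - 0.5) * 2.0 * v_init_jitter : 0.0);
    tref_steps[i] = (int)std::round(tref[i] / dt);
    exp_cap[i] = gL[i] * DeltaT[i] * std::exp((theta[i] - vth[i]) / DeltaT[i]);
  }

  std::vector<double> spike_time;
  std::vector<int> spike_id;
  const int n_lfp = lfp_cells.size(), n_probe = probe_cells.size();
  NumericVector lfp_exc(n_lfp ? n_steps : 0), lfp_inh(n_lfp ? n_steps : 0);
  NumericMatrix probe_V(n_probe, n_probe ? n_steps : 0);
  NumericMatrix probe_exc(n_probe, n_probe ? n_steps : 0);
  NumericMatrix probe_inh(n_probe, n_probe ? n_steps : 0);

  std::vector<int> spikers, chosen;
  spikers.reserve(1024);
  chosen.reserve(256);

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;

    // deliver delayed increments due now
    for (int p = 0; p < n_pw; ++p) {
      double *slotD = D.data() + (size_t)pw_slot[p] * N;
      double *slotR = Rr.data() + (size_t)pw_slot[p] * N;
      double *buf = ring[p].data() + (size_t)(step % ring_len[p]) * N;
      for (int i = 0; i < N; ++i) {
        if (buf[i] != 0.0) {
          slotD[i] += buf[i];
          slotR[i] += buf[i];
          buf[i] = 0.0;
        }
      }
    }

    // external Poisson sources (no delay): binomial count + uniform subset
    for (int e = 0; e < n_ext; ++e) {
      if (t < ex_on[e] || t >= ex_off[e]) continue;
      const int k = (int)R::rbinom((double)ex_nsrc[e], ex_p[e]);
      if (k == 0) continue;
      double *slotD = D.data() + (size_t)ex_slot[e] * N;
      double *slotR = Rr.data() + (size_t)ex_slot[e] * N;
      const int *ptr = INTEGER(ex_ptr[e]);
      const int *tgt = INTEGER(ex_tgt[e]);
      const double wgt = ex_w[e];
      chosen.clear();
      if (k > 64) {
        std::vector<char> mask(ex_nsrc[e], 0);
        int got = 0;
        while (got < k) {
          int idx = (int)(unif_rand() * ex_nsrc[e]);
          if (idx >= ex_nsrc[e]) idx = ex_nsrc[e] - 1;
          if (!mask[idx]) { mask[idx] = 1; chosen.push_back(idx); ++got; }
        }
      } else {
        while ((int)chosen.size() < k) {
          int idx = (int)(unif_rand() * ex_nsrc[e]);
          if (idx >= ex_nsrc[e]) idx = ex_nsrc[e] - 1;
          bool dup = false;
          for (size_t q = 0; q < chosen.size(); ++q)
            if (chosen[q] == idx) { dup = true; break; }
          if (!dup) chosen.push_back(idx);
        }
      }
      for (size_t q = 0; q < chosen.size(); ++q) {
        const int s = chosen[q];
        for (int kk = ptr[s]; kk < ptr[s + 1]; ++kk) {
          slotD[tgt[kk]] += wgt;
          slotR[tgt[kk]] += wgt;
        }
      }
    }

    // slot-major synaptic current accumulation at the current V
    std::fill(I_exc.begin(), I_exc.end(), 0.0);
    std::fill(I_inh.begin(), I_inh.end(), 0.0);
    for (int s = 0; s < n_slot; ++s) {
      const double *slotD = D.data() + (size_t)s * N;
      const double *slotR = Rr.data() + (size_t)s * N;
      const double E = Erev[s];
      double *acc = slot_exc[s] ? I_exc.data() : I_inh.data();
      for (int i = 0; i < N; ++i)
        acc[i] += (slotD[i] - slotR[i]) * (V[i] - E);
    }

    // integrate neurons
    spikers.clear();
    for (int i = 0; i < N; ++i) {
      const double Isyn = I_exc[i] + I_inh[i];
      if (refr[i] > 0) {
        --refr[i];
        if (has_w[i] != 0.0)
          w[i] += dt / tauw[i] * (a_ad[i] * (V[i] - Vrest[i]) - w[i]);
      } else {
        const double arg = (V[i] - vth[i]) / DeltaT[i];
        double expterm = 0.0;
        if (arg > -9.0) {
          expterm = gL[i] * DeltaT[i] * std::exp(arg);
          if (expterm > exp_cap[i]) expterm = exp_cap[i];
        }
        const double Vold = V[i];
        V[i] += dt / Cm[i] * (-(gL[i] * (V[i] - Vrest[i]) - expterm + Isyn + w[i]));
        if (has_w[i] != 0.0)
          w[i] += dt / tauw[i] * (a_ad[i] * (Vold - Vrest[i]) - w[i]);
        if (V[i] > theta[i]) {
          spike_time.push_back(t + dt);
          spike_id.push_back(i);
          V[i] = Vreset[i];
          if (has_w[i] != 0.0) w[i] += b_ad[i];
          refr[i] = tref_steps[i];
          spikers.push_back(i);
        }
        if (!std::isfinite(V[i]) || !std::isfinite(w[i]))
          stop("non-finite state in neuron %d at t = %.3f ms", i + 1, t);
      }
    }

    // queue outgoing spikes into delay rings
    for (size_t q = 0; q < spikers.size(); ++q) {
      const int i = spikers[q];
      for (int p = 0; p < n_pw; ++p) {
        const int *ptr = INTEGER(pw_ptr[p]);
        if (ptr[i] == ptr[i + 1]) continue;
        const int *tgt = INTEGER(pw_tgt[p]);
        const double *wv = REAL(pw_w[p]);
        double *buf = ring[p].data() +
          (size_t)((step + pw_delay[p] + 1) % ring_len[p]) * N;
        for (int kk = ptr[i]; kk < ptr[i + 1]; ++kk) buf[tgt[kk]] += wv[kk];
      }
    }

    // recordings (currents from the accumulation pass above)
    if (n_lfp) {
      double se = 0.0, si = 0.0;
      for (int q = 0; q < n_lfp; ++q) {
        se += I_exc[lfp_cells[q]];
        si += I_inh[lfp_cells[q]];
      }
      lfp_exc[step] = se;
      lfp_inh[step] = si;
    }
    for (int q = 0; q < n_probe; ++q) {
      const int i = probe_cells[q];
      probe_V(q, step) = V[i];
      probe_exc(q, step) = I_exc[i];
      probe_inh(q, step) = I_inh[i];
    }

    // decay conductances
    for (int s = 0; s < n_slot; ++s) {
      double *slotD = D.data() + (size_t)s * N;
      double *slotR = Rr.data() + (size_t)s * N;
      const double dd = dec_d[s], dr = dec_r[s];
      for (int i = 0; i < N; ++i) {
        slotD[i] *= dd;
        slotR[i] *= dr;
      }
    }
    if ((step & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["spike_t"] = NumericVector(spike_time.begin(), spike_time.end()),
    _["spike_cell"] = IntegerVector(spike_id.begin(), spike_id.end()),
    _["lfp_exc"] = lfp_exc, _["lfp_inh"] = lfp_inh,
    _["probe_V"] = probe_V, _["probe_exc"] = probe_exc,
    _["probe_inh"] = probe_inh);
}

// Single-neuron forward-Euler integration with an injected current time
// series (pA, positive depolarizing). Same dynamics and conventions as the
// network integrator.
// [[Rcpp::export]]
List cpp_simulate_cell(List params, NumericVector I_inj, double dt) {
  const double Cm = params["Cm"], gL = params["gL"], Vrest = params["Vrest"],
               DeltaT = params["DeltaT"], vth = params["vth"],
               theta = params["theta"], Vreset = params["Vreset"],
               tref = params["tref"], tauw = params["tauw"],
               a = params["a"], b = params["b"], has_w = params["has_w"];
  const int n = I_inj.size();
  NumericVector V(n), wtr(n);
  std::vector<double> spikes;
  double v = Vrest, w = 0.0;
  int refr = 0;
  const int tref_steps = (int)std::round(tref / dt);
  const double cap = gL * DeltaT * std::exp((theta - vth) / DeltaT);
  for (int k = 0; k < n; ++k) {
    const double t = k * dt;
    if (refr > 0) {
      --refr;
      if (has_w != 0.0) w += dt / tauw * (a * (v - Vrest) - w);
    } else {
      double expterm = gL * DeltaT * std::exp((v - vth) / DeltaT);
      if (expterm > cap) expterm = cap;
      const double vold = v;
      v += dt / Cm * (-(gL * (v - Vrest) - expterm - I_inj[k] + w));
      if (has_w != 0.0) w += dt / tauw * (a * (vold - Vrest) - w);
      if (v > theta) {
        spikes.push_back(t + dt);
        v = Vreset;
        if (has_w != 0.0) w += b;
        refr = tref_steps;
      }
    }
    if (!std::isfinite(v) || !std::isfinite(w))
      stop("non-finite state at t = %.4f ms", t);
    V[k] = v;
    wtr[k] = w;
  }
  return List::create(_["V"] = V, _["w"] = wtr,
                      _["spikes"] = NumericVector(spikes.begin(), spikes.end()));
}
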