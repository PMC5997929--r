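// Fixed-step simulation core: LIF membrane dynamics with exact exponential
// sub-step integration, spike decoding, first-order synaptic filtering, and
// the online motor-execution module (threshold detection with hysteresis and
// delayed somatosensory injection).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List run_simulation(List args) {
  const int n_steps = args["n_steps"];
  const double dt = args["dt"];
  const double tau_rc = args["tau_rc"];
  const double tau_ref = args["tau_ref"];

  NumericVector gain = args["gain"], bias = args["bias"], v0 = args["v0"];
  IntegerVector ens_start = args["ens_start"];
  IntegerVector sig_ens = args["sig_ens"];
  NumericVector dec = args["dec"];
  IntegerVector dec_start = args["dec_start"];
  IntegerVector fsig_sig = args["fsig_sig"];
  NumericVector fsig_decay = args["fsig_decay"];
  IntegerVector con_fsig = args["con_fsig"];
  IntegerVector con_dst = args["con_dst"];
  NumericVector con_w = args["con_w"];
  NumericMatrix ext = args["ext"];
  const double ext_decay = args["ext_decay"];
  IntegerVector probe_sig = args["probe_sig"];
  const double probe_decay = args["probe_decay"];
  CharacterVector labels = args["labels"];

  const int N = gain.size();
  const int E = ens_start.size() - 1;
  const int S = sig_ens.size();
  const int F = fsig_sig.size();
  const int C = con_fsig.size();
  const int P = probe_sig.size();

  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> refrac(N, 0.0);
  std::vector<char> spike(N, 0);
  std::vector<double> xin(E, 0.0), xext(E, 0.0);
  std::vector<double> raw(S, 0.0), fs(F, 0.0), ps(P, 0.0);
  const double inv_dt = 1.0 / dt;

  NumericMatrix probes(n_steps, P);

  // motor execution module (optional)
  bool has_mexec = !Rf_isNull(args["mexec"]);
  IntegerVector mon_sig, somato_ens;
  NumericMatrix exec_vecs;
  double thr_on = 0, thr_off = 0, amp = 0, mon_decay = 0;
  int delay_steps = 0, pulse_steps = 0, n_syl = 0, D = 0, arm_step = 0;
  std::vector<double> mon_state;
  std::vector<char> armed;
  std::vector<std::pair<int, double> > trig_events;
  if (has_mexec) {
    List mx = args["mexec"];
    mon_sig = as<IntegerVector>(mx["mon_sig"]);
    exec_vecs = as<NumericMatrix>(mx["exec_vecs"]);
    somato_ens = as<IntegerVector>(mx["somato_ens"]);
    thr_on = mx["thr_on"];
    thr_off = mx["thr_off"];
    delay_steps = mx["delay_steps"];
    pulse_steps = mx["pulse_steps"];
    arm_step = mx["arm_step"];
    amp = mx["amp"];
    mon_decay = mx["mon_decay"];
    n_syl = exec_vecs.nrow();
    D = mon_sig.size();
    mon_state.assign(D, 0.0);
    armed.assign(n_syl, 1);
  }

  for (int t = 0; t < n_steps; ++t) {
    // 1. ensemble inputs: filtered connections + filtered external drive
    for (int e = 0; e < E; ++e) {
      xext[e] = xext[e] * ext_decay + (1.0 - ext_decay) * ext(t, e);
      xin[e] = xext[e];
    }
    for (int c = 0; c < C; ++c) xin[con_dst[c]] += con_w[c] * fs[con_fsig[c]];

    // 2. LIF update (exact exponential integration with refractory carry)
    for (int e = 0; e < E; ++e) {
      const double x = xin[e];
      for (int i = ens_start[e]; i < ens_start[e + 1]; ++i) {
        const double J = gain[i] * x + bias[i];
        double r = refrac[i] - dt;
        double delta = dt - (r > 0.0 ? r : 0.0);
        if (delta < 0.0) delta = 0.0;
        refrac[i] = r > 0.0 ? r : 0.0;
        double vi = v[i] + (J - v[i]) * (-expm1(-delta / tau_rc));
        if (vi > 1.0) {
          spike[i] = 1;
          // time left in the step after the threshold crossing
          double t_spike = dt + tau_rc * log1p(-(vi - 1.0) / (J - 1.0));
          refrac[i] = tau_ref + t_spike;
          vi = 0.0;
        } else {
          spike[i] = 0;
          if (vi < 0.0) vi = 0.0;
        }
        v[i] = vi;
      }
    }

    // 3. decode spikes
    for (int s = 0; s < S; ++s) {
      const int e = sig_ens[s];
      double acc = 0.0;
      const double *d = &dec[dec_start[s]];
      int k = 0;
      for (int i = ens_start[e]; i < ens_start[e + 1]; ++i, ++k) {
        if (spike[i]) acc += d[k];
      }
      raw[s] = acc * inv_dt;
    }

    // 4. synaptic filters
    for (int f = 0; f < F; ++f) {
      fs[f] = fs[f] * fsig_decay[f] + (1.0 - fsig_decay[f]) * raw[fsig_sig[f]];
    }

    // 5. probes
    for (int p = 0; p < P; ++p) {
      ps[p] = ps[p] * probe_decay + (1.0 - probe_decay) * raw[probe_sig[p]];
      probes(t, p) = ps[p];
    }

    // 6. motor execution: monitor motor state, schedule delayed feedback
    if (has_mexec && t >= arm_step) {
      for (int j = 0; j < D; ++j) {
        mon_state[j] = mon_state[j] * mon_decay +
          (1.0 - mon_decay) * raw[mon_sig[j]];
      }
      for (int s = 0; s < n_syl; ++s) {
        double sim = 0.0;
        for (int j = 0; j < D; ++j) sim += exec_vecs(s, j) * mon_state[j];
        if (armed[s] && sim >= thr_on) {
          armed[s] = 0;
          trig_events.push_back(std::make_pair(s, t * dt));
          const int a = t + delay_steps;
          const int b = a + pulse_steps;
          for (int u = a; u < b && u < n_steps; ++u) {
            for (int j = 0; j < D; ++j) {
              ext(u, somato_ens[j]) += amp * exec_vecs(s, j);
            }
          }
        } else if (!armed[s] && sim < thr_off) {
          armed[s] = 1;
        }
      }
    }

    // divergence guard
    if ((t & 127) == 0) {
      for (int f = 0; f < F; ++f) {
        if (!std::isfinite(fs[f])) {
          stop("simulation diverged (non-finite value) in ensemble '%s' "
               "at t = %f s",
               std::string(labels[sig_ens[fsig_sig[f]]]).c_str(), t * dt);
        }
      }
    }
  }

  NumericMatrix trig(trig_events.size(), 2);
  for (size_t i = 0; i < trig_events.size(); ++i) {
    trig(i, 0) = trig_events[i].first;
    trig(i, 1) = trig_events[i].second;
  }
  return List::create(Named("probes") = probes, Named("triggers") = trig);
}

// Deterministic regularised least-squares solve (normal equations +
// Cholesky), independent of BLAS threading so that a seeded network build
// is bit-for-bit reproducible across machines.
// [[Rcpp::export]]
NumericVector solve_normal_eq(NumericMatrix A, NumericVector f,
                              double lambda) {
  const int S = A.nrow(), n = A.ncol();
  std::vector<double> G(n * n, 0.0), b(n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double acc = 0.0;
      for (int k = 0; k < S; ++k) acc += A(k, i) * A(k, j);
      G[i * n + j] = acc;
      G[j * n + i] = acc;
    }
    double acc = 0.0;
    for (int k = 0; k < S; ++k) acc += A(k, i) * f[k];
    b[i] = acc;
    G[i * n + i] += lambda;
  }
  // Cholesky G = L L^T
  std::vector<double> L(n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j <= i; ++j) {
      double acc = G[i * n + j];
      for (int k = 0; k < j; ++k) acc -= L[i * n + k] * L[j * n + k];
      if (i == j) {
        if (acc <= 0.0) stop("normal equations not positive definite");
        L[i * n + i] = std::sqrt(acc);
      } else {
        L[i * n + j] = acc / L[j * n + j];
      }
    }
  }
  std::vector<double> y(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double acc = b[i];
    for (int k = 0; k < i; ++k) acc -= L[i * n + k] * y[k];
    y[i] = acc / L[i * n + i];
  }
  NumericVector d(n);
  for (int i = n - 1; i >= 0; --i) {
    double acc = y[i];
    for (int k = i + 1; k < n; ++k) acc -= L[k * n + i] * d[k];
    d[i] = acc / L[i * n + i];
  }
  return d;
}
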