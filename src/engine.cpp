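// Time-stepped integrator for the spiking continuous attractor network.
//
// Izhikevich neurons (forward Euler, configurable membrane substeps),
// Tsodyks-Markram synapses with event-driven (u, x) relaxation at spike
// delivery, and per-connection-class conductance accumulators decayed
// exponentially each step. Single-threaded and free of internal
// randomness: identical inputs give bit-identical rasters.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline double nmda_gate(double v) {
  double z = (v + 80.0) / 60.0;
  z *= z;
  return z / (1.0 + z);
}

// class_par columns
enum { CP_U = 0, CP_TAUU, CP_TAUX, CP_TAUF, CP_TAUS,
       CP_GF, CP_GS, CP_EF, CP_ES, CP_EXC, CP_NPAR };

// [[Rcpp::export]]
List cpp_run_network(NumericVector pC, NumericVector pk, NumericVector pVr,
                     NumericVector pVt, NumericVector pa, NumericVector pb,
                     NumericVector pVpeak, NumericVector pVreset,
                     NumericVector pd,
                     NumericVector v0, NumericVector u0,
                     IntegerVector syn_ptr, IntegerVector syn_post,
                     NumericVector syn_w, IntegerVector syn_class,
                     NumericMatrix class_par,
                     IntegerVector class_lo, IntegerVector class_hi,
                     NumericMatrix drive, IntegerVector drive_idx,
                     int frame_steps,
                     NumericVector I_const,
                     int n_steps, double dt, int substeps, int delay_steps,
                     IntegerVector mon_idx, int mon_stride,
                     double blowup_mv, IntegerVector rec_flag) {
  const int n = pC.size();
  const int n_class = class_par.nrow();
  const int n_syn = syn_post.size();
  const int n_drive = drive_idx.size();
  const int n_mon = mon_idx.size();

  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> vnext(v0.begin(), v0.end());
  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> Isyn(n, 0.0), Iext(I_const.begin(), I_const.end());

  // per-class conductance accumulators over the full index range
  std::vector<double> gF((size_t)n_class * n, 0.0);
  std::vector<double> gS((size_t)n_class * n, 0.0);

  // per-step decay factors per class
  std::vector<double> decF(n_class), decS(n_class);
  for (int c = 0; c < n_class; ++c) {
    decF[c] = std::exp(-dt / class_par(c, CP_TAUF));
    decS[c] = std::exp(-dt / class_par(c, CP_TAUS));
  }

  // TM state per synapse; last delivery time per presynaptic neuron
  std::vector<double> tm_u(n_syn, 0.0), tm_x(n_syn, 1.0);
  std::vector<double> last_del(n, -1.0);

  // spike delay ring buffer
  const int ring_len = delay_steps + 1;
  std::vector< std::vector<int> > ring(ring_len);

  std::vector<int> spike_id;
  std::vector<double> spike_t;
  spike_id.reserve(1 << 20);
  spike_t.reserve(1 << 20);

  // monitors: v plus four receptor-group currents
  int n_rec = (n_mon > 0) ? (n_steps + mon_stride - 1) / mon_stride : 0;
  NumericMatrix mon_v(n_mon > 0 ? n_mon : 1, std::max(n_rec, 1));
  NumericMatrix mon_ampa(n_mon > 0 ? n_mon : 1, std::max(n_rec, 1));
  NumericMatrix mon_nmda(n_mon > 0 ? n_mon : 1, std::max(n_rec, 1));
  NumericMatrix mon_gabaa(n_mon > 0 ? n_mon : 1, std::max(n_rec, 1));
  NumericMatrix mon_gabab(n_mon > 0 ? n_mon : 1, std::max(n_rec, 1));
  std::vector<int> monslot(n, -1);
  for (int m = 0; m < n_mon; ++m) monslot[mon_idx[m]] = m;

  // rolling voltage history for blow-up diagnostics
  const int hist_len = 100;
  NumericMatrix vhist(hist_len, n);
  int hist_row = 0;

  std::vector<double> relaxF(n_class), relaxX(n_class);

  bool ok = true;
  int blow_neuron = -1, blow_step = -1;
  int cur_frame = -1;

  int step;
  for (step = 0; step < n_steps; ++step) {
    // (0) zero-order-hold external drive
    if (n_drive > 0 && frame_steps > 0) {
      int frame = step / frame_steps;
      if (frame >= drive.ncol()) frame = drive.ncol() - 1;
      if (frame != cur_frame) {
        cur_frame = frame;
        for (int j = 0; j < n_drive; ++j)
          Iext[drive_idx[j]] = I_const[drive_idx[j]] + drive(j, frame);
      }
    }

    // (1) decay conductances
    for (int c = 0; c < n_class; ++c) {
      double fF = decF[c], fS = decS[c];
      double *gf = &gF[(size_t)c * n], *gs = &gS[(size_t)c * n];
      for (int i = class_lo[c]; i < class_hi[c]; ++i) {
        gf[i] *= fF;
        gs[i] *= fS;
      }
    }

    // (2) deliver delayed spikes through TM synapses
    std::vector<int> &due = ring[step % ring_len];
    if (!due.empty()) {
      double t_now = (step + 1) * dt;
      for (size_t q = 0; q < due.size(); ++q) {
        int pre = due[q];
        double elapsed = (last_del[pre] >= 0.0) ? t_now - last_del[pre] : -1.0;
        if (elapsed > 0.0) {
          for (int c = 0; c < n_class; ++c) {
            relaxF[c] = std::exp(-elapsed / class_par(c, CP_TAUU));
            relaxX[c] = std::exp(-elapsed / class_par(c, CP_TAUX));
          }
        }
        for (int s = syn_ptr[pre]; s < syn_ptr[pre + 1]; ++s) {
          int c = syn_class[s];
          double uu = tm_u[s], xx = tm_x[s];
          if (elapsed > 0.0) {
            uu *= relaxF[c];
            xx = 1.0 - (1.0 - xx) * relaxX[c];
          }
          uu += class_par(c, CP_U) * (1.0 - uu);
          double R = uu * xx;
          xx -= R;
          tm_u[s] = uu;
          tm_x[s] = xx;
          double amp = syn_w[s] * R;
          int post = syn_post[s];
          gF[(size_t)c * n + post] += class_par(c, CP_GF) * amp;
          gS[(size_t)c * n + post] += class_par(c, CP_GS) * amp;
        }
        last_del[pre] = t_now;
      }
      due.clear();
    }

    // (3) receptor currents
    std::fill(Isyn.begin(), Isyn.end(), 0.0);
    bool rec_now = (n_mon > 0) && (step % mon_stride == 0);
    int rec_col = rec_now ? step / mon_stride : 0;
    for (int c = 0; c < n_class; ++c) {
      double Ef = class_par(c, CP_EF), Es = class_par(c, CP_ES);
      bool exc = class_par(c, CP_EXC) > 0.5;
      double *gf = &gF[(size_t)c * n], *gs = &gS[(size_t)c * n];
      for (int i = class_lo[c]; i < class_hi[c]; ++i) {
        double vv = v[i];
        double If = gf[i] * (Ef - vv);
        double s = exc ? nmda_gate(vv) : 1.0;
        double Is = s * gs[i] * (Es - vv);
        Isyn[i] += If + Is;
        if (rec_now && monslot[i] >= 0) {
          int m = monslot[i];
          if (exc) {
            mon_ampa(m, rec_col) += If;
            mon_nmda(m, rec_col) += Is;
          } else {
            mon_gabaa(m, rec_col) += If;
            mon_gabab(m, rec_col) += Is;
          }
        }
      }
    }

    // (4) Izhikevich step
    double h = dt / substeps;
    double t_spk = (step + 1) * dt;
    for (int i = 0; i < n; ++i) {
      double vv = vnext[i], uu = u[i];
      double I = Iext[i] + Isyn[i];
      bool spiked = false;
      for (int s = 0; s < substeps; ++s) {
        vv += h * (pk[i] * (vv - pVr[i]) * (vv - pVt[i]) - uu + I) / pC[i];
        if (vv >= pVpeak[i]) { spiked = true; break; }
      }
      uu += dt * pa[i] * (pb[i] * (vv - pVr[i]) - uu);
      if (spiked) {
        v[i] = pVpeak[i];
        vnext[i] = pVreset[i];
        uu += pd[i];
        if (rec_flag[i]) {
          spike_id.push_back(i);
          spike_t.push_back(t_spk);
        }
        ring[(step + delay_steps) % ring_len].push_back(i);
      } else {
        v[i] = vv;
        vnext[i] = vv;
      }
      u[i] = uu;
      if (!(v[i] > -blowup_mv && v[i] < blowup_mv) || !std::isfinite(uu)) {
        ok = false;
        blow_neuron = i;
        blow_step = step;
      }
    }

    // (5) record
    if (rec_now)
      for (int m = 0; m < n_mon; ++m) mon_v(m, rec_col) = v[mon_idx[m]];
    for (int i = 0; i < n; ++i) vhist(hist_row, i) = v[i];
    hist_row = (hist_row + 1) % hist_len;

    if (!ok) break;
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  // unroll the voltage-history ring so rows are chronological
  NumericMatrix dump(hist_len, n);
  for (int r = 0; r < hist_len; ++r) {
    int src = (hist_row + r) % hist_len;
    for (int i = 0; i < n; ++i) dump(r, i) = vhist(src, i);
  }

  return List::create(
    _["ok"] = ok,
    _["blow_neuron"] = blow_neuron + 1,
    _["blow_step"] = blow_step + 1,
    _["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
    _["spike_t"] = NumericVector(spike_t.begin(), spike_t.end()),
    _["mon_v"] = mon_v,
    _["mon_ampa"] = mon_ampa,
    _["mon_nmda"] = mon_nmda,
    _["mon_gabaa"] = mon_gabaa,
    _["mon_gabab"] = mon_gabab,
    _["v"] = NumericVector(v.begin(), v.end()),
    _["u"] = NumericVector(u.begin(), u.end()),
    _["vdump"] = dump);
}
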