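// Rejection-free (n-fold way) kinetic Monte Carlo engines.
//
// (a) Restricted solid-on-solid step edge: integer column heights on a
//     periodic 1D lattice, neighbor differences limited to {-1, 0, +1}.
//     Attachment at every admissible site at rate nu * (C/Ce) (direct
//     incorporation from a 3D supply field); detachment at rate
//     nu * exp(-dE/kT) with dE the bond-energy change of the reverse move,
//     so that forward/backward rate ratios satisfy detailed balance at
//     C/Ce = 1. Edge energy: omega per unit |height difference| (each unit
//     is one kink).
//
// (b) Anisotropic lattice gas of a single (200) molecular layer: occupancy
//     on a periodic 2D lattice with bonds E_010 (rows direction, pi-pi),
//     E_001 (columns direction, in-plane vdW) and E_011 (one diagonal
//     family, H-bond chains). Attachment at rate nu * exp(dmu/kT),
//     detachment nu * exp(-sum(bonds)/kT): grand-canonical detailed balance
//     at dmu = 0.
//
// Randomness comes from R's RNG stream (unif_rand), so set.seed() on the
// R side makes event sequences bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// exponential waiting time from R's RNG
static inline double rexp_total(double total_rate) {
  double u = unif_rand();
  if (u <= 0.0) u = 1e-300;
  return -std::log(u) / total_rate;
}

// ---------------------------------------------------------------- step edge

struct EdgeSim {
  int L;
  bool periodic;
  std::vector<int> h;
  double omega_kT;   // kink energy in units of kT
  double sat;        // C/Ce
  double nu;
  std::vector<double> r_att, r_det;
  double total;

  // neighbor index, or -1 when absent (free boundary)
  int left(int i) const {
    if (i == 0) return periodic ? L - 1 : -1;
    return i - 1;
  }
  int right(int i) const {
    if (i == L - 1) return periodic ? 0 : -1;
    return i + 1;
  }

  double edge_energy_local(int i, int hi) const {
    int l = left(i), r = right(i);
    double e = 0.0;
    if (l >= 0) e += omega_kT * std::abs(hi - h[l]);
    if (r >= 0) e += omega_kT * std::abs(h[r] - hi);
    return e;
  }

  void site_rates(int i, double &att, double &det) const {
    int l = left(i), r = right(i), hi = h[i];
    bool ok_att = (l < 0 || std::abs(hi + 1 - h[l]) <= 1) &&
                  (r < 0 || std::abs(h[r] - hi - 1) <= 1);
    att = ok_att ? nu * sat : 0.0;
    bool ok_det = (l < 0 || std::abs(hi - 1 - h[l]) <= 1) &&
                  (r < 0 || std::abs(h[r] - hi + 1) <= 1);
    det = 0.0;
    if (ok_det) {
      double dE = edge_energy_local(i, hi - 1) - edge_energy_local(i, hi);
      det = nu * std::exp(-dE);
    }
  }

  void refresh(int i) {
    site_rates(i, r_att[i], r_det[i]);
  }

  // The total is recomputed exactly every event rather than maintained
  // incrementally: rates span many orders of magnitude (up to e^{2w/kT}),
  // and incremental updates suffer catastrophic cancellation that starves
  // the rare low-rate moves at the tail of the selection scan.
  void recompute_total() {
    total = 0.0;
    for (int i = 0; i < L; ++i) total += r_att[i] + r_det[i];
  }

  void init() {
    r_att.assign(L, 0.0);
    r_det.assign(L, 0.0);
    for (int i = 0; i < L; ++i) site_rates(i, r_att[i], r_det[i]);
    recompute_total();
  }

  // kinks per bond (per molecular site of step length)
  double kink_density() const {
    int k = 0, nb = 0;
    for (int i = 0; i < L; ++i) {
      int r = right(i);
      if (r < 0) continue;
      k += std::abs(h[r] - h[i]);
      ++nb;
    }
    return (double)k / nb;
  }

  double roughness() const {
    double m = 0.0, s = 0.0;
    for (int i = 0; i < L; ++i) m += h[i];
    m /= L;
    for (int i = 0; i < L; ++i) s += (h[i] - m) * (h[i] - m);
    return std::sqrt(s / L);
  }
};

// [[Rcpp::export(name = ".kmc_step_edge_cpp")]]
List kmc_step_edge_cpp(int L, double omega_kT, double sat, double nu,
                       double n_events, double burn_frac, int n_batches,
                       bool periodic, IntegerVector h0) {
  EdgeSim sim;
  sim.L = L;
  sim.periodic = periodic;
  sim.h.assign(L, 0);
  if (h0.size() == L) {
    for (int i = 0; i < L; ++i) sim.h[i] = h0[i];
  }
  sim.omega_kT = omega_kT;
  sim.sat = sat;
  sim.nu = nu;
  sim.init();

  long long N = (long long)n_events;
  long long burn = (long long)(burn_frac * N);
  long long n_att = 0, n_det = 0;
  double t = 0.0, t_meas = 0.0;
  long long net_meas = 0;

  // batch means for kink density (time-weighted) and velocity
  std::vector<double> kink_batch(n_batches, 0.0), time_batch(n_batches, 0.0);
  std::vector<double> net_batch(n_batches, 0.0);
  long long meas_events = N - burn;
  if (meas_events < n_batches) n_batches = 1;
  long long per_batch = meas_events / n_batches;

  for (long long ev = 0; ev < N; ++ev) {
    sim.recompute_total();
    if (sim.total <= 0.0) break;  // frozen (only possible at sat = 0)
    double dt = rexp_total(sim.total);
    bool measuring = ev >= burn;
    int b = 0;
    if (measuring) {
      b = (int)((ev - burn) / per_batch);
      if (b >= n_batches) b = n_batches - 1;
      double kd = sim.kink_density();
      kink_batch[b] += kd * dt;
      time_batch[b] += dt;
      t_meas += dt;
    }
    t += dt;
    // select event by linear scan of cumulative rates
    double u = unif_rand() * sim.total;
    double acc = 0.0;
    int site = -1;
    bool attach = true;
    for (int i = 0; i < L; ++i) {
      acc += sim.r_att[i];
      if (u < acc) { site = i; attach = true; break; }
      acc += sim.r_det[i];
      if (u < acc) { site = i; attach = false; break; }
    }
    if (site < 0) {  // u fell into float round-off at the scan tail
      for (int i = L - 1; i >= 0; --i) {
        if (sim.r_det[i] > 0) { site = i; attach = false; break; }
        if (sim.r_att[i] > 0) { site = i; attach = true; break; }
      }
      if (site < 0) break;
    }
    sim.h[site] += attach ? 1 : -1;
    if (attach) ++n_att; else ++n_det;
    if (measuring) {
      net_meas += attach ? 1 : -1;
      net_batch[b] += attach ? 1.0 : -1.0;
    }
    sim.refresh(site);
    if (sim.left(site) >= 0) sim.refresh(sim.left(site));
    if (sim.right(site) >= 0) sim.refresh(sim.right(site));
  }

  // overall time-weighted kink density and velocity; batch detail goes to R
  double kd_mean = 0.0, tw = 0.0;
  for (int b = 0; b < n_batches; ++b) {
    if (time_batch[b] > 0) { kd_mean += kink_batch[b]; tw += time_batch[b]; }
  }
  kd_mean = tw > 0 ? kd_mean / tw : NA_REAL;
  double velocity = t_meas > 0 ? (double)net_meas / (L * t_meas) : NA_REAL;

  return List::create(
    _["velocity"] = velocity,
    _["kink_density"] = kd_mean,
    _["roughness"] = sim.roughness(),
    _["n_attach"] = (double)n_att,
    _["n_detach"] = (double)n_det,
    _["time"] = t,
    _["kink_batch"] = NumericVector(kink_batch.begin(), kink_batch.end()),
    _["net_batch"] = NumericVector(net_batch.begin(), net_batch.end()),
    _["time_batch"] = NumericVector(time_batch.begin(), time_batch.end()),
    _["heights"] = IntegerVector(sim.h.begin(), sim.h.end())
  );
}

// ------------------------------------------------------------- lattice gas

struct SurfSim {
  int nr, nc;
  std::vector<int> occ;       // row-major occupancy
  double Eb_kT, Ec_kT, Ed_kT; // bonds along [010] (rows dir), [001], [011]
  double dmu_kT, nu;
  std::vector<double> rate;   // one move per site (flip)
  std::vector<double> rowsum;
  double total;

  int idx(int r, int c) const { return r * nc + c; }
  int wrap_r(int r) const { return (r + nr) % nr; }
  int wrap_c(int c) const { return (c + nc) % nc; }

  double bond_sum(int r, int c) const {
    double s = 0.0;
    if (occ[idx(wrap_r(r - 1), c)]) s += Eb_kT;   // neighbor along -[010]
    if (occ[idx(wrap_r(r + 1), c)]) s += Eb_kT;
    if (occ[idx(r, wrap_c(c - 1))]) s += Ec_kT;   // along [001]
    if (occ[idx(r, wrap_c(c + 1))]) s += Ec_kT;
    if (occ[idx(wrap_r(r + 1), wrap_c(c + 1))]) s += Ed_kT;  // [011] diagonal
    if (occ[idx(wrap_r(r - 1), wrap_c(c - 1))]) s += Ed_kT;
    return s;
  }

  double site_rate(int r, int c) const {
    if (occ[idx(r, c)]) {
      return nu * std::exp(-bond_sum(r, c));     // detach
    }
    return nu * std::exp(dmu_kT);                // attach
  }

  void refresh(int r, int c) {
    double nr_rate = site_rate(r, c);
    int i = idx(r, c);
    double d = nr_rate - rate[i];
    rate[i] = nr_rate;
    rowsum[r] += d;
    total += d;
  }

  // periodic exact resync of the cached sums: incremental updates of sums
  // over rates of very different magnitudes accumulate cancellation error
  // that would starve rare low-rate moves
  void resync() {
    total = 0.0;
    for (int r = 0; r < nr; ++r) {
      double s = 0.0;
      for (int c = 0; c < nc; ++c) s += rate[idx(r, c)];
      rowsum[r] = s;
      total += s;
    }
  }

  void init() {
    rate.assign(nr * nc, 0.0);
    rowsum.assign(nr, 0.0);
    total = 0.0;
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c < nc; ++c) {
        double x = site_rate(r, c);
        rate[idx(r, c)] = x;
        rowsum[r] += x;
        total += x;
      }
  }
};

// [[Rcpp::export(name = ".kmc_surface_cpp")]]
List kmc_surface_cpp(IntegerMatrix lattice, double Eb_kT, double Ec_kT,
                     double Ed_kT, double dmu_kT, double nu,
                     double n_events) {
  SurfSim sim;
  sim.nr = lattice.nrow();
  sim.nc = lattice.ncol();
  sim.occ.assign(sim.nr * sim.nc, 0);
  for (int r = 0; r < sim.nr; ++r)
    for (int c = 0; c < sim.nc; ++c)
      sim.occ[sim.idx(r, c)] = lattice(r, c) != 0 ? 1 : 0;
  sim.Eb_kT = Eb_kT;
  sim.Ec_kT = Ec_kT;
  sim.Ed_kT = Ed_kT;
  sim.dmu_kT = dmu_kT;
  sim.nu = nu;
  sim.init();

  long long N = (long long)n_events;
  long long n_att = 0, n_det = 0;
  double t = 0.0;

  for (long long ev = 0; ev < N; ++ev) {
    if ((ev & 1023) == 0) sim.resync();
    if (sim.total <= 0.0) break;
    t += rexp_total(sim.total);
    double u = unif_rand() * sim.total;
    int r = 0;
    double acc = 0.0;
    for (; r < sim.nr - 1; ++r) {
      if (u < acc + sim.rowsum[r]) break;
      acc += sim.rowsum[r];
    }
    double u2 = u - acc;
    int c = 0;
    double acc2 = 0.0;
    for (; c < sim.nc - 1; ++c) {
      acc2 += sim.rate[sim.idx(r, c)];
      if (u2 < acc2) break;
    }
    int i = sim.idx(r, c);
    if (sim.occ[i]) { sim.occ[i] = 0; ++n_det; } else { sim.occ[i] = 1; ++n_att; }
    // refresh the flipped site and its six bond partners
    sim.refresh(r, c);
    sim.refresh(sim.wrap_r(r - 1), c);
    sim.refresh(sim.wrap_r(r + 1), c);
    sim.refresh(r, sim.wrap_c(c - 1));
    sim.refresh(r, sim.wrap_c(c + 1));
    sim.refresh(sim.wrap_r(r + 1), sim.wrap_c(c + 1));
    sim.refresh(sim.wrap_r(r - 1), sim.wrap_c(c - 1));
  }

  IntegerMatrix out(sim.nr, sim.nc);
  for (int r = 0; r < sim.nr; ++r)
    for (int c = 0; c < sim.nc; ++c)
      out(r, c) = sim.occ[sim.idx(r, c)];

  return List::create(
    _["lattice"] = out,
    _["n_attach"] = (double)n_att,
    _["n_detach"] = (double)n_det,
    _["time"] = t
  );
}

// connected vacancy clusters, 4-connectivity, periodic boundaries
// [[Rcpp::export(name = ".vacancy_clusters_cpp")]]
int vacancy_clusters_cpp(IntegerMatrix lattice) {
  int nr = lattice.nrow(), nc = lattice.ncol();
  std::vector<int> seen(nr * nc, 0);
  int clusters = 0;
  std::vector<int> stack;
  for (int r0 = 0; r0 < nr; ++r0)
    for (int c0 = 0; c0 < nc; ++c0) {
      int i0 = r0 * nc + c0;
      if (lattice(r0, c0) != 0 || seen[i0]) continue;
      ++clusters;
      stack.push_back(i0);
      seen[i0] = 1;
      while (!stack.empty()) {
        int i = stack.back();
        stack.pop_back();
        int r = i / nc, c = i % nc;
        int nbr[4][2] = {{(r + 1) % nr, c}, {(r + nr - 1) % nr, c},
                         {r, (c + 1) % nc}, {r, (c + nc - 1) % nc}};
        for (int k = 0; k < 4; ++k) {
          int j = nbr[k][0] * nc + nbr[k][1];
          if (!seen[j] && lattice(nbr[k][0], nbr[k][1]) == 0) {
            seen[j] = 1;
            stack.push_back(j);
          }
        }
      }
    }
  return clusters;
}
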