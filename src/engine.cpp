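#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gillespie (direct method) simulation of one microtubule end.
//
// State: per-protofilament stacks of nucleotide codes (0 = CPP, 1 = GDP),
// gap-free, with `seed_layers` immutable seed layers at the bottom. Channel
// order per protofilament is fixed as (association, dissociation,
// exchange->CPP, exchange->GDP) so that the pure-R reference engine, which
// consumes the same R RNG stream through runif(), reproduces the event
// sequence bitwise. Rates are re-derived from the lattice at every step;
// with 13 protofilaments the full enumeration is O(13) and cheap.

// Lateral registry: the ordinary interfaces are flush (a subunit at layer L
// contacts the neighbour iff that stack occupies layer L, bond weight 1).
// Across the seam the subunit's axial span is shifted by `seam_offset`
// layers (fractional allowed) so it overlaps up to two partner layers; each
// overlap fraction counts as that fraction of a lateral bond. At the
// plus-end protofilament 0 sits `seam_offset` layers high relative to
// protofilament N-1; `pf0_high` encodes the mirrored minus-end orientation.
// Mirrors lateral_weight() in R/lattice.R.
static inline double lateral_weight(const std::vector<int>& h, int npf,
                                    int pf, int layer, double seam_offset,
                                    bool pf0_high) {
  if (npf == 1) return 0.0;  // a single protofilament has no lateral partners
  double w = 0.0;
  for (int side = -1; side <= 1; side += 2) {
    int q = (pf + side + npf) % npf;
    bool is_seam = (pf == 0 && side == -1) || (pf == npf - 1 && side == 1);
    if (!is_seam) {
      if (h[q] > layer) w += 1.0;
    } else {
      bool shift_down = (pf == 0) ? pf0_high : !pf0_high;
      double z0 = shift_down ? layer - seam_offset : layer + seam_offset;
      double j = std::floor(z0);
      double frac_hi = z0 - j;
      if (frac_hi < 1e-12) {
        if (h[q] > j) w += 1.0;
      } else {
        if (h[q] > j) w += 1.0 - frac_hi;
        if (h[q] > j + 1) w += frac_hi;
      }
    }
  }
  return w;
}

// f^w in half-bond steps (w a multiple of 0.5); mirrors lateral_kd_factor()
static inline double lateral_kd_factor(double f, double w) {
  int m = (int) std::lround(2.0 * w);
  double out = 1.0;
  for (int i = 0; i < m / 2; ++i) out *= f;
  if (m % 2 == 1) out *= std::sqrt(f);
  return out;
}

// [[Rcpp::export]]
List run_kmc_cpp(List stacks0, int seed_layers, bool is_plus,
                 double seam_offset, double dimer_rise,
                 double kon, double kd_long, double kd_corner,
                 double gdp_factor, bool interface_acting,
                 double k_exch_gdp, double affinity_ratio,
                 double tub_total, double f_gdp_tub, double p_cpp_nuc,
                 double duration, double record_interval,
                 bool keep_event_log) {
  const int npf = stacks0.size();
  std::vector< std::vector<int> > st(npf);
  for (int p = 0; p < npf; ++p) {
    IntegerVector v = stacks0[p];
    st[p] = std::vector<int>(v.begin(), v.end());
  }
  std::vector<int> h(npf);
  long above = 0;
  for (int p = 0; p < npf; ++p) {
    h[p] = (int) st[p].size();
    above += h[p] - seed_layers;
  }
  const double f_lat = kd_corner / kd_long;  // KD factor per lateral bond
  const double a_rate = kon * tub_total;  // association, per protofilament
  // length in nm computed as (subunits * rise) / npf, matching mean_length_nm()

  // recording grid
  int n_grid = (int) std::floor(duration / record_interval + 1e-9);
  std::vector<double> rec_t, rec_len;
  rec_t.reserve(n_grid + 2);
  rec_len.reserve(n_grid + 2);
  rec_t.push_back(0.0);
  rec_len.push_back((double) above * dimer_rise / npf);
  int next_rec = 1;

  std::vector<double> log_t;
  std::vector<int> log_ev, log_pf, log_nt;

  long n_assoc = 0, n_dissoc = 0, n_exch = 0;
  double t = 0.0;
  const int nchan = 4 * npf;
  std::vector<double> rate(nchan);

  RNGScope scope;

  while (t < duration) {
    // enumerate channels
    long double total_ld = 0.0L;
    for (int p = 0; p < npf; ++p) {
      double d_rate = 0.0, xc = 0.0, xd = 0.0;
      if (h[p] > seed_layers) {
        int tip_layer = h[p] - 1;
        int self_nt = st[p][h[p] - 1];
        int inter_nt = is_plus ? st[p][h[p] - 2] : self_nt;
        int gov = interface_acting ? inter_nt : self_nt;
        double w = lateral_weight(h, npf, p, tip_layer, seam_offset, is_plus);
        double kd = kd_long * lateral_kd_factor(f_lat, w);
        if (gov == 1) kd *= gdp_factor;
        d_rate = kon * kd;
        if (is_plus && k_exch_gdp > 0) {
          double xtot = (self_nt == 1) ? k_exch_gdp
                                       : affinity_ratio * k_exch_gdp;
          xc = xtot * p_cpp_nuc;
          xd = xtot * (1.0 - p_cpp_nuc);
        }
      }
      rate[4 * p] = a_rate;
      rate[4 * p + 1] = d_rate;
      rate[4 * p + 2] = xc;
      rate[4 * p + 3] = xd;
      total_ld += a_rate + d_rate + xc + xd;
    }
    double total = (double) total_ld;
    if (total <= 0.0) break;  // frozen: flat-line to the end

    double u1 = unif_rand();
    double dt = -std::log(u1) / total;
    double t_new = t + dt;

    // record grid points passed before this event fires
    while (next_rec <= n_grid &&
           next_rec * record_interval <= std::min(t_new, duration)) {
      rec_t.push_back(next_rec * record_interval);
      rec_len.push_back((double) above * dimer_rise / npf);
      ++next_rec;
    }
    if (t_new >= duration) { t = t_new; break; }

    // select channel
    double u2 = unif_rand();
    double target = u2 * total;
    long double cum = 0.0L;
    int chosen = nchan - 1;
    for (int k = 0; k < nchan; ++k) {
      cum += rate[k];
      if ((double) cum > target) { chosen = k; break; }
    }
    int p = chosen / 4;
    int kind = chosen % 4;

    if (kind == 0) {                      // association
      int nt = 0;
      if (f_gdp_tub > 0) {
        double u3 = unif_rand();
        nt = (u3 < f_gdp_tub) ? 1 : 0;
      }
      st[p].push_back(nt);
      ++h[p];
      ++above;
      ++n_assoc;
      if (keep_event_log) {
        log_t.push_back(t_new); log_ev.push_back(1);
        log_pf.push_back(p + 1); log_nt.push_back(nt);
      }
    } else if (kind == 1) {               // dissociation
      int nt = st[p].back();
      st[p].pop_back();
      --h[p];
      --above;
      ++n_dissoc;
      if (keep_event_log) {
        log_t.push_back(t_new); log_ev.push_back(2);
        log_pf.push_back(p + 1); log_nt.push_back(nt);
      }
    } else {                              // exchange (2 -> CPP, 3 -> GDP)
      int nt = (kind == 2) ? 0 : 1;
      st[p][h[p] - 1] = nt;
      ++n_exch;
      if (keep_event_log) {
        log_t.push_back(t_new); log_ev.push_back(3);
        log_pf.push_back(p + 1); log_nt.push_back(nt);
      }
    }
    t = t_new;
  }

  // remaining grid points (frozen lattice or exact finish)
  while (next_rec <= n_grid) {
    rec_t.push_back(next_rec * record_interval);
    rec_len.push_back((double) above * dimer_rise / npf);
    ++next_rec;
  }
  if (rec_t.back() < duration - 1e-9) {
    rec_t.push_back(duration);
    rec_len.push_back((double) above * dimer_rise / npf);
  }

  List out_st(npf);
  for (int p = 0; p < npf; ++p)
    out_st[p] = IntegerVector(st[p].begin(), st[p].end());

  List out = List::create(
    _["times"] = NumericVector(rec_t.begin(), rec_t.end()),
    _["mean_length"] = NumericVector(rec_len.begin(), rec_len.end()),
    _["n_assoc"] = (double) n_assoc,
    _["n_dissoc"] = (double) n_dissoc,
    _["n_exch"] = (double) n_exch,
    _["final_stacks"] = out_st);
  if (keep_event_log) {
    out["event_time"] = NumericVector(log_t.begin(), log_t.end());
    out["event_type"] = IntegerVector(log_ev.begin(), log_ev.end());
    out["event_pf"] = IntegerVector(log_pf.begin(), log_pf.end());
    out["event_nt"] = IntegerVector(log_nt.begin(), log_nt.end());
  }
  return out;
}
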