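#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Event-driven exact simulation of the single-cell process: per-cell
// competing exponential clocks for plasmid replication (logistic, +1 capped
// at z_hat), cell division (binomial segregation of the mother's plasmids)
// and death (plasmid-free cells under antibiotics only). Cells with equal
// copy number are exchangeable, so events are drawn per copy-number class
// and the concrete cell is then picked uniformly within the class; this is
// equivalent to the naive per-cell algorithm but O(z_hat) per event.
//
// Population control: whenever the census exceeds max_cells, uniformly
// random cells are removed until exactly max_cells remain; the cumulative
// log correction sum(log(N/(N-1))) is tracked so growth-rate estimates can
// refer to pre-subsampling counts.
//
// Uses R's RNG throughout (reproducible under set.seed()).

struct Pop {
  std::vector<int> z_of, lin_of;            // slot-indexed cell state
  std::vector<int> aidx, bidx;              // positions in alive / bucket
  std::vector<int> alive;                   // alive slot ids
  std::vector<std::vector<int>> bucket;     // slot ids by copy number
  std::vector<int> freelist;

  explicit Pop(int z_hat) : bucket(z_hat + 1) {}

  int size() const { return (int)alive.size(); }
  int count(int z) const { return (int)bucket[z].size(); }

  int add(int z, int lin) {
    int slot;
    if (freelist.empty()) {
      slot = (int)z_of.size();
      z_of.push_back(z); lin_of.push_back(lin);
      aidx.push_back(0); bidx.push_back(0);
    } else {
      slot = freelist.back(); freelist.pop_back();
      z_of[slot] = z; lin_of[slot] = lin;
    }
    aidx[slot] = (int)alive.size(); alive.push_back(slot);
    bidx[slot] = (int)bucket[z].size(); bucket[z].push_back(slot);
    return slot;
  }

  void remove(int slot) {
    int ai = aidx[slot], last = alive.back();
    alive[ai] = last; aidx[last] = ai; alive.pop_back();
    int z = z_of[slot], bi = bidx[slot], lastb = bucket[z].back();
    bucket[z][bi] = lastb; bidx[lastb] = bi; bucket[z].pop_back();
    freelist.push_back(slot);
  }

  void move(int slot, int znew) {
    int z = z_of[slot], bi = bidx[slot], lastb = bucket[z].back();
    bucket[z][bi] = lastb; bidx[lastb] = bi; bucket[z].pop_back();
    z_of[slot] = znew;
    bidx[slot] = (int)bucket[znew].size(); bucket[znew].push_back(slot);
  }

  int pick_in_class(int z) const {
    int n = count(z);
    int j = (int)std::floor(unif_rand() * n);
    if (j >= n) j = n - 1;
    return bucket[z][j];
  }

  int pick_alive() const {
    int n = size();
    int j = (int)std::floor(unif_rand() * n);
    if (j >= n) j = n - 1;
    return alive[j];
  }
};

// [[Rcpp::export]]
List sim_lineages_cpp(int z_hat, double b, double beta0, double mu0,
                      double burden_scale, NumericVector p,
                      NumericVector seg_dur, IntegerVector seg_alpha,
                      double t_max, int max_cells, IntegerVector init_z,
                      bool drop_plasmid_free, double ts_dt,
                      int max_records) {
  if (z_hat < 2) stop("z_hat must be >= 2");
  if (p.size() != z_hat) stop("strategy length must equal z_hat");
  if (t_max <= 0) stop("t_max must be positive");
  if (max_cells < 1) stop("max_cells must be >= 1");

  // per-class rates; index z = 0..z_hat
  std::vector<double> r_repl(z_hat + 1), beta_z(z_hat + 1);
  for (int z = 0; z <= z_hat; ++z) {
    r_repl[z] = b * z * (1.0 - (double)z / z_hat);
    beta_z[z] = (z == 0)
      ? beta0
      : beta0 * std::max(0.0, 1.0 - burden_scale * (double)z / z_hat);
  }

  Pop pop(z_hat);
  for (int i = 0; i < init_z.size(); ++i) {
    int z = init_z[i];
    if (z < 0 || z > z_hat) stop("initial copy numbers must lie in 0..z_hat");
    if (drop_plasmid_free && z == 0)
      stop("initial cells must carry plasmids when drop_plasmid_free=TRUE");
    pop.add(z, i + 1);
  }

  // division records
  std::vector<int> rec_lin, rec_mz, rec_d1, rec_d2;
  std::vector<double> rec_t;
  long long records_skipped = 0;

  // population time series for growth estimation
  std::vector<double> ts_t, ts_logcorr;
  std::vector<int> ts_n;
  double next_ts = 0.0;

  double t = 0.0, log_corr = 0.0;
  long long n_birth = 0, n_div = 0, n_death = 0, n_sub = 0, n_dropped = 0;
  int nseg = seg_dur.size();
  int seg_i = 0;
  double seg_left = seg_dur[0];

  while (t < t_max && pop.size() > 0) {
    if (t >= next_ts) {
      ts_t.push_back(t); ts_n.push_back(pop.size());
      ts_logcorr.push_back(log_corr);
      next_ts += ts_dt;
    }
    int alpha = seg_alpha[seg_i];
    // total event rate over classes
    double R = 0.0;
    for (int z = 0; z <= z_hat; ++z) {
      int n = pop.count(z);
      if (n == 0) continue;
      double div = (z == 0 && alpha == 1) ? 0.0 : beta_z[z];
      double dth = (z == 0 && alpha == 1) ? mu0 : 0.0;
      R += n * (r_repl[z] + div + dth);
    }
    if (R <= 0.0) {                        // absorbing census; jump ahead
      double jump = std::min(seg_left, t_max - t);
      t += jump; seg_left -= jump;
      if (seg_left <= 0.0 && t < t_max) {
        seg_i = (seg_i + 1) % nseg; seg_left = seg_dur[seg_i];
        continue;
      }
      break;
    }
    double dt = exp_rand() / R;
    if (dt > seg_left) {                   // environment switches first
      t += seg_left;
      seg_i = (seg_i + 1) % nseg; seg_left = seg_dur[seg_i];
      continue;
    }
    if (t + dt > t_max) { t = t_max; break; }
    t += dt; seg_left -= dt;

    // pick class and event type
    double u = unif_rand() * R, acc = 0.0;
    int ez = -1, etype = -1;               // 0 repl, 1 division, 2 death
    for (int z = 0; z <= z_hat && ez < 0; ++z) {
      int n = pop.count(z);
      if (n == 0) continue;
      double div = (z == 0 && alpha == 1) ? 0.0 : beta_z[z];
      double dth = (z == 0 && alpha == 1) ? mu0 : 0.0;
      acc += n * r_repl[z];
      if (u < acc) { ez = z; etype = 0; break; }
      acc += n * div;
      if (u < acc) { ez = z; etype = 1; break; }
      acc += n * dth;
      if (u < acc) { ez = z; etype = 2; break; }
    }
    if (ez < 0) continue;                  // float dust at the top of [0, R)

    if (etype == 0) {                      // plasmid replication
      int slot = pop.pick_in_class(ez);
      pop.move(slot, ez + 1);
      ++n_birth;
    } else if (etype == 1) {               // cell division
      int slot = pop.pick_in_class(ez);
      int lin = pop.lin_of[slot];
      int d1 = (ez >= 1) ? (int)R::rbinom((double)ez, p[ez - 1]) : 0;
      int d2 = ez - d1;
      if (ez >= 1) {
        if ((int)rec_t.size() < max_records) {
          rec_lin.push_back(lin); rec_t.push_back(t);
          rec_mz.push_back(ez); rec_d1.push_back(d1); rec_d2.push_back(d2);
        } else ++records_skipped;
      }
      ++n_div;
      if (drop_plasmid_free && d1 == 0) { ++n_dropped; pop.remove(slot); }
      else pop.move(slot, d1);
      if (drop_plasmid_free && d2 == 0) ++n_dropped;
      else pop.add(d2, lin);
      while (pop.size() > max_cells) {     // uniform subsampling to the cap
        int n = pop.size();
        log_corr += std::log((double)n / (n - 1));
        pop.remove(pop.pick_alive());
        ++n_sub;
      }
    } else {                               // death (plasmid-free, alpha=1)
      pop.remove(pop.pick_in_class(ez));
      ++n_death;
    }
  }

  ts_t.push_back(t); ts_n.push_back(pop.size());
  ts_logcorr.push_back(log_corr);

  IntegerVector census(pop.size());
  IntegerVector census_lin(pop.size());
  for (int i = 0; i < pop.size(); ++i) {
    census[i] = pop.z_of[pop.alive[i]];
    census_lin[i] = pop.lin_of[pop.alive[i]];
  }

  return List::create(
    _["rec_lineage"] = wrap(rec_lin), _["rec_time"] = wrap(rec_t),
    _["rec_mother_z"] = wrap(rec_mz), _["rec_d1"] = wrap(rec_d1),
    _["rec_d2"] = wrap(rec_d2),
    _["census_z"] = census, _["census_lineage"] = census_lin,
    _["ts_t"] = wrap(ts_t), _["ts_n"] = wrap(ts_n),
    _["ts_log_corr"] = wrap(ts_logcorr),
    _["t_end"] = t, _["log_corr"] = log_corr,
    _["n_replications"] = (double)n_birth, _["n_divisions"] = (double)n_div,
    _["n_deaths"] = (double)n_death, _["n_subsampled"] = (double)n_sub,
    _["n_dropped_plasmid_free"] = (double)n_dropped,
    _["records_skipped"] = (double)records_skipped);
}
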