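#include <Rcpp.h>
using namespace Rcpp;

// Time-weighted occupancy recording shared by both simulators. The
// interval [t0, t1) spent in protein state n is split across the
// post-burn-in blocks; occupancy outside [burn_t, t_end) is discarded.
static inline void record_interval(NumericMatrix &occ, int n, double t0,
                                   double t1, double burn_t,
                                   double block_len, int n_blocks) {
  if (t1 <= burn_t) return;
  if (t0 < burn_t) t0 = burn_t;
  double rel0 = t0 - burn_t, rel1 = t1 - burn_t;
  int b0 = (int)(rel0 / block_len);
  int b1 = (int)(rel1 / block_len);
  if (b0 >= n_blocks) return;
  if (b1 >= n_blocks) b1 = n_blocks - 1;
  if (b0 == b1) {
    occ(n, b0) += rel1 - rel0;
    return;
  }
  occ(n, b0) += (b0 + 1) * block_len - rel0;
  for (int b = b0 + 1; b < b1; ++b) occ(n, b) += block_len;
  occ(n, b1) += rel1 - b1 * block_len;
}

// Reduced bursty model: bursts of geometric size G (P[G=k] = q p^k on
// k = 0, 1, ...) arrive at rate c(n); single-protein decay at rate d*n.
// [[Rcpp::export]]
List cpp_gillespie_bursty(NumericVector c_grid, double d, double p,
                          int n0, double t_end, double burn_t,
                          int n_blocks) {
  const int n_cap = c_grid.size() - 1;
  const double block_len = (t_end - burn_t) / n_blocks;
  const double logp = std::log(p);
  NumericMatrix occ(n_cap + 1, n_blocks);
  int n = n0;
  double t = 0.0;
  long long events = 0;
  bool exceeded = false;
  while (t < t_end) {
    double cn = c_grid[n];
    double total = cn + d * n;
    if (total <= 0.0) {  // absorbing state: sit here until t_end
      record_interval(occ, n, t, t_end, burn_t, block_len, n_blocks);
      t = t_end;
      break;
    }
    double dt = exp_rand() / total;
    double t1 = t + dt < t_end ? t + dt : t_end;
    record_interval(occ, n, t, t1, burn_t, block_len, n_blocks);
    t += dt;
    if (t >= t_end) break;
    ++events;
    if (unif_rand() * total < cn) {
      int g = (int)std::floor(std::log(unif_rand()) / logp);
      if (n + g > n_cap) { exceeded = true; break; }
      n += g;
    } else {
      --n;
    }
    if (events % 4194304 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["occupancy"] = occ, _["exceeded"] = exceeded,
                      _["events"] = (double)events, _["final_n"] = n);
}

// Full three-stage chain: promoter activity i (0/1) switching at rates
// a_n (on) / b_n (off), transcription at s (active) or r (inactive),
// mRNA decay v*m, translation u*m, protein decay d*n.
// [[Rcpp::export]]
List cpp_gillespie_full(double s, double r, double u, double v, double d,
                        NumericVector a_grid, NumericVector b_grid,
                        int i0, int m0, int n0, double t_end,
                        double burn_t, int n_blocks, int m_cap) {
  const int n_cap = a_grid.size() - 1;
  const double block_len = (t_end - burn_t) / n_blocks;
  NumericMatrix occ(n_cap + 1, n_blocks);
  NumericVector m_occ(m_cap + 1);
  double active_time = 0.0, recorded_time = 0.0;
  int i = i0, m = m0, n = n0;
  double t = 0.0;
  long long events = 0;
  bool exceeded = false;
  while (t < t_end) {
    double w_sw = i == 0 ? a_grid[n] : b_grid[n];
    double w_tx = i == 1 ? s : r;
    double w_md = v * m;
    double w_tl = u * m;
    double w_pd = d * n;
    double total = w_sw + w_tx + w_md + w_tl + w_pd;
    if (total <= 0.0) {
      record_interval(occ, n, t, t_end, burn_t, block_len, n_blocks);
      if (t_end > burn_t) {
        double dt_rec = t_end - (t > burn_t ? t : burn_t);
        if (dt_rec > 0) {
          m_occ[m] += dt_rec;
          recorded_time += dt_rec;
          if (i == 1) active_time += dt_rec;
        }
      }
      t = t_end;
      break;
    }
    double dt = exp_rand() / total;
    double t1 = t + dt < t_end ? t + dt : t_end;
    record_interval(occ, n, t, t1, burn_t, block_len, n_blocks);
    if (t1 > burn_t) {
      double dt_rec = t1 - (t > burn_t ? t : burn_t);
      m_occ[m] += dt_rec;
      recorded_time += dt_rec;
      if (i == 1) active_time += dt_rec;
    }
    t += dt;
    if (t >= t_end) break;
    ++events;
    double x = unif_rand() * total;
    if (x < w_sw) {
      i = 1 - i;
    } else if (x < w_sw + w_tx) {
      if (m + 1 > m_cap) { exceeded = true; break; }
      ++m;
    } else if (x < w_sw + w_tx + w_md) {
      --m;
    } else if (x < w_sw + w_tx + w_md + w_tl) {
      if (n + 1 > n_cap) { exceeded = true; break; }
      ++n;
    } else {
      --n;
    }
    if (events % 4194304 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["occupancy"] = occ, _["m_occupancy"] = m_occ,
                      _["active_time"] = active_time,
                      _["recorded_time"] = recorded_time,
                      _["exceeded"] = exceeded,
                      _["events"] = (double)events,
                      _["final_state"] = IntegerVector::create(i, m, n));
}
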