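#include <Rcpp.h>
using namespace Rcpp;

// Edge transfer function. type: 1 = linear (p1 = slope), 2 = normalized Hill
// (p1 = n, p2 = k). x is assumed in [0,1].
static inline double edge_tf(double x, int type, double p1, double p2) {
  if (type == 1) return p1 * x;
  if (x <= 0.0) return 0.0;
  double xn = std::pow(x, p1);
  double kn = std::pow(p2, p1);
  return xn * (1.0 + kn) / (xn + kn);
}

// Synchronous fixed-point simulation of a cFL model over a set of
// experimental conditions.
//
// Gates are stored flat: gate g owns slots gate_start[g] .. gate_start[g] +
// gate_len[g] - 1. A gate is active iff none of its slots has type 0
// (absent). Node update: OR over that node's active gates of the AND over
// the gate's per-input transferred values. operator mode: 0 = min/max,
// 1 = product/capped-sum, 2 = Boolean (inputs thresholded at 0.5).
//
// clamp is n_nodes x n_cond; NA entries are free nodes, non-NA entries are
// held fixed (stimulus values, inhibited nodes clamped to 0).
// [[Rcpp::export]]
List cfl_sim_cpp(int n_nodes,
                 IntegerVector gate_output,
                 IntegerVector gate_start,
                 IntegerVector gate_len,
                 IntegerVector slot_input,
                 IntegerVector slot_sign,
                 IntegerVector slot_type,
                 NumericVector slot_p1,
                 NumericVector slot_p2,
                 NumericMatrix clamp,
                 int mode,
                 double tol,
                 int max_iter) {
  int w = gate_output.size();
  int n_cond = clamp.ncol();

  std::vector<bool> gate_active(w);
  std::vector<bool> node_has_gate(n_nodes, false);
  for (int g = 0; g < w; ++g) {
    bool act = true;
    for (int s = gate_start[g]; s < gate_start[g] + gate_len[g]; ++s)
      if (slot_type[s] == 0) { act = false; break; }
    gate_active[g] = act;
    if (act) node_has_gate[gate_output[g]] = true;
  }

  NumericMatrix x_out(n_nodes, n_cond);
  LogicalVector converged(n_cond);
  IntegerVector iters(n_cond);

  std::vector<double> x(n_nodes), xn(n_nodes), agg(n_nodes);

  for (int c = 0; c < n_cond; ++c) {
    for (int i = 0; i < n_nodes; ++i) {
      double cl = clamp(i, c);
      x[i] = NumericMatrix::is_na(cl) ? 0.0 : cl;
    }
    bool ok = false;
    int it = 0;
    for (it = 1; it <= max_iter; ++it) {
      std::fill(agg.begin(), agg.end(), 0.0);
      for (int g = 0; g < w; ++g) {
        if (!gate_active[g]) continue;
        double v;
        bool first = true;
        double gv = 1.0;
        for (int s = gate_start[g]; s < gate_start[g] + gate_len[g]; ++s) {
          double xi = x[slot_input[s]];
          if (mode == 2) {
            double b = xi >= 0.5 ? 1.0 : 0.0;
            v = slot_sign[s] > 0 ? b : 1.0 - b;
          } else {
            v = edge_tf(xi, slot_type[s], slot_p1[s], slot_p2[s]);
            if (slot_sign[s] < 0) v = 1.0 - v;
          }
          if (mode == 1) {
            gv *= v;
          } else {
            gv = first ? v : std::min(gv, v);
          }
          first = false;
        }
        int out = gate_output[g];
        if (mode == 1) {
          agg[out] += gv;            // capped below
        } else {
          agg[out] = std::max(agg[out], gv);
        }
      }
      double dmax = 0.0;
      for (int i = 0; i < n_nodes; ++i) {
        double cl = clamp(i, c);
        if (!NumericMatrix::is_na(cl)) {
          xn[i] = cl;
        } else if (node_has_gate[i]) {
          double v = agg[i];
          if (mode == 1 && v > 1.0) v = 1.0;
          xn[i] = v;
        } else {
          xn[i] = 0.0;               // no basal activity
        }
        double d = std::fabs(xn[i] - x[i]);
        if (d > dmax) dmax = d;
      }
      std::swap(x, xn);
      if (dmax < tol) { ok = true; break; }
    }
    converged[c] = ok;
    iters[c] = std::min(it, max_iter);
    for (int i = 0; i < n_nodes; ++i) x_out(i, c) = x[i];
  }

  return List::create(_["x"] = x_out,
                      _["converged"] = converged,
                      _["iterations"] = iters);
}
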