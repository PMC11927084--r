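#include <Rcpp.h>
using namespace Rcpp;

// One sequential-update simulation of the threshold dynamics.
//
// adj_ptr/adj_idx: CSR adjacency (0-based), ignored when complete = true
// (every node is then adjacent to every other node and neighbourhood
// statistics come from the maintained group counters in O(1)).
// Node selection consumes exactly one unif_rand() per step so an R-side
// reference implementation can reproduce the run bit for bit.

static inline int pick_node(int n) {
  int v = (int)(n * unif_rand());
  if (v == n) v = n - 1;
  return v;
}

// net drive (numerator; compared against delta * degree)
static inline double drive_counts(double alpha, double beta, int in1,
                                  int in0, int out1, int out0) {
  return alpha * (double)(in1 - in0) - beta * (double)(out1 - out0);
}

// [[Rcpp::export]]
List abm_run_cpp(IntegerVector adj_ptr, IntegerVector adj_idx, bool complete,
                 IntegerVector group, IntegerVector h0, double alpha,
                 double beta, double delta, int max_steps, int record_every,
                 bool stop_on_absorption, int check_every) {
  const int n = group.size();
  std::vector<int> h(h0.begin(), h0.end());
  // group sizes and per-group choice-1 counts
  int ng[2] = {0, 0}, n1[2] = {0, 0};
  for (int v = 0; v < n; ++v) {
    ng[group[v]] += 1;
    n1[group[v]] += h[v];
  }
  const int nrec = max_steps / record_every + 1;
  NumericVector rec_tB(nrec), rec_tR(nrec);
  IntegerVector rec_step(nrec);
  int j = 0;
  rec_step[0] = 0;
  rec_tB[0] = ng[0] ? (double)n1[0] / ng[0] : NA_REAL;
  rec_tR[0] = ng[1] ? (double)n1[1] / ng[1] : NA_REAL;
  bool absorbed = false;
  int absorbed_step = NA_INTEGER;
  long flips = 0;

  for (int k = 1; k <= max_steps; ++k) {
    int v = pick_node(n);
    int deg = complete ? (n - 1) : (adj_ptr[v + 1] - adj_ptr[v]);
    if (deg > 0) {
      int g = group[v];
      int in1, in0, out1, out0;
      if (complete) {
        in1 = n1[g] - h[v];
        in0 = ng[g] - 1 - in1;
        out1 = n1[1 - g];
        out0 = ng[1 - g] - out1;
      } else {
        in1 = in0 = out1 = out0 = 0;
        for (int e = adj_ptr[v]; e < adj_ptr[v + 1]; ++e) {
          int u = adj_idx[e];
          if (group[u] == g) { if (h[u]) ++in1; else ++in0; }
          else { if (h[u]) ++out1; else ++out0; }
        }
      }
      double d = drive_counts(alpha, beta, in1, in0, out1, out0);
      double thr = delta * (double)deg;
      int hnew = h[v];
      if (d > thr) hnew = 1;
      else if (d < -thr) hnew = 0;
      if (hnew != h[v]) {
        n1[g] += hnew - h[v];
        h[v] = hnew;
        ++flips;
      }
    }
    if (k % record_every == 0 && j + 1 < nrec) {
      ++j;
      rec_step[j] = k;
      rec_tB[j] = ng[0] ? (double)n1[0] / ng[0] : NA_REAL;
      rec_tR[j] = ng[1] ? (double)n1[1] / ng[1] : NA_REAL;
    }
    if (stop_on_absorption && (k % check_every == 0)) {
      // full stability sweep: would any node change if selected?
      bool stable = true;
      if (complete) {
        for (int g = 0; g < 2 && stable; ++g) {
          for (int hv = 0; hv < 2 && stable; ++hv) {
            int cnt = hv ? n1[g] : ng[g] - n1[g];
            if (cnt == 0) continue;
            int in1 = n1[g] - hv, in0 = ng[g] - 1 - in1;
            int out1 = n1[1 - g], out0 = ng[1 - g] - out1;
            double d = drive_counts(alpha, beta, in1, in0, out1, out0);
            double thr = delta * (double)(n - 1);
            int hnew = hv;
            if (d > thr) hnew = 1;
            else if (d < -thr) hnew = 0;
            if (hnew != hv) stable = false;
          }
        }
      } else {
        for (int v2 = 0; v2 < n && stable; ++v2) {
          int deg2 = adj_ptr[v2 + 1] - adj_ptr[v2];
          if (deg2 == 0) continue;
          int g = group[v2];
          int in1 = 0, in0 = 0, out1 = 0, out0 = 0;
          for (int e = adj_ptr[v2]; e < adj_ptr[v2 + 1]; ++e) {
            int u = adj_idx[e];
            if (group[u] == g) { if (h[u]) ++in1; else ++in0; }
            else { if (h[u]) ++out1; else ++out0; }
          }
          double d = drive_counts(alpha, beta, in1, in0, out1, out0);
          double thr = delta * (double)deg2;
          int hnew = h[v2];
          if (d > thr) hnew = 1;
          else if (d < -thr) hnew = 0;
          if (hnew != h[v2]) stable = false;
        }
      }
      if (stable) {
        absorbed = true;
        absorbed_step = k;
        // the state can no longer change: fill the remaining records
        double tB = ng[0] ? (double)n1[0] / ng[0] : NA_REAL;
        double tR = ng[1] ? (double)n1[1] / ng[1] : NA_REAL;
        while (j + 1 < nrec) {
          ++j;
          rec_step[j] = rec_step[j - 1] + record_every;
          rec_tB[j] = tB;
          rec_tR[j] = tR;
        }
        break;
      }
    }
  }
  return List::create(_["step"] = rec_step, _["theta_B"] = rec_tB,
                      _["theta_R"] = rec_tR, _["n_recorded"] = j + 1,
                      _["absorbed"] = absorbed,
                      _["absorbed_step"] = absorbed_step,
                      _["choices"] = IntegerVector(h.begin(), h.end()),
                      _["n_flips"] = (double)flips);
}
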