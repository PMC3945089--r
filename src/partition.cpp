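#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Statistical-thermodynamics partition sums over non-overlapping binding
// configurations, computed by dynamic programming over sites in left-to-right
// order.  Pair interactions (self-cooperativity, short-range quenching) act
// between consecutively bound sites only, which keeps the DP exact.

namespace {

struct Par {
  NumericVector K, alpha, omega, beta;
  IntegerVector activ;          // 1 = activator, 0 = repressor
  double q_btm;
  int mode;                     // 0 = DIRECT, 1 = SRR
  int coop, srr;
};

Par unpack(const List& p) {
  Par P;
  P.K = p["K"]; P.alpha = p["alpha"]; P.omega = p["omega"]; P.beta = p["beta"];
  P.activ = p["activ"];
  P.q_btm = as<double>(p["q_btm"]);
  P.mode = as<int>(p["mode"]);
  P.coop = as<int>(p["coop_dist"]);
  P.srr = as<int>(p["srr_range"]);
  return P;
}

// DP over the given site subset (sorted by start, 0-based half-open coords).
// conc indexes by 0-based TF.  Returns E = Zon/(Zoff+Zon).  If zout is
// non-null, stores Zoff and Zon (valid only while no overflow rescale fires,
// i.e. for the small instances the raw sums are requested for).
double dp_expr(const std::vector<int>& ss, const std::vector<int>& se,
               const std::vector<int>& st, const std::vector<double>& sa,
               const double* conc, const Par& P, double* zout) {
  const int n = (int)ss.size();
  if (n == 0) {
    if (zout) { zout[0] = 1.0; zout[1] = P.q_btm; }
    return P.q_btm / (1.0 + P.q_btm);
  }
  int maxR = P.coop;
  if (P.mode == 1 && P.srr > maxR) maxR = P.srr;
  int Lmax = 0;
  for (int i = 0; i < n; ++i) Lmax = std::max(Lmax, se[i] - ss[i]);

  std::vector<double> A(n, 0.0), B(n, 0.0);
  double one = 1.0, farA = 0.0, farB = 0.0, totA = 0.0, totB = 0.0;
  int p = 0;  // sites with index < p are beyond interaction range of site i
  for (int i = 0; i < n; ++i) {
    while (p < i && ss[p] < ss[i] - (maxR + Lmax)) {
      farA += A[p]; farB += B[p]; ++p;
    }
    double q = P.K[st[i]] * conc[st[i]] * sa[i];
    if (q == 0.0) continue;  // absent TF: site never bound
    double sA = one + farA, sB = one + farB;
    for (int j = i - 1; j >= p; --j) {
      if (se[j] > ss[i]) continue;  // overlapping sites mutually exclusive
      int gap = ss[i] - se[j];
      double wf = 1.0, qf = 1.0;
      if (st[j] == st[i] && gap <= P.coop) wf = P.omega[st[i]];
      if (P.mode == 1 && gap <= P.srr && P.activ[st[i]] != P.activ[st[j]]) {
        int rep = P.activ[st[i]] ? st[j] : st[i];
        qf = 1.0 - P.beta[rep];
      }
      sA += wf * A[j];
      sB += wf * qf * B[j];
    }
    double af = (P.mode == 0) ? P.alpha[st[i]]
                              : (P.activ[st[i]] ? P.alpha[st[i]] : 1.0);
    A[i] = q * sA;
    B[i] = q * af * sB;
    totA += A[i]; totB += B[i];
    if (totA > 1e250 || totB > 1e250) {
      const double s = 1e-250;
      one *= s; farA *= s; farB *= s; totA *= s; totB *= s;
      for (int k = 0; k <= i; ++k) { A[k] *= s; B[k] *= s; }
    }
  }
  double Zoff = one + totA;
  double Zon = P.q_btm * (one + totB);
  if (zout) { zout[0] = Zoff; zout[1] = Zon; }
  return Zon / (Zoff + Zon);
}

}  // namespace

// Partition sums (Zoff, Zon) for one trans-context (concentration vector).
// [[Rcpp::export]]
NumericVector cpp_partition(IntegerVector start, IntegerVector end,
                            IntegerVector tf, NumericVector aff,
                            NumericVector conc, List par) {
  Par P = unpack(par);
  int n = start.size();
  std::vector<int> ss(n), se(n), st(n);
  std::vector<double> sa(n);
  for (int i = 0; i < n; ++i) {
    ss[i] = start[i]; se[i] = end[i]; st[i] = tf[i]; sa[i] = aff[i];
    if (i > 0 && ss[i] < ss[i - 1]) stop("sites must be sorted by start");
  }
  double z[2];
  dp_expr(ss, se, st, sa, REAL(conc), P, z);
  return NumericVector::create(z[0], z[1]);
}

// Expression readout E(x) for each window at each axis bin.
// conc is a (n_tf x n_bins) matrix; win_start/win_end are bp coordinates
// (0-based half-open); sites must be sorted by start.  A site belongs to a
// window iff it lies fully inside it.
// [[Rcpp::export]]
NumericMatrix cpp_window_readouts(IntegerVector start, IntegerVector end,
                                  IntegerVector tf, NumericVector aff,
                                  NumericMatrix conc, List par,
                                  IntegerVector win_start,
                                  IntegerVector win_end) {
  Par P = unpack(par);
  const int n = start.size(), nw = win_start.size(), nb = conc.ncol();
  const int ntf = conc.nrow();
  for (int i = 1; i < n; ++i)
    if (start[i] < start[i - 1]) stop("sites must be sorted by start");
  for (int i = 0; i < n; ++i)
    if (tf[i] < 0 || tf[i] >= ntf) stop("site TF index out of range");
  NumericMatrix out(nw, nb);
  std::vector<int> ss, se, st;
  std::vector<double> sa;
  for (int w = 0; w < nw; ++w) {
    int a = win_start[w], b = win_end[w];
    ss.clear(); se.clear(); st.clear(); sa.clear();
    // first site with start >= a
    int lo = (int)(std::lower_bound(start.begin(), start.end(), a) -
                   start.begin());
    for (int i = lo; i < n && start[i] < b; ++i) {
      if (end[i] <= b) {
        ss.push_back(start[i]); se.push_back(end[i]);
        st.push_back(tf[i]); sa.push_back(aff[i]);
      }
    }
    for (int x = 0; x < nb; ++x)
      out(w, x) = dp_expr(ss, se, st, sa, &conc(0, x), P, nullptr);
  }
  return out;
}
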