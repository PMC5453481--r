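#include <Rcpp.h>
using namespace Rcpp;

// Kahan-compensated accumulator; the W sums run over up to ~54k terms.
struct Kahan {
  double s = 0.0, c = 0.0;
  inline void add(double x) {
    double y = x - c;
    double t = s + y;
    c = (t - s) - y;
    s = t;
  }
};

// Within/between pair sums of a labeling over a precomputed similarity
// matrix.  Pairs are unordered and distinct (each counted once, no self
// pairs).
// [[Rcpp::export]]
List wf_components_cpp(const NumericMatrix& S, const IntegerVector& labels) {
  const int N = S.nrow();
  if (labels.size() != N) stop("labels/similarity size mismatch");
  Kahan within, between;
  double n_within = 0.0, n_between = 0.0;
  for (int i = 0; i < N - 1; ++i) {
    const int li = labels[i];
    for (int j = i + 1; j < N; ++j) {
      const double s = S(j, i);
      if (labels[j] == li) {
        within.add(s);
        n_within += 1.0;
      } else {
        between.add(s);
        n_between += 1.0;
      }
    }
  }
  return List::create(_["within_sum"] = within.s,
                      _["between_sum"] = between.s,
                      _["n_within"] = n_within,
                      _["n_between"] = n_between);
}

static inline double move_delta(const NumericMatrix& S,
                                const IntegerVector& labels,
                                const std::vector<int>& counts,
                                int i, int g, int h, double wS, double wD) {
  // W change when chip i moves from label g to label h (1-based labels)
  if (g == h) return 0.0;
  const int N = S.nrow();
  double sum_g = 0.0, sum_h = 0.0;
  for (int j = 0; j < N; ++j) {
    if (j == i) continue;
    const double s = S(j, i);
    if (labels[j] == g) sum_g += s;
    else if (labels[j] == h) sum_h += s;
  }
  const double cnt_g = counts[g - 1] - 1.0;  // co-members of i, excluding i
  const double cnt_h = counts[h - 1];
  return wS * (sum_h - sum_g) + wD * ((cnt_g - sum_g) - (cnt_h - sum_h));
}

// [[Rcpp::export]]
double delta_w_cpp(const NumericMatrix& S, const IntegerVector& labels,
                   int i0, int new_label, int k, double wS, double wD) {
  const int N = S.nrow();
  if (i0 < 0 || i0 >= N) stop("chip index out of range");
  if (new_label < 1 || new_label > k) stop("label out of range");
  std::vector<int> counts(k, 0);
  for (int j = 0; j < N; ++j) counts[labels[j] - 1]++;
  return move_delta(S, labels, counts, i0, labels[i0], new_label, wS, wD);
}

// One greedy sweep: visit chips in `order` (0-based), move each to the label
// with the greatest strictly positive W increase.  Returns the updated
// labels, the number of moves, and the total W gain of the sweep.
// [[Rcpp::export]]
List greedy_sweep_cpp(const NumericMatrix& S, const IntegerVector& labels_in,
                      int k, const IntegerVector& order,
                      double wS, double wD) {
  const int N = S.nrow();
  IntegerVector labels = clone(labels_in);
  std::vector<int> counts(k, 0);
  for (int j = 0; j < N; ++j) counts[labels[j] - 1]++;
  std::vector<double> sums(k);
  int moves = 0;
  double gain = 0.0;
  const double tol = 1e-12;
  for (int oi = 0; oi < order.size(); ++oi) {
    const int i = order[oi];
    const int g = labels[i];
    std::fill(sums.begin(), sums.end(), 0.0);
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      sums[labels[j] - 1] += S(j, i);
    }
    const double base_g = counts[g - 1] - 1.0 - sums[g - 1];
    int best_h = g;
    double best_delta = 0.0;
    for (int h = 1; h <= k; ++h) {
      if (h == g) continue;
      const double d = wS * (sums[h - 1] - sums[g - 1]) +
                       wD * (base_g - (counts[h - 1] - sums[h - 1]));
      if (d > best_delta + tol) {
        best_delta = d;
        best_h = h;
      }
    }
    if (best_h != g) {
      labels[i] = best_h;
      counts[g - 1]--;
      counts[best_h - 1]++;
      moves++;
      gain += best_delta;
    }
  }
  return List::create(_["labels"] = labels, _["moves"] = moves,
                      _["gain"] = gain);
}

// Assign each point to its nearest reference point (squared Euclidean,
// ties to the lowest index).  `centers` is k x 3, `coords` is N x 3.
// [[Rcpp::export]]
IntegerVector nearest_assign_cpp(const NumericMatrix& coords,
                                 const NumericMatrix& centers) {
  const int N = coords.nrow(), k = centers.nrow();
  IntegerVector out(N);
  for (int i = 0; i < N; ++i) {
    double best = R_PosInf;
    int arg = 1;
    for (int c = 0; c < k; ++c) {
      double d = 0.0;
      for (int m = 0; m < 3; ++m) {
        const double t = coords(i, m) - centers(c, m);
        d += t * t;
      }
      if (d < best) { best = d; arg = c + 1; }
    }
    out[i] = arg;
  }
  return out;
}

// Batch PSO fitness: each row of `par` encodes k centroids in the layout
// (L_1..L_k, a_1..a_k, b_1..b_k); fitness is W of the decoded partition.
// [[Rcpp::export]]
NumericVector pso_eval_batch_cpp(const NumericMatrix& coords,
                                 const NumericMatrix& S,
                                 const NumericMatrix& par, int k,
                                 double wS, double wD) {
  const int P = par.nrow(), N = coords.nrow();
  NumericVector out(P);
  NumericMatrix centers(k, 3);
  for (int p = 0; p < P; ++p) {
    for (int c = 0; c < k; ++c)
      for (int m = 0; m < 3; ++m)
        centers(c, m) = par(p, m * k + c);
    IntegerVector lab = nearest_assign_cpp(coords, centers);
    Kahan within, between;
    double n_between = 0.0;
    for (int i = 0; i < N - 1; ++i) {
      const int li = lab[i];
      for (int j = i + 1; j < N; ++j) {
        if (lab[j] == li) within.add(S(j, i));
        else { between.add(S(j, i)); n_between += 1.0; }
      }
    }
    out[p] = wS * within.s + wD * (n_between - between.s);
  }
  return out;
}

// W values of many labelings at once (columns of `labmat`); used for
// random-clustering ensembles and rotation scans.
// [[Rcpp::export]]
NumericVector w_batch_cpp(const NumericMatrix& S, const IntegerMatrix& labmat,
                          double wS, double wD) {
  const int N = S.nrow(), M = labmat.ncol();
  NumericVector out(M);
  for (int m = 0; m < M; ++m) {
    Kahan within, between;
    double n_between = 0.0;
    for (int i = 0; i < N - 1; ++i) {
      const int li = labmat(i, m);
      for (int j = i + 1; j < N; ++j) {
        if (labmat(j, m) == li) within.add(S(j, i));
        else { between.add(S(j, i)); n_between += 1.0; }
      }
    }
    out[m] = wS * within.s + wD * (n_between - between.s);
  }
  return out;
}
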